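#' Saccade detection parameters
#'
#' @param lambda Threshold multiplier applied to the robust (median-based)
#'   velocity noise estimate; default 6.
#' @param min_duration_ms Minimum duration of a suprathreshold run, in ms;
#'   default 6 (3 samples at 500 Hz).
#' @param overshoot_gap_ms Maximum offset-to-onset gap below which a
#'   following saccade is treated as a dynamic overshoot and merged into the
#'   preceding one; default 20.
#' @param refine_speed_cutoff Speed (deg/s) below which an
#'   acceleration-sign change qualifies as a refined saccade bound;
#'   default 20.
#' @param sigma_floor Velocity-noise floor (deg/s) used when the robust
#'   estimate degenerates to zero; default 0.1.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(lambda = 6, min_duration_ms = 6,
                             overshoot_gap_ms = 20, refine_speed_cutoff = 20,
                             sigma_floor = 0.1) {
  p <- list(lambda = lambda, min_duration_ms = min_duration_ms,
            overshoot_gap_ms = overshoot_gap_ms,
            refine_speed_cutoff = refine_speed_cutoff,
            sigma_floor = sigma_floor)
  if (any(vapply(p, function(v) !is.numeric(v) || v <= 0, TRUE)))
    stop("all detection parameters must be strictly positive")
  class(p) <- "detection_params"
  p
}

#' Compute a smoothed 2D velocity trace
#'
#' Velocity is estimated with the 5-point smoothed differentiator
#' `v[n] = (p[n+2] + p[n+1] - p[n-1] - p[n-2]) / (6 dt)` applied to each
#' component; the two endpoint samples on each side, and any sample whose
#' 5-point stencil touches an invalid sample, are marked invalid. Scalar
#' acceleration is the centered first difference of speed divided by `dt`.
#'
#' @param trace An `eye_trace`.
#' @return A list of class `velocity_trace` with `vx`, `vy`, `speed`,
#'   `accel`, `valid`, `rate` (same length as the trace).
#' @export
compute_velocity <- function(trace) {
  assert_eye_trace(trace)
  n <- length(trace$x)
  if (n < 5) stop("trace must have at least 5 samples")
  dt <- 1 / trace$rate
  x <- trace$x; y <- trace$y
  vx <- vy <- rep(NA_real_, n)
  i <- 3:(n - 2)
  vx[i] <- (x[i + 2] + x[i + 1] - x[i - 1] - x[i - 2]) / (6 * dt)
  vy[i] <- (y[i + 2] + y[i + 1] - y[i - 1] - y[i - 2]) / (6 * dt)
  # a velocity sample is valid only if its whole stencil is valid
  v_ok <- rep(FALSE, n)
  ok <- trace$valid
  v_ok[i] <- ok[i - 2] & ok[i - 1] & ok[i] & ok[i + 1] & ok[i + 2]
  vx[!v_ok] <- NA_real_
  vy[!v_ok] <- NA_real_
  speed <- sqrt(vx^2 + vy^2)
  accel <- rep(NA_real_, n)
  j <- 2:(n - 1)
  accel[j] <- (speed[j + 1] - speed[j - 1]) / (2 * dt)
  structure(list(vx = vx, vy = vy, speed = speed, accel = accel,
                 valid = v_ok, rate = trace$rate),
            class = "velocity_trace")
}

#' Adaptive component-wise velocity threshold
#'
#' The detection threshold adapts to the noise of each recording:
#' `eta_c = lambda * sigma_c` with
#' `sigma_c = sqrt(median(v_c^2) - median(v_c)^2)` computed over valid
#' velocity samples, for c in \{x, y\}. The median-based scale is robust to
#' the saccades themselves. A degenerate (zero) scale falls back to
#' `sigma_floor` with a warning.
#'
#' @param vel A `velocity_trace`.
#' @param params A `detection_params` list.
#' @return Named numeric vector `c(eta_x =, eta_y =)` in deg/s.
#' @export
adaptive_threshold <- function(vel, params = detection_params()) {
  ok <- vel$valid
  if (sum(ok) < 100)
    stop("need at least 100 valid velocity samples to estimate noise")
  eta <- vapply(list(vel$vx[ok], vel$vy[ok]), function(v) {
    s2 <- stats::median(v^2) - stats::median(v)^2
    s <- if (s2 > 0) sqrt(s2) else 0
    if (s <= 0) {
      warning("degenerate velocity noise estimate; using floor")
      s <- params$sigma_floor
    }
    params$lambda * s
  }, 0)
  c(eta_x = eta[1], eta_y = eta[2])
}

# saccade tables are plain data.frames with these columns
saccade_table <- function(onset_idx = integer(), offset_idx = integer(),
                          onset_t = numeric(), offset_t = numeric(),
                          x0 = numeric(), y0 = numeric(),
                          x1 = numeric(), y1 = numeric(),
                          peak_velocity = numeric(),
                          binocular = logical(0),
                          merged_overshoot = logical(0)) {
  d <- data.frame(onset_idx = as.integer(onset_idx),
                  offset_idx = as.integer(offset_idx),
                  onset_t = onset_t, offset_t = offset_t,
                  x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                  peak_velocity = peak_velocity,
                  binocular = if (length(binocular)) binocular
                              else rep(FALSE, length(onset_idx)),
                  merged_overshoot = if (length(merged_overshoot))
                    merged_overshoot else rep(FALSE, length(onset_idx)))
  recompute_geometry(d)
}

# magnitude, direction (deg in [0,360)), duration from endpoints
recompute_geometry <- function(sacc) {
  dx <- sacc$x1 - sacc$x0
  dy <- sacc$y1 - sacc$y0
  sacc$magnitude <- sqrt(dx^2 + dy^2)
  sacc$direction <- (atan2(dy, dx) * 180 / pi) %% 360
  sacc$duration <- sacc$offset_t - sacc$onset_t
  sacc
}

#' Refine saccade bounds with acceleration-sign criteria
#'
#' The onset is moved to the last sample before the peak-speed sample where
#' scalar acceleration changes sign from negative to positive and speed is
#' below `refine_speed_cutoff`; the offset to the first such sample after
#' the peak. If no qualifying sample exists on a side, the original
#' threshold-crossing bound is kept. Duration, endpoints and peak velocity
#' are recomputed from the refined bounds.
#'
#' @param trace The source `eye_trace`.
#' @param vel Its `velocity_trace`.
#' @param candidate A one-row saccade data.frame (threshold-crossing bounds).
#' @param params A `detection_params` list.
#' @return The refined one-row saccade data.frame.
#' @export
refine_bounds <- function(trace, vel, candidate, params = detection_params()) {
  on <- candidate$onset_idx
  off <- candidate$offset_idx
  seg <- on:off
  pk <- seg[which.max(vel$speed[seg])]
  n <- length(trace$x)
  cut <- params$refine_speed_cutoff
  # search window: up to 50 ms beyond each threshold bound
  w <- max(1L, as.integer(round(0.050 * trace$rate)))
  qualifies <- function(i) {
    isTRUE(vel$valid[i]) && isTRUE(vel$valid[i - 1]) &&
      is.finite(vel$accel[i]) && is.finite(vel$accel[i - 1]) &&
      vel$accel[i - 1] < 0 && vel$accel[i] >= 0 && vel$speed[i] < cut
  }
  new_on <- on
  lo <- max(2L, on - w)
  if (pk - 1 >= lo) for (i in (pk - 1):lo) if (qualifies(i)) { new_on <- i; break }
  new_off <- off
  hi <- min(n, off + w)
  if (pk + 1 <= hi) for (i in (pk + 1):hi) if (qualifies(i)) { new_off <- i; break }
  if (new_off <= new_on) { new_on <- on; new_off <- off }
  candidate$onset_idx <- new_on
  candidate$offset_idx <- new_off
  candidate$onset_t <- trace$time[new_on]
  candidate$offset_t <- trace$time[new_off]
  candidate$x0 <- trace$x[new_on]; candidate$y0 <- trace$y[new_on]
  candidate$x1 <- trace$x[new_off]; candidate$y1 <- trace$y[new_off]
  sp <- vel$speed[new_on:new_off]
  candidate$peak_velocity <- max(sp[is.finite(sp)], -Inf)
  recompute_geometry(candidate)
}

#' Detect saccades in 2D velocity space
#'
#' Candidate events are maximal runs of samples whose velocity lies outside
#' the adaptive threshold ellipse, `(vx/eta_x)^2 + (vy/eta_y)^2 > 1`,
#' lasting at least `min_duration_ms`. Each run's bounds are refined with
#' [refine_bounds()]; events touching invalid samples are discarded;
#' dynamic overshoots are merged with [merge_dynamic_overshoots()] (disable
#' with `merge_overshoots = FALSE`).
#'
#' @param trace An `eye_trace`.
#' @param params A `detection_params` list.
#' @param merge_overshoots Merge dynamic overshoots after detection
#'   (default `TRUE`).
#' @return A data.frame of saccades sorted by onset, with columns
#'   `onset_idx`, `offset_idx`, `onset_t`, `offset_t`, `x0`, `y0`, `x1`,
#'   `y1`, `peak_velocity`, `binocular`, `merged_overshoot`, `magnitude`,
#'   `direction`, `duration`. Sample intervals are half-open
#'   `[onset_idx, offset_idx)`.
#' @export
detect_saccades <- function(trace, params = detection_params(),
                            merge_overshoots = TRUE) {
  if (is_binocular(trace)) {
    l <- detect_saccades(trace$left, params, merge_overshoots)
    r <- detect_saccades(trace$right, params, merge_overshoots)
    return(binocular_filter(l, r))
  }
  vel <- compute_velocity(trace)
  eta <- adaptive_threshold(vel, params)
  crit <- (vel$vx / eta[1])^2 + (vel$vy / eta[2])^2
  above <- !is.na(crit) & crit > 1 & vel$valid
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths >= params$min_duration_ms / 1000 * trace$rate)
  out <- saccade_table()
  for (k in which(keep)) {
    cand <- saccade_table(onset_idx = starts[k], offset_idx = ends[k],
                          onset_t = trace$time[starts[k]],
                          offset_t = trace$time[ends[k]],
                          x0 = trace$x[starts[k]], y0 = trace$y[starts[k]],
                          x1 = trace$x[ends[k]], y1 = trace$y[ends[k]],
                          peak_velocity = max(vel$speed[starts[k]:ends[k]],
                                              na.rm = TRUE))
    cand <- refine_bounds(trace, vel, cand, params)
    # drop events that touch invalid position samples
    if (all(trace$valid[cand$onset_idx:cand$offset_idx]))
      out <- rbind(out, cand)
  }
  if (nrow(out)) {
    out <- out[order(out$onset_t), ]
    # refinement can make neighbouring runs collide; keep the first of any
    # overlapping pair
    if (nrow(out) > 1) {
      drop <- c(FALSE, out$onset_idx[-1] < out$offset_idx[-nrow(out)])
      out <- out[!drop, ]
    }
    if (merge_overshoots)
      out <- merge_dynamic_overshoots(out, params$overshoot_gap_ms)
    rownames(out) <- NULL
  }
  out
}

#' Merge dynamic overshoots into their parent saccades
#'
#' A saccade whose onset follows the previous saccade's offset by less than
#' `overshoot_gap_ms` is a dynamic overshoot: it is deleted and the previous
#' saccade's offset and end position are replaced by its own, with
#' magnitude and direction recomputed from the new endpoints. Merging
#' cascades left to right and is idempotent.
#'
#' @param saccades A saccade data.frame sorted by onset.
#' @param overshoot_gap_ms Gap threshold in ms (default 20), measured
#'   offset-of-first to onset-of-second.
#' @return The merged saccade data.frame; merged rows have
#'   `merged_overshoot = TRUE`.
#' @export
merge_dynamic_overshoots <- function(saccades, overshoot_gap_ms = 20) {
  if (nrow(saccades) < 2) return(saccades)
  if (is.unsorted(saccades$onset_t)) stop("saccades must be sorted by onset")
  gap_s <- overshoot_gap_ms / 1000
  keep <- list(saccades[1, ])
  for (i in 2:nrow(saccades)) {
    cur <- saccades[i, ]
    last <- keep[[length(keep)]]
    if (cur$onset_t - last$offset_t < gap_s) {
      last$offset_idx <- cur$offset_idx
      last$offset_t <- cur$offset_t
      last$x1 <- cur$x1; last$y1 <- cur$y1
      last$peak_velocity <- max(last$peak_velocity, cur$peak_velocity)
      last$merged_overshoot <- TRUE
      keep[[length(keep)]] <- recompute_geometry(last)
    } else {
      keep[[length(keep) + 1L]] <- cur
    }
  }
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  out
}

#' Keep only binocular saccades
#'
#' Returns the reference eye's saccades that overlap a saccade of the other
#' eye by at least one data sample (half-open index intervals). Matching is
#' one-to-one and greedy in time order, ties broken by earliest onset.
#'
#' @param left,right Saccade data.frames from each eye, sorted by onset.
#' @param reference Which eye's events to return (default `"left"`).
#' @return The reference eye's matched saccades with `binocular = TRUE`.
#' @export
binocular_filter <- function(left, right, reference = c("left", "right")) {
  reference <- match.arg(reference)
  ref <- if (reference == "left") left else right
  oth <- if (reference == "left") right else left
  if (!nrow(ref) || !nrow(oth)) return(ref[0, ])
  used <- rep(FALSE, nrow(oth))
  keep <- logical(nrow(ref))
  for (i in seq_len(nrow(ref))) {
    # >= 1 shared sample in [onset, offset)
    j <- which(!used & oth$onset_idx < ref$offset_idx[i] &
                 oth$offset_idx > ref$onset_idx[i])
    if (length(j)) {
      used[j[1]] <- TRUE
      keep[i] <- TRUE
    }
  }
  out <- ref[keep, ]
  if (nrow(out)) out$binocular <- TRUE
  rownames(out) <- NULL
  out
}
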