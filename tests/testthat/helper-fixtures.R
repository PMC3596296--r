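# Fixtures built in code: hand-made saccade rows and traces with injected
# minimum-jerk saccades, used as ground truth across the suite.

# one saccade row with the geometry fields consistent by construction
make_saccade <- function(onset_t, magnitude, direction_deg, duration = 0.02,
                         rate = 500, x0 = 0, y0 = 0, peak_velocity = NULL) {
  th <- direction_deg * pi / 180
  x1 <- x0 + magnitude * cos(th)
  y1 <- y0 + magnitude * sin(th)
  if (is.null(peak_velocity)) peak_velocity <- 1.875 * magnitude / duration
  data.frame(onset_idx = as.integer(round(onset_t * rate) + 1),
             offset_idx = as.integer(round((onset_t + duration) * rate) + 1),
             onset_t = onset_t, offset_t = onset_t + duration,
             x0 = x0, y0 = y0, x1 = x1, y1 = y1,
             peak_velocity = peak_velocity,
             binocular = FALSE, merged_overshoot = FALSE,
             magnitude = magnitude, direction = direction_deg %% 360,
             duration = duration)
}

# a chain of saccades at given onsets; each starts where the last ended
make_saccade_chain <- function(onsets, magnitudes, directions,
                               duration = 0.02, rate = 500) {
  out <- NULL
  x0 <- y0 <- 0
  for (i in seq_along(onsets)) {
    s <- make_saccade(onsets[i], magnitudes[i], directions[i],
                      duration, rate, x0, y0)
    x0 <- s$x1; y0 <- s$y1
    out <- rbind(out, s)
  }
  out
}

# minimum-jerk displacement fraction
mj <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

# flat noisy trace with injected minimum-jerk saccades; returns the trace
# plus the ground-truth event table
trace_with_saccades <- function(duration = 10, rate = 500, noise = 0.01,
                                onsets = numeric(), magnitudes = numeric(),
                                directions = numeric(), sacc_dur = 0.03,
                                seed = 1) {
  set.seed(seed)
  n <- duration * rate
  x <- rnorm(n, 0, noise)
  y <- rnorm(n, 0, noise)
  truth <- NULL
  for (i in seq_along(onsets)) {
    i0 <- round(onsets[i] * rate) + 1
    ns <- round(sacc_dur * rate)
    th <- directions[i] * pi / 180
    ramp <- c(rep(0, i0 - 1), mj(seq_len(ns) / ns),
              rep(1, max(0, n - i0 - ns + 1)))[seq_len(n)]
    x <- x + magnitudes[i] * cos(th) * ramp
    y <- y + magnitudes[i] * sin(th) * ramp
    truth <- rbind(truth, data.frame(onset_t = (i0 - 1) / rate,
                                     offset_t = (i0 - 1 + ns) / rate,
                                     magnitude = magnitudes[i],
                                     direction = directions[i]))
  }
  list(trace = eye_trace(x, y, rate), truth = truth)
}

# independent enumeration oracle for the SWJ conflict rule: repeatedly pick
# the highest-index (earliest on ties) candidate pair whose saccades are
# still free
swj_conflict_oracle <- function(cand) {
  chosen <- NULL
  free <- rep(TRUE, max(cand$second))
  repeat {
    ok <- cand[free[cand$first] & free[cand$second], , drop = FALSE]
    if (!nrow(ok)) break
    best <- ok[order(-ok$index, ok$first)[1], ]
    chosen <- rbind(chosen, best)
    free[c(best$first, best$second)] <- FALSE
  }
  if (is.null(chosen)) chosen else chosen[order(chosen$first), ]
}
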