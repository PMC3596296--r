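#' Saccade rate over valid fixation time
#'
#' @param saccades A saccade data.frame.
#' @param trace The `eye_trace` they were detected in; invalid spans are
#'   excluded from the denominator.
#' @return Saccades per second.
#' @export
saccade_rate <- function(saccades, trace) {
  dur <- valid_duration(if (is_binocular(trace)) trace$left else trace)
  if (dur <= 0) stop("trace has zero valid duration")
  nrow(saccades) / dur
}

#' Gaze position error relative to the trial median
#'
#' Absolute calibration is unreliable in eye trackers, so fixation error is
#' measured against the median gaze position of the trial (computed over
#' valid samples) rather than the tracker's zero: the error at a time point
#' is the Euclidean distance between gaze there and that median.
#'
#' @param trace An `eye_trace`.
#' @param at_time Time(s) in seconds at which to evaluate the error. Times
#'   falling in an invalid span use the nearest valid sample (with a
#'   warning).
#' @return Numeric vector of errors in degrees.
#' @export
position_error <- function(trace, at_time) {
  ok <- trace$valid
  if (!any(ok)) stop("no valid samples")
  mx <- stats::median(trace$x[ok])
  my <- stats::median(trace$y[ok])
  idx <- vapply(at_time, function(tt) {
    i <- which.min(abs(trace$time - tt))
    if (!ok[i]) {
      vi <- which(ok)
      i2 <- vi[which.min(abs(trace$time[vi] - tt))]
      warning("query time in an invalid span; using nearest valid sample")
      i2
    } else i
  }, 0L)
  sqrt((trace$x[idx] - mx)^2 + (trace$y[idx] - my)^2)
}

#' Main-sequence (peak velocity vs magnitude) linear fit
#'
#' The peak velocity-magnitude relationship is approximately linear for
#' small saccades; its slope indexes saccade speed and is compared across
#' subject groups.
#'
#' @param saccades A saccade data.frame with at least 3 rows.
#' @return List with `slope` ((deg/s)/deg), `intercept` (deg/s), `r`
#'   (Pearson correlation), `n`.
#' @export
main_sequence_fit <- function(saccades) {
  linear_fit(saccades$magnitude, saccades$peak_velocity)
}

#' Duration vs magnitude linear fit
#'
#' @param saccades A saccade data.frame with at least 3 rows.
#' @return List with `slope` (s/deg), `intercept` (s), `r`, `n`.
#' @export
duration_magnitude_fit <- function(saccades) {
  linear_fit(saccades$magnitude, saccades$duration)
}

linear_fit <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 saccades")
  if (stats::sd(x) == 0) stop("singular fit: all magnitudes identical")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(x, y), n = length(x))
}

#' Normalized vertical component of saccade directions
#'
#' Per saccade, the unitless ratio |vertical displacement| / magnitude
#' (0 = purely horizontal, 1 = purely vertical), averaged over saccades.
#' Uniformly distributed directions give 2/pi.
#'
#' @param saccades A saccade data.frame with at least one row of positive
#'   magnitude.
#' @return Mean normalized vertical component in \[0, 1\].
#' @export
vertical_component <- function(saccades) {
  keep <- saccades$magnitude > 0
  if (!any(keep)) stop("need at least one saccade with positive magnitude")
  mean(abs(saccades$y1[keep] - saccades$y0[keep]) / saccades$magnitude[keep])
}

#' SWJ coupling probability as a function of saccade magnitude
#'
#' Logistic regression of SWJ membership on saccade magnitude, fitted by
#' maximum likelihood, quantifying whether larger saccades are more likely
#' to trigger return saccades and thus form SWJs. Binned observed
#' proportions are returned for display curves; the fit uses unbinned data.
#'
#' @param saccades A saccade data.frame (>= 20 rows).
#' @param flags Logical SWJ-membership flags from [coupling_flags()].
#' @param bin_width Magnitude bin width in degrees for the display curve
#'   (default 0.25).
#' @return List of class `coupling_fit`: `beta0`, `beta1`, `p_value` (Wald
#'   test on `beta1`), `bin_curve` (data.frame `mid`, `prop`, `n`), `n`.
#' @export
coupling_vs_magnitude <- function(saccades, flags, bin_width = 0.25) {
  if (nrow(saccades) < 20) stop("need at least 20 saccades")
  if (length(unique(flags)) < 2)
    stop("degenerate fit: both SWJ and non-SWJ saccades required")
  m <- saccades$magnitude
  if (stats::sd(m) == 0) stop("degenerate fit: all magnitudes equal")
  fit <- stats::glm(flags ~ m, family = stats::binomial())
  s <- summary(fit)$coefficients
  bins <- floor(m / bin_width)
  bc <- do.call(rbind, lapply(split(seq_along(m), bins), function(i)
    data.frame(mid = (bins[i[1]] + 0.5) * bin_width,
               prop = mean(flags[i]), n = length(i))))
  rownames(bc) <- NULL
  structure(list(beta0 = unname(stats::coef(fit)[1]),
                 beta1 = unname(stats::coef(fit)[2]),
                 p_value = s["m", "Pr(>|z|)"],
                 bin_curve = bc[order(bc$mid), ],
                 n = length(m)),
            class = "coupling_fit")
}

#' Intra-SWJ interval summary
#'
#' The interval between the two saccades of an SWJ (offset of the first to
#' onset of the second) reflects the time needed to trigger the corrective
#' return saccade; under a common coupling mechanism it should be similar
#' across subject groups.
#'
#' @param swjs Output of [detect_swjs()].
#' @return List with `mean`, `sd`, `n` (seconds; `sd = 0` with `n <= 1`).
#' @export
intra_swj_intervals <- function(swjs) {
  n <- nrow(swjs)
  if (n == 0) return(list(mean = NA_real_, sd = NA_real_, n = 0L))
  list(mean = mean(swjs$interval),
       sd = if (n > 1) stats::sd(swjs$interval) else 0,
       n = n)
}

#' Position-error correction and latency structure of SWJs
#'
#' Two analyses of the error-correcting role of SWJ return saccades:
#' (i) paired comparison of the gaze position error at the end of the first
#' versus the second saccade of each SWJ (paired two-sided t-test) — return
#' saccades should reduce the error the first saccade introduced; and
#' (ii) linear regression (with Pearson correlation) of the inter-saccadic
#' interval to the next saccade on the position error at the end of each
#' saccade — larger errors should trigger the next saccade sooner, giving
#' a negative slope. The regression is computed twice: over every saccade
#' with a successor (`slope`, `r`, `reg_p`), and restricted to SWJ return
#' saccades (`ret_slope`, `ret_r`, `ret_p`), i.e. the return latency
#' against the error left by the first SWJ saccade, where the triggering
#' relation is expressed most directly.
#'
#' @param trace The `eye_trace`.
#' @param saccades Saccades detected in it.
#' @param swjs SWJs classified among them (>= 2 required).
#' @return List of class `error_latency_fit`: `err_first`, `err_second`
#'   (per-SWJ errors, deg), `t_stat`, `t_p`; `slope` (s/deg), `intercept`,
#'   `r`, `reg_p`, `n_pairs`; `ret_slope`, `ret_r`, `ret_p` for the
#'   SWJ-return restriction (NA with fewer than 3 SWJs).
#' @export
error_latency_analysis <- function(trace, saccades, swjs) {
  if (nrow(swjs) < 2) stop("need at least 2 SWJs")
  if (is_binocular(trace)) trace <- trace$left
  e1 <- position_error(trace, saccades$offset_t[swjs$first])
  e2 <- position_error(trace, saccades$offset_t[swjs$second])
  tt <- stats::t.test(e1, e2, paired = TRUE)
  # latency to the next saccade vs error at the end of each saccade,
  # computed for every saccade with a successor
  n <- nrow(saccades)
  err <- position_error(trace, saccades$offset_t[-n])
  lat <- saccades$onset_t[-1] - saccades$offset_t[-n]
  fit <- stats::lm(lat ~ err)
  ct <- stats::cor.test(err, lat)
  # return-saccade restriction: latency of the second SWJ saccade vs the
  # error after the first
  ret_slope <- ret_r <- ret_p <- NA_real_
  if (nrow(swjs) >= 3 && stats::sd(e1) > 0) {
    rct <- stats::cor.test(e1, swjs$interval)
    ret_slope <- unname(stats::coef(stats::lm(swjs$interval ~ e1))[2])
    ret_r <- unname(rct$estimate)
    ret_p <- rct$p.value
  }
  structure(list(err_first = e1, err_second = e2,
                 t_stat = unname(tt$statistic), t_p = tt$p.value,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = unname(ct$estimate), reg_p = ct$p.value,
                 n_pairs = n - 1L,
                 ret_slope = ret_slope, ret_r = ret_r, ret_p = ret_p),
            class = "error_latency_fit")
}

#' Run the full fixational-saccade pipeline on one recording
#'
#' Detection (with overshoot merging and, for binocular input, the
#' binocular overlap filter), SWJ classification, and the per-subject
#' metric vector used for group comparison: saccade rate, mean magnitude,
#' main-sequence slope and normalized vertical component. Deterministic
#' given the input and parameters.
#'
#' @param trace An `eye_trace` or `binocular_trace`.
#' @param det_params Detection parameters ([detection_params()]).
#' @param swj_pars SWJ parameters ([swj_params()]).
#' @return Object of class `subject_summary`: `rate`, `mean_magnitude`,
#'   `median_magnitude`, `ms_slope`, `ms_intercept`, `vertical_component`,
#'   `duration_slope`, `n_saccades`, `n_swjs`, `swj_interval_mean`,
#'   `subject`, `group`, plus the `saccades` and `swjs` tables.
#' @export
summarize_subject <- function(trace, det_params = detection_params(),
                              swj_pars = swj_params()) {
  base <- if (is_binocular(trace)) trace$left else trace
  if (!length(base$x)) stop("empty trace")
  sacc <- detect_saccades(trace, det_params)
  if (nrow(sacc) < 3)
    stop("too few saccades detected to summarize recording")
  swjs <- detect_swjs(sacc, swj_pars)
  ms <- main_sequence_fit(sacc)
  dm <- duration_magnitude_fit(sacc)
  structure(list(
    rate = saccade_rate(sacc, base),
    mean_magnitude = mean(sacc$magnitude),
    median_magnitude = stats::median(sacc$magnitude),
    ms_slope = ms$slope, ms_intercept = ms$intercept,
    vertical_component = vertical_component(sacc),
    duration_slope = dm$slope,
    n_saccades = nrow(sacc), n_swjs = nrow(swjs),
    swj_interval_mean = intra_swj_intervals(swjs)$mean,
    subject = base$meta$subject, group = base$meta$group,
    saccades = sacc, swjs = swjs
  ), class = "subject_summary")
}

#' @export
print.subject_summary <- function(x, ...) {
  cat("<subject_summary>",
      if (nzchar(x$subject)) sprintf(" %s (%s)", x$subject, x$group) else "",
      "\n", sep = "")
  cat(sprintf("  saccades: %d (%.2f /s), SWJs: %d\n",
              x$n_saccades, x$rate, x$n_swjs))
  cat(sprintf("  magnitude: mean %.2f deg (median %.2f)\n",
              x$mean_magnitude, x$median_magnitude))
  cat(sprintf("  main-sequence slope: %.1f (deg/s)/deg\n", x$ms_slope))
  cat(sprintf("  vertical component: %.2f\n", x$vertical_component))
  if (is.finite(x$swj_interval_mean))
    cat(sprintf("  mean intra-SWJ interval: %.0f ms\n",
                1000 * x$swj_interval_mean))
  invisible(x)
}
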