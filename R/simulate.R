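#' Configuration for the synthetic fixation-trace generator
#'
#' The generator composes (i) ocular drift, modelled as a mean-reverting
#' (Ornstein-Uhlenbeck) random walk around the fixation target, (ii)
#' fixational saccades at Poisson times with lognormal magnitudes,
#' horizontally biased directions and minimum-jerk waveforms whose peak
#' velocity follows the linear main sequence
#' `v_peak = ms_intercept + ms_slope * m`, (iii) SWJ structure: after each
#' primary saccade a corrective return saccade is triggered with
#' probability `plogis(coupling_beta0 + coupling_beta1 * m)`, at a latency
#' that decreases linearly with the post-saccadic position error, moving
#' the eye back toward its pre-saccade position with a Gaussian gain, and
#' (iv) white measurement noise. Every realized saccade is annotated with
#' its true parameters and SWJ membership.
#'
#' `saccade_rate` is the target rate of all saccades (primary + return);
#' the underlying primary-event rate is derived from it and the expected
#' coupling probability.
#'
#' @param duration Trace duration in seconds.
#' @param rate_hz Sampling rate (default 500).
#' @param noise_rms Measurement noise RMS per component, deg (default 0.01).
#' @param drift_diffusion Drift diffusion coefficient, deg^2/s
#'   (default 0.005).
#' @param drift_reversion Drift mean-reversion rate toward the target, 1/s
#'   (default 5).
#' @param saccade_rate Target overall saccade rate, events/s.
#' @param magnitude_mean Mean saccade magnitude, deg.
#' @param magnitude_sdlog Lognormal log-scale SD of magnitudes
#'   (default 0.45).
#' @param ms_slope,ms_intercept Main-sequence slope ((deg/s)/deg) and
#'   intercept (deg/s, default 10).
#' @param vertical_target Target mean normalized vertical component; the
#'   direction-concentration parameter kappa is calibrated numerically so
#'   the direction mixture realizes it.
#' @param direction_uniform_w Weight of the uniform component of the
#'   direction mixture (default 0.05); the rest is a pair of opposite
#'   horizontal von Mises lobes.
#' @param coupling_beta0,coupling_beta1 Logistic coefficients of return
#'   probability on magnitude (defaults -2, 2).
#' @param latency_base_ms,latency_slope_ms_per_deg,latency_floor_ms Return
#'   latency model `max(floor, base + slope * error)` in ms (defaults 250,
#'   -100, 80).
#' @param return_gain_mean,return_gain_sd Gaussian gain of the return
#'   saccade, fraction of the error corrected (defaults 0.9, 0.1).
#' @param binocular Generate a binocular pair (shared events, independent
#'   noise)? Default `FALSE`.
#' @param seed Integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(duration = 60, rate_hz = 500, noise_rms = 0.01,
                       drift_diffusion = 0.005, drift_reversion = 5,
                       saccade_rate = 1.1, magnitude_mean = 0.46,
                       magnitude_sdlog = 0.45,
                       ms_slope = 69, ms_intercept = 10,
                       vertical_target = 0.51, direction_uniform_w = 0.05,
                       coupling_beta0 = -2, coupling_beta1 = 2,
                       latency_base_ms = 250,
                       latency_slope_ms_per_deg = -100,
                       latency_floor_ms = 80,
                       return_gain_mean = 0.9, return_gain_sd = 0.1,
                       binocular = FALSE, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(duration > 0, rate_hz > 0, noise_rms > 0, drift_diffusion > 0,
            saccade_rate > 0, magnitude_mean > 0, magnitude_sdlog > 0,
            ms_slope > 0, latency_floor_ms > 0,
            return_gain_mean > 0, return_gain_mean <= 1.2,
            vertical_target > direction_uniform_w * 2 / pi,
            vertical_target < 2 / pi)
  cfg$direction_kappa <- calibrate_kappa(vertical_target, direction_uniform_w)
  class(cfg) <- "sim_config"
  cfg
}

#' Preset simulator configurations for subject groups
#'
#' Named presets whose generating saccade rate, mean magnitude,
#' main-sequence slope and expected normalized vertical component equal
#' the group averages observed with the analysis pipeline: healthy
#' controls (rate 1.1/s, magnitude 0.46 deg, slope 69, vertical 0.51),
#' Parkinson's disease (2.2/s, 0.62 deg, 71, 0.40) and progressive
#' supranuclear palsy (2.1/s, 1.38 deg, 43, 0.16 — frequent, large, slow,
#' strongly horizontal saccades). Other parameters take the documented
#' defaults.
#'
#' @param name One of `"control"`, `"pd"`, `"psp"`.
#' @param ... Overrides passed on to [sim_config()] (e.g. `duration`,
#'   `seed`).
#' @return A `sim_config`.
#' @export
sim_preset <- function(name = c("control", "pd", "psp"), ...) {
  name <- match.arg(name)
  p <- switch(name,
    control = list(saccade_rate = 1.1, magnitude_mean = 0.46,
                   ms_slope = 69, vertical_target = 0.51),
    pd      = list(saccade_rate = 2.2, magnitude_mean = 0.62,
                   ms_slope = 71, vertical_target = 0.40),
    psp     = list(saccade_rate = 2.1, magnitude_mean = 1.38,
                   ms_slope = 43, vertical_target = 0.16)
  )
  cfg <- do.call(sim_config, utils::modifyList(p, list(...)))
  cfg$preset <- name
  cfg
}

# expected |sin(theta)| of the direction mixture: uniform weight w plus
# opposite horizontal von Mises lobes of concentration kappa
expected_abs_sin <- function(kappa, w) {
  vm <- if (kappa < 1e-8) 2 / pi else
    (1 - exp(-2 * kappa)) /
      (pi * kappa * besselI(kappa, 0, expon.scaled = TRUE))
  w * 2 / pi + (1 - w) * vm
}

# solve expected_abs_sin(kappa, w) = target for kappa
calibrate_kappa <- function(target, w) {
  lo <- expected_abs_sin(700, w)
  if (target <= lo || target >= 2 / pi)
    stop("vertical_target outside the range realizable by the direction mixture")
  stats::uniroot(function(k) expected_abs_sin(k, w) - target,
                 c(1e-6, 700), tol = 1e-10)$root
}

# Best-Fisher von Mises sampler, mean 0, concentration kappa (radians)
rvonmises <- function(n, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c_ <- kappa * (r - f)
      if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  out
}

# minimum-jerk displacement fraction at normalized time tau in [0,1]
minjerk_s <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

# saccade duration implied by the main sequence for a minimum-jerk
# waveform: v_peak = 1.875 * m / D
saccade_duration <- function(m, cfg) 1.875 * m / (cfg$ms_intercept + cfg$ms_slope * m)

# expected return probability over the magnitude distribution
expected_coupling <- function(cfg) {
  mu <- log(cfg$magnitude_mean) - cfg$magnitude_sdlog^2 / 2
  stats::integrate(function(m)
    stats::plogis(cfg$coupling_beta0 + cfg$coupling_beta1 * m) *
      stats::dlnorm(m, mu, cfg$magnitude_sdlog), 0, Inf)$value
}

#' Simulate a fixation recording with ground-truth annotations
#'
#' Deterministic given `config$seed`: all random draws come from one seeded
#' generator, in a fixed order (primary-event gaps first, then per-event
#' magnitude, direction, coupling, gain and latency draws in time order,
#' then drift innovations and measurement noise).
#'
#' Primary saccades whose waveform would overlap a preceding event are
#' deferred until the eye is free again (events too close to the trace end
#' are dropped), so the realized event rate tracks the target closely. The direction of each primary
#' is drawn from the configured mixture and assigned the sign (of the two
#' opposite lobes) that moves gaze toward the target, which keeps the eye
#' in a bounded neighbourhood of the target without changing magnitude or
#' vertical-component statistics.
#'
#' @param config A `sim_config`.
#' @return A list of class `sim_output` with `trace` (an `eye_trace`, or
#'   `binocular_trace` if configured), `annotations` (data.frame:
#'   `onset_t`, `offset_t`, `kind` in \{saccade, swj_first, swj_second\},
#'   `magnitude`, `direction`, `peak_velocity`, `swj_id`) and `config`.
#' @export
simulate_trace <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  dt <- 1 / cfg$rate_hz
  n <- round(cfg$duration * cfg$rate_hz)
  margin <- 10L                       # samples kept event-free at each edge
  min_gap <- max(3L, round(0.050 / dt))  # min event separation, samples

  # --- primary event times (Poisson process via exponential gaps) ---
  p_rate <- cfg$saccade_rate / (1 + expected_coupling(cfg))
  gaps <- stats::rexp(ceiling(cfg$duration * p_rate * 2 + 20), p_rate)
  t_prim <- cumsum(gaps)
  t_prim <- t_prim[t_prim < cfg$duration - 0.1]

  mu_log <- log(cfg$magnitude_mean) - cfg$magnitude_sdlog^2 / 2

  # --- event-driven composition of the saccadic displacement signal ---
  disp_x <- numeric(n)   # per-sample increments, cumsum'd later
  disp_y <- numeric(n)
  pos <- c(0, 0)         # saccadic displacement component of gaze
  busy_until <- margin
  ann <- list()
  swj_id <- 0L

  place_saccade <- function(i_on, dx, dy, m) {
    D <- saccade_duration(m, cfg)
    ns <- ceiling(D / dt)
    frac <- minjerk_s((seq_len(ns) * dt) / D)
    inc <- diff(c(0, frac))
    idx <- i_on + seq_len(ns) - 1L
    disp_x[idx] <<- disp_x[idx] + dx * inc
    disp_y[idx] <<- disp_y[idx] + dy * inc
    pos <<- pos + c(dx, dy)
    busy_until <<- i_on + ns
    list(i_off = i_on + ns, v_peak = 1.875 * m / D)
  }

  for (tp in t_prim) {
    # events that would overlap a busy period are deferred past it
    i_on <- max(round(tp / dt) + 1L, busy_until + min_gap)
    m <- stats::rlnorm(1, mu_log, cfg$magnitude_sdlog)
    # direction: uniform component or horizontal von Mises lobe
    th <- if (stats::runif(1) < cfg$direction_uniform_w)
      stats::runif(1, -pi, pi) else rvonmises(1, cfg$direction_kappa)
    u_ret <- stats::runif(1)
    gain <- stats::rnorm(1, cfg$return_gain_mean, cfg$return_gain_sd)
    dvec <- m * c(cos(th), sin(th))
    # pick the lobe that keeps gaze near the target
    if (sum((pos + dvec)^2) > sum((pos - dvec)^2)) dvec <- -dvec
    p_pre <- pos
    if (i_on + ceiling(saccade_duration(m, cfg) / dt) > n - margin) next
    pl <- place_saccade(i_on, dvec[1], dvec[2], m)
    th_real <- (atan2(dvec[2], dvec[1]) * 180 / pi) %% 360
    ann[[length(ann) + 1L]] <- data.frame(
      onset_t = (i_on - 1) * dt, offset_t = (pl$i_off - 1) * dt,
      kind = "saccade", magnitude = m, direction = th_real,
      peak_velocity = pl$v_peak, swj_id = NA_integer_)
    # --- return saccade (SWJ coupling) ---
    if (u_ret < stats::plogis(cfg$coupling_beta0 + cfg$coupling_beta1 * m)) {
      err <- sqrt(sum(pos^2))   # position error after the primary
      lat_ms <- max(cfg$latency_floor_ms,
                    cfg$latency_base_ms + cfg$latency_slope_ms_per_deg * err)
      j_on <- pl$i_off + round(lat_ms / 1000 / dt)
      rvec <- gain * (p_pre - pos)
      m2 <- sqrt(sum(rvec^2))
      if (m2 > 0.02 && gain > 0 &&
          j_on + ceiling(saccade_duration(m2, cfg) / dt) <= n - margin) {
        pl2 <- place_saccade(j_on, rvec[1], rvec[2], m2)
        swj_id <- swj_id + 1L
        ann[[length(ann)]]$kind <- "swj_first"
        ann[[length(ann)]]$swj_id <- swj_id
        ann[[length(ann) + 1L]] <- data.frame(
          onset_t = (j_on - 1) * dt, offset_t = (pl2$i_off - 1) * dt,
          kind = "swj_second", magnitude = m2,
          direction = (atan2(rvec[2], rvec[1]) * 180 / pi) %% 360,
          peak_velocity = pl2$v_peak, swj_id = swj_id)
      }
    }
  }
  sx <- cumsum(disp_x)
  sy <- cumsum(disp_y)

  # --- ocular drift: OU walk around the target ---
  a <- exp(-cfg$drift_reversion * dt)
  s_inn <- sqrt(cfg$drift_diffusion * dt)
  drift_x <- as.numeric(stats::filter(stats::rnorm(n, 0, s_inn), a,
                                      method = "recursive"))
  drift_y <- as.numeric(stats::filter(stats::rnorm(n, 0, s_inn), a,
                                      method = "recursive"))

  make_eye <- function(eye) {
    eye_trace(sx + drift_x + stats::rnorm(n, 0, cfg$noise_rms),
              sy + drift_y + stats::rnorm(n, 0, cfg$noise_rms),
              cfg$rate_hz, eye = eye,
              subject = sprintf("sim-seed%d", cfg$seed),
              group = if (!is.null(cfg$preset)) cfg$preset else "sim")
  }
  trace <- if (isTRUE(cfg$binocular))
    binocular_trace(make_eye("left"), make_eye("right")) else make_eye("left")

  annotations <- if (length(ann)) do.call(rbind, ann) else
    data.frame(onset_t = numeric(), offset_t = numeric(),
               kind = character(), magnitude = numeric(),
               direction = numeric(), peak_velocity = numeric(),
               swj_id = integer())
  rownames(annotations) <- NULL
  structure(list(trace = trace, annotations = annotations, config = cfg),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("<sim_output> %s preset, %.0f s, %d annotated saccades (%d SWJs)\n",
              if (!is.null(x$config$preset)) x$config$preset else "custom",
              x$config$duration, nrow(x$annotations),
              sum(x$annotations$kind == "swj_first")))
  invisible(x)
}

# Table-derived between-subject SDs (SD = SEM * sqrt(N); N = 14/4/10)
preset_subject_sd <- function(name) {
  switch(name,
    control = c(rate = 0.2 * sqrt(14), magnitude = 0.04 * sqrt(14),
                slope = 2 * sqrt(14), vertical = 0.04 * sqrt(14)),
    pd      = c(rate = 0.3 * sqrt(4), magnitude = 0.3 * sqrt(4),
                slope = 4 * sqrt(4), vertical = 0.07 * sqrt(4)),
    psp     = c(rate = 0.2 * sqrt(10), magnitude = 0.22 * sqrt(10),
                slope = 4 * sqrt(10), vertical = 0.03 * sqrt(10))
  )
}

#' Simulate a cohort of subjects across group presets
#'
#' Per-subject generating parameters (rate, magnitude mean, main-sequence
#' slope, vertical component) are drawn around each preset's means with
#' between-subject spreads derived from the group-level standard errors
#' (SD = SEM * sqrt(N)), then each subject's trace is simulated. With
#' `traces = FALSE` only the generating parameter table is returned (for
#' group-statistics work that does not need the raw recordings).
#'
#' @param n_per_group Named integer vector of subjects per preset, default
#'   `c(psp = 10, pd = 4, control = 14)`.
#' @param duration Per-subject trace duration in seconds (default 60).
#' @param between_subject_sd Multiplier on the derived between-subject SDs
#'   (default 1; 0 makes every subject equal to the preset mean).
#' @param seed Integer seed for the whole cohort.
#' @param traces Simulate the traces (default `TRUE`)?
#' @return List with `subjects` (list of `sim_output`, `NULL` if
#'   `traces = FALSE`) and `parameters` (data.frame: `subject`, `group`,
#'   `rate`, `mean_magnitude`, `ms_slope`, `vertical_component`).
#' @export
simulate_cohort <- function(n_per_group = c(psp = 10, pd = 4, control = 14),
                            duration = 60, between_subject_sd = 1,
                            seed = 1, traces = TRUE) {
  set.seed(seed)
  rows <- list()
  for (g in names(n_per_group)) {
    base <- sim_preset(g)
    sd <- preset_subject_sd(g) * between_subject_sd
    for (k in seq_len(n_per_group[[g]])) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sprintf("%s-%02d", g, k), group = g,
        rate = max(0.3, stats::rnorm(1, base$saccade_rate, sd["rate"])),
        mean_magnitude = max(0.1, stats::rnorm(1, base$magnitude_mean,
                                               sd["magnitude"])),
        ms_slope = max(10, stats::rnorm(1, base$ms_slope, sd["slope"])),
        vertical_component = min(0.62, max(0.05,
          stats::rnorm(1, base$vertical_target, sd["vertical"]))))
    }
  }
  params <- do.call(rbind, rows)
  rownames(params) <- NULL
  subjects <- NULL
  if (traces) {
    seeds <- sample.int(2^30, nrow(params))
    subjects <- lapply(seq_len(nrow(params)), function(i) {
      out <- simulate_trace(sim_preset(
        params$group[i], duration = duration,
        saccade_rate = params$rate[i],
        magnitude_mean = params$mean_magnitude[i],
        ms_slope = params$ms_slope[i],
        vertical_target = params$vertical_component[i],
        seed = seeds[i]))
      out$trace$meta$subject <- params$subject[i]
      out$trace$meta$group <- params$group[i]
      out
    })
  }
  list(subjects = subjects, parameters = params)
}
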