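test_that("saccade rate uses valid fixation time as the denominator", {
  tr <- eye_trace(rnorm(5000, 0, 0.01), rnorm(5000, 0, 0.01), 500)
  sacc <- make_saccade_chain(seq(0.5, 9.5, by = 1), rep(0.5, 10), rep(0, 10))
  expect_equal(saccade_rate(sacc, tr), 1.0)
  tr$valid[1:1000] <- FALSE  # mask 2 s of the 10 s trace
  expect_equal(saccade_rate(sacc, tr), 10 / 8)
  expect_equal(saccade_rate(sacc[0, ], tr), 0)
  tr$valid[] <- FALSE
  expect_error(saccade_rate(sacc, tr), "zero valid")
})

test_that("position error is the distance to the median gaze and is shift-invariant", {
  set.seed(21)
  tr <- eye_trace(rnorm(2000, 0, 0.01), rnorm(2000, 0, 0.01), 500)
  # gaze at the median position -> ~0; a 1-deg offset point -> ~1
  tr$x[1000] <- median(tr$x) ; tr$y[1000] <- median(tr$y)
  expect_lt(position_error(tr, tr$time[1000]), 1e-4)
  tr$x[1500] <- median(tr$x) + 1; tr$y[1500] <- median(tr$y)
  expect_equal(position_error(tr, tr$time[1500]), 1, tolerance = 1e-4)
  # adding a constant offset to the whole trace changes nothing
  tr2 <- tr; tr2$x <- tr$x + 3; tr2$y <- tr$y - 5
  expect_equal(position_error(tr2, tr$time[c(1000, 1500)]),
               position_error(tr, tr$time[c(1000, 1500)]), tolerance = 1e-12)
  # invalid query time falls back to the nearest valid sample
  tr$valid[1500] <- FALSE
  expect_warning(position_error(tr, tr$time[1500]), "invalid span")
})

test_that("main-sequence and duration fits recover exact and noisy lines", {
  sacc <- make_saccade_chain(seq(1, 20, by = 1), runif(20, 0.2, 2), rep(0, 20))
  sacc$peak_velocity <- 69 * sacc$magnitude
  f <- main_sequence_fit(sacc)
  expect_equal(f$slope, 69, tolerance = 1e-9)
  expect_equal(f$r, 1, tolerance = 1e-9)
  # two points define the line exactly
  two <- make_saccade_chain(c(1, 2), c(1, 2), c(0, 0))
  two$peak_velocity <- c(50, 100)
  expect_error(main_sequence_fit(two), "at least 3")
  # noisy recovery: 200 saccades, slope 43, 10% velocity noise, 20 seeds
  slopes <- vapply(1:20, function(s) {
    set.seed(s)
    m <- runif(200, 0.2, 3)
    pv <- 43 * m * (1 + rnorm(200, 0, 0.1))
    sk <- make_saccade_chain(seq_len(200), m, rep(0, 200))
    sk$peak_velocity <- pv
    main_sequence_fit(sk)$slope
  }, 0)
  expect_lt(abs(median(slopes) - 43) / 43, 0.05)
  # duration line: 20 ms + 10 ms/deg exactly
  sacc$duration <- 0.02 + 0.010 * sacc$magnitude
  fd <- duration_magnitude_fit(sacc)
  expect_equal(fd$slope, 0.010, tolerance = 1e-9)
  same <- sacc; same$magnitude <- rep(1, 20)
  expect_error(main_sequence_fit(same), "singular")
})

test_that("vertical component handles pure axes and the uniform 2/pi law", {
  horiz <- make_saccade_chain(1:5, rep(1, 5), rep(0, 5))
  expect_equal(vertical_component(horiz), 0)
  vert <- make_saccade_chain(1:5, rep(1, 5), rep(90, 5))
  expect_equal(vertical_component(vert), 1)
  set.seed(8)
  unif <- make_saccade_chain(seq(1, 1e4), rep(1, 1e4), runif(1e4, 0, 360))
  expect_equal(vertical_component(unif), 2 / pi, tolerance = 0.02)
})

test_that("logistic coupling fit recovers generating coefficients and rejects nulls", {
  b1 <- vapply(1:20, function(s) {
    set.seed(s)
    m <- rlnorm(2000, log(0.8), 0.6)
    fl <- runif(2000) < plogis(-2 + 2 * m)
    sk <- make_saccade_chain(seq_len(2000) * 0.5, m, rep(0, 2000))
    coupling_vs_magnitude(sk, fl)$beta1
  }, 0)
  expect_true(all(b1 >= 1.5 & b1 <= 2.5))
  # flags independent of magnitude: beta1 CI covers 0 in >= 90% of seeds
  cover <- vapply(1:50, function(s) {
    set.seed(100 + s)
    m <- rlnorm(300, log(0.8), 0.6)
    fl <- runif(300) < 0.3
    sk <- make_saccade_chain(seq_len(300) * 0.5, m, rep(0, 300))
    fit <- coupling_vs_magnitude(sk, fl)
    fit$p_value > 0.05
  }, TRUE)
  expect_gte(mean(cover), 0.9)
  # degenerate inputs
  sk <- make_saccade_chain(1:30, rep(1, 30), rep(0, 30))
  expect_error(coupling_vs_magnitude(sk, rep(TRUE, 30)), "degenerate")
  sk2 <- make_saccade_chain(1:30, runif(30, 0.2, 2), rep(0, 30))
  expect_error(coupling_vs_magnitude(sk2[1:10, ], rep(c(TRUE, FALSE), 5)),
               "at least 20")
  # bin curve proportions are in [0, 1] and cover all saccades
  set.seed(2)
  m <- runif(100, 0.1, 2)
  fl <- runif(100) < plogis(-1 + m)
  sk3 <- make_saccade_chain(seq_len(100) * 0.4, m, rep(0, 100))
  cf <- coupling_vs_magnitude(sk3, fl)
  expect_true(all(cf$bin_curve$prop >= 0 & cf$bin_curve$prop <= 1))
  expect_equal(sum(cf$bin_curve$n), 100)
})

test_that("intra-SWJ interval summaries handle n = 1, Gaussian data, and n = 0", {
  one <- data.frame(first = 1, second = 2, index = 1, s_dir = 1, s_mag = 1,
                    s_time = 1, interval = 0.2)
  s <- intra_swj_intervals(one)
  expect_equal(s$mean, 0.2)
  expect_equal(s$sd, 0)
  expect_equal(s$n, 1)
  set.seed(4)
  many <- one[rep(1, 500), ]
  many$interval <- rnorm(500, 0.2, 0.03)
  expect_true(abs(intra_swj_intervals(many)$mean - 0.2) < 0.005)
  expect_equal(intra_swj_intervals(one[0, ])$n, 0)
})

test_that("error-latency analysis detects constructed effects and respects nulls", {
  # end-to-end: returns correct most of the error, latency decreases with it
  out <- simulate_trace(sim_preset("pd", duration = 90, seed = 15))
  sacc <- detect_saccades(out$trace)
  swjs <- detect_swjs(sacc)
  el <- error_latency_analysis(out$trace, sacc, swjs)
  expect_lt(mean(el$err_second), mean(el$err_first))
  expect_lt(el$t_p, 0.05)
  expect_lt(el$ret_slope, 0)
  expect_lt(el$ret_p, 0.05)
  expect_error(error_latency_analysis(out$trace, sacc, swjs[0, ]), "at least 2")
})

test_that("summarize_subject is deterministic and matches its parts", {
  out <- simulate_trace(sim_preset("control", duration = 60, seed = 31))
  s1 <- summarize_subject(out$trace)
  s2 <- summarize_subject(out$trace)
  expect_identical(s1[names(s1) != "saccades"], s2[names(s2) != "saccades"])
  expect_equal(s1$rate, saccade_rate(s1$saccades, out$trace))
  expect_equal(s1$ms_slope, main_sequence_fit(s1$saccades)$slope)
  expect_equal(s1$n_swjs, nrow(s1$swjs))
  expect_error(summarize_subject(eye_trace(numeric(), numeric(), 500)), "empty")
})

test_that("PSP saccades last longer than control saccades at matched magnitude", {
  # slow PSP saccades: the fitted duration-magnitude line predicts a longer
  # duration at any common magnitude (evaluated at 1 deg)
  s_psp <- summarize_subject(simulate_trace(sim_preset("psp", duration = 60,
                                                       seed = 5))$trace)
  s_ctl <- summarize_subject(simulate_trace(sim_preset("control", duration = 60,
                                                       seed = 5))$trace)
  d_psp <- duration_magnitude_fit(s_psp$saccades)
  d_ctl <- duration_magnitude_fit(s_ctl$saccades)
  expect_gt(d_psp$intercept + d_psp$slope * 1,
            d_ctl$intercept + d_ctl$slope * 1)
})
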