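test_that("smoothed velocity is exact on constant and linear-ramp inputs", {
  n <- 100
  t <- (0:(n - 1)) / 500
  # constant position -> zero velocity
  tr <- eye_trace(rep(1, n), rep(-2, n), 500)
  v <- compute_velocity(tr)
  expect_equal(v$vx[v$valid], rep(0, sum(v$valid)))
  expect_equal(v$vy[v$valid], rep(0, sum(v$valid)))
  # x = 10 t deg -> vx = 10 deg/s at interior samples
  v <- compute_velocity(eye_trace(10 * t, rep(0, n), 500))
  expect_equal(v$vx[v$valid], rep(10, sum(v$valid)), tolerance = 1e-10)
  # pure y ramp 5 deg/s -> speed 5, vx 0 (filter symmetry)
  v <- compute_velocity(eye_trace(rep(0, n), 5 * t, 500))
  expect_equal(v$speed[v$valid], rep(5, sum(v$valid)), tolerance = 1e-10)
  expect_equal(v$vx[v$valid], rep(0, sum(v$valid)))
  # endpoints and samples near invalid spans are themselves invalid
  tr <- eye_trace(10 * t, rep(0, n), 500)
  tr$valid[50] <- FALSE
  v <- compute_velocity(tr)
  expect_false(any(v$valid[48:52]))
  expect_false(any(v$valid[c(1, 2, n - 1, n)]))
  expect_error(compute_velocity(eye_trace(1:4, 1:4, 500)), "5 samples")
})

test_that("adaptive threshold matches the Gaussian median-scale law and is homogeneous", {
  set.seed(42)
  n <- 1e5
  # i.i.d. N(0, 1 deg/s) velocity: the median-based scale
  # sqrt(median(v^2) - median(v)^2) converges to sqrt(qchisq(0.5, 1)) for a
  # standard Gaussian, so eta -> lambda * 0.6745 (Monte-Carlo oracle)
  vel <- structure(list(vx = rnorm(n), vy = rnorm(n),
                        valid = rep(TRUE, n)), class = "velocity_trace")
  eta <- adaptive_threshold(vel, detection_params(lambda = 6))
  expect_equal(unname(eta[1]), 6 * sqrt(qchisq(0.5, 1)), tolerance = 0.03)
  expect_equal(unname(eta[2]), 6 * sqrt(qchisq(0.5, 1)), tolerance = 0.03)
  # homogeneity: doubling velocities doubles eta
  vel2 <- vel; vel2$vx <- 2 * vel$vx; vel2$vy <- 2 * vel$vy
  expect_equal(unname(adaptive_threshold(vel2)), 2 * unname(eta), tolerance = 1e-12)
  # degenerate all-zero velocity falls back to the floor
  velz <- structure(list(vx = rep(0, 200), vy = rep(0, 200),
                         valid = rep(TRUE, 200)), class = "velocity_trace")
  expect_warning(expect_warning(etaz <- adaptive_threshold(velz),
                                "degenerate"))
  expect_equal(unname(etaz), rep(6 * 0.1, 2))
})

test_that("a single injected saccade is recovered with accurate bounds and magnitude", {
  sim <- trace_with_saccades(duration = 4, onsets = 2, magnitudes = 1.0,
                             directions = 0, sacc_dur = 0.03, seed = 5)
  det <- detect_saccades(sim$trace)
  expect_equal(nrow(det), 1)
  expect_lte(abs(det$onset_t - sim$truth$onset_t), 0.004)
  expect_lte(abs(det$magnitude - 1.0), 0.05)
  expect_lt(min(det$direction, 360 - det$direction), 5)
})

test_that("50 injected saccades are recovered with no spurious detections", {
  onsets <- seq(0.5, 25, by = 0.5)[1:50]
  set.seed(9)
  mags <- runif(50, 0.2, 3)
  dirs <- runif(50, 0, 360)
  sim <- trace_with_saccades(duration = 26, onsets = onsets,
                             magnitudes = mags, directions = dirs, seed = 9)
  det <- detect_saccades(sim$trace)
  hits <- vapply(onsets, function(t0) any(abs(det$onset_t - t0) < 0.05), TRUE)
  expect_gte(sum(hits), 48)
  spurious <- vapply(det$onset_t, function(t0) all(abs(onsets - t0) > 0.05), TRUE)
  expect_equal(sum(spurious), 0)
})

test_that("noise-free constant trace yields no saccades", {
  tr <- eye_trace(rep(0, 2000) + rnorm(2000, 0, 1e-4),
                  rnorm(2000, 0, 1e-4), 500)
  expect_equal(nrow(detect_saccades(tr)), 0)
})

test_that("detection is rotation-invariant up to a 90-degree direction shift", {
  sim <- trace_with_saccades(duration = 8, onsets = c(2, 4, 6),
                             magnitudes = c(0.8, 1.5, 0.5),
                             directions = c(10, 200, 120), seed = 3)
  tr <- sim$trace
  rot <- eye_trace(-tr$y, tr$x, tr$rate)  # rotate +90 deg
  d1 <- detect_saccades(tr)
  d2 <- detect_saccades(rot)
  expect_equal(nrow(d1), nrow(d2))
  expect_equal(d2$magnitude, d1$magnitude, tolerance = 1e-6)
  expect_equal(d2$direction, (d1$direction + 90) %% 360, tolerance = 1e-6)
})

test_that("refine_bounds recovers the analytic duration and keeps fallbacks", {
  # clean minimum-jerk saccade: the 5-point velocity filter smears each
  # bound by up to 2 samples and the acceleration criterion adds one more,
  # so the refined duration can exceed the analytic one by a few samples
  # but never by more than 5, and never undershoot by more than 1
  sim <- trace_with_saccades(duration = 4, onsets = 2, magnitudes = 1,
                             directions = 0, sacc_dur = 0.04, noise = 1e-4,
                             seed = 2)
  det <- detect_saccades(sim$trace)
  expect_equal(nrow(det), 1)
  expect_gte(det$duration, 0.04 - 1 / 500)
  expect_lte(det$duration, 0.04 + 5 / 500 + 1e-9)
  # monotone speed with no qualifying crossing: original bounds kept
  n <- 3000
  tr <- eye_trace(cumsum(seq(0, 1, length.out = n))/100, rep(0, n), 500)
  vel <- compute_velocity(tr)
  cand <- make_saccade(2, 0.5, 0, duration = 0.02)
  ref <- refine_bounds(tr, vel, cand)
  expect_equal(ref$onset_idx, cand$onset_idx)
})

test_that("dynamic overshoots merge under 20 ms and survive above it", {
  # 15 ms gap -> merged into one saccade ending at the second's end point
  pair15 <- make_saccade_chain(c(1, 1 + 0.02 + 0.015), c(1, 0.2), c(0, 180))
  m <- merge_dynamic_overshoots(pair15, 20)
  expect_equal(nrow(m), 1)
  expect_equal(m$x1, pair15$x1[2])
  expect_true(m$merged_overshoot)
  expect_equal(m$magnitude, 0.8, tolerance = 1e-12)  # 1.0 right, 0.2 back
  # 25 ms gap -> both kept
  pair25 <- make_saccade_chain(c(1, 1 + 0.02 + 0.025), c(1, 0.2), c(0, 180))
  expect_equal(nrow(merge_dynamic_overshoots(pair25, 20)), 2)
  # cascade: three events 10 ms apart collapse to one; idempotent
  tri <- make_saccade_chain(c(1, 1.03, 1.06), c(1, 0.2, 0.1), c(0, 180, 0))
  m1 <- merge_dynamic_overshoots(tri, 20)
  expect_equal(nrow(m1), 1)
  expect_equal(merge_dynamic_overshoots(m1, 20), m1)
  expect_error(merge_dynamic_overshoots(tri[c(2, 1, 3), ], 20), "sorted")
})

test_that("binocular filter applies the one-sample overlap rule", {
  l <- make_saccade(0.2, 1, 0)   # indices [101, 111)
  l$onset_idx <- 100L; l$offset_idx <- 120L
  r1 <- l; r1$onset_idx <- 120L; r1$offset_idx <- 140L  # zero shared samples
  expect_equal(nrow(binocular_filter(l, r1)), 0)
  r2 <- l; r2$onset_idx <- 119L; r2$offset_idx <- 140L  # one shared sample
  kept <- binocular_filter(l, r2)
  expect_equal(nrow(kept), 1)
  expect_true(kept$binocular)
  # identical events in both eyes are kept
  expect_equal(nrow(binocular_filter(l, l)), 1)
  # one-to-one: two left events cannot both claim a single right event
  l2 <- rbind(l, within(l, { onset_idx <- 115L; offset_idx <- 130L }))
  expect_equal(nrow(binocular_filter(l2, l)), 1)
})

test_that("false positives on pure instrument noise are rare", {
  fp <- vapply(1:5, function(s) {
    set.seed(300 + s)
    tr <- eye_trace(rnorm(15000, 0, 0.01), rnorm(15000, 0, 0.01), 500)
    nrow(detect_saccades(tr)) / 30
  }, 0)
  expect_lt(mean(fp), 0.2)
})
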