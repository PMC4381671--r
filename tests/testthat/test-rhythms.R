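test_that("detect_rhythm finds a clean 22 h cosine and rejects constants", {
  t <- tiny_times
  y <- cosine_series(A = log(3) / 2)       # fold amplitude 3, noiseless
  d <- detect_rhythm(y, t)
  expect_lt(d$p_value, 1e-6)
  expect_equal(d$period, 22, tolerance = 0.5 / 22)
  # constant series: p = 1, period undefined
  d0 <- detect_rhythm(rep(7, 12), t)
  expect_equal(d0$p_value, 1)
  expect_true(is.na(d0$period))
  # contract checks
  expect_error(detect_rhythm(1:6, (0:5) * 2), "8 time points")
  expect_error(detect_rhythm(1:12, rev(seq_len(12))), "increasing")
})

test_that("null p-values are calibrated despite the period scan", {
  # 600 arrhythmic NB genes (the acceptance suite runs the full 2000)
  mu <- 100; v <- mu + 0.05 * mu^2
  Y <- with(list(), {
    set.seed(1204)
    matrix(rnbinom(600 * 12, mu = mu, size = mu^2 / (v - mu)), ncol = 12)
  })
  d <- detect_rhythm_matrix(Y, tiny_times, refine = FALSE)
  expect_lt(mean(d$p_value < 0.05), 0.10)
  expect_gt(stats::ks.test(d$p_value, "punif")$p.value, 0.01)
  # the raw scan p is anti-conservative relative to the calibrated one
  expect_gt(mean(d$p_raw < 0.05), mean(d$p_value < 0.05))
})

test_that("dual run rescues light-spiked rhythms and takes the smaller p", {
  t <- tiny_times
  y <- cosine_series(A = log(3) / 2, phase = 8)
  y_spiked <- y; y_spiked[1] <- y_spiked[1] * 6
  d <- detect_rhythm_dual(y_spiked, t)
  expect_gte(d$p_with_t0, d$p_without_t0)
  expect_identical(d$run, "without_t0")
  expect_true(d$rhythmic)
  # unspiked series: reported p is the minimum of the two runs
  d2 <- detect_rhythm_dual(y, t)
  expect_equal(d2$p_value, min(d2$p_with_t0, d2$p_without_t0))
  expect_error(detect_rhythm_dual(y, t + 2), "include 0")
})

test_that("arrhythmic spiked genes are mostly not called rhythmic", {
  # 300 seeded replicates of a flat NB gene with a 4x t=0 spike
  set.seed(77)
  mu <- rep(200, 12); mu[1] <- 800
  v <- mu + 0.05 * mu^2
  Y <- matrix(rnbinom(300 * 12, mu = rep(mu, each = 300),
                      size = rep(mu^2 / (v - mu), each = 300)), nrow = 300)
  d <- detect_rhythm_dual_matrix(Y, tiny_times, refine = FALSE)
  # the spike costs specificity in the with-t0 run (a t=0 peak resembles a
  # dawn-phased cosine), so the min-p rule calls ~20% of these genes;
  # most are still rejected, and far more than the spike-free dual null
  expect_gt(mean(!d$rhythmic), 0.70)
  # the rescue direction dominates: the without-t0 run alone stays ~5%
  d_wo <- detect_rhythm_matrix(Y[, -1], tiny_times[-1], refine = FALSE)
  expect_lt(mean(d_wo$p_value < 0.05), 0.10)
})

test_that("fit_sine_nb inverts the generative model", {
  t <- tiny_times
  y <- round(exp(5 + 0.55 * cos(2 * pi / 22 * (t - 6))))
  f <- fit_sine_nb(y, t)
  expect_true(f$converged)
  expect_equal(f$phase, 6, tolerance = 0.2 / 6)
  expect_equal(f$fold_amplitude, exp(1.1), tolerance = 0.05)
  expect_equal(f$mean_level, exp(5), tolerance = 0.05)
  # constant series: amplitude 1, phase missing
  f0 <- fit_sine_nb(rep(50, 12), t)
  expect_equal(f0$fold_amplitude, 1, tolerance = 1e-6)
  expect_true(is.na(f0$phase))
  # peak at t = 0: phase wraps to ~0 (== 22)
  fp <- fit_sine_nb(round(exp(5 + 0.5 * cos(2 * pi / 22 * t))), t)
  expect_lt(min(fp$phase, 22 - fp$phase), 0.2)
})

test_that("phase and amplitude are equivariant/invariant as expected", {
  t <- tiny_times
  base_phase <- 5
  f1 <- fit_sine_nb(cosine_series(A = 0.5, phase = base_phase), t)
  # generating with phase + 4 shifts the fit by 4 (mod period)
  f2 <- fit_sine_nb(cosine_series(A = 0.5, phase = base_phase + 4), t)
  expect_equal(phase_difference(f2$phase, f1$phase + 4, 22), 0,
               tolerance = 0.1)
  expect_equal(f2$fold_amplitude, f1$fold_amplitude, tolerance = 0.02)
  # scaling the series leaves phase and fold amplitude invariant (log link)
  y <- cosine_series(A = 0.5, phase = base_phase)
  f3 <- fit_sine_nb(y * 8, t)
  expect_equal(f3$phase, f1$phase, tolerance = 0.05)
  expect_equal(f3$fold_amplitude, f1$fold_amplitude, tolerance = 0.02)
  # detection p-value is invariant under time relabeling by full periods
  d1 <- detect_rhythm(y, t)
  d2 <- detect_rhythm(y, t + 44)
  expect_equal(d1$p_value, d2$p_value, tolerance = 1e-9)
})

test_that("NB sine fit agrees with weighted LS on log counts for Poisson data", {
  t <- tiny_times
  set.seed(5)
  for (ph in c(2, 9, 17)) {
    mu <- 400 * exp(0.4 * cos(2 * pi / 22 * (t - ph)))
    y <- rpois(12, mu)
    f <- fit_sine_nb(y, t, variance_model = function(m) m)
    w <- 2 * pi / 22
    X <- cbind(1, cos(w * t), sin(w * t))
    b <- unname(stats::lm(log(y) ~ X - 1, weights = y)$coefficients)
    A_ls <- sqrt(b[2]^2 + b[3]^2)
    expect_equal(f$fold_amplitude, exp(2 * A_ls), tolerance = 0.02)
    expect_equal(phase_difference(f$phase, (atan2(b[3], b[2]) / w) %% 22),
                 0, tolerance = 0.15)
  }
})

test_that("detector power rises with true amplitude", {
  set.seed(31)
  t <- tiny_times
  folds <- c(1.3, 2, 3.5)
  power <- vapply(folds, function(F) {
    A <- log(F) / 2
    mu <- sapply(runif(120, 0, 22), function(ph)
      300 * exp(A * cos(2 * pi / 22 * (t - ph))))
    v <- mu + 0.05 * mu^2
    Y <- t(matrix(rnbinom(length(mu), mu = c(mu),
                          size = c(mu^2 / (v - mu))), nrow = 12))
    mean(detect_rhythm_matrix(Y, t, refine = FALSE)$p_value < 0.05)
  }, numeric(1))
  expect_true(all(diff(power) > 0))
  expect_gt(power[3], 0.9)
})

test_that("phase classification bins and circular distance behave", {
  expect_equal(classify_phase(c(23, 12, 6, 21, 3.9, 4, 8, 16)),
               c("dawn", "dusk", "other", "dawn", "dawn", "other",
                 "dusk", "other"))
  expect_true(is.na(classify_phase(NA_real_)))
  expect_equal(phase_difference(21, 1, 22), 2)
  expect_equal(phase_difference(0, 11, 22), 11)
  expect_equal(phase_difference(5, 5, 22), 0)
})
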