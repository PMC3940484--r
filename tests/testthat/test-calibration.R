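# Two-part calibration: single-line and segmented fits, change-point
# selection, bootstrap model comparison and the correction map.

test_that("single-line fit recovers an exact line with zero CV error", {
  x <- 0:4
  p <- calibration_pairs(letters[1:5], 2 * x + 1, x)
  fit <- fit_single_line(p)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$cv_rmse, 0)
})

test_that("single-line LOOCV matches the pencil-and-paper hold-out fits", {
  # points (0,0), (1,1), (2,4): OLS slope 2, intercept -1/3.
  # Holding out each point, the line through the remaining two predicts
  # -2, 2 and 2, giving hold-out residuals 2, -1, 2 and
  # cv_rmse = sqrt((4 + 1 + 4)/3) = sqrt(3).
  p <- calibration_pairs(c("a", "b", "c"), c(0, 1, 4), c(0, 1, 2))
  fit <- fit_single_line(p)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, -1 / 3)
  expect_equal(fit$cv_rmse, sqrt(3))
})

test_that("single-line fit rejects degenerate input", {
  expect_error(fit_single_line(calibration_pairs("a", 1, 1)), "3")
  expect_error(
    fit_single_line(calibration_pairs(letters[1:4], 1:4, rep(2, 4))),
    "variance")
})

test_that("segmented fit of collinear data recovers the line exactly", {
  x <- seq(1, 5, length.out = 20)
  p <- calibration_pairs(sprintf("g%d", 1:20), 0.8 * x + 0.3, x)
  m <- fit_segmented(p)
  expect_equal(m$lower_slope, 0.8, tolerance = 1e-8)
  expect_equal(m$upper_slope, 0.8, tolerance = 1e-8)
  expect_equal(m$lower_intercept, 0.3, tolerance = 1e-8)
  expect_equal(m$upper_intercept, 0.3, tolerance = 1e-8)
  expect_lt(m$cv_rmse, 1e-10)
})

test_that("noise-free two-part data refits the generating model exactly", {
  truth <- reference_two_part()
  p <- generate_calibration_set(truth, n = 200, noise_sd = 0, seed = 3)
  m <- fit_segmented(p)
  expect_equal(m$lower_slope, 0.56, tolerance = 1e-6)
  expect_equal(m$lower_intercept, 2.64, tolerance = 1e-6)
  expect_equal(m$upper_slope, 1.06, tolerance = 1e-6)
  expect_equal(m$upper_intercept, -0.41, tolerance = 1e-6)
  expect_lt(abs(m$changepoint_log10 - 6), 0.15)
  # refitting corrected pairs against the reference gives the identity
  corrected <- apply_correction(m, p$survey_log10)
  refit <- fit_single_line(calibration_pairs(p$gene_id, p$reference_log10,
                                             corrected))
  expect_equal(refit$slope, 1, tolerance = 0.05)
  expect_equal(refit$intercept, 0, tolerance = 0.05)
})

test_that("change-point recovery under noise agrees with a brute-force
           leave-one-out oracle", {
  truth <- reference_two_part()
  p <- generate_calibration_set(truth, n = 200, noise_sd = 0.2, seed = 7)
  m <- fit_segmented(p)
  expect_lt(abs(m$changepoint_log10 - 6), 0.25)
  # selected CV RMSE is minimal over the whole candidate curve
  expect_true(all(m$cv_rmse <= attr(m, "grid_cv_rmse") + 1e-12))

  # independent oracle on a subset: explicit lm() refits per held-out
  # point for every candidate, no PRESS shortcut
  sub <- p[seq(1, 200, by = 5), ]
  grid <- seq(4, 7, by = 0.25)
  oracle_cv <- vapply(grid, function(cp) {
    x <- sub$survey_log10; y <- sub$reference_log10
    if (sum(x < cp) < 3 || sum(x >= cp) < 3) return(Inf)
    press <- vapply(seq_along(x), function(i) {
      xs <- x[-i]; ys <- y[-i]
      side <- if (x[i] < cp) xs < cp else xs >= cp
      if (sum(side) < 2) return(Inf)
      fit <- lm(ys[side] ~ xs[side])
      y[i] - (coef(fit)[1] + coef(fit)[2] * x[i])
    }, numeric(1))
    sqrt(mean(press^2))
  }, numeric(1))
  m_sub <- fit_segmented(sub, changepoint_grid = grid)
  expect_equal(attr(m_sub, "grid_cv_rmse"), oracle_cv, tolerance = 1e-8)
  expect_equal(m_sub$changepoint_log10, grid[which.min(oracle_cv)])
})

test_that("segmented fit rejects inadmissible candidate sets", {
  p <- calibration_pairs(letters[1:6], 1:6, c(1, 1, 1, 1, 1, 1))
  expect_error(fit_segmented(p), "admissible")
})

test_that("correction maps survey values through the containing segment", {
  m <- reference_two_part()
  # identity model passes values through unchanged
  id <- segmented_model(5, 1, 0, 1, 0)
  v <- c(2.2, 5, 7.9)
  expect_equal(apply_correction(id, v), v)
  # hand arithmetic on the reference model: 0.56*4 + 2.64 = 4.88
  expect_equal(apply_correction(m, 4), 4.88)
  # the change point itself belongs to the upper segment
  expect_equal(apply_correction(m, 6), 1.06 * 6 - 0.41)
  # monotone within segments, extrapolation not clamped
  s <- sort(runif(50, 0, 10))
  cor_lo <- apply_correction(m, s[s < 6])
  cor_up <- apply_correction(m, s[s >= 6])
  expect_true(all(diff(cor_lo) > 0))
  expect_true(all(diff(cor_up) > 0))
  # predict() is an alias
  expect_equal(predict(m, v), apply_correction(m, v))
})

test_that("invert_correction is the right inverse of apply_correction", {
  m <- reference_two_part()
  y <- c(3.5, 4.9, 5.8, 6.4, 8.1)
  expect_equal(apply_correction(m, invert_correction(m, y)), y,
               tolerance = 1e-10)
})

test_that("bias ratio profile is flat at one for unbiased pairs and
           reproduces hand-computed fold ratios", {
  x <- seq(3, 8, length.out = 40)
  flat <- bias_ratio_profile(calibration_pairs(seq_along(x), x, x))
  expect_equal(flat$pairs$ratio, rep(1, 40))
  expect_equal(flat$smooth$ratio, rep(1, 40), tolerance = 1e-12)

  # pairs generated by the reference model: ratio at survey 1e4 is
  # 10^4.88 / 10^4 = 10^0.88
  m <- reference_two_part()
  p <- generate_calibration_set(m, n = 50, noise_sd = 0, seed = 2)
  prof <- bias_ratio_profile(p)
  i4 <- which.min(abs(p$survey_log10 - 4))
  expect_equal(log10(prof$pairs$ratio[i4]),
               apply_correction(m, p$survey_log10[i4]) - p$survey_log10[i4],
               tolerance = 1e-12)
  expect_equal(apply_correction(m, 4) - 4, 0.88)
  # after correction the profile collapses to ratio one
  corrected <- bias_ratio_profile(p, model = m)
  expect_equal(corrected$pairs$ratio, rep(1, 50), tolerance = 1e-10)
  expect_error(bias_ratio_profile(p[1:3, ]), "5")
})

test_that("bootstrap LRT is reproducible, rejects under a real change
           point and keeps its level under the null", {
  truth <- reference_two_part()
  p <- generate_calibration_set(truth, n = 61, noise_sd = 0.2, seed = 7)
  a <- bootstrap_lrt(p, n_boot = 199, seed = 11)
  b <- bootstrap_lrt(p, n_boot = 199, seed = 11)
  expect_identical(a$p_value, b$p_value)
  expect_lte(a$p_value, 0.01)
  expect_error(bootstrap_lrt(p, n_boot = 50), "99")

  # under a single line, large p-values dominate: >= 90% of repetitions
  # should fail to reject at the 5% level
  n_rep <- 100
  set.seed(42)
  keep <- vapply(seq_len(n_rep), function(i) {
    x <- runif(40, 3, 8)
    y <- 1.1 * x + 0.5 + rnorm(40, 0, 0.25)
    bootstrap_lrt(calibration_pairs(seq_along(x), y, x),
                  n_boot = 99)$p_value > 0.05
  }, logical(1))
  expect_gte(mean(keep), 0.90)
})

test_that("two-part model beats the single line on the gold protein
           pairs of a compressed survey", {
  b <- default_bundle()
  m <- fit_segmented(b$calibration)
  expect_lt(m$cv_rmse, m$single_cv_rmse)
})
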