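test_that("iron relaxivity fit recovers exact linear data and flags df=0", {
  conc <- seq(0, 1, length.out = 6)
  fit <- iron_relaxivity_fit(conc, 5 * conc + 2, kind = "iron_r1")
  expect_equal(fit$slope, 5)
  expect_equal(fit$intercept, 2)
  expect_equal(fit$r_squared, 1)
  expect_true(fit$ci95_slope[1] <= fit$slope && fit$slope <= fit$ci95_slope[2])
  two <- iron_relaxivity_fit(c(0, 1), c(2, 7), kind = "iron_r1")
  expect_equal(two$slope, 5)
  expect_true(two$degenerate)
  expect_identical(two$ci95_slope, c(-Inf, Inf))
  expect_error(iron_relaxivity_fit(c(1, 1, 1), c(1, 2, 3)), "identical")
})

test_that("slope CI covers the true relaxivity at the nominal rate", {
  conc <- seq(0, 1, length.out = 6)
  covered <- vapply(1:500, function(s) {
    set.seed(s)
    rate <- 5 * conc + 2 + rnorm(6, 0, 0.3)
    ci <- iron_relaxivity_fit(conc, rate, kind = "iron_r1")$ci95_slope
    ci[1] <= 5 && 5 <= ci[2]
  }, NA)
  # binomial 2 SE band around 0.95 with 500 draws: ~ +/- 0.02
  expect_gt(mean(covered), 0.92)
  expect_lt(mean(covered), 0.98)
})

test_that("sample-level R1-R2* fit is order-invariant and range-invariant", {
  x <- c(12, 15, 20, 26, 33, 41)
  y <- 0.04 * x + 0.2
  fit <- r1r2star_fit(x, y)
  expect_equal(fit$slope, 0.04)
  perm <- sample(seq_along(x))
  expect_equal(r1r2star_fit(x[perm], y[perm])$slope, fit$slope)
  expect_equal(r1r2star_fit(x[1:3], y[1:3])$slope,
               r1r2star_fit(x[4:6], y[4:6])$slope, tolerance = 1e-12)
  expect_error(r1r2star_fit(rep(10, 4), 1:4), "identical")
})

test_that("model-object methods behave like a standard regression object", {
  set.seed(21)
  x <- runif(40, 5, 45)
  y <- 0.02 * x + 0.3 + rnorm(40, 0, 0.01)
  fit <- r1r2star_fit(x, y)
  expect_named(coef(fit), c("intercept", "slope"))
  ci <- confint(fit)
  expect_true(ci[1] < fit$slope && fit$slope < ci[2])
  expect_equal(unname(predict(fit, newdata = c(10, 20))),
               fit$intercept + fit$slope * c(10, 20))
  expect_length(residuals(fit), 40)
  expect_output(print(fit), "R1-R2\\* relaxivity")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("ROI estimator fits exact linear data through the binned medians", {
  set.seed(5)
  r2s <- runif(400, 5, 45)
  r1 <- 0.02 * r2s + 0.3
  res <- roi_relaxivity(r1, r2s)
  expect_equal(res$fit$slope, 0.02, tolerance = 1e-12)
  expect_equal(res$fit$intercept, 0.3, tolerance = 1e-10)
  expect_equal(nrow(res$curve), 36)
  # bin width is range/36
  expect_equal(res$curve$bin_high - res$curve$bin_low,
               rep(50 / 36, 36), tolerance = 1e-12)
  expect_error(roi_relaxivity(numeric(0), numeric(0)), "empty")
})

test_that("the 4% occupancy filter uses a strict 'smaller than' rule", {
  # 200 voxels; engineer one bin with 7 voxels (3.5%, dropped) and one with
  # 8 (4.0%, retained); a dense bin absorbs the rest
  width <- 50 / 36
  mk <- function(b, n) runif(n, (b - 1) * width, b * width - 1e-9)
  set.seed(9)
  r2s <- c(mk(5, 7), mk(10, 8), mk(20, 92), mk(21, 93))
  r1 <- 0.02 * r2s + 0.3
  expect_length(r2s, 200)
  res <- roi_relaxivity(r1, r2s)
  expect_identical(res$curve$count[c(5, 10, 20, 21)], c(7L, 8L, 92L, 93L))
  expect_false(res$curve$retained[5])   # 7 < 8 = 0.04 * 200
  expect_true(res$curve$retained[10])   # exactly 4% is kept
  expect_true(all(res$curve$retained[c(20, 21)]))
})

test_that("voxels outside the binning range are excluded, not clipped", {
  set.seed(13)
  inside <- runif(160, 10, 40)
  outside <- c(runif(20, -5, -0.01), runif(20, 50, 80), 50)  # 50 itself out
  r2s <- c(inside, outside)
  r1 <- 0.02 * r2s + 0.3
  res <- roi_relaxivity(r1, r2s)
  expect_equal(sum(res$curve$count), length(inside))
  # with count_base = "roi" the threshold still counts the excluded voxels
  res2 <- roi_relaxivity(r1, r2s, count_base = "in_range")
  expect_gte(sum(res2$curve$retained), sum(res$curve$retained))
})

test_that("ROI estimator matches the brute-force loop implementation", {
  set.seed(31)
  for (k in 1:5) {
    n <- sample(50:200, 1)
    r2s <- runif(n, 0, 55)  # includes out-of-range voxels
    r1 <- 0.03 * r2s + 0.25 + rnorm(n, 0, 0.02)
    res <- roi_relaxivity(r1, r2s)
    ora <- naive_roi_relaxivity(r1, r2s)
    expect_identical(res$curve$count, ora$counts)
    expect_identical(res$curve$retained, ora$retained)
    expect_identical(res$curve$median_r2star, ora$median_r2star)
    expect_identical(res$curve$median_r1, ora$median_r1)
    expect_equal(res$fit$slope, ora$slope, tolerance = 1e-12)
    expect_equal(res$fit$intercept, ora$intercept, tolerance = 1e-12)
  }
})

test_that("slope is invariant under a constant shift of R1; intercept moves", {
  set.seed(17)
  r2s <- runif(300, 8, 42)
  r1 <- 0.025 * r2s + 0.4 + rnorm(300, 0, 0.03)
  a <- roi_relaxivity(r1, r2s)$fit
  b <- roi_relaxivity(r1 + 0.2, r2s)$fit
  expect_equal(a$slope, b$slope, tolerance = 1e-12)
  expect_equal(b$intercept - a$intercept, 0.2, tolerance = 1e-10)
})

test_that("per-label ROI table reports every label and merges id lists", {
  spec <- brain_phantom_spec(demo_rois(), dim = c(24, 16, 16), seed = 3L)
  vol <- simulate_brain_volume(spec)
  tab <- roi_relaxivity_table(vol$r1, vol$r2star, vol$labels)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$slope, vol$truth$slope, tolerance = 1e-10)
  merged <- roi_relaxivity_table(vol$r1, vol$r2star, vol$labels,
                                 roi_labels = list(deep = c(1L, 2L)))
  expect_equal(nrow(merged), 1)
  expect_equal(merged$n_voxels, sum(vol$labels %in% 1:2))
})

test_that("sliding-window map recovers a global slope and honours the
          10-neighbour minimum", {
  set.seed(23)
  d <- c(10, 10, 10)
  r2s <- array(runif(prod(d), 5, 45), d)
  r1 <- 0.03 * r2s + 0.2
  full <- array(TRUE, d)
  sw <- sliding_window_map(r1, r2s, full)
  expect_equal(sw$n_used[5, 5, 5], 125L)  # interior box is 5x5x5
  est <- sw$slope[is.finite(sw$slope)]
  expect_true(all(abs(est - 0.03) < 1e-8))
  # corner voxel: truncated 3x3x3 box = 27 voxels
  expect_equal(sw$n_used[1, 1, 1], 27L)

  # a mask with exactly 9 in-mask voxels near one corner -> NaN there;
  # adding a 10th makes it finite
  m <- array(FALSE, d)
  m[1:3, 1:3, 1] <- TRUE  # 9 voxels in the corner voxel's box
  sw9 <- sliding_window_map(r1, r2s, m)
  expect_true(is.nan(sw9$slope[1, 1, 1]))
  m[1, 1, 2] <- TRUE      # 10th in-mask neighbour
  sw10 <- sliding_window_map(r1, r2s, m)
  expect_false(is.nan(sw10$slope[1, 1, 1]))
  expect_equal(sw10$n_used[1, 1, 1], 10L)
})

test_that("sliding-window slopes match a brute-force per-voxel fit", {
  set.seed(29)
  d <- c(8, 7, 6)
  r2s <- array(runif(prod(d), 5, 45), d)
  r1 <- array(0.02 * r2s + 0.3 + rnorm(prod(d), 0, 0.05), d)
  mask <- array(runif(prod(d)) > 0.25, d)
  sw <- sliding_window_map(r1, r2s, mask)
  for (at in list(c(1, 1, 1), c(4, 4, 3), c(8, 7, 6), c(2, 5, 4))) {
    ora <- naive_window_slope(r1, r2s, mask, at)
    got <- sw$slope[at[1], at[2], at[3]]
    if (is.nan(ora$slope)) expect_true(is.nan(got))
    else expect_equal(got, ora$slope, tolerance = 1e-8)
  }
  expect_error(sliding_window_map(r1, array(0, c(2, 2, 2))), "grid")
})

test_that("ratio map equals the slope only when the intercept vanishes", {
  d <- c(6, 6, 6)
  r2s <- array(runif(prod(d), 5, 45), d)
  no_int <- ratio_map(0.02 * r2s, r2s)
  expect_true(all(abs(no_int$ratio - 0.02) < 1e-12))
  with_int <- ratio_map(0.02 * r2s + 0.3, r2s)
  expect_gt(diff(range(with_int$ratio)), 0.001)  # non-constant
  z <- ratio_map(c(1, 1), c(2, 0))
  expect_true(is.nan(z$ratio[2]) && z$undefined[2])
})

test_that("scan-rescan slope differences stay inside the joint 95% CIs", {
  # two noisy realizations of the same ROI should rarely disagree beyond
  # the union of their confidence intervals
  n_sim <- 200
  ok <- logical(n_sim)
  for (s in seq_len(n_sim)) {
    set.seed(1000 + s)
    r2s <- runif(250, 10, 40)
    scan1 <- 0.02 * r2s + 0.3 + rnorm(250, 0, 0.05)
    scan2 <- 0.02 * r2s + 0.3 + rnorm(250, 0, 0.05)
    f1 <- roi_relaxivity(scan1, r2s)$fit
    f2 <- roi_relaxivity(scan2, r2s)$fit
    lo <- min(f1$ci95_slope[1], f2$ci95_slope[1])
    hi <- max(f1$ci95_slope[2], f2$ci95_slope[2])
    ok[s] <- f1$slope >= lo && f1$slope <= hi &&
      f2$slope >= lo && f2$slope <= hi
  }
  expect_gte(mean(ok), 0.95)
})
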