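test_that("R2* log-linear fit inverts noiseless decays and flags failures", {
  te <- seq(4.45, 20.85, length.out = 5)
  s <- 100 * exp(-0.02 * te)
  f <- fit_r2star(s, te)
  expect_equal(f$r2star, 20, tolerance = 1e-9)
  expect_identical(f$status, 0L)
  # constant signal: zero decay
  expect_equal(fit_r2star(rep(50, 5), te)$r2star, 0)
  # increasing signal: negative rate clipped with flag
  up <- fit_r2star(100 * exp(0.005 * te), te)
  expect_equal(up$r2star, 0)
  expect_identical(up$status, 1L)
  # non-positive signal fails with NaN
  bad <- fit_r2star(c(10, 5, -1, 2, 1), te)
  expect_true(is.nan(bad$r2star))
  expect_identical(bad$status, 2L)
  expect_error(fit_r2star(s[1:2], te[1:2]), "3 echoes")
})

test_that("flip-angle averaging equals the per-angle fit on noiseless data", {
  te <- seq(4.45, 20.85, length.out = 5)
  series <- lapply(c(4, 8, 16, 30), function(a)
    spgr_signal(1000, a, 27, r1 = 1.2, te_ms = te, r2star = 25))
  f <- fit_r2star(series, te)
  expect_equal(f$r2star, 25, tolerance = 1e-9)
  expect_true(all(abs(f$per_flip - 25) < 1e-9))
})

test_that("log-linear R2* agrees with a nonlinear LS oracle at high SNR", {
  te <- seq(4.45, 20.85, length.out = 5)
  set.seed(3)
  n_rep <- 400
  est <- matrix(NA_real_, n_rep, 2)
  for (i in seq_len(n_rep)) {
    s <- 100 * exp(-0.030 * te) + rnorm(5, 0, 1)  # sigma = 1% of S0
    if (any(s <= 0)) next
    est[i, 1] <- fit_r2star(s, te)$r2star
    nl <- nls(s ~ a * exp(-r * te), start = list(a = 100, r = 0.03))
    est[i, 2] <- coef(nl)[["r"]] * 1000
  }
  ok <- complete.cases(est)
  # mean estimate within 2 SE of the truth (30 1/s)
  se <- sd(est[ok, 1]) / sqrt(sum(ok))
  expect_lt(abs(mean(est[ok, 1]) - 30), 2 * se + 0.05)
  # log-linear tracks the nonlinear oracle within 1% at this SNR
  expect_lt(median(abs(est[ok, 1] - est[ok, 2]) / est[ok, 2]), 0.01)
})

test_that("R2 fit inverts a spin-echo series and checks its echo list", {
  te <- seq(10.5, 157.5, length.out = 15)
  f <- fit_r2(50 * exp(-0.01 * te), te)
  expect_equal(f$r2, 10, tolerance = 1e-9)
  expect_error(fit_r2(rep(1, 15), rev(te)), "increasing")
  # minimal 3-echo noiseless case equals the closed-form ln-ratio
  te3 <- c(10, 60, 110)
  s3 <- 80 * exp(-0.02 * te3)
  expect_equal(fit_r2(s3, te3)$r2,
               1000 * log(s3[1] / s3[2]) / (te3[2] - te3[1]), tolerance = 1e-9)
})

test_that("VFA R1 fit inverts the SPGR forward model, with B1 handled", {
  flips <- c(4, 10, 20, 30)
  s <- spgr_signal(800, flips, 19, r1 = 1)
  f <- fit_r1_vfa(s, flips, 19)
  expect_equal(f$r1, 1, tolerance = 1e-9)
  expect_equal(f$m0, 800, tolerance = 1e-6)
  # two angles suffice (noiseless)
  f2 <- fit_r1_vfa(spgr_signal(800, c(4, 30), 19, 1), c(4, 30), 19)
  expect_equal(f2$r1, 1, tolerance = 1e-9)
  # matched B1 in generation and fitting recovers exactly
  s_b1 <- spgr_signal(800, flips, 19, r1 = 1, b1 = 0.8)
  f3 <- fit_r1_vfa(s_b1, flips, 19, b1 = 0.8)
  expect_equal(f3$r1, 1, tolerance = 1e-9)
  # ignoring a B1 < 1 biases R1 upward (smaller effective angles look like
  # a steeper approach to saturation)
  f4 <- fit_r1_vfa(s_b1, flips, 19, b1 = 1)
  expect_gt(f4$r1, 1.05)
})

test_that("B1 calibration recovers the transmit factor from an R1 reference", {
  flips <- c(4, 8, 16, 30)
  sig <- t(sapply(seq(0.9, 1.1, length.out = 9), function(m)
    spgr_signal(500 * m, flips, 18, r1 = 0.7, b1 = 0.9)))
  cal <- calibrate_b1(sig, flips, 18, r1_ref = 0.7)
  expect_equal(cal$b1, 0.9, tolerance = 1e-3)
  expect_equal(median(cal$r1_corrected), 0.7, tolerance = 1e-4)
  expect_false(cal$low_confidence)
  one <- calibrate_b1(sig[1, , drop = FALSE], flips, 18, 0.7)
  expect_true(one$low_confidence)
  expect_error(calibrate_b1(sig, flips, 18, numeric(0)), "empty")
})

test_that("IR R1 fit recovers the gold-standard rate from magnitude data", {
  ti <- c(50, 400, 800, 1200, 2000)
  s <- ir_signal(300, ti, r1 = 0.85)
  f <- fit_r1_ir(s, ti)
  expect_equal(f$r1, 0.85, tolerance = 1e-4)
  expect_equal(f$m0, 300, tolerance = 1e-2)
})

test_that("MTV is the normalised proton-density deficit, clipped into [0,1]", {
  expect_equal(compute_mtv(10, 10)$mtv, 0)
  expect_equal(compute_mtv(7, 10)$mtv, 0.3)
  over <- compute_mtv(11, 10)
  expect_equal(over$mtv, 0)
  expect_true(over$clipped)
  expect_error(compute_mtv(1, 0), "positive")
  # whole-array use keeps shape and stays in [0,1]
  pd <- array(runif(27, 0, 12), c(3, 3, 3))
  m <- compute_mtv(pd, 10)
  expect_identical(dim(m$mtv), dim(pd))
  expect_true(all(m$mtv >= 0 & m$mtv <= 1))
})

test_that("MTsat evaluates its closed form with scale invariance", {
  a <- 10 * pi / 180
  # algebraic zero: S_MT chosen so the saturation term cancels
  r1 <- 1; tr <- 0.027; m0 <- 1000
  s0 <- m0 * a * (r1 * tr) / (a^2 / 2 + r1 * tr)
  expect_equal(compute_mtsat(s0, m0, a, r1, tr)$mtsat, 0, tolerance = 1e-12)
  # direct evaluation
  direct <- m0 * a * (r1 * tr) / 60 - a^2 / 2 - r1 * tr
  expect_equal(compute_mtsat(60, m0, a, r1, tr)$mtsat, direct)
  # doubling m0 and s_mt together changes nothing
  expect_equal(compute_mtsat(120, 2 * m0, a, r1, tr)$mtsat,
               compute_mtsat(60, m0, a, r1, tr)$mtsat)
  z <- compute_mtsat(0, m0, a, r1, tr)
  expect_true(is.nan(z$mtsat) && z$failed)
})

test_that("noiseless simulate-then-fit round trip recovers R1, R2*, M0", {
  env <- iron_environment("fer", r1 = 5, r2star = 60, c1 = 2, c2 = 10)
  proto <- acquisition_protocol(noise_sd = 0, seed = 5L)
  ds <- simulate_phantom_dataset(env, seq(0, 0.4, length.out = 6), proto,
                                 m0 = 1200)
  r2s <- fit_r2star(lapply(1:4, function(j) ds$spgr[, j, ]), proto$te_ms)
  expect_lt(max(abs(r2s$r2star / ds$samples$true_r2star - 1)), 1e-6)
  # undo the TE decay of the first echo, then VFA across flip angles
  s_te0 <- ds$spgr[, , 1] * exp(outer(ds$samples$true_r2star,
                                      rep(proto$te_ms[1] / 1000, 4)))
  r1f <- fit_r1_vfa(s_te0, proto$flip_angles_deg, proto$tr_ms)
  expect_lt(max(abs(r1f$r1 / ds$samples$true_r1 - 1)), 1e-6)
  expect_lt(max(abs(r1f$m0 / 1200 - 1)), 1e-6)
})
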