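# Map estimation from signal series. All fitters operate on a numeric
# vector (one voxel/sample) or a matrix with one row per voxel and one
# column per echo / flip angle; 3-D map inputs are handled by reshaping at
# the call site. Rates are returned in s^-1 with times supplied in ms.

as_signal_matrix <- function(signal, ncol_expected) {
  if (is.null(dim(signal))) signal <- matrix(signal, nrow = 1)
  if (ncol(signal) != ncol_expected)
    stop("signal has ", ncol(signal), " columns but ", ncol_expected,
         " sampling times were given")
  signal
}

# log-linear mono-exponential decay fit for each row; returns rate (s^-1)
# and an integer status: 0 ok, 1 negative rate clipped to 0, 2 failed.
loglin_decay_fit <- function(signal, te_ms) {
  if (length(te_ms) < 3L) stop("at least 3 echoes are required")
  if (is.unsorted(te_ms, strictly = TRUE))
    stop("echo times must be strictly increasing")
  signal <- as_signal_matrix(signal, length(te_ms))
  te_s <- te_ms / 1000
  n <- nrow(signal)
  rate <- rep(NA_real_, n)
  status <- rep(2L, n)
  ok <- apply(signal, 1L, function(s) all(is.finite(s)) && all(s > 0))
  if (any(ok)) {
    y <- log(signal[ok, , drop = FALSE])
    xc <- te_s - mean(te_s)
    slope <- as.vector(y %*% xc) / sum(xc^2)
    r <- -slope
    st <- rep(0L, length(r))
    st[r < 0] <- 1L
    r[r < 0] <- 0
    rate[ok] <- r
    status[ok] <- st
  }
  list(rate = rate, status = status)
}

#' Estimate R2* from multi-echo SPGR signals
#'
#' Fits a mono-exponential decay \eqn{S(TE) = S_0 e^{-TE \cdot R_2^*}} by
#' log-linear least squares, independently for the signal series of each
#' flip angle, and averages the per-flip-angle estimates (arithmetic mean)
#' for increased SNR. Negative fitted rates are clipped to 0 and flagged;
#' non-positive signals make the voxel fail with NaN and status 2.
#'
#' @param signal_by_flip A list with one element per flip angle, each a
#'   matrix (voxels x echoes) or vector of signals; or a single
#'   matrix/vector for a one-flip-angle fit.
#' @param te_ms Strictly increasing echo times, ms; at least 3.
#' @return A list with \code{r2star} (s\eqn{^{-1}}, NaN on failure),
#'   \code{status} (0 ok, 1 clipped, 2 failed; per voxel, worst across flip
#'   angles), and \code{per_flip}: matrix of per-flip-angle estimates.
#' @export
fit_r2star <- function(signal_by_flip, te_ms) {
  if (!is.list(signal_by_flip)) signal_by_flip <- list(signal_by_flip)
  fits <- lapply(signal_by_flip, loglin_decay_fit, te_ms = te_ms)
  per_flip <- do.call(cbind, lapply(fits, `[[`, "rate"))
  status <- do.call(pmax, lapply(fits, `[[`, "status"))
  r2star <- rowMeans(per_flip)
  r2star[status == 2L] <- NaN
  list(r2star = r2star, status = status, per_flip = per_flip)
}

#' Estimate R2 from a multi-echo spin-echo series
#'
#' Single-series mono-exponential log-linear fit (no flip-angle averaging).
#'
#' @param signal Matrix (voxels x echoes) or vector of spin-echo signals.
#' @param te_ms Strictly increasing echo times, ms; at least 3.
#' @return List with \code{r2} (s\eqn{^{-1}}) and \code{status} as in
#'   \code{\link{fit_r2star}}.
#' @export
fit_r2 <- function(signal, te_ms) {
  f <- loglin_decay_fit(signal, te_ms)
  r2 <- f$rate
  r2[f$status == 2L] <- NaN
  list(r2 = r2, status = f$status)
}

#' Variable-flip-angle R1 and M0 estimation from SPGR signals
#'
#' Linearises the SPGR steady-state equation: with
#' \eqn{y = S/\sin\alpha_{eff}} and \eqn{x = S/\tan\alpha_{eff}}
#' (\eqn{\alpha_{eff} = B_1^+ \alpha}), the model becomes the straight line
#' \eqn{y = E_1 x + M_0 (1 - E_1)}, so the slope across flip angles gives
#' \eqn{E_1 = e^{-TR \cdot R_1}} and the intercept gives M0. Voxels
#' whose fitted \eqn{E_1} falls outside (0, 1) get NaN and status 2.
#'
#' @param signal Matrix (voxels x flip angles) or vector of SPGR signals at
#'   a common TE.
#' @param flip_deg Nominal flip angles, degrees; at least 2 distinct
#'   effective angles.
#' @param tr_ms Repetition time, ms.
#' @param b1 Transmit-field factor (scalar or per-voxel vector) scaling the
#'   achieved flip angles; 1 = nominal.
#' @return List with \code{r1} (s\eqn{^{-1}}), \code{m0} (signal units) and
#'   \code{status} (0 ok, 2 failed).
#' @export
fit_r1_vfa <- function(signal, flip_deg, tr_ms, b1 = 1) {
  signal <- as_signal_matrix(signal, length(flip_deg))
  n <- nrow(signal)
  if (length(b1) == 1L) b1 <- rep(b1, n)
  if (length(b1) != n) stop("b1 must be scalar or one value per voxel")
  r1 <- rep(NaN, n)
  m0 <- rep(NaN, n)
  status <- rep(2L, n)
  for (i in seq_len(n)) {
    a <- b1[i] * flip_deg * pi / 180
    if (length(unique(round(a, 12))) < 2L)
      stop("at least 2 distinct effective flip angles are required")
    s <- signal[i, ]
    if (!all(is.finite(s)) || all(s <= 0)) next
    y <- s / sin(a)
    x <- s / tan(a)
    xc <- x - mean(x)
    if (sum(xc^2) == 0) next
    e1 <- sum(xc * (y - mean(y))) / sum(xc^2)
    if (!is.finite(e1) || e1 <= 0 || e1 >= 1) next
    b0 <- mean(y) - e1 * mean(x)  # = M0 (1 - E1)
    r1[i] <- -log(e1) / (tr_ms / 1000)
    m0[i] <- b0 / (1 - e1)
    status[i] <- 0L
  }
  list(r1 = r1, m0 = m0, status = status)
}

#' Estimate R1 and M0 from an inversion-recovery series
#'
#' Nonlinear least-squares fit of the magnitude IR signal
#' \eqn{|M_0 (1 - (1+\epsilon) e^{-TI R_1})|} over a grid-initialised
#' Levenberg-free Gauss-Newton (via \code{stats::optim}), used as the
#' gold-standard R1 for B1+ calibration.
#'
#' @param signal Matrix (voxels x TIs) or vector of magnitude signals.
#' @param ti_ms Inversion times, ms.
#' @param inv_efficiency Assumed inversion efficiency (default 1).
#' @return List with \code{r1}, \code{m0}, \code{status}.
#' @export
fit_r1_ir <- function(signal, ti_ms, inv_efficiency = 1) {
  signal <- as_signal_matrix(signal, length(ti_ms))
  n <- nrow(signal)
  r1 <- rep(NaN, n)
  m0 <- rep(NaN, n)
  status <- rep(2L, n)
  for (i in seq_len(n)) {
    s <- signal[i, ]
    if (!all(is.finite(s)) || max(s) <= 0) next
    obj <- function(p) {
      sum((ir_signal(p[1], ti_ms, p[2], inv_efficiency) - s)^2)
    }
    best <- NULL
    for (r0 in c(0.3, 0.7, 1, 2, 4)) {
      fit <- stats::optim(c(max(s), r0), obj, method = "L-BFGS-B",
                          lower = c(1e-6, 1e-4), upper = c(Inf, 100))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    r1[i] <- best$par[2]
    m0[i] <- best$par[1]
    status[i] <- 0L
  }
  list(r1 = r1, m0 = m0, status = status)
}

#' Calibrate the transmit field against a gold-standard R1 reference
#'
#' Finds the scalar B1+ factor such that the variable-flip-angle R1,
#' refitted with effective flip angles \eqn{B_1^+ \alpha}, matches the
#' gold-standard (inversion-recovery) R1 in a reference region: the
#' calibration minimises the absolute log-ratio of the median corrected VFA
#' R1 to the median reference R1.
#'
#' @param signal SPGR signals of the reference-region voxels (voxels x flip
#'   angles).
#' @param flip_deg,tr_ms Acquisition parameters as in
#'   \code{\link{fit_r1_vfa}}.
#' @param r1_ref Gold-standard R1 value(s) in the reference region,
#'   s\eqn{^{-1}}.
#' @param interval Search interval for the B1+ factor.
#' @return List with \code{b1} (scalar factor), \code{low_confidence}
#'   (TRUE when the reference region has a single voxel), and
#'   \code{r1_corrected}: the corrected VFA R1 of the reference voxels.
#' @export
calibrate_b1 <- function(signal, flip_deg, tr_ms, r1_ref,
                         interval = c(0.5, 1.5)) {
  if (length(r1_ref) == 0L) stop("reference region is empty")
  signal <- as_signal_matrix(signal, length(flip_deg))
  target <- stats::median(r1_ref)
  obj <- function(b1) {
    r1 <- fit_r1_vfa(signal, flip_deg, tr_ms, b1 = b1)$r1
    m <- stats::median(r1, na.rm = TRUE)
    if (!is.finite(m) || m <= 0) return(1e6)
    abs(log(m / target))
  }
  opt <- stats::optimize(obj, interval = interval, tol = 1e-6)
  list(b1 = opt$minimum,
       low_confidence = nrow(signal) == 1L,
       r1_corrected = fit_r1_vfa(signal, flip_deg, tr_ms,
                                 b1 = opt$minimum)$r1)
}

#' Macromolecular tissue volume from proton density
#'
#' MTV is one minus the proton density normalised by the proton density of
#' a pure-water reference: \code{MTV = 1 - pd / water_reference_pd}, clipped
#' into [0, 1] with a flag wherever clipping occurred.
#'
#' @param pd Proton-density values (array or vector, arbitrary units).
#' @param water_reference_pd Positive scalar: proton density of the water
#'   reference (same units as \code{pd}).
#' @return List with \code{mtv} (same shape as \code{pd}) and logical
#'   \code{clipped}.
#' @export
compute_mtv <- function(pd, water_reference_pd) {
  if (!is.numeric(water_reference_pd) || length(water_reference_pd) != 1L ||
      water_reference_pd <= 0)
    stop("water_reference_pd must be a positive scalar")
  mtv <- 1 - pd / water_reference_pd
  clipped <- !is.na(mtv) & (mtv < 0 | mtv > 1)
  mtv[!is.na(mtv)] <- pmin(pmax(mtv[!is.na(mtv)], 0), 1)
  list(mtv = mtv, clipped = clipped)
}

#' Magnetization-transfer saturation from an MT-weighted SPGR signal
#'
#' Computes the MT saturation
#' \deqn{MT_{sat} = M_0 (B_1^+ \alpha) \frac{R_1 TR}{S_{MT}}
#'       - \frac{(B_1^+ \alpha)^2}{2} - R_1 TR}
#' with the flip angle in radians (the expression comes from a small-angle
#' expansion of the MT-weighted SPGR steady state). The result is
#' dimensionless; multiply by 100 for percent units.
#'
#' @param s_mt MT-weighted SPGR signal (> 0; 0 yields NaN with a flag).
#' @param m0 Equilibrium magnetization, same units as \code{s_mt}.
#' @param alpha_rad Nominal excitation flip angle, radians.
#' @param r1 Longitudinal relaxation rate, s\eqn{^{-1}}.
#' @param tr_s Repetition time of the MT-weighted scan, seconds.
#' @param b1 Transmit-field factor (1 = nominal).
#' @return List with \code{mtsat} and logical \code{failed} (where
#'   \code{s_mt <= 0}). Vectorised.
#' @export
compute_mtsat <- function(s_mt, m0, alpha_rad, r1, tr_s, b1 = 1) {
  if (any(b1 <= 0)) stop("b1 must be positive")
  failed <- !is.na(s_mt) & s_mt <= 0
  a <- b1 * alpha_rad
  mtsat <- m0 * a * (r1 * tr_s) / s_mt - a^2 / 2 - r1 * tr_s
  mtsat[failed] <- NaN
  list(mtsat = mtsat, failed = failed)
}
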