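#' Describe a simulated multi-flip-angle multi-echo acquisition
#'
#' Default values mirror a typical 3T phantom relaxometry protocol:
#' multi-echo SPGR at flip angles 4/8/16/30 degrees with TR 27 ms and five
#' echoes equally spaced between 4.45 and 20.85 ms, plus an
#' inversion-recovery series for the gold-standard R1 reference.
#'
#' @param flip_angles_deg Flip angles in degrees, each in (0, 90].
#' @param tr_ms Repetition time of the SPGR scans, ms; must exceed the last
#'   echo.
#' @param te_ms Strictly increasing echo times, ms.
#' @param ti_ms Inversion times for the IR series, ms; \code{NULL} to skip.
#' @param noise_sd Additive Gaussian noise standard deviation, in signal
#'   units (0 = noiseless).
#' @param rician Logical; if \code{TRUE}, noise is applied to the two
#'   quadrature channels and the magnitude taken (Rician magnitude noise)
#'   instead of plain additive Gaussian.
#' @param seed Integer RNG seed making the simulation reproducible.
#' @return An object of class \code{"acquisition_protocol"}.
#' @export
acquisition_protocol <- function(flip_angles_deg = c(4, 8, 16, 30),
                                 tr_ms = 27,
                                 te_ms = seq(4.45, 20.85, length.out = 5),
                                 ti_ms = c(50, 400, 800, 1200, 2000),
                                 noise_sd = 0, rician = FALSE, seed = 1L) {
  if (any(flip_angles_deg <= 0) || any(flip_angles_deg > 90))
    stop("flip angles must be in (0, 90] degrees")
  if (is.unsorted(te_ms, strictly = TRUE))
    stop("te_ms must be strictly increasing")
  if (tr_ms <= max(te_ms)) stop("TR must exceed the last echo time")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(flip_angles_deg = flip_angles_deg, tr_ms = tr_ms,
                 te_ms = te_ms, ti_ms = ti_ms, noise_sd = noise_sd,
                 rician = rician, seed = as.integer(seed)),
            class = "acquisition_protocol")
}

add_noise <- function(signal, sd, rician = FALSE) {
  if (sd == 0) return(signal)
  if (rician) {
    sqrt((signal + stats::rnorm(length(signal), 0, sd))^2 +
           stats::rnorm(length(signal), 0, sd)^2)
  } else {
    signal + stats::rnorm(length(signal), 0, sd)
  }
}

#' Simulate a phantom sample set for a panel of iron environments
#'
#' Generates, for every iron environment and every concentration on the
#' grid, the hidden true relaxation rates from the linear iron-relaxivity
#' model and the corresponding multi-flip-angle multi-echo SPGR signals
#' (plus an IR series when the protocol includes inversion times). This is
#' the in-silico analogue of scanning vials of an iron compound at varying
#' concentrations relative to the water fraction.
#'
#' @param envs A single \code{\link{iron_environment}} or a list of them.
#' @param conc_grid Numeric vector of concentrations (mg/wet ml) applied to
#'   every environment; at least two distinct values are needed for a
#'   relaxivity slope to be estimable downstream (a single concentration
#'   triggers a warning).
#' @param protocol An \code{\link{acquisition_protocol}}.
#' @param m0 Equilibrium magnetization of every sample (signal units).
#' @return A list of class \code{"phantom_dataset"} with
#'   \describe{
#'     \item{samples}{data frame of per-sample ground truth: environment,
#'       concentration, \code{true_r1}, \code{true_r2star}, \code{m0}.}
#'     \item{spgr}{numeric array \code{[sample, flip, echo]} of signals.}
#'     \item{ir}{numeric matrix \code{[sample, ti]} or \code{NULL}.}
#'     \item{protocol}{the protocol used.}
#'   }
#'   Identical inputs (including seed) give bit-identical output.
#' @export
simulate_phantom_dataset <- function(envs, conc_grid, protocol = acquisition_protocol(),
                                     m0 = 1000) {
  if (inherits(envs, "iron_environment")) envs <- list(envs)
  stopifnot(length(envs) >= 1L, inherits(protocol, "acquisition_protocol"))
  if (any(conc_grid < 0)) stop("concentrations must be non-negative")
  if (length(unique(conc_grid)) < 2L)
    warning("fewer than 2 distinct concentrations: relaxivity slopes will not be estimable")

  samples <- do.call(rbind, lapply(envs, function(e) {
    r <- rates_from_concentration(e, conc_grid)
    data.frame(environment = e$name, concentration = conc_grid,
               true_r1 = r$r1, true_r2star = r$r2star, m0 = m0,
               stringsAsFactors = FALSE)
  }))
  rownames(samples) <- NULL
  ns <- nrow(samples)
  nf <- length(protocol$flip_angles_deg)
  ne <- length(protocol$te_ms)

  set.seed(protocol$seed)
  spgr <- array(NA_real_, dim = c(ns, nf, ne),
                dimnames = list(NULL,
                                paste0("fa", protocol$flip_angles_deg),
                                paste0("te", seq_len(ne))))
  for (i in seq_len(ns)) {
    for (j in seq_len(nf)) {
      s <- spgr_signal(samples$m0[i], protocol$flip_angles_deg[j],
                       protocol$tr_ms, samples$true_r1[i],
                       protocol$te_ms, samples$true_r2star[i])
      spgr[i, j, ] <- add_noise(s, protocol$noise_sd, protocol$rician)
    }
  }
  ir <- NULL
  if (!is.null(protocol$ti_ms)) {
    ir <- matrix(NA_real_, ns, length(protocol$ti_ms))
    for (i in seq_len(ns)) {
      s <- ir_signal(samples$m0[i], protocol$ti_ms, samples$true_r1[i])
      ir[i, ] <- add_noise(s, protocol$noise_sd, protocol$rician)
    }
  }
  structure(list(samples = samples, spgr = spgr, ir = ir,
                 protocol = protocol),
            class = "phantom_dataset")
}

#' Specify a brain-like labelled phantom volume
#'
#' Each region of interest (ROI) is given a ground-truth linear dependency
#' of R1 on R2*: voxels receive R2* drawn uniformly from the ROI's range and
#' R1 = slope * R2* + intercept + Gaussian noise. This emulates the premise
#' that, within an ROI sharing one molecular iron environment, R1 depends
#' linearly on R2* with a slope characteristic of that environment.
#'
#' @param rois Data frame with columns \code{label} (positive integer id),
#'   \code{slope} (dimensionless), \code{intercept} (s\eqn{^{-1}}),
#'   \code{r2star_min}, \code{r2star_max} (s\eqn{^{-1}}). Optional column
#'   \code{mtv} adds a constant macromolecular-tissue-volume fraction per
#'   ROI.
#' @param dim Integer vector of length 3: volume dimensions. ROIs are laid
#'   out as equal slabs along the first axis unless \code{label_volume} is
#'   supplied.
#' @param label_volume Optional integer 3-D array of ROI ids (0 = outside).
#' @param sigma_r1 Standard deviation of additive Gaussian noise on R1,
#'   s\eqn{^{-1}}.
#' @param sigma_r2star Standard deviation of additive Gaussian noise on R2*,
#'   s\eqn{^{-1}} (applied after R1 is formed from the noiseless R2*, so the
#'   ground-truth slope is preserved in expectation).
#' @param seed Integer RNG seed.
#' @return Object of class \code{"brain_phantom_spec"}.
#' @export
brain_phantom_spec <- function(rois, dim = c(24, 24, 24), label_volume = NULL,
                               sigma_r1 = 0, sigma_r2star = 0, seed = 1L) {
  stopifnot(is.data.frame(rois),
            all(c("label", "slope", "intercept", "r2star_min", "r2star_max")
                %in% names(rois)))
  if (any(rois$label <= 0)) stop("ROI labels must be positive integers")
  if (any(rois$r2star_max <= rois$r2star_min))
    stop("each ROI needs r2star_max > r2star_min")
  if (sigma_r1 < 0 || sigma_r2star < 0) stop("noise SDs must be non-negative")
  if (!is.null(label_volume)) dim <- base::dim(label_volume)
  structure(list(rois = rois, dim = dim, label_volume = label_volume,
                 sigma_r1 = sigma_r1, sigma_r2star = sigma_r2star,
                 seed = as.integer(seed)),
            class = "brain_phantom_spec")
}

#' Simulate a brain-like labelled volume with known relaxivity ground truth
#'
#' @param spec A \code{\link{brain_phantom_spec}}.
#' @return A list of class \code{"brain_phantom"} with 3-D arrays \code{r1}
#'   and \code{r2star} (NA outside labelled tissue), the integer
#'   \code{labels} array, an optional \code{mtv} array, and \code{truth}:
#'   the per-ROI ground-truth slope/intercept table. ROIs mapped to fewer
#'   than 2 voxels are dropped with a warning. Reproducible under the spec
#'   seed.
#' @export
simulate_brain_volume <- function(spec) {
  stopifnot(inherits(spec, "brain_phantom_spec"))
  d <- spec$dim
  labels <- spec$label_volume
  if (is.null(labels)) {
    # equal slabs along the first axis, in the row order of spec$rois
    labels <- array(0L, dim = d)
    k <- nrow(spec$rois)
    edges <- round(seq(0, d[1], length.out = k + 1))
    for (i in seq_len(k)) {
      if (edges[i + 1] > edges[i])
        labels[(edges[i] + 1):edges[i + 1], , ] <- spec$rois$label[i]
    }
  }
  set.seed(spec$seed)
  r1 <- array(NA_real_, dim = d)
  r2s <- array(NA_real_, dim = d)
  mtv <- if ("mtv" %in% names(spec$rois)) array(NA_real_, dim = d) else NULL
  keep <- logical(nrow(spec$rois))
  for (i in seq_len(nrow(spec$rois))) {
    roi <- spec$rois[i, ]
    idx <- which(labels == roi$label)
    if (length(idx) < 2L) {
      warning(sprintf("ROI label %d has %d voxel(s); excluded", roi$label,
                      length(idx)))
      labels[idx] <- 0L
      next
    }
    keep[i] <- TRUE
    x <- stats::runif(length(idx), roi$r2star_min, roi$r2star_max)
    y <- roi$slope * x + roi$intercept
    if (spec$sigma_r1 > 0) y <- y + stats::rnorm(length(idx), 0, spec$sigma_r1)
    if (spec$sigma_r2star > 0)
      x <- x + stats::rnorm(length(idx), 0, spec$sigma_r2star)
    r2s[idx] <- x
    r1[idx] <- y
    if (!is.null(mtv)) mtv[idx] <- roi$mtv
  }
  truth <- spec$rois[keep, , drop = FALSE]
  rownames(truth) <- NULL
  structure(list(r1 = r1, r2star = r2s, labels = labels, mtv = mtv,
                 truth = truth, spec = spec),
            class = "brain_phantom")
}
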