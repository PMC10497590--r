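# The central estimator: linear dependency of one relaxation quantity on
# another, returned as a classed model object. Internals build on stats::lm
# so that inference (t-based slope CIs, R^2) follows the standard OLS
# machinery.

new_relaxivity_fit <- function(x, y, kind, xlab = "x", ylab = "y",
                               weights = NULL) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (!is.null(weights)) weights <- weights[keep]
  n <- length(x)
  if (n < 2L) stop("at least 2 points are required for a relaxivity fit")
  if (length(unique(x)) < 2L)
    stop("all ", xlab, " values are identical; the slope is undefined")
  df <- data.frame(x = x, y = y)
  fit <- if (is.null(weights)) stats::lm(y ~ x, data = df)
         else stats::lm(y ~ x, data = df, weights = weights)
  cf <- stats::coef(fit)
  degenerate <- n == 2L
  ci <- if (degenerate) c(-Inf, Inf)
        else as.vector(suppressWarnings(stats::confint(fit))["x", ])
  r2 <- if (degenerate) 1 else suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(cf["x"]), intercept = unname(cf["(Intercept)"]),
                 ci95_slope = ci, r_squared = r2, n_points = n,
                 kind = kind, degenerate = degenerate,
                 xlab = xlab, ylab = ylab, lm = fit),
            class = "relaxivity_fit")
}

#' Iron relaxivity: linear dependence of a relaxation rate on concentration
#'
#' Fits, by ordinary least squares, the linear model
#' \eqn{rate = r \cdot conc + c} across samples of one molecular iron
#' environment; the slope is the iron relaxivity of that rate (R1 or R2*)
#' for that environment, in s\eqn{^{-1}} per (mg/wet ml). Sample rates are
#' typically the per-vial median map values.
#'
#' @param concentration Iron-compound concentrations, mg/wet ml; at least
#'   2 distinct values.
#' @param rate Median relaxation rate of each sample, s\eqn{^{-1}}.
#' @param kind Which rate the samples carry: \code{"iron_r1"} or
#'   \code{"iron_r2star"}.
#' @return A \code{\link[=print.relaxivity_fit]{relaxivity_fit}} object:
#'   slope, intercept, two-sided 95\% t-interval on the slope
#'   (infinite-width and flagged degenerate for the exact two-point fit),
#'   R\eqn{^2}, number of points.
#' @examples
#' env <- iron_environment("demo", r1 = 5, r2star = 60, c1 = 2, c2 = 10)
#' conc <- seq(0, 1, length.out = 6)
#' r <- rates_from_concentration(env, conc)
#' iron_relaxivity_fit(conc, r$r1, kind = "iron_r1")  # slope 5
#' @export
iron_relaxivity_fit <- function(concentration, rate,
                                kind = c("iron_r1", "iron_r2star")) {
  kind <- match.arg(kind)
  new_relaxivity_fit(concentration, rate, kind,
                     xlab = "concentration [mg/wet ml]",
                     ylab = if (kind == "iron_r1") "R1 [1/s]" else "R2* [1/s]")
}

#' R1-R2* relaxivity across sample medians
#'
#' Ordinary least squares of median R1 on median R2* across samples of one
#' iron environment at varying concentrations. The slope is the
#' (dimensionless) R1-R2* relaxivity, the empirical counterpart of the
#' relaxivity ratio \code{\link{predict_r1r2star_slope}}; it needs no
#' concentration estimate, which is what allows the same quantity to be
#' measured in vivo.
#'
#' @param r2star Median R2* of each sample, s\eqn{^{-1}}; at least 2
#'   distinct values.
#' @param r1 Median R1 of each sample, s\eqn{^{-1}}.
#' @return A \code{relaxivity_fit} with \code{kind = "r1_vs_r2star"}.
#' @export
r1r2star_fit <- function(r2star, r1) {
  new_relaxivity_fit(r2star, r1, "r1_vs_r2star",
                     xlab = "R2* [1/s]", ylab = "R1 [1/s]")
}

#' Binned ROI estimator of the R1-R2* relaxivity
#'
#' The in vivo estimator. Voxel R2* values of a region of interest are
#' pooled into \code{n_bins} equal-width bins spanning \code{rate_range}
#' (half-open \code{[low, high)} bins; voxels outside the range are
#' excluded), so that the linear fit is not dominated by the density of
#' voxels in different R2* regimes. Bins holding fewer voxels than
#' \code{min_bin_frac} of the total ROI voxel count (strict inequality) are
#' dropped. The median R2* and median R1 of each retained bin form the
#' points of a simple (unweighted) linear regression \eqn{R_1 = a R_2^* + b};
#' the slope \eqn{a} is the ROI's R1-R2* relaxivity and \eqn{b} the residual
#' R1 not explained by R2*.
#'
#' @param r1,r2star Numeric vectors or arrays of co-registered voxel values,
#'   s\eqn{^{-1}}.
#' @param mask Logical vector/array selecting the ROI voxels; \code{NULL}
#'   uses every finite voxel.
#' @param n_bins Number of equal-width bins (default 36).
#' @param rate_range Binning range for R2*, s\eqn{^{-1}} (default 0 to 50).
#' @param min_bin_frac Minimum bin occupancy as a fraction of the total
#'   voxel count (default 0.04); bins with \code{count < min_bin_frac *
#'   total} are discarded.
#' @param count_base Population against which the 4\% occupancy is judged:
#'   \code{"roi"} (default) uses all ROI voxels before range exclusion,
#'   \code{"in_range"} uses only voxels inside \code{rate_range}.
#' @param weight_by_count If \code{TRUE}, the regression across bin medians
#'   is weighted by bin voxel count (off by default: simple regression).
#' @return A list with components \code{fit} (a \code{relaxivity_fit}) and
#'   \code{curve}: a data frame with one row per bin (edges, counts, median
#'   R2*, median R1, and whether the bin was retained).
#' @examples
#' set.seed(7)
#' r2s <- runif(500, 5, 45)
#' r1 <- 0.02 * r2s + 0.3
#' roi_relaxivity(r1, r2s)$fit  # slope 0.02, intercept 0.3
#' @export
roi_relaxivity <- function(r1, r2star, mask = NULL, n_bins = 36,
                           rate_range = c(0, 50), min_bin_frac = 0.04,
                           count_base = c("roi", "in_range"),
                           weight_by_count = FALSE) {
  count_base <- match.arg(count_base)
  if (length(r1) != length(r2star))
    stop("r1 and r2star must have the same length")
  if (is.null(mask)) mask <- is.finite(r1) & is.finite(r2star)
  if (length(mask) != length(r1)) stop("mask must match the map dimensions")
  x <- as.vector(r2star)[as.vector(mask) & is.finite(as.vector(r1)) &
                           is.finite(as.vector(r2star))]
  y <- as.vector(r1)[as.vector(mask) & is.finite(as.vector(r1)) &
                       is.finite(as.vector(r2star))]
  total <- length(x)
  if (total == 0L) stop("the ROI is empty")

  edges <- seq(rate_range[1], rate_range[2], length.out = n_bins + 1)
  in_range <- x >= rate_range[1] & x < rate_range[2]
  bin <- findInterval(x[in_range], edges, rightmost.closed = FALSE)
  counts <- tabulate(bin, nbins = n_bins)
  base_n <- if (count_base == "roi") total else sum(in_range)
  retained <- counts >= min_bin_frac * base_n & counts > 0

  med_x <- rep(NA_real_, n_bins)
  med_y <- rep(NA_real_, n_bins)
  xr <- x[in_range]; yr <- y[in_range]
  for (b in which(counts > 0)) {
    sel <- bin == b
    med_x[b] <- stats::median(xr[sel])
    med_y[b] <- stats::median(yr[sel])
  }
  curve <- data.frame(bin_low = edges[-(n_bins + 1)], bin_high = edges[-1],
                      count = counts, median_r2star = med_x,
                      median_r1 = med_y, retained = retained)
  if (sum(retained) < 2L)
    stop("fewer than 2 bins retained; the ROI relaxivity is not estimable")
  fit <- new_relaxivity_fit(med_x[retained], med_y[retained],
                            kind = "r1_vs_r2star",
                            xlab = "R2* [1/s]", ylab = "R1 [1/s]",
                            weights = if (weight_by_count)
                              counts[retained] else NULL)
  list(fit = fit, curve = curve)
}

#' ROI relaxivities for every label of an anatomical segmentation
#'
#' Applies \code{\link{roi_relaxivity}} to each requested label (or group of
#' labels, e.g. bilateral ROIs merged by id list) of an integer label
#' volume.
#'
#' @param r1,r2star Co-registered maps (arrays or vectors).
#' @param labels Integer label volume of the same shape.
#' @param roi_labels Labels to fit. Either a vector of single ids or a
#'   named list of id vectors (ids in one element are merged into one ROI).
#'   Default: every positive label present.
#' @param ... Passed to \code{\link{roi_relaxivity}}.
#' @return Data frame with one row per ROI: label(s), slope, intercept,
#'   CI bounds, R^2, number of points and of retained bins. ROIs whose fit
#'   fails are reported with NA estimates and the error message.
#' @export
roi_relaxivity_table <- function(r1, r2star, labels, roi_labels = NULL, ...) {
  if (is.null(roi_labels)) {
    ids <- sort(unique(as.vector(labels)))
    roi_labels <- as.list(ids[ids > 0])
    names(roi_labels) <- as.character(unlist(roi_labels))
  }
  if (!is.list(roi_labels)) {
    roi_labels <- as.list(roi_labels)
    names(roi_labels) <- as.character(unlist(roi_labels))
  }
  rows <- lapply(names(roi_labels), function(nm) {
    ids <- roi_labels[[nm]]
    mask <- array(as.vector(labels) %in% ids, dim = dim(labels))
    res <- tryCatch(roi_relaxivity(r1, r2star, mask, ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(roi = nm, labels = paste(ids, collapse = ";"),
                 slope = NA_real_, intercept = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_,
                 r_squared = NA_real_, n_voxels = sum(mask),
                 n_bins_retained = NA_integer_,
                 note = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      f <- res$fit
      data.frame(roi = nm, labels = paste(ids, collapse = ";"),
                 slope = f$slope, intercept = f$intercept,
                 ci_low = f$ci95_slope[1], ci_high = f$ci95_slope[2],
                 r_squared = f$r_squared, n_voxels = sum(mask),
                 n_bins_retained = sum(res$curve$retained),
                 note = "", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Voxel-wise sliding-window R1-R2* relaxivity map
#'
#' For each voxel inside the brain mask, collects the R1 and R2* values of
#' the voxel and its neighbours in a box of \code{box^3} voxels (125 for the
#' default 5), truncated at the volume edges, and — provided at least
#' \code{min_in_mask} of those voxels are inside the mask — fits
#' \eqn{R_1 = a R_2^* + b} across them by ordinary least squares at the
#' voxel level (no binning). The slope map visualises the local relaxivity;
#' voxels with too few in-mask neighbours (or outside the mask) are NaN.
#'
#' Implemented with 3-D integral images, so the cost is linear in the
#' volume size.
#'
#' @param r1,r2star 3-D arrays, s\eqn{^{-1}}, on the same grid.
#' @param mask Logical 3-D array (brain mask); \code{NULL} takes all finite
#'   voxels.
#' @param box Odd box side length in voxels (default 5).
#' @param min_in_mask Minimum number of in-mask voxels in the box required
#'   to fit (default 10).
#' @return List of 3-D arrays \code{slope}, \code{intercept} and integer
#'   \code{n_used}.
#' @export
sliding_window_map <- function(r1, r2star, mask = NULL, box = 5,
                               min_in_mask = 10) {
  if (!identical(dim(r1), dim(r2star)))
    stop("r1 and r2star are not on the same grid")
  if (length(dim(r1)) != 3L) stop("maps must be 3-D arrays")
  if (box %% 2 != 1) stop("box must be odd")
  if (is.null(mask)) mask <- is.finite(r1) & is.finite(r2star)
  if (!identical(dim(mask), dim(r1))) stop("mask is not on the same grid")
  mask <- mask & is.finite(r1) & is.finite(r2star)

  m <- array(as.numeric(mask), dim = dim(mask))
  x <- ifelse(mask, r2star, 0)
  y <- ifelse(mask, r1, 0)
  r <- (box - 1) / 2
  n <- box_sum_3d(m, r)
  sx <- box_sum_3d(x, r)
  sy <- box_sum_3d(y, r)
  sxx <- box_sum_3d(x * x, r)
  sxy <- box_sum_3d(x * y, r)

  denom <- sxx - sx * sx / n
  slope <- (sxy - sx * sy / n) / denom
  intercept <- sy / n - slope * sx / n
  bad <- !mask | n < min_in_mask | !is.finite(denom) | abs(denom) < 1e-12
  slope[bad] <- NaN
  intercept[bad] <- NaN
  storage.mode(n) <- "integer"
  n[!mask] <- NA_integer_
  list(slope = slope, intercept = intercept, n_used = n)
}

# sum of arr over a (2r+1)^3 box centred at each voxel, truncated at the
# edges, via a 3-D integral image
box_sum_3d <- function(arr, r) {
  d <- dim(arr)
  ii <- arr
  for (ax in 1:3) ii <- apply(ii, setdiff(1:3, ax), cumsum) |>
      aperm(order(c(ax, setdiff(1:3, ax))))
  pad <- array(0, dim = d + 1L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- ii
  lo <- lapply(d, function(n) pmax(seq_len(n) - r, 1L))
  hi <- lapply(d, function(n) pmin(seq_len(n) + r, n))
  g <- function(i, j, k) pad[cbind(i, j, k)]
  out <- array(0, dim = d)
  idx <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  i1 <- lo[[1]][idx$i]; i2 <- hi[[1]][idx$i] + 1L
  j1 <- lo[[2]][idx$j]; j2 <- hi[[2]][idx$j] + 1L
  k1 <- lo[[3]][idx$k]; k2 <- hi[[3]][idx$k] + 1L
  out[] <- g(i2, j2, k2) - g(i1, j2, k2) - g(i2, j1, k2) - g(i2, j2, k1) +
    g(i1, j1, k2) + g(i1, j2, k1) + g(i2, j1, k1) - g(i1, j1, k1)
  out
}

#' Voxel-wise R1/R2* ratio map
#'
#' The plain quotient map, provided for comparison with the relaxivity
#' slope: the two agree only when the R1-R2* intercept is zero, so in
#' general the ratio map carries different information than the local
#' slope.
#'
#' @param r1,r2star Co-registered arrays, s\eqn{^{-1}}.
#' @return List with \code{ratio} (NaN where \code{r2star <= 0}) and the
#'   logical \code{undefined} flag array.
#' @export
ratio_map <- function(r1, r2star) {
  if (!identical(dim(r1), dim(r2star)) || length(r1) != length(r2star))
    stop("r1 and r2star are not on the same grid")
  undefined <- !is.na(r2star) & r2star <= 0
  ratio <- r1 / r2star
  ratio[undefined] <- NaN
  list(ratio = ratio, undefined = undefined)
}
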