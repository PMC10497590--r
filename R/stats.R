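# Statistical battery used to validate the relaxivity contrast: slope
# homogeneity across groups, per-predictor regression F-tests with FDR
# correction, paired effect sizes and distribution contrasts.

#' Test homogeneity of regression slopes across groups (ANCOVA)
#'
#' Fits a linear model with a common set of group intercepts and tests the
#' group-by-x interaction: under the null, every group shares one slope.
#' The F statistic (numerator df = number of groups minus 1) is referred to
#' the upper tail of the F distribution; upper-tailed use of F is what
#' "one-sided" means here. Used to ask whether different iron environments
#' have different (iron or R1-R2*) relaxivities.
#'
#' @param groups Named list; each element a list/data frame with numeric
#'   components \code{x} and \code{y} (at least 3 points each, \code{x} not
#'   constant within a group).
#' @return List of class \code{"slope_comparison"}: \code{f_stat},
#'   \code{df_numerator}, \code{df_denominator}, \code{p_value}, and
#'   \code{group_slopes}, a data frame of per-group slopes with 95\% CIs.
#' @examples
#' g <- list(a = list(x = 1:6, y = 0.02 * (1:6) + rnorm(6, 0, 1e-3)),
#'           b = list(x = 1:6, y = 0.04 * (1:6) + rnorm(6, 0, 1e-3)))
#' ancova_slopes(g)
#' @export
ancova_slopes <- function(groups) {
  if (length(groups) < 2L) stop("at least 2 groups are required")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  for (nm in names(groups)) {
    g <- groups[[nm]]
    if (length(g$x) < 3L)
      stop(sprintf("group '%s' has fewer than 3 points", nm))
    if (length(unique(g$x)) < 2L)
      stop(sprintf("group '%s' has constant x; its slope is undefined", nm))
  }
  dat <- do.call(rbind, lapply(names(groups), function(nm) {
    data.frame(g = nm, x = groups[[nm]]$x, y = groups[[nm]]$y)
  }))
  dat$g <- factor(dat$g)
  m0 <- stats::lm(y ~ g + x, data = dat)
  m1 <- stats::lm(y ~ g * x, data = dat)
  an <- suppressWarnings(stats::anova(m0, m1))
  f <- an$F[2]
  df1 <- an$Df[2]
  df2 <- an$Res.Df[2]
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  slopes <- do.call(rbind, lapply(names(groups), function(nm) {
    fit <- stats::lm(y ~ x, data = dat[dat$g == nm, ])
    ci <- if (nrow(dat[dat$g == nm, ]) > 2)
            suppressWarnings(stats::confint(fit))["x", ]
          else c(-Inf, Inf)
    data.frame(group = nm, slope = unname(stats::coef(fit)["x"]),
               ci_low = ci[1], ci_high = ci[2], row.names = NULL)
  }))
  structure(list(f_stat = f, df_numerator = df1, df_denominator = df2,
                 p_value = p, group_slopes = slopes),
            class = "slope_comparison")
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf("Slope-homogeneity ANCOVA: F(%d, %d) = %.4g, p = %.3g\n",
              x$df_numerator, x$df_denominator, x$f_stat, x$p_value))
  print(x$group_slopes, row.names = FALSE)
  invisible(x)
}

#' Simple regression with a one-sided (upper-tail) F-test
#'
#' Ordinary least squares of \code{y} on \code{x}; returns the coefficient
#' of determination and the overall regression F statistic with its
#' upper-tail p-value.
#'
#' @param x,y Numeric vectors, length \eqn{\ge 3}.
#' @return List: \code{r_squared}, \code{f_stat}, \code{df1}, \code{df2},
#'   \code{p_one_sided}, \code{slope}, \code{intercept}.
#' @export
regression_ftest <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("at least 3 points are required")
  fit <- stats::lm(y ~ x)
  s <- suppressWarnings(summary(fit))
  fs <- s$fstatistic
  list(r_squared = s$r.squared, f_stat = unname(fs[1]),
       df1 = unname(fs[2]), df2 = unname(fs[3]),
       p_one_sided = stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE),
       slope = unname(stats::coef(fit)["x"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment of a vector of p-values (monotonicity enforced),
#' with an optional rejection set at level \code{q}.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param q Optional FDR level; when given, the result includes the logical
#'   rejection vector \code{reject} at that level.
#' @return Adjusted p-values (same order as input), or a list with
#'   \code{p_adjusted} and \code{reject} when \code{q} is supplied.
#' @export
fdr_bh <- function(p, q = NULL) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  if (is.null(q)) return(adj)
  list(p_adjusted = adj, reject = !is.na(adj) & adj <= q)
}

#' Paired contrast: Cohen's d and a two-sided paired t-test
#'
#' Differences are taken as \code{b - a}; Cohen's d is the mean difference
#' divided by the standard deviation of the differences (the paired-design
#' convention; an average-variance denominator is available via
#' \code{denominator = "average_sd"}).
#'
#' @param a,b Paired numeric vectors of equal length \eqn{\ge 2}.
#' @param denominator \code{"sd_diff"} (default) or \code{"average_sd"}
#'   (pooled across the two conditions).
#' @return List: \code{cohens_d}, \code{t_stat}, \code{df},
#'   \code{p_two_sided}, \code{mean_diff}.
#' @examples
#' paired_contrast(c(1, 2, 3), c(2, 3, 5))  # d ~ 2.309
#' @export
paired_contrast <- function(a, b, denominator = c("sd_diff", "average_sd")) {
  denominator <- match.arg(denominator)
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 2L) stop("at least 2 pairs are required")
  d <- b - a
  sdd <- stats::sd(d)
  if (sdd == 0 && denominator == "sd_diff")
    stop("zero-variance differences: Cohen's d is undefined")
  tt <- stats::t.test(b, a, paired = TRUE)
  denom <- if (denominator == "sd_diff") sdd
           else sqrt((stats::var(a) + stats::var(b)) / 2)
  if (denom == 0) stop("zero variance: Cohen's d is undefined")
  list(cohens_d = mean(d) / denom,
       t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p_two_sided = tt$p.value, mean_diff = mean(d))
}

#' Two-sample Kolmogorov-Smirnov contrast
#'
#' Compares two empirical distributions. When the samples carry different
#' physical quantities (e.g. a relaxivity distribution against an R1
#' distribution across ROIs), set \code{standardize = TRUE} to z-score each
#' sample before the comparison, so only distribution shape is contrasted;
#' the output records whether standardization was applied.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @param standardize Z-score each sample first (default \code{FALSE}).
#' @return List: \code{ks_stat}, \code{p_value}, \code{standardized}.
#' @export
ks_contrast <- function(sample_a, sample_b, standardize = FALSE) {
  if (length(sample_a) == 0L || length(sample_b) == 0L)
    stop("both samples must be non-empty")
  if (standardize) {
    sample_a <- (sample_a - mean(sample_a)) / stats::sd(sample_a)
    sample_b <- (sample_b - mean(sample_b)) / stats::sd(sample_b)
  }
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b))
  list(ks_stat = unname(kt$statistic), p_value = kt$p.value,
       standardized = standardize)
}
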