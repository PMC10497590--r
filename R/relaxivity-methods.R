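# S3 methods for the central relaxivity_fit model object.

#' @export
print.relaxivity_fit <- function(x, ...) {
  kind <- switch(x$kind,
                 iron_r1 = "R1-iron relaxivity",
                 iron_r2star = "R2*-iron relaxivity",
                 r1_vs_r2star = "R1-R2* relaxivity",
                 x$kind)
  cat(sprintf("%s fit (%d points)\n", kind, x$n_points))
  cat(sprintf("  slope     %.6g  [95%% CI %.6g, %.6g]\n",
              x$slope, x$ci95_slope[1], x$ci95_slope[2]))
  cat(sprintf("  intercept %.6g\n", x$intercept))
  cat(sprintf("  R-squared %.4f\n", x$r_squared))
  if (x$degenerate)
    cat("  note: exact two-point fit; the slope interval is unbounded\n")
  invisible(x)
}

#' @export
summary.relaxivity_fit <- function(object, ...) {
  s <- summary(object$lm, ...)
  cat("Relaxivity model: ", object$ylab, " ~ ", object$xlab, "\n\n", sep = "")
  print(s)
  invisible(s)
}

#' @export
coef.relaxivity_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
confint.relaxivity_fit <- function(object, parm = "slope", level = 0.95,
                                   ...) {
  if (object$degenerate) {
    ci <- matrix(c(-Inf, Inf), 1, dimnames = list("slope", c("low", "high")))
    return(ci[parm, , drop = FALSE])
  }
  ci <- stats::confint(object$lm, level = level)
  rownames(ci) <- c("intercept", "slope")
  ci[parm, , drop = FALSE]
}

#' @export
predict.relaxivity_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$lm))
  if (is.numeric(newdata)) newdata <- data.frame(x = newdata)
  stats::predict(object$lm, newdata = newdata, ...)
}

#' @export
residuals.relaxivity_fit <- function(object, ...) {
  stats::residuals(object$lm)
}

#' Plot a relaxivity fit
#'
#' Scatter of the fitted points with the regression line and its 95\%
#' confidence band.
#'
#' @param x A \code{relaxivity_fit}.
#' @param ... Passed to \code{plot}.
#' @export
plot.relaxivity_fit <- function(x, ...) {
  d <- x$lm$model
  graphics::plot(d$x, d$y, xlab = x$xlab, ylab = x$ylab,
                 main = sprintf("slope = %.4g", x$slope), ...)
  xs <- seq(min(d$x), max(d$x), length.out = 100)
  graphics::abline(x$lm, col = "red3")
  if (!x$degenerate) {
    pr <- stats::predict(x$lm, data.frame(x = xs), interval = "confidence")
    graphics::lines(xs, pr[, "lwr"], lty = 2, col = "red3")
    graphics::lines(xs, pr[, "upr"], lty = 2, col = "red3")
  }
  invisible(x)
}
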