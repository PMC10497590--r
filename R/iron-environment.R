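#' Define a molecular iron environment by its relaxivities
#'
#' A molecular iron environment (e.g. free ferritin, liposomal transferrin,
#' ferrous iron ions) is characterised by the linear dependence of the MR
#' relaxation rates on the concentration of the iron compound:
#' \deqn{R_1 = r_1 [IC] + c_1, \qquad R_2^* = r_2^* [IC] + c_2}
#' where \eqn{[IC]} is the iron-compound concentration relative to the water
#' fraction (mg/wet ml). The slopes \eqn{r_1} and \eqn{r_2^*} are the iron
#' relaxivities of the environment; \eqn{c_1}, \eqn{c_2} are the baseline
#' rates of the iron-free milieu.
#'
#' @param name Text label for the environment.
#' @param r1 R1-iron relaxivity, s\eqn{^{-1}} per (mg/wet ml).
#' @param r2star R2*-iron relaxivity, s\eqn{^{-1}} per (mg/wet ml).
#' @param c1 Baseline R1 at zero iron, s\eqn{^{-1}}. Must be \eqn{\ge 0}.
#' @param c2 Baseline R2* at zero iron, s\eqn{^{-1}}. Must be \eqn{\ge 0}.
#' @return An object of class \code{"iron_environment"}.
#' @examples
#' env <- iron_environment("ferritin-like", r1 = 0.1, r2star = 5,
#'                         c1 = 0.3, c2 = 2)
#' rates_from_concentration(env, 2.5)
#' predict_r1r2star_slope(env)
#' @export
iron_environment <- function(name, r1, r2star, c1 = 0, c2 = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  for (v in c(r1 = r1, r2star = r2star, c1 = c1, c2 = c2)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("relaxivity parameters must be finite scalars")
  }
  if (c1 < 0 || c2 < 0) stop("baseline rates c1, c2 must be non-negative")
  structure(list(name = name, r1 = r1, r2star = r2star, c1 = c1, c2 = c2),
            class = "iron_environment")
}

#' @export
print.iron_environment <- function(x, ...) {
  cat(sprintf("Iron environment '%s'\n", x$name))
  cat(sprintf("  r1     = %g s^-1/(mg/wet ml)   baseline c1 = %g s^-1\n",
              x$r1, x$c1))
  cat(sprintf("  r2*    = %g s^-1/(mg/wet ml)   baseline c2 = %g s^-1\n",
              x$r2star, x$c2))
  if (x$r2star != 0)
    cat(sprintf("  predicted r1-r2* relaxivity (r1/r2*) = %g\n",
                x$r1 / x$r2star))
  invisible(x)
}

#' Relaxation rates of an iron environment at a given concentration
#'
#' Evaluates the linear iron-relaxivity model of an environment at one or
#' more iron-compound concentrations.
#'
#' @param env An \code{\link{iron_environment}}.
#' @param conc Iron-compound concentration(s), mg/wet ml; must be
#'   non-negative.
#' @return A list with numeric components \code{r1} and \code{r2star}
#'   (s\eqn{^{-1}}), each the same length as \code{conc}.
#' @export
rates_from_concentration <- function(env, conc) {
  stopifnot(inherits(env, "iron_environment"), is.numeric(conc))
  if (any(conc < 0)) stop("concentration must be non-negative")
  list(r1 = env$c1 + env$r1 * conc,
       r2star = env$c2 + env$r2star * conc)
}

#' Relaxation rates of a mixture of iron environments
#'
#' Combines several iron compounds by linear additivity of their rate
#' contributions on top of a common baseline:
#' \eqn{R_1 = R_{1,base} + \sum_i r_{1,i} c_i} (and analogously for R2*).
#' Linear additivity is the package's working model for heterogeneous iron
#' milieus (including a myelin/lipid pseudo-compound); see the methods
#' vignette for its assumptions.
#'
#' @param envs List of \code{\link{iron_environment}} objects.
#' @param concs Numeric vector of concentrations, one per environment,
#'   mg/wet ml.
#' @param base_r1,base_r2star Baseline rates of the iron-free milieu,
#'   s\eqn{^{-1}}. The per-environment intercepts \code{c1}/\code{c2} are
#'   ignored here: the mixture has a single baseline.
#' @return A list with scalar components \code{r1} and \code{r2star}.
#' @export
mixture_rates <- function(envs, concs, base_r1 = 0, base_r2star = 0) {
  if (length(envs) != length(concs))
    stop("'envs' and 'concs' must have the same length")
  if (any(concs < 0)) stop("concentrations must be non-negative")
  r1 <- base_r1
  r2s <- base_r2star
  for (i in seq_along(envs)) {
    e <- envs[[i]]
    stopifnot(inherits(e, "iron_environment"))
    r1 <- r1 + e$r1 * concs[i]
    r2s <- r2s + e$r2star * concs[i]
  }
  list(r1 = r1, r2star = r2s)
}

#' Theoretical R1-vs-R2* slope of a single iron environment
#'
#' Within one molecular iron environment, eliminating the (unobservable)
#' iron concentration from the two linear rate equations leaves R1 linearly
#' dependent on R2* with slope equal to the ratio of the iron relaxivities:
#' \deqn{R_1 = \frac{r_1}{r_2^*} R_2^* + c.}
#' That dimensionless ratio is the theoretical prediction for the measured
#' R1-R2* relaxivity, and requires no concentration estimate — which is what
#' makes the contrast accessible in vivo.
#'
#' @param env An \code{\link{iron_environment}} with \code{r2star != 0}.
#' @return The dimensionless slope \code{r1/r2star}.
#' @seealso \code{\link{r1r2star_fit}} for the empirical counterpart.
#' @export
predict_r1r2star_slope <- function(env) {
  stopifnot(inherits(env, "iron_environment"))
  if (env$r2star == 0)
    stop("r2star relaxivity is zero; the r1/r2* ratio is undefined")
  env$r1 / env$r2star
}

#' Intercept of the R1-vs-R2* dependency implied by an environment
#'
#' The residual R1 not explained by R2*: \eqn{c = c_1 - (r_1/r_2^*) c_2}.
#'
#' @inheritParams predict_r1r2star_slope
#' @return Intercept in s\eqn{^{-1}}.
#' @export
predict_r1r2star_intercept <- function(env) {
  env$c1 - predict_r1r2star_slope(env) * env$c2
}
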