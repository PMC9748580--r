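#' Exponential-family specification for a longitudinal marker
#'
#' Builds the family object used throughout the package: the cumulant
#' function `b()`, its first two derivatives, the canonical link and its
#' inverse, and whether the family carries a free dispersion (residual
#' variance) parameter.  Supported families are `"gaussian"` (identity
#' link, \eqn{b(x) = x^2/2}), `"poisson"` (log link, \eqn{b(x) = e^x})
#' and `"bernoulli"` (logit link, \eqn{b(x) = \log(1 + e^x)}).
#'
#' @param family Character scalar: `"gaussian"`, `"poisson"` or
#'   `"bernoulli"`.
#' @return An object of class `glmm_family`: a list with elements
#'   `family`, `b`, `b1`, `b2`, `link`, `linkinv`, `has_dispersion`.
#' @examples
#' f <- glmm_family("bernoulli")
#' f$b(0)            # log(2)
#' f$linkinv(0)      # 0.5
#' @export
glmm_family <- function(family) {
  family <- match.arg(family, c("gaussian", "poisson", "bernoulli"))
  out <- switch(family,
    gaussian = list(
      family = "gaussian",
      b = function(x) x^2 / 2,
      b1 = function(x) x,
      b2 = function(x) rep(1, length(x)),
      link = "identity",
      linkinv = identity,
      has_dispersion = TRUE
    ),
    poisson = list(
      family = "poisson",
      b = exp,
      b1 = exp,
      b2 = exp,
      link = "log",
      linkinv = exp,
      has_dispersion = FALSE
    ),
    bernoulli = list(
      family = "bernoulli",
      b = function(x) log1p(exp(-abs(x))) + pmax(x, 0),
      b1 = stats::plogis,
      b2 = function(x) stats::plogis(x) * (1 - stats::plogis(x)),
      link = "logit",
      linkinv = stats::plogis,
      has_dispersion = FALSE
    )
  )
  structure(out, class = "glmm_family")
}

#' Per-marker model specification
#'
#' Declares one longitudinal marker of the multivariate model: its name
#' (matching the `marker` column of the long-format data), its
#' exponential family, and the covariate columns entering its fixed- and
#' random-effect design matrices.  The reserved column name
#' `"(Intercept)"` denotes a constant column of ones and need not be
#' present in the data.
#'
#' @param name Marker name (character scalar).
#' @param family `"gaussian"`, `"poisson"` or `"bernoulli"`, or a
#'   `glmm_family` object.
#' @param fixed Character vector of fixed-effect columns (length
#'   \eqn{p_r \ge 1}).
#' @param random Character vector of random-effect columns (length
#'   \eqn{q_r \ge 1}).  Need not be a subset of `fixed`.
#' @return An object of class `marker_spec`.
#' @examples
#' marker_spec("hba1c", "gaussian",
#'             fixed = c("(Intercept)", "time"),
#'             random = c("(Intercept)", "time"))
#' @export
marker_spec <- function(name, family,
                        fixed = c("(Intercept)", "x"),
                        random = fixed) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_config("marker name must be a non-empty character scalar")
  if (!inherits(family, "glmm_family")) family <- glmm_family(family)
  if (length(fixed) < 1L) stop_config("marker '", name, "': at least one fixed-effect column required")
  if (length(random) < 1L) stop_config("marker '", name, "': at least one random-effect column required")
  structure(
    list(name = name, family = family,
         fixed = as.character(fixed), random = as.character(random),
         p_r = length(fixed), q_r = length(random)),
    class = "marker_spec"
  )
}

#' @export
print.marker_spec <- function(x, ...) {
  cat(sprintf("marker '%s' [%s]: fixed = {%s}, random = {%s}\n",
              x$name, x$family$family,
              paste(x$fixed, collapse = ", "),
              paste(x$random, collapse = ", ")))
  invisible(x)
}

## classed conditions used across the package: configuration errors exit
## with status 2 at the command line, numerical failures with status 1
stop_config <- function(...) {
  stop(structure(class = c("mglmm_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_validation <- function(...) {
  stop(structure(class = c("mglmm_validation_error", "mglmm_config_error",
                           "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_numeric <- function(..., state = NULL) {
  stop(structure(class = c("mglmm_numeric_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1),
                      state = state)))
}
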