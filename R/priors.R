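#' Prior configuration
#'
#' Hyperparameters of the Bayesian multivariate GLMM.  Fixed effects
#' carry a \eqn{N(0, \sigma^2_\beta I_p)} prior.  The joint
#' random-effects covariance \eqn{\Sigma_R} carries an inverse-Wishart
#' prior with inverse-gamma auxiliary variables \eqn{a_k} (one per
#' random effect), which induces Half-t(\eqn{\nu}) marginal priors on
#' the standard deviations and, at \eqn{\nu = 2}, uniform priors on the
#' correlations.  Each Gaussian marker's residual variance carries an
#' inverse-gamma prior with its own auxiliary \eqn{a_{\varepsilon r}},
#' equivalent to a Half-Cauchy prior on the residual standard deviation
#' with scale \eqn{A_{\varepsilon r}}.
#'
#' @param sigma2_beta Fixed-effect prior variance (default `1e4`).
#' @param nu Degrees-of-freedom modifier of the covariance prior
#'   (default 2).
#' @param A_k Auxiliary scale(s) for the random-effect standard
#'   deviations; scalar or one per random effect (default `1e4`).
#' @param A_eps Auxiliary scale(s) for Gaussian residual standard
#'   deviations; scalar or one per Gaussian marker (default `1e4`).
#' @return Object of class `prior_config`.
#' @export
prior_config <- function(sigma2_beta = 1e4, nu = 2, A_k = 1e4, A_eps = 1e4) {
  if (!is.numeric(sigma2_beta) || length(sigma2_beta) != 1L || sigma2_beta <= 0)
    stop_config("sigma2_beta must be a positive scalar")
  if (!is.numeric(nu) || length(nu) != 1L || nu <= 0)
    stop_config("nu must be a positive scalar")
  if (any(A_k <= 0) || any(A_eps <= 0))
    stop_config("all auxiliary scales A_k, A_eps must be strictly positive")
  structure(list(sigma2_beta = sigma2_beta, nu = nu,
                 A_k = A_k, A_eps = A_eps),
            class = "prior_config")
}

#' Fitter controls
#'
#' @param tolerance Stopping threshold on the relative change of the
#'   variational lower bound, \eqn{|\Delta \ell| / (1 + |\ell|)}
#'   (default `1e-7`).
#' @param max_iter Maximum number of coordinate-ascent cycles
#'   (default 500).
#' @param damping Step factor in `(0, 1]` applied to the mean updates of
#'   \eqn{q(\beta, u)}; 1 (default) is the undamped update, smaller
#'   values can stabilise hard semiparametric fits.
#' @param verbose Print the lower bound each cycle.
#' @return Object of class `fit_control`.
#' @export
fit_control <- function(tolerance = 1e-7, max_iter = 500L,
                        damping = 1, verbose = FALSE) {
  if (tolerance <= 0) stop_config("tolerance must be > 0")
  if (max_iter < 1) stop_config("max_iter must be >= 1")
  if (damping <= 0 || damping > 1) stop_config("damping must lie in (0, 1]")
  structure(list(tolerance = tolerance, max_iter = as.integer(max_iter),
                 damping = damping, verbose = isTRUE(verbose)),
            class = "fit_control")
}
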