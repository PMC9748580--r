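#' Accuracy of a variational marginal against reference posterior draws
#'
#' The integrated-absolute-error accuracy
#' \deqn{100 \left(1 - \tfrac12 \int |q^*(\theta) - \hat p(\theta)|
#' \, d\theta\right) \%,}
#' where \eqn{\hat p} is a kernel density estimate of the reference
#' draws (typically an MCMC sample) with a direct-plug-in bandwidth.
#' 100 means the densities coincide; 0 means disjoint supports.  The
#' integral is taken by the trapezoid rule on an equispaced grid of at
#' least 1024 points covering both supports padded by three times the
#' largest bandwidth.  If the variational marginal is supplied as
#' draws it is density-estimated identically; if both arguments are
#' density functions they are compared directly on the grid.
#'
#' @param q_marginal The variational marginal: a `q_marginal` object
#'   from [q_marginals()], a density function, or a numeric vector of
#'   draws.
#' @param reference Reference posterior draws (numeric vector, at
#'   least 100), or a density function.
#' @param n_grid Number of grid points per side (minimum 1024); the
#'   integration grid is the union of the two sides' padded-support
#'   grids, so well-separated densities remain fully resolved.
#' @param bandwidth Optional bandwidth override for the reference KDE.
#' @param support Numeric range for a side supplied as a bare density
#'   function (a `q_marginal` object carries its own; draws use their
#'   sample range).
#' @return Accuracy in percent.
#' @examples
#' accuracy_score(dnorm, dnorm, support = c(-8, 8))   # exactly 100
#' @export
accuracy_score <- function(q_marginal, reference, n_grid = 1024,
                           bandwidth = NULL, support = NULL) {
  n_grid <- max(as.integer(n_grid), 1024L)

  side <- function(obj, bw_override = NULL) {
    if (inherits(obj, "q_marginal")) {
      if (!is.null(obj$density))
        return(list(fun = obj$density, support = obj$support, bw = 0))
      obj <- obj$samples
    }
    if (is.function(obj)) {
      if (is.null(support))
        stop_config("a bare density function needs an explicit 'support' range")
      return(list(fun = obj, support = range(support), bw = 0))
    }
    x <- as.numeric(obj)
    if (length(x) < 100)
      stop_validation("at least 100 draws are required for a kernel density estimate")
    bw <- if (!is.null(bw_override)) bw_override else KernSmooth::dpik(x)
    list(samples = x, support = range(x), bw = bw)
  }
  a <- side(q_marginal)
  b <- side(reference, bandwidth)
  pad <- 3 * max(a$bw, b$bw,
                 diff(a$support) / 100, diff(b$support) / 100)
  int_a <- a$support + c(-pad, pad)
  int_b <- b$support + c(-pad, pad)
  segments <- if (int_a[2] >= int_b[1] && int_b[2] >= int_a[1])
    list(range(c(int_a, int_b)))            # overlapping supports: one grid
  else list(int_a, int_b)                   # disjoint: integrate separately

  dens <- function(s, grid) {
    if (!is.null(s$fun)) return(s$fun(grid))
    rng <- s$support + c(-pad, pad)
    kd <- KernSmooth::bkde(s$samples, bandwidth = s$bw,
                           gridsize = n_grid, range.x = rng)
    stats::approx(kd$x, pmax(kd$y, 0), xout = grid, yleft = 0, yright = 0)$y
  }
  iae <- sum(vapply(segments, function(rng) {
    grid <- seq(rng[1], rng[2], length.out = n_grid)
    gap <- abs(dens(a, grid) - dens(b, grid))
    sum((gap[-1] + gap[-n_grid]) / 2) * (grid[2] - grid[1])
  }, 0))
  100 * (1 - iae / 2)
}

dinvgamma <- function(x, shape, rate) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- exp(shape * log(rate) - lgamma(shape) -
                    (shape + 1) * log(x[pos]) - rate / x[pos])
  out
}

qinvgamma <- function(p, shape, rate) 1 / stats::qgamma(1 - p, shape, rate = rate)

#' Variational marginal of a single scalar parameter
#'
#' Extracts the marginal q-density of one parameter from a fit:
#' normal for fixed effects (`"beta:<marker>:<column>"`) and random
#' effects (`"u:<subject>:<marker>:<column>"`); inverse-gamma for
#' residual variances (`"sigma2:<marker>"`); and, for entries of the
#' random-effects covariance (`"Sigma_R[i,j]"`), seeded Monte Carlo
#' draws from the inverse-Wishart factor (the element-wise marginal has
#' no convenient closed form).
#'
#' @param fit An `mglmm_fit`.
#' @param parameter Parameter name as above (also accepted: a bare
#'   design coefficient name such as `"marker1:(Intercept)"`, treated
#'   as a fixed effect).
#' @param n_draws Monte Carlo draws for covariance entries.
#' @param seed Seed for those draws.
#' @return Object of class `q_marginal` with fields `type`, `mean`,
#'   `sd`, and either a `density`/`quantile` pair (closed-form cases,
#'   with a plotting `support`) or `samples`.
#' @export
q_marginals <- function(fit, parameter, n_draws = 1e5, seed = 1L) {
  st <- fit$state
  des <- fit$design
  parts <- strsplit(parameter, ":", fixed = TRUE)[[1]]

  normal_marginal <- function(mu, sd) {
    structure(list(type = "normal", mean = mu, sd = sd,
                   density = function(x) stats::dnorm(x, mu, sd),
                   quantile = function(p) stats::qnorm(p, mu, sd),
                   support = c(mu - 6 * sd, mu + 6 * sd)),
              class = "q_marginal")
  }

  if (parts[1] == "beta" || parameter %in% des$beta_names) {
    nm <- if (parts[1] == "beta") paste(parts[-1], collapse = ":") else parameter
    j <- match(nm, des$beta_names)
    if (is.na(j)) stop_config("unknown fixed effect: ", nm)
    return(normal_marginal(st$mu_beta[j], sqrt(st$Sigma_beta[j, j])))
  }
  if (parts[1] == "u") {
    i <- match(parts[2], as.character(des$subjects))
    k <- match(paste(parts[-(1:2)], collapse = ":"), des$u_names)
    if (is.na(i) || is.na(k))
      stop_config("unknown random effect: ", parameter)
    return(normal_marginal(st$mu_u[k, i], sqrt(st$Sigma_u[[i]][k, k])))
  }
  if (parts[1] == "sigma2") {
    g <- match(parts[2], names(des$specs)[des$gauss_markers])
    if (is.na(g)) stop_config("unknown gaussian marker: ", parts[2])
    N_r <- unname(des$N_r[des$gauss_markers[g]])
    shape <- 0.5 * (N_r + 1); rate <- st$B_sig2[g]
    mu <- rate / (shape - 1)
    v <- if (shape > 2) rate^2 / ((shape - 1)^2 * (shape - 2)) else NA_real_
    return(structure(list(type = "invgamma", mean = mu, sd = sqrt(v),
                          shape = shape, rate = rate,
                          density = function(x) dinvgamma(x, shape, rate),
                          quantile = function(p) qinvgamma(p, shape, rate),
                          support = qinvgamma(c(1e-5, 1 - 1e-5), shape, rate)),
                     class = "q_marginal"))
  }
  sig_el <- regmatches(parameter, regexec("^Sigma_R\\[(\\d+),(\\d+)\\]$", parameter))[[1]]
  if (length(sig_el) == 3) {
    i <- as.integer(sig_el[2]); j <- as.integer(sig_el[3])
    q <- des$q
    if (i > q || j > q) stop_config("Sigma_R index out of range")
    kap <- fit$priors$nu + q + des$m - 1
    draws <- riw_element(st$B_Sigma_R, kap, i, j, n_draws, seed)
    return(structure(list(type = "iw_mc",
                          mean = st$B_Sigma_R[i, j] / (kap - q - 1),
                          sd = stats::sd(draws), samples = draws),
                     class = "q_marginal"))
  }
  stop_config("unknown parameter name: ", parameter)
}

## seeded draws of element (i, j) of Sigma_R ~ IW(kap, B):
## Sigma^{-1} ~ Wishart(kap, B^{-1})
riw_element <- function(B, kap, i, j, n_draws, seed) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  W <- stats::rWishart(n_draws, kap, chol2inv(chol(B)))
  vapply(seq_len(n_draws), function(t) chol2inv(chol(W[, , t]))[i, j], 0)
}

#' Posterior summary table
#'
#' One row per scalar parameter with variational posterior mean, sd and
#' central 95% interval: Gaussian quantiles for fixed effects,
#' inverse-gamma quantiles for residual variances and analytic
#' inverse-Wishart means/sds for entries of \eqn{\Sigma_R} (interval
#' columns are `NA` there; use [q_marginals()] for Monte Carlo
#' intervals).
#'
#' @param object An `mglmm_fit`.
#' @param ... Unused.
#' @return A data frame with columns `parameter`, `mean`, `sd`,
#'   `q2.5`, `q97.5`.
#' @export
summary.mglmm_fit <- function(object, ...) {
  st <- object$state
  des <- object$design
  rows <- list()
  for (j in seq_len(des$p)) {
    mu <- st$mu_beta[j]; sd <- sqrt(st$Sigma_beta[j, j])
    rows[[length(rows) + 1]] <- data.frame(
      parameter = paste0("beta:", des$beta_names[j]), mean = mu, sd = sd,
      q2.5 = stats::qnorm(0.025, mu, sd), q97.5 = stats::qnorm(0.975, mu, sd))
  }
  for (g in seq_along(des$gauss_markers)) {
    r <- des$gauss_markers[g]
    N_r <- unname(des$N_r[r])
    shape <- 0.5 * (N_r + 1); rate <- st$B_sig2[g]
    if (object$state$frozen$sigma2) next
    rows[[length(rows) + 1]] <- data.frame(
      parameter = paste0("sigma2:", names(des$specs)[r]),
      mean = rate / (shape - 1),
      sd = if (shape > 2) rate / ((shape - 1) * sqrt(shape - 2)) else NA_real_,
      q2.5 = qinvgamma(0.025, shape, rate),
      q97.5 = qinvgamma(0.975, shape, rate))
  }
  if (!st$frozen$Sigma_R) {
    q <- des$q
    kap <- object$priors$nu + q + des$m - 1
    B <- st$B_Sigma_R
    for (i in seq_len(q)) for (j in i:q) {
      vv <- ((kap - q + 1) * B[i, j]^2 + (kap - q - 1) * B[i, i] * B[j, j]) /
        ((kap - q) * (kap - q - 1)^2 * (kap - q - 3))
      rows[[length(rows) + 1]] <- data.frame(
        parameter = sprintf("Sigma_R[%d,%d]", i, j),
        mean = B[i, j] / (kap - q - 1),
        sd = if (kap - q - 3 > 0) sqrt(vv) else NA_real_,
        q2.5 = NA_real_, q97.5 = NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fitted per-observation trajectories
#'
#' Link-scale fit \eqn{x_j^T \mu_{q(\beta)} + z_j^T \mu_{q(u_i)}} and
#' its inverse-link transform (identity / exp / expit), per observation
#' row of the fitted design, in the same row order as the canonical
#' dataset.
#'
#' @param fit An `mglmm_fit`.
#' @param subjects Optional subset of subject ids.
#' @return Data frame: `subject`, `marker`, `observed`, `eta` (link
#'   scale) and `fitted` (response scale).
#' @export
predict_trajectories <- function(fit, subjects = NULL) {
  des <- fit$design
  st <- fit$state
  eta <- drop(des$X %*% st$mu_beta)
  for (i in seq_len(des$m))
    eta[des$rows[[i]]] <- eta[des$rows[[i]]] +
      drop(des$Zi[[i]] %*% st$mu_u[, i])
  fitted <- eta
  for (tag in unique(des$fam_tags)) {
    idx <- which(des$row_family == tag)
    fitted[idx] <- glmm_family(tag)$linkinv(eta[idx])
  }
  out <- data.frame(subject = des$subjects[des$row_subject],
                    marker = names(des$specs)[des$row_marker],
                    observed = des$y, eta = eta, fitted = fitted)
  if (!is.null(subjects)) {
    if (!all(subjects %in% des$subjects))
      stop_config("unknown subject id(s) in 'subjects'")
    out <- out[out$subject %in% subjects, , drop = FALSE]
  }
  out
}
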