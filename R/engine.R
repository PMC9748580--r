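## Coordinate-ascent mean field variational Bayes engine.
##
## The variational family is
##   q(beta, u) q(Sigma_R) prod_r { q(sigma2_eps_r) q(a_eps_r) } prod_k q(a_k),
## with q(beta, u) Gaussian (exact for all-Gaussian markers, fixed-form
## semiparametric otherwise), q(Sigma_R) inverse-Wishart and all scalar
## factors inverse-gamma.  The (beta, u) update never forms the full
## (p + mq) covariance: the precision is block-diagonal-plus-border, so
## a rank-structured inverse gives per-subject blocks at O(m) cost with
## cubic work only in p and q.

symmetrize <- function(A) (A + t(A)) / 2

chol_or_fail <- function(A, what, state = NULL) {
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch))
    stop_numeric("matrix not positive definite in ", what, state = state)
  ch
}

log_mvgamma <- function(a, q) {
  (q * (q - 1) / 4) * log(pi) + sum(lgamma(a + (1 - seq_len(q)) / 2))
}

expand_priors <- function(priors, design) {
  ng <- length(design$gauss_markers)
  A_k <- rep_len(priors$A_k, design$q)
  A_eps <- if (ng) rep_len(priors$A_eps, ng) else numeric(0)
  list(sigma2_beta = priors$sigma2_beta, nu = priors$nu,
       A_k = A_k, A_eps = A_eps)
}

#' Initialize the variational state
#'
#' Identity / zero initialization: \eqn{M_{q(\Sigma_R^{-1})} = I_q},
#' all inverse-moment scalars set to 1, \eqn{\mu_{q(\beta)} = 0},
#' \eqn{\Sigma_{q(\beta)} = I_p}, \eqn{\mu_{q(u_i)} = 0},
#' \eqn{\Sigma_{q(u_i)} = I_q}.
#'
#' @param design An `mglmm_design`.
#' @param priors A [prior_config()].
#' @return A `mglmm_state` list of variational parameters.
#' @export
initialize_state <- function(design, priors = prior_config()) {
  p <- design$p; q <- design$q; m <- design$m
  ng <- length(design$gauss_markers)
  structure(list(
    mu_beta = numeric(p),
    Sigma_beta = diag(p),
    mu_u = matrix(0, q, m),
    Sigma_u = rep(list(diag(q)), m),
    M_q_inv = diag(q),                    # E_q[Sigma_R^{-1}]
    B_Sigma_R = diag(q),
    mu_inv_sig2 = rep(1, ng),             # E_q[1/sigma2_eps_r]
    B_sig2 = rep(NA_real_, ng),
    mu_inv_a_eps = rep(1, ng),
    B_a_eps = rep(NA_real_, ng),
    mu_inv_a = rep(1, q),
    B_a = rep(NA_real_, q),
    frozen = list(Sigma_R = FALSE, sigma2 = FALSE),
    sigma2_fixed = NULL,
    work = NULL
  ), class = "mglmm_state")
}

## per-row diagonal of E[Sigma_eps^{-1}]: E[1/sigma2_eps_r] on Gaussian
## rows, 1 elsewhere
einv_rows <- function(state, design) {
  e <- rep(1, design$N)
  for (g in seq_along(design$gauss_markers)) {
    r <- design$gauss_markers[g]
    val <- if (state$frozen$sigma2) 1 / state$sigma2_fixed[g] else state$mu_inv_sig2[g]
    e[design$row_marker == r] <- val
  }
  e
}

## family moments of the linear predictor for every row
row_moments <- function(design, pm, basis = ms_basis()) {
  b1 <- numeric(design$N); b2 <- numeric(design$N)
  for (tag in unique(design$fam_tags)) {
    idx <- which(design$row_family == tag)
    if (!length(idx)) next
    mm <- cumulant_moments(tag, pm$mu[idx], pm$sigma2[idx], basis)
    b1[idx] <- mm$b1; b2[idx] <- mm$b2
  }
  list(b1 = b1, b2 = b2)
}

#' One streamlined update of the Gaussian factor q(beta, u)
#'
#' Natural-parameter coordinate update of the joint Gaussian factor
#' without ever forming the \eqn{(p + mq)} covariance.  Per subject,
#' with \eqn{W_i = E[\Sigma_{\varepsilon_i}^{-1}]\,
#' \mathrm{diag}(E[b''])_i}: \eqn{G_i = X_i^T W_i Z_i},
#' \eqn{H_i = (Z_i^T W_i Z_i + M_{q(\Sigma_R^{-1})})^{-1}}, border
#' corrections \eqn{S = \sum_i G_i H_i G_i^T} and \eqn{s = \sum_i G_i
#' H_i (M_{q(\Sigma_R^{-1})} \mu_{q(u_i)} - Z_i^T e_i)} with working
#' residual \eqn{e = E[\Sigma_\varepsilon^{-1}](y - E[b'])}; then
#' \eqn{\Sigma_{q(\beta)} = (X^T W X + \sigma_\beta^{-2} I_p - S)^{-1}},
#' the mean step on \eqn{\mu_{q(\beta)}}, and per subject
#' \eqn{\Sigma_{q(u_i)} = H_i + H_i G_i^T \Sigma_{q(\beta)} G_i H_i}
#' plus the mean step on \eqn{\mu_{q(u_i)}} carrying the
#' \eqn{-G_i^T(\mu_{q(\beta)} - \mu_{q(\beta)}^{old})} coupling.
#'
#' @param state Current `mglmm_state`.
#' @param design An `mglmm_design`.
#' @param moments List with per-row `b1`, `b2` (computed from the
#'   current state's predictor moments).
#' @param priors A [prior_config()].
#' @param damping Step factor in `(0, 1]` on the mean updates.
#' @return Updated state; the per-subject workspace (`G_i H_i`,
#'   \eqn{H_i}, \eqn{\Sigma_{q(\beta)} G_i H_i}, log-determinants) is
#'   retained for the predictor-moment and lower-bound computations.
#' @export
update_beta_u_streamlined <- function(state, design, moments,
                                      priors = prior_config(), damping = 1) {
  p <- design$p; m <- design$m
  pri <- expand_priors(priors, design)
  einv <- einv_rows(state, design)
  w <- einv * moments$b2
  e <- einv * (design$y - moments$b1)
  Mq <- state$M_q_inv

  A <- crossprod(design$X, design$X * w)
  S <- matrix(0, p, p)
  svec <- numeric(p)
  GiHi <- vector("list", m); Hi <- vector("list", m)
  logdetH <- numeric(m)
  Zte <- vector("list", m)
  for (i in seq_len(m)) {
    idx <- design$rows[[i]]
    Zi <- design$Zi[[i]]; Xi <- design$Xi[[i]]
    WZ <- Zi * w[idx]
    Gi <- crossprod(Xi, WZ)
    ch <- chol_or_fail(symmetrize(crossprod(Zi, WZ)) + Mq,
                       paste0("H block of subject ", i), state)
    H <- chol2inv(ch)
    logdetH[i] <- -2 * sum(log(diag(ch)))
    GH <- Gi %*% H
    S <- S + tcrossprod(GH, Gi)
    Zte[[i]] <- crossprod(Zi, e[idx])
    svec <- svec + GH %*% (Mq %*% state$mu_u[, i] - Zte[[i]])
    GiHi[[i]] <- GH; Hi[[i]] <- H
  }

  prec_beta <- symmetrize(A + diag(1 / pri$sigma2_beta, p) - S)
  ch_b <- chol_or_fail(prec_beta, "Sigma_q(beta)", state)
  Sigma_beta <- symmetrize(chol2inv(ch_b))
  mu_beta_old <- state$mu_beta
  grad_beta <- crossprod(design$X, e) - mu_beta_old / pri$sigma2_beta + svec
  mu_beta <- mu_beta_old + damping * drop(Sigma_beta %*% grad_beta)
  delta_beta <- mu_beta - mu_beta_old

  Ti <- vector("list", m)
  mu_u <- state$mu_u
  Sigma_u <- state$Sigma_u
  for (i in seq_len(m)) {
    GH <- GiHi[[i]]; H <- Hi[[i]]
    T_i <- Sigma_beta %*% GH                       # p x q
    Ti[[i]] <- T_i
    Sigma_u[[i]] <- symmetrize(H + crossprod(GH, T_i))
    ## H_i G_i^T = (G_i H_i)^T because H_i is symmetric
    mu_u[, i] <- mu_u[, i] +
      damping * drop(H %*% (Zte[[i]] - Mq %*% mu_u[, i])) -
      drop(crossprod(GH, delta_beta))
  }

  state$mu_beta <- mu_beta
  state$Sigma_beta <- Sigma_beta
  state$mu_u <- mu_u
  state$Sigma_u <- Sigma_u
  state$work <- list(GiHi = GiHi, Hi = Hi, Ti = Ti, logdetH = logdetH,
                     logdet_total = sum(logdetH) - 2 * sum(log(diag(ch_b))))
  state
}

#' Mean and variance of the linear predictor per observation row
#'
#' \eqn{\mu = X \mu_{q(\beta)} + Z_i \mu_{q(u_i)}} (stacked) and
#' \eqn{\sigma^2_{row} = \mathrm{diag}(X \Sigma_{q(\beta)} X^T)
#' - 2\,\mathrm{diag}(X_i \Sigma_{q(\beta)} G_i H_i Z_i^T)
#' + \mathrm{diag}(Z_i \Sigma_{q(u_i)} Z_i^T)}, using the streamlined
#' covariance blocks (the cross term vanishes before the first cycle
#' when no workspace exists yet).  Variances are clamped at zero.
#'
#' @param state Current `mglmm_state`.
#' @param design An `mglmm_design`.
#' @return List with per-row numeric vectors `mu` and `sigma2`.
#' @export
update_predictor_moments <- function(state, design) {
  mu <- drop(design$X %*% state$mu_beta)
  sigma2 <- rowSums((design$X %*% state$Sigma_beta) * design$X)
  for (i in seq_len(design$m)) {
    idx <- design$rows[[i]]
    Zi <- design$Zi[[i]]
    mu[idx] <- mu[idx] + drop(Zi %*% state$mu_u[, i])
    cross <- if (!is.null(state$work$Ti))
      -2 * rowSums((design$Xi[[i]] %*% state$work$Ti[[i]]) * Zi)
    else 0
    sigma2[idx] <- sigma2[idx] + cross + rowSums((Zi %*% state$Sigma_u[[i]]) * Zi)
  }
  neg <- sigma2 < 0
  if (any(neg)) {
    if (any(sigma2 < -1e-6))
      warning("predictor variances clamped at zero (most negative: ",
              format(min(sigma2)), ")")
    sigma2[neg] <- 0
  }
  list(mu = mu, sigma2 = sigma2)
}

#' Update the residual-variance factors of the Gaussian markers
#'
#' For each Gaussian marker \eqn{r}:
#' \eqn{B_{q(\sigma^2_{\varepsilon r})} = \mu_{q(1/a_{\varepsilon r})}
#' + \frac12 \{\|y_r - C_r \mu\|^2 + \mathrm{tr}(C_r^T C_r \Sigma)\}}
#' (the bracket is \eqn{\sum_j (y_j - \mu_j)^2 + \sigma^2_j} over the
#' marker's rows), \eqn{\mu_{q(1/\sigma^2_{\varepsilon r})} =
#' \frac12(\sum_i n_{ir} + 1) / B_{q(\sigma^2_{\varepsilon r})}}, then
#' the auxiliary \eqn{B_{q(a_{\varepsilon r})} =
#' \mu_{q(1/\sigma^2_{\varepsilon r})} + A_{\varepsilon r}^{-2}} and
#' \eqn{\mu_{q(1/a_{\varepsilon r})} = 1 / B_{q(a_{\varepsilon r})}}.
#' A no-op when the model has no Gaussian marker.
#'
#' @param state Current `mglmm_state`.
#' @param design An `mglmm_design`.
#' @param pred_moments Predictor moments from
#'   [update_predictor_moments()] at the current state.
#' @param priors A [prior_config()].
#' @return Updated state.
#' @export
update_residual_variances <- function(state, design, pred_moments,
                                      priors = prior_config()) {
  pri <- expand_priors(priors, design)
  for (g in seq_along(design$gauss_markers)) {
    r <- design$gauss_markers[g]
    idx <- which(design$row_marker == r)
    ss <- sum((design$y[idx] - pred_moments$mu[idx])^2 + pred_moments$sigma2[idx])
    B <- state$mu_inv_a_eps[g] + ss / 2
    state$B_sig2[g] <- B
    state$mu_inv_sig2[g] <- 0.5 * (length(idx) + 1) / B
    state$B_a_eps[g] <- state$mu_inv_sig2[g] + pri$A_eps[g]^-2
    state$mu_inv_a_eps[g] <- 1 / state$B_a_eps[g]
  }
  state
}

#' Update the covariance-prior auxiliary factors
#'
#' \eqn{B_{q(a_k)} = \nu M_{q(\Sigma_R^{-1})kk} + A_k^{-2}} and
#' \eqn{\mu_{q(1/a_k)} = \frac12(\nu + q) / B_{q(a_k)}} for each of the
#' \eqn{q} random effects.
#'
#' @inheritParams update_residual_variances
#' @return Updated state.
#' @export
update_auxiliaries <- function(state, design, priors = prior_config()) {
  pri <- expand_priors(priors, design)
  q <- design$q
  state$B_a <- pri$nu * diag(state$M_q_inv) + pri$A_k^-2
  state$mu_inv_a <- 0.5 * (pri$nu + q) / state$B_a
  state
}

#' Update the inverse-Wishart factor of the random-effects covariance
#'
#' \eqn{B_{q(\Sigma_R)} = \sum_i (\mu_{q(u_i)} \mu_{q(u_i)}^T +
#' \Sigma_{q(u_i)}) + 2 \nu\, \mathrm{diag}(\mu_{q(1/a_1)}, \dots,
#' \mu_{q(1/a_q)})} and \eqn{M_{q(\Sigma_R^{-1})} = (\nu + q + m - 1)
#' B_{q(\Sigma_R)}^{-1}}.
#'
#' @inheritParams update_residual_variances
#' @return Updated state.
#' @export
update_random_effects_covariance <- function(state, design, priors = prior_config()) {
  pri <- expand_priors(priors, design)
  q <- design$q; m <- design$m
  B <- tcrossprod(state$mu_u) + Reduce(`+`, state$Sigma_u) +
    2 * pri$nu * diag(state$mu_inv_a, q)
  B <- symmetrize(B)
  ch <- chol_or_fail(B, "B_q(Sigma_R)", state)
  state$B_Sigma_R <- B
  state$M_q_inv <- symmetrize((pri$nu + q + m - 1) * chol2inv(ch))
  state$logdet_B_Sigma_R <- 2 * sum(log(diag(ch)))
  state
}

#' Variational lower bound on the log marginal likelihood
#'
#' Assembles \eqn{\log \underline{p}(y, q) = E_q[\log p(y, \theta)] -
#' E_q[\log q(\theta)]} term by term: the expected exponential-family
#' log likelihood (exact for Gaussian and Poisson rows; through the
#' probit-mixture surrogate of \eqn{E[\log(1 + e^\eta)]} for binary
#' rows, whose gradient matches the moments used in the updates),
#' Gaussian prior and entropy of \eqn{(\beta, u)}, and inverse-Wishart
#' / inverse-gamma cross-entropy and entropy terms for \eqn{\Sigma_R},
#' the residual variances and their auxiliaries.  All constants are
#' kept, so traces are comparable across runs.  Components frozen at
#' fixed values (see [fit_mglmm()]) contribute only through the
#' likelihood.
#'
#' @param state Current `mglmm_state` (after a full cycle).
#' @param design An `mglmm_design`.
#' @param priors A [prior_config()].
#' @param pred_moments Predictor moments at the current state.
#' @param basis Probit-mixture basis.
#' @return Scalar lower bound.
#' @export
compute_elbo <- function(state, design, priors = prior_config(),
                         pred_moments = update_predictor_moments(state, design),
                         basis = ms_basis()) {
  pri <- expand_priors(priors, design)
  p <- design$p; q <- design$q; m <- design$m
  nu <- pri$nu
  kap0 <- nu + q - 1
  kap <- nu + q + m - 1
  pm <- pred_moments
  y <- design$y
  elbo <- 0

  ## expected log-likelihood
  for (g in seq_along(design$gauss_markers)) {
    r <- design$gauss_markers[g]
    idx <- which(design$row_marker == r)
    N_r <- length(idx)
    ss <- sum((y[idx] - pm$mu[idx])^2 + pm$sigma2[idx])
    if (state$frozen$sigma2) {
      einv <- 1 / state$sigma2_fixed[g]
      elog <- log(state$sigma2_fixed[g])
    } else {
      alpha_r <- 0.5 * (N_r + 1)
      einv <- state$mu_inv_sig2[g]
      elog <- log(state$B_sig2[g]) - digamma(alpha_r)
    }
    elbo <- elbo - 0.5 * N_r * (log(2 * pi) + elog) - 0.5 * einv * ss
  }
  pois <- which(design$row_family == "poisson")
  if (length(pois))
    elbo <- elbo + sum(y[pois] * pm$mu[pois] -
                         exp(pm$mu[pois] + pm$sigma2[pois] / 2) -
                         lgamma(y[pois] + 1))
  bern <- which(design$row_family == "bernoulli")
  if (length(bern))
    elbo <- elbo + sum(y[bern] * pm$mu[bern] -
                         expected_log1pexp(pm$mu[bern], pm$sigma2[bern], basis))

  ## Gaussian prior on beta
  elbo <- elbo - 0.5 * p * log(2 * pi * pri$sigma2_beta) -
    (sum(state$mu_beta^2) + sum(diag(state$Sigma_beta))) / (2 * pri$sigma2_beta)

  ## random effects: E[log p(u | Sigma_R)]
  Mq <- state$M_q_inv
  SSu <- tcrossprod(state$mu_u) + Reduce(`+`, state$Sigma_u)
  if (state$frozen$Sigma_R) {
    elogdet_inv <- determinant(Mq, logarithm = TRUE)$modulus[1]
  } else {
    ldB <- if (!is.null(state$logdet_B_Sigma_R)) state$logdet_B_Sigma_R else
      determinant(state$B_Sigma_R, logarithm = TRUE)$modulus[1]
    elogdet_inv <- sum(digamma((kap + 1 - seq_len(q)) / 2)) + q * log(2) - ldB
  }
  elbo <- elbo - 0.5 * m * q * log(2 * pi) + 0.5 * m * elogdet_inv -
    0.5 * sum(Mq * SSu)

  ## entropy of q(beta, u): 0.5 log|Sigma| + dim/2 (1 + log 2 pi)
  if (is.null(state$work))
    stop_numeric("compute_elbo requires the workspace of a (beta, u) update")
  elbo <- elbo + 0.5 * state$work$logdet_total +
    0.5 * (p + m * q) * (1 + log(2 * pi))

  ## Sigma_R, a_k terms (skipped when Sigma_R frozen at a point mass)
  if (!state$frozen$Sigma_R) {
    elog_a <- log(state$B_a) - digamma(0.5 * (nu + q))
    einv_a <- state$mu_inv_a
    ## E[log p(Sigma_R | a)]
    elbo <- elbo + 0.5 * kap0 * (q * log(2 * nu) - sum(elog_a)) -
      0.5 * kap0 * q * log(2) - log_mvgamma(kap0 / 2, q) +
      0.5 * (kap0 + q + 1) * elogdet_inv -
      nu * sum(einv_a * diag(Mq))
    ## E[log p(a_k)] with IG(1/2, A_k^{-2})
    elbo <- elbo + sum(-log(pri$A_k) - lgamma(0.5) - 1.5 * elog_a -
                         pri$A_k^-2 * einv_a)
    ## entropy of q(Sigma_R) = IW(kap, B)
    elbo <- elbo - 0.5 * kap * ldB + 0.5 * kap * q * log(2) +
      log_mvgamma(kap / 2, q) - 0.5 * (kap + q + 1) * elogdet_inv +
      0.5 * kap * q
    ## entropy of q(a_k) = IG((nu+q)/2, B_a)
    alpha_a <- 0.5 * (nu + q)
    elbo <- elbo + sum(alpha_a + log(state$B_a) + lgamma(alpha_a) -
                         (1 + alpha_a) * digamma(alpha_a))
  }

  ## residual variance and auxiliary terms
  if (!state$frozen$sigma2) {
    for (g in seq_along(design$gauss_markers)) {
      r <- design$gauss_markers[g]
      N_r <- sum(design$row_marker == r)
      alpha_r <- 0.5 * (N_r + 1)
      elog_s <- log(state$B_sig2[g]) - digamma(alpha_r)
      einv_s <- state$mu_inv_sig2[g]
      elog_ae <- log(state$B_a_eps[g]) - digamma(1)
      einv_ae <- state$mu_inv_a_eps[g]
      ## E[log p(sigma2 | a_eps)], IG(1/2, 1/a_eps)
      elbo <- elbo - 0.5 * elog_ae - lgamma(0.5) - 1.5 * elog_s - einv_ae * einv_s
      ## E[log p(a_eps)], IG(1/2, A_eps^{-2})
      elbo <- elbo - log(pri$A_eps[g]) - lgamma(0.5) - 1.5 * elog_ae -
        pri$A_eps[g]^-2 * einv_ae
      ## entropies of q(sigma2) = IG(alpha_r, B) and q(a_eps) = IG(1, B)
      elbo <- elbo + alpha_r + log(state$B_sig2[g]) + lgamma(alpha_r) -
        (1 + alpha_r) * digamma(alpha_r)
      elbo <- elbo + 1 + log(state$B_a_eps[g]) + lgamma(1) - 2 * digamma(1)
    }
  }
  as.numeric(elbo)
}

apply_fixed <- function(state, design, fixed) {
  if (is.null(fixed)) return(state)
  if (!is.null(fixed$Sigma_R)) {
    Sig <- as.matrix(fixed$Sigma_R)
    if (nrow(Sig) != design$q || ncol(Sig) != design$q)
      stop_config("fixed$Sigma_R must be q x q")
    state$M_q_inv <- symmetrize(chol2inv(chol_or_fail(Sig, "fixed Sigma_R")))
    state$frozen$Sigma_R <- TRUE
  }
  if (!is.null(fixed$sigma2_eps)) {
    ng <- length(design$gauss_markers)
    s2 <- rep_len(fixed$sigma2_eps, ng)
    if (any(s2 <= 0)) stop_config("fixed residual variances must be positive")
    state$sigma2_fixed <- s2
    state$frozen$sigma2 <- TRUE
  }
  state
}

run_mfvb <- function(design, priors, control, fixed, stepper) {
  state <- apply_fixed(initialize_state(design, priors), design, fixed)
  pm <- update_predictor_moments(state, design)
  elbo_trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < control$max_iter) {
    it <- it + 1L
    res <- stepper(state, pm)
    state <- res$state; pm <- res$pm
    elbo <- compute_elbo(state, design, priors, pm)
    if (!is.finite(elbo))
      stop_numeric("variational lower bound became non-finite at iteration ", it,
                   state = state)
    elbo_trace <- c(elbo_trace, elbo)
    rel <- if (it >= 2L) abs(elbo - elbo_trace[it - 1L]) / (1 + abs(elbo)) else NA_real_
    if (control$verbose)
      message(sprintf("iter %4d  elbo %.8f  rel_change %s", it, elbo,
                      if (is.na(rel)) "NA" else format(rel, digits = 3)))
    if (!is.na(rel) && rel < control$tolerance) { converged <- TRUE; break }
  }
  list(state = state, elbo = elbo_trace, converged = converged, iterations = it)
}

#' Fit a multivariate GLMM by streamlined mean field variational Bayes
#'
#' Runs the coordinate-ascent cycle — joint \eqn{(\beta, u)} Gaussian
#' factor, predictor and family moments, Gaussian residual variances,
#' covariance-prior auxiliaries, random-effects covariance — until the
#' relative change of the variational lower bound falls below
#' `control$tolerance` or `control$max_iter` cycles are reached.  The
#' fit is deterministic.  For all-Gaussian models each cycle is an
#' exact coordinate-ascent step and the lower bound is non-decreasing;
#' with Poisson or binary markers the Gaussian \eqn{(\beta, u)} factor
#' is a fixed-form choice and monotonicity is not guaranteed, so
#' non-convergence within `max_iter` returns the final state with
#' `converged = FALSE` rather than failing.
#'
#' @param dataset An `mglmm_data` (from [read_long_table()] or
#'   [simulate_mglmm()]) or a pre-built `mglmm_design`.
#' @param priors A [prior_config()].
#' @param control A [fit_control()].
#' @param fixed Optional list freezing variance components at known
#'   values: `Sigma_R` (q x q matrix) and/or `sigma2_eps` (one value
#'   per Gaussian marker).  Frozen components are held at point masses
#'   and not updated — useful for empirical-Bayes style fits and for
#'   conjugate-limit checks.
#' @return An object of class `mglmm_fit`.
#' @export
fit_mglmm <- function(dataset, priors = prior_config(),
                      control = fit_control(), fixed = NULL) {
  design <- if (inherits(dataset, "mglmm_design")) dataset else build_design(dataset)
  stepper <- function(state, pm) {
    mom <- row_moments(design, pm)
    state <- update_beta_u_streamlined(state, design, mom, priors, control$damping)
    pm <- update_predictor_moments(state, design)
    if (!state$frozen$sigma2 && length(design$gauss_markers))
      state <- update_residual_variances(state, design, pm, priors)
    if (!state$frozen$Sigma_R) {
      state <- update_auxiliaries(state, design, priors)
      state <- update_random_effects_covariance(state, design, priors)
    }
    list(state = state, pm = pm)
  }
  out <- run_mfvb(design, priors, control, fixed, stepper)
  new_mglmm_fit(out, design, priors, control, method = "streamlined")
}

new_mglmm_fit <- function(out, design, priors, control, method) {
  structure(list(state = out$state, design = design, priors = priors,
                 control = control, elbo = out$elbo,
                 converged = out$converged, iterations = out$iterations,
                 method = method),
            class = "mglmm_fit")
}

#' @export
print.mglmm_fit <- function(x, ...) {
  cat(sprintf("mglmm_fit (%s): m = %d subjects, p = %d fixed effects, q = %d random effects\n",
              x$method, x$design$m, x$design$p, x$design$q))
  cat(sprintf("  %s after %d iterations; final lower bound %.4f\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, utils::tail(x$elbo, 1)))
  invisible(x)
}
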