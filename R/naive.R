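#' Fit by naive full-matrix mean field variational Bayes
#'
#' Performs exactly the same variational updates as [fit_mglmm()] but
#' on the full \eqn{(p + mq)}-dimensional mean and covariance of
#' \eqn{q(\beta, u)}, forming and inverting the dense precision matrix
#' each cycle.  Mathematically identical to the streamlined path — it
#' exists as an internal equivalence oracle and for didactic use — but
#' its cost is cubic in \eqn{p + mq}, so it refuses problems with
#' \eqn{p + mq > 2000}.
#'
#' @inheritParams fit_mglmm
#' @return An object of class `mglmm_fit` whose `state` carries, in
#'   addition to the block quantities, the full mean `mu_full` and
#'   covariance `Sigma_full`.
#' @export
fit_mglmm_naive <- function(dataset, priors = prior_config(),
                            control = fit_control(), fixed = NULL) {
  design <- if (inherits(dataset, "mglmm_design")) dataset else build_design(dataset)
  p <- design$p; q <- design$q; m <- design$m
  dim_full <- p + m * q
  if (dim_full > 2000)
    stop_config("naive fitter refused: p + mq = ", dim_full,
                " exceeds the dense-solve guard of 2000")

  ## dense C = [X Z] with u blocks grouped by subject
  C <- matrix(0, design$N, dim_full)
  C[, seq_len(p)] <- design$X
  for (i in seq_len(m))
    C[design$rows[[i]], p + (i - 1L) * q + seq_len(q)] <- design$Zi[[i]]

  u_cols <- function(i) p + (i - 1L) * q + seq_len(q)

  extract_blocks <- function(state) {
    state$mu_beta <- state$mu_full[seq_len(p)]
    state$Sigma_beta <- symmetrize(state$Sigma_full[seq_len(p), seq_len(p), drop = FALSE])
    for (i in seq_len(m)) {
      ci <- u_cols(i)
      state$mu_u[, i] <- state$mu_full[ci]
      state$Sigma_u[[i]] <- symmetrize(state$Sigma_full[ci, ci, drop = FALSE])
    }
    state
  }

  pred_full <- function(state) {
    list(mu = drop(C %*% state$mu_full),
         sigma2 = pmax(rowSums((C %*% state$Sigma_full) * C), 0))
  }

  pri <- expand_priors(priors, design)
  stepper <- function(state, pm) {
    if (is.null(state$mu_full)) {            # first cycle: identity init
      state$mu_full <- numeric(dim_full)
      state$Sigma_full <- diag(dim_full)
    }
    mom <- row_moments(design, pm)
    einv <- einv_rows(state, design)
    w <- einv * mom$b2
    e <- einv * (design$y - mom$b1)
    prec <- crossprod(C, C * w)
    prec[seq_len(p), seq_len(p)] <- prec[seq_len(p), seq_len(p)] +
      diag(1 / pri$sigma2_beta, p)
    Dmu <- numeric(dim_full)
    Dmu[seq_len(p)] <- state$mu_full[seq_len(p)] / pri$sigma2_beta
    for (i in seq_len(m)) {
      ci <- u_cols(i)
      prec[ci, ci] <- prec[ci, ci] + state$M_q_inv
      Dmu[ci] <- state$M_q_inv %*% state$mu_full[ci]
    }
    ch <- chol_or_fail(symmetrize(prec), "full (beta, u) precision", state)
    Sigma_full <- symmetrize(chol2inv(ch))
    state$Sigma_full <- Sigma_full
    state$mu_full <- state$mu_full +
      control$damping * drop(Sigma_full %*% (crossprod(C, e) - Dmu))
    state$work <- list(logdet_total = -2 * sum(log(diag(ch))))
    state <- extract_blocks(state)

    pm <- pred_full(state)
    if (!state$frozen$sigma2 && length(design$gauss_markers))
      state <- update_residual_variances(state, design, pm, priors)
    if (!state$frozen$Sigma_R) {
      state <- update_auxiliaries(state, design, priors)
      state <- update_random_effects_covariance(state, design, priors)
    }
    list(state = state, pm = pm)
  }

  out <- run_mfvb(design, priors, control, fixed, stepper)
  new_mglmm_fit(out, design, priors, control, method = "naive")
}
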