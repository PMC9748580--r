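#' Serialize a fit to a structured JSON file
#'
#' Writes every variational parameter (fixed-effect mean and
#' covariance, per-subject random-effect means and covariances,
#' inverse-Wishart and inverse-gamma factors), the lower-bound trace,
#' the priors and the convergence status, together with the marker
#' specifications needed to rebuild summaries.
#'
#' @param fit An `mglmm_fit`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fit_json <- function(fit, path) {
  st <- fit$state
  des <- fit$design
  obj <- list(
    package = "mglmmvb", format = 1L, method = fit$method,
    converged = fit$converged, iterations = fit$iterations,
    elbo = fit$elbo,
    markers = lapply(des$specs, function(sp)
      list(name = sp$name, family = sp$family$family,
           fixed = sp$fixed, random = sp$random)),
    subjects = as.character(des$subjects),
    n_ir = apply(des$n_ir, 1, as.integer, simplify = FALSE),
    priors = unclass(fit$priors),
    control = unclass(fit$control),
    frozen = st$frozen,
    sigma2_fixed = st$sigma2_fixed,
    state = list(
      mu_beta = st$mu_beta,
      Sigma_beta = apply(st$Sigma_beta, 1, as.numeric, simplify = FALSE),
      mu_u = apply(st$mu_u, 2, as.numeric, simplify = FALSE),
      Sigma_u = lapply(st$Sigma_u, function(S) apply(S, 1, as.numeric, simplify = FALSE)),
      B_Sigma_R = apply(st$B_Sigma_R, 1, as.numeric, simplify = FALSE),
      M_q_inv = apply(st$M_q_inv, 1, as.numeric, simplify = FALSE),
      B_sig2 = st$B_sig2, mu_inv_sig2 = st$mu_inv_sig2,
      B_a_eps = st$B_a_eps, mu_inv_a_eps = st$mu_inv_a_eps,
      B_a = st$B_a, mu_inv_a = st$mu_inv_a))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Rebuild a fit from its JSON serialization
#'
#' Restores the variational state written by [write_fit_json()].  If
#' the original long-format data are supplied the full design is
#' rebuilt and the fit supports every downstream operation (including
#' [predict_trajectories()]); without data, a reduced design carrying
#' dimensions, coefficient names and per-marker counts is attached,
#' which is sufficient for [summary.mglmm_fit()] and [q_marginals()].
#'
#' @param path JSON path written by [write_fit_json()].
#' @param data Optional: the long-format table (path or data frame)
#'   the fit was estimated from.
#' @param ... Passed to [read_long_table()] when `data` is given.
#' @return An `mglmm_fit`.
#' @export
read_fit_json <- function(path, data = NULL, ...) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$package) || obj$package != "mglmmvb")
    stop_config("not a mglmmvb fit file: ", path)
  markers <- if (is.data.frame(obj$markers))
    lapply(seq_len(nrow(obj$markers)), function(r) as.list(obj$markers[r, ]))
  else obj$markers
  specs <- lapply(markers, function(mk)
    marker_spec(unlist(mk$name), unlist(mk$family),
                fixed = unlist(mk$fixed), random = unlist(mk$random)))
  marker_names <- vapply(specs, `[[`, "", "name")
  names(specs) <- marker_names

  if (!is.null(data)) {
    design <- build_design(read_long_table(data, specs, ...))
  } else {
    n_ir <- if (is.matrix(obj$n_ir)) obj$n_ir else do.call(rbind, obj$n_ir)
    colnames(n_ir) <- marker_names
    p_r <- vapply(specs, `[[`, 0L, "p_r")
    q_r <- vapply(specs, `[[`, 0L, "q_r")
    design <- structure(list(
      m = length(obj$subjects), R = length(specs),
      p = sum(p_r), q = sum(q_r), p_r = p_r, q_r = q_r,
      beta_names = unlist(lapply(specs, function(sp) paste(sp$name, sp$fixed, sep = ":"))),
      u_names = unlist(lapply(specs, function(sp) paste(sp$name, sp$random, sep = ":"))),
      subjects = obj$subjects, specs = specs,
      gauss_markers = which(vapply(specs, function(s) s$family$family, "") == "gaussian"),
      n_ir = n_ir, N_r = colSums(n_ir)), class = "mglmm_design")
  }

  s <- obj$state
  Sigma_u <- if (is.array(s$Sigma_u) && length(dim(s$Sigma_u)) == 3)
    lapply(seq_len(dim(s$Sigma_u)[1]), function(i) s$Sigma_u[i, , ])
  else lapply(s$Sigma_u, as.matrix)
  state <- structure(list(
    mu_beta = as.numeric(s$mu_beta),
    Sigma_beta = as.matrix(s$Sigma_beta),
    mu_u = t(as.matrix(s$mu_u)),
    Sigma_u = Sigma_u,
    M_q_inv = as.matrix(s$M_q_inv),
    B_Sigma_R = as.matrix(s$B_Sigma_R),
    B_sig2 = as.numeric(s$B_sig2), mu_inv_sig2 = as.numeric(s$mu_inv_sig2),
    B_a_eps = as.numeric(s$B_a_eps), mu_inv_a_eps = as.numeric(s$mu_inv_a_eps),
    B_a = as.numeric(s$B_a), mu_inv_a = as.numeric(s$mu_inv_a),
    frozen = list(Sigma_R = isTRUE(obj$frozen$Sigma_R),
                  sigma2 = isTRUE(obj$frozen$sigma2)),
    sigma2_fixed = obj$sigma2_fixed,
    work = NULL), class = "mglmm_state")

  priors <- do.call(prior_config, obj$priors)
  control <- do.call(fit_control, obj$control[c("tolerance", "max_iter", "damping", "verbose")])
  structure(list(state = state, design = design, priors = priors,
                 control = control, elbo = as.numeric(obj$elbo),
                 converged = isTRUE(obj$converged),
                 iterations = obj$iterations, method = obj$method),
            class = "mglmm_fit")
}
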