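#' Generating truths for the two benchmark simulation scenarios
#'
#' Both scenarios share three markers, each with a fixed intercept and
#' slope on a scaled time covariate `x`, a random intercept and random
#' slope per marker (so \eqn{q = 6}), and one joint \eqn{6 \times 6}
#' random-effects covariance across the markers.  Scenario 1 has three
#' Gaussian markers with residual variances \eqn{(0.1, 0.25, 0.15)};
#' scenario 2 keeps marker 1 Gaussian but makes marker 2 Poisson (log
#' link) and marker 3 binary (logit link), with identical coefficients
#' and covariance.
#'
#' @param scenario 1 or 2.
#' @return An object of class `mglmm_truth`: marker specs, per-marker
#'   coefficient vectors `beta`, Gaussian residual variances
#'   `sigma2_eps`, the joint covariance `Sigma_R`, and the visit-count
#'   range.
#' @export
scenario_truth <- function(scenario) {
  if (!scenario %in% c(1, 2))
    stop_config("scenario must be 1 or 2")
  beta <- list(marker1 = c(0.68, -0.95),
               marker2 = c(-2.50, 0.12),
               marker3 = c(0.45, 1.21))
  Sigma_R <- matrix(c(
    2.58, 0.46, 0.22, 0.42, 0.78, 0.23,
    0.46, 1.21, 0.37, 0.69, 0.14, 0.19,
    0.22, 0.37, 1.04, 0.73, 0.61, 0.38,
    0.42, 0.69, 0.73, 1.36, 0.87, 0.14,
    0.78, 0.14, 0.61, 0.87, 1.73, 0.92,
    0.23, 0.19, 0.38, 0.14, 0.92, 1.47), 6, 6, byrow = TRUE)
  families <- if (scenario == 1) rep("gaussian", 3) else
    c("gaussian", "poisson", "bernoulli")
  specs <- lapply(seq_len(3), function(r)
    marker_spec(names(beta)[r], families[r],
                fixed = c("(Intercept)", "x"),
                random = c("(Intercept)", "x")))
  sigma2_eps <- c(0.1, 0.25, 0.15)[families == "gaussian"]
  structure(list(specs = specs, beta = beta, sigma2_eps = sigma2_eps,
                 Sigma_R = Sigma_R, visit_range = c(5L, 10L),
                 scenario = scenario),
            class = "mglmm_truth")
}

#' Custom generating truth
#'
#' @param specs List of [marker_spec()] (fixed/random columns must be
#'   `"(Intercept)"` and/or `"x"`; `x` is scaled visit time).
#' @param beta List of per-marker fixed-effect vectors (lengths
#'   \eqn{p_r}).
#' @param Sigma_R Joint random-effects covariance (\eqn{q \times q}
#'   SPD).
#' @param sigma2_eps Residual variances, one per Gaussian marker.
#' @param visit_range Integer range of visits per subject (discrete
#'   uniform).
#' @return An `mglmm_truth` object.
#' @export
mglmm_truth <- function(specs, beta, Sigma_R, sigma2_eps = numeric(0),
                        visit_range = c(5L, 10L)) {
  if (inherits(specs, "marker_spec")) specs <- list(specs)
  q <- sum(vapply(specs, `[[`, 0L, "q_r"))
  Sigma_R <- as.matrix(Sigma_R)
  if (nrow(Sigma_R) != q || ncol(Sigma_R) != q)
    stop_config("Sigma_R must be ", q, " x ", q)
  chol_or_fail(Sigma_R, "Sigma_R of the generating truth")
  p_r <- vapply(specs, `[[`, 0L, "p_r")
  if (length(beta) != length(specs) ||
      any(lengths(beta) != p_r))
    stop_config("beta must hold one coefficient vector per marker, lengths p_r")
  ng <- sum(vapply(specs, function(s) s$family$has_dispersion, TRUE))
  if (length(sigma2_eps) != ng || any(sigma2_eps <= 0))
    stop_config("sigma2_eps must hold one positive variance per gaussian marker")
  names(beta) <- vapply(specs, `[[`, "", "name")
  structure(list(specs = specs, beta = beta, sigma2_eps = sigma2_eps,
                 Sigma_R = Sigma_R,
                 visit_range = as.integer(visit_range), scenario = NA),
            class = "mglmm_truth")
}

#' Simulate a multivariate longitudinal dataset
#'
#' For each subject a visit count is drawn uniformly on
#' `truth$visit_range`; the covariate is scaled visit time
#' \eqn{x_j = (j - 1) / (n_i - 1) \in [0, 1]}, shared across markers
#' (one visit schedule per subject); the joint random effects are drawn
#' \eqn{u_i \sim N(0, \Sigma_R)}; responses are then drawn from each
#' marker's conditional family given the linear predictor.  The draw
#' order (visit counts, then \eqn{u}, then responses subject by
#' subject) is fixed, so a dataset is fully reproducible from `seed`.
#' An optional per-marker missingness rate deletes observed rows at
#' random, emulating markers not collected at every visit.
#'
#' @param truth An `mglmm_truth`.
#' @param m Number of subjects.
#' @param seed Integer seed.
#' @param missing_rate Probability that any single marker x visit
#'   response is missing (dropped), default 0.
#' @return List with `dataset` (an `mglmm_data`), the raw long `data`
#'   frame, the latent random effects `u` (\eqn{m \times q}) and the
#'   `truth`.
#' @export
simulate_mglmm <- function(truth, m, seed = 1L, missing_rate = 0) {
  if (!inherits(truth, "mglmm_truth")) stop_config("truth must be an mglmm_truth")
  if (m < 1) stop_config("m must be >= 1")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  specs <- truth$specs
  R <- length(specs)
  q_r <- vapply(specs, `[[`, 0L, "q_r")
  q_off <- c(0L, cumsum(q_r))[seq_len(R)]
  q <- sum(q_r)

  n_i <- sample(seq(truth$visit_range[1], truth$visit_range[2]), m, replace = TRUE)
  u <- matrix(stats::rnorm(m * q), m, q) %*% chol(truth$Sigma_R)

  gslot <- cumsum(vapply(specs, function(s) s$family$has_dispersion, TRUE))
  rows <- vector("list", m)
  for (i in seq_len(m)) {
    x <- if (n_i[i] > 1) (seq_len(n_i[i]) - 1) / (n_i[i] - 1) else 0
    per_marker <- vector("list", R)
    for (r in seq_len(R)) {
      sp <- specs[[r]]
      Xr <- vapply(sp$fixed, function(nm) if (nm == "(Intercept)") rep(1, n_i[i]) else x,
                   numeric(n_i[i]))
      Zr <- vapply(sp$random, function(nm) if (nm == "(Intercept)") rep(1, n_i[i]) else x,
                   numeric(n_i[i]))
      eta <- drop(matrix(Xr, n_i[i]) %*% truth$beta[[r]]) +
        drop(matrix(Zr, n_i[i]) %*% u[i, q_off[r] + seq_len(q_r[r])])
      y <- switch(sp$family$family,
        gaussian = stats::rnorm(n_i[i], eta, sqrt(truth$sigma2_eps[gslot[r]])),
        poisson = stats::rpois(n_i[i], exp(eta)),
        bernoulli = stats::rbinom(n_i[i], 1, stats::plogis(eta)))
      per_marker[[r]] <- data.frame(subject = i, marker = sp$name,
                                    visit = seq_len(n_i[i]), x = x,
                                    response = y)
    }
    rows[[i]] <- do.call(rbind, per_marker)
  }
  df <- do.call(rbind, rows)
  if (missing_rate > 0) {
    keep <- stats::runif(nrow(df)) >= missing_rate
    df <- df[keep, , drop = FALSE]
  }
  rownames(df) <- NULL
  dataset <- read_long_table(df, specs, visit_col = "visit")
  list(dataset = dataset, data = df, u = u, truth = truth, seed = seed, m = m)
}

#' Write a simulated dataset and its truth sidecar to disk
#'
#' Writes the long-format CSV plus a YAML sidecar recording the
#' generating coefficients, residual variances, covariance matrix and
#' seed.
#'
#' @param sim Output of [simulate_mglmm()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data_path <- file.path(dir, "data.csv")
  truth_path <- file.path(dir, "truth.yml")
  utils::write.csv(sim$data, data_path, row.names = FALSE)
  tr <- sim$truth
  yaml::write_yaml(list(
    scenario = if (is.na(tr$scenario)) NULL else tr$scenario,
    seed = sim$seed, m = sim$m,
    markers = lapply(tr$specs, function(sp)
      list(name = sp$name, family = sp$family$family,
           fixed = sp$fixed, random = sp$random)),
    beta = lapply(tr$beta, as.numeric),
    sigma2_eps = as.numeric(tr$sigma2_eps),
    Sigma_R = apply(tr$Sigma_R, 1, as.numeric, simplify = FALSE),
    visit_range = as.integer(tr$visit_range)), truth_path)
  invisible(c(data = data_path, truth = truth_path))
}
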