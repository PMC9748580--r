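# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths: dense index-by-index assembly, raw
# Gauss-Hermite quadrature, direct mixed-model-equation solves.

# Gauss-Hermite nodes/weights by Golub-Welsch (eigen decomposition of
# the Jacobi matrix); E[f(Z)] for Z ~ N(0,1) is sum(w_i f(sqrt(2) x_i))/sqrt(pi)
gauss_hermite <- function(n) {
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  ev <- eigen(J, symmetric = TRUE)
  list(x = ev$values, w = sqrt(pi) * ev$vectors[1, ]^2)
}

gh_expect <- function(f, mu, sigma2, n = 50) {
  gh <- gauss_hermite(n)
  sum(gh$w * f(mu + sqrt(2 * sigma2) * gh$x)) / sqrt(pi)
}

# dense stacked [X Z] built row by row straight from the canonical data
# frame, independently of build_design's block logic
brute_force_C <- function(dataset) {
  specs <- dataset$specs
  df <- dataset$data
  m <- dataset$m; R <- dataset$R
  p_r <- vapply(specs, function(s) length(s$fixed), 0L)
  q_r <- vapply(specs, function(s) length(s$random), 0L)
  p <- sum(p_r); q <- sum(q_r)
  N <- nrow(df)
  C <- matrix(0, N, p + m * q)
  val <- function(nm, row) if (nm == "(Intercept)") 1 else df[[nm]][row]
  for (row in seq_len(N)) {
    i <- match(df$subject[row], dataset$subjects)
    r <- match(as.character(df$marker[row]), names(specs))
    for (k in seq_along(specs[[r]]$fixed))
      C[row, sum(p_r[seq_len(r - 1)]) + k] <- val(specs[[r]]$fixed[k], row)
    for (k in seq_along(specs[[r]]$random))
      C[row, p + (i - 1) * q + sum(q_r[seq_len(r - 1)]) + k] <-
        val(specs[[r]]$random[k], row)
  }
  C
}

# Henderson mixed-model-equations solution with known variance
# components and a ridge prior on the fixed effects
henderson_solution <- function(dataset, sigma2_eps, Sigma_R, sigma2_beta) {
  des <- build_design(dataset)
  C <- cbind(des$X, matrix(0, des$N, des$m * des$q))
  for (i in seq_len(des$m))
    C[des$rows[[i]], des$p + (i - 1) * des$q + seq_len(des$q)] <- des$Zi[[i]]
  gslot <- match(des$row_marker, des$gauss_markers)
  w <- 1 / sigma2_eps[gslot]
  D <- matrix(0, ncol(C), ncol(C))
  D[seq_len(des$p), seq_len(des$p)] <- diag(1 / sigma2_beta, des$p)
  SRinv <- solve(Sigma_R)
  for (i in seq_len(des$m)) {
    ci <- des$p + (i - 1) * des$q + seq_len(des$q)
    D[ci, ci] <- SRinv
  }
  solve(crossprod(C, C * w) + D, crossprod(C, des$y * w))
}

# small random mixed-family instance for property tests
random_instance <- function(seed, m = 8, families = NULL) {
  set.seed(seed)
  if (is.null(families))
    families <- sample(c("gaussian", "poisson", "bernoulli"), 3, replace = TRUE)
  R <- length(families)
  specs <- lapply(seq_len(R), function(r)
    marker_spec(paste0("m", r), families[r],
                fixed = c("(Intercept)", "x"),
                random = if (r %% 2) c("(Intercept)", "x") else "(Intercept)"))
  q <- sum(vapply(specs, function(s) s$q_r, 0L))
  A <- matrix(rnorm(q * q, sd = 0.3), q, q)
  Sigma_R <- crossprod(A) + diag(0.5, q)
  betas <- lapply(specs, function(s) rnorm(s$p_r, sd = 0.5))
  ng <- sum(families == "gaussian")
  truth <- mglmm_truth(specs, betas, Sigma_R,
                       sigma2_eps = if (ng) runif(ng, 0.1, 0.5) else numeric(0))
  simulate_mglmm(truth, m, seed = seed + 1000)
}

# states (streamlined / naive) compared block by block at relative tol
expect_states_equal <- function(s1, s2, tol = 1e-8) {
  rel <- function(x, y) max(abs(x - y)) / (1 + max(abs(y)))
  expect_lt(rel(s1$mu_beta, s2$mu_beta), tol)
  expect_lt(rel(s1$Sigma_beta, s2$Sigma_beta), tol)
  expect_lt(rel(s1$mu_u, s2$mu_u), tol)
  expect_lt(max(vapply(seq_along(s1$Sigma_u), function(i)
    rel(s1$Sigma_u[[i]], s2$Sigma_u[[i]]), 0)), tol)
  expect_lt(rel(s1$B_Sigma_R, s2$B_Sigma_R), tol)
  expect_lt(rel(s1$M_q_inv, s2$M_q_inv), tol)
  if (length(s1$B_sig2)) {
    expect_lt(rel(s1$B_sig2, s2$B_sig2), tol)
    expect_lt(rel(s1$mu_inv_sig2, s2$mu_inv_sig2), tol)
  }
  expect_lt(rel(s1$B_a, s2$B_a), tol)
}

# the scenario-1 benchmark fit is shared between acceptance checks
.fit_cache <- new.env(parent = emptyenv())

scenario1_benchmark <- function() {
  if (is.null(.fit_cache$s1)) {
    sim <- simulate_mglmm(scenario_truth(1), m = 1000, seed = 1)
    .fit_cache$s1 <- list(sim = sim, fit = fit_mglmm(sim$dataset))
  }
  .fit_cache$s1
}
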