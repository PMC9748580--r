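test_that("initialization obeys the stated defaults and SPD invariants", {
  sim <- random_instance(1, m = 4, families = c("gaussian", "poisson", "bernoulli"))
  des <- build_design(sim$dataset)
  st <- initialize_state(des)
  expect_equal(st$M_q_inv, diag(des$q))
  expect_equal(st$mu_beta, numeric(des$p))
  expect_equal(st$Sigma_beta, diag(des$p))
  expect_equal(st$mu_u, matrix(0, des$q, des$m))
  expect_true(all(st$mu_inv_sig2 == 1))
  expect_true(all(st$mu_inv_a == 1))
  # SPD assertable by Cholesky on every block
  expect_no_error(chol(st$Sigma_beta))
  expect_no_error(chol(st$M_q_inv))
  for (S in st$Sigma_u) expect_no_error(chol(S))
})

test_that("scalar updates evaluate the printed formulas", {
  sim <- random_instance(2, m = 3, families = c("gaussian", "gaussian"))
  des <- build_design(sim$dataset)
  st <- initialize_state(des)

  # residual variance: N_r = 10, SSQ + trace = 4, mu_q(1/a_eps) = 1
  # gives B = 3 and mu_q(1/sigma2) = 5.5/3
  fake_des <- des
  idx <- which(des$row_marker == 1)[1:10]
  fake_pm <- list(mu = des$y, sigma2 = rep(0, des$N))
  fake_pm$mu[idx] <- des$y[idx] - sqrt(4 / 10)   # SSQ = 4 over 10 rows
  fake_des$row_marker[-idx] <- 2L
  st1 <- update_residual_variances(st, fake_des, fake_pm)
  expect_equal(st1$B_sig2[1], 3)
  expect_equal(st1$mu_inv_sig2[1], 5.5 / 3)

  # perfect fit: B collapses to mu_q(1/a_eps)
  pm0 <- list(mu = des$y, sigma2 = rep(0, des$N))
  st2 <- update_residual_variances(st, des, pm0)
  expect_equal(st2$B_sig2, c(1, 1))

  # trace term equals the brute-force row-wise quadratic form
  st3 <- fit_mglmm(sim$dataset, control = fit_control(max_iter = 3))$state
  pm3 <- update_predictor_moments(st3, des)
  C <- brute_force_C(sim$dataset)
  Sig_full <- fit_mglmm_naive(sim$dataset,
                              control = fit_control(max_iter = 3))$state$Sigma_full
  expect_equal(pm3$sigma2, rowSums((C %*% Sig_full) * C), tolerance = 1e-8)

  # auxiliary update: nu = 2, M_kk = 0.5, A_k = 1e4
  priors <- prior_config()
  des6 <- des; des6$q <- 6L
  st4 <- st; st4$M_q_inv <- diag(0.5, 6)
  st4 <- update_auxiliaries(st4, des6, priors)
  expect_equal(st4$B_a, rep(1 + 1e-8, 6))
  expect_equal(st4$mu_inv_a, rep(0.5 * (2 + 6) / (1 + 1e-8), 6))
  expect_true(all(st4$B_a > 0))

  # covariance update: m = 1, mu_u = 0, Sigma_u = I, all mu_q(1/a) = 1
  q <- des$q
  st5 <- initialize_state(des)
  st5$mu_u <- st5$mu_u[, 1, drop = FALSE]
  st5$Sigma_u <- st5$Sigma_u[1]
  des1 <- des; des1$m <- 1L
  st5 <- update_random_effects_covariance(st5, des1, priors)
  expect_equal(st5$B_Sigma_R, diag(5, q))
  expect_equal(st5$M_q_inv, diag((2 + q + 1 - 1) / 5, q))

  # direct-summation oracle on a random m = 3, q = 2 configuration
  st6 <- initialize_state(des)
  set.seed(9)
  st6$mu_u <- matrix(rnorm(des$q * 3), des$q, 3)
  st6$Sigma_u <- lapply(1:3, function(i) crossprod(matrix(rnorm(9), 3, 3))[seq_len(des$q), seq_len(des$q)] + diag(des$q))
  st6$mu_inv_a <- runif(des$q, 0.5, 2)
  B_oracle <- 2 * 2 * diag(st6$mu_inv_a, des$q)
  for (i in 1:3)
    B_oracle <- B_oracle + st6$mu_u[, i] %*% t(st6$mu_u[, i]) + st6$Sigma_u[[i]]
  st6 <- update_random_effects_covariance(st6, des, priors)
  expect_equal(st6$B_Sigma_R, (B_oracle + t(B_oracle)) / 2, tolerance = 1e-12)
})

test_that("predictor moments reproduce the dense-covariance variances", {
  sim <- random_instance(3, m = 3, families = c("gaussian", "bernoulli"))
  f_str <- fit_mglmm(sim$dataset, control = fit_control(max_iter = 2))
  f_nai <- fit_mglmm_naive(sim$dataset, control = fit_control(max_iter = 2))
  des <- f_str$design
  pm <- update_predictor_moments(f_str$state, des)
  C <- brute_force_C(sim$dataset)
  expect_equal(pm$mu, drop(C %*% f_nai$state$mu_full), tolerance = 1e-8)
  expect_equal(pm$sigma2, rowSums((C %*% f_nai$state$Sigma_full) * C),
               tolerance = 1e-8)

  # degenerate blocks: no workspace and zero covariances
  st0 <- initialize_state(des)
  st0$Sigma_beta <- st0$Sigma_beta * 0
  st0$Sigma_u <- lapply(st0$Sigma_u, function(S) S * 0)
  pm0 <- update_predictor_moments(st0, des)
  expect_equal(pm0$sigma2, rep(0, des$N))
  expect_equal(pm0$mu, drop(des$X %*% st0$mu_beta))
})

test_that("streamlined and naive fits coincide cycle by cycle", {
  for (seed in 1:4) {
    fams <- list(c("gaussian", "gaussian"),
                 c("gaussian", "poisson", "bernoulli"),
                 c("bernoulli", "poisson"),
                 c("poisson", "gaussian"))[[seed]]
    sim <- random_instance(seed + 10, m = sample(3:8, 1), families = fams)
    for (k in c(1L, 3L)) {
      f1 <- fit_mglmm(sim$dataset, control = fit_control(max_iter = k))
      f2 <- fit_mglmm_naive(sim$dataset, control = fit_control(max_iter = k))
      expect_states_equal(f1$state, f2$state, tol = 1e-8)
      expect_equal(tail(f1$elbo, 1), tail(f2$elbo, 1), tolerance = 1e-8)
    }
  }
})

test_that("the full covariance has the advertised block structure", {
  sim <- random_instance(30, m = 4, families = c("gaussian", "gaussian"))
  k <- 3L
  f1 <- fit_mglmm(sim$dataset, control = fit_control(max_iter = k))
  f2 <- fit_mglmm_naive(sim$dataset, control = fit_control(max_iter = k))
  des <- f1$design
  W <- f2$state$Sigma_full
  p <- des$p; q <- des$q
  GiHi <- f1$state$work$GiHi
  for (i in seq_len(des$m)) {
    ci <- p + (i - 1) * q + seq_len(q)
    # cross block -Sigma_beta G_i H_i
    expect_equal(W[seq_len(p), ci],
                 -f1$state$Sigma_beta %*% GiHi[[i]], tolerance = 1e-8,
                 ignore_attr = TRUE)
    # diagonal block H_i + H_i G_i' Sigma_beta G_i H_i
    expect_equal(W[ci, ci],
                 f1$state$work$Hi[[i]] +
                   crossprod(GiHi[[i]], f1$state$Sigma_beta %*% GiHi[[i]]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  # naive guard refuses oversized problems
  big <- structure(list(), class = "mglmm_design")
  big$p <- 10L; big$q <- 10L; big$m <- 500L
  expect_error(fit_mglmm_naive(big), class = "mglmm_config_error")
})

test_that("lower bound is monotone for all-gaussian models", {
  for (seed in 1:6) {
    sim <- random_instance(seed + 40, m = 6,
                           families = rep("gaussian", sample(1:3, 1)))
    f <- fit_mglmm(sim$dataset, control = fit_control(max_iter = 40))
    expect_true(all(diff(f$elbo) >= -1e-8 * (1 + abs(f$elbo[-1]))))
  }
})

test_that("SPD and positivity invariants hold after every cycle", {
  sim <- random_instance(77, m = 5, families = c("gaussian", "poisson", "bernoulli"))
  for (k in 1:4) {
    st <- fit_mglmm(sim$dataset, control = fit_control(max_iter = k))$state
    expect_no_error(chol(st$Sigma_beta))
    expect_no_error(chol(st$M_q_inv))
    expect_no_error(chol(st$B_Sigma_R))
    for (S in st$Sigma_u) expect_no_error(chol(S))
    expect_true(all(st$mu_inv_sig2 > 0))
    expect_true(all(st$mu_inv_a_eps > 0))
    expect_true(all(st$mu_inv_a > 0))
    expect_true(all(st$B_a > 0))
  }
})

test_that("frozen-variance gaussian fit solves the Henderson equations", {
  sim <- random_instance(55, m = 6, families = c("gaussian", "gaussian"))
  truth <- sim$truth
  f <- fit_mglmm(sim$dataset,
                 fixed = list(Sigma_R = truth$Sigma_R,
                              sigma2_eps = truth$sigma2_eps),
                 control = fit_control(max_iter = 200, tolerance = 1e-13))
  mme <- henderson_solution(sim$dataset, truth$sigma2_eps, truth$Sigma_R,
                            prior_config()$sigma2_beta)
  des <- f$design
  est <- c(f$state$mu_beta, as.vector(f$state$mu_u))
  expect_lt(max(abs(est - mme)) / (1 + max(abs(mme))), 1e-6)
})

test_that("fitter control contract: one cycle, determinism, damping", {
  sim <- random_instance(91, m = 5, families = c("gaussian", "bernoulli"))
  f1 <- fit_mglmm(sim$dataset, control = fit_control(max_iter = 1))
  expect_equal(f1$iterations, 1L)
  expect_false(f1$converged)
  expect_length(f1$elbo, 1)

  fa <- fit_mglmm(sim$dataset, control = fit_control(max_iter = 10))
  fb <- fit_mglmm(sim$dataset, control = fit_control(max_iter = 10))
  expect_identical(fa$elbo, fb$elbo)
  expect_identical(fa$state$mu_beta, fb$state$mu_beta)

  # damped fit agrees with the damped naive path too
  fd1 <- fit_mglmm(sim$dataset, control = fit_control(max_iter = 4, damping = 0.5))
  fd2 <- fit_mglmm_naive(sim$dataset, control = fit_control(max_iter = 4, damping = 0.5))
  expect_states_equal(fd1$state, fd2$state, tol = 1e-8)
})

test_that("ridge limit: single subject with frozen spherical precision", {
  # with M_q(Sigma_R^-1) ~ 0 (variance -> infinity) and one subject, the
  # converged mean is the generalized ridge solution
  tiny <- data.frame(subject = 1, marker = "g", visit = 1:6,
                     x = seq(0, 1, length.out = 6))
  set.seed(4)
  tiny$response <- 1 + tiny$x + rnorm(6, sd = 0.3)
  sp <- marker_spec("g", "gaussian", fixed = c("(Intercept)", "x"),
                    random = c("(Intercept)", "x"))
  ds <- read_long_table(tiny, list(sp), visit_col = "visit")
  big_var <- diag(1e8, 2)
  f <- fit_mglmm(ds, fixed = list(Sigma_R = big_var, sigma2_eps = 0.09),
                 control = fit_control(max_iter = 300, tolerance = 1e-14))
  des <- f$design
  C <- cbind(des$X, des$Zi[[1]])
  ridge <- solve(crossprod(C) / 0.09 + diag(c(rep(1e-4, 2), rep(1e-8, 2))),
                 crossprod(C, des$y) / 0.09)
  est <- c(f$state$mu_beta, f$state$mu_u[, 1])
  expect_equal(est, drop(ridge), tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("fixed effects recover the generating values across seeds", {
  truth <- scenario_truth(1)
  hits <- 0L; total <- 0L
  for (seed in 1:5) {
    sim <- simulate_mglmm(truth, m = 150, seed = seed)
    f <- fit_mglmm(sim$dataset)
    tv <- unlist(truth$beta)
    sds <- sqrt(diag(f$state$Sigma_beta))
    hits <- hits + sum(abs(f$state$mu_beta - tv) <= 3 * sds)
    total <- total + length(tv)
  }
  expect_gte(hits / total, 0.95)
})
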