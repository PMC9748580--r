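make_long_df <- function() {
  data.frame(
    subject = rep(c("a", "b"), each = 4),
    marker = rep(rep(c("g1", "g2"), each = 2), 2),
    visit = rep(1:2, 4),
    x = rep(c(0, 1), 4),
    response = c(1.2, 0.8, 3, 1, 0.5, -0.1, 2, 4)
  )
}

two_specs <- function(fam2 = "poisson") list(
  marker_spec("g1", "gaussian", fixed = c("(Intercept)", "x"),
              random = c("(Intercept)", "x")),
  marker_spec("g2", fam2, fixed = c("(Intercept)", "x"),
              random = "(Intercept)")
)

test_that("family objects expose the correct cumulant functions", {
  expect_equal(glmm_family("gaussian")$b(3), 4.5)
  expect_equal(glmm_family("poisson")$b(1), exp(1))
  expect_equal(glmm_family("bernoulli")$b(0), log(2))
  # only the gaussian family has a free dispersion
  expect_true(glmm_family("gaussian")$has_dispersion)
  expect_false(glmm_family("poisson")$has_dispersion)
  expect_false(glmm_family("bernoulli")$has_dispersion)
  # large-argument stability of log(1 + e^x)
  expect_equal(glmm_family("bernoulli")$b(800), 800)
})

test_that("read_long_table validates, drops missing responses and counts blocks", {
  df <- make_long_df()
  ds <- read_long_table(df, two_specs(), visit_col = "visit")
  expect_s3_class(ds, "mglmm_data")
  expect_equal(ds$m, 2)
  expect_equal(unname(ds$n_ir["a", ]), c(2L, 2L))

  # minimal well-formed input: one subject, one gaussian marker, 2 visits
  one <- df[df$subject == "a" & df$marker == "g1", ]
  ds1 <- read_long_table(one, two_specs()[1], visit_col = "visit")
  expect_equal(ds1$m, 1)
  expect_equal(unname(ds1$n_ir[1, 1]), 2L)

  # a missing response drops exactly that row
  df_na <- df; df_na$response[3] <- NA
  expect_message(ds_na <- read_long_table(df_na, two_specs(), visit_col = "visit"),
                 "dropped 1")
  expect_equal(nrow(ds_na$data), nrow(df) - 1)
  expect_equal(ds_na$n_dropped, 1L)

  # domain violations
  df_bad <- df; df_bad$response[df_bad$marker == "g2"] <- c(0, 1, 2, 0)
  expect_error(read_long_table(df_bad, two_specs("bernoulli"), visit_col = "visit"),
               class = "mglmm_validation_error")
  df_frac <- df; df_frac$response[4] <- 2.5
  expect_error(read_long_table(df_frac, two_specs(), visit_col = "visit"),
               class = "mglmm_validation_error")
  # unknown marker name
  df_unk <- df; df_unk$marker[1] <- "mystery"
  expect_error(read_long_table(df_unk, two_specs(), visit_col = "visit"),
               class = "mglmm_config_error")
})

test_that("a subject may lack a marker entirely (n_ir = 0)", {
  df <- make_long_df()
  df <- df[!(df$subject == "b" & df$marker == "g2"), ]
  ds <- read_long_table(df, two_specs(), visit_col = "visit")
  expect_equal(unname(ds$n_ir["b", ]), c(2L, 0L))
  des <- build_design(ds)
  expect_equal(nrow(des$Zi[[2]]), 2)
  # the missing marker's random-effect columns are exactly zero
  expect_true(all(des$Zi[[2]][, 3] == 0))
  # and the model still fits, shrinking those effects to the prior
  fit <- fit_mglmm(ds, control = fit_control(max_iter = 30))
  expect_true(all(is.finite(fit$state$mu_u)))
})

test_that("block-diagonal designs match a brute-force dense constructor", {
  # smallest design: intercept-only, one subject, two visits
  tiny <- data.frame(subject = 1, marker = "g", visit = 1:2, response = c(1, 2))
  sp <- marker_spec("g", "gaussian", fixed = "(Intercept)", random = "(Intercept)")
  des <- build_design(read_long_table(tiny, list(sp), visit_col = "visit"))
  expect_equal(des$Xi[[1]], matrix(1, 2, 1))
  expect_equal(des$Zi[[1]], matrix(1, 2, 1))
  expect_equal(dim(cbind(des$X, des$Zi[[1]])), c(2, 2))

  # two markers on one subject: marker-2 rows have exact zeros in
  # marker-1 columns (block-diagonal structure)
  df <- make_long_df()[1:4, ]
  des2 <- build_design(read_long_table(df, two_specs(), visit_col = "visit"))
  m2_rows <- which(des2$row_marker == 2)
  expect_true(all(des2$X[m2_rows, 1:2] == 0))

  # m = 3, R = 2, mixed q_r: stacked design equals index-by-index assembly
  set.seed(42)
  df3 <- expand.grid(subject = 1:3, marker = c("g1", "g2"), visit = 1:3)
  df3$x <- runif(nrow(df3))
  df3$response <- rpois(nrow(df3), 2)
  df3$response[df3$marker == "g1"] <- rnorm(sum(df3$marker == "g1"))
  ds3 <- read_long_table(df3, two_specs(), visit_col = "visit")
  des3 <- build_design(ds3)
  expect_equal(des3$p, 4)
  expect_equal(des3$q, 3)
  C_pkg <- cbind(des3$X, matrix(0, des3$N, des3$m * des3$q))
  for (i in 1:3)
    C_pkg[des3$rows[[i]], des3$p + (i - 1) * des3$q + seq_len(des3$q)] <- des3$Zi[[i]]
  expect_equal(C_pkg, brute_force_C(ds3), tolerance = 0, ignore_attr = TRUE)
})

test_that("row order within a group does not change the model (canonical sort)", {
  set.seed(7)
  df <- make_long_df()
  ds_ref <- read_long_table(df, two_specs(), visit_col = "visit")
  perm <- df[sample(nrow(df)), ]
  ds_perm <- read_long_table(perm, two_specs(), visit_col = "visit")
  expect_equal(ds_perm$data$response, ds_ref$data$response)
  d1 <- build_design(ds_ref); d2 <- build_design(ds_perm)
  nu <- rnorm(d1$p)
  expect_equal(drop(d1$X %*% nu), drop(d2$X %*% nu))
})

test_that("round trip: design blocks recover the input rows exactly", {
  df <- make_long_df()
  ds <- read_long_table(df, two_specs(), visit_col = "visit")
  des <- build_design(ds)
  for (i in seq_len(des$m)) {
    rows <- des$rows[[i]]
    expect_equal(des$yi[[i]], ds$data$response[rows])
    # slicing the g1 block of X_i gives back (1, x) for g1 rows
    g1 <- which(des$row_marker[rows] == 1)
    expect_equal(des$Xi[[i]][g1, 1:2],
                 cbind(1, ds$data$x[rows[g1]]), ignore_attr = TRUE)
  }
  # missing covariate column is a configuration error
  sp_bad <- list(marker_spec("g1", "gaussian", fixed = c("(Intercept)", "zzz")),
                 two_specs()[[2]])
  expect_error(build_design(read_long_table(df, sp_bad, visit_col = "visit")),
               class = "mglmm_config_error")
})
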