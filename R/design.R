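#' Build subject-level block-diagonal design matrices
#'
#' Constructs, for every subject \eqn{i}, the fixed-effect design
#' \eqn{X_i = \mathrm{blockdiag}(X_{i1}, \dots, X_{iR})} (\eqn{n_i
#' \times p}) and random-effect design \eqn{Z_i =
#' \mathrm{blockdiag}(Z_{i1}, \dots, Z_{iR})} (\eqn{n_i \times q}),
#' with \eqn{p = \sum_r p_r}, \eqn{q = \sum_r q_r}.  Rows are stacked
#' subject-major with marker blocks inside each subject, matching the
#' canonical ordering of [read_long_table()]; coefficients are laid out
#' \eqn{\beta} first (marker-block order) then \eqn{u_1, \dots, u_m}.
#'
#' @param dataset An `mglmm_data` object.
#' @return An object of class `mglmm_design`: stacked `X` (\eqn{N
#'   \times p}) and response `y`, per-subject lists `Xi`, `Zi`, `yi`,
#'   `rows` (global row indices), row-level metadata (`row_subject`,
#'   `row_marker`, `row_family`), dimensions and coefficient names.
#' @export
build_design <- function(dataset) {
  if (!inherits(dataset, "mglmm_data"))
    stop_config("dataset must be an mglmm_data object")
  specs <- dataset$specs
  df <- dataset$data
  cols <- dataset$cols
  R <- dataset$R
  m <- dataset$m

  p_r <- vapply(specs, `[[`, 0L, "p_r")
  q_r <- vapply(specs, `[[`, 0L, "q_r")
  p <- sum(p_r)
  q <- sum(q_r)
  p_off <- c(0L, cumsum(p_r))[seq_len(R)]
  q_off <- c(0L, cumsum(q_r))[seq_len(R)]

  needed <- unique(unlist(lapply(specs, function(sp) c(sp$fixed, sp$random))))
  needed <- setdiff(needed, "(Intercept)")
  absent <- setdiff(needed, names(df))
  if (length(absent))
    stop_config("covariate column(s) named in marker specs absent from table: ",
                paste(absent, collapse = ", "))

  covariate_cols <- function(nms, rows) {
    out <- matrix(0, length(rows), length(nms))
    for (k in seq_along(nms))
      out[, k] <- if (nms[k] == "(Intercept)") 1 else df[[nms[k]]][rows]
    out
  }

  N <- nrow(df)
  X <- matrix(0, N, p)
  y <- df[[cols$response]]
  subj_idx <- match(df[[cols$subject]], dataset$subjects)
  mk_idx <- match(as.character(df[[cols$marker]]), names(specs))
  fam_tags <- vapply(specs, function(sp) sp$family$family, "")
  row_family <- fam_tags[mk_idx]

  Xi <- vector("list", m); Zi <- vector("list", m)
  yi <- vector("list", m); rows_i <- vector("list", m)
  for (i in seq_len(m)) {
    rows <- which(subj_idx == i)
    n_i <- length(rows)
    Xl <- matrix(0, n_i, p)
    Zl <- matrix(0, n_i, q)
    for (r in seq_len(R)) {
      loc <- which(mk_idx[rows] == r)
      if (!length(loc)) next
      Xl[loc, p_off[r] + seq_len(p_r[r])] <- covariate_cols(specs[[r]]$fixed, rows[loc])
      Zl[loc, q_off[r] + seq_len(q_r[r])] <- covariate_cols(specs[[r]]$random, rows[loc])
    }
    Xi[[i]] <- Xl; Zi[[i]] <- Zl
    yi[[i]] <- y[rows]; rows_i[[i]] <- rows
    X[rows, ] <- Xl
  }

  beta_names <- unlist(lapply(specs, function(sp) paste(sp$name, sp$fixed, sep = ":")))
  u_names <- unlist(lapply(specs, function(sp) paste(sp$name, sp$random, sep = ":")))
  colnames(X) <- beta_names

  structure(
    list(X = X, y = y, N = N, m = m, R = R,
         p = p, q = q, p_r = p_r, q_r = q_r,
         p_off = p_off, q_off = q_off,
         Xi = Xi, Zi = Zi, yi = yi, rows = rows_i,
         row_subject = subj_idx, row_marker = mk_idx,
         row_family = row_family, fam_tags = fam_tags,
         gauss_markers = which(fam_tags == "gaussian"),
         beta_names = beta_names, u_names = u_names,
         subjects = dataset$subjects, specs = specs,
         n_ir = dataset$n_ir, N_r = colSums(dataset$n_ir)),
    class = "mglmm_design"
  )
}

#' @export
print.mglmm_design <- function(x, ...) {
  cat(sprintf("mglmm_design: N = %d rows, m = %d subjects, p = %d, q = %d (R = %d markers)\n",
              x$N, x$m, x$p, x$q, x$R))
  invisible(x)
}
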