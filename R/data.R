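#' Read a long-format multivariate longitudinal table
#'
#' Ingests one row per subject x marker x visit and validates it against
#' the marker specifications.  Rows are reordered canonically:
#' subject-major (subjects sorted), then markers in the order of
#' `marker_specs`, then by the `visit` column if present (original order
#' otherwise).  Rows with a missing response are dropped with a message.
#' A subject may lack a marker entirely (\eqn{n_{ir} = 0}); its random
#' effects for that marker are still estimated and shrink to the prior.
#'
#' @param table_source A data frame, or the path of a delimited text
#'   file (comma-separated by default) with a header row.
#' @param marker_specs List of [marker_spec()] objects.
#' @param subject_col,marker_col,response_col,visit_col Column names;
#'   `visit_col` is optional (`NULL` to keep input order within a
#'   subject x marker group).
#' @param sep Field separator when `table_source` is a path.
#' @return An object of class `mglmm_data`: list with the canonical
#'   data frame (`data`), `specs`, sorted `subjects`, counts `m`, `R`,
#'   the \eqn{m \times R} visit-count matrix `n_ir` and `n_dropped`.
#' @export
read_long_table <- function(table_source, marker_specs,
                            subject_col = "subject", marker_col = "marker",
                            response_col = "response", visit_col = NULL,
                            sep = ",") {
  if (is.character(table_source)) {
    if (!file.exists(table_source))
      stop_config("data file not found: ", table_source)
    df <- utils::read.table(table_source, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE)
  } else if (is.data.frame(table_source)) {
    df <- as.data.frame(table_source)
  } else {
    stop_config("table_source must be a data frame or a file path")
  }
  if (inherits(marker_specs, "marker_spec")) marker_specs <- list(marker_specs)
  if (!length(marker_specs) || !all(vapply(marker_specs, inherits, TRUE, "marker_spec")))
    stop_config("marker_specs must be a list of marker_spec objects")
  names(marker_specs) <- vapply(marker_specs, `[[`, "", "name")
  if (anyDuplicated(names(marker_specs)))
    stop_config("duplicate marker names in marker_specs")

  for (col in c(subject_col, marker_col, response_col))
    if (!col %in% names(df))
      stop_config("required column '", col, "' absent from table")
  if (!is.null(visit_col) && !visit_col %in% names(df))
    stop_config("visit column '", visit_col, "' absent from table")

  unknown <- setdiff(unique(as.character(df[[marker_col]])), names(marker_specs))
  if (length(unknown))
    stop_config("marker name(s) in table without a specification: ",
                paste(unknown, collapse = ", "))

  miss <- is.na(df[[response_col]]) |
    (is.character(df[[response_col]]) & !nzchar(df[[response_col]]))
  n_dropped <- sum(miss)
  if (n_dropped > 0L) {
    message("read_long_table: dropped ", n_dropped, " row(s) with missing response")
    df <- df[!miss, , drop = FALSE]
  }
  df[[response_col]] <- as.numeric(df[[response_col]])

  ## canonical ordering: subject-major, marker blocks in spec order,
  ## then visit within a block
  subj <- df[[subject_col]]
  subjects <- sort(unique(subj))
  mk <- factor(as.character(df[[marker_col]]), levels = names(marker_specs))
  ord_keys <- list(match(subj, subjects), as.integer(mk))
  if (!is.null(visit_col)) ord_keys <- c(ord_keys, list(df[[visit_col]]))
  df <- df[do.call(order, ord_keys), , drop = FALSE]
  rownames(df) <- NULL

  ## family-specific response validation
  for (sp in marker_specs) {
    y <- df[[response_col]][df[[marker_col]] == sp$name]
    if (sp$family$family == "bernoulli" && length(y) && !all(y %in% c(0, 1)))
      stop_validation("marker '", sp$name, "': bernoulli responses must lie in {0,1}")
    if (sp$family$family == "poisson" && length(y) &&
        (any(y < 0) || any(abs(y - round(y)) > 1e-8)))
      stop_validation("marker '", sp$name, "': poisson responses must be non-negative integers")
  }

  m <- length(subjects)
  R <- length(marker_specs)
  n_ir <- matrix(0L, m, R, dimnames = list(as.character(subjects), names(marker_specs)))
  tab <- table(factor(match(df[[subject_col]], subjects), levels = seq_len(m)),
               factor(as.character(df[[marker_col]]), levels = names(marker_specs)))
  n_ir[] <- as.integer(tab)

  structure(
    list(data = df, specs = marker_specs, subjects = subjects,
         m = m, R = R, n_ir = n_ir, n_dropped = n_dropped,
         cols = list(subject = subject_col, marker = marker_col,
                     response = response_col, visit = visit_col)),
    class = "mglmm_data"
  )
}

#' @export
print.mglmm_data <- function(x, ...) {
  cat(sprintf("mglmm_data: %d subjects, %d markers, %d observations\n",
              x$m, x$R, nrow(x$data)))
  for (sp in x$specs)
    cat(sprintf("  %-12s %-9s n = %d\n", sp$name, sp$family$family,
                sum(x$n_ir[, sp$name])))
  invisible(x)
}
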