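# internal helpers shared across modules

# linear-interpolation percentile (quantile type 7), the package-wide
# convention for every threshold in the pipeline
pctl <- function(x, p) {
  stats::quantile(x, probs = p / 100, type = 7, names = FALSE, na.rm = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# coerce a matrix-like to dgCMatrix without densifying sparse input
as_sparse <- function(x) {
  if (inherits(x, "sparseMatrix")) methods::as(x, "CsparseMatrix")
  else Matrix::Matrix(as.matrix(x), sparse = TRUE)
}

check_cols <- function(df, cols, what = "metadata") {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stopf("%s is missing required column(s): %s", what,
          paste(miss, collapse = ", "))
  invisible(df)
}
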