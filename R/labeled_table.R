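#' Labeled patient-by-feature table
#'
#' The universal data container of the package: a numeric matrix of clinical
#' features (rows = patients, columns = indicators; `NA` marks a missing
#' cell) plus a binary outcome label per patient (1 = the outcome occurred).
#'
#' @param x numeric matrix, n samples by p features. Column names are used
#'   as feature names (generated as `V1..Vp` if absent).
#' @param y binary labels, length `nrow(x)`, coercible to 0/1.
#' @param sample_ids optional character ids, defaults to `s1..sn`.
#' @return an object of class `labeled_table` with elements `x`, `y`.
#' @examples
#' lt <- labeled_table(matrix(rnorm(20), 10, 2), rep(c(0, 1), 5))
#' dim(lt)
#' @export
labeled_table <- function(x, y, sample_ids = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  if (nrow(x) != length(y))
    stop("nrow(x) must equal length(y)")
  if (!all(y %in% c(0L, 1L)))
    stop("labels must be binary 0/1")
  if (is.null(colnames(x)))
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x)))
    stop("feature names must be unique")
  if (is.null(sample_ids))
    sample_ids <- if (!is.null(rownames(x))) rownames(x) else
      paste0("s", seq_len(nrow(x)))
  rownames(x) <- sample_ids
  structure(list(x = x, y = y), class = "labeled_table")
}

#' @export
dim.labeled_table <- function(x) dim(x$x)

#' @export
print.labeled_table <- function(x, ...) {
  cat(sprintf("<labeled_table> %d samples x %d features; %d positives (%.1f%%); %d missing cells\n",
              nrow(x$x), ncol(x$x), sum(x$y), 100 * mean(x$y),
              sum(is.na(x$x))))
  invisible(x)
}

#' Subset a labeled table
#'
#' @param x a `labeled_table`.
#' @param i,j row / column indices (any standard matrix index).
#' @param ... ignored.
#' @return a `labeled_table` restricted to the requested rows/features.
#' @export
`[.labeled_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$x))
  if (missing(j)) j <- seq_len(ncol(x$x))
  labeled_table(x$x[i, j, drop = FALSE], x$y[i],
                sample_ids = rownames(x$x)[i])
}

#' Read / write the cohort CSV dialect
#'
#' Plain CSV with a header; first column `sample_id`, last column
#' `label` in \{0,1\}, missing cells empty.
#'
#' @param path file path.
#' @return `read_cohort_csv`: a [labeled_table()].
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df)[1], "sample_id") ||
      !identical(names(df)[ncol(df)], "label"))
    stop("expected first column 'sample_id' and last column 'label'")
  p <- ncol(df) - 2L
  x <- as.matrix(df[, seq(2L, 1L + p), drop = FALSE])
  labeled_table(x, df$label, sample_ids = as.character(df$sample_id))
}

#' @param table a `labeled_table` to write.
#' @rdname read_cohort_csv
#' @return `write_cohort_csv`: `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  df <- data.frame(sample_id = rownames(table$x), table$x,
                   label = table$y, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

# Derive a per-stage seed from a global seed; keeps results < 2^31 and
# decorrelates stages by a simple name hash.
derive_seed <- function(seed, stage) {
  hash <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 7919 + hash * 104729) %% 2147483647)
}

# round-half-up to `digits` decimals (base round() is banker's rounding)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

sigmoid <- function(z) 1 / (1 + exp(-z))
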