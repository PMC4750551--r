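#' Construct a mixture data object
#'
#' Wraps an \eqn{N \times r} numeric matrix of continuous observations
#' together with the per-variable ranges and medians that drive the
#' data-dependent default priors, and (optionally) true class labels used
#' only for evaluation.
#'
#' @param y Numeric matrix (observations in rows) or a data frame of numeric
#'   columns.
#' @param labels Optional integer vector of true class labels, length
#'   `nrow(y)`. Used only by evaluation helpers, never by the sampler.
#' @return An object of class `mix_data`: a list with elements `y` (matrix),
#'   `N`, `r`, `R` (per-variable range, `max - min`), `med` (per-variable
#'   median) and `labels_true` (or `NULL`).
#' @examples
#' d <- mixture_data(matrix(rnorm(40), 20, 2))
#' d$R
#' @export
mixture_data <- function(y, labels = NULL) {
  if (is.data.frame(y)) y <- as.matrix(y)
  if (!is.matrix(y) || !is.numeric(y))
    stop("'y' must be a numeric matrix or data frame of numeric columns")
  if (anyNA(y)) stop("'y' contains missing values")
  N <- nrow(y)
  r <- ncol(y)
  if (N < 1L || r < 1L) stop("'y' must have at least one row and one column")
  R <- apply(y, 2L, function(col) diff(range(col)))
  if (any(R <= 0)) {
    bad <- which(R <= 0)
    nm <- colnames(y)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop("constant column(s) with zero range: ", paste(nm, collapse = ", "))
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != N)
      stop("'labels' must have length nrow(y) = ", N)
  }
  structure(
    list(y = y, N = N, r = r, R = R,
         med = apply(y, 2L, stats::median), labels_true = labels),
    class = "mix_data")
}

#' Read mixture data from a delimited text file
#'
#' Reads a CSV or TSV file with a header row and numeric columns; an optional
#' label column is split off as the true classification.
#'
#' @param path Path to a CSV (`.csv`) or otherwise tab-separated file.
#' @param label_col Optional name of a column holding true class labels.
#' @param sep Field separator; guessed from the file extension when `NULL`.
#' @return A `mix_data` object.
#' @export
read_mixture_data <- function(path, label_col = NULL, sep = NULL) {
  if (!file.exists(path)) stop("data file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          dec = ".", check.names = FALSE)
  labels <- NULL
  if (!is.null(label_col)) {
    if (!label_col %in% names(df))
      stop("label column '", label_col, "' not found in ", path)
    labels <- df[[label_col]]
    if (!is.numeric(labels)) labels <- as.integer(factor(labels))
    df[[label_col]] <- NULL
  }
  if (!all(vapply(df, is.numeric, logical(1L))))
    stop("all data columns must be numeric")
  mixture_data(as.matrix(df), labels = labels)
}

#' @export
print.mix_data <- function(x, ...) {
  cat("Mixture data: ", x$N, " observations of ", x$r, " variable(s)\n",
      sep = "")
  cat("  ranges: ", paste(signif(x$R, 4L), collapse = ", "), "\n", sep = "")
  if (!is.null(x$labels_true))
    cat("  true labels present (", length(unique(x$labels_true)),
        " classes)\n", sep = "")
  invisible(x)
}
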