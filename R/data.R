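#' Discrete datasets
#'
#' A `discrete_dataset` is a complete table of categorical records: every
#' variable has a declared, ordered level set and an integer layer tag
#' (0 = most upstream; used to build layering blacklists), and every cell
#' is a valid level.  Internally records are stored as a 1-based integer
#' matrix for fast counting.
#'
#' @param df a data frame of factors / character columns, or an integer
#'   matrix of level indices (then `levels` is required).
#' @param layers named integer vector (or single integer recycled) of layer
#'   tags; defaults to 0 for all variables.
#' @param levels optional named list of character level vectors; defaults
#'   to the observed factor levels.
#' @return An object of class `discrete_dataset`.
#' @export
discrete_dataset <- function(df, layers = NULL, levels = NULL) {
  if (is.matrix(df)) {
    if (is.null(levels)) stop_contract("levels are required with a matrix input")
    x <- df
    storage.mode(x) <- "integer"
    vars <- colnames(x)
  } else {
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    vars <- names(df)
    if (is.null(levels)) {
      levels <- lapply(df, function(col) {
        if (is.factor(col)) base::levels(col) else sort(unique(as.character(col)))
      })
      names(levels) <- vars
    }
    x <- matrix(0L, nrow(df), length(vars), dimnames = list(NULL, vars))
    for (j in seq_along(vars)) {
      v <- vars[j]
      col <- as.character(df[[j]])
      m <- match(col, levels[[v]])
      if (anyNA(m))
        stop_contract("variable %s has values outside its declared levels", v)
      x[, j] <- m
    }
  }
  if (nrow(x) < 1L) stop_contract("a dataset needs at least one record")
  if (anyNA(x)) stop_contract("dataset must be complete (no missing entries)")
  if (is.null(vars)) stop_contract("variables must be named")
  levels <- levels[vars]
  nl <- vapply(levels, length, 1L)
  if (any(nl < 2L)) stop_contract("every variable needs at least 2 levels")
  if (any(vapply(levels, anyDuplicated, 1L) > 0L))
    stop_contract("level labels must be unique")
  rng <- apply(x, 2L, max)
  if (any(rng > nl) || any(x < 1L))
    stop_contract("level index out of range")
  if (is.null(layers)) layers <- stats::setNames(rep(0L, length(vars)), vars)
  if (length(layers) == 1L && is.null(names(layers)))
    layers <- stats::setNames(rep(as.integer(layers), length(vars)), vars)
  layers <- as.integer(layers[vars])
  if (anyNA(layers) || any(layers < 0L))
    stop_contract("every variable needs a non-negative layer tag")
  names(layers) <- vars
  structure(list(x = x, levels = levels, layers = layers), class = "discrete_dataset")
}

#' @export
dim.discrete_dataset <- function(x) dim(x$x)

#' @export
print.discrete_dataset <- function(x, ...) {
  cat(sprintf("<discrete_dataset> %d records, %d variables\n",
              nrow(x$x), ncol(x$x)))
  cat("  ", paste0(colnames(x$x), "(", vapply(x$levels, length, 1L), ")",
                   collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.discrete_dataset <- function(x, ...) {
  out <- as.data.frame(lapply(seq_along(x$levels), function(j)
    factor(x$levels[[j]][x$x[, j]], levels = x$levels[[j]])))
  names(out) <- colnames(x$x)
  out
}

dataset_vars <- function(d) colnames(d$x)
dataset_nlev <- function(d) vapply(d$levels, length, 1L)

## Row subset preserving metadata.
dataset_subset <- function(d, idx) {
  d$x <- d$x[idx, , drop = FALSE]
  d
}

## Column subset preserving metadata.
dataset_select <- function(d, vars) {
  if (!all(vars %in% dataset_vars(d)))
    stop_identifier("unknown variable(s): %s",
                    paste(setdiff(vars, dataset_vars(d)), collapse = ", "))
  d$x <- d$x[, vars, drop = FALSE]
  d$levels <- d$levels[vars]
  d$layers <- d$layers[vars]
  d
}

#' Read / write datasets as CSV
#'
#' Plain UTF-8 comma-separated text with a header row; cells are level
#' labels compared as exact strings.  `write_dataset_csv` output is
#' byte-stable for identical inputs.
#'
#' @param d a `discrete_dataset`.
#' @param path file path.
#' @param layers,levels passed to [discrete_dataset()] on read.
#' @return `read_dataset_csv`: a `discrete_dataset`; `write_dataset_csv`:
#'   `path`, invisibly.
#' @export
write_dataset_csv <- function(d, path) {
  df <- as.data.frame(d)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path, layers = NULL, levels = NULL) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  discrete_dataset(df, layers = layers, levels = levels)
}
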