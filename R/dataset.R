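#' Construct a validated orchard dataset
#'
#' An \code{orchard_dataset} holds a samples-by-variables numeric matrix whose
#' columns are registered variable codes, together with the registry itself.
#' Columns are stored in registry order; validation rejects unregistered
#' columns, non-numeric values and missing values (the pipeline assumes
#' complete data and performs no imputation).
#'
#' @param values numeric matrix or data frame; column names must be registered
#'   codes. A subset of the registry (e.g. factors only) is allowed.
#' @param registry variable registry data frame (default packaged).
#' @param sample_ids optional character vector of sample identifiers; defaults
#'   to \code{orchard_001, ...}.
#' @return An object of class \code{orchard_dataset}: a list with elements
#'   \code{sample_ids}, \code{values} (matrix) and \code{registry}.
#' @examples
#' d <- make_study_like_dataset(n = 10, seed = 1)
#' dim(d$values)
#' @export
orchard_dataset <- function(values, registry = variable_registry(),
                            sample_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("values must have column names (variable codes)")
  unknown <- setdiff(colnames(values), registry$code)
  if (length(unknown) > 0)
    stop("unknown variable code(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated variable code(s) in columns")
  if (!is.numeric(values))
    stop("non-numeric values in dataset")
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at row %d, column %s",
                 idx[["row"]], colnames(values)[idx[["col"]]]))
  }
  # normalize column order to registry order
  ord <- intersect(registry$code, colnames(values))
  values <- values[, ord, drop = FALSE]
  n <- nrow(values)
  if (is.null(sample_ids)) sample_ids <- sprintf("orchard_%03d", seq_len(n))
  if (length(sample_ids) != n) stop("sample_ids length does not match rows")
  rownames(values) <- NULL
  structure(list(sample_ids = as.character(sample_ids),
                 values = values, registry = registry),
            class = "orchard_dataset")
}

#' @export
print.orchard_dataset <- function(x, ...) {
  cat(sprintf("<orchard_dataset> %d samples x %d variables\n",
              nrow(x$values), ncol(x$values)))
  cat("variables:", paste(colnames(x$values), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.orchard_dataset <- function(x) dim(x$values)

#' Read an orchard dataset from a delimited text file
#'
#' The file must be comma-separated with a header row of variable codes,
#' \code{"."} as decimal mark, UTF-8 encoded. All cells must be numeric and
#' present; violations raise an error naming the offending row and column.
#'
#' @param path file path.
#' @param registry variable registry (default packaged).
#' @return An \code{orchard_dataset}.
#' @seealso [write_dataset()]
#' @export
read_dataset <- function(path, registry = variable_registry()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  unknown <- setdiff(colnames(raw), registry$code)
  if (length(unknown) > 0)
    stop("unknown variable code(s) in header: ", paste(unknown, collapse = ", "))
  if (nrow(raw) == 0) {
    m <- matrix(numeric(0), nrow = 0, ncol = ncol(raw),
                dimnames = list(NULL, colnames(raw)))
    return(orchard_dataset(m, registry))
  }
  num <- matrix(NA_real_, nrow = nrow(raw), ncol = ncol(raw),
                dimnames = list(NULL, colnames(raw)))
  for (j in seq_len(ncol(raw))) {
    cell <- raw[[j]]
    bad <- which(is.na(cell) | cell == "")
    if (length(bad) > 0)
      stop(sprintf("missing value at row %d, column %s", bad[1L], colnames(raw)[j]))
    v <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(v))
    if (length(bad) > 0)
      stop(sprintf("non-numeric value '%s' at row %d, column %s",
                   cell[bad[1L]], bad[1L], colnames(raw)[j]))
    num[, j] <- v
  }
  orchard_dataset(num, registry)
}

#' Write an orchard dataset to CSV
#'
#' Emits a header of variable codes and one row per sample, at full double
#' precision (17 significant digits) so that \code{read_dataset()} reproduces
#' the matrix exactly and rewriting is byte-identical.
#'
#' @param dataset an \code{orchard_dataset}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "orchard_dataset"))
  v <- dataset$values
  header <- paste(colnames(v), collapse = ",")
  lines <- character(nrow(v))
  if (nrow(v) > 0) {
    txt <- matrix(sprintf("%.17g", v), nrow = nrow(v))
    lines <- apply(txt, 1L, paste, collapse = ",")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, lines), con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# internal: extract named columns as a matrix, erroring on absence
dataset_columns <- function(dataset, codes) {
  missing <- setdiff(codes, colnames(dataset$values))
  if (length(missing) > 0)
    stop("dataset lacks column(s): ", paste(missing, collapse = ", "))
  dataset$values[, codes, drop = FALSE]
}
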