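#' Pearson correlation matrix with two-level significance marks
#'
#' Product-moment correlations among all dataset columns, with two-sided
#' p-values from the t transform \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on
#' \eqn{n-2} degrees of freedom. Marks follow the usual star convention:
#' \code{"**"} for p <= 0.01, \code{"*"} for 0.01 < p <= 0.05, blank
#' otherwise; the diagonal is unmarked. No multiple-testing correction is
#' applied (the marks report raw per-pair levels).
#'
#' @param dataset an \code{orchard_dataset} with n >= 3 samples and no
#'   zero-variance column.
#' @return List of class \code{correlation_result} with \code{codes},
#'   \code{r}, \code{p} and \code{marks} matrices.
#' @examples
#' d <- make_study_like_dataset(n = 99, seed = 1)
#' cr <- pearson_matrix(d)
#' cr$marks["Y9", "S1"]
#' @export
pearson_matrix <- function(dataset) {
  v <- dataset$values
  n <- nrow(v)
  if (n < 3) stop("need at least 3 samples for correlation tests")
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "))
  r <- stats::cor(v)
  # exact |r| = 1 pairs get p = 0; clamp the t transform elsewhere
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1 - 1e-15] <- 0
  diag(p) <- 0
  marks <- matrix("", nrow = ncol(v), ncol = ncol(v),
                  dimnames = dimnames(r))
  marks[p <= 0.05] <- "*"
  marks[p <= 0.01] <- "**"
  diag(marks) <- ""
  structure(list(codes = colnames(v), r = r, p = p, marks = marks),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %d variables, %d marked pairs\n",
              length(x$codes),
              sum(x$marks[upper.tri(x$marks)] != "")))
  invisible(x)
}
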