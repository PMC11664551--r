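#' Per-variable descriptive statistics
#'
#' Maximum, minimum, mean, sample (n-1) standard deviation, coefficient of
#' variation (CV = std/mean, a proportion) and a variability class per
#' variable, in the layout of a field-survey summary table.
#'
#' @param dataset an \code{orchard_dataset} with at least 2 samples.
#' @return Data frame with columns \code{code}, \code{max}, \code{min},
#'   \code{mean}, \code{std}, \code{cv}, \code{variability}.
#' @examples
#' d <- make_study_like_dataset(n = 99, seed = 1)
#' head(summarize_dataset(d))
#' @export
summarize_dataset <- function(dataset) {
  v <- dataset$values
  if (nrow(v) < 2) stop("need at least 2 samples")
  out <- data.frame(
    code = colnames(v),
    max = apply(v, 2, max),
    min = apply(v, 2, min),
    mean = colMeans(v),
    std = apply(v, 2, stats::sd),
    stringsAsFactors = FALSE)
  out$cv <- ifelse(out$std == 0, 0, out$std / out$mean)
  out$variability = vapply(out$cv, classify_variability, character(1))
  rownames(out) <- NULL
  out
}

#' Classify a coefficient of variation
#'
#' Tripartition used throughout the package's reports: below 10 percent is
#' low variability, 10--30 percent moderate, above 30 percent high.
#'
#' @param cv coefficient of variation as a proportion (must be >= 0).
#' @return \code{"low"}, \code{"moderate"} or \code{"high"}.
#' @export
classify_variability <- function(cv) {
  if (is.na(cv) || cv < 0) stop("cv must be a nonnegative proportion")
  if (cv < 0.10) "low" else if (cv <= 0.30) "moderate" else "high"
}

#' Compare trait distributions above and below a factor's mean
#'
#' Splits the samples at the split factor's mean (samples exactly at the
#' threshold go to the above-group) and reports per-trait group sizes and
#' min/max/mean within each group, the layout used to assess how fruit
#' qualities differ under low versus high precipitation or temperature.
#'
#' @param dataset an \code{orchard_dataset}.
#' @param split_factor factor code to split on.
#' @param traits trait codes to compare (default all quality columns present).
#' @return List with \code{split_factor}, \code{threshold}, \code{n_below},
#'   \code{n_above} and a data frame \code{traits} of per-group statistics.
#' @export
split_compare <- function(dataset, split_factor,
                          traits = intersect(quality_codes(),
                                             colnames(dataset$values))) {
  x <- drop(dataset_columns(dataset, split_factor))
  threshold <- mean(x)
  above <- x >= threshold
  if (all(above) || !any(above))
    stop("split on ", split_factor, " leaves an empty group")
  tv <- dataset_columns(dataset, traits)
  stat <- function(m) data.frame(min = apply(m, 2, min),
                                 max = apply(m, 2, max),
                                 mean = colMeans(m))
  lo <- stat(tv[!above, , drop = FALSE])
  hi <- stat(tv[above, , drop = FALSE])
  tab <- data.frame(trait = traits,
                    below_min = lo$min, below_max = lo$max, below_mean = lo$mean,
                    above_min = hi$min, above_max = hi$max, above_mean = hi$mean,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(split_factor = split_factor, threshold = threshold,
       n_below = sum(!above), n_above = sum(above), traits = tab)
}

#' Quadratic trend of a trait against a factor
#'
#' Least-squares fit of \eqn{y = a_0 + a_1 x + a_2 x^2} (the second-order
#' polynomial used for trait-versus-topography trends), with R-squared from
#' residual and total sums of squares. A constant response is reported with
#' zero slope coefficients and R-squared defined as 0.
#'
#' @param dataset an \code{orchard_dataset}.
#' @param factor factor code (x).
#' @param trait trait code (y).
#' @return List with \code{factor}, \code{trait}, \code{coefficients}
#'   (\code{a0}, \code{a1}, \code{a2}) and \code{r_squared}.
#' @export
quadratic_trend <- function(dataset, factor, trait) {
  x <- drop(dataset_columns(dataset, factor))
  y <- drop(dataset_columns(dataset, trait))
  if (length(unique(x)) < 3)
    stop("need at least 3 distinct values of ", factor, " for a quadratic fit")
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- stats::coef(fit)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else 1 - sum(stats::residuals(fit)^2) / sst
  list(factor = factor, trait = trait,
       coefficients = c(a0 = unname(cf[1]), a1 = unname(cf[2]),
                        a2 = unname(cf[3])),
       r_squared = r2)
}
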