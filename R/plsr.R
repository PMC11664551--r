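#' Partial least squares regression by NIPALS (single response)
#'
#' Predictors and response are autoscaled (centered, unit variance), then
#' components are extracted one at a time: the weight vector is the
#' normalized covariance \eqn{w_a = X_a^T y_a / \|X_a^T y_a\|}, scores
#' \eqn{t_a = X_a w_a}, Y-loading \eqn{q_a = t_a^T y_a / t_a^T t_a}, and both
#' blocks are deflated by \eqn{t_a}. For a single response no inner iteration
#' is needed; each component is exact in one pass. Extraction stops early if
#' the response is numerically exhausted.
#'
#' @param X samples-by-predictors numeric matrix with column names.
#' @param y response vector.
#' @param A number of components, \code{1 <= A <= min(n - 1, ncol(X))}.
#' @param trait optional trait code recorded on the fit.
#' @return Object of class \code{plsr_fit}: weights \code{W} (columns of unit
#'   norm), X-loadings \code{P}, scores \code{T}, Y-loadings \code{q},
#'   per-component explained share of Y variance \code{explained}, component
#'   Y sums of squares \code{ssy}, and the autoscaling parameters.
#' @export
fit_plsr <- function(X, y, A, trait = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (A < 1 || A > min(n - 1, p))
    stop("A must satisfy 1 <= A <= min(n - 1, ncol(X))")
  xm <- colMeans(X); xs <- apply(X, 2, stats::sd)
  if (any(xs == 0))
    stop("zero-variance predictor column(s): ",
         paste(colnames(X)[xs == 0], collapse = ", "))
  ym <- mean(y); ys <- stats::sd(y)
  if (ys == 0) stop("zero-variance response")
  Xa <- scale(X, center = xm, scale = xs)
  ya <- (y - ym) / ys
  ssy_total <- sum(ya^2)
  W <- P <- matrix(0, p, 0); Tm <- matrix(0, n, 0); q <- ssy <- numeric(0)
  for (a in seq_len(A)) {
    wv <- drop(crossprod(Xa, ya))
    nw <- sqrt(sum(wv^2))
    if (nw < 1e-12) break     # response exhausted
    wv <- wv / nw
    tv <- drop(Xa %*% wv)
    tt <- sum(tv^2)
    if (tt < 1e-24) break
    pv <- drop(crossprod(Xa, tv)) / tt
    qa <- sum(tv * ya) / tt
    Xa <- Xa - tcrossprod(tv, pv)
    ya <- ya - tv * qa
    W <- cbind(W, wv); P <- cbind(P, pv); Tm <- cbind(Tm, tv)
    q <- c(q, qa); ssy <- c(ssy, qa^2 * tt)
  }
  if (ncol(W) == 0) stop("no component could be extracted")
  rownames(W) <- rownames(P) <- colnames(X)
  structure(list(trait = trait, predictors = colnames(X),
                 n_components = ncol(W), W = W, P = P, T = Tm, q = q,
                 ssy = ssy, explained = ssy / ssy_total,
                 x_center = xm, x_scale = xs, y_center = ym, y_scale = ys),
            class = "plsr_fit")
}

#' @export
print.plsr_fit <- function(x, ...) {
  cat(sprintf("<plsr_fit>%s %d predictors, %d components, cum. explained Y variance %.1f%%\n",
              if (is.null(x$trait)) "" else paste0(" ", x$trait),
              length(x$predictors), x$n_components,
              100 * sum(x$explained)))
  invisible(x)
}

#' Predict from a PLS fit
#' @param object a \code{plsr_fit}.
#' @param newdata matrix with the fit's predictor columns.
#' @param ... unused.
#' @return Numeric vector of predictions on the response's original scale.
#' @export
predict.plsr_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)[, object$predictors, drop = FALSE]
  B <- object$W %*% solve(crossprod(object$P, object$W), object$q)
  Xs <- scale(newdata, center = object$x_center, scale = object$x_scale)
  drop(object$y_center + object$y_scale * (Xs %*% B))
}

#' Variable importance for the projection (VIP)
#'
#' \deqn{VIP_j = \sqrt{ p \sum_a SSY_a w_{aj}^2 / \sum_a SSY_a }}
#' with \eqn{SSY_a = q_a^2 t_a^T t_a} the Y sum of squares captured by
#' component a and \eqn{w_a} the unit-norm weights; the mean of squared VIPs
#' is 1 by construction.
#'
#' @param fit a \code{plsr_fit}.
#' @return Named numeric vector of VIP scores, one per predictor.
#' @export
compute_vip <- function(fit) {
  if (sum(fit$ssy) <= 0) stop("response unexplained: all component SSY are zero")
  p <- length(fit$predictors)
  v <- sqrt(p * drop(fit$W^2 %*% fit$ssy) / sum(fit$ssy))
  stats::setNames(v, fit$predictors)
}

#' Choose the number of PLS components
#'
#' The smallest number of components whose cumulative explained share of the
#' response variance reaches \code{threshold}, capped at \code{max_A}. A
#' deterministic rule (rather than cross-validation) keeps the pipeline
#' reproducible; override the result explicitly where desired.
#'
#' @param X predictor matrix.
#' @param y response vector.
#' @param max_A cap on the number of components.
#' @param threshold cumulative explained-variance target (default 0.9).
#' @return Integer number of components.
#' @export
select_components <- function(X, y, max_A, threshold = 0.9) {
  fit <- fit_plsr(X, y, max_A)
  cum <- cumsum(fit$explained)
  hit <- which(cum >= threshold)
  if (length(hit) > 0) hit[1L] else fit$n_components
}

#' Screen predictors by VIP threshold
#'
#' Retains predictors whose VIP strictly exceeds the threshold (the
#' conventional importance cut-off is 1.0). An empty selection is allowed
#' and signals that the trait should be excluded from equation building.
#'
#' @param fit a \code{plsr_fit}.
#' @param threshold VIP cut-off (default 1.0, strict inequality).
#' @return List of class \code{screen_result}: \code{trait}, \code{selected},
#'   \code{vip}, \code{threshold}.
#' @export
screen_variables <- function(fit, threshold = 1.0) {
  vip <- compute_vip(fit)
  structure(list(trait = fit$trait, selected = names(vip)[vip > threshold],
                 vip = vip, threshold = threshold),
            class = "screen_result")
}

#' Factor contribution percentages
#'
#' Importance of each predictor expressed as a percentage:
#' \eqn{100 \cdot VIP_j^2 / \sum_k VIP_k^2}, which sums to 100 and is
#' additive over predictor subsets (so category totals are sums of member
#' percentages).
#'
#' @param fit a \code{plsr_fit}.
#' @return Named numeric vector of percentages summing to 100.
#' @export
contribution_percentages <- function(fit) {
  vip <- compute_vip(fit)
  100 * vip^2 / sum(vip^2)
}

#' PLSR screening of one trait of a dataset
#'
#' Convenience wrapper: selects the number of components on the trait,
#' fits the PLS model on the 16 factors, and screens by VIP.
#'
#' @param dataset an \code{orchard_dataset} containing the factor columns and
#'   the trait.
#' @param trait trait code.
#' @param components number of components, or \code{"auto"} (default) for
#'   the cumulative explained-variance rule.
#' @param vip_threshold VIP cut-off (default 1.0).
#' @param explained_threshold target for the automatic component rule.
#' @return A \code{screen_result} with the fit attached as \code{$fit}.
#' @export
plsr_screen <- function(dataset, trait, components = "auto",
                        vip_threshold = 1.0, explained_threshold = 0.9) {
  X <- dataset_columns(dataset, factor_codes())
  y <- drop(dataset_columns(dataset, trait))
  max_A <- min(nrow(X) - 1L, ncol(X))
  A <- if (identical(components, "auto"))
    select_components(X, y, max_A, explained_threshold)
  else as.integer(components)
  fit <- fit_plsr(X, y, A, trait = trait)
  res <- screen_variables(fit, vip_threshold)
  res$fit <- fit
  res
}
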