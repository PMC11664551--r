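#' Construct a linear trait equation
#'
#' One row of the equation system: a quality trait expressed as intercept
#' plus a linear combination of environmental factors, with the fit
#' statistics of the underlying regression.
#'
#' @param trait trait code.
#' @param intercept numeric intercept.
#' @param coefficients named numeric vector, names are factor codes.
#' @param n sample size of the fit (NA for packaged equations).
#' @param r_squared coefficient of determination (NA if unknown).
#' @param F overall F statistic (NA if unknown).
#' @param p_value two-sided p of the F test (NA if unknown).
#' @param p_printed p as printed in a report, e.g. \code{"<0.001"}.
#' @return Object of class \code{linear_equation}.
#' @export
linear_equation <- function(trait, intercept, coefficients,
                            n = NA_integer_, r_squared = NA_real_,
                            F = NA_real_, p_value = NA_real_,
                            p_printed = NA_character_) {
  stopifnot(is.numeric(intercept), is.numeric(coefficients),
            !is.null(names(coefficients)))
  bad <- setdiff(names(coefficients), factor_codes())
  if (length(bad) > 0)
    stop("coefficients reference unregistered factor code(s): ",
         paste(bad, collapse = ", "))
  structure(list(trait = trait, intercept = unname(intercept),
                 coefficients = coefficients, n = n, r_squared = r_squared,
                 F = F, p_value = p_value, p_printed = p_printed),
            class = "linear_equation")
}

#' @export
format.linear_equation <- function(x, digits = 3, ...) {
  cf <- round(x$coefficients, digits)
  terms <- sprintf("%s%s%s", ifelse(cf < 0, " - ", " + "), abs(cf), names(cf))
  paste0(x$trait, " = ", round(x$intercept, digits), paste(terms, collapse = ""))
}

#' @export
print.linear_equation <- function(x, ...) {
  cat(format(x), "\n")
  if (!is.na(x$F)) cat(sprintf("  F = %.2f, p = %s\n", x$F,
                               if (!is.na(x$p_printed)) x$p_printed
                               else format.pval(x$p_value, digits = 3)))
  invisible(x)
}

#' Evaluate a trait equation at given factor values
#'
#' @param eq a \code{linear_equation}.
#' @param factor_values named numeric vector (or single-row matrix/data frame)
#'   covering every factor code the equation references.
#' @return The predicted trait value.
#' @examples
#' eq <- table4_equations()$equations[["Y9"]]
#' evaluate_equation(eq, c(S1 = 7.50, S9 = 0.46, S11 = 2.66, S12 = 4.00))
#' @export
evaluate_equation <- function(eq, factor_values) {
  if (is.matrix(factor_values) || is.data.frame(factor_values))
    factor_values <- unlist(as.data.frame(factor_values)[1L, ])
  missing <- setdiff(names(eq$coefficients), names(factor_values))
  if (length(missing) > 0)
    stop("missing factor value(s): ", paste(missing, collapse = ", "))
  eq$intercept + sum(eq$coefficients * factor_values[names(eq$coefficients)])
}

#' Ordinary least squares refit of a trait on selected factors
#'
#' After VIP screening, the retained factors are refit by OLS (via
#' \code{stats::lm}), yielding the classical overall F statistic
#' \eqn{F = (R^2/k) / ((1-R^2)/(n-k-1))} and its p-value from the F
#' distribution with \eqn{(k, n-k-1)} degrees of freedom.
#'
#' @param dataset an \code{orchard_dataset}.
#' @param trait trait code (response).
#' @param selected non-empty character vector of factor codes.
#' @return A \code{linear_equation} with fit statistics.
#' @export
fit_ols <- function(dataset, trait, selected) {
  if (length(selected) == 0)
    stop("empty selection for trait ", trait,
         ": exclude this trait from the equation system")
  y <- drop(dataset_columns(dataset, trait))
  X <- dataset_columns(dataset, selected)
  n <- length(y)
  k <- length(selected)
  if (n <= k + 1) stop("need n > k + 1 samples for the F test")
  df <- data.frame(.y = y, X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df)
  if (anyNA(stats::coef(fit))) stop("singular design for trait ", trait)
  r2 <- summary(fit)$r.squared
  Fstat <- (r2 / k) / ((1 - r2) / (n - k - 1))
  p <- stats::pf(Fstat, k, n - k - 1, lower.tail = FALSE)
  cf <- stats::coef(fit)
  linear_equation(trait, intercept = cf[["(Intercept)"]],
                  coefficients = cf[setdiff(names(cf), "(Intercept)")],
                  n = n, r_squared = r2, F = Fstat, p_value = p,
                  p_printed = if (p < 0.001) "<0.001"
                              else sprintf("%.3f", p))
}

#' Assemble an equation system from screening results
#'
#' One OLS equation per trait with a non-empty VIP selection; traits whose
#' screening selected no factor are omitted with a warning (as TSS, for which
#' no factor passes VIP screening, has no equation).
#'
#' @param dataset an \code{orchard_dataset}.
#' @param screen_results list of screening results (from
#'   [screen_variables()]), one per candidate trait.
#' @return Object of class \code{equation_system} with provenance
#'   \code{"fitted"}.
#' @export
build_system <- function(dataset, screen_results) {
  eqs <- list()
  for (sr in screen_results) {
    if (length(sr$selected) == 0) {
      warning("no factor passed VIP screening for trait ", sr$trait,
              "; omitted from the equation system", call. = FALSE)
      next
    }
    eqs[[sr$trait]] <- fit_ols(dataset, sr$trait, sr$selected)
  }
  equation_system(eqs, provenance = "fitted")
}

#' Construct an equation system
#' @param equations named (or trait-named) list of \code{linear_equation}.
#' @param provenance \code{"fitted"} or \code{"packaged-table-4"}.
#' @return Object of class \code{equation_system}.
#' @export
equation_system <- function(equations, provenance = "fitted") {
  traits <- vapply(equations, function(e) e$trait, character(1))
  if (anyDuplicated(traits)) stop("duplicate trait codes in system")
  names(equations) <- traits
  structure(list(equations = equations, provenance = provenance),
            class = "equation_system")
}

#' @export
print.equation_system <- function(x, ...) {
  cat(sprintf("<equation_system> %d equations (%s)\n",
              length(x$equations), x$provenance))
  for (eq in x$equations) cat(" ", format(eq), "\n")
  invisible(x)
}

# cache for the packaged system (fixture parse is cheap but called often)
.navelopt_cache <- new.env(parent = emptyenv())

#' The packaged trait-equation system for the Gannan core production area
#'
#' Eleven regression equations linking the modeled fruit-quality traits
#' (Y1--Y11) to the environmental factors retained by VIP screening in the
#' 99-orchard survey, with their published overall F statistics. Coefficients
#' are stored exactly as published.
#'
#' @return An \code{equation_system} with provenance
#'   \code{"packaged-table-4"}.
#' @examples
#' sys <- table4_equations()
#' sys$equations[["Y1"]]
#' @export
table4_equations <- function() {
  if (!is.null(.navelopt_cache$table4)) return(.navelopt_cache$table4)
  coefs <- utils::read.csv(system.file("extdata", "table4_equations.csv",
                                       package = "navelopt", mustWork = TRUE),
                           stringsAsFactors = FALSE)
  stats_tab <- utils::read.csv(system.file("extdata", "table4_fit_stats.csv",
                                           package = "navelopt", mustWork = TRUE),
                               stringsAsFactors = FALSE,
                               colClasses = c("character", "numeric", "character"))
  eqs <- lapply(split(coefs, factor(coefs$trait, levels = unique(coefs$trait))),
                function(d) {
    tr <- d$trait[1L]
    ic <- d$coefficient[d$term == "(Intercept)"]
    cf <- stats::setNames(d$coefficient[d$term != "(Intercept)"],
                          d$term[d$term != "(Intercept)"])
    st <- stats_tab[stats_tab$trait == tr, ]
    linear_equation(tr, ic, cf, n = 99L, F = st$F, p_printed = st$p)
  })
  sys <- equation_system(eqs, provenance = "packaged-table-4")
  .navelopt_cache$table4 <- sys
  sys
}
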