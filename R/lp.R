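#' Default optimization bounds
#'
#' Box bounds for the 16 environmental factors (lower = survey mean, upper =
#' survey maximum) and one bound per modeled trait: traits whose sense is
#' maximize must stay at or above their survey mean, and the two
#' minimize-sense traits (shape index Y4, titratable acid Y9) at or below
#' theirs. This encodes the rule that every quality index must reach at least
#' the sampled average while factors stay within observed upper limits.
#'
#' @param marginals marginal statistics table (default packaged).
#' @param registry variable registry (default packaged).
#' @return List of class \code{bounds_spec} with data frames
#'   \code{factor_bounds} (\code{code}, \code{lower}, \code{upper}) and
#'   \code{trait_bounds} (\code{trait}, \code{direction}, \code{bound}).
#' @export
default_bounds <- function(marginals = default_marginals(),
                           registry = variable_registry()) {
  fm <- marginals[match(factor_codes(), marginals$code), ]
  factor_bounds <- data.frame(code = fm$code, lower = fm$mean, upper = fm$max,
                              stringsAsFactors = FALSE)
  tr <- modeled_traits()
  tm <- marginals[match(tr, marginals$code), ]
  sense <- trait_sense(tr, registry)
  trait_bounds <- data.frame(trait = tr,
                             direction = ifelse(sense == "minimize", "<=", ">="),
                             bound = tm$mean, stringsAsFactors = FALSE)
  bounds_spec(factor_bounds, trait_bounds)
}

#' Construct a bounds specification
#' @param factor_bounds data frame \code{code}, \code{lower}, \code{upper}.
#' @param trait_bounds data frame \code{trait}, \code{direction}
#'   (\code{">="} or \code{"<="}), \code{bound}.
#' @return Object of class \code{bounds_spec}.
#' @export
bounds_spec <- function(factor_bounds, trait_bounds) {
  stopifnot(all(c("code", "lower", "upper") %in% names(factor_bounds)),
            all(c("trait", "direction", "bound") %in% names(trait_bounds)),
            all(trait_bounds$direction %in% c("<=", ">=")))
  if (any(factor_bounds$lower > factor_bounds$upper))
    stop("factor bound with lower > upper")
  structure(list(factor_bounds = factor_bounds, trait_bounds = trait_bounds),
            class = "bounds_spec")
}

#' Build the linear program for one target trait
#'
#' The target trait's equation becomes the objective (maximized, or minimized
#' for the two minimize-sense traits); every other equation in the system
#' becomes a linear constraint at its registered direction and bound; the 16
#' factors carry box constraints. The target's own trait bound is omitted.
#'
#' @param system an \code{equation_system}.
#' @param target trait code present in the system.
#' @param bounds a \code{bounds_spec} (default [default_bounds()]).
#' @param registry variable registry (default packaged).
#' @return List of class \code{lp_problem}.
#' @export
build_lp <- function(system, target, bounds = default_bounds(),
                     registry = variable_registry()) {
  if (!target %in% names(system$equations))
    stop("target trait ", target, " is not in the equation system")
  fb <- bounds$factor_bounds
  if (!setequal(fb$code, factor_codes()) || any(!is.finite(fb$lower)) ||
      any(!is.finite(fb$upper)))
    stop("every factor must have finite box bounds")
  sense <- trait_sense(target, registry)
  if (sense == "none")
    stop("trait ", target, " has no optimization sense")
  constraints <- list()
  for (tr in setdiff(names(system$equations), target)) {
    tb <- bounds$trait_bounds[bounds$trait_bounds$trait == tr, ]
    if (nrow(tb) != 1) stop("no trait bound for ", tr)
    constraints[[tr]] <- list(trait = tr, equation = system$equations[[tr]],
                              direction = tb$direction, bound = tb$bound)
  }
  structure(list(target = target, sense = sense,
                 objective = system$equations[[target]],
                 constraints = constraints, box = fb),
            class = "lp_problem")
}

# internal: dense coefficient row over the 16 factors
lp_row <- function(eq) {
  v <- stats::setNames(numeric(16), factor_codes())
  v[names(eq$coefficients)] <- eq$coefficients
  v
}

#' Solve a quality linear program
#'
#' Solves via the package's dense two-phase simplex (see
#' \code{\link{simplex_solve}}) after shifting each factor to its lower
#' bound so all decision variables are nonnegative. Factors that appear
#' neither in the objective nor in any binding constraint are flagged: their
#' value at the optimum is arbitrary within the box (alternative optima), so
#' only the objective value is vertex-independent for them.
#'
#' @param problem an \code{lp_problem}.
#' @param tol feasibility/binding tolerance (absolute, default 1e-6).
#' @return List of class \code{lp_solution}: \code{status} (\code{"optimal"},
#'   \code{"infeasible"} or \code{"unbounded"}), \code{factor_values},
#'   \code{objective_value}, \code{binding} (constraint trait codes active
#'   within tolerance) and \code{nonunique} (factor codes with possibly
#'   non-unique values).
#' @export
solve_lp <- function(problem, tol = 1e-6) {
  fac <- factor_codes()
  lo <- stats::setNames(problem$box$lower, problem$box$code)[fac]
  hi <- stats::setNames(problem$box$upper, problem$box$code)[fac]
  obj <- lp_row(problem$objective)
  # z = x - lo >= 0; upper box as identity rows
  A <- diag(length(fac)); dirs <- rep("<=", length(fac)); rhs <- hi - lo
  for (cn in problem$constraints) {
    a <- lp_row(cn$equation)
    A <- rbind(A, a)
    dirs <- c(dirs, cn$direction)
    rhs <- c(rhs, cn$bound - cn$equation$intercept - sum(a * lo))
  }
  s <- simplex_solve(obj, A, dirs, rhs,
                     maximize = (problem$sense == "maximize"))
  if (s$status != "optimal")
    return(structure(list(status = s$status, factor_values = NULL,
                          objective_value = NA_real_, binding = character(0),
                          nonunique = character(0), target = problem$target),
                     class = "lp_solution"))
  x <- lo + stats::setNames(s$x[seq_along(fac)], fac)
  objective_value <- problem$objective$intercept + sum(obj * x)
  binding <- character(0)
  viol <- 0
  for (cn in problem$constraints) {
    val <- evaluate_equation(cn$equation, x)
    gap <- if (cn$direction == "<=") cn$bound - val else val - cn$bound
    viol <- max(viol, -gap)
    if (abs(gap) <= tol) binding <- c(binding, cn$trait)
  }
  viol <- max(viol, lo - x, x - hi)
  if (viol > tol)
    warning(sprintf("solution violates a constraint by %.2e", viol))
  active_rows <- lapply(problem$constraints[binding],
                        function(cn) lp_row(cn$equation))
  touched <- abs(obj) > 0
  for (a in active_rows) touched <- touched | abs(a) > 0
  structure(list(status = "optimal", factor_values = x,
                 objective_value = objective_value, binding = binding,
                 nonunique = fac[!touched], target = problem$target),
            class = "lp_solution")
}

#' @export
print.lp_solution <- function(x, ...) {
  cat(sprintf("<lp_solution> %s: %s, objective %.4f\n",
              if (is.null(x$target)) "" else x$target, x$status,
              x$objective_value))
  invisible(x)
}

#' Solve one program per modeled trait and assemble optimal ranges
#'
#' Runs [build_lp()]/[solve_lp()] with each equation in the system as the
#' objective in turn, then tabulates every factor's value across the optimal
#' solutions and its min--max range (collapsed to a single value when all
#' solutions agree).
#'
#' @param system an \code{equation_system}.
#' @param bounds a \code{bounds_spec} (default [default_bounds()]).
#' @param tol feasibility tolerance passed to [solve_lp()].
#' @return List with \code{solutions} (named list of \code{lp_solution}) and
#'   \code{range_table}: a data frame with one row per factor, one column per
#'   solved objective, plus \code{range_lower}/\code{range_upper}.
#' @examples
#' res <- optimize_all(table4_equations())
#' res$solutions[["Y9"]]$objective_value
#' subset(res$range_table, code == "S12")
#' @export
optimize_all <- function(system, bounds = default_bounds(), tol = 1e-6) {
  targets <- names(system$equations)
  solutions <- lapply(targets, function(tr)
    solve_lp(build_lp(system, tr, bounds), tol = tol))
  names(solutions) <- targets
  ok <- vapply(solutions, function(s) s$status == "optimal", logical(1))
  fac <- factor_codes()
  vals <- sapply(solutions[ok], function(s) s$factor_values[fac])
  range_table <- data.frame(code = fac,
                            vals,
                            range_lower = apply(vals, 1, min),
                            range_upper = apply(vals, 1, max),
                            stringsAsFactors = FALSE, check.names = FALSE)
  rownames(range_table) <- NULL
  list(solutions = solutions, range_table = range_table)
}
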