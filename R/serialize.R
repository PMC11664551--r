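#' Write an equation system to CSV
#'
#' Long format (\code{trait}, \code{term}, \code{coefficient}) with the
#' intercept as term \code{"(Intercept)"}, at full double precision, plus a
#' companion \code{<path>_stats.csv} holding n, R-squared, F and p per trait.
#' The same format as the packaged equation fixture, so the optimizer
#' consumes fitted and packaged systems interchangeably.
#'
#' @param system an \code{equation_system}.
#' @param path output CSV path for the coefficients.
#' @return \code{path}, invisibly.
#' @export
write_equation_system <- function(system, path) {
  rows <- do.call(rbind, lapply(system$equations, function(eq) {
    data.frame(trait = eq$trait,
               term = c("(Intercept)", names(eq$coefficients)),
               coefficient = sprintf("%.17g", c(eq$intercept, eq$coefficients)),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  stats_rows <- do.call(rbind, lapply(system$equations, function(eq)
    data.frame(trait = eq$trait, n = eq$n,
               r_squared = eq$r_squared, F = eq$F, p_value = eq$p_value,
               stringsAsFactors = FALSE)))
  utils::write.csv(stats_rows, sub("\\.csv$", "_stats.csv", path),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an equation system written by [write_equation_system()]
#' @param path coefficients CSV path.
#' @param provenance provenance tag for the loaded system.
#' @return An \code{equation_system}.
#' @export
read_equation_system <- function(path, provenance = "fitted") {
  coefs <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats_path <- sub("\\.csv$", "_stats.csv", path)
  st <- if (file.exists(stats_path))
    utils::read.csv(stats_path, stringsAsFactors = FALSE) else NULL
  eqs <- lapply(split(coefs, factor(coefs$trait, levels = unique(coefs$trait))),
                function(d) {
    tr <- d$trait[1L]
    ic <- d$coefficient[d$term == "(Intercept)"]
    cf <- stats::setNames(d$coefficient[d$term != "(Intercept)"],
                          d$term[d$term != "(Intercept)"])
    s <- if (!is.null(st) && tr %in% st$trait) st[st$trait == tr, ] else NULL
    linear_equation(tr, ic, cf,
                    n = if (is.null(s)) NA_integer_ else s$n,
                    r_squared = if (is.null(s)) NA_real_ else s$r_squared,
                    F = if (is.null(s)) NA_real_ else s$F,
                    p_value = if (is.null(s)) NA_real_ else s$p_value)
  })
  equation_system(eqs, provenance = provenance)
}
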