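#' Pipeline configuration
#'
#' Exactly one of \code{input} (path to an orchard CSV) and \code{simulate}
#' (a list with \code{n} and optionally \code{noise_sd}) must be given.
#'
#' @param input path to an input dataset CSV, or \code{NULL}.
#' @param simulate list of simulation settings (\code{n}, \code{noise_sd}),
#'   or \code{NULL}.
#' @param seed integer seed governing all stochastic stages.
#' @param components \code{"auto"} or a fixed number of PLS components.
#' @param vip_threshold VIP screening cut-off (default 1.0).
#' @param explained_threshold cumulative explained-variance target for the
#'   automatic component rule (default 0.9).
#' @param bounds a \code{bounds_spec} for the optimization stage.
#' @param out_dir directory for report artifacts, or \code{NULL} to skip
#'   writing.
#' @param verbose print per-stage progress.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input = NULL, simulate = NULL, seed = 1,
                            components = "auto", vip_threshold = 1.0,
                            explained_threshold = 0.9,
                            bounds = default_bounds(), out_dir = NULL,
                            verbose = FALSE) {
  if (is.null(input) == is.null(simulate))
    stop("exactly one of 'input' and 'simulate' must be set")
  structure(list(input = input, simulate = simulate, seed = as.integer(seed),
                 components = components, vip_threshold = vip_threshold,
                 explained_threshold = explained_threshold, bounds = bounds,
                 out_dir = out_dir, verbose = verbose),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: load or simulate the dataset; descriptive summary; Pearson
#' correlation matrix with significance marks; per-trait PLSR with VIP
#' screening; OLS refit of the screened factors into an equation system; one
#' linear program per trait and the optimal-range table. Only the eleven
#' modeled traits enter screening and optimization (TSS carries no
#' optimization sense and no equation). Identical config and seed reproduce
#' the bundle exactly.
#'
#' @param config a \code{pipeline_config}.
#' @return A report bundle: list with \code{dataset}, \code{summary},
#'   \code{correlation}, \code{screens}, \code{system}, \code{optimization}
#'   and \code{config}. If \code{out_dir} is set, CSV artifacts and a
#'   markdown report are written there.
#' @examples
#' cfg <- pipeline_config(simulate = list(n = 99), seed = 7)
#' bundle <- run_pipeline(cfg)
#' bundle$system
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (config$verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dataset <- stage("input", {
    if (!is.null(config$input)) read_dataset(config$input)
    else make_study_like_dataset(n = config$simulate$n, seed = config$seed,
                                 noise_sd = config$simulate$noise_sd)
  })
  say(sprintf("dataset: %d samples x %d variables", nrow(dataset$values),
              ncol(dataset$values)))
  summary_tab <- stage("describe", summarize_dataset(dataset))
  correlation <- stage("correlate", pearson_matrix(dataset))
  screens <- stage("screen", lapply(modeled_traits(), function(tr) {
    sr <- plsr_screen(dataset, tr, components = config$components,
                      vip_threshold = config$vip_threshold,
                      explained_threshold = config$explained_threshold)
    say(sprintf("%s: %d components, selected {%s}", tr, sr$fit$n_components,
                paste(sr$selected, collapse = ", ")))
    sr
  }))
  system <- stage("fit", build_system(dataset, screens))
  optimization <- stage("optimize", optimize_all(system, config$bounds))
  bundle <- list(dataset = dataset, summary = summary_tab,
                 correlation = correlation, screens = screens,
                 system = system, optimization = optimization,
                 config = config)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

# internal: write all bundle artifacts under out_dir
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  write_dataset(bundle$dataset, fp("dataset.csv"))
  utils::write.csv(round_df(bundle$summary, 4), fp("summary.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(round(bundle$correlation$r, 6), fp("correlation_r.csv"),
                   quote = FALSE)
  utils::write.csv(bundle$correlation$marks, fp("correlation_marks.csv"))
  write_equation_system(bundle$system, fp("equations.csv"))
  rt <- bundle$optimization$range_table
  num <- vapply(rt, is.numeric, logical(1))
  rt[num] <- lapply(rt[num], round, 6)
  utils::write.csv(rt, fp("range_table.csv"), row.names = FALSE, quote = FALSE)
  writeLines(render_report(bundle), fp("report.md"))
  invisible(out_dir)
}

round_df <- function(d, digits) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], round, digits)
  d
}

fmt <- function(x, digits) formatC(x, format = "f", digits = digits)

md_table <- function(d) {
  cells <- vapply(d, function(col) as.character(col), character(nrow(d)))
  if (nrow(d) == 1) cells <- matrix(cells, nrow = 1)
  c(paste0("| ", paste(names(d), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(d)), collapse = "|"), "|"),
    apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}

#' Render a report bundle as markdown
#'
#' Print conventions: descriptive statistics at 2 decimals, equation
#' coefficients at 3, contribution percentages at 2, optimization results
#' at 2.
#'
#' @param bundle a bundle from [run_pipeline()].
#' @return Character vector of markdown lines.
#' @export
render_report <- function(bundle) {
  lines <- c("# Orchard environment and fruit quality report", "")
  s <- bundle$summary
  st <- data.frame(code = s$code, max = fmt(s$max, 2), min = fmt(s$min, 2),
                   mean = fmt(s$mean, 2), std = fmt(s$std, 2),
                   cv = paste0(round(100 * s$cv), "%"),
                   variability = s$variability)
  lines <- c(lines, "## Descriptive statistics", "", md_table(st), "")
  m <- bundle$correlation$marks
  n_sig <- sum(m[upper.tri(m)] != "")
  lines <- c(lines, "## Correlation screening", "",
             sprintf("%d of %d variable pairs significant at the 0.05 level or below.",
                     n_sig, sum(upper.tri(m))), "")
  lines <- c(lines, "## VIP screening and equations", "")
  for (sr in bundle$screens) {
    eq <- bundle$system$equations[[sr$trait]]
    pct <- contribution_percentages(sr$fit)
    sel_pct <- paste(sprintf("%s %s%%", sr$selected,
                             fmt(pct[sr$selected], 2)), collapse = ", ")
    lines <- c(lines,
               sprintf("- %s (%d components): selected %s", sr$trait,
                       sr$fit$n_components,
                       if (length(sr$selected) == 0) "none" else sel_pct))
    if (!is.null(eq))
      lines <- c(lines, sprintf("  - `%s` (F = %s, p = %s)", format(eq),
                                fmt(eq$F, 2),
                                if (!is.na(eq$p_printed)) eq$p_printed
                                else fmt(eq$p_value, 3)))
  }
  lines <- c(lines, "", "## Optimal environmental-factor ranges", "")
  rt <- bundle$optimization$range_table
  obj_cols <- setdiff(names(rt), c("code", "range_lower", "range_upper"))
  disp <- data.frame(code = rt$code)
  for (cc in obj_cols) disp[[cc]] <- fmt(rt[[cc]], 2)
  disp$range <- ifelse(abs(rt$range_upper - rt$range_lower) < 5e-3,
                       fmt(rt$range_lower, 2),
                       paste0(fmt(rt$range_lower, 2), "-",
                              fmt(rt$range_upper, 2)))
  lines <- c(lines, md_table(disp), "", "## Optimal objective values", "")
  for (tr in names(bundle$optimization$solutions)) {
    sol <- bundle$optimization$solutions[[tr]]
    lines <- c(lines, sprintf("- %s: %s%s", tr, sol$status,
                              if (sol$status == "optimal")
                                paste0(", objective ", fmt(sol$objective_value, 2))
                              else ""))
  }
  lines
}
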