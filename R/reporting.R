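#' Run one full analysis question and write its result files
#'
#' Orchestrates a complete analysis: builds the scenario grid, runs every
#' scenario to steady state, and writes `scenarios.csv` (inputs),
#' `results.csv` (one row per scenario with final state and outcome), a
#' `summary.json` (outcome counts and, for Q3, the bistable fishing range
#' and `f = 0` recovery threshold) and a `manifest.json` recording the
#' parameter set and grid sizes. Everything is deterministic: the same
#' configuration always produces byte-identical CSV output.
#'
#' @param question `"Q1"`, `"Q2"` or `"Q3"`.
#' @param community Preset name or named `(G0, B0, R0)` vector (ignored
#'   for Q1, which varies the community itself).
#' @param params A [reef_params()] object.
#' @param out_dir Output directory, created if missing. `NULL` skips
#'   writing and just returns the results.
#' @param t_end Integration horizon in years.
#' @inheritParams run_scenarios
#' @param ... Grid overrides passed to [q1_grid()], [q2_grid()] or
#'   [q3_grid()] (e.g. `fishing_levels`, `step`, `coral_step`).
#' @return Invisibly, a list with `results` (data frame) and `summary`.
#' @export
run_question <- function(question = c("Q1", "Q2", "Q3"),
                         community = "even", params = reef_params(),
                         out_dir = NULL, t_end = 1000,
                         herbivore_scale = c("capacity", "absolute"),
                         ...) {
  question <- match.arg(question)
  scen <- switch(question,
    Q1 = q1_grid(...),
    Q2 = q2_grid(community = community, ...),
    Q3 = q3_grid(community = community, ...)
  )
  res <- run_scenarios(scen, params, t_end = t_end,
                       herbivore_scale = herbivore_scale)
  summary <- list(
    question = question,
    n_scenarios = nrow(res),
    n_not_converged = sum(!res$converged),
    outcome_counts = as.list(table(res$outcome)),
    dominant_alga_counts = as.list(table(res$dominant_alga))
  )
  if (question == "Q3") {
    map <- results_to_map(res, community)
    rng <- bistable_fishing_range(map)
    summary$bistable_fishing_range <- if (length(rng) > 0)
      list(min = min(rng), max = max(rng), n = length(rng)) else
      list(min = NA, max = NA, n = 0L)
    summary$recovery_threshold_f0 <- recovery_threshold(map, 0)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(scen, file.path(out_dir, "scenarios.csv"), row.names = FALSE)
    write.csv(res, file.path(out_dir, "results.csv"), row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(
      list(question = question,
           community = if (is.character(community)) community else
             as.list(community),
           params = unclass(params), t_end = t_end,
           n_scenarios = nrow(res),
           written = format(Sys.time(), tz = "UTC")),
      file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(results = res, summary = summary))
}

# Rebuild a bistability_map object from a Q3 results table.
results_to_map <- function(res, community = "custom") {
  coral_axis <- sort(unique(res$C0))
  fishing_axis <- sort(unique(res$f))
  m <- matrix(NA_real_, length(fishing_axis), length(coral_axis))
  m[cbind(match(res$f, fishing_axis), match(res$C0, coral_axis))] <- res$C
  structure(list(
    community = if (is.character(community)) community else "custom",
    coral_axis = coral_axis, fishing_axis = fishing_axis,
    final_coral = m, results = res
  ), class = "bistability_map")
}

#' Repeat an analysis across values of one model parameter
#'
#' Generic one-at-a-time sensitivity capability: re-runs an arbitrary
#' analysis for each value of a single model parameter and collects the
#' results. The analysis is supplied as a function of a [reef_params()]
#' object, e.g. `function(p) bistability_map("even", p, coral_step = 0.05,
#' fishing_step = 0.05)`.
#'
#' @param parameter Name of a [reef_params()] field.
#' @param values Values to substitute.
#' @param run_fn Function taking a `reef_params` object.
#' @param params Base parameter set.
#' @return Named list of `run_fn` outputs, one per value.
#' @export
sensitivity_sweep <- function(parameter, values, run_fn,
                              params = reef_params()) {
  if (!parameter %in% reef_param_names()) {
    stop("unknown parameter name: ", parameter)
  }
  out <- lapply(values, function(v) {
    run_fn(do.call(update_params, setNames(list(params, v),
                                           c("params", parameter))))
  })
  names(out) <- format(values)
  out
}

#' Export a bistability map or hysteresis curves to CSV
#'
#' `write_bistability_map()` writes the final-coral matrix (rows =
#' fishing pressures, columns = initial coral covers). `write_hysteresis()`
#' writes one `fishing, final_coral` table per sweep direction.
#'
#' @param map A [bistability_map()].
#' @param curves A list with `forward` and `reverse` [sweep_fishing()]
#'   curves, as returned by [hysteresis_sweep()].
#' @param path,dir Output file / directory.
#' @return The written path(s), invisibly.
#' @export
write_bistability_map <- function(map, path) {
  stopifnot(inherits(map, "bistability_map"))
  df <- data.frame(f = map$fishing_axis, map$final_coral,
                   check.names = FALSE)
  names(df) <- c("f", format(map$coral_axis))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bistability_map
#' @export
write_hysteresis <- function(curves, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (d in c("forward", "reverse")) {
    cv <- curves[[d]]
    p <- file.path(dir, paste0("hysteresis_", d, ".csv"))
    write.csv(data.frame(f = cv$fishing_axis,
                         final_coral = cv$final_coral),
              p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Heatmap of a bistability map
#'
#' Convenience ggplot of final coral cover over the fishing and
#' initial-coral axes. Requires ggplot2.
#'
#' @param map A [bistability_map()].
#' @return A ggplot object.
#' @export
plot_bistability_map <- function(map) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- map$results
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f, y = .data$C0,
                                   fill = .data$C)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1),
                                  name = "final coral") +
    ggplot2::labs(x = "fishing pressure", y = "initial coral cover",
                  title = paste("Final coral cover:", map$community)) +
    ggplot2::theme_minimal()
}
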