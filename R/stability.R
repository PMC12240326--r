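#' Map final coral cover over initial coral cover and fishing pressure
#'
#' Runs every scenario of [q3_grid()] to steady state and assembles final
#' coral cover into a fishing-by-initial-coral matrix. Bistability shows
#' up as fishing pressures whose column contains both high (> 0.6) and
#' low (< 0.2) final coral cover depending only on the initial coral
#' cover.
#'
#' @inheritParams q3_grid
#' @inheritParams run_scenarios
#' @param params A [reef_params()] object (its `f` is overridden by the
#'   grid).
#' @param t_end Integration horizon in years.
#' @return An object of class `bistability_map`: list with `community`,
#'   `coral_axis`, `fishing_axis`, `final_coral` (matrix, rows = fishing
#'   values, columns = initial coral values) and `results` (the full
#'   per-scenario table).
#' @examples
#' \donttest{
#' bm <- bistability_map("even", coral_step = 0.05, fishing_step = 0.05)
#' bistable_fishing_range(bm)
#' }
#' @export
bistability_map <- function(community = "even", params = reef_params(),
                            coral_step = 0.01, fishing_step = 0.01,
                            coral_max = 0.85, fishing_max = 1,
                            t_end = 1000,
                            herbivore_scale = c("capacity", "absolute")) {
  scen <- q3_grid(community, coral_step = coral_step,
                  fishing_step = fishing_step, coral_max = coral_max,
                  fishing_max = fishing_max)
  res <- run_scenarios(scen, params, t_end = t_end,
                       herbivore_scale = herbivore_scale)
  coral_axis <- lattice_axis(coral_max, coral_step)
  fishing_axis <- lattice_axis(fishing_max, fishing_step)
  final_coral <- matrix(NA_real_, length(fishing_axis), length(coral_axis),
                        dimnames = list(f = format(fishing_axis),
                                        C0 = format(coral_axis)))
  rowi <- match(round(res$f / fishing_step), round(fishing_axis / fishing_step))
  coli <- match(round(res$C0 / coral_step), round(coral_axis / coral_step))
  final_coral[cbind(rowi, coli)] <- res$C
  stopifnot(!anyNA(final_coral), all(final_coral >= 0 & final_coral <= 1))
  structure(list(
    community = if (is.character(community)) community else "custom",
    coral_axis = coral_axis, fishing_axis = fishing_axis,
    final_coral = final_coral, results = res
  ), class = "bistability_map")
}

#' @export
print.bistability_map <- function(x, ...) {
  rng <- bistable_fishing_range(x)
  cat("<bistability_map>", x$community, ":",
      length(x$fishing_axis), "fishing x", length(x$coral_axis),
      "initial-coral values\n")
  if (length(rng) > 0) {
    cat("bistable fishing range:", min(rng), "-", max(rng), "\n")
  } else cat("no bistable fishing values\n")
  invisible(x)
}

#' Fishing pressures exhibiting bistability
#'
#' A fishing pressure is bistable when, across initial coral covers, its
#' outcomes include both the high-coral state (final C > `high`) and the
#' low-coral state (final C < `low`). Intermediate outcomes count toward
#' neither.
#'
#' @param map A [bistability_map()].
#' @param high,low Outcome thresholds on final coral cover.
#' @return The (possibly empty) vector of bistable fishing-axis values.
#' @export
bistable_fishing_range <- function(map, high = 0.6, low = 0.2) {
  stopifnot(inherits(map, "bistability_map"))
  hit <- apply(map$final_coral, 1,
               function(col) any(col > high) && any(col < low))
  map$fishing_axis[hit]
}

#' Recovery threshold on initial coral cover
#'
#' The smallest initial coral cover from which the reef returns to the
#' high-coral state (final C > 0.6) at a given fishing pressure, reported
#' at the grid resolution of the map. This is the minimum coral cover a
#' disturbance can leave behind without pushing the reef into the basin
#' of the degraded state.
#'
#' @param map A [bistability_map()].
#' @param fishing A value of `map$fishing_axis`.
#' @param high High-coral outcome threshold.
#' @return The smallest qualifying initial coral cover, or `NA` if no
#'   initial cover recovers at that fishing pressure.
#' @export
recovery_threshold <- function(map, fishing, high = 0.6) {
  stopifnot(inherits(map, "bistability_map"))
  i <- which(abs(map$fishing_axis - fishing) < 1e-9)
  if (length(i) != 1) stop("fishing value not on the map's axis")
  ok <- map$final_coral[i, ] > high
  if (!any(ok)) return(NA_real_)
  map$coral_axis[which(ok)[1]]
}

#' Minimal dominance fraction that abolishes bistability
#'
#' Scans increasing dominance fractions for one herbivore group (the rest
#' of the community split equally), computing a bistability map for each,
#' and returns the smallest fraction whose bistable fishing range is
#' empty — i.e. the dominance level at which the fold bifurcation gives
#' way to a smooth threshold transition.
#'
#' @param fractions Ascending dominance fractions to test.
#' @param dominant Herbivore group name (see [dominance_community()]).
#' @param total Herbivore community total.
#' @inheritParams bistability_map
#' @return List with `fraction` (smallest qualifying fraction, or `NA` if
#'   bistability persists throughout) and `bistable_ranges` (named list of
#'   the bistable fishing values per fraction).
#' @export
dominance_bistability_loss <- function(fractions = seq(0.6, 0.8, by = 0.05),
                                       dominant = "browser", total = 0.9,
                                       params = reef_params(),
                                       coral_step = 0.05,
                                       fishing_step = 0.05,
                                       t_end = 1000,
                                       herbivore_scale = c("capacity",
                                                           "absolute")) {
  stopifnot(!is.unsorted(fractions))
  ranges <- list()
  for (fr in fractions) {
    comm <- dominance_community(dominant, fr, total)
    bm <- bistability_map(comm, params, coral_step = coral_step,
                          fishing_step = fishing_step, t_end = t_end,
                          herbivore_scale = herbivore_scale)
    ranges[[sprintf("%.2f", fr)]] <- bistable_fishing_range(bm)
  }
  empty <- vapply(ranges, function(r) length(r) == 0, logical(1))
  list(fraction = if (any(empty)) fractions[which(empty)[1]] else NA_real_,
       bistable_ranges = ranges)
}

#' Warm-started sweep over fishing pressure
#'
#' Runs the model to steady state at each fishing value in turn, starting
#' every run from the previous run's final state (numerical continuation
#' by warm-starting). This is the primitive behind [hysteresis_sweep()].
#'
#' @param initial Seed [reef_state()] for the first fishing value.
#' @param params A [reef_params()] object.
#' @param fishing_values Fishing pressures in sweep order.
#' @param t_end Years per fishing value.
#' @return An object of class `hysteresis_curve`: list with `direction`
#'   (`"forward"` if fishing increases), `fishing_axis`, `final_coral`,
#'   `final_states` (matrix) and `seed_state`.
#' @export
sweep_fishing <- function(initial, params, fishing_values, t_end = 1000) {
  initial <- as_reef_state(initial)
  n <- length(fishing_values)
  states <- matrix(NA_real_, n, 6,
                   dimnames = list(NULL, c("C", "T", "M", "G", "B", "R")))
  st <- initial
  for (i in seq_len(n)) {
    res <- run_to_steady_state(st, update_params(params,
                                                 f = fishing_values[i]),
                               t_end = t_end)
    st <- res$final_state
    states[i, ] <- unclass(st)
  }
  structure(list(
    direction = if (n > 1 && fishing_values[n] < fishing_values[1])
      "reverse" else "forward",
    fishing_axis = fishing_values,
    final_coral = states[, "C"],
    final_states = states,
    seed_state = initial
  ), class = "hysteresis_curve")
}

#' Forward and reverse hysteresis sweeps
#'
#' Detects hysteresis by slowly ratcheting fishing pressure up from 0 to
#' 1 and back down in `fishing_step` increments (default 0.005, 201 runs
#' each way), warm-starting every run from the previous final state. The
#' forward sweep is seeded with the steady state, at `f = 0`, of a
#' coral-dominated reef (`C0 = 0.7`, remaining benthos split evenly
#' between turf and macroalgae after the 0.15 empty allowance) with the
#' chosen herbivore community; the reverse sweep starts from the forward
#' sweep's final state at `f = 1`. Path dependence — the two curves
#' disagreeing over a range of fishing pressures — is the hysteresis
#' signature of alternative stable states.
#'
#' @param community Preset name or named `(G0, B0, R0)` vector.
#' @param params A [reef_params()] object.
#' @param fishing_step Sweep increment.
#' @param fishing_max Upper end of the sweep.
#' @param t_end Years per fishing value.
#' @param seed_C0 Initial coral cover used to equilibrate the forward
#'   seed.
#' @param herbivore_scale How to interpret the preset herbivore values
#'   when building the seed state (see [run_scenarios()]).
#' @return List with `forward` and `reverse` [sweep_fishing()] curves.
#' @examples
#' \donttest{
#' hc <- hysteresis_sweep("even", fishing_step = 0.05)
#' hysteresis_width(hc$forward, hc$reverse)
#' }
#' @export
hysteresis_sweep <- function(community = "even", params = reef_params(),
                             fishing_step = 0.005, fishing_max = 1,
                             t_end = 1000, seed_C0 = 0.7,
                             herbivore_scale = c("capacity", "absolute")) {
  herbivore_scale <- match.arg(herbivore_scale)
  h <- if (is.character(community)) community_preset(community) else
    community
  alg <- (1 - seed_C0 - 0.15) / 2
  hscale <- if (herbivore_scale == "capacity")
    carrying_capacity(seed_C0, params$sigma) else 1
  seed0 <- reef_state(C = seed_C0, T = alg, M = alg,
                      G = h[["G0"]] * hscale, B = h[["B0"]] * hscale,
                      R = h[["R0"]] * hscale)
  seed <- run_to_steady_state(seed0, update_params(params, f = 0),
                              t_end = t_end)$final_state
  fv <- lattice_axis(fishing_max, fishing_step)
  fwd <- sweep_fishing(seed, params, fv, t_end = t_end)
  rev_seed <- as_reef_state(fwd$final_states[nrow(fwd$final_states), ])
  bwd <- sweep_fishing(rev_seed, params, base::rev(fv), t_end = t_end)
  list(forward = fwd, reverse = bwd)
}

#' Width of the hysteresis loop
#'
#' The set of fishing pressures where the forward and reverse steady
#' states disagree in final coral cover by more than `tol`, summarised as
#' its extent.
#'
#' @param forward,reverse [sweep_fishing()] curves over the same fishing
#'   values (in opposite orders).
#' @param tol Final-coral disagreement (proportional cover) above which
#'   the branches count as separated.
#' @return List with `fishing_values` (where the branches separate),
#'   `min`, `max` and `width` (`max - min + step` over a non-empty set,
#'   else 0).
#' @export
hysteresis_width <- function(forward, reverse, tol = 0.05) {
  stopifnot(inherits(forward, "hysteresis_curve"),
            inherits(reverse, "hysteresis_curve"))
  rv <- base::rev(reverse$final_coral)
  rf <- base::rev(reverse$fishing_axis)
  if (length(rf) != length(forward$fishing_axis) ||
      max(abs(rf - forward$fishing_axis)) > 1e-9) {
    stop("forward and reverse sweeps cover different fishing axes")
  }
  sep <- abs(forward$final_coral - rv) > tol
  vals <- forward$fishing_axis[sep]
  if (length(vals) == 0) {
    return(list(fishing_values = numeric(0), min = NA_real_,
                max = NA_real_, width = 0))
  }
  step <- if (length(forward$fishing_axis) > 1)
    forward$fishing_axis[2] - forward$fishing_axis[1] else 0
  list(fishing_values = vals, min = min(vals), max = max(vals),
       width = max(vals) - min(vals) + abs(step))
}

#' Hysteresis detected at the outcome thresholds
#'
#' Fishing pressures where the forward and reverse sweeps sit in opposite
#' outcome states — one branch in the high-coral state (final C > `high`)
#' and the other in the low-coral state (final C < `low`). This uses the
#' same state definitions as [bistable_fishing_range()], so the two
#' hallmarks of alternative stable states can be compared like for like:
#' a fold whose upper branch never reaches the high-coral threshold
#' registers in neither.
#'
#' @inheritParams hysteresis_width
#' @param high,low Outcome thresholds on final coral cover.
#' @return The (possibly empty) vector of fishing values where the
#'   branches occupy opposite outcome states.
#' @export
hysteresis_fishing_range <- function(forward, reverse, high = 0.6,
                                     low = 0.2) {
  stopifnot(inherits(forward, "hysteresis_curve"),
            inherits(reverse, "hysteresis_curve"))
  rv <- base::rev(reverse$final_coral)
  rf <- base::rev(reverse$fishing_axis)
  if (length(rf) != length(forward$fishing_axis) ||
      max(abs(rf - forward$fishing_axis)) > 1e-9) {
    stop("forward and reverse sweeps cover different fishing axes")
  }
  fw <- forward$final_coral
  sep <- (fw > high & rv < low) | (rv > high & fw < low)
  forward$fishing_axis[sep]
}
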