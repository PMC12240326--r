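#' Integrate the reef model to its operational steady state
#'
#' Runs the six-variable model from `initial` for `t_end` years (default
#' 1000) with `deSolve::lsoda` (adaptive, stiff-capable) and returns the
#' state at `t_end` together with convergence diagnostics and the outcome
#' classification of [classify_state()]. "Steady state" is operational: a
#' fixed 1000-year horizon plus a residual check (`rhs_norm`, the max-norm
#' of the derivatives at the final state), rather than event-based
#' termination. Tight tolerances are used because trajectories pass close
#' to invariant manifolds (near-zero herbivore abundances) where loose
#' error control corrupts the dynamics.
#'
#' @param initial A [reef_state()] (or coercible named vector).
#' @param params A [reef_params()] object; fishing pressure is `params$f`.
#' @param t_end Integration horizon in years.
#' @param times Optional vector of output times for trajectory inspection;
#'   by default only the final state is kept.
#' @param rtol,atol Relative and absolute integration tolerances.
#' @param conv_tol Residual threshold below which the run is flagged
#'   converged.
#' @return An object of class `steady_state_result`: a list with
#'   `final_state`, `t_end`, `rhs_norm`, `converged`, `outcome`,
#'   `dominant_alga`, and (when `times` is supplied) `trajectory`, a matrix
#'   with a time column and one column per state variable.
#' @examples
#' st <- reef_state(C = 0.15, T = 0.7, M = 0, G = 0.3, B = 0.3, R = 0.3)
#' res <- run_to_steady_state(st, reef_params(f = 0.1))
#' res$outcome
#' @export
run_to_steady_state <- function(initial, params, t_end = 1000,
                                times = NULL, rtol = 1e-8, atol = 1e-10,
                                conv_tol = 1e-5) {
  stopifnot(t_end > 0)
  initial <- as_reef_state(initial)
  keep_traj <- !is.null(times)
  if (is.null(times)) times <- c(0, t_end)

  out <- tryCatch(
    deSolve::lsoda(
      y = unclass(initial), times = times, func = "reef_rhs",
      parms = param_vector(params), dllname = "reefherb",
      initfunc = "reef_initmod", rtol = rtol, atol = atol,
      maxsteps = 100000
    ),
    warning = function(w) {
      stop("integration failed (", conditionMessage(w), ") from initial ",
           paste(sprintf("%s=%g", names(initial), initial), collapse = ", "),
           ", f=", params$f, call. = FALSE)
    }
  )
  fin <- out[nrow(out), -1]
  if (any(!is.finite(fin)) || any(fin < -1e-6)) {
    stop("corrupted state at t_end from initial ",
         paste(sprintf("%s=%g", names(initial), initial), collapse = ", "),
         ", f=", params$f, call. = FALSE)
  }
  # integration may undershoot zero within its error tolerance
  final <- as_reef_state(pmax(fin, 0))
  rhs_norm <- max(abs(reef_derivatives(final, params)))
  cls <- classify_state(final)
  structure(list(
    final_state = final,
    t_end = t_end,
    rhs_norm = rhs_norm,
    converged = rhs_norm < conv_tol,
    outcome = cls$outcome,
    dominant_alga = cls$dominant_alga,
    trajectory = if (keep_traj) out else NULL
  ), class = "steady_state_result")
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat("<steady_state_result> t_end =", x$t_end, "\n")
  print(unclass(x$final_state))
  cat("outcome:", x$outcome, " dominant alga:", x$dominant_alga,
      " rhs_norm:", format(x$rhs_norm, digits = 3),
      if (!x$converged) " (NOT converged)" else "", "\n")
  invisible(x)
}

#' Classify a final reef state
#'
#' Final coral cover above 0.6 is the high-coral (healthy) state, below
#' 0.2 the low-coral (degraded) state, anything between is intermediate.
#' The dominant alga is whichever of turf and macroalgae has the larger
#' final cover, with ties broken towards macroalgae; if both covers are
#' below 0.01 neither dominates (`"none"`).
#'
#' @param state A [reef_state()].
#' @return A list with `outcome` (one of `"coral_high"`, `"coral_low"`,
#'   `"intermediate"`) and `dominant_alga` (one of `"turf"`,
#'   `"macroalgae"`, `"none"`).
#' @examples
#' classify_state(reef_state(C = 0.05, T = 0.1, M = 0.6))
#' @export
classify_state <- function(state) {
  state <- as_reef_state(state)
  C <- state[["C"]]; Tv <- state[["T"]]; M <- state[["M"]]
  outcome <- if (C > 0.6) "coral_high" else if (C < 0.2) "coral_low" else
    "intermediate"
  dominant <- if (Tv < 0.01 && M < 0.01) "none" else
    if (Tv > M) "turf" else "macroalgae"
  list(outcome = outcome, dominant_alga = dominant)
}

#' Run a table of scenarios to steady state
#'
#' Applies [run_to_steady_state()] to every row of a scenario table from
#' [q1_grid()], [q2_grid()] or [q3_grid()], setting fishing pressure per
#' row. Entirely deterministic; row order is preserved.
#'
#' Initial herbivore abundances in the scenario tables are proportions of
#' the shared carrying capacity, as in the community presets (an "even"
#' community is 0.3/0.3/0.3 of capacity). With the default
#' `herbivore_scale = "capacity"` they are converted to absolute
#' abundances by multiplying by the capacity at the initial coral cover,
#' `K(C0) = (1 - sigma) + sigma * C0`, so that a total of 0.9 always
#' starts a community at 90% of its capacity whatever the initial coral
#' cover. `"absolute"` uses the tabled values as abundances directly.
#'
#' @param scenarios A scenario data frame with columns `id`, `C0`, `T0`,
#'   `M0`, `G0`, `B0`, `R0`, `f` (extra columns are carried through).
#' @param params A [reef_params()] object; its `f` is overridden per row.
#' @param t_end Integration horizon in years.
#' @param herbivore_scale How to interpret the tabled initial herbivore
#'   values: `"capacity"` (proportions of `K(C0)`, the default) or
#'   `"absolute"`.
#' @param ... Passed to [run_to_steady_state()].
#' @return The scenario table with appended columns `C`, `T`, `M`, `G`,
#'   `B`, `R` (final state), `rhs_norm`, `converged`, `outcome`,
#'   `dominant_alga`.
#' @export
run_scenarios <- function(scenarios, params = reef_params(),
                          t_end = 1000,
                          herbivore_scale = c("capacity", "absolute"),
                          ...) {
  herbivore_scale <- match.arg(herbivore_scale)
  need <- c("id", "C0", "T0", "M0", "G0", "B0", "R0", "f")
  stopifnot(all(need %in% names(scenarios)))
  n <- nrow(scenarios)
  fin <- matrix(NA_real_, n, 6,
                dimnames = list(NULL, c("C", "T", "M", "G", "B", "R")))
  rhs_norm <- numeric(n)
  converged <- logical(n)
  outcome <- character(n)
  dominant <- character(n)
  for (i in seq_len(n)) {
    row <- scenarios[i, ]
    hscale <- if (herbivore_scale == "capacity")
      carrying_capacity(row$C0, params$sigma) else 1
    st <- reef_state(C = row$C0, T = row$T0, M = row$M0,
                     G = row$G0 * hscale, B = row$B0 * hscale,
                     R = row$R0 * hscale)
    res <- run_to_steady_state(st, update_params(params, f = row$f),
                               t_end = t_end, ...)
    fin[i, ] <- unclass(res$final_state)
    rhs_norm[i] <- res$rhs_norm
    converged[i] <- res$converged
    outcome[i] <- res$outcome
    dominant[i] <- res$dominant_alga
  }
  if (!all(converged)) {
    warning(sum(!converged), " scenario(s) did not meet the residual ",
            "tolerance at t_end (likely near a bifurcation boundary): ",
            paste(utils::head(scenarios$id[!converged], 5), collapse = ", "))
  }
  cbind(scenarios, as.data.frame(fin), rhs_norm = rhs_norm,
        converged = converged, outcome = outcome,
        dominant_alga = dominant)
}
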