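#' Herbivore community presets
#'
#' Named initial herbivore compositions used throughout the analyses. All
#' presets total 0.9 of the carrying-capacity scale, so populations start
#' below capacity. `even` splits the total equally; each `*_dominated`
#' preset gives the dominant group 0.6 and the other two 0.15 each (see
#' [dominance_community()]).
#'
#' @param name One of `"even"`, `"grazer_dominated"`, `"browser_dominated"`,
#'   `"generalist_dominated"`.
#' @return Named numeric vector `(G0, B0, R0)`.
#' @examples
#' community_preset("grazer_dominated")
#' @export
community_preset <- function(name = c("even", "grazer_dominated",
                                      "browser_dominated",
                                      "generalist_dominated")) {
  name <- match.arg(name)
  switch(name,
    even = c(G0 = 0.3, B0 = 0.3, R0 = 0.3),
    grazer_dominated = dominance_community("grazer", 0.6, 0.9),
    browser_dominated = dominance_community("browser", 0.6, 0.9),
    generalist_dominated = dominance_community("generalist", 0.6, 0.9)
  )
}

#' Build a dominance community
#'
#' Gives `dominant_fraction` of the herbivore total to the dominant
#' functional group and splits the remainder equally between the other
#' two.
#'
#' @param dominant `"grazer"`, `"browser"` or `"generalist"`.
#' @param dominant_fraction Abundance of the dominant group.
#' @param total Total initial herbivore abundance (default 0.9).
#' @return Named numeric vector `(G0, B0, R0)` summing to `total`.
#' @examples
#' dominance_community("browser", 0.6, 0.9) # G0=0.15, B0=0.6, R0=0.15
#' @export
dominance_community <- function(dominant = c("grazer", "browser",
                                             "generalist"),
                                dominant_fraction = 0.6, total = 0.9) {
  dominant <- match.arg(dominant)
  if (dominant_fraction > total + 1e-12) {
    stop("dominant_fraction exceeds the community total")
  }
  rest <- (total - dominant_fraction) / 2
  out <- c(G0 = rest, B0 = rest, R0 = rest)
  out[switch(dominant, grazer = "G0", browser = "B0", generalist = "R0")] <-
    dominant_fraction
  out
}

# Integer-lattice axis: k * step for k = 0..round(maxval/step).
# Built from integers so grids are identical across platforms.
lattice_axis <- function(maxval, step) {
  n <- round(maxval / step)
  if (abs(n * step - maxval) > 1e-9) {
    stop("step must divide the axis range")
  }
  (0:n) * step
}

scenario_frame <- function(question, C0, T0, M0, G0, B0, R0, f, ...) {
  df <- data.frame(question = question, C0 = C0, T0 = T0, M0 = M0,
                   G0 = G0, B0 = B0, R0 = R0, f = f, ...,
                   stringsAsFactors = FALSE)
  df$id <- sprintf("%s_C%.3f_T%.3f_M%.3f_G%.3f_B%.3f_R%.3f_f%.3f",
                   df$question, df$C0, df$T0, df$M0,
                   df$G0, df$B0, df$R0, df$f)
  # invariants shared by every scenario
  stopifnot(all(df$C0 + df$T0 + df$M0 <= 1 + 1e-9),
            all(df$G0 + df$B0 + df$R0 <= 0.9 + 1e-9),
            !anyDuplicated(df$id))
  df[, c("id", setdiff(names(df), "id"))]
}

#' Post-disturbance recovery grid over herbivore composition (Question 1)
#'
#' Scenarios for recovery after a major disturbance that leaves the
#' benthos at 15% coral, 70% turf and no macroalgae. Initial grazer and
#' browser abundances vary on a lattice (default 0 to 0.9 in 0.025 steps)
#' for each fixed generalist level, with total herbivores capped at 0.9;
#' higher generalist levels therefore shrink the grazer-browser triangle.
#' The grid is crossed with the supplied fishing pressures.
#'
#' @param generalist_levels Initial generalist abundances (default
#'   `c(0, 0.2, 0.4)`, the levels shown in the main analyses).
#' @param fishing_levels Fishing pressures (default `0, 0.1, ..., 0.7`).
#' @param step Lattice increment for grazer/browser axes.
#' @param herbivore_cap Maximum total initial herbivore abundance.
#' @return Scenario data frame (one row per scenario); see
#'   [run_scenarios()].
#' @examples
#' nrow(q1_grid(generalist_levels = 0, fishing_levels = 0)) # 703
#' @export
q1_grid <- function(generalist_levels = c(0, 0.2, 0.4),
                    fishing_levels = seq(0, 0.7, by = 0.1),
                    step = 0.025, herbivore_cap = 0.9) {
  nmax <- round(herbivore_cap / step)
  if (abs(nmax * step - herbivore_cap) > 1e-9) {
    stop("step must divide the herbivore cap")
  }
  blocks <- list()
  for (R0 in generalist_levels) {
    kr <- round(R0 / step)
    if (abs(kr * step - R0) > 1e-9) {
      stop("generalist levels must sit on the lattice")
    }
    nrest <- nmax - kr
    if (nrest < 0) next
    ij <- expand.grid(i = 0:nrest, j = 0:nrest)
    ij <- ij[ij$i + ij$j <= nrest, ]
    for (f in fishing_levels) {
      blocks[[length(blocks) + 1]] <- scenario_frame(
        "Q1", C0 = 0.15, T0 = 0.7, M0 = 0,
        G0 = ij$i * step, B0 = ij$j * step, R0 = R0, f = f)
    }
  }
  do.call(rbind, blocks)
}

#' Post-disturbance recovery grid over initial algal cover (Question 2)
#'
#' Scenarios varying initial turf and macroalgal cover (default 0 to 0.7
#' on a 0.025 lattice) at fixed 15% initial coral, keeping total benthic
#' cover at or below 0.85, for a fixed herbivore community, crossed with
#' fishing pressures.
#'
#' @param community Preset name (see [community_preset()]) or a named
#'   vector `(G0, B0, R0)`.
#' @param turf_max,macro_max Upper limits of the algal axes.
#' @param fishing_levels Fishing pressures (default `0, 0.1, ..., 0.7`).
#' @param step Lattice increment for both algal axes.
#' @param benthic_cap Maximum total initial benthic cover `C0 + T0 + M0`.
#' @param C0 Initial coral cover.
#' @return Scenario data frame; see [run_scenarios()].
#' @export
q2_grid <- function(community = "grazer_dominated",
                    turf_max = 0.7, macro_max = 0.7,
                    fishing_levels = seq(0, 0.7, by = 0.1),
                    step = 0.025, benthic_cap = 0.85, C0 = 0.15) {
  h <- if (is.character(community)) community_preset(community) else
    community
  tv <- lattice_axis(turf_max, step)
  mv <- lattice_axis(macro_max, step)
  tm <- expand.grid(T0 = tv, M0 = mv)
  tm <- tm[C0 + tm$T0 + tm$M0 <= benthic_cap + 1e-9, ]
  blocks <- lapply(fishing_levels, function(f) {
    scenario_frame("Q2", C0 = C0, T0 = tm$T0, M0 = tm$M0,
                   G0 = h[["G0"]], B0 = h[["B0"]], R0 = h[["R0"]], f = f)
  })
  do.call(rbind, blocks)
}

#' Bistability grid over initial coral cover and fishing pressure
#' (Question 3)
#'
#' Scenarios crossing initial coral cover (0 to 0.85, default 0.01 steps)
#' with fishing pressure (0 to 1, default 0.01 steps) for a fixed
#' herbivore community. After reserving 0.15 empty space, the remaining
#' benthos is split evenly between turf and macroalgae:
#' `T0 = M0 = (1 - C0 - 0.15) / 2`.
#'
#' @param community Preset name or named vector `(G0, B0, R0)`.
#' @param coral_step,fishing_step Grid increments.
#' @param coral_max,fishing_max Upper limits of the two axes.
#' @return Scenario data frame; 86 x 101 = 8686 rows at default steps.
#' @export
q3_grid <- function(community = "even", coral_step = 0.01,
                    fishing_step = 0.01, coral_max = 0.85,
                    fishing_max = 1) {
  h <- if (is.character(community)) community_preset(community) else
    community
  cv <- lattice_axis(coral_max, coral_step)
  fv <- lattice_axis(fishing_max, fishing_step)
  grid <- expand.grid(C0 = cv, f = fv)
  alg <- pmax(0, (1 - grid$C0 - 0.15) / 2)
  scenario_frame("Q3", C0 = grid$C0, T0 = alg, M0 = alg,
                 G0 = h[["G0"]], B0 = h[["B0"]], R0 = h[["R0"]],
                 f = grid$f)
}
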