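#' Herbivore carrying capacity
#'
#' The shared carrying capacity of the three herbivore functional groups,
#' `K(C) = (1 - sigma) + sigma * C`. Coral contributes shelter in
#' proportion to its cover with weight `sigma`; the remaining `1 - sigma`
#' represents limiting resources unrelated to coral. With `sigma = 1` and
#' no coral the capacity collapses to zero.
#'
#' @param C Coral cover fraction in `[0, 1]`.
#' @param sigma Shelter weight in `[0, 1]`.
#' @return The carrying capacity on the same scale as the herbivore
#'   abundances.
#' @examples
#' carrying_capacity(0.15, 0.6) # 0.49
#' @export
carrying_capacity <- function(C, sigma) {
  stopifnot(all(C >= 0 & C <= 1), all(sigma >= 0 & sigma <= 1))
  (1 - sigma) + sigma * C
}

#' Equilibrium total herbivore abundance at fixed coral cover
#'
#' Summing the three (identical per-capita) herbivore equations gives
#' logistic growth of the total `H = G + B + R` towards
#' `K(C) * (1 - f / r)`; fishing depresses the equilibrium linearly and
#' extirpates herbivores when `f >= r`. Used as a closed-form check on
#' converged steady states.
#'
#' @param C Coral cover fraction.
#' @param params A [reef_params()] object (uses `r`, `f`, `sigma`).
#' @return The unique non-negative equilibrium of total herbivore
#'   abundance at fixed `C`.
#' @examples
#' herbivore_equilibrium_total(0.7, reef_params(f = 0.3)) # 0.574
#' @export
herbivore_equilibrium_total <- function(C, params) {
  stopifnot(params$r > 0)
  pmax(0, carrying_capacity(C, params$sigma) * (1 - params$f / params$r))
}

#' Time derivatives of the reef model
#'
#' Evaluate the right-hand side of the six coupled ODEs. Coral, turf and
#' macroalgae colonise unoccupied space `S = 1 - C - T - M` by propagule
#' import (`i_*`) and lateral expansion (`b_*`); coral recruitment and
#' growth are reduced by algal competition (`alpha_T T + alpha_M M`) and
#' coral decays at `d_C`. Uncropped turf matures into macroalgae at rate
#' `gamma`. Herbivory is Holling type II: grazers remove turf at
#' `g_T T G / (g_T eta_T T + 1)`, browsers remove macroalgae at
#' `g_M M B / (g_M eta_M M + 1)`, and generalists split their effort over
#' both algae through the shared denominator
#' `g_T eta_T T + g_M eta_M M + 1`, so they consume each alga in
#' proportion to its abundance. Each herbivore group grows logistically
#' towards the shared capacity `K(C)` and suffers per-capita fishing
#' mortality `f`.
#'
#' This R implementation is the reference form of the model; numerical
#' integration uses an identical compiled version for speed (see
#' [run_to_steady_state()]).
#'
#' @param state A [reef_state()].
#' @param params A [reef_params()] object.
#' @return Named numeric vector of derivatives `(dC, dT, dM, dG, dB, dR)`,
#'   per year.
#' @examples
#' st <- reef_state(C = 0.15, T = 0.7, M = 0, G = 0.3, B = 0.3, R = 0.3)
#' reef_derivatives(st, reef_params(f = 0.1))
#' @export
reef_derivatives <- function(state, params) {
  s <- as_reef_state(state)
  C <- s[["C"]]; T <- s[["T"]]; M <- s[["M"]]
  G <- s[["G"]]; B <- s[["B"]]; R <- s[["R"]]
  p <- params

  S <- 1 - C - T - M
  den_T <- p$g_T * p$eta_T * T + 1
  den_M <- p$g_M * p$eta_M * M + 1
  den_R <- p$g_T * p$eta_T * T + p$g_M * p$eta_M * M + 1
  K <- (1 - p$sigma) + p$sigma * C
  H <- G + B + R

  dC <- (p$i_C + p$b_C * C) * S * (1 - (p$alpha_T * T + p$alpha_M * M)) -
    p$d_C * C
  dT <- (p$i_T + p$b_T * T) * S - p$gamma * T -
    p$g_T * T * G / den_T - p$g_T * T * R / den_R
  dM <- (p$i_M + p$b_M * M) * S + p$gamma * T -
    p$g_M * M * B / den_M - p$g_M * M * R / den_R

  # zero herbivores stay zero even when K = 0 (0/0 guarded)
  crowd <- if (H == 0 && K == 0) 0 else 1 - H / K
  dG <- p$r * G * crowd - p$f * G
  dB <- p$r * B * crowd - p$f * B
  dR <- p$r * R * crowd - p$f * R

  out <- c(C = dC, T = dT, M = dM, G = dG, B = dB, R = dR)
  if (any(!is.finite(out))) {
    stop("non-finite derivative; invalid state/parameter combination ",
         "(e.g. sigma = 1 with C = 0 and herbivores present)")
  }
  out
}

#' Reduced single-algae, single-herbivore dynamics
#'
#' The three-variable ancestor of the full model, with one algal
#' compartment `A` and one lumped herbivore `H`. The full model collapses
#' onto it exactly when macroalgae and browsers are absent and stay absent
#' (`M0 = 0`, `B0 = 0`, `i_M = 0`, `gamma = 0`): `M = 0` and `B = 0` are
#' then invariant manifolds, `A` obeys the turf equation and `H = G + R`
#' closes because grazers and generalists have identical per-capita
#' dynamics. Used as an equivalence oracle in the test suite, not in the
#' analyses.
#'
#' @param state Named numeric vector with components `C`, `A`, `H`.
#' @param params A [reef_params()] object with `i_M = 0` and `gamma = 0`.
#' @return Named numeric vector `(dC, dA, dH)`.
#' @export
reduced_derivatives <- function(state, params) {
  stopifnot(all(c("C", "A", "H") %in% names(state)))
  p <- params
  if (p$i_M != 0 || p$gamma != 0) {
    stop("reduced model requires i_M = 0 and gamma = 0")
  }
  C <- state[["C"]]; A <- state[["A"]]; H <- state[["H"]]
  S <- 1 - C - A
  K <- (1 - p$sigma) + p$sigma * C
  dC <- (p$i_C + p$b_C * C) * S * (1 - p$alpha_T * A) - p$d_C * C
  dA <- (p$i_T + p$b_T * A) * S - p$g_T * A * H / (p$g_T * p$eta_T * A + 1)
  dH <- p$r * H * (1 - H / K) - p$f * H
  c(C = dC, A = dA, H = dH)
}
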