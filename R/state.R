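#' Reef state vector
#'
#' The six dynamical variables at one time point: benthic cover fractions
#' for coral (`C`), turf algae (`T`) and macroalgae (`M`), and the
#' abundances of the three herbivore functional groups — grazers (`G`,
#' turf specialists), browsers (`B`, macroalgal specialists) and
#' generalists (`R`, consuming both in proportion to availability) — on
#' the carrying-capacity scale. Benthic covers must satisfy
#' `C + T + M <= 1`; unoccupied space is derived, not stored (see
#' [unoccupied_space()]).
#'
#' Tiny negative components (greater than `-1e-9`) arising from
#' floating-point integration are clipped to zero; anything more negative
#' is treated as a corrupted state and rejected.
#'
#' @param C,T,M Benthic cover fractions of coral, turf and macroalgae.
#' @param G,B,R Grazer, browser and generalist abundances.
#' @param x A named numeric vector with elements `C, T, M, G, B, R`.
#' @return A named numeric vector of class `reef_state`.
#' @examples
#' reef_state(C = 0.15, T = 0.7, M = 0, G = 0.3, B = 0.3, R = 0.3)
#' @export
reef_state <- function(C, T, M, G = 0, B = 0, R = 0) {
  as_reef_state(c(C = C, T = T, M = M, G = G, B = B, R = R))
}

#' @rdname reef_state
#' @export
as_reef_state <- function(x) {
  nm <- c("C", "T", "M", "G", "B", "R")
  x <- unclass(x)
  if (!is.numeric(x) || !all(nm %in% names(x))) {
    stop("state must be numeric with components C, T, M, G, B, R")
  }
  x <- x[nm]
  if (any(!is.finite(x))) stop("non-finite state component")
  if (any(x < -1e-9)) {
    stop("negative state component(s): ",
         paste(nm[x < -1e-9], collapse = ", "))
  }
  x[x < 0] <- 0
  if (x[["C"]] + x[["T"]] + x[["M"]] > 1 + 1e-9) {
    stop("benthic cover C + T + M exceeds 1")
  }
  structure(x, class = "reef_state")
}

#' @export
print.reef_state <- function(x, ...) {
  cat("<reef_state>\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Unoccupied benthic space
#'
#' The fraction of the benthos occupied by none of coral, turf or
#' macroalgae: `S = 1 - C - T - M`. This is the space into which all
#' three benthic groups expand.
#'
#' @param state A [reef_state()] (or named vector coercible to one).
#' @return The unoccupied fraction, clipped at zero against rounding.
#' @examples
#' unoccupied_space(reef_state(C = 0.15, T = 0.7, M = 0))
#' @export
unoccupied_space <- function(state) {
  state <- as_reef_state(state)
  max(0, 1 - state[["C"]] - state[["T"]] - state[["M"]])
}
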