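# Independent transcription of the model equations, coded directly from
# the dynamical system with no helpers shared with the package. Used as
# the brute-force oracle for reef_derivatives() and as the RHS of the
# fixed-step reference integrator.
oracle_rhs <- function(y, p) {
  C <- y[["C"]]; Tv <- y[["T"]]; M <- y[["M"]]
  G <- y[["G"]]; B <- y[["B"]]; R <- y[["R"]]
  space <- 1 - C - Tv - M
  grazing_G <- p$g_T * Tv * G / (p$g_T * p$eta_T * Tv + 1)
  grazing_R <- p$g_T * Tv * R /
    (p$g_T * p$eta_T * Tv + p$g_M * p$eta_M * M + 1)
  browsing_B <- p$g_M * M * B / (p$g_M * p$eta_M * M + 1)
  browsing_R <- p$g_M * M * R /
    (p$g_T * p$eta_T * Tv + p$g_M * p$eta_M * M + 1)
  cap <- (1 - p$sigma) + p$sigma * C
  percap <- p$r * (1 - (G + R + B) / cap) - p$f
  c(C = (p$i_C + p$b_C * C) * space *
        (1 - (p$alpha_T * Tv + p$alpha_M * M)) - p$d_C * C,
    T = (p$i_T + p$b_T * Tv) * space - p$gamma * Tv -
        grazing_G - grazing_R,
    M = (p$i_M + p$b_M * M) * space + p$gamma * Tv -
        browsing_B - browsing_R,
    G = G * percap, B = B * percap, R = R * percap)
}

# Classical fixed-step RK4 on the oracle right-hand side.
rk4_integrate <- function(y0, p, t_end, dt) {
  y <- y0
  nsteps <- round(t_end / dt)
  for (i in seq_len(nsteps)) {
    k1 <- oracle_rhs(y, p)
    k2 <- oracle_rhs(y + dt / 2 * k1, p)
    k3 <- oracle_rhs(y + dt / 2 * k2, p)
    k4 <- oracle_rhs(y + dt * k3, p)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# Random valid state: benthic covers drawn so C + T + M <= 1, herbivores
# positive on the capacity scale.
random_state <- function() {
  w <- runif(4)
  benthic <- runif(1) * w[1:3] / sum(w)
  reef_state(C = benthic[1], T = benthic[2], M = benthic[3],
             G = runif(1, 0, 0.4), B = runif(1, 0, 0.4),
             R = runif(1, 0, 0.4))
}

random_params <- function() {
  reef_params(i_C = runif(1, 0, 0.1), i_T = runif(1, 0, 0.1),
              i_M = runif(1, 0, 0.05), b_C = runif(1, 0.1, 0.5),
              b_T = runif(1, 0.4, 1), b_M = runif(1, 0.2, 0.8),
              d_C = runif(1, 0.05, 0.2), gamma = runif(1, 0, 0.3),
              g_T = runif(1, 1, 3), g_M = runif(1, 0.5, 2),
              eta_T = runif(1, 0, 0.5), eta_M = runif(1, 0.5, 1.5),
              alpha_T = runif(1, 0, 0.5), alpha_M = runif(1, 0.2, 0.8),
              r = runif(1, 0.5, 1.5), sigma = runif(1, 0.2, 0.9),
              f = runif(1, 0, 0.8))
}

disturbed_state <- function(G, B, R) {
  reef_state(C = 0.15, T = 0.7, M = 0, G = G, B = B, R = R)
}
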