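test_that("unoccupied space is the benthic remainder and guards corrupt states", {
  expect_equal(unoccupied_space(reef_state(C = 0.15, T = 0.7, M = 0)), 0.15)
  expect_equal(unoccupied_space(reef_state(C = 1, T = 0, M = 0)), 0)
  expect_equal(unoccupied_space(reef_state(C = 0.3, T = 0.2, M = 0.1)), 0.4)
  expect_error(reef_state(C = -0.01, T = 0.5, M = 0), "negative")
  expect_error(reef_state(C = 0.6, T = 0.5, M = 0.2), "exceeds 1")
  # float dust below zero is clipped, not rejected
  expect_equal(unname(reef_state(C = 0.5, T = -1e-13, M = 0)[["T"]]), 0)
})

test_that("carrying capacity interpolates between the shelter floor and 1", {
  expect_equal(carrying_capacity(1, 0.6), 1)
  expect_equal(carrying_capacity(0, 0.6), 0.4)
  expect_equal(carrying_capacity(0.15, 0.6), 0.49)
  expect_equal(carrying_capacity(0.5, 0), 1) # decoupled from coral
})

test_that("derivatives reproduce hand-computed values at the disturbed state", {
  st <- disturbed_state(G = 0.3, B = 0.3, R = 0.3)
  d <- reef_derivatives(st, reef_params(f = 0.1))
  expect_equal(unname(d[["C"]]), -0.00324375)
  expect_equal(unname(d[["T"]]), -0.8185)
  expect_equal(unname(d[["M"]]), 0.07)
  dH <- 0.3 * (1 - 0.9 / 0.49) - 0.1 * 0.3
  expect_equal(unname(d[["G"]]), dH)
  # identical per-capita dynamics force equality of the three groups
  expect_equal(unname(d[["B"]]), unname(d[["G"]]))
  expect_equal(unname(d[["R"]]), unname(d[["G"]]))
})

test_that("zero abundance is absorbing for each herbivore group", {
  st <- reef_state(C = 0.4, T = 0.3, M = 0.1, G = 0, B = 0.2, R = 0.1)
  expect_equal(unname(reef_derivatives(st, reef_params(f = 0.3))[["G"]]), 0)
  res <- run_to_steady_state(st, reef_params(f = 0.2))
  expect_identical(unname(res$final_state[["G"]]), 0)
})

test_that("total-herbivore equilibrium follows the closed form", {
  p0 <- reef_params(f = 0)
  expect_equal(herbivore_equilibrium_total(1, p0), 1)
  expect_equal(herbivore_equilibrium_total(0.7, reef_params(f = 0.3)), 0.574)
  # overfished: net per-capita growth non-positive
  expect_equal(herbivore_equilibrium_total(0.5, reef_params(f = 1)), 0)
  expect_equal(herbivore_equilibrium_total(0.5, reef_params(f = 1.7)), 0)
})

test_that("derivatives agree with an independently coded oracle", {
  set.seed(42)
  for (i in 1:1000) {
    st <- random_state()
    p <- random_params()
    expect_lt(max(abs(reef_derivatives(st, p) - oracle_rhs(st, p))), 1e-12)
  }
})

test_that("production integrator matches fixed-step RK4 on the oracle", {
  st <- disturbed_state(G = 0.3, B = 0.2, R = 0.1)
  p <- reef_params(f = 0.2)
  ref <- rk4_integrate(unclass(st), p, t_end = 10, dt = 1e-3)
  prod <- run_to_steady_state(st, p, t_end = 10)$final_state
  expect_lt(max(abs(unclass(prod) - ref)), 1e-5)
})

test_that("turf and macroalgae are exchangeable when their parameters swap", {
  p <- reef_params(gamma = 0, i_M = 0.03, eta_T = 0.4,
                   alpha_M = 0.5, f = 0.2)
  swapped <- update_params(p,
    i_T = p$i_M, i_M = p$i_T, b_T = p$b_M, b_M = p$b_T,
    g_T = p$g_M, g_M = p$g_T, eta_T = p$eta_M, eta_M = p$eta_T,
    alpha_T = p$alpha_M, alpha_M = p$alpha_T)
  st <- reef_state(C = 0.2, T = 0.4, M = 0.1, G = 0.3, B = 0.1, R = 0.2)
  mirror <- reef_state(C = 0.2, T = 0.1, M = 0.4, G = 0.1, B = 0.3, R = 0.2)
  ts <- seq(0, 200, by = 10)
  a <- run_to_steady_state(st, p, t_end = 200, times = ts)$trajectory
  b <- run_to_steady_state(mirror, swapped, t_end = 200,
                           times = ts)$trajectory
  expect_lt(max(abs(a[, "C"] - b[, "C"])), 1e-6)
  expect_lt(max(abs(a[, "T"] - b[, "M"])), 1e-6)
  expect_lt(max(abs(a[, "M"] - b[, "T"])), 1e-6)
  expect_lt(max(abs(a[, "G"] - b[, "B"])), 1e-6)
  expect_lt(max(abs(a[, "R"] - b[, "R"])), 1e-6)
})

test_that("full model collapses onto the reduced single-algae model", {
  p <- reef_params(i_M = 0, gamma = 0, f = 0.2)
  full0 <- reef_state(C = 0.15, T = 0.7, M = 0, G = 0.25, B = 0, R = 0.2)
  ts <- seq(0, 500, by = 5)
  full <- run_to_steady_state(full0, p, t_end = 500, times = ts)$trajectory

  reduced_fn <- function(t, y, parms) list(reduced_derivatives(y, parms))
  red <- deSolve::lsoda(c(C = 0.15, A = 0.7, H = 0.45), ts, reduced_fn,
                        p, rtol = 1e-8, atol = 1e-10)
  expect_lt(max(abs(full[, "C"] - red[, "C"])), 1e-6)
  expect_lt(max(abs(full[, "T"] - red[, "A"])), 1e-6)
  expect_lt(max(abs(full[, "G"] + full[, "R"] - red[, "H"])), 1e-6)
  # macroalgae and browsers stay on their invariant manifolds
  expect_equal(max(abs(full[, "M"])), 0)
  expect_equal(max(abs(full[, "B"])), 0)
  expect_error(reduced_derivatives(c(C = 0.2, A = 0.3, H = 0.4),
                                   reef_params()), "gamma")
})
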