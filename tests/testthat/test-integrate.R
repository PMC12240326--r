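test_that("final states are classified by the coral-cover thresholds", {
  expect_equal(classify_state(reef_state(C = 0.7, T = 0.1, M = 0))$outcome,
               "coral_high")
  cls <- classify_state(reef_state(C = 0.05, T = 0.1, M = 0.6))
  expect_equal(cls$outcome, "coral_low")
  expect_equal(cls$dominant_alga, "macroalgae")
  expect_equal(classify_state(reef_state(C = 0.4, T = 0.2, M = 0.1))$outcome,
               "intermediate")
  # ties go to macroalgae; trace algae dominate nothing
  expect_equal(classify_state(reef_state(C = 0.1, T = 0.3,
                                         M = 0.3))$dominant_alga,
               "macroalgae")
  expect_equal(classify_state(reef_state(C = 0.7, T = 0.005,
                                         M = 0.002))$dominant_alga,
               "none")
})

test_that("fishing pressure flips the even community between reef states", {
  even <- disturbed_state(G = 0.3, B = 0.3, R = 0.3)
  lo <- run_to_steady_state(even, reef_params(f = 0.1))
  expect_equal(lo$outcome, "coral_high")
  expect_true(lo$converged)
  hi <- run_to_steady_state(even, reef_params(f = 0.9))
  expect_equal(hi$outcome, "coral_low")
  expect_equal(hi$dominant_alga, "macroalgae")
})

test_that("community composition decides the fate at intermediate fishing", {
  gen <- disturbed_state(G = 0.15, B = 0.15, R = 0.6)
  expect_equal(run_to_steady_state(gen, reef_params(f = 0.5))$outcome,
               "coral_high")
  grz <- disturbed_state(G = 0.6, B = 0.15, R = 0.15)
  res <- run_to_steady_state(grz, reef_params(f = 0.5))
  expect_equal(res$dominant_alga, "macroalgae")
  expect_equal(res$outcome, "coral_low")
})

test_that("fishing at or above the growth rate extirpates herbivores", {
  st <- disturbed_state(G = 0.3, B = 0.3, R = 0.3)
  fin <- run_to_steady_state(st, reef_params(f = 1))$final_state
  expect_lt(sum(fin[c("G", "B", "R")]), 1e-3)
})

test_that("integration is deterministic and insensitive to doubling the horizon", {
  st <- reef_state(C = 0.3, T = 0.3, M = 0.1, G = 0.4, B = 0.2, R = 0.1)
  p <- reef_params(f = 0.2)
  r1 <- run_to_steady_state(st, p)
  r2 <- run_to_steady_state(st, p)
  expect_identical(unclass(r1$final_state), unclass(r2$final_state))
  r4 <- run_to_steady_state(st, p, t_end = 2000)
  expect_lt(abs(r4$final_state[["C"]] - r1$final_state[["C"]]), 1e-4)
})

test_that("trajectories conserve space and herbivore ratios", {
  st <- reef_state(C = 0.3, T = 0.3, M = 0.1, G = 0.4, B = 0.2, R = 0.1)
  res <- run_to_steady_state(st, reef_params(f = 0.2),
                             times = seq(0, 1000, by = 2))
  tr <- res$trajectory
  S <- 1 - tr[, "C"] - tr[, "T"] - tr[, "M"]
  expect_gt(min(S), -1e-6)
  expect_gt(min(tr[, c("C", "T", "M")]), -1e-6)
  # identical per-capita rates freeze the group ratios
  gb <- tr[, "G"] / tr[, "B"]
  gr <- tr[, "G"] / tr[, "R"]
  expect_lt(max(abs(gb - gb[1])) / gb[1], 1e-6)
  expect_lt(max(abs(gr - gr[1])) / gr[1], 1e-6)
})

test_that("converged steady states satisfy the closed-form herbivore total", {
  for (f in c(0, 0.2, 0.5)) {
    p <- reef_params(f = f)
    res <- run_to_steady_state(disturbed_state(0.3, 0.3, 0.3), p)
    H <- sum(res$final_state[c("G", "B", "R")])
    expect_gt(H, 0)
    expect_lt(abs(H - herbivore_equilibrium_total(res$final_state[["C"]],
                                                  p)), 1e-6)
  }
})

test_that("run_scenarios appends outcomes and seeds herbivores on the capacity scale", {
  scen <- q3_grid("even", coral_step = 0.85, fishing_step = 0.5)
  res <- run_scenarios(scen, reef_params())
  expect_equal(nrow(res), nrow(scen))
  expect_true(all(c("C", "outcome", "rhs_norm", "converged") %in%
                    names(res)))
  expect_true(all(res$C >= 0 & res$C <= 1))

  # capacity seeding: same proportions start closer to extinction when
  # coral (hence capacity) is scarce, which absolute seeding hides
  one <- scen[scen$C0 == 0 & scen$f == 0, ]
  res_cap <- run_scenarios(one, reef_params())
  res_abs <- run_scenarios(one, reef_params(), herbivore_scale = "absolute")
  expect_false(identical(res_cap$C, res_abs$C))
})
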