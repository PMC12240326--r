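fake_map <- function(final_coral, coral_axis, fishing_axis) {
  structure(list(community = "test", coral_axis = coral_axis,
                 fishing_axis = fishing_axis, final_coral = final_coral,
                 results = NULL),
            class = "bistability_map")
}

fake_curve <- function(fishing, coral, direction = "forward") {
  structure(list(direction = direction, fishing_axis = fishing,
                 final_coral = coral, final_states = NULL,
                 seed_state = NULL),
            class = "hysteresis_curve")
}

test_that("bistable fishing values need both outcome states in one column", {
  m <- fake_map(rbind(c(0.7, 0.7), # monostable high
                      c(0.05, 0.7), # bistable
                      c(0.3, 0.5)), # all intermediate
                coral_axis = c(0, 0.4), fishing_axis = c(0, 0.1, 0.2))
  expect_equal(bistable_fishing_range(m), 0.1)
})

test_that("recovery threshold is the first grid cell reaching the high state", {
  m <- fake_map(rbind(c(0.1, 0.15, 0.7, 0.71),
                      c(0.1, 0.12, 0.14, 0.15)),
                coral_axis = c(0, 0.1, 0.2, 0.3), fishing_axis = c(0, 0.5))
  expect_equal(recovery_threshold(m, 0), 0.2)
  expect_true(is.na(recovery_threshold(m, 0.5))) # nothing recovers
  expect_error(recovery_threshold(m, 0.25), "axis")
})

test_that("hysteresis width summarises branch separation", {
  f <- seq(0, 1, by = 0.25)
  a <- fake_curve(f, c(0.7, 0.7, 0.7, 0.1, 0.1))
  same <- fake_curve(rev(f), rev(c(0.7, 0.7, 0.7, 0.1, 0.1)), "reverse")
  expect_equal(hysteresis_width(a, same)$width, 0)
  split <- fake_curve(rev(f), rev(c(0.7, 0.1, 0.1, 0.1, 0.1)), "reverse")
  w <- hysteresis_width(a, split)
  expect_equal(w$fishing_values, c(0.25, 0.5))
  expect_equal(w$width, 0.5)
  expect_equal(hysteresis_fishing_range(a, split), c(0.25, 0.5))
  short <- fake_curve(c(0, 1), c(0.7, 0.1), "reverse")
  expect_error(hysteresis_width(a, short), "axes")
})

test_that("warm-started sweeps stay on a branch until it disappears", {
  # coarse forward sweep on the even community: coral persists well past
  # the fishing level that defeats a freshly disturbed reef
  hc <- hysteresis_sweep("even", fishing_step = 0.05)
  fwd <- hc$forward
  expect_equal(fwd$direction, "forward")
  expect_gt(fwd$final_coral[fwd$fishing_axis == 0.5], 0.6)
  cold <- run_to_steady_state(disturbed_state(0.3, 0.3, 0.3),
                              reef_params(f = 0.5))
  expect_lt(cold$final_state[["C"]], 0.2)
  # the degraded branch persists on the way back down
  rv <- hc$reverse
  expect_equal(rv$direction, "reverse")
  expect_lt(rv$final_coral[rv$fishing_axis == 0.45], 0.2)
  # total herbivores decline monotonically as fishing rises
  H <- rowSums(fwd$final_states[, c("G", "B", "R")])
  expect_true(all(diff(H) <= 1e-3))
})

test_that("grazer-dominated reefs lose coral above a sharp macroalgal threshold", {
  h <- community_preset("grazer_dominated")
  K <- carrying_capacity(0.15, 0.6)
  outcome_at <- function(M0) {
    st <- reef_state(C = 0.15, T = 0.3, M = M0, G = h[["G0"]] * K,
                     B = h[["B0"]] * K, R = h[["R0"]] * K)
    run_to_steady_state(st, reef_params(f = 0))$outcome
  }
  expect_equal(outcome_at(0.05), "coral_high")
  expect_equal(outcome_at(0.25), "coral_low")
})

test_that("question runner writes traceable, deterministic result files", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  for (d in c(out1, out2)) {
    suppressWarnings(run_question(
      "Q3", community = "grazer_dominated", out_dir = d,
      coral_step = 0.17, fishing_step = 0.25))
  }
  res <- utils::read.csv(file.path(out1, "results.csv"))
  scen <- utils::read.csv(file.path(out1, "scenarios.csv"))
  expect_setequal(res$id, scen$id) # lossless join
  smry <- jsonlite::fromJSON(file.path(out1, "summary.json"))
  expect_equal(smry$n_scenarios, nrow(res))
  expect_identical(readLines(file.path(out1, "results.csv")),
                   readLines(file.path(out2, "results.csv")))
})

test_that("sensitivity sweeps rerun the analysis per parameter value", {
  runs <- sensitivity_sweep("sigma", c(0, 0.6), function(p) {
    run_to_steady_state(disturbed_state(0.3, 0.3, 0.3), p)
  }, params = reef_params(f = 0.3))
  # decoupled from coral (sigma = 0), the herbivore total is exactly 1 - f/r
  H0 <- sum(runs[[1]]$final_state[c("G", "B", "R")])
  expect_lt(abs(H0 - 0.7), 1e-6)
  expect_error(sensitivity_sweep("nope", 1, identity), "unknown")
})
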