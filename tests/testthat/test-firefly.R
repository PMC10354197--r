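test_that("the optimizer is deterministic under a fixed seed", {
  m <- two_mass_chain()
  tg <- make_targets(m, n_points = 6)
  cfg <- fa_config(swarm_size = 6, iterations = 4, seed = 99)
  f1 <- fa_optimize(tg, m, cfg, constraints = model_constraints(m, 5))
  f2 <- fa_optimize(tg, m, cfg, constraints = model_constraints(m, 5))
  expect_identical(f1$best_params, f2$best_params)
  expect_identical(f1$history, f2$history)
})

test_that("an infinite tolerance stops after exactly one iteration", {
  m <- two_mass_chain()
  tg <- make_targets(m, n_points = 6)
  fit <- fa_optimize(tg, m,
                     fa_config(swarm_size = 5, iterations = 50,
                               sse_tolerance = Inf, seed = 3),
                     constraints = model_constraints(m, 5))
  expect_equal(nrow(fit$history), 1)
})

test_that("best-so-far history is non-increasing and feasible", {
  m <- two_mass_chain()
  tg <- make_targets(m, n_points = 6)
  fit <- fa_optimize(tg, m,
                     fa_config(swarm_size = 8, iterations = 12, seed = 21),
                     constraints = model_constraints(m, 5))
  expect_true(all(diff(fit$history$best_objective) <= 0))
  chk <- check_constraints(fit$best_params, m,
                           constraints = model_constraints(m, 5))
  expect_true(all(chk$satisfied))
  expect_equal(sum(fit$best_model$segments$mass_kg), 5, tolerance = 1e-9)
})

test_that("degenerate search spaces are rejected", {
  m <- two_mass_chain()
  tg <- make_targets(m, n_points = 6)
  expect_error(
    fa_optimize(tg, m, fa_config(swarm_size = 4, iterations = 2),
                bounds = default_bounds(cross_abs = 0)),
    "degenerate", class = "seatvibe_validation"
  )
  expect_error(fa_config(swarm_size = 1), "swarm_size",
               class = "seatvibe_validation")
})

test_that("fit accessors expose parameters and summary", {
  m <- two_mass_chain()
  tg <- make_targets(m, n_points = 6)
  fit <- fa_optimize(tg, m,
                     fa_config(swarm_size = 5, iterations = 3, seed = 1),
                     constraints = model_constraints(m, 5))
  td <- tidy(fit)
  expect_equal(nrow(td), 2 + 8 * 2)
  expect_true(all(c("parameter", "value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$best_objective >= 0)
})
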