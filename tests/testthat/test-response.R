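test_that("single-mass response matches the closed-form transmissibility", {
  toy <- single_mass_model(m = 1, k = 1000, c = 5)
  f <- seq(0.5, 20, 0.05)
  tr <- compute_tr(solve_response(toy, f), 1)
  expect_equal(tr$magnitude, toy_transmissibility(f), tolerance = 1e-10)
})

test_that("low-frequency limit is rigid-body follow for every segment", {
  resp <- solve_response(table1_model(), frequencies = c(0.05, 0.1))
  for (s in 1:16) {
    expect_equal(compute_tr(resp, s)$magnitude[1], 1, tolerance = 0.01)
  }
})

test_that("response is linear in the base amplitude and phase-invariant", {
  m <- table1_model()
  f <- seq(1, 15, 1)
  r1 <- solve_response(m, f, base_amplitude = 1)
  r2 <- solve_response(m, f, base_amplitude = 2)
  expect_equal(r2$displacement, 2 * r1$displacement, tolerance = 1e-12)
  expect_equal(compute_tr(r2, 1)$phase_deg, compute_tr(r1, 1)$phase_deg,
               tolerance = 1e-10)
  expect_equal(compute_tr(r2, 1)$magnitude, compute_tr(r1, 1)$magnitude,
               tolerance = 1e-12)
})

test_that("transmissibility of two-mass chains matches the direct 2x2 solve", {
  chain <- two_mass_chain(m1 = 2, m2 = 3, k1 = 4000, k2 = 6000,
                          c1 = 10, c2 = 15)
  f <- seq(0.5, 20, 0.1)
  resp <- solve_response(chain, f)
  for (j in seq_along(f)) {
    w <- 2 * pi * f[j]
    K <- matrix(c(4000, -4000, -4000, 10000), 2, 2)
    C <- matrix(c(10, -10, -10, 25), 2, 2)
    M <- diag(c(2, 3))
    A <- -w^2 * M + 1i * w * C + K
    b <- c(0, 6000 + 1i * w * 15)
    z <- solve(A, b)
    expect_equal(resp$displacement[c(2, 4), j], z, tolerance = 1e-6)
  }
})

test_that("seat-to-head transmissibility modes behave at their limits", {
  m <- table1_model()
  resp <- solve_response(m, frequencies = c(0.05, 5))
  lit <- compute_sthts(resp, projection = TRUE)
  conv <- compute_sthts(resp, projection = FALSE)
  expect_equal(lit$magnitude[1], sin(24 * pi / 180), tolerance = 0.01)
  expect_equal(conv$magnitude[1], 1, tolerance = 0.01)
  # at 90 degrees the projection factor is 1
  lit90 <- compute_sthts(resp, theta1 = 90, projection = TRUE)
  expect_equal(lit90$magnitude, conv$magnitude)
  expect_error(compute_sthts(resp, theta1 = 120), "degrees",
               class = "seatvibe_validation")
})

test_that("apparent mass recovers static mass at low frequency", {
  toy <- single_mass_model(m = 7, k = 2000, c = 8)
  resp <- solve_response(toy, frequencies = c(0.05, 0.1))
  am <- compute_am(resp, mode = "seat")
  expect_equal(am$magnitude[1], 7, tolerance = 0.01)

  chain <- two_mass_chain(m1 = 2.5, m2 = 4.5)
  am2 <- compute_am(solve_response(chain, c(0.05, 0.1)), mode = "seat")
  expect_equal(am2$magnitude[1], 7, tolerance = 0.01)

  # packaged model: the whole body is carried through the seat path
  am3 <- compute_am(solve_response(table1_model(), c(0.05, 0.1)),
                    mode = "pelvis")
  expect_equal(am3$magnitude[1], 75.72, tolerance = 0.01 * 75.72)
  expect_true(all(am3$magnitude >= 0))
})

test_that("transmissibility helpers validate their inputs", {
  resp <- solve_response(table1_model(), frequencies = c(1, 2))
  expect_error(compute_tr(resp, 99), "unknown segment",
               class = "seatvibe_validation")
  expect_error(solve_response(table1_model(), frequencies = c(2, 1)),
               "increasing", class = "seatvibe_validation")
})

test_that("peak refinement matches closed-form and synthetic oracles", {
  # damped closed-form peak of the single-mass toy
  toy <- single_mass_model(m = 1, k = 1000, c = 5)
  tr <- compute_tr(solve_response(toy, default_grid()), 1)
  pk <- find_peak(tr)
  oracle <- optimise(function(f) -toy_transmissibility(f), c(3, 7))
  expect_false(pk$boundary)
  expect_equal(pk$peak_frequency_hz, oracle$minimum,
               tolerance = 0.01 * oracle$minimum)

  # constant curve: tie broken to the lowest frequency, boundary flagged
  flat <- tibble::tibble(frequency_hz = 1:10, magnitude = rep(2, 10))
  pk <- find_peak(flat)
  expect_equal(pk$peak_frequency_hz, 1)
  expect_true(pk$boundary)

  # analytic parabola: interpolated vertex to 1e-6 Hz
  f <- seq(1, 10, 0.25)
  par <- tibble::tibble(frequency_hz = f,
                        magnitude = 5 - (f - 4.6180339)^2)
  pk <- find_peak(par)
  expect_equal(pk$peak_frequency_hz, 4.6180339, tolerance = 1e-6)
})
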