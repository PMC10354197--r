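test_that("the 7-dof car assembly matches a hand-built oracle", {
  car <- default_car()
  sys <- assemble_car(car)
  # hand-assemble from first principles, independent of the package loop
  xs <- c(1.2, 1.2, -1.5, -1.5)
  ys <- c(0.75, -0.75, 0.75, -0.75)
  ks <- c(30000, 30000, 28000, 28000)
  cs <- c(2500, 2500, 2200, 2200)
  kt <- rep(200000, 4)
  K <- matrix(0, 7, 7)
  C <- matrix(0, 7, 7)
  for (i in 1:4) {
    r <- c(1, -xs[i], ys[i], 0, 0, 0, 0)
    u <- numeric(7)
    u[3 + i] <- 1
    d <- r - u
    K <- K + ks[i] * outer(d, d) + kt[i] * outer(u, u)
    C <- C + cs[i] * outer(d, d)
  }
  expect_equal(sys$K, K)
  expect_equal(sys$C, C)
  expect_equal(diag(sys$M), c(1500, 2160, 460, 40, 40, 45, 45))
  expect_error(car_model(sprung_mass = -1, inertia_pitch = 1,
                         inertia_roll = 1, a_front = 1, b_rear = 1,
                         half_track_front = 1, half_track_rear = 1,
                         k_susp = 1, c_susp = 1, unsprung_mass = 1,
                         k_tire = 1),
               "positive", class = "seatvibe_validation")
})

test_that("coupled matrices are symmetric with the right dimensions", {
  coupled <- assemble_coupled(table1_model(), default_car())
  expect_equal(dim(coupled$M), c(39, 39))
  expect_equal(max(abs(coupled$K - t(coupled$K))), 0)
  expect_equal(max(abs(coupled$C - t(coupled$C))), 0)
})

test_that("in-phase symmetric excitation produces no roll", {
  # default car is left/right symmetric and the seat is on the centreline
  freqs <- seq(1, 15, 0.5)
  coupled <- assemble_coupled(table1_model(), default_car())
  wm <- wheel_excitation(freqs, 0.025)
  nh <- coupled$n_human_dofs
  for (j in c(1, 10, 29)) {
    omega <- 2 * pi * freqs[j]
    A <- -omega^2 * coupled$M + 1i * omega * coupled$C + coupled$K
    f <- rep(0 + 0i, nh + 7)
    for (i in 1:4) f[nh + 3 + i] <- coupled$car$k_tire[i] * wm[i, j]
    q <- solve(A, f)
    expect_lt(Mod(q[nh + 3]), 1e-12 * max(Mod(q))) # roll dof
  }
})

test_that("wheel excitation policies behave as declared", {
  f <- c(1, 2, 5)
  wm <- wheel_excitation(f, 0.025)
  expect_true(all(wm == 0.025 + 0i))
  lag <- wheel_excitation(f, 0.025, phase_policy = "wheelbase_lag",
                          speed = 20, wheelbase = 2.7)
  expect_equal(lag[1, ], setNames(rep(0.025 + 0i, 3), NULL),
               ignore_attr = TRUE)
  expect_equal(lag[3, ], 0.025 * exp(-1i * 2 * pi * f * 2.7 / 20),
               ignore_attr = TRUE)
  expect_error(wheel_excitation(f, phase_policy = "wheelbase_lag"),
               "speed", class = "seatvibe_validation")
  # zero amplitude: zero response downstream
  acc <- segmental_acceleration(table1_model(), default_car(),
                                frequencies = c(2, 5), amplitude = 0)
  expect_true(all(acc$acceleration_ms2 == 0))
})

test_that("acceleration scales linearly and follows the road at low frequency", {
  m <- table1_model()
  car <- default_car()
  a1 <- segmental_acceleration(m, car, frequencies = c(0.05, 5, 8),
                               amplitude = 0.025)
  a2 <- segmental_acceleration(m, car, frequencies = c(0.05, 5, 8),
                               amplitude = 0.05)
  expect_equal(a2$acceleration_ms2, 2 * a1$acceleration_ms2,
               tolerance = 1e-9)
  # rigid-chain limit: every segment follows the road, accel = omega^2 Z
  low <- a1[a1$frequency_hz == 0.05, ]
  expect_equal(low$acceleration_ms2,
               rep((2 * pi * 0.05)^2 * 0.025, nrow(low)),
               tolerance = 0.02)
})

test_that("a quasi-rigid car reduces to the standalone occupant model", {
  m <- table1_model()
  stiff <- car_model(
    sprung_mass = 1500, inertia_pitch = 2160, inertia_roll = 460,
    a_front = 1.2, b_rear = 1.5, half_track_front = 0.75,
    half_track_rear = 0.75,
    k_susp = 3e10, c_susp = 2200, unsprung_mass = 40, k_tire = 2e11,
    seat_x = -0.3, seat_y = 0
  )
  freqs <- seq(1, 15, 0.25)
  acc <- segmental_acceleration(m, stiff, frequencies = freqs,
                                amplitude = 0.025, segments = 1:4)
  resp <- solve_response(m, freqs, base_amplitude = 0.025)
  for (s in 1:4) {
    standalone <- (2 * pi * freqs)^2 * compute_tr(resp, s)$magnitude * 0.025
    got <- acc$acceleration_ms2[acc$segment == s]
    expect_equal(got, standalone, tolerance = 0.01)
  }
})

test_that("coupled ride peaks sit in the discomfort band for all trunk segments", {
  acc <- segmental_acceleration(table1_model(), default_car(),
                                frequencies = seq(0.5, 20, 0.05))
  pk <- vapply(1:4, function(s) {
    a <- acc[acc$segment == s, ]
    a$frequency_hz[which.max(a$acceleration_ms2)]
  }, numeric(1))
  # head/thorax/abdomen/pelvis all resonate in the 5-12 Hz band the
  # comfort charts flag as most sensitive
  expect_true(all(pk >= 5 & pk <= 12))
  mag <- vapply(1:4, function(s) max(acc$acceleration_ms2[acc$segment == s]),
                numeric(1))
  # trunk segments ride nearly together through the seat path
  expect_lt(diff(range(mag)) / max(mag), 0.15)
})
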