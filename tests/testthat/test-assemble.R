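test_that("single-element and chain assemblies match hand results", {
  toy <- single_mass_model(m = 3, k = 1200, c = 7)
  sys <- assemble_system(toy)
  expect_equal(sys$M, diag(c(3, 3)))
  expect_equal(sys$K, diag(c(1200, 1200)))
  expect_equal(sys$C, diag(c(7, 7)))

  chain <- two_mass_chain(k1 = 4000, k2 = 6000)
  sys <- assemble_system(chain)
  zi <- c(2, 4) # z dofs of segments 1, 2
  expect_equal(sys$K[zi, zi],
               matrix(c(4000, -4000, -4000, 4000 + 6000), 2, 2))
  expect_equal(sys$M[zi, zi], diag(c(2, 3)))
})

test_that("assembly equals brute-force superposition on random topologies", {
  withr::with_seed(11, {
    for (rep in 1:12) {
      m <- random_small_model()
      sys <- assemble_system(m)
      expect_equal(sys$K, brute_force_matrix(m, "k"), tolerance = 1e-12)
      expect_equal(sys$C, brute_force_matrix(m, "c"), tolerance = 1e-12)
      # exact symmetry under cross-term symmetry
      expect_identical(max(abs(sys$K - t(sys$K))), 0)
      expect_identical(max(abs(sys$C - t(sys$C))), 0)
    }
  })
})

test_that("the packaged model assembles to a symmetric 32-dof system", {
  sys <- assemble_system(table1_model())
  expect_equal(dim(sys$K), c(32, 32))
  expect_equal(diag(sys$M)[1:6], c(6.13, 6.13, 14.39, 14.39, 10.18, 10.18))
  expect_identical(max(abs(sys$K - t(sys$K))), 0)
  expect_identical(max(abs(sys$C - t(sys$C))), 0)
})

test_that("base forcing sums support contributions per connection", {
  toy <- single_mass_model(m = 1, k = 1000, c = 5)
  omega <- 2 * pi * 3
  f <- base_forcing(toy, omega, base_amplitude = 1)
  expect_equal(f[2], complex(real = 1000, imaginary = omega * 5))
  expect_equal(f[1], 0 + 0i) # no cross terms in the toy

  # unsupported model: zero vector (validation relaxed for this case)
  free <- human_model(
    tibble::tibble(id = 1L, name = "m", mass_kg = 1, partner = NA_integer_),
    tibble::tibble(index = 1L, end_a = "1", end_b = 1L,
                   k_xx = 1, k_xz = 0, k_zx = 0, k_zz = 1,
                   c_xx = 0, c_xz = 0, c_zx = 0, c_zz = 0),
    validate = FALSE
  )
  expect_equal(base_forcing(free, omega), rep(0 + 0i, 2))

  # packaged model at 5 Hz: brute-force per-connection summation oracle
  m <- table1_model()
  omega <- 2 * pi * 5
  z0 <- 0.025
  f <- base_forcing(m, omega, z0)
  con <- m$connections
  manual <- rep(0 + 0i, 32)
  for (r in which(con$end_a %in% c("SEAT", "BACKREST", "FLOOR"))) {
    b <- con$end_b[r]
    kc <- matrix(c(con$k_xx[r], con$k_zx[r], con$k_xz[r], con$k_zz[r]), 2, 2) +
      1i * omega *
        matrix(c(con$c_xx[r], con$c_zx[r], con$c_xz[r], con$c_zz[r]), 2, 2)
    manual[c(2 * b - 1, 2 * b)] <- manual[c(2 * b - 1, 2 * b)] +
      kc %*% c(0, z0)
  }
  expect_equal(f, manual)
  expect_error(base_forcing(m, -1), "positive", class = "seatvibe_validation")
})
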