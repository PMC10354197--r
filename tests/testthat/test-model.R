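test_that("the packaged parameter set is transcribed and wired correctly", {
  m <- table1_model()
  expect_equal(nrow(m$segments), 16)
  expect_equal(nrow(m$connections), 26)
  expect_equal(m$segments$mass_kg[1], 6.13) # head
  expect_equal(sum(m$segments$mass_kg), 75.72, tolerance = 1e-12)
  expect_equal(m$backrest_angle_deg, 24)
  # connection 1 direct vertical stiffness on the printed 1e5 scale
  expect_equal(m$connections$k_zz[m$connections$index == 1], 2.39e5)
  # cross terms symmetric as printed
  expect_equal(m$connections$k_xz, m$connections$k_zx)
  expect_equal(m$connections$c_xz, m$connections$c_zx)
  # the alternate contact arrangement is also a valid 26-connection model
  alt <- table1_model(topology = "full_contact")
  expect_equal(nrow(alt$connections), 26)
  expect_equal(sum(alt$connections$end_a %in% c("SEAT", "BACKREST", "FLOOR")), 9)
})

test_that("symmetric limb segments share masses", {
  m <- table1_model()
  for (p in list(c(5, 8), c(6, 9), c(7, 10), c(11, 14), c(12, 15),
                 c(13, 16))) {
    expect_equal(m$segments$mass_kg[p[1]], m$segments$mass_kg[p[2]])
    expect_equal(m$segments$partner[p[1]], p[2])
  }
})

test_that("validation aggregates structural violations", {
  seg <- tibble::tibble(id = 1:2, name = c("a", "b"), mass_kg = c(1, 2),
                        partner = NA_integer_)
  con <- tibble::tibble(index = 1L, end_a = "SEAT", end_b = 1L,
                        k_xx = 1, k_xz = 0, k_zx = 0, k_zz = 1,
                        c_xx = 0, c_xz = 0, c_zx = 0, c_zz = 0)
  # segment 2 unreachable from any support
  expect_error(human_model(seg, con), "no path to a support",
               class = "seatvibe_validation")
  # non-positive mass
  seg2 <- seg
  seg2$mass_kg[1] <- -1
  expect_error(human_model(seg2, con), "finite and > 0",
               class = "seatvibe_validation")
  # non-finite stiffness
  con3 <- con
  con3$k_zz <- NaN
  expect_error(
    human_model(tibble::tibble(id = 1L, name = "a", mass_kg = 1,
                               partner = NA_integer_), con3),
    "non-finite", class = "seatvibe_validation"
  )
  # backrest angle out of range
  expect_error(
    single_mass_model() |> (\(m) human_model(m$segments, m$connections,
                                             backrest_angle_deg = 95))(),
    "backrest", class = "seatvibe_validation"
  )
})

test_that("the packaged fixture file is immutable and round-trips", {
  path <- system.file("extdata", "table1.yaml", package = "seatvibe")
  expect_true(file.exists(path))
  expect_equal(unname(tools::md5sum(path)),
               "710577092ba30f38edaffce064a7f111")
  m <- load_model(path)
  expect_equal(m, table1_model())
})
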