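test_that("limit tables are positive and ordered by exposure duration", {
  lim <- default_comfort_limits()
  expect_true(all(lim$limit_ms2 > 0))
  wide <- tidyr::pivot_wider(lim, names_from = "duration_h",
                             values_from = "limit_ms2")
  expect_true(all(wide$`4` >= wide$`8`))
  expect_true(all(wide$`8` >= wide$`16`))
  # packaged CSV matches the generating function
  path <- system.file("extdata", "comfort_limits_synthetic.csv",
                      package = "seatvibe")
  expect_equal(as.data.frame(read_comfort_limits(path)),
               as.data.frame(lim), tolerance = 1e-9)
  bad <- lim
  bad$limit_ms2[bad$duration_h == 16] <- 10 # 16 h above 4 h: impossible
  expect_error(classify_exposure(tibble::tibble(
    segment = 1, name = "head", frequency_hz = c(1, 5),
    acceleration_ms2 = 0
  ), bad), "duration", class = "seatvibe_validation")
})

test_that("classification follows the ordering of the limit curves", {
  lim <- default_comfort_limits()
  f <- seq(1, 16, 0.5)
  zero <- tibble::tibble(segment = 1, name = "head", frequency_hz = f,
                         acceleration_ms2 = 0)
  v <- classify_exposure(zero, lim)
  expect_true(all(v$verdict == "within"))

  # response exactly on the 8-h curve: above 16-h, not above 4-h
  on8 <- tibble::tibble(
    segment = 1, name = "head", frequency_hz = f,
    acceleration_ms2 = approx(lim$frequency_hz[lim$duration_h == 8],
                              lim$limit_ms2[lim$duration_h == 8], f)$y
  )
  v <- classify_exposure(on8, lim)
  expect_identical(v$verdict[v$duration_h == 16], "exceeds")
  expect_identical(v$verdict[v$duration_h == 4], "within")

  # synthetic narrow peak above the 4-h limit at 6 Hz
  peaky <- tibble::tibble(
    segment = 2, name = "thorax", frequency_hz = f,
    acceleration_ms2 = ifelse(f == 6, 10, 0.01)
  )
  v <- classify_exposure(peaky, lim)
  expect_true(all(v$verdict == "exceeds"))
  expect_equal(unique(v$first_exceedance_hz), 6)
})

test_that("non-overlapping frequency ranges are rejected", {
  lim <- default_comfort_limits(frequencies = c(1, 2, 4))
  acc <- tibble::tibble(segment = 1, name = "head",
                        frequency_hz = c(10, 12),
                        acceleration_ms2 = c(0.1, 0.1))
  expect_error(classify_exposure(acc, lim), "overlap",
               class = "seatvibe_validation")
})
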