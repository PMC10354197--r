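test_that("zero perturbation reproduces the baseline bit-identically", {
  m <- table1_model()
  out <- oat_sensitivity(m, parameters = c("m4", "k_zz_4"), delta = 0,
                         frequencies = seq(3, 8, 0.05))
  expect_true(all(out$peak_change == 0))
  expect_true(all(out$peak_freq_shift_hz == 0))
  base <- attr(out, "baseline_peak")
  expect_identical(out$peak_magnitude, rep(base$peak_magnitude, 4))
})

test_that("toy stiffness sensitivity matches the closed-form finite difference", {
  toy <- single_mass_model(m = 1, k = 1000, c = 5)
  grid <- seq(0.5, 20, 0.01)
  out <- oat_sensitivity(toy, parameters = "k_zz_1", delta = 0.2,
                         frequencies = grid)
  # closed-form peaks: k and c enter the numerator and denominator jointly,
  # so perturb k in the formula directly (x dof decoupled in the toy)
  peak_cf <- function(k) {
    -optimise(function(f) {
      w <- 2 * pi * f
      -Mod((k + 1i * w * 5) / (k - w^2 + 1i * w * 5))
    }, c(2, 12))$objective
  }
  base <- peak_cf(1000)
  expected_plus <- (peak_cf(1200) - base) / base
  expected_minus <- (peak_cf(800) - base) / base
  got <- out[out$valid, ]
  expect_equal(got$peak_change[got$direction == "+"], expected_plus,
               tolerance = 1e-3)
  expect_equal(got$peak_change[got$direction == "-"], expected_minus,
               tolerance = 1e-3)
})

test_that("perturbations that break positivity are flagged invalid", {
  toy <- single_mass_model()
  out <- oat_sensitivity(toy, parameters = "m1", delta = 1.5,
                         frequencies = seq(1, 10, 0.1))
  minus <- out[out$direction == "-", ]
  expect_false(minus$valid)
  expect_true(is.na(minus$peak_change))
  plus <- out[out$direction == "+", ]
  expect_true(plus$valid)
})

test_that("symmetric partners are perturbed jointly", {
  m <- table1_model()
  grid <- seq(3, 8, 0.05)
  joint <- oat_sensitivity(m, parameters = "m11", delta = 0.2,
                           frequencies = grid, joint_symmetry = TRUE)
  single <- oat_sensitivity(m, parameters = "m11", delta = 0.2,
                            frequencies = grid, joint_symmetry = FALSE)
  # moving both thighs changes the peak more than moving one
  expect_gt(max(abs(joint$peak_change)), max(abs(single$peak_change)))
})

test_that("seat-interface parameters dominate the transmissibility peak", {
  # the seat-cushion element carries the whole body, so its direct vertical
  # stiffness and damping are the most influential stiffness/damping
  # parameters, mirroring the identified model's sensitivity story
  m <- table1_model()
  grid <- seq(3, 9, 0.05)
  kzz <- oat_sensitivity(m, parameters = paste0("k_zz_", c(1:4, 11, 12, 14)),
                         delta = 0.2, frequencies = grid)
  ranking <- kzz |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(infl = max(abs(.data$peak_change)), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$infl))
  expect_identical(ranking$parameter[1], "k_zz_4")

  czz <- oat_sensitivity(m, parameters = paste0("c_zz_", c(1:4, 11, 12)),
                         delta = 0.2, frequencies = grid)
  ranking_c <- czz |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(infl = max(abs(.data$peak_change)), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$infl))
  expect_identical(ranking_c$parameter[1], "c_zz_4")
})
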