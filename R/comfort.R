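# Exposure-limit comfort curves and classification of acceleration spectra
# against them.  The packaged limit tables are synthetic
# fatigue-decreased-proficiency-style vertical-acceleration boundaries
# (editable CSV): constant over 4-8 Hz, rising as 2/sqrt(f) below 4 Hz and
# as f/8 above 8 Hz, with shorter permissible exposures allowing higher
# levels (4 h >= 8 h >= 16 h everywhere).

#' Synthetic exposure-limit comfort curves
#'
#' @param durations_h Exposure durations (hours) to tabulate.
#' @param frequencies Frequency grid (Hz).
#' @param base_ms2 Named base levels (m/s^2 r.m.s.) on the 4-8 Hz plateau,
#'   one per duration.
#' @return Tibble: `frequency_hz`, `limit_ms2`, `duration_h`.
#' @export
default_comfort_limits <- function(durations_h = c(4, 8, 16),
                                   frequencies = c(
                                     0.5, 0.63, 0.8, 1, 1.25, 1.6, 2, 2.5,
                                     3.15, 4, 5, 6.3, 8, 10, 12.5, 16, 20
                                   ),
                                   base_ms2 = c(`4` = 0.53, `8` = 0.315,
                                                `16` = 0.20)) {
  shape <- ifelse(frequencies < 4, 2 / sqrt(frequencies),
                  ifelse(frequencies <= 8, 1, frequencies / 8))
  purrr::map_dfr(durations_h, function(d) {
    tibble::tibble(
      frequency_hz = frequencies,
      limit_ms2 = base_ms2[[as.character(d)]] * shape,
      duration_h = d
    )
  })
}

validate_comfort_limits <- function(limits) {
  need <- c("frequency_hz", "limit_ms2", "duration_h")
  missing <- setdiff(need, names(limits))
  if (length(missing)) {
    abort(paste("comfort curves missing columns:", toString(missing)),
          class = "seatvibe_validation")
  }
  if (any(limits$limit_ms2 <= 0)) {
    abort("comfort limits must be positive", class = "seatvibe_validation")
  }
  wide <- limits |>
    dplyr::arrange(.data$duration_h) |>
    tidyr::pivot_wider(names_from = "duration_h", values_from = "limit_ms2")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  if (ncol(mat) > 1 &&
      any(apply(mat, 1, function(r) any(diff(r) > 1e-12)))) {
    abort("limits must not increase with exposure duration",
          class = "seatvibe_validation")
  }
  invisible(limits)
}

#' Classify an acceleration spectrum against exposure limits
#'
#' Limit tables are linearly interpolated onto the response grid (only the
#' overlapping frequency range is judged); for every segment and duration
#' the verdict is `"exceeds"` if the response rises above the limit
#' anywhere, together with the first frequency of exceedance.
#'
#' @param accel Tibble from [segmental_acceleration()] (columns `segment`,
#'   `name`, `frequency_hz`, `acceleration_ms2`).
#' @param limits Limit tibble ([default_comfort_limits()] or
#'   [read_comfort_limits()]).
#' @return Tibble: `segment`, `name`, `duration_h`, `verdict`,
#'   `first_exceedance_hz` (`NA` when within).
#' @export
classify_exposure <- function(accel, limits = default_comfort_limits()) {
  validate_comfort_limits(limits)
  durations <- sort(unique(limits$duration_h))
  groups <- dplyr::distinct(accel, .data$segment, .data$name)
  purrr::map_dfr(seq_len(nrow(groups)), function(g) {
    a <- accel[accel$segment == groups$segment[g], ]
    purrr::map_dfr(durations, function(d) {
      lim <- limits[limits$duration_h == d, ]
      lo <- max(min(a$frequency_hz), min(lim$frequency_hz))
      hi <- min(max(a$frequency_hz), max(lim$frequency_hz))
      if (lo >= hi) {
        abort("response and limit curves do not overlap in frequency",
              class = "seatvibe_validation")
      }
      sel <- a$frequency_hz >= lo & a$frequency_hz <= hi
      f <- a$frequency_hz[sel]
      li <- approx(lim$frequency_hz, lim$limit_ms2, xout = f)$y
      over <- a$acceleration_ms2[sel] > li
      tibble::tibble(
        segment = groups$segment[g],
        name = groups$name[g],
        duration_h = d,
        verdict = if (any(over)) "exceeds" else "within",
        first_exceedance_hz = if (any(over)) f[which(over)[1]] else NA_real_
      )
    })
  })
}

#' Plot segmental accelerations against the comfort limit curves
#'
#' @param accel Tibble from [segmental_acceleration()].
#' @param limits Limit tibble.
#' @return A ggplot.
#' @export
plot_comfort <- function(accel, limits = default_comfort_limits()) {
  ggplot2::ggplot(accel, ggplot2::aes(.data$frequency_hz,
                                      .data$acceleration_ms2)) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$name)) +
    ggplot2::geom_line(
      data = dplyr::mutate(limits, duration = factor(.data$duration_h)),
      ggplot2::aes(y = .data$limit_ms2, linetype = .data$duration),
      colour = "grey30"
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Acceleration (m/s²)",
                  colour = "Segment", linetype = "Limit (h)") +
    ggplot2::theme_minimal()
}
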