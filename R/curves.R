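# Biodynamic response curves derived from a solved frequency response:
# seat-to-head transmissibility (STHT), apparent mass (AM) and segmental
# transmissibility (TR).  All are returned as `response_curve` tibbles with
# columns frequency_hz, magnitude, phase_deg, quantity, segment.

response_curve <- function(frequency_hz, magnitude, phase_deg,
                           quantity, segment) {
  out <- tibble::tibble(
    frequency_hz = frequency_hz,
    magnitude = magnitude,
    phase_deg = phase_deg,
    quantity = quantity,
    segment = segment
  )
  class(out) <- c("response_curve", class(out))
  out
}

#' Seat-to-head transmissibility
#'
#' With `projection = TRUE` (the default) the magnitude is
#' `|Z1| sin(theta1) / z0`, projecting the head motion on the inclined
#' backrest direction; with `projection = FALSE` it is the conventional
#' `|Z1| / z0`.  The projected form goes to `sin(theta1)` instead of 1 in
#' the rigid low-frequency limit and vanishes for a vertical backrest, so
#' both definitions are exposed; the phase is `arg(Z1/z0)` in either mode.
#'
#' @param resp A `freq_response` containing the head segment (id 1).
#' @param theta1 Backrest angle in degrees (default: the model's).
#' @param projection Apply the `sin(theta1)` projection factor.
#' @return A `response_curve` tibble (`quantity = "STHT"`).
#' @export
compute_sthts <- function(resp, theta1 = resp$model$backrest_angle_deg,
                          projection = TRUE) {
  if (is.na(theta1) || theta1 < 0 || theta1 > 90) {
    abort("theta1 must lie in [0, 90] degrees", class = "seatvibe_validation")
  }
  z1 <- segment_row(resp, 1L, "z")
  ratio <- z1 / resp$base_amplitude
  fac <- if (projection) sin(theta1 * pi / 180) else 1
  response_curve(
    resp$frequencies, Mod(ratio) * fac, Arg(ratio) * 180 / pi,
    "STHT", "head"
  )
}

#' Apparent mass at the body-seat interface
#'
#' The complex ratio of transmitted force to acceleration at the seat
#' interface, reported in kg.  `mode = "pelvis"` (default) uses the force
#' carried by the seat-pelvis connection(s) divided by the pelvis vertical
#' acceleration `-omega^2 Z4`; `mode = "seat"` sums the force over every
#' seat-interface connection and divides by the seat acceleration
#' `-omega^2 z0`, which recovers the total seat-borne static mass as
#' `omega -> 0`.
#'
#' @param resp A `freq_response`.
#' @param mode `"pelvis"` or `"seat"`.
#' @param pelvis_id Segment id of the seat-contact segment; defaults to 4
#'   (the pelvis) when present, otherwise to the first SEAT-connected
#'   segment, so reduced test models work unchanged.
#' @return A `response_curve` tibble (`quantity = "AM"`, magnitude in kg).
#'   Grid points where the reference acceleration vanishes are dropped with
#'   a warning.
#' @export
compute_am <- function(resp, mode = c("pelvis", "seat"), pelvis_id = NULL) {
  mode <- match.arg(mode)
  model <- resp$model
  con <- model$connections
  seat <- which(con$end_a == "SEAT")
  if (is.null(pelvis_id)) {
    pelvis_id <- if (4L %in% con$end_b[seat]) 4L else con$end_b[seat][1]
  }
  if (mode == "pelvis") seat <- seat[con$end_b[seat] == pelvis_id]
  if (!length(seat)) {
    abort("model has no SEAT connection for the requested apparent-mass mode",
          class = "seatvibe_validation")
  }
  pos <- setNames(seq_len(nrow(model$segments)), model$segments$id)
  z0 <- resp$base_amplitude
  scale_of <- function(tag) {
    ss <- resp$support_scale
    if (!is.null(ss) && tag %in% names(ss)) ss[[tag]] else 1
  }
  nf <- length(resp$frequencies)
  force <- rep(0 + 0i, nf)
  for (r in seat) {
    m <- conn_matrices(con, r)
    ib <- dof_idx(pos[[as.character(con$end_b[r])]])
    chi <- resp$displacement[ib, , drop = FALSE]
    base <- c(0, z0 * scale_of(con$end_a[r]))
    for (j in seq_len(nf)) {
      omega <- 2 * pi * resp$frequencies[j]
      fj <- (m$k + 1i * omega * m$c) %*% (base - chi[, j])
      force[j] <- force[j] + fj[2]
    }
  }
  omega <- 2 * pi * resp$frequencies
  accel <- if (mode == "pelvis") {
    -omega^2 * segment_row(resp, pelvis_id, "z")
  } else {
    -omega^2 * z0
  }
  keep <- Mod(accel) > 0
  if (!all(keep)) {
    warn(sprintf("dropping %d grid point(s) with zero reference acceleration",
                 sum(!keep)))
  }
  am <- force[keep] / accel[keep]
  response_curve(
    resp$frequencies[keep], Mod(am), Arg(am) * 180 / pi,
    "AM", if (mode == "pelvis") "pelvis" else "seat"
  )
}

#' Segmental vibration transmissibility
#'
#' `TR(f) = |Z_segment(f)| / z0` with phase `arg(Z_segment / z0)`, the
#' displacement transmissibility from the moving seat to a body segment's
#' vertical motion; used with segments 1-4 for the seat-to-head, thorax,
#' abdomen and pelvis curves.
#'
#' @param resp A `freq_response`.
#' @param segment_id Segment id.
#' @return A `response_curve` tibble (`quantity = "TR"`).
#' @export
compute_tr <- function(resp, segment_id) {
  ratio <- segment_row(resp, segment_id, "z") / resp$base_amplitude
  nm <- resp$model$segments$name[match(segment_id, resp$model$segments$id)]
  response_curve(
    resp$frequencies, Mod(ratio), Arg(ratio) * 180 / pi, "TR", nm
  )
}

#' Locate the peak of a response curve
#'
#' Finds the discrete grid maximum (ties broken toward the lower frequency)
#' and refines it by a quadratic fit through the three surrounding points.
#' A maximum sitting on a grid boundary is returned unrefined with
#' `boundary = TRUE`.
#'
#' @param curve A `response_curve` (or any tibble with `frequency_hz` and
#'   `magnitude`).
#' @return One-row tibble: `peak_frequency_hz`, `peak_magnitude`, `boundary`.
#' @export
find_peak <- function(curve) {
  f <- curve$frequency_hz
  m <- curve$magnitude
  if (!length(f)) abort("empty curve", class = "seatvibe_validation")
  i <- which.max(m)
  if (i == 1L || i == length(m)) {
    return(tibble::tibble(
      peak_frequency_hz = f[i], peak_magnitude = m[i], boundary = TRUE
    ))
  }
  # Quadratic through (f[i-1..i+1], m[i-1..i+1]); vertex of the parabola.
  x <- f[(i - 1):(i + 1)]
  y <- m[(i - 1):(i + 1)]
  d <- (y[1] - 2 * y[2] + y[3])
  if (d >= 0) { # flat or degenerate: keep the grid point
    return(tibble::tibble(
      peak_frequency_hz = f[i], peak_magnitude = m[i], boundary = FALSE
    ))
  }
  # General three-point parabola vertex (grids may be non-uniform).
  co <- solve(
    rbind(c(1, x[1], x[1]^2), c(1, x[2], x[2]^2), c(1, x[3], x[3]^2)), y
  )
  fv <- -co[2] / (2 * co[3])
  mv <- co[1] + co[2] * fv + co[3] * fv^2
  tibble::tibble(peak_frequency_hz = fv, peak_magnitude = mv, boundary = FALSE)
}

#' @method autoplot response_curve
#' @export
autoplot.response_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("magnitude", "phase_deg"),
                              names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$frequency_hz, .data$value,
                                     colour = .data$segment)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "Frequency (Hz)", y = NULL,
      title = paste(unique(object$quantity), collapse = ", ")
    ) +
    ggplot2::theme_minimal()
}
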