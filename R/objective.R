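# Weighted sum-square-error objective over STHT/AM magnitude and phase,
# and the goodness-of-fit statistic used to score identified models.

wrap_deg <- function(d) {
  # wrap angle differences to (-180, 180]
  w <- (d + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

analytic_curves <- function(model, frequencies, sthts_mode = "literal",
                            am_mode = "pelvis", base_amplitude = 1) {
  resp <- solve_response(model, frequencies, base_amplitude)
  sthts <- compute_sthts(resp, projection = identical(sthts_mode, "literal"))
  am <- compute_am(resp, mode = am_mode)
  list(sthts = sthts, am = am)
}

#' Identification objective: weighted sum-square curve error
#'
#' `O_f = sum_i (a1 l1 + a2 l2 + a3 l3 + a4 l4)` over the target frequency
#' points, where `l1..l4` are the squared errors of STHT magnitude, STHT
#' phase, AM magnitude and AM phase between the target curves and the
#' analytic curves of the decoded candidate model.  Phase errors are taken
#' in degrees after wrapping differences to (-180, 180].  A candidate whose
#' forward solve fails returns `+Inf`.
#'
#' @param values Parameter vector (layout of [encode_params()]).
#' @param template `human_model` giving topology and backrest angle.
#' @param targets A target-curve tibble from [make_targets()] or
#'   [read_targets()].
#' @param weights Numeric length 4, the four error weights (default all 1).
#' @param sthts_mode `"literal"` (with the backrest projection) or
#'   `"conventional"`.
#' @param am_mode `"pelvis"` or `"seat"`.
#' @return Non-negative scalar.
#' @export
fa_objective <- function(values, template, targets, weights = rep(1, 4),
                         sthts_mode = c("literal", "conventional"),
                         am_mode = c("pelvis", "seat")) {
  sthts_mode <- match.arg(sthts_mode)
  am_mode <- match.arg(am_mode)
  stopifnot(length(weights) == 4, all(weights >= 0))
  model <- tryCatch(decode_params(values, template, validate = TRUE),
                    error = function(e) NULL)
  if (is.null(model)) return(Inf)
  cur <- tryCatch(
    analytic_curves(model, targets$frequency_hz, sthts_mode, am_mode),
    error = function(e) NULL
  )
  if (is.null(cur) || nrow(cur$am) != nrow(targets)) return(Inf)
  l1 <- (targets$sthts_mag - cur$sthts$magnitude)^2
  l2 <- wrap_deg(targets$sthts_phase_deg - cur$sthts$phase_deg)^2
  l3 <- (targets$am_mag_kg - cur$am$magnitude)^2
  l4 <- wrap_deg(targets$am_phase_deg - cur$am$phase_deg)^2
  sum(weights[1] * l1 + weights[2] * l2 + weights[3] * l3 + weights[4] * l4)
}

# Precomputed evaluation context for the optimizer's hot loop: topology
# and targets unpacked into plain numeric structures so candidate vectors
# can be scored without tibble or validation overhead.  Must stay in exact
# agreement with fa_objective(); a test pins the two together.
objective_context <- function(template, targets, sthts_mode = "literal",
                              am_mode = "pelvis") {
  seg <- template$segments
  con <- template$connections
  ns <- nrow(seg)
  nc <- nrow(con)
  pos_of <- setNames(seq_len(ns), seg$id)
  a_pos <- ifelse(is_support(con$end_a), 0L,
                  pos_of[as.character(con$end_a)])
  b_pos <- pos_of[as.character(con$end_b)]
  seat_rows <- which(con$end_a == "SEAT")
  pelvis <- if (4L %in% con$end_b[seat_rows]) 4L else con$end_b[seat_rows][1]
  am_rows <- if (am_mode == "pelvis") {
    seat_rows[con$end_b[seat_rows] == pelvis]
  } else {
    seat_rows
  }
  list(
    ns = ns, nc = nc, a_pos = as.integer(a_pos), b_pos = as.integer(b_pos),
    support_rows = which(a_pos == 0L),
    am_rows = am_rows,
    am_pelvis = am_mode == "pelvis",
    pelvis_pos = pos_of[[as.character(pelvis)]],
    head_pos = match(1L, seg$id),
    sin_factor = if (identical(sthts_mode, "literal")) {
      sin(template$backrest_angle_deg * pi / 180)
    } else {
      1
    },
    omega = 2 * pi * targets$frequency_hz,
    t_sthts_mag = targets$sthts_mag,
    t_sthts_ph = targets$sthts_phase_deg,
    t_am_mag = targets$am_mag_kg,
    t_am_ph = targets$am_phase_deg
  )
}

objective_fast <- function(values, ctx, weights) {
  ns <- ctx$ns
  nc <- ctx$nc
  if (any(!is.finite(values))) return(Inf)
  mass <- values[seq_len(ns)]
  if (any(mass <= 0)) return(Inf)
  kmat <- matrix(values[ns + seq_len(4L * nc)], ncol = 4, byrow = TRUE)
  cmat <- matrix(values[ns + 4L * nc + seq_len(4L * nc)], ncol = 4,
                 byrow = TRUE)
  nd <- 2L * ns
  K <- matrix(0, nd, nd)
  C <- matrix(0, nd, nd)
  for (r in seq_len(nc)) {
    kb <- matrix(c(kmat[r, 1], kmat[r, 3], kmat[r, 2], kmat[r, 4]), 2, 2)
    cb <- matrix(c(cmat[r, 1], cmat[r, 3], cmat[r, 2], cmat[r, 4]), 2, 2)
    ib <- c(2L * ctx$b_pos[r] - 1L, 2L * ctx$b_pos[r])
    K[ib, ib] <- K[ib, ib] + kb
    C[ib, ib] <- C[ib, ib] + cb
    if (ctx$a_pos[r] > 0L) {
      ia <- c(2L * ctx$a_pos[r] - 1L, 2L * ctx$a_pos[r])
      K[ia, ia] <- K[ia, ia] + kb
      C[ia, ia] <- C[ia, ia] + cb
      K[ia, ib] <- K[ia, ib] - kb
      K[ib, ia] <- K[ib, ia] - kb
      C[ia, ib] <- C[ia, ib] - cb
      C[ib, ia] <- C[ib, ia] - cb
    }
  }
  Mdiag <- rep(mass, each = 2L)
  hz <- 2L * ctx$head_pos
  pz <- 2L * ctx$pelvis_pos
  np <- length(ctx$omega)
  sthts_mag <- numeric(np)
  sthts_ph <- numeric(np)
  am_mag <- numeric(np)
  am_ph <- numeric(np)
  for (j in seq_len(np)) {
    w <- ctx$omega[j]
    A <- 1i * w * C + K
    diag(A) <- diag(A) - w^2 * Mdiag
    f <- rep(0 + 0i, nd)
    for (r in ctx$support_rows) {
      ib <- c(2L * ctx$b_pos[r] - 1L, 2L * ctx$b_pos[r])
      f[ib] <- f[ib] +
        c(kmat[r, 2] + 1i * w * cmat[r, 2], kmat[r, 4] + 1i * w * cmat[r, 4])
    }
    x <- tryCatch(solve(A, f), error = function(e) NULL)
    if (is.null(x)) return(Inf)
    zh <- x[hz]
    sthts_mag[j] <- Mod(zh) * ctx$sin_factor
    sthts_ph[j] <- Arg(zh) * 180 / pi
    force <- 0 + 0i
    for (r in ctx$am_rows) {
      ib <- c(2L * ctx$b_pos[r] - 1L, 2L * ctx$b_pos[r])
      rel <- c(0, 1) - x[ib]
      force <- force + (kmat[r, 3] + 1i * w * cmat[r, 3]) * rel[1] +
        (kmat[r, 4] + 1i * w * cmat[r, 4]) * rel[2]
    }
    accel <- if (ctx$am_pelvis) -w^2 * x[pz] else complex(real = -w^2)
    if (Mod(accel) == 0) return(Inf)
    amv <- force / accel
    am_mag[j] <- Mod(amv)
    am_ph[j] <- Arg(amv) * 180 / pi
  }
  sum(
    weights[1] * (ctx$t_sthts_mag - sthts_mag)^2 +
      weights[2] * wrap_deg(ctx$t_sthts_ph - sthts_ph)^2 +
      weights[3] * (ctx$t_am_mag - am_mag)^2 +
      weights[4] * wrap_deg(ctx$t_am_ph - am_ph)^2
  )
}

#' Goodness of fit between two response series
#'
#' `epsilon = 1 - sqrt(sum((tau_e - tau_a)^2) / (N - 2)) / (sum(tau_e) / N)`,
#' a fraction equal to 1 when the analytical series reproduces the reference
#' series exactly.  The companion deviation is `delta = (1 - epsilon) * 100`
#' percent.
#'
#' @param tau_e Reference (experimental) series.
#' @param tau_a Analytical series, same length, `N >= 3`.
#' @return Scalar `epsilon` (dimensionless fraction).
#' @export
#' @examples
#' goodness_of_fit(c(1, 1, 1, 1), c(1, 1, 1, 0)) # 1 - sqrt(1/2)
goodness_of_fit <- function(tau_e, tau_a) {
  n <- length(tau_e)
  if (length(tau_a) != n) {
    abort("series must have equal length", class = "seatvibe_validation")
  }
  if (n < 3) {
    abort("need at least 3 points (N - 2 in the denominator)",
          class = "seatvibe_validation")
  }
  if (sum(tau_e) == 0) {
    abort("reference series must not sum to zero", class = "seatvibe_validation")
  }
  1 - sqrt(sum((tau_e - tau_a)^2) / (n - 2)) / (sum(tau_e) / n)
}

#' @rdname goodness_of_fit
#' @param epsilon A goodness-of-fit fraction.
#' @export
gof_deviation_pct <- function(epsilon) (1 - epsilon) * 100
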