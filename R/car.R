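# Seven-dof full-car model (body heave, pitch, roll + four unsprung
# verticals) and its coupling with the seated-occupant model.
#
# Car dof ordering: (z_s, pitch, roll, z_FL, z_FR, z_RL, z_RR).
# Conventions: x forward, y to the left, z up; body vertical motion at a
# point (x, y) is z_s - x * pitch + y * roll (small angles).

CAR_DOFS <- c("heave", "pitch", "roll", "z_FL", "z_FR", "z_RL", "z_RR")

#' Construct a 7-dof full-car model
#'
#' @param sprung_mass Body mass (kg).
#' @param inertia_pitch,inertia_roll Body inertias (kg m^2).
#' @param a_front,b_rear Distance from the centre of gravity to the front /
#'   rear axle (m, both positive).
#' @param half_track_front,half_track_rear Half track widths (m).
#' @param k_susp,c_susp Suspension stiffness (N/m) and damping (N s/m),
#'   length 4 in corner order FL, FR, RL, RR (scalars recycled).
#' @param unsprung_mass Unsprung masses (kg), length 4.
#' @param k_tire Tire vertical stiffness (N/m), length 4.
#' @param c_tire Tire damping (N s/m), default 0.
#' @param seat_x,seat_y Seat position relative to the centre of gravity (m).
#' @return A list of class `car_model`.
#' @export
car_model <- function(sprung_mass, inertia_pitch, inertia_roll,
                      a_front, b_rear, half_track_front, half_track_rear,
                      k_susp, c_susp, unsprung_mass, k_tire, c_tire = 0,
                      seat_x = 0, seat_y = 0) {
  rec4 <- function(x) {
    if (length(x) == 1) rep(x, 4) else {
      stopifnot(length(x) == 4)
      x
    }
  }
  car <- structure(list(
    sprung_mass = sprung_mass, inertia_pitch = inertia_pitch,
    inertia_roll = inertia_roll, a_front = a_front, b_rear = b_rear,
    half_track_front = half_track_front, half_track_rear = half_track_rear,
    k_susp = rec4(k_susp), c_susp = rec4(c_susp),
    unsprung_mass = rec4(unsprung_mass), k_tire = rec4(k_tire),
    c_tire = rec4(c_tire), seat_x = seat_x, seat_y = seat_y
  ), class = "car_model")
  pos <- c(car$sprung_mass, car$inertia_pitch, car$inertia_roll,
           car$a_front, car$b_rear, car$half_track_front,
           car$half_track_rear, car$k_susp, car$c_susp,
           car$unsprung_mass, car$k_tire)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    abort("car masses, inertias, geometry and stiffness must be positive",
          class = "seatvibe_validation")
  }
  car
}

#' Default mid-size-sedan car parameters
#'
#' A documented synthetic stand-in (the reference publication's own car
#' table is not publicly available): 1500 kg body on a 2.7 m wheelbase,
#' conventional passive suspension, seat on the centreline slightly behind
#' the centre of gravity.
#'
#' @return A `car_model`.
#' @export
default_car <- function() {
  car_model(
    sprung_mass = 1500, inertia_pitch = 2160, inertia_roll = 460,
    a_front = 1.2, b_rear = 1.5,
    half_track_front = 0.75, half_track_rear = 0.75,
    k_susp = c(30000, 30000, 28000, 28000),
    c_susp = c(2500, 2500, 2200, 2200),
    unsprung_mass = c(40, 40, 45, 45),
    k_tire = 200000,
    seat_x = -0.3, seat_y = 0
  )
}

#' Read a car parameter file
#'
#' @param path YAML file whose keys match the arguments of [car_model()].
#' @return A validated `car_model`.
#' @export
read_car <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("car file not found: %s", path),
          class = "seatvibe_validation")
  }
  raw <- yaml::read_yaml(path)
  known <- names(formals(car_model))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste("unknown car fields:", toString(unknown)),
          class = "seatvibe_validation")
  }
  do.call(car_model, raw)
}

# Corner positions (x, y) in order FL, FR, RL, RR.
car_corners <- function(car) {
  rbind(
    c(car$a_front, car$half_track_front),
    c(car$a_front, -car$half_track_front),
    c(-car$b_rear, car$half_track_rear),
    c(-car$b_rear, -car$half_track_rear)
  )
}

# Row vector mapping the 7 car dofs to vertical motion at body point (x, y).
car_point_map <- function(x, y) c(1, -x, y, 0, 0, 0, 0)

#' Assemble the 7-dof car matrices
#'
#' @param car A `car_model`.
#' @return List with `M`, `C`, `K` (7x7) in the documented dof order.
#' @export
assemble_car <- function(car) {
  M <- diag(c(car$sprung_mass, car$inertia_pitch, car$inertia_roll,
              car$unsprung_mass))
  K <- matrix(0, 7, 7)
  C <- matrix(0, 7, 7)
  corners <- car_corners(car)
  for (i in 1:4) {
    r <- car_point_map(corners[i, 1], corners[i, 2])
    u <- numeric(7)
    u[3 + i] <- 1
    d <- r - u # suspension deflection map: body corner minus unsprung
    K <- K + car$k_susp[i] * tcrossprod(d)
    C <- C + car$c_susp[i] * tcrossprod(d)
    K <- K + car$k_tire[i] * tcrossprod(u)
    C <- C + car$c_tire[i] * tcrossprod(u)
  }
  list(M = M, C = C, K = K)
}

#' Couple the seated-occupant model with the car
#'
#' The occupant's support tags (SEAT, BACKREST, FLOOR) no longer receive a
#' prescribed base motion; each support connection instead couples its
#' segment to the car-body vertical motion at the seat position
#' (`heave - seat_x * pitch + seat_y * roll`, linearised).  Human dofs come
#' first, then the 7 car dofs.
#'
#' @param human A `human_model`.
#' @param car A `car_model`.
#' @return A list of class `coupled_model` with 39x39 (for the full
#'   occupant) `M`, `C`, `K`, the dof map, and both submodels.
#' @export
assemble_coupled <- function(human, car) {
  hsys <- assemble_system(human) # includes support diagonal contributions
  csys <- assemble_car(car)
  nh <- nrow(hsys$M)
  nd <- nh + 7L
  M <- matrix(0, nd, nd)
  C <- matrix(0, nd, nd)
  K <- matrix(0, nd, nd)
  M[1:nh, 1:nh] <- hsys$M
  C[1:nh, 1:nh] <- hsys$C
  K[1:nh, 1:nh] <- hsys$K
  M[nh + 1:7, nh + 1:7] <- csys$M
  C[nh + 1:7, nh + 1:7] <- csys$C
  K[nh + 1:7, nh + 1:7] <- csys$K
  t_seat <- car_point_map(car$seat_x, car$seat_y)
  con <- human$connections
  seg <- human$segments
  pos <- setNames(seq_len(nrow(seg)), seg$id)
  car_ix <- nh + 1:7
  for (r in seq_len(nrow(con))) {
    if (!is_support(con$end_a[r])) next
    m <- conn_matrices(con, r)
    ib <- dof_idx(pos[[as.character(con$end_b[r])]])
    # column of the 2x2 matrix acting on the vertical support motion
    kz <- m$k[, 2]
    cz <- m$c[, 2]
    K[ib, car_ix] <- K[ib, car_ix] - kz %o% t_seat
    K[car_ix, ib] <- K[car_ix, ib] - t_seat %o% kz
    C[ib, car_ix] <- C[ib, car_ix] - cz %o% t_seat
    C[car_ix, ib] <- C[car_ix, ib] - t_seat %o% cz
    K[car_ix, car_ix] <- K[car_ix, car_ix] + m$k[2, 2] * tcrossprod(t_seat)
    C[car_ix, car_ix] <- C[car_ix, car_ix] + m$c[2, 2] * tcrossprod(t_seat)
  }
  structure(list(
    M = M, C = C, K = K, human = human, car = car,
    n_human_dofs = nh,
    dof = c(paste0(rep(seg$name, each = 2), "_", rep(c("x", "z"),
                                                     nrow(seg))), CAR_DOFS)
  ), class = "coupled_model")
}

#' Harmonic wheel excitation
#'
#' @param frequencies Frequencies (Hz).
#' @param amplitude Road motion amplitude at the wheels (m), default 0.025.
#' @param phase_policy `"in_phase"` (default: identical complex amplitude at
#'   all four wheels) or `"wheelbase_lag"` (rear wheels lagged by the
#'   travel time `L / speed`).
#' @param speed Vehicle speed (m/s), required for the lag policy.
#' @param wheelbase Wheelbase (m) for the lag policy.
#' @return Complex matrix, 4 rows (FL, FR, RL, RR) by length(frequencies).
#' @export
wheel_excitation <- function(frequencies, amplitude = 0.025,
                             phase_policy = c("in_phase", "wheelbase_lag"),
                             speed = NULL, wheelbase = 2.7) {
  phase_policy <- match.arg(phase_policy)
  if (amplitude < 0) abort("amplitude must be >= 0",
                           class = "seatvibe_validation")
  nf <- length(frequencies)
  z <- matrix(amplitude + 0i, 4, nf)
  if (phase_policy == "wheelbase_lag") {
    if (is.null(speed) || speed <= 0) {
      abort("wheelbase_lag policy needs a positive speed",
            class = "seatvibe_validation")
    }
    lag <- exp(-1i * 2 * pi * frequencies * wheelbase / speed)
    z[3, ] <- z[3, ] * lag
    z[4, ] <- z[4, ] * lag
  }
  rownames(z) <- c("FL", "FR", "RL", "RR")
  z
}

# Direct solve of the coupled system under wheel excitation.
solve_coupled <- function(coupled, frequencies, wheel_motion) {
  car <- coupled$car
  nh <- coupled$n_human_dofs
  nd <- nh + 7L
  disp <- matrix(0 + 0i, nd, length(frequencies))
  for (j in seq_along(frequencies)) {
    omega <- 2 * pi * frequencies[j]
    A <- -omega^2 * coupled$M + 1i * omega * coupled$C + coupled$K
    f <- rep(0 + 0i, nd)
    for (i in 1:4) {
      f[nh + 3 + i] <- f[nh + 3 + i] +
        (car$k_tire[i] + 1i * omega * car$c_tire[i]) * wheel_motion[i, j]
    }
    disp[, j] <- tryCatch(solve(A, f), error = function(e) {
      abort(sprintf("coupled system singular at %.4f Hz", frequencies[j]),
            class = "seatvibe_numerical")
    })
  }
  disp
}

#' Segmental acceleration spectra of the coupled occupant-car system
#'
#' Drives the coupled model with harmonic wheel inputs and reports the
#' acceleration magnitude `omega^2 |Z_segment|` of the requested segments'
#' vertical dofs.
#'
#' @param human,car Submodels (defaults: packaged occupant, default car).
#' @param frequencies Analysis grid (Hz).
#' @param amplitude Wheel motion amplitude (m), default 0.025.
#' @param segments Segment ids to report (default 1:4 -- head, thorax,
#'   abdomen, pelvis).
#' @param phase_policy,speed Passed to [wheel_excitation()].
#' @return Tibble: `segment`, `name`, `frequency_hz`, `acceleration_ms2`.
#' @export
segmental_acceleration <- function(human = table1_model(),
                                   car = default_car(),
                                   frequencies = default_grid(df = 0.05),
                                   amplitude = 0.025, segments = 1:4,
                                   phase_policy = "in_phase", speed = NULL) {
  coupled <- assemble_coupled(human, car)
  wm <- wheel_excitation(frequencies, amplitude, phase_policy, speed)
  disp <- solve_coupled(coupled, frequencies, wm)
  seg <- human$segments
  purrr::map_dfr(segments, function(s) {
    p <- match(s, seg$id)
    if (is.na(p)) abort(sprintf("unknown segment id %s", s),
                        class = "seatvibe_validation")
    tibble::tibble(
      segment = s,
      name = seg$name[p],
      frequency_hz = frequencies,
      acceleration_ms2 = (2 * pi * frequencies)^2 * Mod(disp[2L * p, ])
    )
  })
}
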