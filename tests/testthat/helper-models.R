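# Small models built in code for the test suite.

single_mass_model <- function(m = 1, k = 1000, c = 5) {
  human_model(
    segments = tibble::tibble(id = 1L, name = "mass", mass_kg = m,
                              partner = NA_integer_),
    connections = tibble::tibble(
      index = 1L, end_a = "SEAT", end_b = 1L,
      k_xx = k, k_xz = 0, k_zx = 0, k_zz = k,
      c_xx = c, c_xz = 0, c_zx = 0, c_zz = c
    ),
    backrest_angle_deg = 24
  )
}

# seat -- k2 -- mass2 -- k1 -- mass1 chain (z-dominant couplings).
two_mass_chain <- function(m1 = 2, m2 = 3, k1 = 4000, k2 = 6000,
                           c1 = 10, c2 = 15) {
  human_model(
    segments = tibble::tibble(id = 1:2, name = c("top", "bottom"),
                              mass_kg = c(m1, m2), partner = NA_integer_),
    connections = tibble::tibble(
      index = 1:2, end_a = c("2", "SEAT"), end_b = c(1L, 2L),
      k_xx = c(k1, k2), k_xz = 0, k_zx = 0, k_zz = c(k1, k2),
      c_xx = c(c1, c2), c_xz = 0, c_zx = 0, c_zz = c(c1, c2)
    ),
    backrest_angle_deg = 24
  )
}

# Two-segment model with full cross-coupled 2x2 joints; the recovery
# study's ground truth.
two_segment_truth <- function() {
  human_model(
    segments = tibble::tibble(id = 1:2, name = c("upper", "lower"),
                              mass_kg = c(50, 27.3), partner = NA_integer_),
    connections = tibble::tibble(
      index = 1:2, end_a = c("SEAT", "1"), end_b = c(1L, 2L),
      k_xx = c(1.5e5, 1.7e5), k_xz = c(0.5e5, 0.6e5),
      k_zx = c(0.5e5, 0.6e5), k_zz = c(1.9e5, 2.2e5),
      c_xx = c(1.2e3, 1.3e3), c_xz = c(0.4e3, 0.5e3),
      c_zx = c(0.4e3, 0.5e3), c_zz = c(2.0e3, 1.9e3)
    ),
    backrest_angle_deg = 24
  )
}

# Ground truth for the curve-recovery study: a two-segment stack carried
# by the seat through a vertical-dominant load path (no cross coupling),
# matching the dominant-direction assumption of the full model.
recovery_truth_model <- function() {
  human_model(
    segments = tibble::tibble(id = 1:2, name = c("upper", "lower"),
                              mass_kg = c(50, 27.3), partner = NA_integer_),
    connections = tibble::tibble(
      index = 1:2, end_a = c("SEAT", "1"), end_b = c(1L, 2L),
      k_xx = c(1.5e5, 1.7e5), k_xz = 0, k_zx = 0, k_zz = c(1.9e5, 2.2e5),
      c_xx = c(1.2e3, 1.3e3), c_xz = 0, c_zx = 0, c_zz = c(2.0e3, 1.9e3)
    ),
    backrest_angle_deg = 24
  )
}

# Identification configuration for the recovery study: objective weights
# nondimensionalised by the target scales (magnitudes relative to their
# means, phases to 30 degrees) so all four error terms are commensurate,
# plus a memetic polish of several diverse swarm candidates.
recovery_config <- function(targets, seed = 7) {
  fa_config(
    swarm_size = 30, iterations = 120, walk_steps = 20,
    polish_iterations = 5000, polish_candidates = 4,
    hop_steps = 40, hop_sigma = 0.08,
    restarts = 2, restart_objective = 1e-3,
    sse_tolerance = 1e-8,
    weights = c(1 / mean(targets$sthts_mag)^2, 1 / 900,
                1 / mean(targets$am_mag_kg)^2, 1 / 900),
    seed = seed
  )
}

# Closed-form base-excitation displacement transmissibility of the
# single-mass toy: |Z/Z0| = |k + i w c| / |k - w^2 m + i w c|.
toy_transmissibility <- function(f_hz, m = 1, k = 1000, c = 5) {
  w <- 2 * pi * f_hz
  Mod((k + 1i * w * c) / (k - w^2 * m + 1i * w * c))
}

# Random small connected model (n_seg <= 4) for assembly property tests.
random_small_model <- function(n_seg = sample(2:4, 1)) {
  segs <- tibble::tibble(
    id = seq_len(n_seg),
    name = paste0("seg", seq_len(n_seg)),
    mass_kg = runif(n_seg, 0.5, 20),
    partner = NA_integer_
  )
  # chain to guarantee connectivity, plus a few random extras
  end_a <- c("SEAT", as.character(seq_len(n_seg - 1)))
  end_b <- seq_len(n_seg)
  n_extra <- sample(0:2, 1)
  if (n_extra > 0 && n_seg >= 2) {
    for (i in seq_len(n_extra)) {
      pair <- sample(n_seg, 2)
      end_a <- c(end_a, as.character(pair[1]))
      end_b <- c(end_b, pair[2])
    }
  }
  nc <- length(end_b)
  cross <- runif(nc, -500, 500)
  crossc <- runif(nc, -5, 5)
  cons <- tibble::tibble(
    index = seq_len(nc), end_a = end_a, end_b = as.integer(end_b),
    k_xx = runif(nc, 500, 5000), k_xz = cross, k_zx = cross,
    k_zz = runif(nc, 500, 5000),
    c_xx = runif(nc, 1, 20), c_xz = crossc, c_zx = crossc,
    c_zz = runif(nc, 1, 20)
  )
  human_model(segs, cons, backrest_angle_deg = 24)
}

# Brute-force re-assembly of K (or C) from per-connection contributions,
# independent of the package's assembly loop.
brute_force_matrix <- function(model, which = c("k", "c")) {
  which <- match.arg(which)
  seg <- model$segments
  con <- model$connections
  n <- nrow(seg)
  out <- matrix(0, 2 * n, 2 * n)
  cols <- paste0(which, c("_xx", "_xz", "_zx", "_zz"))
  for (r in seq_len(nrow(con))) {
    v <- unlist(con[r, cols])
    blk <- matrix(c(v[1], v[3], v[2], v[4]), 2, 2) # row-major xx,xz / zx,zz
    b <- match(con$end_b[r], seg$id)
    ib <- c(2 * b - 1, 2 * b)
    out[ib, ib] <- out[ib, ib] + blk
    if (!con$end_a[r] %in% c("SEAT", "BACKREST", "FLOOR")) {
      a <- match(as.integer(con$end_a[r]), seg$id)
      ia <- c(2 * a - 1, 2 * a)
      out[ia, ia] <- out[ia, ia] + blk
      out[ia, ib] <- out[ia, ib] - blk
      out[ib, ia] <- out[ib, ia] - blk
    }
  }
  out
}
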