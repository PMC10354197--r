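# Parameter-vector codec, feasibility projection and constraint checking.
#
# Layout (for a model with n_seg segments and n_con connections):
#   [1..n_seg]                      segment masses (kg)
#   [n_seg + (i-1)*4 + 1..4]        connection i stiffness: k_xx, k_xz, k_zx, k_zz
#   [n_seg + 4 n_con + ...]         connection i damping:  c_xx, c_xz, c_zx, c_zz
# For the full 16-segment, 26-connection model this is 16 + 104 + 104 = 224
# decision variables.

#' Encode a model into its parameter vector
#'
#' @param model A `human_model`.
#' @return Named numeric vector (`m1..`, `k_xx_1..`, `c_zz_26`) in the
#'   documented layout; `decode_params()` inverts it exactly.
#' @export
encode_params <- function(model) {
  seg <- model$segments
  con <- model$connections
  k <- as.matrix(con[, c("k_xx", "k_xz", "k_zx", "k_zz")])
  c_ <- as.matrix(con[, c("c_xx", "c_xz", "c_zx", "c_zz")])
  out <- c(seg$mass_kg, as.vector(t(k)), as.vector(t(c_)))
  names(out) <- c(
    paste0("m", seg$id),
    paste0(rep(c("k_xx_", "k_xz_", "k_zx_", "k_zz_"), nrow(con)),
           rep(con$index, each = 4)),
    paste0(rep(c("c_xx_", "c_xz_", "c_zx_", "c_zz_"), nrow(con)),
           rep(con$index, each = 4))
  )
  out
}

#' Decode a parameter vector into a model
#'
#' @param values Numeric vector in the layout of [encode_params()].
#' @param template A `human_model` supplying topology, names and backrest
#'   angle.
#' @param validate Validate the decoded model (default `FALSE`: the
#'   optimizer decodes candidate vectors that are checked elsewhere).
#' @return A `human_model`.
#' @export
decode_params <- function(values, template, validate = FALSE) {
  ns <- nrow(template$segments)
  nc <- nrow(template$connections)
  if (length(values) != ns + 8L * nc) {
    abort(sprintf("expected %d parameters, got %d", ns + 8L * nc,
                  length(values)), class = "seatvibe_validation")
  }
  seg <- template$segments
  seg$mass_kg <- as.numeric(values[seq_len(ns)])
  con <- template$connections
  k <- matrix(values[ns + seq_len(4L * nc)], ncol = 4, byrow = TRUE)
  c_ <- matrix(values[ns + 4L * nc + seq_len(4L * nc)], ncol = 4, byrow = TRUE)
  con[, c("k_xx", "k_xz", "k_zx", "k_zz")] <- as.data.frame(k)
  con[, c("c_xx", "c_xz", "c_zx", "c_zz")] <- as.data.frame(c_)
  human_model(seg, con, template$backrest_angle_deg, validate = validate)
}

#' Search-space bounds for the identification problem
#'
#' Direct stiffness and damping entries are bounded to (100, 300000) in
#' N/m and N s/m.  Cross-coupled entries share the same magnitude interval
#' but are sign-free.  `mass_range` bounds individual masses before the
#' total-mass rescaling of [project_feasible()].
#'
#' @param k_direct,c_direct Length-2 lower/upper bounds for direct entries.
#' @param cross_abs Magnitude cap for cross-coupled entries.
#' @param mass_range Length-2 bounds for a single segment mass (kg).
#' @return A list of class `svt_bounds`.
#' @export
default_bounds <- function(k_direct = c(100, 300000),
                           c_direct = c(100, 300000),
                           cross_abs = 300000,
                           mass_range = c(0.1, 60)) {
  for (b in list(k_direct, c_direct, mass_range)) {
    if (b[1] >= b[2]) abort("lower bound must be below upper bound",
                            class = "seatvibe_validation")
  }
  structure(list(k_direct = k_direct, c_direct = c_direct,
                 cross_abs = cross_abs, mass_range = mass_range),
            class = "svt_bounds")
}

#' Constraint set implied by a model
#'
#' @param model A `human_model` (symmetry pairs read from the `partner`
#'   column).
#' @param total_mass Total body mass the masses must sum to (kg); the
#'   identification default is 77.3.
#' @param cross_symmetry Enforce `k_xz == k_zx` and `c_xz == c_zx`.
#' @return A list of class `svt_constraints`.
#' @export
model_constraints <- function(model, total_mass = 77.3,
                              cross_symmetry = TRUE) {
  seg <- model$segments
  pairs <- list()
  seen <- integer()
  for (i in seq_len(nrow(seg))) {
    p <- seg$partner[i]
    if (!is.na(p) && !i %in% seen) {
      j <- match(p, seg$id)
      pairs <- c(pairs, list(c(i, j)))
      seen <- c(seen, i, j)
    }
  }
  structure(list(total_mass = total_mass, mass_pairs = pairs,
                 cross_symmetry = cross_symmetry),
            class = "svt_constraints")
}

param_blocks <- function(ns, nc) {
  list(
    mass = seq_len(ns),
    k = ns + seq_len(4L * nc),
    c = ns + 4L * nc + seq_len(4L * nc),
    k_direct = ns + as.vector(vapply(seq_len(nc) - 1L,
                                     function(i) 4L * i + c(1L, 4L), integer(2))),
    k_cross = ns + as.vector(vapply(seq_len(nc) - 1L,
                                    function(i) 4L * i + c(2L, 3L), integer(2))),
    c_direct = ns + 4L * nc + as.vector(vapply(seq_len(nc) - 1L,
                                               function(i) 4L * i + c(1L, 4L), integer(2))),
    c_cross = ns + 4L * nc + as.vector(vapply(seq_len(nc) - 1L,
                                              function(i) 4L * i + c(2L, 3L), integer(2)))
  )
}

#' Project a parameter vector onto the feasible set
#'
#' Applies, in order: clipping of masses into `mass_range`; averaging of
#' symmetric mass pairs; exact multiplicative rescaling of all masses so
#' they sum to `total_mass`; averaging of `xz`/`zx` cross entries (when
#' cross symmetry is active); clipping of direct entries into their bounds
#' and of cross entries into `[-cross_abs, cross_abs]`.  The projection is
#' idempotent.
#'
#' @param values Parameter vector (layout of [encode_params()]).
#' @param template A `human_model` giving the layout.
#' @param bounds An [default_bounds()] object.
#' @param constraints A [model_constraints()] object.
#' @return The projected vector (names preserved).
#' @export
project_feasible <- function(values, template, bounds = default_bounds(),
                             constraints = model_constraints(template)) {
  ns <- nrow(template$segments)
  nc <- nrow(template$connections)
  blk <- param_blocks(ns, nc)
  v <- values
  m <- pmin(pmax(v[blk$mass], bounds$mass_range[1]), bounds$mass_range[2])
  for (p in constraints$mass_pairs) m[p] <- mean(m[p])
  tot <- sum(m)
  if (tot <= 0) abort("non-positive total mass", class = "seatvibe_validation")
  if (abs(tot - constraints$total_mass) / constraints$total_mass > 1e-12) {
    m <- m * (constraints$total_mass / tot)
  }
  v[blk$mass] <- m
  if (isTRUE(constraints$cross_symmetry)) {
    for (b in list(blk$k_cross, blk$c_cross)) {
      x <- matrix(v[b], nrow = 2) # rows: xz, zx per connection
      mid <- colMeans(x)
      v[b] <- rep(mid, each = 2)
    }
  }
  v[blk$k_direct] <- pmin(pmax(v[blk$k_direct], bounds$k_direct[1]),
                          bounds$k_direct[2])
  v[blk$c_direct] <- pmin(pmax(v[blk$c_direct], bounds$c_direct[1]),
                          bounds$c_direct[2])
  v[blk$k_cross] <- pmin(pmax(v[blk$k_cross], -bounds$cross_abs),
                         bounds$cross_abs)
  v[blk$c_cross] <- pmin(pmax(v[blk$c_cross], -bounds$cross_abs),
                         bounds$cross_abs)
  v
}

#' Clause-by-clause constraint check
#'
#' Evaluates every identification constraint on a parameter vector: the
#' total-mass equality, the six left/right mass equalities, cross-term
#' symmetry for stiffness and damping, and the direct-entry bounds.
#'
#' @inheritParams project_feasible
#' @param tol Relative tolerance for the equality clauses.
#' @return Tibble with columns `clause` and `satisfied`.
#' @export
check_constraints <- function(values, template, bounds = default_bounds(),
                              constraints = model_constraints(template),
                              tol = 1e-6) {
  ns <- nrow(template$segments)
  nc <- nrow(template$connections)
  blk <- param_blocks(ns, nc)
  m <- values[blk$mass]
  rows <- list(tibble::tibble(
    clause = sprintf("sum(m) == %g kg", constraints$total_mass),
    satisfied = abs(sum(m) - constraints$total_mass) <=
      tol * constraints$total_mass
  ))
  for (p in constraints$mass_pairs) {
    rows <- c(rows, list(tibble::tibble(
      clause = sprintf("m%d == m%d", template$segments$id[p[1]],
                       template$segments$id[p[2]]),
      satisfied = abs(m[p[1]] - m[p[2]]) <= tol * max(abs(m[p]), 1e-12)
    )))
  }
  if (isTRUE(constraints$cross_symmetry)) {
    for (nmb in c("k", "c")) {
      b <- blk[[paste0(nmb, "_cross")]]
      x <- matrix(values[b], nrow = 2)
      rows <- c(rows, list(tibble::tibble(
        clause = paste0(nmb, "_xz == ", nmb, "_zx (all connections)"),
        satisfied = all(abs(x[1, ] - x[2, ]) <=
                          tol * pmax(abs(x[1, ]), abs(x[2, ]), 1e-12))
      )))
    }
  }
  rows <- c(rows, list(
    tibble::tibble(
      clause = sprintf("%g <= k_direct <= %g", bounds$k_direct[1],
                       bounds$k_direct[2]),
      satisfied = all(values[blk$k_direct] >= bounds$k_direct[1] &
                        values[blk$k_direct] <= bounds$k_direct[2])
    ),
    tibble::tibble(
      clause = sprintf("%g <= c_direct <= %g", bounds$c_direct[1],
                       bounds$c_direct[2]),
      satisfied = all(values[blk$c_direct] >= bounds$c_direct[1] &
                        values[blk$c_direct] <= bounds$c_direct[2])
    ),
    tibble::tibble(
      clause = "masses > 0",
      satisfied = all(m > 0)
    )
  ))
  dplyr::bind_rows(rows)
}
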