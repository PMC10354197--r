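# Constrained firefly identification of the biomechanical parameters.
#
# Standard firefly dynamics: brightness is the negated objective; at every
# iteration each firefly moves toward every brighter one by
# beta0 * exp(-gamma r^2) * (x_j - x_i) plus a decaying uniform random step.
# Distances and steps are taken in bound-normalised coordinates so a single
# gamma covers masses (kg) and stiffness (N/m) alike.  Every candidate is
# passed through the feasibility projection before evaluation, so any
# returned vector satisfies the constraint set exactly.

#' Firefly-algorithm configuration
#'
#' @param swarm_size Number of fireflies (>= 2; identification default 100).
#' @param iterations Iteration cap (identification default 50).
#' @param sse_tolerance Stop once the best objective falls to or below this
#'   value (default 1e-6).
#' @param weights Objective weights `alpha1..alpha4` (default all 1).
#' @param beta0 Attractiveness at zero distance.
#' @param gamma Light absorption in normalised coordinates.
#' @param step0 Initial random-step fraction of each parameter range.
#' @param step_decay Geometric decay of the random step per iteration.
#' @param walk_steps Number of elitist random-walk trials of the best
#'   firefly per iteration (0 disables).  The walk uses a Gaussian step
#'   whose scale adapts by a success rule (grown on improvement, shrunk
#'   otherwise), which is what lets the swarm refine a basin once found.
#' @param walk_sigma0 Initial random-walk scale as a fraction of each
#'   parameter range.
#' @param polish_iterations Iteration budget for an optional derivative-free
#'   Nelder-Mead polish run in bound-normalised coordinates on the
#'   projected objective (0 disables; useful when the swarm has located a
#'   basin whose valley is too ill-conditioned for the random walk to
#'   descend).
#' @param polish_candidates Number of distinct swarm candidates (best
#'   first, then the remaining fireflies most distant from those already
#'   chosen) given their own polish run; the overall best survives.
#' @param hop_steps Number of basin-hopping rounds after the polish: the
#'   best vector is kicked by a Gaussian perturbation of scale `hop_sigma`
#'   (in normalised coordinates) and re-polished, keeping the kicked
#'   result only when it improves (0 disables).
#' @param hop_sigma Kick scale for basin hopping.
#' @param restarts Additional full restarts of the swarm-plus-polish cycle
#'   (fresh draws from the same seeded stream) taken while the best
#'   objective still exceeds `restart_objective`; the best attempt wins.
#' @param restart_objective Objective level below which no restart is
#'   spent.
#' @param seed Integer seed; the same configuration and targets always
#'   reproduce the same best vector.
#' @return A list of class `fa_config`.
#' @export
fa_config <- function(swarm_size = 100, iterations = 50,
                      sse_tolerance = 1e-6, weights = rep(1, 4),
                      beta0 = 1, gamma = 1, step0 = 0.05,
                      step_decay = 0.95, walk_steps = 10,
                      walk_sigma0 = 0.02, polish_iterations = 0L,
                      polish_candidates = 1L, hop_steps = 0L,
                      hop_sigma = 0.08, restarts = 0L,
                      restart_objective = Inf, seed = 1L) {
  if (swarm_size < 2) abort("swarm_size must be >= 2",
                            class = "seatvibe_validation")
  if (any(weights < 0)) abort("weights must be >= 0",
                              class = "seatvibe_validation")
  structure(
    list(swarm_size = as.integer(swarm_size),
         iterations = as.integer(iterations),
         sse_tolerance = sse_tolerance, weights = weights, beta0 = beta0,
         gamma = gamma, step0 = step0, step_decay = step_decay,
         walk_steps = as.integer(walk_steps), walk_sigma0 = walk_sigma0,
         polish_iterations = as.integer(polish_iterations),
         polish_candidates = as.integer(polish_candidates),
         hop_steps = as.integer(hop_steps), hop_sigma = hop_sigma,
         restarts = as.integer(restarts),
         restart_objective = restart_objective,
         seed = as.integer(seed)),
    class = "fa_config"
  )
}

# Per-dimension normalisation ranges used for distances and random steps.
param_ranges <- function(template, bounds) {
  ns <- nrow(template$segments)
  nc <- nrow(template$connections)
  blk <- param_blocks(ns, nc)
  lo <- numeric(ns + 8L * nc)
  hi <- numeric(ns + 8L * nc)
  lo[blk$mass] <- bounds$mass_range[1]; hi[blk$mass] <- bounds$mass_range[2]
  lo[blk$k_direct] <- bounds$k_direct[1]; hi[blk$k_direct] <- bounds$k_direct[2]
  lo[blk$c_direct] <- bounds$c_direct[1]; hi[blk$c_direct] <- bounds$c_direct[2]
  lo[blk$k_cross] <- -bounds$cross_abs; hi[blk$k_cross] <- bounds$cross_abs
  lo[blk$c_cross] <- -bounds$cross_abs; hi[blk$c_cross] <- bounds$cross_abs
  if (any(hi <= lo)) abort("degenerate search space (zero-width bounds)",
                           class = "seatvibe_validation")
  list(lo = lo, hi = hi, width = hi - lo)
}

#' Identify model parameters with the firefly algorithm
#'
#' Minimises [fa_objective()] over the parameter space of `template`,
#' subject to the constraint set (total mass, left/right symmetry,
#' cross-term symmetry, direct-entry bounds) enforced by projection.
#'
#' @param targets Target curves ([make_targets()] / [read_targets()]).
#' @param template `human_model` defining topology, layout and backrest
#'   angle of the candidates.
#' @param config An [fa_config()].
#' @param bounds An [default_bounds()].
#' @param constraints A [model_constraints()].
#' @param sthts_mode,am_mode Curve definitions used in the objective.
#' @return An object of class `fa_fit`: `best_params`, `best_model`,
#'   `best_objective`, `history` (best objective per iteration,
#'   non-increasing), `gof` (goodness of fit of the recovered curves
#'   against the targets), plus the configuration.
#' @export
fa_optimize <- function(targets, template, config = fa_config(),
                        bounds = default_bounds(),
                        constraints = model_constraints(template),
                        sthts_mode = c("literal", "conventional"),
                        am_mode = c("pelvis", "seat")) {
  sthts_mode <- match.arg(sthts_mode)
  am_mode <- match.arg(am_mode)
  validate_targets(targets)
  rng <- param_ranges(template, bounds)
  d <- length(rng$lo)
  n <- config$swarm_size
  ctx <- objective_context(template, targets, sthts_mode, am_mode)
  obj <- function(v) objective_fast(v, ctx, config$weights)
  proj <- function(v) project_feasible(v, template, bounds, constraints)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  run_once <- function() {
  pop <- matrix(runif(n * d, rng$lo, rng$hi), nrow = n, byrow = TRUE)
  pop <- t(apply(pop, 1, proj))
  fit <- apply(pop, 1, obj)
  history <- numeric(0)
  step <- config$step0
  sigma <- config$walk_sigma0
  for (it in seq_len(config$iterations)) {
    ibest <- which.min(fit)
    best_prev <- pop[ibest, ]
    fit_prev <- fit[ibest]
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (fit[j] >= fit[i]) next # j must be strictly brighter
        u <- (pop[i, ] - rng$lo) / rng$width
        v <- (pop[j, ] - rng$lo) / rng$width
        r2 <- sum((u - v)^2)
        beta <- config$beta0 * exp(-config$gamma * r2)
        pop[i, ] <- pop[i, ] + beta * (pop[j, ] - pop[i, ]) +
          step * rng$width * (runif(d) - 0.5)
      }
    }
    # elitist re-insertion keeps the best-so-far monotone
    pop <- t(apply(pop, 1, proj))
    fit <- apply(pop, 1, obj)
    w <- which.max(fit)
    if (min(fit) > fit_prev) {
      pop[w, ] <- best_prev
      fit[w] <- fit_prev
    }
    # elitist random walk of the best firefly with success-adaptive scale
    if (config$walk_steps > 0) {
      ib <- which.min(fit)
      for (s in seq_len(config$walk_steps)) {
        cand <- proj(pop[ib, ] + sigma * rng$width * rnorm(d))
        fc <- obj(cand)
        if (fc < fit[ib]) {
          pop[ib, ] <- cand
          fit[ib] <- fc
          sigma <- min(sigma * 1.5, 0.25)
        } else {
          sigma <- max(sigma * 0.87, 1e-9)
        }
      }
    }
    history <- c(history, min(fit))
    step <- step * config$step_decay
    if (min(fit) <= config$sse_tolerance) break
  }
  ibest <- which.min(fit)
  best <- pop[ibest, ]
  best_fit <- fit[ibest]
  if (config$polish_iterations > 0 && is.finite(best_fit) &&
      best_fit > config$sse_tolerance) {
    # pick diverse starting candidates: the best firefly, then fireflies
    # farthest (in normalised coordinates) from those already selected
    norm_pop <- sweep(sweep(pop, 2, rng$lo), 2, rng$width, "/")
    chosen <- ibest
    while (length(chosen) < min(config$polish_candidates, n)) {
      dmin <- apply(norm_pop, 1, function(u) {
        min(vapply(chosen, function(ci) sum((u - norm_pop[ci, ])^2),
                   numeric(1)))
      })
      dmin[chosen] <- -Inf
      chosen <- c(chosen, which.max(dmin))
    }
    fn <- function(u) obj(proj(rng$lo + u * rng$width))
    for (ci in chosen) {
      nm <- stats::optim(
        norm_pop[ci, ], fn, method = "Nelder-Mead",
        control = list(maxit = config$polish_iterations, reltol = 1e-14)
      )
      cand <- proj(rng$lo + nm$par * rng$width)
      cand_fit <- obj(cand)
      if (cand_fit < best_fit) {
        best <- cand
        best_fit <- cand_fit
      }
      if (best_fit <= config$sse_tolerance) break
    }
    # basin hopping: kick the best vector and re-polish, keep improvements
    if (config$hop_steps > 0) {
      u_best <- (best - rng$lo) / rng$width
      for (hop in seq_len(config$hop_steps)) {
        if (best_fit <= config$sse_tolerance) break
        # cycle through half, unit and double kick scales so the search
        # escapes both shallow and wide basins
        sig <- config$hop_sigma * c(0.5, 1, 2)[1L + (hop - 1L) %% 3L]
        kick <- u_best + sig * rnorm(d)
        nm <- stats::optim(
          kick, fn, method = "Nelder-Mead",
          control = list(maxit = config$polish_iterations, reltol = 1e-13)
        )
        cand <- proj(rng$lo + nm$par * rng$width)
        cand_fit <- obj(cand)
        if (cand_fit < best_fit) {
          best <- cand
          best_fit <- cand_fit
          u_best <- (best - rng$lo) / rng$width
        }
      }
    }
  }
  list(best = best, best_fit = best_fit, history = history)
  }

  res <- run_once()
  best <- res$best
  best_fit <- res$best_fit
  history <- res$history
  attempt <- 0L
  while (attempt < config$restarts && best_fit > config$restart_objective) {
    attempt <- attempt + 1L
    res <- run_once()
    # history stays the across-attempt best so it remains non-increasing
    history <- c(history, pmin(cummin(res$history), min(history)))
    if (res$best_fit < best_fit) {
      best <- res$best
      best_fit <- res$best_fit
    }
  }
  best <- setNames(best, names(encode_params(template)))
  best_model <- decode_params(best, template, validate = FALSE)
  cur <- tryCatch(
    analytic_curves(best_model, targets$frequency_hz, sthts_mode, am_mode),
    error = function(e) NULL
  )
  gof <- if (is.null(cur)) {
    rep(NA_real_, 4)
  } else {
    c(
      sthts_mag = goodness_of_fit(targets$sthts_mag, cur$sthts$magnitude),
      sthts_phase = goodness_of_fit(targets$sthts_phase_deg,
                                    cur$sthts$phase_deg),
      am_mag = goodness_of_fit(targets$am_mag_kg, cur$am$magnitude),
      am_phase = goodness_of_fit(targets$am_phase_deg, cur$am$phase_deg)
    )
  }
  structure(
    list(
      best_params = best,
      best_model = best_model,
      best_objective = best_fit,
      history = tibble::tibble(
        iteration = seq_along(history),
        best_objective = history
      ),
      gof = gof,
      config = config,
      bounds = bounds,
      constraints = constraints,
      sthts_mode = sthts_mode,
      am_mode = am_mode,
      targets = targets
    ),
    class = "fa_fit"
  )
}

#' @export
print.fa_fit <- function(x, ...) {
  cat(sprintf(
    "<fa_fit> best objective %.6g after %d iteration(s); GOF (STHT mag) %.4f\n",
    x$best_objective, nrow(x$history), x$gof[["sthts_mag"]]
  ))
  invisible(x)
}

#' Tidy the identified parameter vector
#'
#' @param x An `fa_fit`.
#' @param ... Unused.
#' @return Tibble with columns `parameter`, `value`.
#' @method tidy fa_fit
#' @export
tidy.fa_fit <- function(x, ...) {
  tibble::tibble(parameter = names(x$best_params),
                 value = unname(x$best_params))
}

#' One-row fit summary
#'
#' @param x An `fa_fit`.
#' @param ... Unused.
#' @return Tibble with the final objective, iteration count, convergence
#'   flag and the four per-curve goodness-of-fit values.
#' @method glance fa_fit
#' @export
glance.fa_fit <- function(x, ...) {
  tibble::tibble(
    best_objective = x$best_objective,
    iterations_run = nrow(x$history),
    converged = x$best_objective <= x$config$sse_tolerance,
    gof_sthts_mag = x$gof[["sthts_mag"]],
    gof_sthts_phase = x$gof[["sthts_phase"]],
    gof_am_mag = x$gof[["am_mag"]],
    gof_am_phase = x$gof[["am_phase"]]
  )
}

#' @method autoplot fa_fit
#' @export
autoplot.fa_fit <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(.data$iteration, .data$best_objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Iteration", y = "Best objective (log scale)") +
    ggplot2::theme_minimal()
}
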