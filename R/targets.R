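# Synthetic target curves: forward-solve a source model on a sparse
# frequency grid and optionally corrupt it with noise, emulating the kind
# of averaged laboratory transmissibility/apparent-mass data (vertical
# random excitation, 1 m/s^2 r.m.s., 0.5-15 Hz) that the identification
# step normally consumes.

#' Generate synthetic target curves from a source model
#'
#' Samples the model's STHT and apparent-mass magnitude/phase at `n_points`
#' frequencies.  Magnitudes receive multiplicative Gaussian noise
#' (`mag * (1 + N(0, noise_mag))`), phases additive Gaussian noise in
#' degrees; `noise_mag = noise_phase_deg = 0` reproduces the model curves
#' exactly.
#'
#' @param model Source `human_model` (default [table1_model()]).
#' @param n_points Number of frequency points `p >= 2` (default 30).
#' @param fmin,fmax Sampling band in Hz (default 0.5-15, the band used for
#'   identification).
#' @param noise_mag Relative magnitude noise s.d. (>= 0).
#' @param noise_phase_deg Additive phase noise s.d. in degrees (>= 0).
#' @param seed Optional integer seed for reproducible noise.
#' @param sthts_mode,am_mode Curve definitions, as in [fa_objective()].
#' @return A tibble of class `target_curves` with columns `frequency_hz`,
#'   `sthts_mag`, `sthts_phase_deg`, `am_mag_kg`, `am_phase_deg` and a
#'   `source` attribute (`"synthetic"`).
#' @export
make_targets <- function(model = table1_model(), n_points = 30,
                         fmin = 0.5, fmax = 15,
                         noise_mag = 0, noise_phase_deg = 0, seed = NULL,
                         sthts_mode = c("literal", "conventional"),
                         am_mode = c("pelvis", "seat")) {
  sthts_mode <- match.arg(sthts_mode)
  am_mode <- match.arg(am_mode)
  if (n_points < 2) abort("need at least 2 frequency points",
                          class = "seatvibe_validation")
  if (noise_mag < 0 || noise_phase_deg < 0) {
    abort("noise levels must be >= 0", class = "seatvibe_validation")
  }
  freqs <- seq(fmin, fmax, length.out = n_points)
  cur <- analytic_curves(model, freqs, sthts_mode, am_mode)
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, globalenv())
    })
    set.seed(seed)
  }
  jitter_mag <- function(x) x * (1 + rnorm(length(x), 0, noise_mag))
  jitter_ph <- function(x) x + rnorm(length(x), 0, noise_phase_deg)
  out <- tibble::tibble(
    frequency_hz = freqs,
    sthts_mag = if (noise_mag > 0) jitter_mag(cur$sthts$magnitude) else
      cur$sthts$magnitude,
    sthts_phase_deg = if (noise_phase_deg > 0) {
      jitter_ph(cur$sthts$phase_deg)
    } else {
      cur$sthts$phase_deg
    },
    am_mag_kg = if (noise_mag > 0) jitter_mag(cur$am$magnitude) else
      cur$am$magnitude,
    am_phase_deg = if (noise_phase_deg > 0) {
      jitter_ph(cur$am$phase_deg)
    } else {
      cur$am$phase_deg
    }
  )
  attr(out, "source") <- "synthetic"
  class(out) <- c("target_curves", class(out))
  out
}

validate_targets <- function(targets) {
  need <- c("frequency_hz", "sthts_mag", "sthts_phase_deg", "am_mag_kg",
            "am_phase_deg")
  missing <- setdiff(need, names(targets))
  if (length(missing)) {
    abort(paste("target curves missing columns:", toString(missing)),
          class = "seatvibe_validation")
  }
  if (nrow(targets) < 2) {
    abort("target curves need at least 2 points", class = "seatvibe_validation")
  }
  invisible(targets)
}
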