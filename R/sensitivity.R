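# One-factor-at-a-time sensitivity of the seat-to-head transmissibility
# peak: each parameter is perturbed by +/- delta (others held fixed), the
# forward model re-solved, and the relative change of the STHT peak value
# recorded, together with the peak-frequency shift as auxiliary output.

#' Enumerate parameter identifiers of a model
#'
#' Identifiers follow the layout naming: `m4` (mass of segment 4),
#' `k_zz_11` (direct vertical stiffness of connection 11), `c_xz_4`
#' (cross-coupled damping of connection 4).
#'
#' @param model A `human_model`.
#' @param types Subset of `c("mass", "stiffness", "damping")`.
#' @param elements Coupling entries to include for stiffness/damping.
#' @return Character vector of parameter ids.
#' @export
parameter_ids <- function(model, types = c("mass", "stiffness", "damping"),
                          elements = c("xx", "xz", "zx", "zz")) {
  types <- match.arg(types, several.ok = TRUE)
  ids <- character()
  if ("mass" %in% types) ids <- c(ids, paste0("m", model$segments$id))
  for (tp in intersect(types, c("stiffness", "damping"))) {
    pre <- if (tp == "stiffness") "k_" else "c_"
    for (el in elements) {
      ids <- c(ids, paste0(pre, el, "_", model$connections$index))
    }
  }
  ids
}

# Positions in the parameter vector touched by one id, optionally widened
# to the symmetric partner (mirror segment / mirror connection, and the
# zx twin of an xz entry when cross symmetry is active).
id_positions <- function(id, model, joint_symmetry = TRUE) {
  nm <- names(encode_params(model))
  grab <- function(x) match(x, nm)
  if (grepl("^m\\d+$", id)) {
    s <- as.integer(sub("^m", "", id))
    pos <- grab(id)
    if (joint_symmetry) {
      p <- model$segments$partner[match(s, model$segments$id)]
      if (!is.na(p)) pos <- c(pos, grab(paste0("m", p)))
    }
    return(pos)
  }
  m <- regmatches(id, regexec("^([kc])_(xx|xz|zx|zz)_(\\d+)$", id))[[1]]
  if (!length(m)) abort(sprintf("unknown parameter id '%s'", id),
                        class = "seatvibe_validation")
  kind <- m[2]; el <- m[3]; cx <- as.integer(m[4])
  els <- el
  if (joint_symmetry && el %in% c("xz", "zx")) els <- c("xz", "zx")
  cons <- cx
  if (joint_symmetry) {
    p <- model$connections$partner[match(cx, model$connections$index)]
    if (!is.na(p)) cons <- c(cons, p)
  }
  pos <- unlist(lapply(cons, function(ci) {
    vapply(els, function(e) grab(paste0(kind, "_", e, "_", ci)), integer(1))
  }))
  unique(pos)
}

#' One-factor-at-a-time sensitivity of the STHT peak
#'
#' For every requested parameter and both signs, the parameter (and, when
#' `joint_symmetry` is on, its sagittal-plane mirror and cross-term twin)
#' is scaled by `1 +/- delta`, the response re-solved, and
#' `Delta = (peak_perturbed - peak_baseline) / peak_baseline` reported.
#' Perturbations that drive a mass or direct entry non-positive are flagged
#' invalid instead of evaluated.
#'
#' @param model Baseline `human_model` (typically [table1_model()]).
#' @param parameters Character vector of ids ([parameter_ids()]); default
#'   all masses, stiffness and damping entries.
#' @param delta Perturbation fraction (default 0.20).
#' @param frequencies Analysis grid; a 0.05 Hz step is enough here because
#'   the peak is refined quadratically.
#' @param sthts_mode STHT definition used for the peak (default the
#'   backrest-projected literal form, consistent with the identification
#'   pipeline).
#' @param joint_symmetry Perturb symmetric partners jointly.
#' @return Tibble of class `oat_sensitivity`: `parameter`, `direction`,
#'   `delta`, `peak_magnitude`, `peak_change` (fraction),
#'   `peak_change_pct`, `peak_frequency_hz`, `peak_freq_shift_hz`, `valid`;
#'   baseline peak stored in attributes.
#' @export
oat_sensitivity <- function(model, parameters = parameter_ids(model),
                            delta = 0.20,
                            frequencies = default_grid(df = 0.05),
                            sthts_mode = c("literal", "conventional"),
                            joint_symmetry = TRUE) {
  sthts_mode <- match.arg(sthts_mode)
  if (delta < 0) abort("delta must be >= 0", class = "seatvibe_validation")
  projection <- identical(sthts_mode, "literal")
  peak_of <- function(m) {
    find_peak(compute_sthts(solve_response(m, frequencies),
                            projection = projection))
  }
  base_vec <- encode_params(model)
  base_peak <- peak_of(model)
  rows <- vector("list", 2L * length(parameters))
  k <- 0L
  for (id in parameters) {
    pos <- id_positions(id, model, joint_symmetry)
    for (sgn in c("+", "-")) {
      k <- k + 1L
      fac <- if (sgn == "+") 1 + delta else 1 - delta
      v <- base_vec
      v[pos] <- v[pos] * fac
      direct_like <- grepl("^m\\d+$|_(xx|zz)_", id)
      if (direct_like && any(v[pos] <= 0)) {
        rows[[k]] <- tibble::tibble(
          parameter = id, direction = sgn, delta = delta,
          peak_magnitude = NA_real_, peak_change = NA_real_,
          peak_change_pct = NA_real_, peak_frequency_hz = NA_real_,
          peak_freq_shift_hz = NA_real_, valid = FALSE
        )
        next
      }
      pk <- if (delta == 0) {
        base_peak # bit-identical baseline reproduction
      } else {
        peak_of(decode_params(v, model))
      }
      ch <- (pk$peak_magnitude - base_peak$peak_magnitude) /
        base_peak$peak_magnitude
      rows[[k]] <- tibble::tibble(
        parameter = id, direction = sgn, delta = delta,
        peak_magnitude = pk$peak_magnitude,
        peak_change = ch, peak_change_pct = 100 * ch,
        peak_frequency_hz = pk$peak_frequency_hz,
        peak_freq_shift_hz = pk$peak_frequency_hz - base_peak$peak_frequency_hz,
        valid = TRUE
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "baseline_peak") <- base_peak
  attr(out, "sthts_mode") <- sthts_mode
  class(out) <- c("oat_sensitivity", class(out))
  out
}

#' @method autoplot oat_sensitivity
#' @export
autoplot.oat_sensitivity <- function(object, top = 20, ...) {
  dat <- object |>
    dplyr::filter(.data$valid) |>
    dplyr::mutate(rank_key = abs(.data$peak_change_pct))
  keep <- dat |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(m = max(.data$rank_key), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$m)) |>
    head(top)
  dat <- dplyr::semi_join(dat, keep, by = "parameter")
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$parameter, .data$rank_key),
    y = .data$peak_change_pct, fill = .data$direction
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "STHT peak change (%)", fill = "Perturbation") +
    ggplot2::theme_minimal()
}
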