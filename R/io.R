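# Configuration and data-file round-trips: YAML model files, CSV response
# curves, CSV target curves, CSV comfort-limit tables, and the JSON run
# manifest emitted by the command-line interface.  All files are UTF-8
# with dot decimal separators; angles in degrees, frequencies in Hz,
# SI units throughout.

#' Write / read a seated-occupant model as YAML
#'
#' The schema mirrors the in-memory structure: `backrest_angle_deg`, a
#' `segments` list (`id`, `name`, `mass_kg`, `partner`) and a
#' `connections` list (`index`, `end_a`, `end_b`, `joint`, `partner`,
#' nested `k:` and `c:` maps with `xx`, `xz`, `zx`, `zz` entries).
#' Numbers are serialised with 15 significant digits so a write/read
#' round trip reproduces the model exactly.
#'
#' @param model A `human_model`.
#' @param path File path.
#' @return `write_model`: the path, invisibly.  `load_model`: a validated
#'   `human_model`; schema violations are aggregated into a single error.
#' @export
write_model <- function(model, path) {
  seg <- purrr::pmap(model$segments, function(id, name, mass_kg, partner) {
    list(id = id, name = name, mass_kg = mass_kg,
         partner = if (is.na(partner)) NULL else partner)
  })
  con <- purrr::pmap(
    model$connections,
    function(index, end_a, end_b, joint, partner,
             k_xx, k_xz, k_zx, k_zz, c_xx, c_xz, c_zx, c_zz, ...) {
      list(
        index = index, end_a = end_a, end_b = end_b,
        joint = if (is.na(joint)) NULL else joint,
        partner = if (is.na(partner)) NULL else partner,
        k = list(xx = k_xx, xz = k_xz, zx = k_zx, zz = k_zz),
        c = list(xx = c_xx, xz = c_xz, zx = c_zx, zz = c_zz)
      )
    }
  )
  yaml::write_yaml(
    list(backrest_angle_deg = model$backrest_angle_deg,
         segments = seg, connections = con),
    path,
    precision = 15L
  )
  invisible(path)
}

#' @rdname write_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("model file not found: %s", path),
          class = "seatvibe_validation")
  }
  raw <- yaml::read_yaml(path)
  problems <- character()
  need <- function(x, field, where) {
    if (is.null(x[[field]])) {
      problems <<- c(problems, sprintf("%s: missing '%s'", where, field))
      NA
    } else {
      x[[field]]
    }
  }
  seg <- purrr::map_dfr(raw$segments, function(s) {
    tibble::tibble(
      id = as.integer(need(s, "id", "segment")),
      name = as.character(need(s, "name", "segment")),
      mass_kg = as.numeric(need(s, "mass_kg", "segment")),
      partner = if (is.null(s$partner)) NA_integer_ else as.integer(s$partner)
    )
  })
  con <- purrr::map_dfr(raw$connections, function(cn) {
    where <- sprintf("connection %s", cn$index %||% "?")
    k <- cn$k
    c_ <- cn$c
    if (is.null(k)) problems <<- c(problems, paste(where, ": missing 'k'"))
    if (is.null(c_)) problems <<- c(problems, paste(where, ": missing 'c'"))
    entry <- function(m, e) {
      if (is.null(m[[e]])) {
        problems <<- c(problems, sprintf("%s: missing %s entry", where, e))
        NA_real_
      } else {
        as.numeric(m[[e]])
      }
    }
    tibble::tibble(
      index = as.integer(need(cn, "index", where)),
      end_a = as.character(need(cn, "end_a", where)),
      end_b = as.integer(need(cn, "end_b", where)),
      joint = if (is.null(cn$joint)) NA_character_ else as.character(cn$joint),
      partner = if (is.null(cn$partner)) NA_integer_ else
        as.integer(cn$partner),
      k_xx = entry(k, "xx"), k_xz = entry(k, "xz"),
      k_zx = entry(k, "zx"), k_zz = entry(k, "zz"),
      c_xx = entry(c_, "xx"), c_xz = entry(c_, "xz"),
      c_zx = entry(c_, "zx"), c_zz = entry(c_, "zz")
    )
  })
  if (length(problems)) {
    abort(paste0("invalid model file:\n  ",
                 paste(problems, collapse = "\n  ")),
          class = "seatvibe_validation")
  }
  human_model(seg, con,
              backrest_angle_deg = raw$backrest_angle_deg %||% 24)
}

#' Write / read response curves as CSV
#'
#' Columns: `frequency_hz`, `magnitude`, `phase_deg`, `quantity`
#' (`STHT`/`AM`/`TR`), `segment`.  Round trips are lossless to full double
#' precision.
#'
#' @param curves A `response_curve` tibble (or several row-bound together).
#' @param path File path.
#' @export
write_curves <- function(curves, path) {
  if (!nrow(curves)) abort("refusing to write an empty curve",
                           class = "seatvibe_validation")
  readr::write_csv(curves, path)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         locale = readr::locale(decimal_mark = "."))
  if (!nrow(out)) abort("empty curve file", class = "seatvibe_validation")
  class(out) <- c("response_curve", class(out))
  out
}

#' Write / read identification target curves as CSV
#'
#' Columns: `frequency_hz`, `sthts_mag`, `sthts_phase_deg`, `am_mag_kg`,
#' `am_phase_deg`.
#'
#' @param targets A `target_curves` tibble.
#' @param path File path.
#' @export
write_targets <- function(targets, path) {
  validate_targets(targets)
  readr::write_csv(targets, path)
  invisible(path)
}

#' @rdname write_targets
#' @export
read_targets <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         locale = readr::locale(decimal_mark = "."))
  validate_targets(out)
  class(out) <- c("target_curves", class(out))
  out
}

#' Read a comfort-limit table
#'
#' @param path CSV with columns `frequency_hz`, `limit_ms2`, `duration_h`.
#' @return Validated limit tibble.
#' @export
read_comfort_limits <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  validate_comfort_limits(out)
  out
}

#' Run manifest
#'
#' Every command-line run emits one JSON manifest recording the command,
#' the MD5 hash of each input file, the seed, a timestamp and the package
#' version, so identical manifests imply identical outputs.
#'
#' @param command Command name.
#' @param inputs Named character vector of input file paths.
#' @param seed Integer seed used (or `NA`).
#' @param path Output path; default `NULL` returns the manifest invisibly
#'   without writing.
#' @return The manifest list, invisibly.
#' @export
run_manifest <- function(command, inputs = character(), seed = NA,
                         path = NULL) {
  hashes <- if (length(inputs)) {
    as.list(tools::md5sum(unlist(inputs)))
  } else {
    list()
  }
  manifest <- list(
    command = command,
    input_md5 = hashes,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("seatvibe"))
  )
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(manifest)
}
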