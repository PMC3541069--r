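#' Write / read a recording as CSV with a JSON metadata sidecar
#'
#' The CSV has columns `time_s`, `cuff_pressure_mmHg` and
#' `oscillation_mmHg` (empty where the filter leaves the signal undefined);
#' scenario metadata goes to a JSON sidecar (default `<path>.json`).
#'
#' @param rec A `bp_recording`.
#' @param path CSV file path.
#' @param meta_path JSON sidecar path, or `NULL` to skip.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, meta_path = paste0(path, ".json")) {
  stopifnot(inherits(rec, "bp_recording"))
  df <- data.frame(
    time_s = rec$t,
    cuff_pressure_mmHg = rec$P,
    oscillation_mmHg = if (is.null(rec$osc)) NA_real_ else rec$osc
  )
  utils::write.csv(df, path, row.names = FALSE, na = "")
  if (!is.null(meta_path)) {
    meta <- c(rec$meta, list(sample_rate = rec$sample_rate))
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_recording
#' @param path CSV file path to read.
#' @return For `read_recording`, a `bp_recording`.
#' @export
read_recording <- function(path, meta_path = paste0(path, ".json")) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "cuff_pressure_mmHg") %in% names(df)))
  meta <- if (!is.null(meta_path) && file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list()
  }
  sr <- meta$sample_rate
  if (is.null(sr)) sr <- 1 / stats::median(diff(df$time_s))
  meta$sample_rate <- NULL
  osc <- if ("oscillation_mmHg" %in% names(df) &&
             any(is.finite(df$oscillation_mmHg))) {
    df$oscillation_mmHg
  } else {
    NULL
  }
  structure(
    list(t = df$time_s, P = df$cuff_pressure_mmHg, osc = osc,
         sample_rate = sr, meta = meta),
    class = "bp_recording"
  )
}

#' Write / read an envelope as CSV
#'
#' Columns `beat_index`, `cuff_pressure_mmHg`, `amplitude_mmHg`.
#'
#' @param env A `bp_envelope`.
#' @param path CSV file path.
#' @return `path` invisibly; for `read_envelope`, a `bp_envelope`.
#' @export
write_envelope <- function(env, path) {
  stopifnot(inherits(env, "bp_envelope"))
  df <- data.frame(
    beat_index = env$beats$beat,
    cuff_pressure_mmHg = env$beats$P_beat,
    amplitude_mmHg = env$beats$amp
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_envelope
#' @export
read_envelope <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("beat_index", "cuff_pressure_mmHg", "amplitude_mmHg")
                %in% names(df)))
  beats <- data.frame(beat = df$beat_index,
                      P_beat = df$cuff_pressure_mmHg,
                      amp = df$amplitude_mmHg)
  i_max <- which.max(beats$amp)
  structure(
    list(beats = beats, peak_amp = beats$amp[i_max],
         P_max = beats$P_beat[i_max]),
    class = "bp_envelope"
  )
}

#' Read a scenario configuration from YAML or JSON
#'
#' Recognised keys (all optional, with standard-normal defaults): `name`,
#' `SBP`, `DBP`, `f_bpm` (or `f_hz`), `a`, `b` (direct stiffness override)
#' or `Pc`, `Cn`, `Pmid` (to derive them), `Va0`, `V0`, `P0`, `r`,
#' `noise_sd`, `seed`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [scenario()].
#' @export
read_scenario <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  get <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else default
  f_bpm <- if (!is.null(cfg$f_hz)) 60 * cfg$f_hz else get("f_bpm", 80)
  a <- cfg$a
  b <- cfg$b
  Va0 <- get("Va0", 0.3)
  if (is.null(a)) a <- derive_a(get("Pc", -20))
  if (is.null(b)) b <- derive_b(get("Cn", 0.0016), a, Va0, get("Pmid", 100))
  scenario(
    name = get("name", tools::file_path_sans_ext(basename(path))),
    SBP = get("SBP", 120), DBP = get("DBP", 80), f_bpm = f_bpm,
    a = a, b = b, Va0 = Va0,
    V0 = get("V0", 300), P0 = get("P0", 150), r = get("r", 3),
    noise_sd = get("noise_sd", 0), seed = cfg$seed
  )
}

#' Write / read a validation report as JSON
#'
#' @param report A `bp_validation` from [run_validation()].
#' @param path JSON file path.
#' @return `path` invisibly; for `read_report`, a `bp_validation`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "bp_validation"))
  jsonlite::write_json(
    list(results = report$results, summary = report$summary),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$results <- as.data.frame(x$results)
  if (is.null(x$results$error)) x$results$error <- NA_character_
  structure(list(results = x$results, summary = x$summary),
            class = "bp_validation")
}

#' Write the validation results as a flat CSV
#'
#' One row per scenario and parameter (`a`, `b`, `SBP`, `DBP`) with actual
#' and algorithm values, mirroring the layout of a validation table.
#'
#' @param report A `bp_validation`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  stopifnot(inherits(report, "bp_validation"))
  r <- report$results
  long <- do.call(rbind, lapply(seq_len(nrow(r)), function(i) {
    data.frame(
      scenario = r$scenario[i],
      parameter = c("a", "b", "SBP", "DBP"),
      actual = c(r$true_a[i], r$true_b[i], r$true_SBP[i], r$true_DBP[i]),
      algorithm = c(r$a_hat[i], r$b_hat[i], r$SBP_hat[i], r$DBP_hat[i])
    )
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
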