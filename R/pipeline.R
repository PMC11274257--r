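spectrum_cols <- c("frequency_hz", "z_real_ohm", "z_imag_ohm")

#' Read an impedance spectrum from CSV
#'
#' The on-disk dialect is deliberately plain: a comma-separated file with a
#' header row naming the columns `frequency_hz`, `z_real_ohm`,
#' `z_imag_ohm` (case-insensitive, any order), `#`-prefixed comment lines,
#' and `.` as the decimal separator regardless of locale. Rows are sorted
#' by ascending frequency on read; duplicate frequencies are rejected.
#' Malformed files fail with an error naming the offending line.
#'
#' @param path Path to a CSV file.
#' @return A spectrum tibble (see [eis_spectrum()]); a `# label:` comment in
#'   the file becomes the spectrum label.
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  lines <- readr::read_lines(path)
  label <- ""
  lab_line <- grep("^#\\s*label:", lines, value = TRUE)
  if (length(lab_line) > 0) {
    label <- trimws(sub("^#\\s*label:\\s*", "", lab_line[1]))
  }
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  rows <- lines[keep]
  if (length(rows) < 1) rlang::abort(paste0(path, ": no header row found"))

  split_csv <- function(x) trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  header <- tolower(split_csv(rows[1]))
  idx <- match(spectrum_cols, header)
  if (anyNA(idx)) {
    rlang::abort(paste0(
      path, " line ", line_no[1], ": missing column(s) ",
      paste(spectrum_cols[is.na(idx)], collapse = ", ")
    ))
  }
  if (length(rows) < 3) {
    rlang::abort(paste0(path, ": need at least 2 data rows, found ",
                        length(rows) - 1))
  }
  parse_row <- function(i) {
    fields <- split_csv(rows[i])
    if (length(fields) < length(header)) {
      rlang::abort(paste0(path, " line ", line_no[i], ": expected ",
                          length(header), " fields, found ", length(fields)))
    }
    vals <- suppressWarnings(as.numeric(fields[idx]))
    if (anyNA(vals)) {
      bad <- spectrum_cols[is.na(vals)][1]
      rlang::abort(paste0(path, " line ", line_no[i],
                          ": non-numeric value in column ", bad))
    }
    vals
  }
  m <- t(vapply(2:length(rows), parse_row, numeric(3)))
  tryCatch(
    eis_spectrum(m[, 1], m[, 2], m[, 3], label = label),
    error = function(e) {
      rlang::abort(paste0(path, ": ", conditionMessage(e)))
    }
  )
}

#' Write an impedance spectrum to CSV
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces every double exactly. A `# label:` provenance comment is
#' emitted when the spectrum has a label, and a `# seed:` comment when
#' `seed` is supplied.
#'
#' @param spectrum A spectrum data frame.
#' @param path Output path.
#' @param seed Optional generator seed recorded as provenance.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path, seed = NULL) {
  s <- as_eis_spectrum(spectrum)
  header <- character(0)
  if (nzchar(spectrum_label(s))) {
    header <- c(header, paste0("# label: ", spectrum_label(s)))
  }
  if (!is.null(seed)) header <- c(header, paste0("# seed: ", seed))
  body <- sprintf("%.17g,%.17g,%.17g",
                  s$frequency_hz, s$z_real_ohm, s$z_imag_ohm)
  out <- c(header, paste(spectrum_cols, collapse = ","), body)
  tryCatch(
    readr::write_lines(out, path),
    error = function(e) {
      rlang::abort(paste0("cannot write spectrum to ", path, ": ",
                          conditionMessage(e)))
    }
  )
  invisible(path)
}

#' Tidy plotting tables for Nyquist and Bode views
#'
#' Returns long-format tables ready for any plotting frontend: the data
#' points plus, when Randles parameters are supplied, the model curve
#' evaluated on a 10-times-denser log grid.
#'
#' @param spectrum A spectrum data frame.
#' @param params Optional [randles_params()] row for the model overlay.
#' @return A list of tibbles: `nyquist` (`source`, `frequency_hz`,
#'   `z_real_ohm`, `neg_z_imag_ohm`) and `bode` (`source`, `frequency_hz`,
#'   `magnitude_ohm`, `phase_deg`).
#' @export
export_plots_data <- function(spectrum, params = NULL) {
  s <- as_eis_spectrum(spectrum)
  as_tables <- function(df, source) {
    polar <- to_polar(spectrum_z(df))
    list(
      nyquist = tibble::tibble(
        source = source,
        frequency_hz = df$frequency_hz,
        z_real_ohm = df$z_real_ohm,
        neg_z_imag_ohm = -df$z_imag_ohm
      ),
      bode = tibble::tibble(
        source = source,
        frequency_hz = df$frequency_hz,
        magnitude_ohm = polar$magnitude_ohm,
        phase_deg = polar$phase_rad * 180 / pi
      )
    )
  }
  out <- as_tables(s, "data")
  if (!is.null(params)) {
    ppd <- 10 * (nrow(s) - 1) /
      max(log10(max(s$frequency_hz) / min(s$frequency_hz)), 1e-9)
    dense <- frequency_grid(min(s$frequency_hz), max(s$frequency_hz),
                            points_per_decade = ppd)
    model <- as_tables(evaluate_spectrum(params, dense), "model")
    out$nyquist <- dplyr::bind_rows(out$nyquist, model$nyquist)
    out$bode <- dplyr::bind_rows(out$bode, model$bode)
  }
  out
}

#' Pipeline configuration
#'
#' Bundles every switch of the end-to-end workflow. The fitting window is
#' required — published descriptions of comparable experiments disagree on
#' the measured range, so the pipeline never guesses one.
#'
#' @param frequency_window Length-2 numeric, `(f_min, f_max)` in Hz with
#'   `0 < f_min < f_max`: the window the fit uses.
#' @param geometry A [cell_geometry()] row.
#' @param resistance_source `"rp"` (default) or `"ru"`: which fitted
#'   resistance enters the conductivity formula (see
#'   [conductivity_from_resistance()]).
#' @param weighting Fit weighting, see [fit_randles()].
#' @param medium_sigma,medium_eps DC conductivity (S/m) and static relative
#'   permittivity of the suspending medium used for the DEP prediction.
#'   Defaults are deionized water: 5.5e-6 S/m, eps_r 78.4.
#' @param volume_fraction Optional particle volume fraction for
#'   Maxwell-Wagner inversion paths; `NULL` when unknown.
#' @param relative_sd,seed Noise level and seed used by simulation
#'   commands.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(frequency_window,
                            geometry = cell_geometry(),
                            resistance_source = c("rp", "ru"),
                            weighting = c("modulus", "unit", "proportional"),
                            medium_sigma = 5.5e-6, medium_eps = 78.4,
                            volume_fraction = NULL,
                            relative_sd = 0.005, seed = NULL) {
  if (length(frequency_window) != 2 || !all(is.finite(frequency_window)) ||
      frequency_window[1] <= 0 || frequency_window[1] >= frequency_window[2]) {
    rlang::abort("frequency_window must be (f_min, f_max) with 0 < f_min < f_max")
  }
  if (!is.null(volume_fraction) &&
      (!is.finite(volume_fraction) || volume_fraction <= 0 || volume_fraction >= 1)) {
    rlang::abort("volume_fraction must lie in (0, 1) when given")
  }
  structure(
    list(
      frequency_window = as.numeric(frequency_window),
      geometry = geometry,
      resistance_source = match.arg(resistance_source),
      weighting = match.arg(weighting),
      medium_sigma = medium_sigma,
      medium_eps = medium_eps,
      volume_fraction = volume_fraction,
      relative_sd = relative_sd,
      seed = seed
    ),
    class = "pipeline_config"
  )
}

#' Run the full EIS-to-DEP pipeline over a batch of spectrum files
#'
#' Per input spectrum: restrict to the configured frequency window, fit the
#' Randles circuit, derive the suspension conductivity from the configured
#' resistance source, convert the windowed spectrum to permittivity, and
#' predict the DEP response of the sample treated as the particle phase
#' against the configured medium. Failures are isolated per sample: one
#' malformed file yields an error record, not an aborted batch. The run is
#' deterministic for fixed `(config, inputs)`.
#'
#' @param paths Character vector of spectrum CSV paths. May be empty.
#' @param config A [pipeline_config()].
#' @param quiet Suppress the startup log of configuration switches.
#' @return A tibble with one row per input: `label`, `file`, `error`
#'   (NA on success), the five fitted parameters, `residual_norm`,
#'   `converged`, `resistance_source`, `resistance_ohm`,
#'   `conductivity_s_per_m`, `n_crossovers`, `band_low_hz`, `band_high_hz`,
#'   plus list-columns `fit` (`randles_fit`) and `dep` (`dep_prediction`).
#'   The configuration is attached as attribute `"config"`.
#' @export
run_pipeline <- function(paths, config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!quiet) {
    rlang::inform(c(
      "eisdep pipeline configuration:",
      paste0("  frequency window: ", config$frequency_window[1], " - ",
             config$frequency_window[2], " Hz"),
      paste0("  resistance source for conductivity: ", config$resistance_source),
      paste0("  fit weighting: ", config$weighting),
      paste0("  medium: sigma = ", config$medium_sigma, " S/m, eps_r = ",
             config$medium_eps),
      paste0("  cell constant: ",
             signif(config$geometry$cell_constant_per_m, 6), " 1/m")
    ))
  }
  empty_row <- function(file, msg) {
    tibble::tibble(
      label = NA_character_, file = file, error = msg,
      r_u = NA_real_, y0 = NA_real_, alpha = NA_real_, w_d = NA_real_,
      r_p = NA_real_, residual_norm = NA_real_, converged = NA,
      resistance_source = config$resistance_source,
      resistance_ohm = NA_real_, conductivity_s_per_m = NA_real_,
      n_crossovers = NA_integer_, band_low_hz = NA_real_,
      band_high_hz = NA_real_, fit = list(NULL), dep = list(NULL)
    )
  }
  one <- function(file) {
    tryCatch({
      s <- read_spectrum_csv(file)
      record_sample(s, config, file = file)
    }, error = function(e) empty_row(file, conditionMessage(e)))
  }
  out <- purrr::map(paths, one) |> purrr::list_rbind()
  if (length(paths) == 0) out <- empty_row("", "")[0, ]
  attr(out, "config") <- config
  out
}

#' @rdname run_pipeline
#' @param spectrum A spectrum data frame (already in memory).
#' @param file Provenance string recorded in the report row.
#' @export
record_sample <- function(spectrum, config, file = "") {
  s <- as_eis_spectrum(spectrum)
  win <- config$frequency_window
  windowed <- dplyr::filter(tibble::as_tibble(s),
                            .data$frequency_hz >= win[1],
                            .data$frequency_hz <= win[2])
  if (nrow(windowed) < 5) {
    rlang::abort("fewer than 5 points inside the fitting window")
  }
  ws <- as_eis_spectrum(windowed, label = spectrum_label(s))
  fit <- fit_randles(ws, weighting = config$weighting)
  resistance <- switch(config$resistance_source,
                       rp = fit$params$r_p, ru = fit$params$r_u)
  sigma <- conductivity_from_resistance(resistance, config$geometry)
  perm <- permittivity_from_impedance(ws, config$geometry)
  eps_p <- complex_permittivity(perm)
  eps_m <- medium_permittivity(perm$frequency_hz, config$medium_eps,
                               config$medium_sigma)
  dep <- dep_response(perm$frequency_hz, eps_p, eps_m)
  band <- dep$recommended_band %||% c(NA_real_, NA_real_)
  tibble::tibble(
    label = spectrum_label(s), file = file, error = NA_character_,
    r_u = fit$params$r_u, y0 = fit$params$y0, alpha = fit$params$alpha,
    w_d = fit$params$w_d, r_p = fit$params$r_p,
    residual_norm = fit$residual_norm, converged = fit$converged,
    resistance_source = config$resistance_source,
    resistance_ohm = resistance, conductivity_s_per_m = sigma,
    n_crossovers = length(dep$crossover_hz),
    band_low_hz = band[1], band_high_hz = band[2],
    fit = list(fit), dep = list(dep)
  )
}

#' Write a machine-readable pipeline report
#'
#' JSON with a provenance block (tool version, configuration hash, seed,
#' resistance source) and one record per sample (scalar fields of the
#' [run_pipeline()] output). The companion human-readable table is just
#' `print()` of the records tibble.
#'
#' @param records Output of [run_pipeline()].
#' @param path Output path for the JSON report.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(records, path) {
  config <- attr(records, "config")
  scalars <- dplyr::select(tibble::as_tibble(records), -dplyr::any_of(c("fit", "dep")))
  cfg_fields <- config[c("frequency_window", "resistance_source", "weighting",
                         "medium_sigma", "medium_eps")]
  report <- list(
    provenance = list(
      tool = "eisdep",
      version = as.character(utils::packageVersion("eisdep")),
      config_hash = rlang::hash(cfg_fields),
      seed = config$seed %||% NA,
      resistance_source = config$resistance_source
    ),
    config = c(cfg_fields,
               list(cell_constant_per_m = config$geometry$cell_constant_per_m)),
    samples = scalars
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @importFrom rlang .data
NULL
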