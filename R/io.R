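#' Read and write ECG records as CSV
#'
#' A fixed plain-text dialect for bit-stable interchange: an initial
#' comment line `# fs: <Hz>`, then a comma-separated header `time_s` plus
#' one column per lead, dot-decimal values. `read_ecg_csv()` refuses files
#' without the sampling-frequency line and files containing non-finite
#' samples.
#'
#' @param path File path.
#' @param record An [ecg_record()].
#' @param digits Significant digits written (default 15, round-trip safe).
#'
#' @return `read_ecg_csv()` returns an [ecg_record()];
#'   `write_ecg_csv()` returns `path` invisibly.
#' @export
read_ecg_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^#\\s*fs:\\s*([0-9.eE+-]+)", first))[[1]]
  if (length(m) < 2)
    stop("missing '# fs: <Hz>' header line in ", path, call. = FALSE)
  fs <- as.numeric(m[2])
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!"time_s" %in% names(df))
    stop("missing time_s column in ", path, call. = FALSE)
  leads <- setdiff(names(df), "time_s")
  if (length(leads) == 0) stop("no lead columns in ", path, call. = FALSE)
  ecg_record(as.matrix(df[leads]), fs = fs, lead_names = leads)
}

#' @rdname read_ecg_csv
#' @export
write_ecg_csv <- function(record, path, digits = 15) {
  stopifnot(inherits(record, "ecg_record"))
  df <- as.data.frame(as_tibble(record))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs: %.10g", record$fs), con)
  utils::write.table(format(df, digits = digits, trim = TRUE, scientific = FALSE),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write R-peak annotations as single-column CSV
#'
#' @param path File path.
#' @param r_peaks Integer vector of 1-based sample indices.
#' @return `read_rpeaks_csv()` returns an integer vector.
#' @export
read_rpeaks_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"r_peak" %in% names(df)) stop("missing r_peak column", call. = FALSE)
  as.integer(df$r_peak)
}

#' @rdname read_rpeaks_csv
#' @export
write_rpeaks_csv <- function(r_peaks, path) {
  utils::write.csv(data.frame(r_peak = as.integer(r_peaks)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Save and restore a fitted GP model as JSON
#'
#' Persists the learned state (phase mean, phase variances, optional full
#' covariance, noise variance, phase geometry) so a model can be reused or
#' inspected without refitting.
#'
#' @param model A [gp_fit()] object.
#' @param path File path.
#' @return `read_gp_model()` returns a `gp_model`.
#' @export
write_gp_model <- function(model, path) {
  stopifnot(inherits(model, "gp_model"))
  obj <- list(mu = model$mu, k_diag = model$k_diag,
              k_full = model$k_full, noise_var = model$noise_var,
              mode = model$mode, n_phase = model$n_phase,
              r_phase = model$r_phase, n_beats = model$n_beats)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_gp_model
#' @export
read_gp_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    mu = as.numeric(obj$mu), k_diag = as.numeric(obj$k_diag),
    k_full = if (is.null(obj$k_full)) NULL else as.matrix(obj$k_full),
    noise_var = obj$noise_var, mode = obj$mode,
    n_phase = as.integer(obj$n_phase),
    r_phase = if (is.null(obj$r_phase)) NA_integer_ else as.integer(obj$r_phase),
    n_beats = as.integer(obj$n_beats)), class = "gp_model")
}

#' Pipeline configuration
#'
#' Validated bundle of every tunable the pipeline uses; unknown keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param band Preprocessing passband in Hz.
#' @param n_phase Fixed integer phase length, or `"auto"` for 10% headroom
#'   over the longest beat.
#' @param alignment `"r_aligned"` or `"single"`.
#' @param gp_mode `"diagonal"` or `"full"`.
#' @param v_n_method `"baseline"` or `"oracle"`.
#' @param wavelet_levels Benchmark decomposition depth.
#' @param levels Grid SNR levels in dB.
#' @param reps Grid repetitions.
#' @param seed0 Grid base seed.
#' @param lead Lead selection (`NULL` = all).
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(band = c(5, 80), n_phase = "auto",
                            alignment = "r_aligned", gp_mode = "diagonal",
                            v_n_method = "baseline", wavelet_levels = 4L,
                            levels = seq(-5, 30, by = 5), reps = 5L,
                            seed0 = 1L, lead = NULL) {
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2])
  if (!identical(n_phase, "auto")) {
    n_phase <- as.integer(n_phase)
    stopifnot(is.finite(n_phase), n_phase >= 2)
  }
  alignment <- match.arg(alignment, c("r_aligned", "single"))
  gp_mode <- match.arg(gp_mode, c("diagonal", "full"))
  v_n_method <- match.arg(v_n_method, c("baseline", "oracle"))
  stopifnot(wavelet_levels >= 1, reps >= 1)
  structure(list(band = as.numeric(band), n_phase = n_phase,
                 alignment = alignment, gp_mode = gp_mode,
                 v_n_method = v_n_method,
                 wavelet_levels = as.integer(wavelet_levels),
                 levels = as.numeric(levels), reps = as.integer(reps),
                 seed0 = as.integer(seed0), lead = lead),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path File path for the JSON form.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(obj), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, obj)
}
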