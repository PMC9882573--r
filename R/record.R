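#' ECG record container
#'
#' An `ecg_record` holds a multi-lead sample matrix (rows are time samples,
#' columns are leads, in millivolts) together with its sampling frequency.
#' It is the signal container used by every function in the package.
#'
#' @param samples Numeric vector (single lead) or matrix with one column per
#'   lead, in mV. Must be finite.
#' @param fs Sampling frequency in Hz (> 0).
#' @param lead_names Optional character vector of lead labels; defaults to
#'   existing column names or `"lead1"`, `"lead2"`, ...
#'
#' @return An object of class `ecg_record` with elements `samples`
#'   (numeric matrix, samples x leads), `fs` and `lead_names`.
#' @export
#' @examples
#' rec <- ecg_record(sin(seq(0, 2 * pi, length.out = 100)), fs = 100)
#' n_samples(rec)
ecg_record <- function(samples, fs, lead_names = NULL) {
  if (is.null(dim(samples))) samples <- matrix(as.numeric(samples), ncol = 1)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  if (nrow(samples) < 1L)
    stop("record must contain at least one sample", call. = FALSE)
  if (anyNA(samples) || any(!is.finite(samples))) {
    bad <- which(!is.finite(samples))[1L]
    stop("non-finite sample at index ", bad, call. = FALSE)
  }
  if (is.null(lead_names)) {
    lead_names <- colnames(samples)
    if (is.null(lead_names)) lead_names <- paste0("lead", seq_len(ncol(samples)))
  }
  if (length(lead_names) != ncol(samples))
    stop("`lead_names` must have one entry per lead", call. = FALSE)
  colnames(samples) <- lead_names
  structure(list(samples = samples, fs = fs, lead_names = lead_names),
            class = "ecg_record")
}

#' @rdname ecg_record
#' @param record,x An `ecg_record`.
#' @export
n_samples <- function(record) nrow(record$samples)

#' @rdname ecg_record
#' @export
n_leads <- function(record) ncol(record$samples)

#' @rdname ecg_record
#' @param lead Lead index or name.
#' @export
get_lead <- function(record, lead = 1L) {
  stopifnot(inherits(record, "ecg_record"))
  as.numeric(record$samples[, lead])
}

#' Replace the sample matrix of a record, keeping fs and lead names
#' @noRd
set_samples <- function(record, samples) {
  ecg_record(samples, fs = record$fs, lead_names = record$lead_names)
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples x %d lead(s) @ %g Hz (%.1f s)\n",
              n_samples(x), n_leads(x), x$fs, n_samples(x) / x$fs))
  invisible(x)
}

#' @rdname ecg_record
#' @param ... Passed on to methods (unused).
#' @importFrom tibble as_tibble
#' @export
as_tibble.ecg_record <- function(x, ...) {
  tibble::as_tibble(cbind(
    data.frame(time_s = (seq_len(n_samples(x)) - 1) / x$fs),
    as.data.frame(x$samples)
  ))
}

#' @export
as.matrix.ecg_record <- function(x, ...) x$samples
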