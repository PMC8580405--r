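#' Multichannel region-level recording
#'
#' Container for a region-by-samples time-series matrix with its sampling rate,
#' region labels, and lesion-side metadata. All downstream stages
#' ([condition()], [segment_epochs()], [epoch_spectra()]) consume this type.
#'
#' @param data Numeric matrix, regions (rows) by samples (columns). Must be
#'   free of NA/NaN.
#' @param fs Sampling rate in Hz, > 0.
#' @param labels Character vector of unique region labels, one per row.
#' @param lesion_side `"left"`, `"right"`, or `"none"` (controls / simulation
#'   without a lesion).
#' @return An object of class `region_recording`: a list with fields `data`,
#'   `fs`, `labels`, `lesion_side`.
#' @export
region_recording <- function(data, fs, labels = rownames(data),
                             lesion_side = c("none", "left", "right")) {
  lesion_side <- match.arg(lesion_side)
  if (!is.matrix(data) || !is.numeric(data)) stop("data must be a numeric matrix")
  if (anyNA(data)) stop("recording contains NA/NaN values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  labels <- as.character(labels)
  if (length(labels) != nrow(data)) stop("one label per channel/region required")
  if (anyDuplicated(labels)) stop("duplicate region labels: ",
                                  paste(unique(labels[duplicated(labels)]), collapse = ", "))
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels, lesion_side = lesion_side),
            class = "region_recording")
}

#' @export
print.region_recording <- function(x, ...) {
  cat(sprintf("<region_recording> %d regions x %d samples @ %g Hz (%.1f s), lesion side: %s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$lesion_side))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording A [region_recording()].
#' @return Scalar duration (s).
#' @export
recording_duration <- function(recording) {
  stopifnot(inherits(recording, "region_recording"))
  ncol(recording$data) / recording$fs
}
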