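# On-disk formats: a recording is one delimited numeric matrix (rows =
# regions, first column = label) plus a YAML sidecar with sampling rate,
# labels, lesion side, and seed; a connectivity matrix is a delimited square
# matrix with a label header row/column plus a YAML sidecar (band, n_epochs).

#' Write / read a region recording
#'
#' `write_recording()` writes `<prefix>.tsv` (tab-delimited, one row per
#' region, first column the region label) and `<prefix>.meta.yaml`.
#' `read_recording()` reads the pair back.
#'
#' @param recording A [region_recording()].
#' @param prefix Path prefix (without extension).
#' @param seed Optional seed to record in the sidecar.
#' @return `write_recording()`: the prefix, invisibly. `read_recording()`:
#'   a [region_recording()].
#' @export
write_recording <- function(recording, prefix, seed = NULL) {
  stopifnot(inherits(recording, "region_recording"))
  df <- data.frame(region = recording$labels, recording$data,
                   check.names = FALSE)
  utils::write.table(df, paste0(prefix, ".tsv"), sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  meta <- list(fs = recording$fs, labels = as.list(recording$labels),
               lesion_side = recording$lesion_side)
  if (!is.null(seed)) meta$seed <- seed
  yaml::write_yaml(meta, paste0(prefix, ".meta.yaml"))
  invisible(prefix)
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, ".meta.yaml"))
  raw <- utils::read.table(paste0(prefix, ".tsv"), sep = "\t",
                           stringsAsFactors = FALSE)
  labels <- raw[[1]]
  data <- as.matrix(raw[, -1, drop = FALSE])
  dimnames(data) <- NULL
  region_recording(data, fs = meta$fs, labels = labels,
                   lesion_side = meta$lesion_side)
}

#' Write / read a connectivity matrix
#'
#' CSV with a header row and a leading label column, plus
#' `<path>.meta.yaml` holding the band name and epoch count.
#'
#' @param matrix A `coherence_matrix`.
#' @param path CSV path.
#' @return `write_coherence()`: the path, invisibly. `read_coherence()`: a
#'   `coherence_matrix`.
#' @export
write_coherence <- function(matrix, path) {
  df <- data.frame(region = rownames(matrix), unclass(matrix),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(band = attr(matrix, "band"),
                        n_epochs = attr(matrix, "n_epochs")),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_coherence
#' @export
read_coherence <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  labels <- df[[1]]
  M <- as.matrix(df[, -1, drop = FALSE])
  dimnames(M) <- list(labels, labels)
  meta_path <- paste0(path, ".meta.yaml")
  band <- NULL; n_epochs <- NULL
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    band <- meta$band; n_epochs <- meta$n_epochs
  }
  structure(M, band = band, n_epochs = n_epochs,
            class = c("coherence_matrix", "matrix"))
}
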