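#' Canonical EEG frequency bands
#'
#' The seven frequency bands used throughout the package: Delta (1-3 Hz),
#' Theta (4-7 Hz), Alpha1 (8-10 Hz), Alpha2 (11-13 Hz), Beta1 (14-21 Hz),
#' Beta2 (22-30 Hz), and the whole alpha band Alpha (8-13 Hz). Band membership
#' of a frequency bin is decided on the closed interval `[lo, hi]`.
#'
#' @return A data frame with columns `band`, `lo`, `hi` (Hz).
#' @examples
#' band_table()
#' @export
band_table <- function() {
  data.frame(
    band = c("Delta", "Theta", "Alpha1", "Alpha2", "Beta1", "Beta2", "Alpha"),
    lo   = c(1, 4, 8, 11, 14, 22, 8),
    hi   = c(3, 7, 10, 13, 21, 30, 13),
    stringsAsFactors = FALSE
  )
}

#' Frequency range of a named band
#'
#' @param band Band name, one of the seven in [band_table()].
#' @return Numeric `c(lo, hi)` in Hz.
#' @examples
#' band_range("Alpha1")
#' @export
band_range <- function(band) {
  tb <- band_table()
  i <- match(band, tb$band)
  if (length(band) != 1L || is.na(i)) {
    stop("unknown band: ", paste(band, collapse = ", "),
         " (known: ", paste(tb$band, collapse = ", "), ")")
  }
  c(lo = tb$lo[i], hi = tb$hi[i])
}

#' Bands containing a frequency
#'
#' Returns every band whose closed interval contains `freq_hz`; bands overlap
#' (Alpha contains both Alpha1 and Alpha2) and there are gaps between the
#' printed ranges (e.g. 3.5 Hz belongs to no band).
#'
#' @param freq_hz Frequency in Hz (scalar).
#' @return Character vector of band names (possibly empty).
#' @examples
#' band_lookup(9)    # "Alpha1" "Alpha"
#' band_lookup(3.5)  # character(0)
#' @export
band_lookup <- function(freq_hz) {
  stopifnot(is.numeric(freq_hz), length(freq_hz) == 1L)
  tb <- band_table()
  tb$band[freq_hz >= tb$lo & freq_hz <= tb$hi]
}
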