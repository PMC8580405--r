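# Signal conditioning and epoch segmentation.
#
# Conditioning mirrors the standard resting-state EEG chain: zero-phase
# band-pass (order-4 Butterworth), narrow 50-Hz notch (RBJ biquad, Q = 30),
# polyphase resampling to the target rate, then common average reference.
# Phase preservation matters for coherence estimation downstream, so the IIR
# designs are applied as zero-phase (magnitude-squared) responses.

# Zero-phase filtering in the frequency domain: the spectrum is multiplied by
# the magnitude-squared response |H|^2 of the IIR design, which is exactly the
# response a forward-backward (filtfilt) pass applies, without the edge
# transients a recursive implementation leaves behind (boundary effects become
# circular and are negligible for band-limited signals).
polyval_unit_circle <- function(coefs, z) {
  acc <- rep(0 + 0i, length(z))
  for (j in rev(seq_along(coefs))) acc <- acc * z + coefs[j]
  acc
}

zero_phase_gain <- function(b, a, n) {
  z <- exp(-2i * pi * (seq_len(n) - 1) / n)
  Mod(polyval_unit_circle(b, z) / polyval_unit_circle(a, z))^2
}

apply_zero_phase <- function(x, filters) {
  n <- length(x)
  G <- rep(1, n)
  for (f in filters) G <- G * zero_phase_gain(f$b, f$a, n)
  Re(stats::fft(stats::fft(x) * G, inverse = TRUE)) / n
}

# RBJ cookbook notch biquad; returns list(b, a).
notch_coefs <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  list(b = c(1, -2 * cos(w0), 1) / (1 + alpha),
       a = c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha)))
}

#' Condition a recording: band-pass, notch, resample, common average reference
#'
#' Applies, in order: a zero-phase order-4 Butterworth band-pass, a zero-phase
#' 50-Hz notch (quality factor 30), polyphase resampling to `target_fs`, and
#' common average referencing (subtracting the instantaneous mean across
#' channels, so the channel mean is exactly zero at every sample; skipped
#' below 3 channels, where it would make the channels collinear).
#'
#' The input rate must satisfy `fs >= 2 * band[2]` when resampling is needed;
#' data already at `target_fs` (e.g. re-conditioning) has its upper band edge
#' clipped to `0.45 * fs` so the pass band stays below Nyquist, which makes
#' conditioning idempotent up to passband ripple.
#'
#' @param recording A [region_recording()].
#' @param band Length-2 numeric, band-pass edges in Hz. Default `c(1, 145)`.
#' @param notch Notch center frequency in Hz (`NULL` to skip). Default 50.
#' @param target_fs Output sampling rate in Hz. Default 250.
#' @param notch_q Notch quality factor. Default 30.
#' @return A conditioned [region_recording()] at `target_fs`.
#' @examples
#' rec <- region_recording(matrix(rnorm(4 * 1000), 4), fs = 500)
#' out <- condition(rec)
#' out$fs                      # 250
#' max(abs(colMeans(out$data)))  # ~0 (common average reference)
#' @export
condition <- function(recording, band = c(1, 145), notch = 50,
                      target_fs = 250, notch_q = 30) {
  stopifnot(inherits(recording, "region_recording"))
  fs <- recording$fs
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1])
    stop("band must be c(lo, hi) with 0 < lo < hi")
  if (fs == target_fs) {
    band[2] <- min(band[2], 0.45 * fs)
  } else if (fs < 2 * band[2]) {
    stop(sprintf("input sampling rate %g Hz is below 2 x band edge (%g Hz)", fs, 2 * band[2]))
  }
  if (fs < target_fs) stop("upsampling not supported: input fs below target_fs")

  x <- recording$data
  bp <- signal::butter(4, band / (fs / 2), type = "pass")
  filters <- list(list(b = bp$b, a = bp$a))
  if (!is.null(notch)) filters <- c(filters, list(notch_coefs(notch, fs, notch_q)))
  for (i in seq_len(nrow(x))) x[i, ] <- apply_zero_phase(x[i, ], filters)
  if (fs != target_fs) {
    g <- gcd_int(round(target_fs), round(fs))
    p <- round(target_fs) / g
    q <- round(fs) / g
    y <- t(apply(x, 1, function(row) signal::resample(row, p, q)))
  } else {
    y <- x
  }
  # CAR is degenerate below 3 channels (it makes a pair collinear), so it is
  # only applied to genuinely multichannel recordings
  if (nrow(y) >= 3) y <- sweep(y, 2, colMeans(y))
  region_recording(y, target_fs, recording$labels, recording$lesion_side)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Segment a recording into overlapping epochs
#'
#' Cuts the recording into epochs of `length_s` seconds whose start times form
#' an arithmetic sequence with step `length_s - overlap_s` (consecutive epochs
#' share `overlap_s` seconds of signal). Only epochs lying fully inside the
#' recording are kept; no padding. At the default 2-s epochs with 0.5-s
#' overlap, a 300-s recording yields `floor((300 - 2) / 1.5) + 1 = 199` epochs.
#'
#' @param recording A [region_recording()].
#' @param length_s Epoch length in seconds. Default 2.
#' @param overlap_s Shared signal between consecutive epochs, in seconds
#'   (must be `< length_s`). Default 0.5.
#' @return An object of class `epoch_set`: list with `epochs`
#'   (n_epochs x channels x samples array), `fs`, `length_s`, `overlap_s`,
#'   `labels`, and `starts` (epoch start times, s).
#' @export
segment_epochs <- function(recording, length_s = 2, overlap_s = 0.5) {
  stopifnot(inherits(recording, "region_recording"))
  if (overlap_s < 0 || overlap_s >= length_s) stop("need 0 <= overlap_s < length_s")
  fs <- recording$fs
  nsamp <- length_s * fs
  if (abs(nsamp - round(nsamp)) > 1e-9)
    stop("epoch length times sampling rate must be an integer number of samples")
  nsamp <- round(nsamp)
  step <- round((length_s - overlap_s) * fs)
  total <- ncol(recording$data)
  if (total < nsamp)
    stop(sprintf("recording too short: %.3f s < epoch length %g s", total / fs, length_s))
  n_ep <- (total - nsamp) %/% step + 1L
  K <- nrow(recording$data)
  ep <- array(NA_real_, dim = c(n_ep, K, nsamp))
  starts <- (seq_len(n_ep) - 1L) * step
  for (k in seq_len(n_ep)) ep[k, , ] <- recording$data[, (starts[k] + 1L):(starts[k] + nsamp)]
  structure(list(epochs = ep, fs = fs, length_s = length_s, overlap_s = overlap_s,
                 labels = recording$labels, starts = starts / fs),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples (%g s @ %g Hz, %g s overlap)\n",
              d[1], d[2], d[3], x$length_s, x$fs, x$overlap_s))
  invisible(x)
}

#' Artifact-removal hook
#'
#' Placeholder for an independent-component-analysis artifact cleaner
#' (blink/cardiac removal) on real recordings. Synthetic recordings are
#' artifact-free, so the default is the identity; supply `cleaner` to plug in
#' an external routine.
#'
#' @param recording A [region_recording()].
#' @param cleaner Optional function `recording -> recording`.
#' @return The (possibly cleaned) recording.
#' @export
remove_artifacts <- function(recording, cleaner = NULL) {
  stopifnot(inherits(recording, "region_recording"))
  if (is.null(cleaner)) recording else cleaner(recording)
}
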