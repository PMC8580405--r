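# Synthetic oscillatory cohorts with known coupling structure.
#
# Oscillators are Gaussian white noise band-pass filtered (zero-phase,
# order-4 Butterworth) to a stated band, so their spectra are stationary and
# analytically tractable. A coupling injects one shared oscillator into two
# regions with a time lag (default: a quarter cycle of the band center, which
# maximizes the imaginary part of coherency) and a strength in [0, 1]. Purely
# instantaneous cross-talk is expressed separately as a mixing matrix applied
# after signal assembly, emulating volume conduction; imaginary coherence must
# stay at the noise floor under such mixing. SNR is defined as band-limited
# oscillatory signal variance over broadband white-noise variance and is
# recorded in every ground truth.

#' Oscillator specification
#'
#' @param band_name One of the seven bands in [band_table()].
#' @param center_hz Oscillator center frequency; default the band midpoint.
#'   Must lie inside the named band.
#' @param bandwidth_hz Full bandwidth of the band-limited noise; default the
#'   band width (upper - lower edge), and always > 0.
#' @param amplitude Standard-deviation scale of the oscillation. Default 1.
#' @return A list of class `oscillator_spec`.
#' @export
oscillator_spec <- function(band_name, center_hz = NULL, bandwidth_hz = NULL,
                            amplitude = 1) {
  rng <- band_range(band_name)
  if (is.null(center_hz)) center_hz <- mean(rng)
  if (is.null(bandwidth_hz)) bandwidth_hz <- max(rng[2] - rng[1], 1)
  if (center_hz < rng[1] || center_hz > rng[2])
    stop(sprintf("center %g Hz outside band %s (%g-%g Hz)", center_hz, band_name, rng[1], rng[2]))
  if (bandwidth_hz <= 0) stop("bandwidth_hz must be > 0")
  structure(list(band_name = band_name, center_hz = center_hz,
                 bandwidth_hz = bandwidth_hz, amplitude = amplitude),
            class = "oscillator_spec")
}

#' Coupling specification
#'
#' Describes one phase-lagged interaction: region `region_j` receives region
#' `region_i`'s band-limited component delayed by `lag_s` and scaled by
#' `strength`. Zero-lag (instantaneous) coupling is deliberately not
#' expressible here; that is the role of the mixing matrix
#' ([mixing_spec()]), keeping lagged "true" connectivity and
#' volume-conduction-style cross-talk distinct in the ground truth.
#'
#' @param region_i,region_j Distinct region labels.
#' @param band_name Band of the shared oscillator.
#' @param strength Coupling strength in `[0, 1]`.
#' @param lag_s Time lag in seconds, nonzero. Default: a quarter cycle of the
#'   band center frequency.
#' @return A list of class `coupling_spec`.
#' @export
coupling_spec <- function(region_i, region_j, band_name, strength,
                          lag_s = NULL) {
  if (identical(region_i, region_j)) stop("coupling requires two distinct regions")
  if (strength < 0 || strength > 1) stop("strength must be in [0, 1]")
  rng <- band_range(band_name)
  if (is.null(lag_s)) lag_s <- 1 / (4 * mean(rng))
  if (lag_s == 0) stop("lag_s must be nonzero; use a mixing matrix for instantaneous coupling")
  structure(list(region_i = region_i, region_j = region_j, band_name = band_name,
                 strength = strength, lag_s = lag_s),
            class = "coupling_spec")
}

#' Instantaneous mixing specification
#'
#' A K x K matrix applied to the assembled signals (signal + noise) as the
#' last simulation step, emulating volume conduction: every output channel is
#' an instantaneous weighted sum of the sources. The identity leaves signals
#' untouched.
#'
#' @param matrix Square numeric mixing matrix, or `NULL` with `k` given for
#'   the identity.
#' @param k Number of channels (used when `matrix` is `NULL`).
#' @return A list of class `mixing_spec` with fields `matrix` and `identity`.
#' @export
mixing_spec <- function(matrix = NULL, k = NULL) {
  if (is.null(matrix)) {
    if (is.null(k)) stop("supply a matrix or k")
    matrix <- diag(k)
  }
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop("mixing matrix must be square")
  structure(list(matrix = matrix,
                 identity = isTRUE(all.equal(matrix, diag(nrow(matrix))))),
            class = "mixing_spec")
}

#' Ground truth of a simulation
#'
#' Records every generative parameter so downstream estimates can be compared
#' against what was injected: the couplings, the mixing matrix, the SNR,
#' behavioral effect sizes (for cohorts), and the seed. Identical ground truth
#' plus identical seed reproduces the simulation bit for bit.
#'
#' @param couplings List of [coupling_spec()] objects.
#' @param mixing A [mixing_spec()] or `NULL` (identity).
#' @param behavioral_effects Named list of injected cohort-level effects.
#' @param snr Signal-to-noise ratio (band-limited signal variance over
#'   broadband noise variance); `Inf` for noiseless.
#' @param seed Integer seed.
#' @param lesion_side Lesion side for the simulated subject.
#' @return A list of class `ground_truth`.
#' @export
ground_truth <- function(couplings = list(), mixing = NULL,
                         behavioral_effects = list(), snr = Inf, seed = 1L,
                         lesion_side = "none") {
  if (inherits(couplings, "coupling_spec")) couplings <- list(couplings)
  stopifnot(all(vapply(couplings, inherits, logical(1), "coupling_spec")))
  structure(list(couplings = couplings, mixing = mixing,
                 behavioral_effects = behavioral_effects, snr = snr,
                 seed = as.integer(seed), lesion_side = lesion_side),
            class = "ground_truth")
}

# Band-limited unit-variance Gaussian noise.
band_noise <- function(n, fs, lo, hi) {
  if (hi >= fs / 2) stop(sprintf("band edge %g Hz at or above Nyquist (%g Hz)", hi, fs / 2))
  bp <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bp, rnorm(n + 2 * fs))        # pad against filter edge effects
  x <- x[(fs + 1):(fs + n)]
  x / stats::sd(x)
}

osc_band_edges <- function(spec) {
  c(spec$center_hz - spec$bandwidth_hz / 2, spec$center_hz + spec$bandwidth_hz / 2)
}

#' Simulate one coupled signal pair
#'
#' Generates two signals x and y at sampling rate `fs`: x is a band-limited
#' oscillator; y contains x's oscillatory component delayed by the coupling
#' lag and scaled by the coupling strength, blended with an independent
#' oscillator of the same band (weight `sqrt(1 - strength^2)`, keeping y's
#' oscillatory variance constant across strengths), plus independent broadband
#' noise at the stated SNR on both channels.
#'
#' @param spec An [oscillator_spec()].
#' @param coupling A [coupling_spec()] (its regions label the two channels).
#' @param snr Band-limited signal variance over broadband noise variance;
#'   `Inf` for noiseless.
#' @param duration_s Duration in seconds; must cover at least two epochs
#'   (>= 3.5 s at the default epoching).
#' @param fs Sampling rate; must be at least twice the oscillator's upper
#'   band edge.
#' @param seed Integer seed; identical inputs give bit-identical signals.
#' @return List with `recording` (a 2-channel [region_recording()]) and
#'   `truth` (a [ground_truth()]).
#' @export
make_coupled_pair <- function(spec, coupling, snr = Inf, duration_s = 60,
                              fs = 250, seed = 1L) {
  stopifnot(inherits(spec, "oscillator_spec"), inherits(coupling, "coupling_spec"))
  edges <- osc_band_edges(spec)
  if (fs < 2 * edges[2])
    stop(sprintf("fs = %g Hz is below Nyquist for band edge %g Hz", fs, edges[2]))
  if (duration_s < 3.5) stop("duration must cover at least two epochs (>= 3.5 s)")
  set.seed(seed)
  n <- round(duration_s * fs)
  lag_samp <- round(coupling$lag_s * fs)
  pad <- abs(lag_samp)
  shared <- band_noise(n + pad, fs, edges[1], edges[2])
  x_sig <- shared[(pad + 1):(pad + n)]
  y_lagged <- shared[(pad + 1 - lag_samp):(pad + n - lag_samp)]
  y_own <- band_noise(n, fs, edges[1], edges[2])
  s <- coupling$strength
  x <- spec$amplitude * x_sig
  y <- spec$amplitude * (s * y_lagged + sqrt(1 - s^2) * y_own)
  if (is.finite(snr)) {
    nsd <- spec$amplitude / sqrt(snr)
    x <- x + rnorm(n, sd = nsd)
    y <- y + rnorm(n, sd = nsd)
  }
  rec <- region_recording(rbind(x, y), fs,
                          labels = c(coupling$region_i, coupling$region_j))
  list(recording = rec,
       truth = ground_truth(couplings = list(coupling), snr = snr, seed = seed))
}

#' Simulate one subject's region-level recording
#'
#' Every region receives an independent broadband (1-30 Hz) background
#' oscillation of unit variance; each coupling adds a shared band-limited
#' oscillator to its two regions (the receiving region gets the lagged copy
#' scaled by the coupling strength, blended with an independent same-band
#' oscillator so its band power does not depend on the strength). Independent
#' white noise is added per region at the stated SNR, and the mixing matrix
#' is applied last, so uncoupled regions are mutually independent before
#' mixing.
#'
#' @param regions Character vector of unique region labels.
#' @param truth A [ground_truth()]; every coupling must name regions from
#'   `regions`, and `truth$mixing` (if any) must be K x K.
#' @param duration_s Recording duration (s).
#' @param fs Sampling rate (Hz).
#' @param snr Oscillatory signal variance over white-noise variance.
#' @param osc_amplitude Amplitude of injected coupled oscillators relative to
#'   the unit-variance background. Default 1.5.
#' @param seed Integer seed (defaults to `truth$seed`).
#' @return A [region_recording()].
#' @export
simulate_subject <- function(regions, truth, duration_s = 60, fs = 250,
                             snr = 5, osc_amplitude = 1.5, seed = truth$seed) {
  stopifnot(inherits(truth, "ground_truth"))
  regions <- as.character(regions)
  if (anyDuplicated(regions))
    stop("duplicate region labels: ", paste(unique(regions[duplicated(regions)]), collapse = ", "))
  K <- length(regions)
  for (cp in truth$couplings) {
    if (!all(c(cp$region_i, cp$region_j) %in% regions))
      stop("coupling names unknown region(s): ", cp$region_i, " / ", cp$region_j)
  }
  if (!is.null(truth$mixing) && nrow(truth$mixing$matrix) != K)
    stop("mixing matrix dimension does not match number of regions")
  set.seed(seed)
  n <- round(duration_s * fs)
  S <- matrix(0, K, n, dimnames = list(regions, NULL))
  for (r in seq_len(K)) S[r, ] <- band_noise(n, fs, 1, 30)
  for (cp in truth$couplings) {
    rng <- band_range(cp$band_name)
    lag_samp <- round(cp$lag_s * fs)
    pad <- abs(lag_samp)
    shared <- band_noise(n + pad, fs, rng[1], rng[2])
    own <- band_noise(n, fs, rng[1], rng[2])
    i <- match(cp$region_i, regions); j <- match(cp$region_j, regions)
    S[i, ] <- S[i, ] + osc_amplitude * shared[(pad + 1):(pad + n)]
    S[j, ] <- S[j, ] + osc_amplitude *
      (cp$strength * shared[(pad + 1 - lag_samp):(pad + n - lag_samp)] +
         sqrt(1 - cp$strength^2) * own)
  }
  if (is.finite(snr)) {
    for (r in seq_len(K)) S[r, ] <- S[r, ] + rnorm(n, sd = stats::sd(S[r, ]) / sqrt(snr))
  }
  if (!is.null(truth$mixing)) S <- truth$mixing$matrix %*% S
  rownames(S) <- regions
  region_recording(S, fs, regions, lesion_side = truth$lesion_side)
}

#' Reduced 10-region montage
#'
#' Desk-scale montage: per hemisphere one Frontal, Temporal, and Parietal
#' region plus two occipital subregions (Occipital_Sup, Occipital_Mid), so
#' within-occipital, interhemispheric-occipital, and occipito-temporal
#' coherence are all expressible at 10 nodes. See [aal90_atlas()] for the
#' full 90-region table.
#'
#' @return Data frame with columns `index`, `label`, `hemisphere`, `lobe`.
#' @export
reduced_atlas <- function() {
  base <- c("Frontal", "Temporal", "Parietal", "Occipital_Sup", "Occipital_Mid")
  lobe <- c("Frontal", "Temporal", "Parietal", "Occipital", "Occipital")
  data.frame(index = 1:10,
             label = paste0(rep(base, each = 2), c("_L", "_R")),
             hemisphere = rep(c("L", "R"), 5),
             lobe = rep(lobe, each = 2),
             stringsAsFactors = FALSE)
}

#' Cohort simulation design
#'
#' Assembles and validates the design for [simulate_cohort()]. Defaults mirror
#' the study layout: three stimulation groups (Sham, AC, ACDC) of eight
#' patients, three time points (Pre, Post, FU), lesion side randomized, and a
#' slight global instantaneous leak as volume conduction. The `effects` list
#' holds every injected group-by-time change; setting all of them to zero (and
#' `fov_change_sd = 0`) yields an exact null cohort.
#'
#' Effects (all act on the ACDC group unless noted):
#' \describe{
#'   \item{alpha_occsup_fu}{Added alpha coupling strength into
#'     Occipital_Sup of the lesioned hemisphere at FU.}
#'   \item{delta_interhem_post}{Added (typically negative) delta coupling
#'     strength between the two middle-occipital regions at Post.}
#'   \item{beta_occtemp_post}{Added low-beta (Beta1) coupling strength between
#'     intact occipital and intact temporal regions at Post.}
#'   \item{fov_cpl_slope}{Negative association between visual-field change and
#'     alpha-band characteristic path length: FOV change of ACDC patients at
#'     Post/FU is decreased by `slope * scale(CPL)` computed from their own
#'     simulated recordings. Requires `make_recordings = TRUE`.}
#'   \item{alpha_strength_effect}{Shift (in within-subject SD units) of the
#'     latent occipital alpha node-strength metric for ACDC at FU.}
#'   \item{fov_change_mean}{Named per-group mean FOV change (dB) at Post/FU.}
#'   \item{fov_change_sd}{SD of the FOV change noise (dB).}
#' }
#'
#' @param groups Group labels. Default `c("Sham", "AC", "ACDC")`.
#' @param n_per_group Patients per group, >= 2. Default 8.
#' @param timepoints Time point labels. Default `c("Pre", "Post", "FU")`.
#' @param montage `"reduced10"` or `"aal90"`.
#' @param duration_s,fs,snr Recording parameters (defaults 60 s, 250 Hz,
#'   SNR 5).
#' @param base_strength Baseline coupling strength of the standing couplings.
#' @param mixing_leak Fraction of global instantaneous leak (0 disables
#'   mixing). Default 0.1.
#' @param make_recordings Simulate EEG (`TRUE`) or only the behavioral table
#'   and latent metrics (`FALSE`, fast path for statistical simulations).
#' @param effects Named list overriding individual effect defaults.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(groups = c("Sham", "AC", "ACDC"), n_per_group = 8,
                          timepoints = c("Pre", "Post", "FU"),
                          montage = c("reduced10", "aal90"),
                          duration_s = 60, fs = 250, snr = 5,
                          base_strength = 0.35, mixing_leak = 0.1,
                          make_recordings = TRUE, effects = list()) {
  montage <- match.arg(montage)
  if (n_per_group < 2) stop("group sizes < 2 are rejected: statistics undefined")
  if (length(groups) < 1 || anyDuplicated(groups)) stop("groups must be distinct")
  def <- list(alpha_occsup_fu = 0.3, delta_interhem_post = -0.2,
              beta_occtemp_post = 0.2, fov_cpl_slope = 1,
              alpha_strength_effect = 1.5,
              fov_change_mean = c(Sham = 0, AC = 0, ACDC = 1),
              fov_change_sd = 1.2)
  unknown <- setdiff(names(effects), names(def))
  if (length(unknown)) stop("unknown effect(s): ", paste(unknown, collapse = ", "))
  def[names(effects)] <- effects
  structure(list(groups = groups, n_per_group = n_per_group,
                 timepoints = timepoints, montage = montage,
                 duration_s = duration_s, fs = fs, snr = snr,
                 base_strength = base_strength, mixing_leak = mixing_leak,
                 make_recordings = make_recordings, effects = def),
            class = "cohort_config")
}

null_effects <- function() {
  list(alpha_occsup_fu = 0, delta_interhem_post = 0, beta_occtemp_post = 0,
       fov_cpl_slope = 0, alpha_strength_effect = 0,
       fov_change_mean = c(Sham = 0, AC = 0, ACDC = 0), fov_change_sd = 0)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Standing couplings of one subject in the lesioned/intact frame, mapped to
# the montage's L/R labels, with group-by-time effect increments applied.
subject_couplings <- function(cfg, group, timepoint, lesion_side) {
  lh <- if (lesion_side == "left") "_L" else "_R"
  ih <- if (lesion_side == "left") "_R" else "_L"
  e <- cfg$effects
  is_acdc <- group == "ACDC"
  s_alpha <- cfg$base_strength +
    if (is_acdc && timepoint == "FU") e$alpha_occsup_fu else 0
  s_delta <- cfg$base_strength +
    if (is_acdc && timepoint == "Post") e$delta_interhem_post else 0
  s_beta <- cfg$base_strength - 0.1 +
    if (is_acdc && timepoint == "Post") e$beta_occtemp_post else 0
  list(
    coupling_spec(paste0("Occipital_Mid", lh), paste0("Occipital_Sup", lh),
                  "Alpha", clamp(s_alpha, 0, 1)),
    coupling_spec(paste0("Occipital_Mid", lh), paste0("Occipital_Mid", ih),
                  "Delta", clamp(s_delta, 0, 1)),
    coupling_spec(paste0("Occipital_Mid", ih), paste0("Temporal", ih),
                  "Beta1", clamp(s_beta, 0, 1)),
    coupling_spec(paste0("Frontal", lh), paste0("Parietal", lh),
                  "Theta", cfg$base_strength)
  )
}

rpos <- function(n, mean, sd, lo = 0) round(clamp(rnorm(n, mean, sd), lo, Inf))

#' Simulate a full cohort: recordings, behavioral table, ground truth
#'
#' Generates one recording per subject per time point (unless
#' `make_recordings = FALSE`), a behavioral table in the patient-table schema
#' (HRP black/gray/white counts, gray/white reaction times, FOV in dB, at
#' Pre/Post/FU), a latent per-subject network-metric table used for fast
#' statistical simulations, and a [ground_truth()] recording every injected
#' effect. Identical `(config, seed)` reproduce the cohort exactly.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return List of class `cohort_sim` with elements `recordings` (nested list
#'   `[[subject_id]][[timepoint]]`), `behavior` (data frame, patient-table
#'   schema with `group` coded 0 = Sham, 1 = AC, 2 = ACDC), `metrics` (long
#'   data frame: subject, group, time, alpha_occ_strength), and `truth`.
#' @export
simulate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  groups <- config$groups
  n <- config$n_per_group * length(groups)
  atlas <- if (config$montage == "reduced10") reduced_atlas() else aal90_atlas()
  regions <- atlas$label
  e <- config$effects

  # randomized group assignment, as in a randomized trial
  assignment <- sample(rep(groups, each = config$n_per_group))
  lesion_side <- sample(c("left", "right"), n, replace = TRUE)
  subj_id <- seq_len(n)

  # behavioral baseline (calibrated to the patient table's printed scale)
  beh <- data.frame(
    id = subj_id,
    group = match(assignment, c("Sham", "AC", "ACDC")) - 1L,
    lesion_age_mo = round(clamp(exp(rnorm(n, log(28), 0.9)), 6, 160)),
    hrp_black_pre = rpos(n, 164, 52), hrp_gray_pre = rpos(n, 44, 36),
    hrp_white_pre = rpos(n, 233, 54))
  for (tp in c("post", "fu")) {
    beh[[paste0("hrp_black_", tp)]] <- clamp(beh$hrp_black_pre + round(rnorm(n, 0, 12)), 0, Inf)
    beh[[paste0("hrp_gray_", tp)]] <- clamp(beh$hrp_gray_pre + round(rnorm(n, 0, 10)), 0, Inf)
    beh[[paste0("hrp_white_", tp)]] <- clamp(beh$hrp_white_pre + round(rnorm(n, 0, 10)), 0, Inf)
  }
  for (tp in c("pre", "post", "fu")) {
    beh[[paste0("rt_gray_", tp)]] <- round(clamp(rnorm(n, 0.52, 0.05), 0.3, 0.9), 2)
    beh[[paste0("rt_white_", tp)]] <- round(clamp(rnorm(n, 0.43, 0.06), 0.3, 0.9), 2)
  }
  beh$fov_pre <- round(clamp(rnorm(n, 25.4, 2.2), 18, 30), 1)
  beh$gender <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.75, 0.25))
  beh$age <- round(clamp(rnorm(n, 57, 10.5), 18, 75))

  # latent network-metric layer: subject random intercept (SD 1) + residual
  # (SD 1 = the within-subject unit for alpha_strength_effect)
  tps <- config$timepoints
  subj_re <- rnorm(n)
  metrics <- expand.grid(subject = subj_id, time = tps, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
  metrics$group <- assignment[metrics$subject]
  shift <- ifelse(metrics$group == "ACDC" & metrics$time == "FU",
                  e$alpha_strength_effect, 0)
  metrics$alpha_occ_strength <- subj_re[metrics$subject] + shift +
    rnorm(nrow(metrics))
  metrics$time <- factor(metrics$time, levels = tps)

  # signal layer
  recordings <- NULL
  cpl_post <- cpl_fu <- rep(NA_real_, n)
  all_couplings <- list()
  if (config$make_recordings) {
    mix <- NULL
    if (config$mixing_leak > 0) {
      K <- length(regions)
      mix <- mixing_spec((1 - config$mixing_leak) * diag(K) +
                           config$mixing_leak / K * matrix(1, K, K))
    }
    recordings <- vector("list", n)
    need_cpl <- e$fov_cpl_slope != 0
    for (s in seq_len(n)) {
      recordings[[s]] <- setNames(vector("list", length(tps)), tps)
      for (ti in seq_along(tps)) {
        cps <- subject_couplings(config, assignment[s], tps[ti], lesion_side[s])
        tr <- ground_truth(couplings = cps, mixing = mix, snr = config$snr,
                           seed = (seed %% 100000L) + 7919L * s + ti,
                           lesion_side = lesion_side[s])
        rec <- simulate_subject(regions, tr, config$duration_s, config$fs,
                                snr = config$snr)
        recordings[[s]][[ti]] <- rec
        all_couplings[[length(all_couplings) + 1L]] <-
          list(subject = s, time = tps[ti], couplings = cps)
        if (need_cpl && assignment[s] == "ACDC" && tps[ti] %in% c("Post", "FU")) {
          M <- connectivity_matrices(condition(rec), bands = "Alpha")$Alpha
          g <- proportional_threshold(M, 0.30)
          L <- characteristic_path_length(g)$L
          if (tps[ti] == "Post") cpl_post[s] <- L else cpl_fu[s] <- L
        }
      }
    }
  }

  # FOV at Post/FU: group mean change + (for ACDC) the injected negative
  # CPL association + noise
  fov_change <- function(cpl_vec) {
    ch <- e$fov_change_mean[assignment]
    ch[is.na(ch)] <- 0
    if (e$fov_cpl_slope != 0 && any(!is.na(cpl_vec))) {
      idx <- which(!is.na(cpl_vec))
      z <- as.numeric(scale(cpl_vec[idx]))
      if (length(idx) == 1L) z <- 0
      ch[idx] <- ch[idx] - e$fov_cpl_slope * z
    }
    ch + rnorm(n, sd = e$fov_change_sd)
  }
  beh$fov_post <- round(beh$fov_pre + fov_change(cpl_post), 1)
  beh$fov_fu <- round(beh$fov_pre + fov_change(cpl_fu), 1)
  beh <- beh[, cohort_schema()]

  truth <- ground_truth(
    couplings = list(), mixing = NULL,
    behavioral_effects = c(e, list(per_subject_couplings = all_couplings,
                                   assignment = assignment,
                                   lesion_side = lesion_side,
                                   cpl_post = cpl_post, cpl_fu = cpl_fu)),
    snr = config$snr, seed = seed)
  structure(list(recordings = recordings, behavior = beh, metrics = metrics,
                 truth = truth, config = config),
            class = "cohort_sim")
}
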