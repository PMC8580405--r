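# Atlas topology: region-to-lobe mapping, the lesioned/intact hemisphere
# frame, and local / long-range lobe coherence.

#' The 90-region anatomical atlas table
#'
#' Region labels, hemisphere, and lobe for the 90 cerebral regions of the
#' standard automated-anatomical-labeling parcellation (45 per hemisphere).
#' Occipital subregions (Calcarine, Cuneus, Lingual, Occipital_Sup/Mid/Inf)
#' map to the Occipital lobe; limbic and subcortical structures (cingulate,
#' hippocampus, amygdala, basal ganglia, thalamus, insula, olfactory) map to
#' `"Other"` and are excluded from the four-lobe coherence profile. This
#' packaged table is the single point of truth for lobe membership.
#'
#' @return Data frame with columns `index`, `label`, `hemisphere` (L/R),
#'   `lobe` (Frontal/Temporal/Parietal/Occipital/Other).
#' @export
aal90_atlas <- function() {
  path <- system.file("extdata", "aal90_atlas.csv", package = "fcnet",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

hemi_suffix <- function(labels) {
  suf <- sub("^.*_(L|R|LH|IH)$", "\\1", labels)
  if (any(suf == labels)) stop("labels must end in _L/_R (or _LH/_IH)")
  suf
}

label_base <- function(labels) sub("_(L|R|LH|IH)$", "", labels)

#' Relabel a connectivity matrix into the lesioned/intact hemisphere frame
#'
#' Maps anatomical left/right labels (`*_L`, `*_R`) to lesioned/intact labels
#' (`*_LH`, `*_IH`) according to the patient's lesion side, so that regions
#' of different patients are aligned by their relation to the lesion. Applied
#' to a matrix already in the LH/IH frame, the same call inverts the mapping
#' (back to L/R), so relabeling twice returns the original matrix.
#'
#' @param matrix A `coherence_matrix` (or any labeled square matrix) whose
#'   dimnames end in `_L`/`_R` (or `_LH`/`_IH` for the inverse direction).
#' @param lesion_side `"left"` or `"right"`; `"none"` (controls) is rejected
#'   because the frame is undefined without a lesion.
#' @return The same matrix with relabeled dimnames.
#' @export
relabel_frame <- function(matrix, lesion_side = c("left", "right")) {
  lesion_side <- match.arg(lesion_side)
  labels <- rownames(matrix)
  if (is.null(labels)) stop("matrix must carry region labels as dimnames")
  suf <- hemi_suffix(labels)
  base <- label_base(labels)
  if (all(suf %in% c("L", "R"))) {
    map <- if (lesion_side == "left") c(L = "LH", R = "IH") else c(L = "IH", R = "LH")
  } else if (all(suf %in% c("LH", "IH"))) {
    map <- if (lesion_side == "left") c(LH = "L", IH = "R") else c(LH = "R", IH = "L")
  } else {
    stop("labels mix anatomical (L/R) and lesion (LH/IH) frames")
  }
  new_labels <- paste0(base, "_", map[suf])
  dimnames(matrix) <- list(new_labels, new_labels)
  matrix
}

#' Atlas table in the lesioned/intact frame
#'
#' Applies the same L/R to LH/IH mapping as [relabel_frame()] to an atlas
#' table, so lobe lookups can be done directly on relabeled matrices.
#'
#' @param atlas Atlas data frame ([aal90_atlas()] or [reduced_atlas()]).
#' @param lesion_side `"left"` or `"right"`.
#' @return The atlas with `label` and `hemisphere` rewritten to the LH/IH
#'   frame.
#' @export
frame_atlas <- function(atlas, lesion_side = c("left", "right")) {
  lesion_side <- match.arg(lesion_side)
  map <- if (lesion_side == "left") c(L = "LH", R = "IH") else c(L = "IH", R = "LH")
  atlas$hemisphere <- unname(map[atlas$hemisphere])
  atlas$label <- paste0(label_base(atlas$label), "_", atlas$hemisphere)
  atlas
}

lobe_regions <- function(atlas, lobe, hemisphere) {
  atlas$label[atlas$lobe == lobe & atlas$hemisphere == hemisphere]
}

block_mean <- function(matrix, rows, cols) {
  rows <- intersect(rows, rownames(matrix))
  cols <- intersect(cols, colnames(matrix))
  mean(matrix[rows, cols, drop = FALSE])
}

#' Local (within-lobe) coherence
#'
#' Mean connectivity over the unordered pairs of regions inside one lobe of
#' one hemisphere.
#'
#' @param matrix Labeled connectivity matrix.
#' @param lobe Lobe name (Frontal/Temporal/Parietal/Occipital).
#' @param hemisphere Hemisphere code matching the matrix frame
#'   (L/R or LH/IH).
#' @param atlas Atlas table in the matching frame.
#' @return Scalar mean coherence.
#' @export
local_coherence <- function(matrix, lobe, hemisphere, atlas) {
  regions <- intersect(lobe_regions(atlas, lobe, hemisphere), rownames(matrix))
  if (length(regions) < 2)
    stop(sprintf("lobe %s_%s has fewer than 2 regions in the matrix", lobe, hemisphere))
  sub <- matrix[regions, regions]
  mean(sub[upper.tri(sub)])
}

#' Long-range (seed lobe to target lobes) coherence
#'
#' Mean connectivity between the regions of a seed lobe (typically an
#' occipital lobe) and the regions of the target lobes. The default target is
#' the full profile: every other Frontal/Temporal/Parietal/Occipital lobe of
#' either hemisphere (e.g. seed RO against RT, RF, RP, LT, LF, LP, LO),
#' regions of lobe `"Other"` excluded. A specific lobe-pair block (e.g.
#' intact occipital to intact temporal) is selected by passing `targets`.
#'
#' @param matrix Labeled connectivity matrix.
#' @param seed_lobe,seed_hemisphere Seed lobe and hemisphere.
#' @param atlas Atlas table in the matching frame.
#' @param targets `NULL` for the full profile, or a data frame / list with
#'   elements `lobe` and `hemisphere` naming the target lobe blocks.
#' @return Scalar mean coherence over the seed-by-target block.
#' @export
long_coherence <- function(matrix, seed_lobe, seed_hemisphere, atlas,
                           targets = NULL) {
  seed <- intersect(lobe_regions(atlas, seed_lobe, seed_hemisphere),
                    rownames(matrix))
  if (length(seed) == 0) stop("seed lobe has no regions in the matrix")
  if (is.null(targets)) {
    keep <- atlas$lobe != "Other" &
      !(atlas$lobe == seed_lobe & atlas$hemisphere == seed_hemisphere)
    target_regions <- atlas$label[keep]
  } else {
    targets <- as.data.frame(targets, stringsAsFactors = FALSE)
    target_regions <- unlist(Map(lobe_regions, list(atlas),
                                 targets$lobe, targets$hemisphere))
  }
  target_regions <- setdiff(intersect(target_regions, rownames(matrix)), seed)
  if (length(target_regions) == 0) stop("empty target region set")
  block_mean(matrix, seed, target_regions)
}

#' Lobe-coherence profile of one connectivity matrix
#'
#' Tidy table of local (within-lobe) and long-range (occipital seed) mean
#' coherence values for the four lobes of both hemispheres, plus the specific
#' interhemispheric-occipital and occipito-temporal blocks analyzed in
#' stroke-cohort studies.
#'
#' @param matrix Labeled connectivity matrix.
#' @param atlas Atlas table in the matching frame.
#' @return Data frame with columns `block`, `value`.
#' @export
lobe_profile <- function(matrix, atlas) {
  hemis <- unique(atlas$hemisphere)
  lobes <- setdiff(unique(atlas$lobe), "Other")
  rows <- list()
  for (h in hemis) for (lb in lobes) {
    regs <- intersect(lobe_regions(atlas, lb, h), rownames(matrix))
    if (length(regs) >= 2)
      rows[[length(rows) + 1L]] <- data.frame(
        block = sprintf("local_%s_%s", lb, h),
        value = local_coherence(matrix, lb, h, atlas))
  }
  for (h in hemis) {
    rows[[length(rows) + 1L]] <- data.frame(
      block = sprintf("long_Occipital_%s_rest", h),
      value = long_coherence(matrix, "Occipital", h, atlas))
  }
  h1 <- hemis[1]; h2 <- hemis[2]
  rows[[length(rows) + 1L]] <- data.frame(
    block = sprintf("Occipital_%s_Occipital_%s", h1, h2),
    value = long_coherence(matrix, "Occipital", h1, atlas,
                           targets = list(lobe = "Occipital", hemisphere = h2)))
  for (h in hemis) {
    rows[[length(rows) + 1L]] <- data.frame(
      block = sprintf("Occipital_%s_Temporal_%s", h, h),
      value = long_coherence(matrix, "Occipital", h, atlas,
                             targets = list(lobe = "Temporal", hemisphere = h)))
  }
  do.call(rbind, rows)
}
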