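---
title: "Methods: EEG functional connectivity networks in hemianopic stroke cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG functional connectivity networks in hemianopic stroke cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcnet)
```

## The problem

Occipital stroke produces homonymous hemianopia: loss of up to half of the
visual field in both eyes. Non-invasive brain stimulation (combined tACS/tDCS)
can partially restore visual function, and the working hypothesis is that
recovery is mediated by a reorganization of the brain's functional
connectivity network (FCN) — the graph whose nodes are atlas-parcellated brain
regions and whose edges quantify oscillatory synchronization between their
resting-state EEG signals.

`fcnet` implements the full analysis chain for such cohorts: signal
conditioning, band-limited imaginary coherence between 90 atlas regions,
graph-theoretic network measures under proportional thresholding, local and
long-range lobe coherence in a lesioned/intact hemisphere frame, responder
classification from visual-field change, and the statistical battery
(mixed-design ANOVA with Greenhouse–Geisser correction, Tukey–Kramer post-hoc
tests, Pearson correlation, Mann–Whitney U). Because patient EEG is not
publicly deposited, the package ships a synthetic cohort generator with fully
known ground truth, so that every stage has a parameter-recovery benchmark.

## Connectivity estimator

For two regions with tapered epoch spectra $S_{1n}(f)$, $S_{2n}(f)$
($n = 1,\dots,N$ epochs), the coherency is

$$
C_{12}(f) \;=\;
\frac{\sum_n S_{1n}(f)\, S_{2n}^{*}(f)}
     {\sqrt{\sum_n |S_{1n}(f)|^2 \;\sum_n |S_{2n}(f)|^2}},
$$

and the band connectivity value is the unweighted mean over band bins of
$|\mathrm{Im}\,C_{12}(f)|$ (absolute value per bin, then the band average).
Discarding the real part removes all zero-phase-lag synchronization. Since
instantaneous mixing of sources (volume conduction, reference effects) can
only produce zero-lag correlations, imaginary coherence (icoh) is insensitive
to this class of spurious connectivity — the property the synthetic mixing
benchmark verifies directly.

Numerical notes:

* The normalization carries the square root of the product of the summed
  power spectra. This guarantees $|C_{12}| \le 1$ (Cauchy–Schwarz) and scale
  invariance; `imaginary_coherence()` is exactly invariant under positive
  per-channel rescaling.
* Spectral decomposition is a Hann-tapered FFT per 2-s epoch (0.5-Hz bins);
  cross-spectra are summed over epochs exactly as in the formula. The taper is
  switchable (`taper = "none"`), the default is Hann.
* Band membership of a bin is the closed interval $[lo, hi]$. The seven bands
  are Delta (1–3), Theta (4–7), Alpha1 (8–10), Alpha2 (11–13), Beta1 (14–21),
  Beta2 (22–30), and Alpha (8–13 Hz); edges are inclusive, so 13 Hz belongs to
  both Alpha2 and Alpha, and 3.5 Hz to no band.
* The diagonal is set to 0 (auto-coherency is real, so its imaginary part
  vanishes identically).
* Whether to take $|\cdot|$ per bin or after band-averaging is genuinely open;
  per-bin is the default because it keeps the value a mean of per-bin
  magnitudes in $[0,1]$ regardless of phase sign changes across the band.

## Preprocessing

`condition()` applies, in order: an order-4 Butterworth band-pass (default
1–145 Hz), a 50-Hz notch (RBJ biquad, quality factor 30), polyphase
resampling to 250 Hz, and common average referencing. Phase must be preserved
for coherence estimation, so the IIR designs are applied as zero-phase
filters: the spectrum is multiplied by the magnitude-squared response
$|H(f)|^2$, which is exactly the response a forward–backward (filtfilt) pass
applies, without the recursion's edge transients (boundary effects become
circular and are negligible for band-limited signals). Two consequences:

* Re-conditioning already-conditioned data is idempotent up to passband
  ripple (the tested invariant: re-running changes per-channel RMS by < 1%).
  For data already at the target rate, the upper band edge is clipped to
  0.45·fs, since a 145-Hz edge is meaningless above the 125-Hz Nyquist of
  250-Hz data.
* Common average referencing is skipped below 3 channels, where subtracting
  the channel mean would make the channels collinear and destroy the
  imaginary part of any cross-spectrum.

`segment_epochs()` reads "2-s epochs with 0.5-s overlap" literally: epoch
starts form an arithmetic sequence with step 1.5 s (0.5 s of *shared signal*,
not 50% overlap), so 300 s yield $\lfloor(300-2)/1.5\rfloor + 1 = 199$
epochs. The alternative 50% reading is one parameter away
(`overlap_s = 1`). Only full epochs are kept; samples are copied verbatim.

An ICA artifact-removal hook (`remove_artifacts()`) exists as an identity
pass-through: synthetic recordings are artifact-free, and real data can plug
in an external cleaner.

## Graph metrics and thresholding

`proportional_threshold()` retains the fraction $p$ (default 0.30) of
strongest edges of the $K(K{-}1)/2$ possible ones and binarizes. The retained
count is round-half-up of $p \cdot E$; ties at the cutoff break by ascending
(row, column) index, so the operation is deterministic and depends only on
the rank order of the weights (any strictly monotone weight transform yields
the same graph — a tested invariant).

Convention (parameterized, defaults declared here): node **strength** is the
row sum of the full weighted matrix; **clustering**, **characteristic path
length** (CPL), and **betweenness** are computed on the thresholded binary
graph, because their defining formulas use integer degree and triangle
counts:

$$
C_i = \frac{2 t_i}{K_i (K_i - 1)} \ (C_i = 0 \text{ for } K_i < 2), \qquad
C = \frac{1}{n}\sum_i C_i, \qquad
L = \frac{1}{n}\sum_i l_i,
$$

with $l_i$ the mean shortest-path distance from node $i$. Shortest paths are
unweighted; $l_i$ averages only finite distances, and a fully isolated node
contributes $l_i = 0$ and is flagged (`$isolated`), making the
disconnected-component policy auditable. A graph with no edges has no defined
CPL and is rejected. Betweenness is the standard shortest-path count
(each unordered pair once), unnormalized by default with a
$(n-1)(n-2)/2$ normalization switch.

Shortest paths, local transitivity, and betweenness are delegated to
`igraph`; the test suite checks all three against independent brute-force
oracles (Floyd–Warshall, exhaustive triangle counting, explicit enumeration
of every shortest path) on dozens of random graphs.

## Atlas topology and the lesion frame

The packaged 90-region table follows the standard automated anatomical
labeling scheme (45 regions per hemisphere). Occipital subregions (calcarine,
cuneus, lingual, superior/middle/inferior occipital) map to the Occipital
lobe; limbic and subcortical structures (cingulate, hippocampus,
parahippocampal, amygdala, basal ganglia, thalamus, insula, olfactory) map to
"Other" and are excluded from the four-lobe coherence profile. Which
structures count toward a "lobe" is not fully standardized; the packaged CSV
is the single point of truth and this paragraph its documentation.

`relabel_frame()` maps anatomical left/right labels to lesioned/intact labels
(`*_LH`, `*_IH`) given the patient's lesion side, so patients with left and
right lesions can be pooled; applied twice it returns the original frame.
`local_coherence()` is the unweighted mean over within-lobe region pairs;
`long_coherence()` is the unweighted mean over the seed-lobe × target block
(default: occipital seed against all other lobes of both hemispheres,
excluding "Other"). Block means are unweighted over region pairs — no
weighting scheme is claimed by the analysis this package reproduces, and the
full profile then equals the block-size-weighted average of the per-lobe-pair
values (a tested consistency identity).

## Behavioral cohort and responders

The packaged 24-patient table carries high-resolution perimetry counts
(black/gray/white), gray/white reaction times, and perimetric visual-field
sensitivity (FOV, dB) at three time points, plus group (0 = Sham, 1 = AC,
2 = ACDC), lesion age, gender, and age. Summary display values are
**truncated** (not rounded) to two decimals — the convention of the printed
table, which e.g. shows a mean age of 57.37 for an arithmetic mean of 57.375.
One printed cell (the gray reaction-time Pre mean, 0.51) does not match the
arithmetic mean of its own column (0.5225); reaction-time means are therefore
excluded from the regression checks.

A **responder** is a patient whose FOV percentage change from baseline is
strictly above zero. The comparison time point is a parameter (default Post;
on the packaged table both Post and FU yield 10 responders / 14
non-responders, with one membership swap).

## Statistics

* `mixed_anova()` — two-way mixed (split-plot) ANOVA, between = group,
  within = time, fitted as a multivariate linear model with sum-to-zero
  contrasts (required for type-3 tests) via `car::Anova`. Mauchly's W tests
  sphericity of the within factor; Greenhouse–Geisser epsilon and corrected
  p-values are always reported, and `p_report` applies the correction only
  when Mauchly rejects at 0.05. With two within levels sphericity holds
  trivially (W = 1, ε = 1). With a single group the model reduces to one-way
  repeated measures — the form used for within-group analyses. Note that
  "GG-corrected p ≥ uncorrected p" is a *tail* property: shrinking both
  degrees of freedom can lower mid-range p-values (crossover near F ≈ 1.4);
  the correction is conservative where tests reject, which is what the suite
  asserts.
* `tukey_kramer()` — pairwise comparisons from the pooled error mean square
  with the unequal-n Tukey–Kramer standard error and studentized-range
  p-values; reduces to the pooled-variance t test at two groups via
  $q = \sqrt{2}\,|t|$.
* `pearson_cor()` — sample correlation with the two-sided t-based p.
* `mann_whitney_z()` — U counts pairs with ties at 1/2; z uses the
  tie-corrected normal approximation, continuity correction off by default
  (switchable); `exact = TRUE` computes the permutation p by full enumeration
  for small samples. At complete separation with $n_1 = 10$, $n_2 = 14$,
  $U = 140$ and $z = 70/\sqrt{10\cdot 14\cdot 25/12} \approx 4.099$.
* No multiple-comparison adjustment is applied across region × band tests by
  default, mirroring the exploratory analysis convention; a
  Benjamini–Hochberg pass can be applied externally via `p.adjust`.

## The synthetic cohort generator

No generative model for patient EEG is published, so every simulator choice
is an explicit artifact decision:

* **Oscillators** are Gaussian white noise band-pass filtered (zero-phase,
  order-4 Butterworth) to a stated band — stationary, with analytically
  tractable spectra.
* **Coupling** injects one shared oscillator into two regions with a time lag
  (default a quarter cycle of the band center, which maximizes
  $|\mathrm{Im}\,C|$) and strength $s \in [0,1]$; the receiving region blends
  the lagged copy with an independent same-band oscillator at weight
  $\sqrt{1-s^2}$, keeping its band power constant across strengths so that
  estimated icoh isolates the coupling itself.
* **Volume conduction** is a separate instantaneous mixing matrix applied
  last (after signal and noise assembly). Lagged coupling and zero-lag
  cross-talk are therefore distinct entries of the ground truth, and
  imaginary coherence must respond to the first and not the second.
* **SNR** is band-limited oscillatory variance over broadband white-noise
  variance, recorded in every ground truth (default 5 — a strong
  resting-state rhythm).
* The desk-scale montage has 10 regions: per hemisphere one frontal,
  temporal, and parietal region plus two occipital subregions, so
  within-lobe, interhemispheric-occipital, and occipito-temporal coherence
  are all expressible at 10 nodes. The full 90-region montage is available
  (`montage = "aal90"`).

`simulate_cohort()` emulates the study layout: three groups (Sham, AC, ACDC)
of eight patients, three time points, lesion side randomized, 5-min-class
recordings (default 60 s for desk-scale work; the spectral estimator's epoch
count is what matters, and tests state their durations explicitly). Injected
effects mirror the reported phenomenology and default to: +0.3 alpha coupling
into the lesioned superior occipital region at follow-up (ACDC), −0.2 delta
interhemispheric occipital coupling at Post (ACDC), +0.2 low-beta intact
occipito-temporal coupling at Post (ACDC), a mean FOV gain of +1 dB in ACDC
(none elsewhere — the published FOV group effect is a trend, not a
significant main effect), and a negative FOV–CPL association: the FOV change
of ACDC patients is decreased by `fov_cpl_slope` (default 1) times the
standardized alpha-band CPL computed from their own simulated recordings,
plus noise (SD 1.2 dB). With slope 1 and noise 1.2 the implied correlation is
about −0.8 at the default sample size, the magnitude reported for real
cohorts.

The generator has two layers. The **signal layer** (recordings with couplings
and mixing) feeds the estimator benchmarks: coupling-ladder recovery,
volume-conduction insensitivity, ranking checks, FOV–CPL recovery. The
**latent metric layer** (a per-subject `alpha_occ_strength` column with
subject intercept SD 1, residual SD 1, and a +1.5-residual-SD shift for ACDC
at FU) feeds the statistical simulations — type-I error and power over
hundreds of cohorts, where full EEG synthesis would be pointless cost: the
ANOVA consumes one number per subject per time point either way. Power for
the 1.5-SD effect is ≈ 0.48 under the full three-group mixed design (the
time main effect is diluted threefold) and ≈ 0.83 for the within-ACDC
repeated-measures analysis, the form actually used for within-group
questions.

What the generator does **not** emulate: 1/f background spectra, artifacts
(blinks, cardiac), non-stationarity, individual head geometry, or any source
reconstruction — the simulator produces region-level series directly. Passing
tests therefore validate the estimators and statistics, not the
sensor-to-source chain of real recordings.

## Monte-Carlo null and the volume-conduction benchmark

`icoh_null()` simulates mutually independent white-noise channels at a
matched epoch count through the package's own estimator. Because the
volume-conduction benchmark screens *all* pairs and *all* seven bands at
once, the appropriate null statistic is the **maximum** over pairs and bands
(`statistic = "max"`): comparing each of ~40 values against a per-value 95th
percentile would flag ~5% of them by construction. The benchmark then
requires the mixed recording's maximal band icoh to stay below the 95th
percentile of the max-statistic null while ordinary magnitude-squared
coherence of the mixed pairs exceeds 0.5.

## Pipeline and reproducibility

`run_pipeline()` chains simulate → condition → connectivity → relabel →
graph/lobe metrics → responders → statistics, writing per-subject per-band
coherence matrices, tidy metric and lobe tables, responder labels,
statistical tables, a config snapshot, and a log; every output row carries
the config snapshot's MD5 hash. All randomness derives from the single config
seed, and re-running a config byte-reproduces every numeric output (tested).
A thin command-line wrapper ships at `inst/cli/fcnet.R`.

## Problem sizes used by the test suite

Unit benchmarks use 2–10-channel recordings of 8–300 s at 250 Hz (2-s epochs,
0.5-s overlap), 50-graph oracle batches at 6–12 nodes, 1000-replicate
Monte-Carlo nulls, 1000-replicate ANOVA null simulations, and 100-cohort
power batches on the latent layer — sizes chosen so the whole suite runs in a
few minutes on one core while keeping every Monte-Carlo margin wide.

## Known limitations

* Imaginary coherence is insensitive to true zero-lag physiological coupling
  by construction, not only to volume conduction.
* The finite-distance CPL convention makes disconnected graphs comparable at
  the cost of rewarding fragmentation slightly; the `disconnected` flag and
  isolated-node report exist so users can filter.
* The generator's behavioral table matches the printed cohort's scale but not
  its covariance structure (e.g., reaction times are independent across time
  points).
* Whether strength/centrality should be computed on weighted or thresholded
  graphs is not standardized; the package's convention (strength weighted,
  the rest thresholded) is a declared, switchable default.
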