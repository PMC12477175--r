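---
title: "Quantifying killer T-follicular cells in lymphoid tissue: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying killer T-follicular cells in lymphoid tissue: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfkscope)
```

## The biological question

Germinal centers (GCs) inside B-cell follicles are where B cells mature
under the supervision of CD4⁺BCL6⁺ T-follicular helper (T~FH~) cells.
A subset of T~FH~-like cells additionally carries cytotoxic granule
cargo (TIA-1/NKG7, granzymes) — killer T-follicular cells, here called
T~FK~ (imaging definition CD4⁺BCL6⁺TIA-1⁺). Their abundance, their
localization relative to follicles and GCs, and their physical contact
with FOXP3⁺ regulatory T cells are informative readouts when comparing
reactive lymph nodes with follicular lymphoma of increasing grade.

`tfkscope` implements the image-quantification chain behind those
readouts so that every step — from raw multi-channel confocal images to
group-level p-values — is reproducible, parameterized and testable.

## The measurement model

The pipeline assumes 4–5 channel immunofluorescence of FFPE tissue
sections (CD19/CD4/BCL6/TIA-1 for localization, FOXP3/CD4/BCL6/TIA-1
for the Treg contact panel). Stages, in order:

1. **Background correction, then deconvolution.** The background of
   each channel is estimated by grayscale morphological opening with a
   disc of radius 50 px (≥ 5× the default cell radius) and subtracted;
   this is the rolling-ball idea in morphological form. Optional
   Richardson–Lucy deconvolution with a normalized Gaussian PSF
   (default σ = 2 px, 10 iterations) may follow. `preprocess()`
   refuses the reverse order unless explicitly overridden, because the
   background estimate is only valid on un-deconvolved data and
   downstream thresholds assume corrected input. Deconvolution is off
   by default: on synthetic data, recovery is already exact without
   it, and Richardson–Lucy amplifies noise.
2. **Denoising and per-channel thresholds.** Channels are smoothed
   with a small Gaussian (σ = 1 px, configurable) and thresholded with
   Otsu's method. Acquisition gain differs between tissues, so
   thresholds are always per channel and per sample, and the chosen
   value is recorded for audit. Otsu assumes a meaningfully bimodal
   histogram; on sparsely stained channels (TIA-1, FOXP3 — a few
   hundred positive cells in a megapixel field) the optimum can fall
   inside the background. We therefore re-fit Otsu on the
   above-threshold pixels whenever the resulting mask would cover more
   than 25 % of the field (`max_fg_frac`), reflecting the prior that
   stained cells occupy a minority of tissue area. Manual and quantile
   thresholds are available as overrides.
3. **Colocalization phenotyping.** Connected components (8-connected
   by default, matching common particle-analysis behavior) of the
   pixelwise AND of two marker masks are candidate double-positive
   cells. Components smaller than 20 px or larger than 200 px are
   discarded — bounds inclusive, since the reference procedure deletes
   ROIs *strictly* larger than 200 or smaller than 20 px — but kept in
   a discard ledger so that retained + discarded always equals the
   component total. GC-B cells are CD19⁺BCL6⁺ ROIs; CD4⁺BCL6⁺ ROIs
   split into T~FK~ (≥ 50 % of ROI pixels TIA-1⁺, `tia1_overlap_frac`)
   and T~FH~ (otherwise), so the two counts always sum to the retained
   CD4⁺BCL6⁺ count. The 50 % split fraction is a package choice — the
   reference workflow overlays channels without stating a fraction —
   and is exposed as a parameter. In the FOXP3 panel, CD4⁺BCL6⁺ ROIs
   with ≥ 25 % FOXP3 overlap are rerouted to a separate T~FR~-like
   class rather than contaminating the T~FH~/T~FK~ split.
4. **Intensity-profile confirmation.** Each T~FK~ candidate is probed
   along a horizontal line through its centroid (half-length 15 px).
   The candidate passes when CD4, BCL6 and TIA-1 all peak inside the
   candidate's pixel span above their channel thresholds, and CD19
   does not. This formalizes a visual confirmation step; the pass/fail
   flag is recorded per call and never silently drops calls.
5. **Regions and allocation.** Follicle and GC regions come either
   from imported ImageJ ROIs (`import_regions()`, the reference
   procedure: regions drawn manually on CD19/BCL6 staining) or from
   `auto_regions()`, an automated stand-in that closes, hole-fills and
   size-filters the CD19 mask (follicles) and the BCL6 mask (GCs,
   clipped to their follicle). GC pixels are always a subset of their
   parent follicle's pixels, so a cell centroid lookup resolves
   boundary ties inward (GC over follicle over outside) and every
   GC-assigned cell counts toward its follicle. Allocation is by
   centroid containment: one unambiguous compartment per cell.
   Morphometry (areas in px² and µm², counts, coverage fractions on
   the union of regions) comes from pixel counting.
6. **Tregs and contacts.** A CD4 cell is a Treg when at least 25 % of
   its own pixels are FOXP3⁺ (inclusive threshold, denominator the
   cell's own area). A T~FK~–Treg pair is "in direct contact" when the
   boundary gap between their pixel sets is at most 1 background pixel
   in the chessboard metric — the smallest non-degenerate digital
   adjacency that allows diagonal touching. The reference procedure
   checked contacts by eye; the gap tolerance is a parameter
   (`max_gap_px`) so its sensitivity can be explored.
7. **Statistics.** Per-sample summaries (counts, the T~FK~-of-T~FH~
   percentage, compartment percentages of all detected T~FK~,
   morphometry, contact percentage) feed `compare_groups()`, which
   dispatches to a two-sided Mann–Whitney test for two groups or
   Kruskal–Wallis for more. The Mann–Whitney p is exact (full
   enumeration) for combined n ≤ 12 without ties — group sizes in this
   setting are single-digit numbers of patients — and otherwise uses
   the normal approximation with tie and continuity correction.
   Significance stars follow the convention used for these readouts:
   `*` p < 0.05, `**` p < 0.005 (note: 0.005, not the usual 0.01),
   `***` p < 0.001, `****` p < 0.0001. Percentages with an empty
   denominator are `NA` and excluded (with a report), never coerced to
   zero. No multiple-testing correction is applied by default,
   matching the reference analysis; only the nonparametric tests are
   exposed because the per-sample metrics are small-n counts and
   percentages with no distributional guarantee.

## The synthetic-tissue generator

Patient FFPE slides are not public, so validation rests on
`simulate_tissue()`: a forward model whose ground truth (cell
phenotypes, positions, compartments, contact pairs) is known exactly.

Default study conditions (all configurable via `synth_config()`):

* 1024 × 1024 px field at 0.5 µm/px — plausible for a 20×/0.8
  objective; no calibration was published, so absolute µm² values are
  nominal.
* 3 elliptical follicles (major semi-axis 140 ± 10 px, axis ratio
  0.7–1.0) with concentric GCs at 0.6 of the follicle radius;
  follicles pairwise disjoint and fully inside the field.
* 300 cells: 90 B, 60 GC-B, 60 T~FH~, 20 T~FK~, 40 Treg, 30
  bystanders, each a hard disk of radius 4 ± 0.5 px (truncated to
  3.2–5.5 px so every planted cell renders inside the 20–200 px
  measurable window that the area filter defines).
* Compartment placement probabilities per type (GC-B always in GCs;
  T~FH~ mostly GC; T~FK~ 0.5/0.3/0.2 over GC/follicle/outside; Tregs
  mostly interfollicular).
* Marker amplitudes of 1.0 on each positive channel (B→CD19;
  GC-B→CD19+BCL6; T~FH~→CD4+BCL6; T~FK~→CD4+BCL6+TIA-1;
  Treg→CD4+FOXP3; bystanders CD4 only), Gaussian PSF σ = 1.5 px, a
  low-frequency background ramp of amplitude 0.1, and additive
  Gaussian noise clipped at zero.
* Non-contact cells keep a center distance of at least the radius sum
  plus 6 px so that blurred, thresholded blobs remain separable —
  ground-truth counts are then unambiguous. Planted contact pairs are
  placed with exactly touching boundaries. An `allow_overlap` flag
  exists for stress tests.

What the generator deliberately does **not** emulate: photon (Poisson)
statistics, spectral bleed-through, mantle-zone asymmetry, dark/light
GC zonation, 3-D structure, or touching/overlapping cells of the same
marker. Passing recovery tests therefore demonstrates correctness of
the measurement chain, not robustness to every artifact of real
confocal data; on real images the per-sample thresholds and the
optional manual-ROI route are expected to carry more weight.

## Numerical choices and degenerate inputs

* Images are numeric matrices indexed `[row, col]`, 1-based, pixel
  centers at integers; ImageJ ROI coordinates (0-based, corner origin)
  are shifted on import. Writers quantize to 16-bit TIFF.
* Otsu on a constant channel is undefined: the package returns an
  empty mask with a warning. An all-tied Kruskal–Wallis input returns
  H = 0, p = 1 with a warning. A contact percentage with zero T~FK~
  is flagged undefined.
* 4-connected labeling is delegated to `EBImage::bwlabel`;
  8-connectivity merges diagonally touching 4-components via a label
  adjacency graph. Both agree with a flood-fill oracle in the tests.
* `auto_regions()` grows its final masks by 4 px (`grow_px`) to
  compensate for the margin between the outermost cell bodies and the
  anatomical boundary. Region proposal from membrane staining needs
  reasonably confluent CD19 signal; with the sparse default cell
  counts it still finds every follicle but underestimates their
  extent, which is why allocation validation uses the generator's true
  regions (the analogue of the manually drawn ROIs) and region
  recovery is tested on a denser configuration.
* Per-sample aggregation sums counts over a sample's images before
  computing percentages; `compare_groups()` refuses groups reduced
  below two samples by undefined-metric exclusions.

## Problem sizes used in validation

The shipped tests and the acceptance script run the full pipeline on
1024² fields with 300 planted cells (about 7–10 s per field), ten
noisy replicates for the ±5 % recovery check, exhaustive Mann–Whitney
enumeration up to combined n = 10, and 100-replicate power
simulations at n = 8 per group. These sizes were chosen so the whole
validation suite completes comfortably on a laptop-class single core
while still exercising every stage at realistic densities.

## Known limitations

* The T~FH~/T~FK~ split fraction (50 %) and the profile pass criteria
  formalize steps the reference workflow performed by eye; both are
  parameters, and their defaults are package choices.
* Colocalization is pairwise-with-split, not full 2⁴ marker
  combinatorics; touching same-marker cells are not watershed-split by
  default (an optional 4-connectivity or manual threshold can help;
  the generator's non-overlap guarantee makes the default sound on
  synthetic data).
* Contact detection is 2-D; a gap tolerance in pixels is not a synapse
  measurement.
* Whether per-sample averages should pool per image or per region
  before comparison can matter for unbalanced samples; both routes are
  possible by summing inputs before `summarize_sample()`, which
  reports exactly what it pooled.
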