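# tfkscope

Quantification of cytotoxic ("killer") T-follicular cells in multiplex
immunofluorescence images of lymphoid tissue.

## What it does, and for whom

Killer T-follicular cells (T<sub>FK</sub>, imaging definition
CD4⁺BCL6⁺TIA-1⁺) are T<sub>FH</sub>-like cells with cytotoxic granule
cargo. Counting them, locating them relative to B-cell follicles and
germinal centers (GCs), and measuring their direct contacts with
FOXP3⁺ regulatory T cells are the imaging readouts used to compare
reactive lymph nodes with follicular lymphoma of increasing grade.
`tfkscope` is for imaging scientists and hematopathology researchers
who want that quantification chain as reproducible, scriptable code
instead of an interactive macro workflow.

The pipeline:

1. **Preprocessing** — rolling-ball style background subtraction
   (grayscale opening, radius 50 px), optional Richardson–Lucy
   deconvolution with a Gaussian PSF; background correction always
   precedes deconvolution.
2. **Segmentation** — per-channel, per-sample Otsu thresholds (manual
   and quantile overrides), connected-component cell detection.
3. **Phenotyping** — colocalization ROIs: connected components of the
   pixelwise AND of two marker masks, filtered to the inclusive
   20–200 px area window (smaller or larger ROIs are discarded but
   ledgered). GC-B = CD19⁺BCL6⁺; CD4⁺BCL6⁺ ROIs split into
   T<sub>FK</sub> (≥ 50 % TIA-1⁺ pixels) vs T<sub>FH</sub>;
   candidates confirmed by intensity profiles through the centroid.
4. **Regions** — follicle/GC geometry from imported ImageJ ROIs
   (`.roi`/`.zip`) or proposed automatically from CD19/BCL6 masks;
   morphometry (areas, counts, coverage); allocation of each cell to
   GC / follicle / extrafollicular by centroid containment with
   inward boundary ties (GC counts also accrue to the parent
   follicle).
5. **Contacts** — Tregs are CD4 cells with ≥ 25 % FOXP3 overlap
   (inclusive); a T<sub>FK</sub>–Treg pair is in direct contact when
   the boundary gap is ≤ 1 px.
6. **Statistics** — per-sample summaries (e.g.
   100·T<sub>FK</sub>/(T<sub>FH</sub>+T<sub>FK</sub>), compartment
   percentages, contact percentage) compared with a two-sided
   Mann–Whitney test (exact by enumeration for combined n ≤ 12
   without ties) or Kruskal–Wallis for ≥ 3 groups; stars `*` p<0.05,
   `**` p<0.005, `***` p<0.001, `****` p<0.0001.

A synthetic lymphoid-tissue generator (`simulate_tissue()`) renders
follicles, GCs and marker-specific cell blobs with PSF blur,
background and noise, together with a full ground-truth table — so
every stage is validated against known truth. See the methods
vignette (`vignettes/tfkscope-methods.Rmd`) for the model, parameter
defaults and design decisions.

## Worked example

Simulate one 1024×1024 px sample (300 cells: 90 B, 60 GC-B, 60
T<sub>FH</sub>, 20 T<sub>FK</sub>, 40 Treg, 30 bystanders in 3
follicles) and analyse it against the generator's true regions:

```r
library(tfkscope)

cfg <- synth_config(seed = 7)
tis <- simulate_tissue(cfg)
res <- analyze_image(tis$image, regions = tis$regions)
res
```

```
<subtype_calls> [localization] GC-B=60, T_FH=60, T_FK=20
  sample_id n_gcb n_tfh n_tfk pct_tfk_of_tfh pct_tfk_in_gcs
1 synthetic    60    60    20             25             50
```

All 60 GC-B, 60 T<sub>FH</sub> and 20 T<sub>FK</sub> planted cells
are recovered exactly in the noiseless image; `pct_tfk_of_tfh` = 25 %
is 20/(60+20), and 50 % of the detected T<sub>FK</sub> sit inside a
GC (this sample's realisation of the 50 % planting probability).
Per-sample rows stack into group comparisons:

```r
s1 <- res$summary                    # one row per sample
comp <- compare_groups(rbind(sA, sB, sC), metric = "pct_tfk_of_tfh")
comp                                 # test, statistic, p, stars, n per group
```

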