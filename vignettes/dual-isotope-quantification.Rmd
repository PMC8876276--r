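---
title: "Quantifying ligand-ASO conjugates in NanoSIMS images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ligand-ASO conjugates in NanoSIMS images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sims34)
```

## The measurement problem

NanoSIMS rasters a Cs+ primary beam over a resin section and counts, per
pixel and per detector, the secondary ions of several species at once —
here ^13^C^12^C^-^ and ^13^C^14^N^-^ (cellular structure), ^32^S^-^ and
^34^S^-^ (sulfur isotopes), and ^127^I^-^. An antisense oligonucleotide
(ASO) with a phosphorothioate backbone can carry ^34^S at each labelled
linkage (15 or 19 per molecule in the designs considered here), and a
targeting peptide such as eGLP1 can carry two ^127^I atoms via
diiodotyrosine. The task is to turn raw ion counts into per-molecule drug
and ligand signal maps, and to decide, per endosome-scale region, whether
ligand and drug are still together (a coupled conjugate) or have separated.

Two obstacles shape the whole pipeline:

* **Sulfur is everywhere.** The endogenous sulfur density varies by about
  two orders of magnitude across a cell, so raw ^34^S counts mostly track
  local biology, not drug. The drug signal must be measured as ^34^S counts
  *in excess* of what the local ^32^S counts predict at the average isotope
  ratio. Unlabelled material sits at the natural ^34^S/^32^S abundance,
  1/22.22 = 0.0450045 (the CDT reference, exported as `CDT_S34_S32`).
* **Counting noise.** Ion counts are Poisson. A 256 × 256 ratio image has
  ~65000 pixels with a measurement, so chance alone puts
  `expected_exceedance_count(65536, 1)` ≈ 1.04 × 10^4 pixels above 1σ;
  per-pixel thresholding cannot isolate sparse enrichment. Counts are
  therefore accumulated over planes and binned into ~468 nm blocks before
  any threshold is applied.

## The pipeline

1. **Stack I/O and alignment** (`read_stack`, `align_planes`,
   `accumulate`). Sequential planes are realigned to the first plane by the
   integer-pixel shift maximising the cross-correlation of the structural
   CN channel (computed via FFT); the same shift is applied to all channels
   and shifted-in borders are zero-filled. Integer shifts keep count
   semantics exact; sub-pixel interpolation would turn integer counts into
   reals and correlate neighbouring pixels. Offsets above a quarter of the
   image width are treated as registration failures, warned about and
   clamped. Accumulation is a plane-wise sum, conserving totals exactly
   when no shift was applied.
2. **Signal maps** (`mean_sulfur_ratio`, `aso_signal_map`,
   `ligand_signal_map`). The average sulfur ratio is the ratio of channel
   totals (Σ^34^S / Σ^32^S), not the mean of per-pixel ratios: the ratio of
   sums is the bulk-isotope convention and is robust to low-count pixels
   (the per-pixel mean is exposed as an option for sensitivity checks).
   The ASO map is
   `(counts34 − counts32 × ratio_ave) / (N_labels × counts13C12C)`,
   and the ligand map `counts127I / (N_labels × counts13C12C)`. Pixels
   whose ^13^C^12^C counts fall below a floor (default 1) are masked
   rather than clipped or pseudocounted — an empty pixel carries no
   information and must not fabricate signal. Negative ASO values are
   retained: under the null they are ordinary downward sampling
   fluctuations, and in treated images the per-image `ratio_ave` is pulled
   up by the labelled material, which systematically pushes unenriched
   regions negative — the very effect the coupled/decoupled sign rule
   reads out.
3. **Binning and ROI selection** (`bin_counts`, `build_roi_table`). Counts
   are summed over k × k blocks with k = round(468 / pixel size) (6 px at a
   20 µm field, 78.125 nm/px, realising 468.75 nm bins; 5 px at 25 µm; 8 px
   at 15 µm); trailing partial blocks are dropped. Signals are recomputed
   from the summed counts — the Poisson-optimal aggregate — never averaged
   from per-pixel ratios, which differ on heteroscedastic blocks and are
   unstable at low counts. A bin is selected as a ligand ROI when its
   ligand value exceeds 3 × the standard deviation of all unmasked bin
   values, taking "3σ" literally (a mean + 3σ variant is available via
   `threshold_rule`). A zero-variance ligand image is flagged as degenerate
   and falls back to selecting positive bins.
4. **Coupling classification** (`classify_coupling`, `coupling_summary`).
   A selected ROI with strictly positive ASO signal is "coupled", otherwise
   "decoupled" (a tie at exactly 0 is decoupled, keeping "positive"
   strict). The rule is scale-free: any positive rescaling of the ASO map
   leaves classes unchanged. Because one endosome can straddle several
   468 nm bins, `coupling_summary(..., collapse = "components")` merges
   adjacent selected bins into one ROI per structure, classified by the
   sign of its summed ASO value; use this when counting structures, and the
   default when counting bins.
5. **Hotspot analysis** (`hotspot_rois`). ^34^S hotspots are connected
   components above a percentile of the ^34^S/^32^S ratio image; ^32^S
   hotspots are detected the same way on the raw ^32^S image. A ratio
   hotspot that overlaps a ^32^S hotspot is excluded (default: any overlap
   excludes), removing "enrichment" that merely tracks dense endogenous
   sulfur. Retained ROIs are annotated with their mean ASO signal; manual
   ROI label masks are accepted in place of automatic detection.
6. **Calibration** (`fit_linear_response`, `estimate_lod`,
   `check_dual_label_linearity`). Standards of known label concentration
   (2.6–260 µM, bracketing the ~100 µM endo-lysosomal accumulation expected
   from receptor numbers and endosomal volume) are fitted by ordinary least
   squares. The limit of detection uses the standard analytical-chemistry
   rule — the concentration whose predicted signal equals background mean
   + 3 × background SD (multiplier configurable). Equimolar dual-label
   standards are checked for mutual linearity by regressing the ligand
   signal on the ASO signal.

## The synthetic scene generator

No public raw instrument data accompany this method, so the package ships
a first-class simulator (`scene_params`, `make_scene`, `simulate_stack`)
whose draws are the test bed for every stage. It emulates exactly the
statistical structure the analysis relies on:

* per-pixel, per-plane, per-channel **independent Poisson counts** at
  ground-truth rates;
* an endogenous **sulfur density field** spanning two orders of magnitude
  (a smooth log-scale random field), a disc cell with a nucleus, and a
  structural density driving the carbon channels;
* **endosomes** as non-overlapping discs (default radius 400 nm) carrying
  the conjugate at a set concentration; each is coupled with probability
  `coupling_fraction` — a decoupled endosome keeps its ligand (^127^I) but
  has no excess ^34^S;
* optional **sulfur-dense bodies** at natural isotope abundance (the
  confound the hotspot exclusion removes) and **cumulative integer drift**
  matching the alignment model.

Defaults are fixed once and are the package's study conditions: 256 × 256
pixels, 20 µm field (78.125 nm/px), 10 planes, 5 ms dwell, yields of
20/50/5 counts · plane⁻¹ · px⁻¹ (at unit density) for ^13^C^12^C /
^13^C^14^N / ^32^S, natural ratio at CDT, endosome concentration 100 µM,
and `signal_per_uM_per_label = 1.1e-3` counts · plane⁻¹ · px⁻¹ · µM⁻¹ per
label. The last value is anchored so that, at the 468 nm bin scale and a
representative mid-cell sulfur density, 20 µM sits near 3σ above the
natural-abundance background — the detection-limit regime of the real
measurement (the blank-bin SD is
`sqrt(λ34 + r² λ32) / (N_labels × λC)`; `generator_lod()` returns the
closed form, and the simulated estimate lands on it to within a few
percent).

What the simulator does **not** model: sputter-yield and matrix effects,
detector dead time and quasi-simultaneous-arrival corrections, irregular
endosome shapes, 3-D section geometry, and mass interference. Passing
tests therefore validate the statistics of the analysis, not instrument
physics; absolute molar accuracy on real data still requires measured
standards.

### Conditions used for validation experiments

Coupling-fraction recovery is tested on 20 seeded scenes at a saturating
endosomal load (2000 µM, the regime of mM incubations where uptake is
receptor-saturated) with `coupling_fraction = 0.7` and 12 endosomes.
The load matters for a reason worth stating: a decoupled endosome has *no*
excess ^34^S, so its ASO value is centred below zero only because the
per-image average ratio is inflated by the coupled endosomes. A power
analysis of that bias (bias ≈ λ32,bin × Δ/Σ32 against a noise SD of
`sqrt(λ34 + r²λ32)`) shows it exceeds ~2σ at millimolar loads but drowns
at 100 µM — so at low loads the sign of a decoupled ROI is close to a coin
flip, a limitation inherent to the sign rule, not to this implementation.
Per-structure fractions are compared with exact (Clopper–Pearson) binomial
confidence intervals. Linearity of the endosome signal is checked at
50/100/200 µM on scenes with 4 endosomes (keeping the ratio-inflation bias
below the fit's confidence width), and calibration/LOD recovery uses
128 × 128 standard slabs and 10 seeds. These sizes keep the full suite
within a couple of minutes on one core while leaving every comparison
statistically meaningful.

## Numerical and interface choices

* **Interchange format**: multi-page 16-bit TIFF (plane-major, then
  channel) plus a JSON sidecar holding channel names, field of view, dwell
  time and plane count. Signal maps are exported as 32-bit scaled-integer
  TIFF with offset/scale in the sidecar (round-trip error ~1e-9), because
  native float TIFF writing is not available in the underlying TIFF
  library; `read_signal_map()` restores values exactly enough for any
  downstream use.
* **Coordinates**: 0-based physical convention documented as (dy, dx)
  row/column offsets applied to move a plane into the first plane's frame;
  R matrices are 1-based internally.
* **Ties and degeneracies**: ASO = 0 classifies as decoupled; zero-variance
  ligand images are flagged; an all-masked bin table errors
  (`"no valid bins"`); zero total ^32^S errors rather than returning NaN;
  LOD with non-positive slope errors (`"uncalibratable"`); LOD is floored
  at 0.
* **`ratio_ave`** defaults to the per-image ratio of sums; the CDT constant
  is available (`ratio_ave = "cdt"` in run configs) for cross-image
  comparisons. Whether to prefer per-image or fixed reference is a genuine
  judgement call: per-image absorbs instrument drift between fields but
  couples the baseline to the amount of label in the field; the package
  defaults to per-image and records the value used in every run log.

## Known limitations

* The sign rule classifies noise-limited decoupled ROIs correctly only
  when labelled material dominates the image sulfur budget (see the power
  analysis above); reporting both bin-level and component-level counts is
  recommended.
* Integer binning cannot realise 468 nm exactly for every field of view;
  the realised bin edge is logged and stored on every table.
* Drift correction is rigid and integer-valued; fields with rotation or
  shear would need external registration first.
* The LOD depends on the local sulfur density through the background SD;
  the reported value refers to the calibration matrix, not to every pixel
  of a heterogeneous cell.
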