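# sims34

Quantification of dual-isotope NanoSIMS images of ligand–antisense-oligonucleotide
(ASO) conjugates.

NanoSIMS imaging counts secondary ions per pixel for several mass channels at
once. An ASO can carry ³⁴S labels in its phosphorothioate backbone (15 or 19
per molecule) and a targeting peptide such as eGLP1 can carry two ¹²⁷I atoms,
so drug and ligand can be mapped independently in the same subcellular image.
The catch is that sulfur is abundant in cells — its density varies by ~2 orders
of magnitude across a single cell — and ion counts are Poisson, so the drug
signal must be measured as ³⁴S counts *in excess* of what the local ³²S counts
predict at the average sulfur isotope ratio, and all thresholding must happen
on physically binned, plane-accumulated counts.

`sims34` is aimed at analysts of subcellular isotope-imaging experiments. It
implements:

* stack I/O (multi-page TIFF + JSON sidecar), rigid integer drift correction
  and plane accumulation;
* the per-molecule scaled signal maps

  ```
  ASO    = (counts34 − counts32 × ratio_ave) / (N_labels × counts13C12C)
  ligand =  counts127I / (N_labels × counts13C12C)
  ```

  with the image-average ratio `ratio_ave = Σ34S/Σ32S` (natural abundance:
  ³⁴S/³²S = 1/22.22 = 0.0450045, the CDT reference);
* binning to ~468 nm blocks, ligand-ROI selection at 3σ, and classification of
  each selected ROI as **coupled** (positive excess-³⁴S, intact conjugate) or
  **decoupled** (non-positive, ligand without drug);
* hotspot-ROI analysis with exclusion of ³⁴S/³²S hotspots that merely track
  dense endogenous sulfur (³²S hotspots);
* linear calibration against standards of known label concentration with
  3σ-above-background limit-of-detection estimation and dual-label linearity
  checks;
* a seeded synthetic scene generator (Poisson counts, log-scale sulfur density
  field, labelled endosomes with a tunable coupled fraction, optional drift)
  providing ground truth for every stage.

## Worked example

Simulate a field of GLP1R-expressing cells at a saturating endosomal conjugate
load where 70% of endosomes carry the intact conjugate, then run the full
quantification:

```r
library(sims34)

p <- scene_params(seed = 42, endosome_conc_uM = 2000, coupling_fraction = 0.7)
truth <- make_scene(p)
stack <- simulate_stack(truth)
print(stack)
#> ion_count_stack: 10 plane(s), 5 channel(s), 256x256 px
#>   FOV 20 um (78.125 nm/px), dwell 5 ms
#>   total counts: 13C12C=8.834e+06, 13C14N=2.208e+07, 32S=2.547e+07, 34S=1.445e+06, 127I=4.378e+04

acc <- accumulate(align_planes(stack))
mean_sulfur_ratio(acc)
#> [1] 0.0567456

binned <- bin_counts(acc, 468)          # 6 px blocks -> 468.75 nm bins
tab <- build_roi_table(binned, p$conjugate)
coupling_summary(tab, collapse = "components")
#> coupling_summary: 11 coupled, 1 decoupled (fraction 0.917)

mean(ground_truth_table(truth)$is_coupled)   # realized truth for this seed
#> [1] 0.9166667
```

The measured average ratio (0.0567) sits above the natural 0.0450 because the
labelled endosomes inflate the image's ³⁴S budget — exactly the effect that
pushes unenriched (decoupled) regions to negative excess. At this seed 11 of
12 endosomes were drawn coupled, and the pipeline classifies all 12 ligand
structures correctly. `run_conjugate_analysis()`, `run_hepatocyte_analysis()`
and `run_calibration()` wrap these steps into configured, logged runs (YAML
configs via `read_run_config()`; a thin CLI lives in `inst/scripts/sims-cli.R`).

The closed-form detection limit implied by the generator's defaults is
`generator_lod(p)$lod_uM` ≈ 20.8 µM, and the calibration module recovers it
from simulated 2.6–260 µM standards to within a few percent.

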