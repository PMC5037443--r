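# cartT2

Layer-specific femorotibial cartilage T2 relaxometry from multi-echo
spin-echo (MESE) knee MRI.

Cartilage T2 relaxation time tracks the composition of the cartilage
matrix (hydration, collagen content and orientation) and is studied as an
imaging biomarker of early knee osteoarthritis. Because T2 rises from the
bone interface to the articular surface, sensitive analyses split the
cartilage through its thickness into **deep** and **superficial** 50%
layers and compare them separately across subject groups. `cartT2`
implements that analysis chain for researchers working with quantitative
MRI cohorts:

1. **T2 mapping** — voxelwise fit of the mono-exponential decay
   S(TE) = S₀·exp(−TE/T₂) by Levenberg–Marquardt nonlinear least squares,
   with the first echo excluded (stimulated-echo contamination) and voxels
   with fit R² < 0.66 eliminated (low image quality).
2. **Laminar analysis** — normalized depth d = d_bone/(d_bone + d_surface)
   from exact Euclidean distance transforms of the segmentation's
   bone-interface and surface labels; superficial layer where d > 0.5;
   weight-bearing femoral region of interest; plate means for MT, LT, cMF,
   cLF and their unweighted femorotibial average.
3. **Cohort statistics** — pooled-variance t comparisons with 95% CIs,
   Cohen's d, ANCOVA adjustment for age/sex/BMI, Bonferroni multiplicity
   (0.05/6 for the primary 3-group × 2-layer family), paired one-year
   change tests and the superficial-vs-deep change contrast. Summary-mode
   functions reproduce published contrasts directly from printed
   mean ± SD (n) cells.
4. **Synthetic data** — MESE knee phantoms (slab and curved-shell plates,
   through-thickness T2 gradients, stimulated-echo bias, Gaussian/Rician
   noise) with exact voxelwise ground truth, and a three-group subject
   cohort simulator parameterized by published OAI reference-cohort
   summary statistics — so the entire pipeline is testable without
   access-controlled images.

## Worked example

Reproduce a published baseline contrast from its printed summary cells
(healthy vs. riskROA, superficial layer, 45.4 ± 2.3 ms n = 89 vs.
48.1 ± 3.1 ms n = 28):

```r
library(cartT2)
ref <- oai_t2_reference("avg")
h <- ref[ref$group == "healthy" & ref$layer == "superficial", ]
r <- ref[ref$group == "riskROA" & ref$layer == "superficial", ]
comparison_from_summary(h$baseline_mean, h$baseline_sd, h$n,
                        r$baseline_mean, r$baseline_sd, r$n)
#> <comparison> diff = -2.70 ms, 95% CI [-3.78, -1.62], p = 2.43e-06, d = -1.08 *
```

Healthy knees are 2.7 ms shorter in superficial T2 than risk-factor knees;
the effect is large (|d| ≈ 1) and significant at the Bonferroni-adjusted
0.05/6 level (the `*`). The one-year deep-layer change in healthy knees
(0.8 ± 1.3 ms, n = 89):

```r
change_from_summary(0.8, 1.3, 89)
#> <change> 0.80 +/- 1.30 ms, 95% CI [0.53, 1.07], p = 9.98e-08, n = 89
```

Run the imaging arm on a synthetic phantom with known truth
(deep 35.8 ms / superficial 45.4 ms, 2% noise):

```r
ph  <- generate_phantom(phantom_spec(noise_sd = 2, n_slices = 1, seed = 1))
map <- build_t2_map(ph$series, Reduce(`|`, ph$seg$plate_masks))
map
#> <t2_map> 2712 masked voxels, 2712 valid (100.0%), R^2 threshold 0.66
lab <- partition_layers(compute_normalized_depth(ph$seg, "MT"))
summarize_plate(map, lab, NULL, "MT")
#>   plate       layer mean_t2_ms n_voxels_valid n_voxels_total
#> 1    MT        deep   36.07706            320            320
#> 2    MT superficial   45.67138            320            320
```

The plate means land on the simulated deep/superficial levels, and the
superficial layer is correctly the longer one. `run_pipeline()` chains all
stages (phantom → T2 map → laminar summaries → the six primary group
comparisons) behind one seeded, provenance-tracked configuration; a thin
command-line wrapper lives at `inst/cli/cartt2.R`.

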