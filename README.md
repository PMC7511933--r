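# eaims — enzyme-activity imaging mass spectrometry analysis

Enzyme-activity MALDI imaging (EA-IMS) maps *where* enzymes are active in
a tissue section: a solution of peptide substrates for proteases, kinases
and phosphatases is spray-applied to the section, the section's
endogenous enzymes convert the substrates during incubation, and MALDI
imaging MS then records one spectrum per raster pixel in which both the
applied substrates and their conversion products appear at predictable
masses.  Because one enzyme converts many substrate molecules, the
readout is intrinsically amplified.

`eaims` is for analysts designing or evaluating such experiments.  It
implements the full computational chain:

* **Substrate panel arithmetic** — isotope-averaged (or monoisotopic)
  masses for every substrate and expected product.  A protease substrate
  cleaved after residue *c* yields two fragments with
  `M1 + M2 − M(H2O) = M(substrate)`; kinase/phosphatase products shift by
  ±HPO3 (79.980 Da average).  Modifications (phospho, MCA, DNP) are
  registered with deltas from elemental formulas.
* **Panel validation** — flags species below the ~600 Da MALDI background
  region and pairs of targets closer than two extraction half-widths
  (2 × 0.156 Da), which fixed-interval imaging cannot distinguish; plus a
  regression of computed against published masses with every deviation
  reported and known anomalies annotated.
* **Ground-truth simulation** — imzML/ibd studies on a kidney-like
  cortex/medulla phantom with per-region first-order kinetics
  `S(t) = S0·exp(−k·t)`, optional product degradation, per-species
  ionization factors, TOF-like peaks over m/z 400–2,200, a low-mass
  baseline hump and seeded noise; active time series (5/15/60/120 min),
  heat-inactivated and no-substrate controls.
* **Preprocessing** — convolution (top-hat) baseline removal (width 20
  points), ordinal-strength Gaussian smoothing, mean-interval extraction
  in closed ±0.156 Da windows.
* **Activity mapping** — ion images, conversion maps
  `f = ΣP / (ΣP + S)`, cortex/medulla ROI statistics, time courses,
  SNR-based detectability grades (−/+/++/+++), and rank-effect contrasts
  against controls.

## Worked example

```r
library(eaims)

lib <- load_library(system.file("extdata", "table1_library.tsv", package = "eaims"))
lib
#> Substrate library: 20 substrates ( 14 protease, 4 kinase, 2 phosphatase )

panel <- expected_species(lib)
subset(panel, substrate_id == 6,
       select = c(species_id, role, sequence, mass_average, printed_mass))
#>       species_id               role       sequence mass_average printed_mass
#> 16 s06.substrate          substrate VSRLRAYLLPAPPA    1523.8418      1523.87
#> 17        s06.p1 cleavage_product_1        VSRLRAY     864.0153       864.02
#> 18        s06.p2 cleavage_product_2        LLPAPPA     677.8418       677.85

validate_panel(panel)
#> Panel report: 54 species
#>   low-mass (< 600 Da): 0
#>   m/z collisions (< 0.312 Da): 2
#>     s01.p2 (640.7165) ~ s04.p1 (640.8001), d = 0.0836
#>     s09.p2 (822.9360) ~ s12.p1 (822.9383), d = 0.0023
#>   substrate/product identity violations: 0
```

The computed masses match the published panel values to ~0.01 Da
(`regression_against_printed()` lists every deviation and flags the
table's known irregularities).  The two collision pairs are the panel's
only target masses too close to separate with ±0.156 Da windows.

Simulating a study and recovering the conversion fraction:

```r
phantom  <- make_phantom(16, 16, seed = 1)
activity <- uniform_activity_model(panel, k = 0.02)   # 0.02/min everywhere
study    <- make_study(panel, phantom, activity, acquisition_config(),
                       times = 60, controls = NULL, seed = 1)
prep     <- preprocess_study(study, panel, preprocess_config())

ds <- prep$datasets$active_t060
s8 <- subset(panel, substrate_id == 8)
cm <- conversion_map(
  ion_image(ds, subset(s8, role == "substrate")),
  list(ion_image(ds, subset(s8, role == "cleavage_product_1")),
       ion_image(ds, subset(s8, role == "cleavage_product_2"))),
  floor = 5)
roi_stats(cm, phantom)
#>   region region_name n_pixels      mean    median        q1        q3
#> 1      1      cortex      118 0.7104606 0.7098573 0.7041651 0.7165006
#> 2      2     medulla       38 0.7122458 0.7125707 0.7039691 0.7179730

median(cm$values[phantom$labels > 0], na.rm = TRUE)
#> [1] 0.7105976     # ground truth: 1 - exp(-0.02 * 60) = 0.6988
```

With a uniform rate the cortex and medulla medians agree, and the
pixel-median product fraction recovers the closed-form conversion within
a few percent (weak signals carry a small positive bias from clipping;
see the methods vignette).

## Analysis workflow

The `analysis/` scripts run the study end to end, driven by
`analysis/config.yaml` and writing provenance-headed TSVs under
`results/` (simulated imzML lands under `scratch/`):

```sh
Rscript analysis/01_design_panel.R       # panel, collisions, mass regression
Rscript analysis/02_simulate_study.R     # six imzML datasets (4 times + 2 controls)
Rscript analysis/03_preprocess_extract.R # per-target pixel intensity table
Rscript analysis/04_activity_maps.R      # maps, ROI stats, time courses, grades
```

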