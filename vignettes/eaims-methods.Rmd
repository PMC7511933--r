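---
title: "Enzyme-activity imaging MS: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enzyme-activity imaging MS: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement this package models

Enzyme-activity imaging mass spectrometry (EA-IMS) inverts the usual
MALDI-imaging workflow: instead of spraying a protease onto tissue to
digest endogenous proteins, a library of synthetic peptide substrates for
proteases, kinases and phosphatases is sprayed onto a fixed tissue
section.  During incubation the section's endogenous enzymes convert the
substrates into products of predictable mass — cleavage fragments,
phosphorylated or dephosphorylated forms — and MALDI imaging then maps
each substrate and product mass pixel by pixel.  Because one enzyme
molecule converts many substrate molecules, the method carries an
intrinsic amplification that can reveal even lowly expressed activities.

The package covers the computational side of this experiment end to end:

1. **Panel arithmetic** — expected masses for every measurable species;
2. **Panel validation** — low-mass background and m/z-collision rules;
3. **Ground-truth simulation** — imzML datasets with known regional
   kinetics;
4. **Preprocessing** — baseline removal, smoothing, interval extraction;
5. **Activity mapping** — ion images, conversion maps, ROI statistics,
   time courses, detectability grades, control contrasts.

## Mass arithmetic

Neutral peptide masses are sums of residue masses plus one water:
$M = \sum_i m_{r_i} + m_{\mathrm{H_2O}}$.  The residue table ships as
data (`inst/extdata/residue_masses.tsv`, ExPASy average and monoisotopic
values) so alternative tables can be swapped in; published panel masses
are isotope-averaged, so `scale = "average"` is the default and
reproduces them.  Modifications are registered with deltas computed from
elemental formulas: phosphorylation (+HPO$_3$, 79.980 Da average), the
(7-methoxycoumarin-4-yl)acetyl fluorophore (C$_{12}$H$_8$O$_4$) and the
2,4-dinitrophenyl quencher (C$_6$H$_2$N$_2$O$_4$).

Product enumeration is exact by construction: a protease substrate cleaved
after residue $c$ yields fragments whose masses obey
$M_1 + M_2 - m_{\mathrm{H_2O}} = M_S$ (hydrolysis adds one water across
the two fragments), and phospho transfer shifts the mass by exactly the
HPO$_3$ delta.  The test suite asserts both identities to floating-point
precision for the whole packaged panel.

The packaged library reproduces the published masses to better than
0.01 Da for most species.  The regression table reports every deviation
and annotates — rather than silently correcting — the known
irregularities of the published table: the phosphorylated kinase products
are printed exactly 79.90 Da above their substrates instead of +79.98
(HPO$_3$); one phosphatase substrate mass is ~1.29 Da away from any mass
derivable from its printed sequence; the doubly tagged phosphatase
substrate's printed masses differ by 79.00 Da, matching no phospho delta,
and sit ~88 Da above the masses derived from the tag formulas; one
printed cleavage-product sequence is inconsistent with its substrate, so
products are always derived from the substrate sequence (the derived
fragment's computed mass matches the printed product mass, confirming the
printed sequence is a typo).

## Panel validation rules

Two design rules are screened:

* **Low-mass background** — in undigested tissue sections the bulk of the
  MALDI background lies below ~600 Da, so every targeted species should
  sit above `min_mass` (default 600 Da).
* **m/z collisions** — two targets closer than `min_separation` cannot be
  told apart by fixed-interval extraction.  The default separation is two
  interval half-widths ($2 \times 0.156$ Da): if two windows overlap, the
  species are not distinguishable.  The packaged panel has exactly two
  such collision pairs (printed masses 639.71/639.80 and 821.90/821.93),
  and downstream conversion-recovery analyses exclude the affected
  substrates.

The collision scan sorts by target m/z and sweeps adjacent pairs; a test
compares it against a brute-force $O(n^2)$ oracle on random panels.

## The synthetic-data generator

The generator emulates the study design — a kidney-like section with
cortex and medulla ROIs, incubated 5/15/60/120 min, plus heat-inactivated
and no-substrate controls — with a fully known ground truth.

**Phantom.** A concentric layout: background border, cortex annulus,
medulla core, on a default $32 \times 32$ grid at 100 µm pixel size (the
analysis scripts use $16 \times 16$ to keep a full six-dataset study
small).  A seeded angular perturbation varies the boundary shape between
seeds while keeping each seed reproducible.

**Kinetics.** No kinetic equations accompany the original experiment;
first-order conversion with optional first-order product degradation is
the generator's own model — the simplest one that reproduces the
qualitative rise-then-plateau/decline of product signals.  Per region and
substrate, with effective rate $k_{\mathrm{eff}} = k \cdot a$
(attenuation $a = 0$ for complete heat inactivation):

$$S(t) = S_0 e^{-k_{\mathrm{eff}} t}, \qquad
  P(t) = S_0 \frac{k_{\mathrm{eff}}}{k_{\mathrm{eff}} - d}
  \left(e^{-d t} - e^{-k_{\mathrm{eff}} t}\right)
  \;\xrightarrow{\,d \to 0\,}\; S_0 (1 - e^{-k_{\mathrm{eff}} t}),$$

with the limit form $P = S_0 k t e^{-kt}$ when $k_{\mathrm{eff}} = d$.
The converted amount is split equally between the two cleavage fragments
of a protease substrate (kinase/phosphatase products carry the full
amount), so that $S + \sum P = S_0$ when $d = 0$ and the pixelwise
product fraction equals $1 - e^{-k_{\mathrm{eff}} t}$ — the closed form
every recovery check is scored against.  Defaults: $S_0 = 100$,
$k = 0.02\,\mathrm{min^{-1}}$, $d = 0$; regionally contrasted substrates
convert 4-fold faster in their strong region.

**Ionization.** Peptides differ strongly in MALDI response even at equal
applied amounts.  Each species carries an ionization factor; the default
map derives it from the published detectability grades
(`-`/`+`/`++`/`+++` → 0.25/0.5/1.5/5).  The floor is non-zero by design:
the control-condition contracts (heat-inactivated tissue must still show
every applied substrate) presuppose that all substrates are renderable,
and 0.25 places the weakest substrate at an expected SNR of roughly 12,
well clear of the detection threshold.  Which substrates were genuinely
undetectable on real tissue is an instrument/tissue property this
generator does not attempt to reproduce.

**Spectra.** Each pixel's spectrum over m/z 400–2,200 (0.05 Da grid,
continuous mode) is a sum of Gaussian peaks
(height = amount × ionization factor) at the species' [M+H]$^+$ targets,
a smooth exponentially decaying baseline concentrated below ~600 Da
(amplitude 30, decay constant 150 Da — the low-mass background hump), and
Gaussian noise with a signal-dependent variance
($\sigma^2 = \sigma_0^2 + c \cdot \mathrm{signal}$, $\sigma_0 = 2$,
$c = 0.02$; a Poisson model is available behind a flag).  Noise is seeded
per (dataset seed, pixel index), which makes whole studies byte-identical
under one master seed.

**Peak width.** The width model is FWHM at a reference m/z with a linear
m/z slope.  The default slope is 0 — a constant 0.25 Da FWHM — rather
than a TOF-like increase.  This is deliberate: extraction uses a *fixed*
±0.156 Da interval at every target, so an m/z-dependent width would make
the captured peak fraction mass-dependent and systematically bias the
product fraction $\sum P / (\sum P + S)$ by up to ~0.06 between a
1.5 kDa substrate and its 700–900 Da fragments.  With a constant width,
the interval response is uniform across the panel and ratio-based maps
are unbiased.  Users modelling resolution effects can set a positive
slope and should then expect exactly that bias.

**imzML.** Datasets round-trip through a minimal continuous-mode
imzML 1.1 writer/reader (UUID, MD5-checksummed `.ibd`, 64-bit m/z axis,
32-bit intensities, condition metadata as user parameters), verified in
tests against an independent Python imzML parser.  No installed R package
provides imzML I/O, so it is implemented here directly.

## Preprocessing

* **Baseline** — "convolution baseline removal, width 20": implemented as
  an iterative clipped minimum-convolution with the width in axis points,
  the unit the original software exposes.  A morphological opening
  (running minimum then maximum over the window) removes structure
  narrower than the kernel, a running mean smooths the estimate, one
  clip-and-resmooth pass refines it, and the estimate is subtracted with
  negative values clipped to zero.  The operation is idempotent within
  tolerance and preserves apex heights of narrow peaks within 10 %.
* **Smoothing** — the ordinal strengths map to Gaussian kernels of 0
  (none), 1 (weak), 2 (medium, default), 4 (strong) grid points standard
  deviation; kernels are normalized and edges reflected, so the total ion
  current is preserved.
* **Interval extraction** — the statistic (mean by default) over the
  *closed* window [target − 0.156, target + 0.156] Da; grid points
  exactly on a boundary are included, windows partially outside the axis
  truncate, fully outside return 0 with a warning.
* **Normalization** — none by default (no normalization step is part of
  the mirrored pipeline); TIC normalization is available behind the
  config.

One configuration is applied to every dataset of a study and its hash is
recorded; cross-condition contrasts refuse to compare datasets processed
differently.

## Activity mapping

* **Conversion map** — per pixel, $f = \sum P / (\sum P + S)$.  The
  bounded, scale-invariant fraction is preferred over the unbounded ratio
  $P/S$; pixels with $\sum P + S$ below a floor are marked undefined
  rather than reported as 0.  When two cleavage products exist their
  intensities are summed; per-product maps are available because product
  detectability can be asymmetric.
* **ROI statistics** — per-region pixel summaries (n, mean, median,
  quartiles, extremes), the values behind dot/box plots; empty regions
  produce explicit zero-pixel records.
* **Detectability grades** — the ordinal `-`/`+`/`++`/`+++` scale is
  reproduced by a documented rule of this package's own design (the
  original grading rule is unstated): a background-corrected SNR,
  (mean on-tissue window intensity − off-target center) / off-target
  scale, graded `-` below 3 and stepping up each decade (3/30/300).  The
  off-target center matters because baseline clipping leaves a small
  positive offset in signal-free windows.
* **Contrasts** — difference of region means, their ratio, and Cliff's
  delta (a rank-based effect size in [−1, 1]).  No p-value machinery: the
  mirrored outputs are descriptive dot/box plots, so effect sizes are
  reported, not test decisions.

## Numerical behavior worth knowing

* **Grid alignment.** A ±0.156 Da window on a 0.05 Da grid holds 6 or 7
  points depending on where the target falls; with the mean statistic the
  per-unit response therefore differs a few percent between species.
  Within one species the response is exactly linear in amount, and
  conversion fractions are affected only at the percent level.
* **Clipping bias.** Clipping negative intensities after baseline
  subtraction leaves signal-free windows with a small positive mean, which
  inflates weak product signals; at low conversion (e.g.
  $k = 0.005\,\mathrm{min^{-1}}$, 60 min) the recovered median fraction
  sits ~0.03–0.04 above the closed form at the default noise level.  The
  detectability grading corrects for this offset; the conversion map, by
  design, reports what the intensities say.
* **Collisions.** The two colliding panel pairs cross-contaminate each
  other's windows by construction; conversion recovery is assessed on the
  collision-free substrates.

## Problem sizes used by tests and scripts

Conversion recovery runs on $32 \times 32$ phantoms with the full
54-species panel over the full 400–2,200 Da axis; time-course, regional
discrimination (20 seeded replicates) and control checks use
$16 \times 16$ phantoms, a choice of this package to keep a full study
generation fast while leaving hundreds of on-tissue pixels per region.
Unit tests exercise the same code paths on reduced m/z windows.

## Limitations

The generator does not model isotope envelopes, adduct series, matrix
cluster chemistry, detector saturation, spatial spray inhomogeneity, or
real kidney morphology; a passing recovery check certifies the pipeline's
arithmetic on data following the generator's assumptions, not instrument
behavior on tissue.  Which real substrates and products are detectable on
tissue — and any conversion occurring already during room-temperature
spray application (the generator exposes a time offset for it, with no
stated magnitude to default to) — are empirical questions outside the
simulation's reach.
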