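---
title: "Copy-number stoichiometry of nanoparticle-delivered mRNA: methods and models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number stoichiometry of nanoparticle-delivered mRNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesikin)
```

## The problem

When therapeutic mRNA is delivered to cells in lipid nanoparticles (LNPs),
the interesting questions are stoichiometric: how many mRNA copies does a
single particle carry, how many intact copies does a cell hold at a given
time, how many copies does a secreted extracellular vesicle (EV) re-export,
and how many protein molecules does each delivered mRNA copy ultimately
produce. All of these reduce to one primitive — converting a measured mass
to a molecule count through a molecular weight and the Avogadro constant —
wrapped in assay-specific plumbing: sequence-derived molecular weights,
qPCR standard-curve interpolation, particle counting, and nonparametric
comparisons across timepoints. `vesikin` implements that chain end to end
and ships a seeded simulator so the whole pipeline can be validated without
wet-lab data.

## Sequence chemistry

RNA molecular weights are linear in nucleotide composition:

$$M = 329.2\,n_A + 306.2\,n_U + 305.2\,n_C + 345.2\,n_G + 159,$$

where the final term is the mass contribution of a 5'-triphosphate and is
applied by default (it is an optional flag; the bare value of an internal
fragment such as a CDS omits it conceptually, but we follow the field's
convention of reporting the triphosphate-inclusive number for transcripts).
Chemically modified bases (5-methylcytidine, pseudouridine) are treated as
their parent bases; no modification mass corrections are attempted, since
per-residue mass shifts are below the resolution at which these numbers are
used.

Protein molecular weights sum standard *average* (not monoisotopic) residue
masses plus one water (18.01524 g/mol). For the bundled 191-residue VEGF-A
protein this yields 22313.64 g/mol, matching standard protein MW
calculators to all printed digits; a monoisotopic table would deviate by
more than 10 Da.

Translation uses the standard genetic code from the AUG start to the first
stop codon, warning rather than erroring on a missing terminal stop so that
fragments remain analyzable.

The working molecular weight of the full-length 852-nt VEGF-A construct
(CleanCap, UTRs, poly(A) tail) deserves a note: the full sequence is not
available, only its 576-nt CDS, so `vegfa_mrna_mw()` returns **277900
g/mol**, a constant *back-solved* from the construct's dose stoichiometry
(3 µg ≙ 6.5×10¹² copies). It is flagged as derived in its documentation and
every function that consumes a molecular weight accepts an override.

## Absolute qPCR quantification

The standard curve is an ordinary least-squares fit of Cq on
log₁₀(quantity) over a 10-fold dilution series (100 ng down to 0.0001 ng),
the universal qPCR orientation, so the slope is in Cq per decade and
−1/log₁₀(2) ≈ −3.3219 corresponds to 100% amplification efficiency. Design
choices:

* The QC gate is **strict**: the fit passes only if R² *exceeds* 0.975
  (and the slope is negative). Interpolation against a failing curve
  requires an explicit `force` and warns.
* Technical Cq replicates are averaged **on the Cq scale** before
  interpolation — the conservative default where the assay convention is
  unstated.
* Quantities falling outside the standards' span are flagged as
  extrapolations, not refused; at the low end of a kinetic series the EV
  signal legitimately dips slightly below the lowest standard.
* No ΔΔCq normalization is applied: the absolute pipeline interpolates
  directly, and a housekeeping-gene Cq column is carried only as QC
  metadata. An optional reverse-transcription efficiency factor is *not*
  silently applied; quantities refer to the cDNA loaded.

Copies follow as `ng → g → copies` through the molecular weight; per-cell
and per-EV values divide by entity counts. Copy counts are kept as reals
everywhere (they are bulk-mass estimates); rounding to integers
(26 copies per LNP) and 2-significant-figure yields (0.15 protein copies
per mRNA) happen only at display, with full precision preserved
underneath.

## Particle metrics

NTA summaries report mean ± SEM over captures (SEM over a single capture is
`NA`, never 0) and rescale concentrations by the dilution factor.
Radiolabel uptake normalizes a sample's scintillation reading linearly
between a medium-only (0%) and a t0-spiked (100%) reference after blank
subtraction, clamping to [0, 100] with a flag. The LNP particle-count
estimator is deliberately transparent: its default mode divides dose copies
by a stated copies-per-particle calibration (26 for this construct), and
the alternative geometric mode (sphere volume × assumed core density ×
mRNA weight fraction) is labelled an order-of-magnitude approximation —
refractive-index-based particle counting from instrument data is out of
scope, and we prefer a visible calibration constant to an unverifiable
physics model.

The N:P helper computes amine-to-phosphate mole ratios from user-supplied
lipid molar masses and the lipid:mRNA weight ratio; published N:P values
additionally depend on preparation details not captured by this record, so
it is a bookkeeping aid, not a reproduction of any printed value.

## Kinetics and tests

Time courses are long-format tables (timepoint × compartment × replicate).
Peaks are the argmax of per-timepoint means with ties broken toward the
earlier timepoint (flagged); contrasts are ratios of per-timepoint means.
The test battery mirrors standard practice for small-n assay data:
Mann-Whitney (exact when the smaller group has n ≤ 8 and no ties, normal
approximation with tie correction otherwise), Kruskal-Wallis with Dunn's
pooled-rank z post hoc, and Friedman with the matched-samples Dunn variant.
Dunn's adjustment defaults to Holm — a choice had to be made where common
software defaults to a Bonferroni-family correction — and is configurable
to Bonferroni or none. All tests are two-sided. Fully tied inputs return a
statistic of 0 with p = 1 rather than NaN. Unbalanced group sizes enter
Dunn's z through the pooled-rank formula.

## The synthetic-data simulator

The simulator is **bookkeeping, not biology**: the experiments it emulates
report kinetics but no dynamical model, so we use the simplest first-order
mass-action structure able to reproduce the observed measurement summaries,
and document it as scaffolding. Pools: medium, endosome-sequestered
internalized mRNA, translatable cytosolic mRNA, degraded, EV, and two
protein pools (lysate/secreted). Forward-Euler steps (default Δt = 0.01 h,
capped at 0.05 h) evaluate all fluxes at the start of each step, which
makes mRNA copy conservation exact to floating-point rounding; the
conservation error is tracked at every step and exposed as an attribute.

Two modelling commitments matter for interpretation:

* **The measurable cell pool is the translatable pool.** Uptake flux splits
  at entry: a fraction `f_escape` reaches the translatable pool, the rest
  enters the endosome-sequestered pool fated for lysosomal destruction.
  Only the former is counted as per-cell copies. This mirrors the striking
  empirical gap between lipid-label uptake (~80% of particles consumed
  within 5 h) and intact-mRNA detection (~10³ copies per cell out of ~10⁷
  delivered per cell): the overwhelming majority of internalized cargo is
  never recoverable as amplifiable mRNA.
* **Per-EV copies divide by cumulative EVs secreted since t = 0**, matching
  experiments that harvest all EVs accumulated in the medium. A wash event
  (medium replacement) is supported as a parameter.

Default parameters are a *calibration, fixed once*: with sampled timepoints
{0.5, 1, 5, 24} h they reproduce four anchor observations of the benchmark
LNP-VEGF-A experiment — per-cell copies peaking at 1 h at ≈1355, per-EV
copies peaking at 5 h at ≈31, ≤20% of the dose remaining in the medium at
5 h, and ≥90% payload-positive cells at 2 h. The rate constants were chosen
from the anchor timings (uptake 0.35/h puts medium retention at 17.4% at
5 h; a translatable-pool outflow of 1.0/h places the sampled cell peak at
1 h and the cumulative per-EV peak at 5 h), after which `f_escape`
(4.579×10⁻⁴), `ev_rate` (1.769 EVs/cell/h), and `k_translate` (336
proteins/mRNA/h) were solved numerically against the discrete integrator
for the anchor magnitudes and a cumulative protein output of 10¹² copies at
24 h. Cell count is held constant at 4×10⁵ (a typical seeding density);
per-timepoint counts vary in real experiments.

Observation operators add the assay noise on top of the latent truth:
Gaussian Cq noise per well (sd 0.2) with the 7-point standard series and
technical triplicates per biological replicate, matching the assay design;
mean-one lognormal noise on ELISA readings (CV 15%); lognormal NTA capture
diameters; and a lognormal cell-to-cell heterogeneity model (shape 1.0,
positivity threshold 100 copies) for the positivity readout. Every
observation operator reduces to an exact inverse of the quantification
pipeline when its noise parameter is zero — this round-trip property is
tested — and a fixed seed makes datasets bitwise-reproducible, with
identical ground truth across seeds.

What the simulator does *not* capture: endosomal-escape mechanics,
single-vesicle stochastics beyond the lognormal spread, cell growth and
division, RT efficiency, and matrix effects on ELISA. Passing recovery
tests therefore demonstrates that the *quantification pipeline* is
unbiased under the stated noise model — not that real measurements obey
that noise model.

## Numerical choices and degenerate inputs

* Avogadro constant fixed at the 2019 SI exact value 6.02214076×10²³.
* Standard-curve fitting requires ≥3 distinct quantities; fully collinear
  points give R² = 1 exactly; constant-Cq input gives R² = 0 and fails QC.
* The Euler step is validated (`dt ≤ 0.05 h`) and negative pools abort.
* Mass/copy round trips are exact to 1e-12 relative; simulator copy
  conservation holds to 1e-9 relative (observed ≈5e-15).
* Peak ties break toward the earlier timepoint with an explicit flag.

## Problem sizes

The shipped examples and the test suite run at the scale of the emulated
experiments: 576-nt/191-aa sequences, 7-point standard curves in technical
triplicate, n = 6 biological replicates per timepoint, 4×10⁵ simulated
cells, 2400 Euler steps per 24 h trajectory, and 4000-replicate null
simulations for the type-I-error checks of the rank tests. Everything
completes in well under a minute on a laptop.

## Worked example

```{r, eval = FALSE}
cds <- vegfa_cds()
composition(cds)$counts          # A 157, U 118, G 158, C 143
protein_molecular_weight(translate_rna(cds))  # 22313.64 g/mol

dose <- mass_to_copies(3e-6, vegfa_mrna_mw()) # ~6.5e12 copies in 3 ug
per_unit_copies(dose, 2.5e11)                 # 26 copies per LNP

ds <- simulate_dataset(default_sim_params(seed = 1))
tab <- ds$qpcr$cell_1h
fit <- standard_curve(tab$standards$quantity_ng, tab$standards$cq)
q <- quantify_unknowns(fit, tab$unknowns, mw = vegfa_mrna_mw(), force = TRUE)
mean(q$copies) / ds$params$n_cells            # ~1355 copies per cell
```

## Limitations

The package quantifies; it does not infer. There is no uncertainty
propagation beyond SEM pass-through, no dose-response or Bayesian
machinery, no ODE fitting to experimental kinetics (the simulator's rate
constants are a calibration device, not estimates), and no handling of raw
instrument output (fluorescence traces, NTA videos, DLS correlograms).
The back-solved construct molecular weight is only as good as the dose
stoichiometry it came from; supply a measured value when one exists.
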