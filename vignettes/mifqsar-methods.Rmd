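---
title: "Molecular-interaction-field QSAR: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular-interaction-field QSAR: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pancreatic lipase hydrolyses dietary triglycerides; inhibiting it reduces
fat absorption, which is why lipase inhibitors are studied as
anti-obesity agents. Tea polyphenols — catechins, their galloyl esters,
and a zoo of dimeric oxidation products — inhibit the enzyme with IC50
values spanning three orders of magnitude. `mifqsar` implements the
grid-based 3D-QSAR workflow used to rationalize that spread: align a
congeneric series on its shared benzopyran core, sample molecular
interaction fields on a lattice around the aligned structures, regress
activity on the field values by partial least squares (PLS), and read the
resulting coefficient maps as "put bulk here, avoid charge there"
design guidance. The package ships the 37-compound tea-polyphenol
activity table (with its 30/7 train/test split) as packaged data, and a
synthetic congeneric-series generator with known ground truth so the
whole pipeline is verifiable end to end.

## Structure preparation

Structures enter as SDF, MOL2 or SMILES and are normalized to explicit
hydrogens (hydrogen-bond donor fields need them). Molecules without
coordinates are embedded by ETKDG distance geometry with an explicit
random seed (`embed_seed` in `preparation_config()`), so the same input
and seed always give the same conformation. Geometries are then relaxed
with the MMFF94 force field by conjugate gradients, with a convergence
tolerance of 0.05 kcal/(Å·mol) and a 20000-step budget as defaults. The
minimizer exposes an energy-change criterion rather than a gradient norm,
so convergence is flagged by probing whether a short continuation run
still lowers the energy by more than the tolerance; a molecule that
exhausts its budget is flagged, not rejected.

Partial charges use plain Gasteiger iterative partial equalization. The
hybrid "Gasteiger–Hückel" scheme of commercial modelling suites is
proprietary; plain Gasteiger is its closest open, deterministic relative,
and the substitution is recorded in every prepared molecule's provenance.
All catechol/pyrogallol hydroxyls are treated as neutral — the un-ionized
species dominates below the first phenolic pKa (~9), and the registry
documents the assumption.

Van der Waals parameters (radius, well depth) ship as a versioned
plain-text table patterned on the Tripos force field, so CoMFA energies
are bit-for-bit reproducible and do not depend on any third-party
library's internal tables. The CoMSIA atomic property weights follow the
published CoMSIA parameterization: steric weight r³ (Å³), electrostatic
weight = partial charge, hydrophobic weight from a coarse editable
atom-class table, and hydrogen-bond donor/acceptor as rule-based
indicator weights (O/N with a hydrogen donate; O, and N below four
connections, accept).

## Alignment

All molecules are rigidly superposed onto a template through the shared
benzopyran (chromane) core, found by element-colored subgraph matching;
bond orders and aromaticity are deliberately ignored so one query hits
flavan-3-ols, gallocatechins and the synthetic benzopyranone scaffold
alike. When several core embeddings exist, the one minimizing the
post-superposition RMSD wins; exact ties break toward the lowest atom
index sequence, making the choice deterministic. The superposition itself
is the closed-form rigid least-squares (Kabsch) solution, constrained to
proper rotations.

The matcher reports *induced* subgraph matches: a candidate set of core
atoms must carry exactly the core's bonds among themselves. For a fused
bicyclic query this is the correct semantics (none of the catalogued
compounds has an extra bond inside its chromane core), and it prevents
spurious matches through macrocyclic shortcuts.

For the packaged dataset the natural template is compound 8
((−)-epigallocatechin-3,5-di-*O*-gallate), the most active training
compound. Its conformation here is the prepared (embedded, minimized)
one; the original study aligned to a docking pose from a commercial
engine, which cannot be regenerated openly. This is a documented
reproducibility caveat, and is the main reason the published model
statistics are treated as context rather than as regression targets (see
*Limitations*).

## Fields

A rectilinear grid is laid over the union bounding box of the aligned
molecules, extended by a 4 Å margin (two cells at the default 2 Å
spacing); origin and counts are deterministic functions of the inputs.
Grid points are ordered x-major with z varying fastest — the same order
the OpenDX exporter uses.

**CoMFA.** The steric field is the Lennard-Jones 6-12 energy of an
sp³-carbon probe (radii summed, well depths combined geometrically); the
electrostatic field is the Coulomb energy `332.0636 q_probe q_i / (ε(r) r)`
with a distance-dependent dielectric ε(r) = r and probe charge +1 e. Both
are truncated at ±30 kcal/mol. At points where the steric energy hits the
cutoff (inside the van der Waals envelope) the electrostatic value is
replaced by the mean of that molecule's non-truncated electrostatic
values — the conventional treatment, which stops singular columns from
dominating the regression; affected points are recorded in the block's
metadata.

**CoMSIA.** The similarity-index field for property *k* at grid point *q*
is `A_k(q) = −Σ_i w_probe,k · w_ik · exp(−α r_iq²)` with attenuation
α = 0.3 and unit probe weights. The Gaussian kernel is finite everywhere,
needs no cutoff, and varies smoothly — the point of the method.

Descriptor columns are (field type, grid point) pairs in a fixed,
documented order. Columns whose standard deviation across molecules falls
below a per-field minimum sigma are masked (2.0 kcal/mol for CoMFA, 0 for
CoMSIA — the classic defaults) and never enter any fit. Before PLS, each
field block is scaled to equal total variance ("block scaling", on by
default and recorded in the model); without it, multi-field CoMSIA models
are dominated by whichever property happens to have the largest numeric
range.

## PLS, validation, contours

The regression is NIPALS PLS1 on centered (and block-scaled) columns with
a centered response. The reported statistics are the conventional ones:
non-cross-validated r², `SEE = sqrt(RSS/(n − c − 1))`,
`F = (r²/c)/((1 − r²)/(n − c − 1))`, leave-one-out `q² = 1 − PRESS/TSS`,
and per-field contribution fractions `Σ|coefficient × column sd|`
normalized to 1. The component count is chosen by exhaustive LOO over
1..max components, ties broken toward fewer. Inside each LOO fold the
column filter and block-scale factors are frozen from the full training
set (the behavior of the reference commercial implementation); a
`refilter` flag re-does filtering per fold for sensitivity analysis.

External validation reports `r²_pred = 1 − PRESS/SD`, where SD sums
squared deviations of the *test* activities from the *training-set mean*
— the standard reading, and the only one that yields a scale-free
coefficient. Residuals are predicted − actual throughout, matching the
packaged reference table's arithmetically consistent columns.

Contour maps are StDev*Coeff surfaces: each active column's coefficient
times its standard deviation mapped back to its grid point, zero at
masked columns. The product is invariant to block scaling, so maps are
comparable across configurations. "Favored"/"disfavored" levels are the
80th/20th percentiles of the active-column value distribution — the
conventional reading of "80%/20% contribution" contour levels, which is a
display convention, not a probability statement. Maps export as
plain-text OpenDX next to the aligned SDF for standard molecular viewers.

## The packaged dataset

`load_activities()` returns all 37 compounds with IC50 (μM), pIC50
(`6 − log10(IC50 μM)`), and the fixed 30/7 split (test compounds 6, 11,
14, 15, 21, 31, 37). Two compounds were only bounded (">30 μM"); they
keep their printed pIC50 of 4.5229 with an explicit censoring flag.
`load_reference_predictions()` returns the published actual/predicted
table verbatim — regression fixtures only, never training input; its
CoMFA residual column is arithmetically consistent
(residual = predicted − actual within 5e-4) while the CoMSIA residual
column is not, so only the CoMFA columns are used as fixtures. Checksums
guard all packaged tables against silent edits.

Structures are not published in machine-readable form, so
`load_structures()` serves a curated SMILES registry: the monomeric
flavan-3-ols and their simple esters (compounds 3–10, 15) with full
confidence, procyanidin B2 and theasinensin A with provenance caveats
(approximate linkage stereodescriptors; un-encoded axial chirality), and
every remaining polymeric compound as an explicit "structure unavailable"
marker rather than a guess. Every curated SMILES was verified against its
literature molecular formula. The QSAR pipeline runs on whatever subset
has structures; coverage is declared on the returned collection.

## The synthetic generator

The generator exists so that alignment, fields, PLS and validation can be
tested end to end against a known truth, with no circularity. It builds a
chroman-4-one (benzopyranone) scaffold — which the default alignment core
matches unmodified — with substituent slots at C2 and C7, filled from a
menu of H, methyl, ethyl, propyl, isopropyl, *tert*-butyl, cyclopentyl,
cyclohexyl, hydroxyl and methoxy. The larger substituents are rings on
purpose: their grid occupancy barely depends on the embedded conformer,
so the steric signal is clean at 2 Å grid spacing.

True activity is `pIC50 = 5 + 0.02·bulk + 0·polar + ε`, where `bulk` is
the substituent van der Waals volume proxy (Σ r³ over substituent atoms,
Å³ — the same per-atom measure the CoMSIA steric weights use, but
computed from composition, never from the fields themselves) and `polar`
counts substituent O/N atoms (weight 0 by default, so the generating
signal is purely steric; the dial exists for sensitivity studies). The
0.02 pIC50/Å³ weight gives a ~2.3 log-unit activity range across the
menu, a realistic congeneric-series spread; the default noise of
0.1 pIC50 units matches good replicate IC50 measurements. With 20
molecules under these defaults, the pipeline recovers LOO q² ≈ 0.85–0.95
with the steric field dominant — the package's stand-in acceptance
surface for model quality, since the published statistics are not
reproducible openly (below).

What the generator does *not* emulate: polyphenol chemistry (galloyl
esters, catechol B-rings), conformational ensembles, activity cliffs,
censored measurements, or experimental error structure beyond i.i.d.
Gaussian noise. Passing the recovery test therefore shows the machinery
is correct and sensitive at realistic noise, not that any particular real
dataset will model well.

## Numerical choices

* Distances in field kernels are floored at 1e-6 Å; a grid point on an
  atom center gets the clamped +30 kcal/mol steric value.
* Grid counts are `ceil(span/spacing) + 1`, at least 2 per axis.
* The component cap is `min(max_components, n − 2, active columns)` so
  every LOO fold stays fittable.
* NIPALS stops early if the residual response is numerically orthogonal
  to the residual columns.
* Collinear core coordinates (second singular value < 1e-8) abort the
  superposition rather than return an arbitrary rotation.
* Sizes used by the test-suite and acceptance runs: a 20-molecule series,
  ~1600 grid points per field, up to 8 PLS components — small enough to
  rerun casually, large enough for the recovery bounds to be meaningful.

## Limitations

The published model statistics for this dataset (q² 0.622/0.631, r²
0.956/0.932, the field contributions, and r²_pred 0.918/0.773) were
produced with proprietary structures, a docking-pose alignment and a
commercial implementation's internal parameters; they cannot be
regenerated from open components, and the source itself reports
conflicting SEE values between its summary and its results table, and an
r²_pred that is not derivable from its own printed predictions under the
standard formula. This package therefore validates itself by analytic
fixtures, independent oracles (brute-force LOO, least-squares limits,
exhaustive subgraph matching, rotation grid search) and synthetic-data
recovery, and treats the published numbers as context. Other limits:
rigid-body alignment only (no torsional fitting), one conformer per
molecule, no protonation-state or tautomer enumeration, and a
deliberately coarse hydrophobic weight table.
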