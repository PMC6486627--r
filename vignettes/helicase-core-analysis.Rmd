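---
title: "Measuring the open/closed cycle of DEAH-box helicase cores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the open/closed cycle of DEAH-box helicase cores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helicore)
```

## The scientific problem

Spliceosomal DEAH-box ATPases move along single-stranded RNA in the 3′→5′
direction, one nucleotide per ATP hydrolysed. In crystal structures this
shows up as two core geometries: ADP/ATP-bound structures hold the RecA1
and RecA2 domains close together (a *closed* helicase core) around a
four-nucleotide base stack in the RNA-binding tunnel, while
adenosine-nucleotide-free, RNA-bound structures relax into an *open* core
whose tunnel accommodates a five-nucleotide stack. The switch is read out
by a serine in motif V whose backbone is forced out of a helical
conformation only when ATP is bound. `helicore` turns the measurements
behind these statements into tested functions: domain superposition,
center-of-mass distances, interaction fingerprints, stack counting,
helicity assessment, and the accompanying solution assays.

This vignette records the model each function implements, the tunable
parameters with their defaults and units, the numerical decisions, what
the synthetic generators do and do not emulate, and known limitations.

## The atomic data model

A structure is a tibble of heavy atoms in author numbering (chain, author
residue number, insertion code, residue name, atom name, element,
coordinates in Å, occupancy, B-factor, polymer class). Author numbering is
used throughout because that is how domain boundaries and functional
residues are cited (RecA1 557–733, RecA2 734–909, S837, …). Three policies
are applied on ingestion and are deliberate:

* hydrogens and zero-occupancy atoms are dropped — at 2.2–3.25 Å
  resolution they carry no reliable geometric signal;
* alternate locations are collapsed to the highest-occupancy conformer,
  ties broken alphabetically by alt-loc id (a fixed, arbitrary but
  documented tie-break);
* waters and ions are kept but flagged `other`, so they never enter
  domain selections or center-of-mass sums.

Parsing is delegated to `bio3d`'s PDB and mmCIF readers; the package's own
writers exist so that generated fixtures are real files and the readers
are exercised, not bypassed.

## Superposition and decomposition

`kabsch_fit()` is a weighted least-squares superposition via SVD of the
weighted covariance matrix. A reflection in the SVD solution is always
corrected by flipping the smallest singular direction; a collinear atom
configuration is refused with an error rather than silently producing an
improper rotation. The default atom set for superposition and centers of
mass is **CA-only with uniform weights**: side chains are frequently
disordered at these resolutions, and the backbone trace is the robust
common denominator. Backbone, all-heavy, and atomic-mass-weighted variants
exist so results can be bracketed across conventions; on rigid fixtures
all variants agree exactly, and on real structures the spread across atom
sets is the honest uncertainty of any single printed number.

`decompose_transform()` reports the rotation angle from the matrix trace
(degrees, in [0, 180]), the axis from the antisymmetric part (eigenvector
for eigenvalue 1 when the angle approaches 180°), and the displacement of
a caller-chosen reference point. Reporting the displacement *of the mobile
domain's center of mass* rather than the translation vector is what makes
statements like "rotated ~19° about an axis near the center of mass, which
itself moves only ~1.8 Å" well-defined.

## The center-of-mass distance protocol

The conformational coordinate is the distance between the RecA1 and RecA2
centers of mass — but computed so that every structure is measured over
the *same* atom set. For each domain, the reference structure's domain is
least-squares fitted onto the corresponding domain of the target (pairing
atoms by residue number, or through an explicit equivalence table for
cross-protein comparisons), the full reference domain is transplanted by
that fit, and its center of mass taken. Differently modeled targets (the
apo RecA2 domains are 20–40 residues short) therefore cannot bias the
coordinate: gaps only reduce the number of fitted pairs.

Numerical safeguards: fewer than three common atoms in a domain is an
error; a per-domain fit RMSD above 5 Å (configurable) triggers a warning
but still returns, because a bad fit should be visible, not fatal, in a
multi-entry run.

**Threshold.** Closed cores cluster at 27.3–27.7 Å and open ones at
~31 Å and above; no cutoff is stated in the literature, so the package
uses the midpoint of the gap, 29.5 Å, exposed as a parameter, with the
boundary value assigned to *open* (a fixed tie-break; classification is
monotone in the distance by construction). At ±1 Å around the default the
assignment of all known states is unchanged, which is what makes the
midpoint an acceptable convention.

`domain_shift()` measures inter-state RecA2 motion by first aligning the
RecA1 anchors, then fitting the anchor-aligned mobile domains onto each
other and decomposing at the mobile center of mass.
`modeled_rna_displacement()` uses the same anchor alignment to ask how far
individual RNA-contacting residues move between catalytic states — the
geometry behind transplanting the ssRNA of a nucleotide-bound complex
into another state. Unmodeled tracked residues are flagged rather than
dropped, so a disordered loop cannot silently shrink a reported range.

## Interaction criteria

All criteria are config objects echoed into every output.

* **Hydrogen bonds** (`hbond_criteria()`): donor–acceptor heavy-atom
  distance ≤ 3.5 Å; where a covalent antecedent of the donor exists,
  antecedent–donor–acceptor angle ≥ 90°. Hydrogens are not modeled at
  these resolutions, so bonded heavy-atom neighbours stand in for
  directionality. The search is symmetric in donor/acceptor roles, and
  the RNA partner is classified by moiety from atom-name tables
  (P/OP1/OP2/O5′/O3′ → phosphate; primed carbons, O4′, O2′ → ribose; ring
  atoms → base). Counts such as "residues gripping the backbone per
  domain" are sensitive to these cutoffs, which is exactly why they are
  parameters and are echoed into the output.
* **Ring interactions** (`stack_criteria()`): base stacking requires ring
  centroid distance ≤ 4.5 Å, interplanar angle ≤ 30°, lateral centroid
  offset ≤ 2.0 Å. Generic π–π contacts are collected to 5.5 Å (edge-to-face
  geometries sit further apart than stacks) and split at a 50° interplanar
  angle into parallel-displaced vs edge-to-face. Cation–π uses charged
  side-chain nitrogen to ring centroid ≤ 6.0 Å. One convention is used for
  ring centroids throughout: the six-membered ring, also for purines; the
  proline ring is included as a stackable (CH–π) partner so His-Pro-Phe
  triads are detectable.
* **Stack segmentation**: nucleotides are ordered 5′→3′ from O3′–P
  connectivity (author numbering is not trusted for directionality;
  fragments are concatenated in author order), consecutive pairs are
  marked stacked by the criteria above, and maximal runs assembled.
  Protein atoms falling between the base centroids of a broken step are
  reported as the interrupting element — in the helicase this is the
  RecA2 β-hairpin that bounds the stack.
* **Helicity** (`motif_helicity()`): φ/ψ from N/CA/C backbone atoms;
  a residue is helical when φ ∈ [−100, −30]° and ψ ∈ [−80, −5]°, a window
  bracketing the canonical (−57, −47); a range labels *helical* at ≥ 80 %
  helical assessable residues. Dihedrals spanning a chain break (peptide
  C–N > 2 Å) are non-assessable, never guessed.

## Fitting machinery

`nadh_rate()` converts the initial slope of an A340 trace to velocity via
Beer–Lambert with ε(NADH, 340 nm) = 6220 M⁻¹cm⁻¹ (standard literature
value, overridable). The fitting window is the initial 10 % of the
observed consumption, where a first-order consumption curve is linear to
well under the assay noise; a non-decreasing trace yields zero with a
warning instead of a negative rate.

`fit_michaelis_menten()` and `fit_fp_binding()` use Levenberg–Marquardt
nonlinear least squares on pooled replicate points (not replicate means),
with data-derived starting values and a small deterministic grid of scaled
starts (×1, ×0.3–0.5, ×2–3) to guard against local minima — a fixed grid
rather than RNG-jittered starts, so fits are bit-reproducible without any
RNG state. Non-convergence is a flagged result, never a silent fallback.
Asymptotic standard errors are reported for every free parameter.

The FP model is the exact quadratic single-site isotherm, which remains
correct when the titrated protein concentration approaches the labeled
RNA concentration (6 nM by default). Whether the polarization plateaus are
co-fit or fixed is an explicit mode (`normalize = "fit"` / `"fixed"` /
`"none"`): published protocols are usually silent on this point, so both
are provided and neither is asserted as canonical. A titration whose top
concentration is below ~2·K~d~ warns that the confidence interval is wide.

`mean_residue_ellipticity()` is the standard CD conversion
θ·MRW/(10·l·c) in deg·cm²·dmol⁻¹.

## What the generators emulate — and what they do not

The synthetic module produces every input class with recorded ground
truth: rigid pairs (`B = R·A + t + noise`), two-lobe structures whose
uniform and mass-weighted lobe COMs coincide exactly at a chosen
separation, idealized stacked poly-U (3.4 Å rise, 33° twist, covalently
connected minimal backbone), constructed hydrogen-bond and ring
geometries, exact-dihedral peptide backbones, and model-plus-Gaussian-noise
assay data on the grids typical of these experiments (ATP 0–2 mM two-fold
series in triplicate; protein titrations to 70 µM against 6 nM labeled
RNA; 2 % noise as the realistic plate-reader scale). Generators take
explicit seeds, restore the caller's RNG state, and are byte-deterministic.

They deliberately do **not** emulate: side-chain rotamers and real
chemistry (lobes are CA clouds), crystallographic disorder correlated with
B-factors, water-mediated networks, base-sequence heterogeneity, or
correlated experimental error. Passing tests therefore demonstrate that
the *measurement machinery* is exact on known ground truth and invariant
where it must be (rigid motions, renumbering, seed changes) — not that any
particular biological value is reproduced. Applying the pipeline to the
deposited coordinate entries requires downloading those files once; the
integration test that does so states plainly when they are absent.

## Problem sizes and numerical tolerances

Test and acceptance runs use fixtures of 20–150 atoms per rigid set,
80-residue lobes, 2–12-mer RNAs, and 200 replicate fits at 2 % noise —
sizes at which every check runs in seconds while leaving the estimators
nowhere to hide (noiseless recoveries are asserted at 1e−6 or tighter,
noisy ones against brute-force oracles at 1e−9 of agreement). Rotation
recovery, COM distances and stack counts are exact on noiseless fixtures;
the only stochastic assertions are the median-relative-error bounds on
parameter recovery.

## Known limitations

* Cross-protein comparisons (e.g. a Prp43 state against the Prp22
  reference) need residue-equivalence tables as input; the package
  computes no sequence alignments, and the shipped domain config contains
  ctPrp22 intervals only — homolog rows must be added once, derived from
  an alignment, before such comparisons run.
* Interaction detection is geometric, not energetic; counts respond to
  the cutoffs, which is why every criterion is a reported parameter.
* Water-mediated hydrogen-bond networks are out of scope; only direct
  contacts are detected.
* Purine stacking uses the six-membered ring centroid; a five-ring
  convention would shift borderline geometries.
* The open/closed threshold is a convention over a bimodal empirical
  distribution, not a physical constant; per-chain distances are always
  reported so the classification can be re-derived under any cutoff.
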