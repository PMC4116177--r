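---
title: "Structure-guided design of estrogen receptor binding-domain variants: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-guided design of estrogen receptor binding-domain variants: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erdesign)
```

# The problem

The estrogen receptor alpha (ERα) binds its natural hormone,
17β-estradiol, and a broad family of endocrine disrupting chemicals
(EDCs) in a hydrophobic pocket of its ligand binding domain (LBD,
residues 303–547 in human numbering). Because the LBD is a convenient
bio-recognition element for EDC assays and biosensors, point variants
with higher affinity or stability for particular ligand classes are
practically valuable. `erdesign` implements a rational-design loop for
this problem:

1. define the binding pocket from crystal structures of receptor–ligand
   complexes (distance-cutoff rule);
2. profile the conservation of pocket positions across an ortholog
   alignment and take residues that occur as *natural variants* in other
   species as mutation candidates — a strong prior that the mutant still
   folds;
3. model each candidate point mutation by rotamer-library side-chain
   substitution and score steric clashes against protein and ligand;
4. analyse the validation assays: fluorescence-polarization competition
   curves (IC50), circular-dichroism thermal melts (Tm), and
   fold-change comparisons between receptor variants.

Every stage is driven by synthetic generators with known ground truth,
so the full workflow is testable without downloading anything.

# Pocket definition

A residue belongs to the pocket of one complex when **any of its heavy
atoms lies within 6 Å of any ligand atom**. Choices baked into
`extract_pocket()`:

* **Closed interval** at the boundary (≤ cutoff): the inclusive reading
  of "within". A residue planted at exactly 6.0 Å is in.
* **Heavy atoms, centre-to-centre.** Crystal structures of this
  resolution class carry no hydrogens, and using van der Waals surfaces
  would change the meaning of the cutoff; hydrogens, if present in a
  file, are parsed but excluded so the rule means the same thing for
  every input.
* **6 Å default** is deliberately generous — a conservative, inclusive
  pocket description rather than a contact shell.
* Waters and a fixed ion/buffer list (HOH/WAT/DOD; NA, CL, MG, ZN, CA,
  K, SO4, PO4, GOL, EDO) are never auto-selected as the ligand, and
  crystallographic waters are *not* counted as part of the ligand. This
  is a genuine open choice; if waters mattered, the `het_code` argument
  of `select_ligand()` allows sensitivity analysis.
* Only `MODEL 1` of multi-model files is read (the intended inputs are
  crystal structures), and alternate locations collapse to the
  highest-occupancy copy (ties: lexicographically smallest altloc).

Pockets from several complexes of the same receptor are unioned in
**reference numbering** (`union_pockets()`), with provenance recording
which structure contributed each position. For human ERα-LBD complex
sets this union is the classic set of ~25 non-contiguous residues
around positions 343–535. Which structures enter the union is
configuration (a manifest file), not code: the pocket size depends on
the ligand set, so no structure list is hard-coded. When author
numbering does not already match the reference register (≥95% identity
at shared numbers), `map_to_reference()` computes a global pairwise
alignment (match +1, mismatch −1, gap open −2, gap extend −1) and maps
through aligned columns; mappings below 30% identity are refused.

# Conservation and candidate mutations

Conservation of a column is its **modal-residue fraction**: the share
of counted sequences carrying the most common residue. This is the
simplest statistic consistent with reading a conservation bar chart
where a full bar is 100%; no entropy weighting, no phylogenetic
down-weighting. Counting rules:

* gaps are absence of evidence, not a 21st residue — excluded from both
  counts and `n_effective`;
* ambiguity codes (X/B/Z) are likewise excluded;
* the **wild type is the reference sequence's residue**, not the modal
  residue. The two differ in practice (human ERα carries L349 where
  most species carry M), and candidate mutations must be relative to
  the protein actually being engineered.

`candidate_mutations()` licenses, per position, every non-wild-type
residue observed in at least `min_support` sequences (default 2 — a
single occurrence could be a database or sequencing artefact), ranked
by variant fraction then position. On an ERα-like ortholog set this
yields the familiar 421 series: with ~200 sequences and a 421 column of
mostly M plus 22 F, 5 L and 3 I, the ranked candidates are M421F,
M421L, M421I.

`clean_alignment()` (exact-duplicate removal plus a reference-coverage
threshold, default 0.8) operationalises "duplicate and incomplete
sequences removed". In the orchestrated design stage it runs only when
the config asks (`clean: true`): curated alignments should not be
thinned twice, and the synthetic generator's alignments carry
intentional exact-duplicate rows (see below).

# Mutant modelling

`mutate_residue()` rebuilds the target side chain from **ideal internal
geometry** (bond lengths/angles from standard amino-acid templates)
onto the existing backbone, using the native CB when present, one
placement per rotamer. The rotamer set is an embedded, backbone-
independent table of canonical chi wells (`inst/extdata/rotamers.tsv`):
for phenylalanine χ1 ∈ {−65°, 180°, 62°} × χ2 ∈ {90°, −85°}, with
analogous wells for I/L/M/V/Y; methionine gets the full 27-combination
χ1×χ2×χ3 grid. This minimal library is enough to pose the design
question for the mutations of interest while the template mechanism
stays general; it does not claim equivalence to any published
rotamer-library's statistics, and users can supply their own table.
Atom placement uses the standard internal-coordinate (NeRF)
construction; the CB improper dihedral C–N–CA–CB is fixed at −122° (the
L-amino-acid convention).

Steric strain is scored as soft-sphere overlap:
`overlap(A,B) = rA + rB − d(A,B) − tolerance` when positive, summed
over pairs. Radii: C 1.70, N 1.55, O 1.52, S 1.80 Å; tolerance 0.4 Å —
the conventional soft allowance that keeps near-contacts from counting
as clashes; pairs within 3 covalent bonds (through the mutated
residue's own backbone and the flanking peptide bonds) are excluded.
The backbone is kept rigid; the *unbound* state is scored with hetero
groups omitted, the *bound* state with the ligand included — a large
side chain can often be accommodated in an empty pocket yet clash with
a bound ligand, and the difference is exactly what the design question
needs. `best_placement()` takes the minimum total overlap (ties: lowest
single-pair maximum, then library order).

For aromatic substitutions, `aromatic_proximity()` reports the
centroid distance between the placed ring and a ligand ring —
the geometric quantity behind "does the mutation bring an aromatic ring
near the ligand's ring". Ligand rings can be named or perceived
automatically (bonds from heavy-atom distances < 1.8 Å, 5–6-membered
cycles); with several rings the closest is reported.

# Assay models

**Polarization** is `P = (F∥ − F⊥)/(F∥ + F⊥)`. Instrument literature
uses "polarization" and "anisotropy" interchangeably for this readout;
the implemented formula is exactly the ratio above (an anisotropy
proper would carry `2 F⊥` in the denominator), and the function is
named for what it computes.

**Competition curves** are fitted in log10-concentration space to the
one-site logistic
`y = min + (max − min)/(1 + 10^(hill·(log10 x − logIC50)))`.
The default `three_param` mode fixes hill = 1 (one-site competition);
`four_param` frees it. Both modes exist because assay write-ups
describe the same curve either way; the mode is recorded in the fit
object. Numerical choices: unweighted least squares (plate readers
give no per-well error model), Levenberg–Marquardt, starts at
`min(y)`, `max(y)`, and the log-concentration interpolated at
half-range; zero-concentration control wells are excluded before
fitting (log undefined) and reported separately. Non-convergence and
flat curves (`max − min` indistinguishable from noise) set
`converged = FALSE` instead of raising. Parameter standard errors come
from the fit covariance; IC50 standard errors by the delta method.

**Melt curves** fit the two-state Boltzmann sigmoid
`signal(T) = unfolded + (folded − unfolded)/(1 + exp((T − Tm)/width))`,
with Tm constrained to be honest: a fitted midpoint outside the data's
temperature range flags the fit as not converged.

**Fold changes** compare IC50s after unit normalisation to mol/L
(`fold = IC50_variant / IC50_reference`; < 1 means the variant binds
tighter). "Significantly different" is operationalised as
**non-overlap of the ±1·SE intervals** — a deliberate package
convention, documented as such, not a formal hypothesis test: with
only a point estimate and one standard error per table cell it is the
classification a bench scientist applies by eye, and on the published
ERα table it classifies 4 of 6 ligands as improved for M421F
(estradiol, ethinylestradiol, bisphenol-A, nonylphenol) and leaves
tamoxifen and octylphenol unchanged.

# What the generators emulate — and what they do not

* `make_complex()` builds complexes whose pocket geometry is exact by
  construction: each pseudo-residue's nearest atom is anchored on the
  ligand atom with maximal projection along a random outward direction,
  which makes the planted minimum distance mathematically exact (only
  PDB 3-decimal rounding remains). Residues are 1–5 heavy-atom groups
  with valid records, not folded protein: pocket extraction depends
  only on distances and record classes, so nothing more is simulated.
  Passing the pocket tests therefore demonstrates the distance rule and
  the parsing stack, not anything about real protein geometry.
* `make_alignment()` produces exactly the requested per-column residue
  counts; unspecified columns are fully conserved, so rows are often
  exact duplicates of one another — intentional, and the reason the
  design stage does not dedup silently.
* Assay generators add Gaussian noise scaled to the signal range
  (the simplest model consistent with an unstated error structure) on
  the standard designs: 12 log-spaced concentrations (10⁻¹¹–10⁻⁵ M)
  for competition, 25–90 °C at 1 °C steps for melts. Real plate data
  have heteroscedastic wells, edge effects and outliers; parameter
  recovery under Gaussian noise is a necessary, not sufficient,
  validation.
* All generators are pure functions of their spec including the seed,
  and restore the caller's RNG state.

# Problem sizes and verification

The test suite validates pocket extraction against an exhaustive
all-pairs brute-force oracle on 100 seeded synthetic complexes (plus
cutoff monotonicity), recovers competition parameters on 500 noisy
replicates at IC50 10 nM (σ = 3% of range: median within 5%, ≥90%
Wald-interval coverage), recovers melting temperatures at 59.5, 61.5
and 65.8 °C (noiseless to 0.01 °C; 200 noisy replicates at σ = 2% to
0.5 °C median), and reproduces the published affinity-table arithmetic
exactly. These sizes run in seconds and were chosen as the smallest
that make the Monte-Carlo summaries stable to the stated tolerances.
`scripts/acceptance.R` recomputes the same quantities end to end from
a single seed.

# Known limitations

* Reproducing the 25-residue ERα pocket union requires the real
  crystal structures; they are not shipped (size, third-party data) and
  must be fetched with `scripts/fetch_structures.R` (network), after
  which the corresponding test runs against the pinned three-structure
  manifest. The union size depends on the manifest: more EDC complexes
  can only grow it.
* Side-chain templates cover G/A/V/L/I/M/F/Y — the residue types the
  natural-variant design space of a hydrophobic pocket needs; other
  targets are refused explicitly rather than modelled badly.
* No docking, energies, or conformational search: clash scoring on a
  rigid backbone answers "does it fit", not "how tightly does it bind".
* IC50s are reported as IC50s — no Cheng–Prusoff conversion to Ki, no
  G-factor correction, no vendor plate-file parsing.
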