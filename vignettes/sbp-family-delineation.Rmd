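---
title: "Delineating solute-binding protein subfamilies and their ligand preferences"
author: "sbpfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating solute-binding protein subfamilies and their ligand preferences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbpfam)
```

## The scientific problem

Solute-binding proteins (SBPs) are the capture subunits of bacterial
ABC importers: a bilobed, pear-shaped receptor closes around its cargo
("Venus-flytrap" mechanism) and delivers it to a membrane permease. Within
SBP cluster 5 — historically the di-/oligopeptide and nickel binders — a
*Pasteurellaceae*-specific subfamily of glutathione binders (GbpA) has
emerged by gene duplication from the canonical dipeptide binder DppA, along
with a third, binding-inert group (HbpA2) that conserves the fold but not
the binding site. `sbpfam` packages the computational arms used to delineate
such subfamilies and to characterise their ligand preferences:

1. **Sequence arm** — multiple alignment, distance phylogeny with bootstrap
   supports, and structure-derived *signature fingerprinting*: the set of
   ligand-contacting residues, read off a liganded crystal structure and
   mapped through the alignment, whose conservation pattern diagnoses family
   membership and binding competence.
2. **Thermofluor arm** — apparent melting temperatures (Tm) from
   dye-binding thermal shift curves and ligand-induced shifts (deltaTm)
   screened against a significance threshold.
3. **ITC arm** — a one-site binding model for perfusion-cell isothermal
   titration calorimetry and its nonlinear least-squares fit, yielding Kd.
4. **Structure arm** — Kabsch superposition and the inter-domain
   hinge-opening angle between apo and liganded conformers.

A synthetic-data module generates every input the pipeline consumes, with
known ground truth, so the whole package is testable without downloads and
parameter recovery can be demonstrated quantitatively.

## Sequence arm

### Alignment

Pairwise alignment is global Needleman–Wunsch with affine gaps (Gotoh's
three-state recursion, implemented in C++), scored by BLOSUM62 with gap
open −11 and gap extension −1 — the standard protein defaults, both
configurable. Traceback tie-breaks are fixed (aligned pair over gap in the
first sequence over gap in the second) so outputs are bit-reproducible. The
pairwise kernel is verified in the test suite against exhaustive enumeration
of every alignment for short sequences.

The multiple aligner is progressive: a UPGMA guide tree (average-linkage
`hclust` on `1 − identity` distances; only the merge order matters, so the
uncorrected identity distance suffices) fixes the order in which
sub-alignments are merged, and each merge aligns two profiles with the same
Gotoh kernel. Profile column scores are the mean substitution score over all
non-gap residue pairs between the two columns, with unscaled gap penalties;
for two sequences this reduces exactly to the pairwise aligner. Gaps, once
inserted, are never removed. This is a heuristic: the sum-of-pairs score of
the progressive result is not guaranteed optimal, and the tests assert
optimality (against an exhaustive three-way dynamic program under linear gap
costs) only on near-identical triples where the heuristic is exact. No
iterative refinement is attempted.

### Phylogeny

Distances are observed proportions of differing residues (p-distances) with
pairwise gap deletion by default (complete deletion available), corrected
for multiple hits with a Jukes–Cantor model generalised to 20 states,

$$d = -\tfrac{19}{20}\,\ln\!\left(1 - \tfrac{20}{19}\,p\right),$$

undefined at saturation ($p \ge 19/20$). The classical 4-state nucleotide
form is available behind a flag for cross-tool comparison, since some
phylogeny suites apply the 4-state constants even to protein data.

Trees are built by Saitou–Nei neighbor joining with the standard
Q-criterion. Two degenerate-input policies are fixed for reproducibility:
at equal Q the pair with lexicographically smallest taxon names is joined,
and a negative branch length produced by the NJ formulas is clamped to zero
with the deficit moved onto the sister branch, preserving the path length
between the joined pair (at the final trifurcation, where no unique sister
exists, residual negatives are simply clamped). NJ is exact on additive
matrices; the tests verify that it inverts distances generated from random
trees of up to 12 taxa to machine precision.

Branch supports come from column bootstrapping: columns are resampled with
replacement, the full p-distance → Jukes–Cantor → NJ pipeline is rerun per
replicate (default 100 replicates), and each internal edge of the
point-estimate tree is annotated with the percentage of successful
replicates containing the same bipartition. Replicates that saturate are
dropped and counted in a warning. Because the same NJ pipeline is
bootstrapped (rather than a likelihood method on the NJ topology), supports
are method-consistent but not numerically comparable to ML-based supports
on real data.

### Signature fingerprinting

A `signature_profile` lists ligand-contacting positions of a reference
liganded structure: reference numbering, reference residue, lobe (N/C) of
the bilobed fold, an allowed-residue set, and whether the position forms a
ligand-stabilising salt bridge. `extract_contacts()` derives such profiles
from coordinates as all protein residues with a heavy atom within a cutoff
of any ligand heavy atom; the default 4.0 Å was chosen from the usual
3.8–4.2 Å range used for polar-plus-van-der-Waals contact definitions.

The packaged GbpA profile has 18 positions (13 in the C lobe, which
dominates the glutathione interface) and the DppA profile 10, in the
reference numbering of the respective liganded structures. Only a handful
of these positions are individually named in the literature (GbpA R33,
Y138, A380, S430, D432, Y521; DppA D408); the remaining entries of the
shipped file are synthetic placeholders that reproduce the documented
counts and lobe distribution so that all profile-driven code paths are
exercised — hence the file name `signature_profiles_synthetic.csv`. Users
with access to the real liganded structures can regenerate a fully
structure-derived profile with `extract_contacts()` and drop it in via
`build_default_profiles(path =)`.

Classification maps each profile through the alignment via its reference
row (aborting loudly if the reference residues do not match — a guard
against numbering drift), computes per-profile match fractions, and calls
the best-matching family when its fraction reaches the threshold (default
0.75) *and* no binding-incompatibility flag stands against that profile.
Flags are raised at salt-bridge positions occupied by a charge-reversing or
physicochemically dissimilar residue (BLOSUM62 score with the reference
residue at or below zero). The threshold and the veto together encode the
biology of the HbpA2 group: its members conserve roughly 10 of the 13
C-lobe GbpA contacts (fraction ≈ 0.77) yet carry salt-bridge-breaking
substitutions (R33T, D432R, and D408R against DppA), so they fall to
`"HbpA2-like/unknown"` rather than being absorbed into GbpA. Conservation
scoring is strict by default (exact reference residue); a relaxed mode
admits conservative substitutions (BLOSUM62 > 0).

## Thermofluor arm

Melt curves are two-state sigmoids between linear baselines; the apparent
Tm is the temperature of the signed extremum of dF/dT. The extractor
smooths with a centred 5-point moving average (preserving a 1 °C-wide
transition at 0.5 °C sampling while damping shot noise), takes centred
finite differences on the (possibly non-uniform) grid, and refines the
extremum by parabolic interpolation through it and its two neighbours,
giving sub-grid precision. Both derivative-sign conventions are explicit
options: dye-binding unfolding curves rise, so the default takes the
maximum of dF/dT; instruments that export an inverted derivative are served
by `derivative_sign = -1`. Neither convention is guessed from the data. The
scan window defaults to the full measured grid (the generator's default
grid is the standard 30–90 °C scan); a narrower window can be set
explicitly. A curve whose derivative extremum does not exceed the window's
median derivative by at least five median absolute deviations is rejected
as "no transition", which catches flat and monotone-drift curves without
tuning per-instrument noise floors.

Shift tables difference holo against apo Tm (replicates averaged at the Tm
level), mask entries below the significance threshold (default 1.5 °C,
inclusive at the boundary, so a shift of exactly 1.5 °C is reported), and
order ligands by descending shift. Tm extraction is invariant to affine
transforms of the fluorescence and to a common baseline slope, which the
tests assert; recovery simulations (200 seeded curves, Tm in 40–85 °C, 2%
noise) bound the bias below 0.1 °C and the RMSE below 0.3 °C.

## ITC arm

The forward model tracks a perfusion cell: each injection of volume $v_i$
displaces the fraction $v_i/V_0$ of the current cell content, so totals
follow $M_i = M_{i-1}(1 - v_i/V_0)$ and
$X_i = X_{i-1}(1 - v_i/V_0) + X_0 v_i/V_0$. The bound complex is the exact
one-site mass-action root

$$[MX]_i = \tfrac12\Big[(nM_i + X_i + K_d) -
  \sqrt{(nM_i + X_i + K_d)^2 - 4\,nM_iX_i}\Big],$$

cumulative heat $Q_i = \Delta H\,V_0\,[MX]_i$, and the reported injection
heat carries the displaced-volume correction
$q_i = Q_i - Q_{i-1} + (v_i/V_0)(Q_i + Q_{i-1})/2$ — the standard
treatment for overfilled-cell instruments, fixed here for reproducibility.
The tests verify the closed-form root against a bisection solver of the
mass-action equation to $10^{-10}$ relative.

Fitting minimises squared residuals over $(n, \log K_a, \Delta H)$ — the
log parameterisation keeps the association constant positive — with
Levenberg–Marquardt from a heuristic start plus a fixed fan of ±50%
perturbed starts to escape shallow minima; the best converged start wins,
so the procedure is deterministic. The customary small first injection is
excluded by default. Standard errors come from the Jacobian at the optimum,
with the Kd error propagated from $\log K_a$. Heats of dilution are assumed
negligible (as in well-matched buffers); an optional constant per-injection
offset is available as a nuisance parameter. A residual standard deviation
above 5% of the largest heat raises a lack-of-fit flag, which catches
biphasic (multi-site) data. Identifiability follows the Wiseman c-value
$c = nM_0/K_d$: recovery is sharp for $c$ within roughly 1–1000 and
degrades outside, which the tests assert as increasing error rather than
"fixing" — it is a property of the experiment design, not of the code. The
`fraction_bound()` helper computes equilibrium occupancy $L/(K_d + L)$
under ligand excess, the calculation relevant to weak binders (e.g. a
655 µM hemin site at 0.5 mM hemin is ~43% occupied, which is why a gel
band splits near its Kd).

## Structure arm

Superposition is Kabsch's SVD solution with the reflection case corrected
to a proper rotation; collinear or under-determined point sets are
rejected. The hinge-opening angle between two conformers superposes
structure B onto A by the paired C-lobe C-alpha atoms, then extracts the
rotation that best superposes the already-C-lobe-aligned N lobe of B onto
that of A; its angle (from the rotation trace) is the hinge opening.
C-alpha-only pairing is the default because it is robust to side-chain
differences between paralogs; for paralogous pairs the residue
correspondence can be derived from the pairwise sequence alignment
(`pair_residues_by_alignment()`, ungapped columns only). Lobe residue
ranges are supplied as data (`domain_definition()`), not hard-coded. Angle
recovery on simulated rigid hinge pairs is exact to better than 0.1°
across 5–120°, including at the ~33° opening characteristic of an apo SBP
against its liganded paralog.

## The synthetic generators, and what passing tests do and do not show

* `simulate_family_sequences()` draws a random ancestor, mutates it at an
  inter-clade rate per clade and a within-clade rate per sequence
  (i.i.d. per site, replacement uniform over the 19 alternatives), then
  plants each clade's diagnostic residues exactly. Defaults: 5 sequences
  per clade, 540 residues, 0.05 within- and 0.5 between-clade
  substitutions/site, signatures from the packaged profiles with the HbpA2
  clade carrying the literature-described substitutions (R33T, A380P,
  S430T, D432R, D408R). It emulates clade-structured divergence only: no
  indels, no rate heterogeneity among sites, no realistic substitution
  process, no compositional bias. Perfect classification on these families
  therefore demonstrates the mapping/scoring machinery, not robustness to
  real evolutionary noise.
* `simulate_melt_curve()` is the exact two-state sigmoid with linear
  baselines and Gaussian noise — no aggregation artefacts, no
  multi-transition unfolding, no dye depletion.
* `simulate_itc()` is the forward model plus Gaussian heat noise — no
  baseline-integration error, no active-site titration error in M0.
* `simulate_hinge_pair()` moves a rigid N lobe about an exact hinge point —
  no internal lobe deformation.

Recovery results on these inputs validate the estimators under their own
assumptions (an internal-consistency check of the kind instrument software
never exposes); performance on real data is bounded by how well those
assumptions hold.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 15-sequence families
(3 clades × 5) of 540 residues with 100 bootstrap replicates; 200 seeded
melt curves for Tm-recovery statistics and duplicate curves per condition
elsewhere (2% noise, matching careful plate-reader practice); 26-injection
titrations (3 µL primer + 25 × 10 µL, 1.4 mL cell) with 20 replicates per
affinity cell and designs holding c between 20 and 100; 20-atom-per-lobe
hinge pairs. These sizes give stable statistics while keeping the whole
suite around half a minute. All randomness flows through explicit integer
seeds; generators restore the global RNG state, so library code never
perturbs a user's stream. Coordinates are rounded to PDB precision (0.001 Å)
at generation so structure files round-trip exactly; the ITC CSV stores
instrument units (µL, µM, µcal), and the decimal unit conversion
round-trips values to within one ulp.

## Known limitations

* The progressive aligner has no iterative refinement; deep alignments of
  highly diverged clades can contain locally suboptimal gap placements
  (the three-clade recovery criterion passes regardless, because distances
  and fingerprints are robust to a few misplaced columns).
* Bootstrap supports are NJ-consistent, not comparable to ML supports.
* The packaged signature profiles are partially synthetic placeholders (see
  above); structure-derived counts on real PDB entries are exercised here
  only through synthetic reference complexes built to the documented
  geometry.
* The ITC arm fits integrated per-injection heats; raw power traces and
  their baseline integration are out of scope, as are multi-site and
  sequential binding models.
* No rooting/outgroup logic is provided — trees are unrooted by design.
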