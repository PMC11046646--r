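---
title: "Models and methods behind pilusmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pilusmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pilusmech)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters that matter, what
the synthetic-data generators do and do not emulate, and the numerical and
design choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Helical filament model

A type IVa pilus is modelled as a 1-start helix: subunit *k* is related to
subunit 0 by a rotation of *k*·twist about the z axis composed with a
translation of *k*·rise along z. All derived descriptors follow from two
numbers:

* subunits per turn = 360 / twist (deg),
* pitch (Å) = subunits per turn × rise (Å),
* subunits per µm = 10⁴ / rise (Å).

For the tightly packed filament symmetry of twist 100.7° and rise 10.0 Å
this yields 3.575 subunits per turn (3.6 at one decimal), a pitch of
35.75 Å and 1,000 subunits per micron.

Assumptions and choices:

* The filament axis is fixed on z; inputs must be pre-posed (deposited
  helical models conventionally are). No axis-fitting helper is provided.
* Handedness is an explicit input, never inferred from coordinates. A
  right-handed helix advances its rotation positively with +z.
* Multi-start helices are out of scope (`start_number` is fixed at 1).
* The default neighbour range for interface work is k ∈ [−9, +9], so the
  central subunit has every offset through ±7 fully surrounded with margin.
* The radial profile reports Σ(x²+y²)² per subunit as a *comparative*
  bending-stiffness proxy (stiffness scales with the fourth power of the
  radial mass distribution); it is not an absolute flexural rigidity.

## Solvent-accessible surface area and buried interfaces

SASA uses the Shrake–Rupley construction: each atom's van der Waals sphere
is inflated by the probe radius (water, 1.4 Å); a quasi-uniform point set
on that sphere is tested against all neighbouring inflated spheres; the
exposed fraction times the sphere area is the atom's SASA.

* **Point set.** A deterministic Fibonacci (golden-spiral) lattice, 960
  points per atom by default (minimum 92). Determinism was chosen over
  Monte Carlo so results are reproducible bit for bit; the isolated-sphere
  case is then *exact* and the two-sphere case agrees with the analytic
  spherical-cap formula to well under 1% at the default point count.
* **Radii.** The Bondi (1964) van der Waals set, bundled as a named table;
  unknown elements fall back to 1.8 Å with a warning. The table behind the
  published interface-area server is not printed anywhere, so a single
  documented published set is used instead.
* **Neighbour search.** A uniform spatial grid with cell edge
  2·max(r+probe), contractually identical to the all-pairs scan (a test
  asserts bit-identity).
* **Buried area.** The N:N−k interface area is
  (SASA(A)+SASA(B)−SASA(A∪B))/2 on the *isolated pair*, the halving
  convention under which PISA-style interface areas are reported. Since
  published totals do not always state their convention, the unhalved
  difference is also reported, flagged as such. A context mode evaluates
  the same difference with all remaining subunits present; it is not the
  default because pairwise evaluation matches how interface servers score
  an interface.
* **Canonical frame.** Before any area is computed the pair is mapped back
  into the frame of subunit 0, so results are exactly independent of which
  subunit is taken as central (the helical-invariance property).
* **Interface calls.** An offset counts as an interface when its halved
  buried area is ≥ 10 Å² — a numerical-dust threshold surfaced in every
  report. Per-pilin totals are exactly twice per-subunit totals; partner
  counts are twice the class count (partners above and below).
* **Salt bridges.** Arg/Lys/His side-chain nitrogens against Asp/Glu
  carboxylate oxygens at ≤ 4.0 Å minimum N–O distance, His counted as
  basic — a common convention; the underlying study names pairs but prints
  no cutoff. Pairs are deduplicated to residue pairs keeping the minimum
  distance, in both charge orientations.
* **Helix segmentation.** Dihedral-window assignment (φ ∈ [−100°, −30°],
  ψ ∈ [−80°, −5°], runs ≥ 4) instead of hydrogen-bond (DSSP-style)
  assignment, so no hydrogens are required — the right trade-off for a
  3 Å cryo-EM heavy-atom model. Windows are parameters. The first helical
  run is α1-N, the second α1-C, the gap between them the melted stretch;
  author residue numbering is authoritative throughout. Run-edge
  assignments can differ from visual assignments by a residue or two.

## Worm-like-chain persistence length from 2D traces

Filaments adsorbed on a grid before blotting equilibrate in two
dimensions, so the tangent-angle correlation decays as
⟨cos θ(s)⟩ = exp(−s/2Lp) — note the factor 2 relative to the 3D decay
exp(−s/Lp). The package fixes the 2D convention as the default and offers
a `dim = "3d"` flag for projected, non-equilibrated data. A regression
test guards the factor: reading 2D-equilibrium data through the 3D formula
misestimates Lp by exactly a factor of two.

* **Tangent-correlation estimator.** Correlations are pooled over all
  tangent pairs at each arc-length separation across traces, then fitted
  by weighted least squares on log ⟨cos θ⟩ through the origin, weights
  proportional to pair counts. The fit range is truncated (with a flag) at
  the first non-positive correlation.
* **MSD estimator.** The pooled mean-squared end-to-end distance is fitted
  to ⟨R²(s)⟩ = 4Lp[s − 2Lp(1 − e^{−s/2Lp})] by one-parameter weighted
  least squares on log Lp. In the rigid limit the form reduces to s², so
  straight ensembles return an infinite-stiffness sentinel rather than a
  number.
* **Fit range.** Default s_max = min(shortest contour/2, 2·mean contour),
  standard practice to avoid the noise-dominated tail; the original
  study's supplementary choice is not printed, so neither estimator claims
  to reproduce its numerics on real micrographs.
* **Uncertainty.** Bootstrap over traces (not points), 200 replicates by
  default, 95% percentile interval. Fewer than three traces yields no CI,
  flagged.
* On synthetic 2D-equilibrium ensembles (200 traces of 4 µm at 10 nm
  steps) both estimators are unbiased within Monte-Carlo error across
  Lp ∈ {11, 13, 21} µm; the acceptance suite verifies mean recovered/true
  within [0.9, 1.1] over 20 replicate ensembles per value.

## AFM force–distance signatures

Retraction curves are classified into *nanospring* (approximately linear
Hookean rise ending in sharp rupture), *plateau* (constant-force extension
before rupture), *both*, or *none*.

* **Baseline.** Two passes: a robust (Theil–Sen) line over the final 10%
  of samples removes gross offset/drift; the last above-threshold event is
  then located and the drift line refitted by least squares over the whole
  post-rupture tail. The second pass exists because extrapolating a line
  fitted on 10% of the curve across its full length amplifies slope noise
  by an order of magnitude.
* **Event detection.** On a running-median (window 7) smoothed force, the
  last contiguous run ≥ 40 pN of at least 5 samples before the final
  return to baseline. Only that event is scored (single-pilus
  assumption); the rupture edge is then refined on the raw force, since
  the running median retreats from an instantaneous rupture by half its
  window.
* **Thresholds.** Plateau: slope ≤ 0.2 pN/nm over ≥ 50 nm at ≥ 40 pN,
  measured on the flat top (≥ 85% of event peak) ending at the rupture
  edge. Nanospring: linear fit r² ≥ 0.9 (judged on the smoothed rise over
  15–97% of peak so short rises keep enough samples) with slope
  ≥ 0.5 pN/nm, ending in a > 50% force drop within 10 nm. The study names
  the signatures but prints no thresholds; these defaults are declared
  configuration, validated on the labelled synthetic suite, and not
  claimed to replicate the original event detection on real data.
* **Parameters.** k_pilus is the least-squares slope between 20% and 95%
  of peak force (avoiding the nonlinear toe and the rupture edge); the
  rupture force is the fitted line extrapolated to the rupture distance,
  which is exact for an ideal spring and unbiased under noise; the plateau
  force is the median over the flat window. Forces to 500 pN are in range.

## Pilin sequence survey

Prepilins carry a class III signal peptide cleaved between the Gly and
Phe of the GFxxxE motif; the mature pilin starts at the Phe (position 1,
so the conserved Glu is position 5 and the conserved Pro is position 22).

* **Motif scan.** Positions 1–60; a strict pass requires Phe at +1, a
  fallback admits F/I/L/M/V (genuine prepilins deviate at +1); first match
  wins, and the strict count remains recoverable from the per-record flag.
* **Size classes.** Mature length ≥ 166 aa is "large" — the published
  criterion, chosen just above the largest structurally characterized
  major pilin; the boundary semantics (165 standard / 166 large) are
  tested explicitly.
* **Redundancy filter.** Greedy clustering in descending length order
  (ties by identifier): a sequence joins the first retained representative
  with global-alignment identity (matches / alignment columns; match 1,
  mismatch 0, gap open 1, gap extend 0.5) above 0.90, else becomes a
  representative. The published pipeline names the cutoff but not the
  aligner, so the scoring is configuration and logged. The implementation
  aligns with Biostrings; an independent hand-written Needleman–Wunsch
  oracle checks the clustering on synthetic families.
* **Summaries.** Mature-length mean, population SD, min/max and
  large-pilin percentages (integer-rounded) globally and per phylum/class;
  taxa under 1% of records are routed to "other". Records without a motif
  are excluded and counted in a drop log, so counts are conserved at every
  stage.
* **Consensus.** Mature sequences are stacked from their shared N terminus
  without gapped alignment — appropriate because the α1-N region is
  essentially ungapped across major pilins — and positions 1–55 are
  flagged conserved at ≥ 60% frequency among covering sequences.

## Synthetic data: the stated world

Each generator realizes the conditions its consumer is specified and
tested under; parameters are fixed once and not tuned to outcomes.

* **Toy subunit.** An ideal α-helix (1.5 Å rise, 100°/residue, 52
  residues; Cα plus one dummy side-chain sphere per residue) as a column
  at radius 7.5 Å, plus a globular shell of pseudo-atoms (radius 8 Å at
  radial offset 11.5 Å, carved where it would interpenetrate the helix).
  Under (100.7°, 10.0 Å) the copies pack with ≥ 3 interface classes, and
  removing the globule removes at least one class — a monotone ablation
  mirroring how the globular domain, not the helix core, supplies the
  additional contacts in tightly packed pili. It emulates packing
  geometry only: no real side chains, no charges, no sequence.
* **WLC traces.** Tangent angles perform a Gaussian walk with per-step
  variance ds/Lp (2D-equilibrium convention); 200 traces of 4 µm contour
  at 10 nm steps per ensemble, Lp at the published comparison values
  (11/13/21 µm). No imaging noise, no tracing error, no excluded-volume
  or boundary effects — so a green recovery test establishes estimator
  correctness, not robustness to micrograph artefacts.
* **FD curves.** Nanosprings (k ~ N(5.5, 0.5) pN/nm, rupture
  ~ N(120, 12) pN), plateaus (~ N(220, 20) pN over ~ N(120, 25) nm after
  a steep grab), and empty curves, mixed 40/30/30, with 5 pN Gaussian
  noise, a ~10 pN baseline offset and up to 0.005 pN/nm drift; rupture is
  instantaneous and snapped to the sampling grid so the labelled truth is
  realized on the curve. Real curves show multiple events, nonlinear
  toes, and slow ruptures; multi-event curves are deliberately scored
  only on their final event.
* **Prepilins.** Random signal peptide (5–30 aa ending in the motif Gly,
  redrawn until the planted motif is the first match), mature length from
  a truncated normal (mean 141, SD 25, range 42–297 aa — the published
  distribution), Glu5 always (part of the motif), Pro22 planted at 80%,
  per-taxon large fractions configurable (e.g. 0.93 to emulate a
  Myxococcota-like taxon), optional ~97%-identity duplicates for the
  redundancy filter.
* **Determinism.** One root seed fans out via a counter-based scheme, so
  generating more items never reshuffles earlier ones; identical
  specifications reproduce identical artifacts.

## Known limitations

* The acceptance surfaces that require externally deposited data (the
  cryo-EM filament model and the curated 1,955-prepilin table) cannot run
  offline; the corresponding tests fail honestly until local copies are
  supplied, and the acceptance script omits those targets with a
  documented rationale.
* SASA point counts trade speed for accuracy; buried areas at 960 points
  agree with 3,840 points to better than 2% on the toy filament, but
  absolute areas on large real filaments carry the usual lattice
  discretization error.
* The MSD persistence-length estimator is nearly degenerate when the
  contour is much shorter than Lp (the signal is a few-percent deviation
  from s²); pooled ensembles of ≥ 200 traces are recommended, as in the
  acceptance protocol.
* The survey's ungapped N-terminal stacking is correct for the conserved
  α1 region but would misalign genuinely gapped N termini; the consensus
  window is capped at 55 residues for that reason.
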