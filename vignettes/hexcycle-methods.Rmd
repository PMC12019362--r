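---
title: "Dissecting the catalytic cycle of a hexameric pilus motor ATPase"
author: "hexcycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting the catalytic cycle of a hexameric pilus motor ATPase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexcycle)
```

## The system and the analysis

PilT/VirB11-like motor ATPases power the assembly and disassembly of type
IV filaments. The Tad (tight adherence) pilus of *Caulobacter crescentus*
is driven by a single bifunctional motor, CpaF: a hexamer whose chains each
comprise an intrinsically disordered region (IDR, residues 1–79, never
resolved), a pore-lining three-helix bundle (3HB, 80–146), an N-terminal
domain (NTD) and a canonical C-terminal ATPase domain (CAD) joined by a
flexible linker. Cryo-EM has captured the hexamer in three conformations —
closed (apo), compact (up to four nucleotides) and expanded (six
nucleotides) — and comparing them supports a rotary model of catalysis:
paired ATP binding and hydrolysis events expand the ring and rotate its
two-fold axis clockwise by 60°, and paired ADP release contracts it back.

`hexcycle` turns that comparative analysis into a reusable pipeline:

1. **Structure I/O** — PDB/mmCIF models in, author residue numbering
   throughout, ATP/ADP/Mg ligands separated from protein chains.
2. **Domain scheme** — a configurable residue-interval map carrying every
   anchor the measurements use (D116, C196, R217, R223, G284, K287, T288,
   E312, E331, R347, …).
3. **Rigid geometry** — Kabsch least-squares superposition, swing/twist
   decomposition of rotations about the hexamer axis, symmetry-axis
   detection, distances and displacements.
4. **State classification** — nucleotide-to-pocket assignment, conformer
   clustering, arginine-finger states, ATP\* detection.
5. **Packing units** — one full chain plus the CAD of the adjacent chain,
   the unit that owns one nucleotide pocket.
6. **Cycle mapping** — the 60° register between two states, per-domain
   rotations and anchor displacements for each catalytic event.
7. **Pore metrics** — extended-pore-loop heights in the axis frame.
8. **Energetics** — extension speed and helical rise converted to pilin
   and ATP consumption rates.
9. **Synthetic structures** — seeded toy hexamers with planted ground
   truth, the package's primary oracle.

## Packing units and the active-site pocket

The hexamer oligomerises hand-to-shoulder: the NTD of one chain packs
against the CAD of its neighbour, and the nucleotide pocket sits between a
chain's own Walker A motif (anchored at G284/K287/T288) and the α9 helix of
the *adjacent* chain's CAD, which contributes the arginine finger R347.
A packing unit is therefore one full chain plus the adjacent CAD. Units
are named `{Clo|Com|Exp}-{ATP|ADP|Apo|ATP*}`, numbered within the
asymmetric unit when a label repeats (`Exp-ADP1`, `Exp-ADP2`), with a
trailing `'` marking the second C2 copy so names stay unique.

Which neighbour donates its CAD is resolved geometrically, not by chain
lettering: for each chain the candidate R347 Cα nearest its Walker A
centroid casts a vote, and the majority fixes the donor direction for the
whole ring. A majority (rather than unanimity) is used because in open
(apo) pockets the facing R347 has swung away and can sit farther from the
pocket than the opposite neighbour's R347; the donor direction is a global
property of the ring, so the pooled vote is the robust estimator.

## Nucleotide assignment and chain states

Each ATP/ADP ligand is assigned to the chain whose Walker A Cα centroid
lies nearest its phosphate centroid, within `contact_cutoff` (default
10 Å); two pockets within `ambiguity_margin` (0.5 Å) of the same ligand
raise an error rather than a silent guess. Mg²⁺ attaches to the pocket of
its nearest nucleotide and never defines a state on its own. ATP analogues
(AMP-PNP and relatives) are normalised to ATP and flagged. Any other
nucleotide-like ligand is reported as `other` and the chain treated as
apo — mirroring the bookkeeping used for the closed state, where residual
pocket density is deliberately not modelled as a nucleotide.

Chains are then clustered into conformers: all-vs-all Cα superposition of
the folded domains, single-linkage clustering at `linkage_cutoff`
(default 2 Å, above the ~1 Å intra-conformer spread of real chains and far
below inter-conformer differences). A chain whose pocket is empty but
whose conformer group contains ATP-bound chains is labelled **ATP\***.
This definition makes ATP\* detection inherently comparative: a lone apo
hexamer with no ATP-bound reference chains anywhere in the clustering
cannot reveal ATP\*, which is why `label_chain_states()` accepts
`reference` models (the deposited closed state is classified jointly with
the nucleotide-soaked structures, exactly as the original 18-chain
analysis grouped all three hexamers at once).

## Arginine-finger states

R347 (adjacent CAD) and R217/R223 (owner NTD) are classified per unit:

* **engaged** (ATP pockets): R347 has a guanidinium nitrogen within
  `hbond_cutoff` (3.5 Å) of a γ-phosphate oxygen, the R347–G284 Cα
  distance is at most `d_engaged`, and the CA→CZ direction points at the
  pocket; R217/R223 point at the occupied pocket.
* **disengaged** (ADP pockets): side chains orient away from the pocket
  and the α9/Walker A interface opens beyond `d_engaged`.
* **intermediate** (apo and ATP\* pockets): R347 points inward toward the
  hexamer pore while R217/R223 still face the (empty) pocket, primed for
  an incoming ATP.

`d_engaged` defaults to 10 Å, the midpoint between the ~8 Å engaged and
~15 Å disengaged regimes observed in the real structures. The
intermediate-vs-disengaged direction test (inward radial for R347, pocket
direction for R217/R223) is this package's geometric operationalisation of
a distinction the source structures describe qualitatively; it is a
package definition, stated here so users can audit it, and every report
echoes the thresholds used.

## Mapping the catalytic cycle

Two states are compared by (i) finding each hexamer's symmetry axis (the
best-fit rotation by 360/order degrees mapping each chain onto its mate;
for C2 on a hexamer chain *i* pairs with *i*+3), (ii) searching the cyclic
chain-register shifts for the one under which every label transition is
catalytically consistent — APO→ATP (binding), ATP→ADP (hydrolysis),
ADP→ADP (carried) — and (iii) fitting the inter-state alignment on the
**carry** chains, the ones not undergoing an event, so that event-specific
motions do not bias the frame. The consistent one-position shift *is* the
60° register (shifts *s* and *s*+3 are equivalent under C2, so the
canonical representative is ±1); its sign, viewed from the platform-facing
top of the hexamer, gives the clockwise direction summary. The measured
twist of the alignment about the axis is reported alongside as a
diagnostic and should agree with the register to within a few degrees.

ADP release is not coupled to binding/hydrolysis in the expanding
transition, so it is mapped in the contracting direction: the expanded
state is superposed back onto the compact state on the same axis, the
original compact model standing in for the post-cycle hexamer. The
`Exp-ADP2` units (the carry targets of the forward map) pair with
`Com-Apo` units there. One consequence of this bookkeeping is that the
`Com-Apo` units appear twice — as sources of binding events and targets of
release events — which is precisely how the cycle closes through them.

Per event, each domain (3HB, NTD, owner CAD, adjacent CAD) is separately
superposed between the aligned states and the transform's **twist** about
the hexamer axis — the rotation component about that axis from the
swing/twist (quaternion) decomposition — is reported with a signed,
viewpoint-explicit convention: clockwise as seen from the platform-facing
side is positive, and the viewpoint is a parameter everywhere a signed
angle appears, because a camera convention is not something a number can
carry implicitly. Anchor displacements (D116, C196, G284, E331) are Cα
distances after the whole-hexamer alignment.

If the two models arrive in the reverse temporal order, the forward search
fails, the opposite order is mapped, and the result is inverted (register
negated, binding and release kinds swapped). Two identical states map with
register 0 and are flagged non-catalytic.

## Pore metrics

Pore-loop heights are coordinates along the hexamer axis, measured
relative to the plane of the six Walker A centroids, so only differences
are meaningful. The extended pore loop (T325–T337) is referenced by the
E331 Cα by default; an interval-centroid mode is provided because the
loop "tip" is not defined numerically anywhere authoritative. The
asymmetric-unit height span is max−min over three cyclically consecutive
chains. D116–D116 distances between adjacent 3HBs and a pore-diameter
estimate (twice the mean radial D116 distance) complete the table.

## ATP economics

A filament extending at *v* Å/s with helical rise *h* Å per pilin adds
*v/h* pilins per second; a rotary cycle spending 2 ATP to assemble 3
pilins (one paired binding+hydrolysis event per 60° step, one pilin per
platform heterodimer) consumes *v/h·(2/3)* ATP per second. For the Tad
pilus (750 Å/s, 5 Å rise) that is 150 pilins/s and 100 ATP/s; for the
*P. aeruginosa* T4aP (3600 Å/s, 10 Å rise), 360 pilins/s and 240 ATP/s.
The arithmetic is exact in the inputs.

```{r energetics}
assembly_rates(750, 5)
assembly_rates(3600, 10)
```

## The synthetic generator: what it emulates and what it does not

The generator builds six idealised Cα traces (3HB/NTD/CAD mimics reusing
the 80–501 numbering so the default scheme applies unchanged) arranged
about the z axis at 60° spacing, with proxy side chains for the three
arginines and planted ATP/ADP/Mg ligands. Its key design property is that
every label-dependent placement is a rigid twist about the hexamer axis
plus a translation:

* CAD: clockwise twist 42° (ATP/ATP\*) vs 0° (ADP/apo), z lift 7.5/3/0 Å
  for ATP/ADP/apo — the lift is what elevates the pore loop of
  nucleotide-bound chains;
* 3HB+NTD: clockwise twist 30° for ADP chains (so hydrolysis, ATP→ADP,
  carries the planted 30° rotation), inward shift 3 Å for ATP chains.

Because these are exact rigid motions about the axis and compose
additively, the per-domain twist of every catalytic event equals the
difference of the label twists — the planted 42° binding rotation and 30°
hydrolysis rotation are recovered by the full pipeline (file round-trip,
state labelling, register search, carry-chain alignment, domain
superposition, twist decomposition) to numerical precision on noise-free
fixtures, and to within ~1.5° at 0.3 Å coordinate noise. Pocket-anchor
positions were designed once so that, under the default thresholds, ATP
pockets classify engaged (R347–G284 ≈ 6–7 Å, hydrogen bond planted at
2.9 Å), ADP pockets disengaged (≈ 14–30 Å) and apo pockets intermediate,
for every label pattern the cycle produces; the planted interface
distances recorded in the ground-truth manifest are the construction's own
analytic values, not the distances of any real structure.

What the toy does **not** emulate: real folds (the mimics are abstract
traces), side-chain rotamer libraries, the magnitude of real pore-loop
height spans (17–26 Å in the deposited hexamers; the toy's default span is
7.5 Å because its loop height rides on a rigid CAD lift that must also
keep engaged pockets closed — larger planted spans are exercised on apo
fixtures), correlated or anisotropic coordinate error, partial occupancy,
or unmodelled residues. Passing the closure suite therefore demonstrates
that the *analysis machinery* is correct and self-consistent, not that
real cryo-EM models will reproduce any particular number; the
deposited-structure validations cover that, and they require the PDB
entries to be downloaded (see `inst/extdata/deposited/`).

Chain counts other than six, and uniform-ATP hexamers (whose every pocket
would need to be simultaneously engaged across a 42° twist, which the
geometry cannot satisfy), are rejected at spec validation. Fixtures with
`symmetry = "none"` add a small per-chain rigid jitter (≤ 0.8°, ≤ 0.4 Å),
enough to break exact C2 while keeping every classification margin.

## Numerical choices and degenerate inputs

* Superposition is Kabsch via SVD with the determinant sign correction;
  collinear point sets warn and return one of the equivalent optima.
  The test suite cross-checks against an independent closed-form
  quaternion (Horn) solution at 1e-9 Å.
* Twist extraction uses the quaternion projection
  `2*atan2(q·a, q_w)`, numerically stable through 180°.
* The C2 axis direction of a 180° rotation is sign-ambiguous; the
  orientation with a non-negative z component is reported. The axis point
  is the Cα centroid projected onto the axis.
* Symmetry-axis fits whose residual exceeds `axis_residual_ceiling`
  (default 3 Å) are flagged, and asymmetric assemblies fall back to the
  Cα-cloud plane normal for chain ordering.
* mmCIF residue numbering uses author numbering as canonical, because all
  anchors are author-numbered; insertion codes at anchor positions are an
  error rather than a guess. Highest-occupancy alternate conformers win.
* The NTD/CAD split is not a published number; it defaults to residue 270
  (past loop 8, before Walker A, inside the flexible linker) and is
  configurable. No anchor-based measurement depends on it.
* Single-linkage clustering at cutoff 0 keeps non-identical chains in
  singleton groups; at infinite cutoff everything merges — the grouping
  coarsens monotonically in the cutoff.

## Problem sizes used by the test and acceptance suites

The closure study runs 25 seeded fixtures (20 single hexamers spanning
exact C2, exact C6, 0.2–0.5 Å noise and asymmetric cases, plus 5 state
pairs), each a full hexamer of ~2 700 atoms; the acceptance script repeats
an independent 18-fixture study and the energetics arithmetic. These sizes
keep the whole suite inside a couple of minutes on one CPU while giving
every classifier margin estimates at the noise levels stated above.

## Known limitations

* ATP\* detection requires ATP-bound reference conformers in the joint
  clustering; a lone apo hexamer reports plain APO chains.
* The register is defined on the canonical one-position shift; assemblies
  whose label patterns admit no consistent shift (or an ambiguous one)
  error out with the per-register mismatch table rather than guessing.
* Event displacement tables require the anchors to be modelled in both
  states; missing anchors are reported as `NA`, not interpolated.
* The contracting-direction release map reuses the earlier state as a
  stand-in for the post-cycle hexamer; for real pairs this is exact only
  insofar as the hexamer returns to the same compact conformation.
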