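---
title: "How turnscout decides whether a scaffold mimics a reverse turn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How turnscout decides whether a scaffold mimics a reverse turn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package answers

Reverse turns reverse the direction of a peptide chain and are central
recognition elements in bioactive peptides. The common types are defined
by an intramolecular hydrogen bond and the ring it closes: a γ-turn
closes a 7-membered pseudo-cycle (a 5→3-type N–H···O=C contact), while
the rarer α-turn spans five residues and closes a 13-membered ring
(5→1, i.e. i+4 → i). A designed scaffold "mimics" a turn when its
accessible conformers place a donor N–H and an acceptor C=O so that the
corresponding ring closes, and when the surrogate Cα(1)–Cα(5) distance
d~α~ falls below the generic reverse-turn probe of 7 Å.

turnscout implements the complete computational protocol by which such
claims are usually established for a small constrained scaffold:

1. a conformer ensemble from a Monte-Carlo multiple-minimum (MCMM)
   search over a molecular-mechanics energy function;
2. duplicate removal and a relative-energy window (default 6 kcal/mol);
3. per-conformer turn geometry: hydrogen bonds classified by
   pseudo-cycle ring size, the d~α~ probe, virtual φ/ψ torsions;
4. Boltzmann population statistics over the windowed ensemble;
5. φ/ψ-region labels composed into a turn designation (e.g. "B-aL-X")
   and a classic/inverse γ-turn call;
6. independent solution-phase evidence from amide-proton NMR:
   temperature coefficients and DMSO titration shifts.

The package ships the tetracyclic THBC-DKP
(tetrahydro-β-carboline / 2,5-diketopiperazine) methylamide scaffold in
both C6 epimers (`thbc_dkp_smiles()`) as its worked example. The
structure is reconstructed from its published IUPAC name — no
machine-readable form is deposited — and is therefore validated before
every use by elemental formula (C~27~H~29~N~5~O~5~) and neutral
monoisotopic mass (503.2169 Da). Exact-mass arithmetic uses a
hard-coded table of most-abundant-isotope masses so that the six
published HRMS reference values (`hrms_reference()`) reproduce
bit-stably; printed EI "calcd" values match the *neutral* molecule to
four decimals, so no electron-mass correction is applied.

## The pseudo-residue map

A non-peptidic scaffold has no canonical backbone, so the mapping from
scaffold atoms to turn positions 1–5 is explicit data (`role_map()`),
not perception. For the THBC-DKP scaffold, `derive_thbc_roles()`
locates the atoms by local connectivity: the C-terminal methylamide
N–H is the position-5 donor; the Cbz carbamate carbonyl is the
position-1 acceptor (its benzyl *ether* oxygen, taken literally as
"the benzyl oxygen", serves as the Cα1 surrogate — this is
configurable); the DKP carbonyl adjacent to the glycine-like methylene
is the position-3 acceptor; the N-methyl carbon is Cα5. The virtual
backbone triples run
Cbz–NH–CH~2~–C6–N(ring)–C12a–C(=O)–N(DKP)–CH~2~–C(=O)–NHMe.

Ring sizes are counted as the atoms on the shortest covalent path from
the donor *hydrogen* to the acceptor *oxygen*, inclusive of both — the
convention that yields the familiar C7/C13 labels. Shortest paths are
breadth-first searches on the bond graph; the two equal-length routes
around the DKP ring tie, and the tie is irrelevant to the size. With
this convention the scaffold's 5→3 contact closes a 7-ring and its
5→1 contact a 13-ring, which is the scaffold's entire claim to α-turn
mimicry in graph terms.

Which pseudo-residue carries the γ-turn φ/ψ? The 7-ring encloses the
residue between the position-3 carbonyl and the position-5 N–H, i.e.
pseudo-residue 4; `role_map()$gamma_residue` records this. (Empirically
the γ-class circular means of φ~4~/ψ~4~ land near (−80°, +73°), the
inverse-γ window, while residue 3 sits near (−170°, −40°) — residue 3
cannot be the γ centre.)

## The conformational search

`mc_search()` is a usage-directed basin-hopping MCMM driver: each start
perturbs a random subset of the rotatable torsions of a parent drawn
from the current low-energy pool, and the backend minimizes it.
Non-amide torsions are redrawn uniformly; amide C–N torsions take a
normal step (SD 40°) about their current value, keeping trans amides
trans (the scaffold's DKP amides are constrained near trans; cis
sampling is out of scope). The default is 972 starts — the ensemble
size of the protocol this package re-implements — with a 6 kcal/mol
window whose boundary is inclusive (a conformer at exactly the window
edge is retained).

Why basin hopping rather than independent random embeddings? Measured
during development: for the 6S epimer, 274 independent distance-
geometry embeddings followed by MMFF94 minimization *never* reached the
13-ring folded basin, although that basin contains the MMFF94 global
minimum (2.5 kcal/mol below the best unconstrained-embedding minimum).
The folded α-turn conformation is a deep but narrow funnel; a Monte
Carlo chain that reseeds from the evolving low-energy pool finds it
within a few dozen starts.

Two safeguards matter more than they might appear. First,
*stereochemistry is enforced, not assumed*: a torsion-perturbed start
can be clashed badly enough that unconstrained force-field
minimization pushes a ring hydrogen through the ring plane and
inverts a stereocentre — after which basin hopping happily amplifies
the wrong diastereomer (observed during development: the 6R-epimer
search converged onto the mirror-image α-fold of an inverted-C12a
species). `mc_search()` therefore compares the tetrahedral parity of
every minimized conformer at the graph's declared stereocentres
against the starting structure (`stereo_parity()`) and discards
mismatches. Second, *two-fold symmetric rotors* (a bare phenyl ring)
are compared modulo 180°, since a 180° flip permutes equivalent atoms;
without this, every phenyl-containing minimum counts twice.

Duplicate minima are merged greedily, lowest energy first: two
conformers are one minimum if all rotatable-torsion differences are
below 20° (circular, period-aware) *or* their best-fit heavy-atom
RMSD is below 0.5 Å. These tolerances are not prescribed by the
protocol being mirrored; they were chosen once to merge vibrational
noise without merging distinct wells, and both are configurable
(`search_config()`). An energy pre-filter (|ΔE| > 1 kcal/mol skips the
geometric comparison) is an optimization only: true duplicates of
minimized conformers have near-identical energies. The driver merges
on the fly to keep the pool small, but its final answer is produced
by a last greedy pass over the whole pool: merging by replacement is
not transitive (a new, lower representative can duplicate members
already cleared against the old one), whereas the greedy
lowest-first pass keeps a mutually non-duplicate set by construction.

The energy function is deliberately *not* part of the contribution: it
is a pluggable backend. The production backend is RDKit's MMFF94
implementation (ETKDG distance-geometry embedding for the initial
structure, MMFF94 minimization), driven through a small bundled Python
worker over batched subprocess calls; batching amortizes interpreter
start-up and has no effect on results. The analytic torsion backend
(`backend_torsion()`) exposes the same interface for arbitrary R energy
functions of the torsion vector and is how the driver is tested against
closed-form ground truth: on a three-well torsional potential the
driver recovers exactly the minima found by a dense 1° grid scan.
Backend absolute energy zeros differ; only relative energies within one
backend are ever used. Minimization inside `backend_torsion()` uses
L-BFGS-B with a tight convergence factor — plain BFGS measurably stalls
on periodic torsional surfaces.

Determinism: all randomness flows from `search_config()$seed` through
an isolated RNG stream (`withr::with_seed`), and the embedding and
minimizer are deterministic, so identical (graph, config, backend,
seed) reproduce the ensemble bit-for-bit.

## Hydrogen-bond criteria and the d~α~ probe

The geometric thresholds for calling an H-bond are not part of the
mirrored protocol (it reports only which bonds exist), so turnscout
uses common practice defaults: H···O ≤ 2.5 Å and ∠N–H···O ≥ 120°,
config-exposed in `hbond_criteria()`, plus a heavy-atom-only mode
(N···O ≤ 3.5 Å) for ensembles without explicit hydrogens. Contacts
closing rings smaller than 5 atoms are excluded — this removes the
trivial 4-ring an amide's own H→O contact would close. Every reported
contact re-satisfies its criteria by construction, and the d~α~ probe
is strict (`dalpha < 7` fails at exactly 7 Å).

## Regions, designations, γ-turns

The published α-turn typology's region boundaries are not reprinted in
the source the package follows, so the default `region_map()` uses
calibrated stand-in rectangles — A: φ∈[−140,−30), ψ∈[−90,45);
B: φ∈[−180,−30), ψ∈[45,180]; aL: φ∈[30,180], ψ∈[−10,120); fallback X —
evaluated first-match-wins with closed-low/open-high boundaries (an
upper bound of exactly 180 is closed so the wrapped domain (−180,180]
is fully covered and every pair receives exactly one label). These
rectangles reproduce the reference torsion averages as "B-aL-X" but do
not claim equivalence with the published nine-type classification; the
map is data (YAML-serializable), so users can substitute the literature
definition. γ-turn windows are symmetric about the canonical
(∓75°, ±65°) ideals: inverse φ∈[−110,−50), ψ∈[40,110); classic the
mirror image.

Ensemble statistics follow the textbook definitions: Boltzmann weights
with R = 0.0019872 kcal mol⁻¹ K⁻¹ at a default 298.15 K (the
temperature is not stated in the mirrored protocol; room temperature
matches the NMR comparison and is configurable), circular means for
torsion averages, and class populations as summed weights. The α-turn
class is "members with the 13-ring H-bond", the γ class "members with
the 7-ring". Mean d~α~ over the α class is unweighted (the reference
value is quoted as a plain average); a Boltzmann-weighted variant is
reported alongside. Torsion means that feed the designation are taken
over the α class when it is non-empty, otherwise over all windowed
members. The γ-class central φ/ψ averages (`gamma_phi`, `gamma_psi`)
are Boltzmann-weighted: the reference protocol quotes them "on
average, based on the conformers accounting" for the dominant share
of the population, and weighting implements that population
restriction without an arbitrary cumulative cut-off — an unweighted
mean over every γ-flagged window member would instead be dominated by
the window's high-energy tail, which carries negligible population. The reported α-class population uses the windowed ensemble as
its denominator; since the window captures essentially all Boltzmann
mass at room temperature (a 6 kcal/mol cut-off leaves < 10⁻⁴ of the
population outside), the distinction from "all generated conformers"
is numerically immaterial.

## NMR evidence

In CDCl₃, an amide proton's temperature coefficient Δδ/ΔT discriminates
hydrogen-bonding states: turnscout classifies |Δδ/ΔT| ≥ 4 ppb K⁻¹ as an
equilibrium between bonded and free states, ≤ 3 ppb K⁻¹ as uniformly
non-bonded, and the gap as indeterminate. DMSO titration (0→30% v/v)
gives a second, independent axis: a shift response below 0.5 ppm marks
a solvent-shielded (intramolecularly bonded) N–H, at or above it an
exposed one. The two thresholds are not universal constants; they were
fixed once so that the four published observables of the reference
scaffold (7.0 and 2.3 ppb K⁻¹; 0.24 and 0.82 ppm) classify as the
original interpretation reads them, and they are arguments, not
constants, in the code. Slopes are least-squares fits over all points
(signed, classified on magnitude — the published values are absolute,
so the underlying sign is unrecoverable); titration deltas depend only
on the endpoints. DMSO-mode temperature-coefficient semantics (the
opposite convention) are out of scope; the `solvent` argument reserves
the namespace.

## The synthetic-data module

Real multi-conformer references for this scaffold do not exist in any
databank, so validation substrates are built in code.
`build_backbone()` places ideal glycine-like backbones atom by atom
from internal coordinates (NeRF placement; N–Cα 1.458 Å, Cα–C′
1.525 Å, C′–N 1.329 Å, C′=O 1.231 Å, N–H 1.010 Å; angles
111.0°/116.2°/121.7°; ω fixed at 180°; carbonyl O and amide H trans in
the amide plane). The builder is exact enough that recomputing φ/ψ
from the coordinates reproduces the spec within 0.5°, and it generates
the canonical positive controls: an all-(−63,−42) pentapeptide closes
the 13-ring with Cα1–Cα5 ≈ 6.3 Å; a central-(−75,65) tripeptide closes
the inverse-γ 7-ring; an all-trans chain closes nothing.
`make_decoys()` draws φ/ψ uniformly for negative controls;
`make_energy_set()` and `make_nmr_series()` produce labelled energies
and linear-with-noise shift series with known ground truth.

What the synthetic substrate does *not* emulate: side chains, force-
field energetics (decoy class labels are assigned, not computed), cis
amides, solvent. Passing tests on these substrates therefore validate
the *geometry and statistics machinery*, not the force field; the
scaffold-level conclusions rest on the MMFF94 ensembles.

## Problem sizes and reproducibility

The package's own validation runs use: 972-start MCMM searches per
epimer for the ensemble-level checks (the full protocol size; about
three minutes per compound with the MMFF94 backend on one core),
50-start searches for the analytic-potential driver checks, 100
decoys, and 200 replicates for the NMR slope-recovery statistics.
`scripts/acceptance.R` re-runs the full pipeline from scratch —
structure reconstruction, validation, both 972-start ensembles,
windowing, flagging, statistics — from a single `--seed` argument.

## Known limitations

* The MMFF94 ensemble is a gas-phase picture; solvation and entropy
  are not modelled, so Boltzmann fractions are qualitative weights,
  not free-energy populations.
* Ring-pucker space is explored only through minimization from
  perturbed (optionally jittered) geometries, not by explicit ring
  sampling; for scaffolds whose turn geometry hinges on a flexible
  ring this may undersample (`jitter_sd` mitigates).
* Exact conformer *counts* in a 6 kcal/mol window are force-field- and
  duplicate-criterion-dependent and should be read qualitatively;
  class dominance, ring-size taxonomy and torsion means are the robust
  outputs.
* `derive_thbc_roles()` is scaffold-family-specific by design; other
  scaffolds need a hand-written `role_map()`.
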