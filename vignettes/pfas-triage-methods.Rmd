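---
title: "Methods: in silico triage of PFAS chemicals against nuclear receptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in silico triage of PFAS chemicals against nuclear receptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfastriage)
```

## The screening problem

Per- and polyfluoroalkyl substances (PFASs) are a large, structurally
diverse family of fluorinated organics, many of which are suspected
endocrine disruptors. A practical way to prioritise thousands of such
chemicals for experimental follow-up is a computational triage: dock every
library member against the ligand-binding domains of the nuclear receptors
of interest, estimate a binding free energy for the docked pose, compare
both scores against those of known (reference) ligands, and gate the
surviving candidates through receptor-specific activity classifiers.

`pfastriage` implements everything around the two commercial engines of
such a campaign. Docking scores, MM-GBSA binding free energies and
machine-learning activity labels are *inputs* (CSV tables); the package
supplies the library curation, the reference-anchored decision rules, the
consensus calling, a PFAS taxonomy, chemical-space mapping, interaction
fingerprints, and a seeded synthetic generator that emulates the missing
engines so the entire pipeline is testable offline.

Ten receptors are supported: AR, ERA, ERB, GR, PR, PPARA, PPARD, PPARG,
MR and RXRA. Eight have activity models (binding-class models for AR, ERA,
ERB, GR, PR and PPARG, which label chemicals agonist / antagonist /
agonist–antagonist / inactive; effector models for PPARD and RXRA, which
label active / inactive). MR and PPARA have no models and are triaged on
the scores alone.

## Library curation

An entry is included when it parses, contains a perfluorinated unit, and
carries at least three fluorine atoms; duplicate structures are removed on
their InChIKey. Two choices deserve comment.

* **"Perfluorinated unit"** is implemented as a saturated carbon bearing
  at least two fluorines — the SMARTS `[CX4](F)F`, i.e. a CF2 or CF3
  group. This is the minimal moiety common to working PFAS definitions;
  a stricter CF2–CF2 chain rule would exclude trifluoromethyl acids that
  PFAS inventories contain. The pattern is an argument, not a constant.
* **Filter order** is fixed — parseability, perfluorinated unit, fluorine
  count, deduplication — so each excluded entry carries exactly one
  deterministic reason, and audit counts always sum to the library size.
  Deduplication keys on the InChIKey of the largest covalent fragment
  (salts dropped first), falling back to canonical SMILES when no InChIKey
  can be produced; the first occurrence in input order survives.

Ionisation, tautomer and stereoisomer enumeration is deliberately out of
scope: triage operates per chemical identifier, so one neutral-form record
per chemical suffices.

## Shortlisting and binder-strength classification

For each receptor the reference ligands define two anchors: their **best**
(most negative) docking score and binding free energy, and their **mean**
of each metric. Both anchors are honoured because they serve different
rules:

* **Shortlist** — a candidate is shortlisted when both metrics lie within
  10% of the best reference value:
  $\mathrm{dock} \le 0.9\,\mathrm{dock}^{\mathrm{best}}_{\mathrm{ref}}$ and
  $\Delta G \le 0.9\,\Delta G^{\mathrm{best}}_{\mathrm{ref}}$
  (scores are negative, so the bound is 10% less favourable than the best
  reference). The two criteria are conjunctive, and the threshold is a
  parameter.
* **Strength** — each metric's percent change against the reference mean,
  $100\,(x - \bar{x}_{\mathrm{ref}})/\bar{x}_{\mathrm{ref}}$, is averaged
  over the two metrics; a chemical is a *strong* binder when the average
  exceeds 0, *moderate* in $(-10, 0]$, and *weak* at or below $-10$. With
  negative scores this sign convention makes stronger-than-reference
  binders positive. Chemicals failing the shortlist are reported
  `not_shortlisted`, never `weak`, so summary tables count only
  shortlisted chemicals.

One algebraic consequence of the dual anchors is worth stating. If the
best reference is at least as favourable as the mean
($x^{\mathrm{best}} \le \bar{x} < 0$), then any shortlisted candidate
satisfies, per metric,

$$\mathrm{pc} \;=\; 100\left(\frac{x}{\bar x} - 1\right)
  \;\ge\; 100\left(\frac{0.9\,x^{\mathrm{best}}}{\bar x} - 1\right)
  \;\ge\; -10,$$

with equality only when the references are all identical. Shortlisted
chemicals therefore always classify strong or moderate; a weak percent
change and a passing shortlist are mutually exclusive under these rules.
The synthetic generator respects this: planted weak binders carry an
average percent change at or below −10 *and* fail the shortlist, and their
stratum is recovered from the percent-change statistic rather than from
the strength column. It also means the strength histogram over actives
contains no weak binders — a property of the rules, not a bug.

## Consensus calling

For the eight receptors with models, a shortlisted chemical becomes an
active call only when its predicted label is an active mode, and the label
is carried through (`active_agonist`, `active_antagonist`,
`active_ago_ant`, `active`). For MR and PPARA the shortlist alone decides.
Supplying a label for MR or PPARA is treated as a contract violation, as
is a shortlisted chemical without a label at a model receptor.
Out-of-applicability-domain predictions are retained (the flag is kept and
reported, not used to drop rows).

## PFAS taxonomy

Classes are assigned by an ordered substructure-rule hierarchy shipped as
data (`inst/extdata/pfas_class_rules.yaml`): each rule has a priority, a
primary and secondary class, and a conjunction of SMARTS patterns; the
first matching rule wins and a catch-all guarantees total coverage. The
priority order places side-chain aromatics first (an aromatic core with a
perfluoroalkyl chain outranks an acid head), then the perfluoroalkyl acids
(PFCAs, PFSAs), the perfluoroalkane sulfonamide family (FASAs, N-alkyl
FASAs, sulfonamido acetic acids and ethanols), the fluorotelomers (n:2
alcohols and acrylates), perfluoroalkane sulfonyl fluorides, and other
aliphatics (with perfluoroethers as a named subclass). Users can override
or extend individual rules from a YAML file without touching code. The
acceptance surface for the builtin rules is a 22-compound panel of
literature-consensus assignments (PFOA, PFOS, PFBA, 6:2/8:2 FTOH, n:2
acrylates, FOSA and N-alkyl derivatives, sulfonyl fluorides, side-chain
aromatics, and perfluorinated aliphatics).

## Chemical-space map

Structures are encoded as Morgan / extended-connectivity fingerprints of
radius 2 (ECFP4). The OpenBabel implementation emits fingerprints folded
to 4096 bits; the package refolds them to the requested length (default
2048) by OR-ing positions modulo the target width. The map is a batch-mode
Kohonen self-organizing map: each epoch assigns every fingerprint to its
best-matching unit (BMU: minimal Euclidean distance, ties to the lower
row-major unit), then replaces each codebook vector by the
Gaussian-neighbourhood-weighted mean of the assigned data. The
neighbourhood sigma decays linearly from `max(rows, cols)/2` to 1 grid
unit; codebooks initialise from a seeded uniform draw. Batch updates were
chosen over online updates because they are order-independent (exactly so
for 0/1 data, where all accumulations are integer sums) and easier to
test; the quantization error is recorded after every epoch and is
non-increasing in practice across seeds. The default grid is 20×20
rectangular — large enough to separate a few hundred structures without
starving units. Activity overlays label each unit with the modal final
call of its chemicals, ties resolving to `inactive` as the conservative
default, and unoccupied units reported as empty rather than inactive.

## Interaction fingerprints

Protein–ligand complexes (PDB) are reduced to one bit triple per residue:
hydrophobic contact, residue-donated hydrogen bond, residue-accepted
hydrogen bond. The geometric criteria follow common interaction-
fingerprint practice and are all arguments: apolar heavy atoms (C, S, and
halogens including fluorine on the ligand side; C and S on the residue
side) within 4.5 Å constitute a hydrophobic contact; donor–acceptor pairs
of N/O atoms within 3.5 Å form a hydrogen bond, additionally requiring a
donor–H–acceptor angle of at least 120° whenever explicit hydrogens are
present (without them the distance criterion alone decides). Fluorine is
treated as hydrophobic, not as an acceptor, by default — the perfluoroalkyl
chain is the hydrophobic moiety of a PFAS — with a toggle for the acceptor
role. Fingerprints over a shared residue universe are compared by
Tanimoto similarity, defined as 1 when both fingerprints are empty.

## The synthetic generator

The generator stands in for the library download, the docking and MM-GBSA
engines, and the activity models. Its defaults describe the study
conditions under which the package's properties are verified: a 500-entry
library with 30% planted decoys (no fluorine, fewer than three fluorines,
no CF2/CF3 unit, duplicates), and per-receptor score tables with binder
strata planted at fractions 0.1 / 0.2 / 0.3 / 0.4 (strong / moderate /
weak / nonbinder). Reference docking scores centre on −10 kcal/mol — the
range typical of nuclear-receptor docking — with a 0.5 kcal/mol spread,
and binding free energies on −50 ± 2.5 kcal/mol.

Counts are apportioned by largest remainder, never sampled, so planted
fractions are recovered exactly. Candidate scores are *solved from the
decision inequalities*: strong binders get positive percent changes on
both metrics, moderate binders sit inside the shortlist bound with an
average in (−10, 0], weak binders sit below −10 (and hence outside the
shortlist, as shown above), and nonbinders fail the shortlist on exactly
one metric while keeping a moderate-band percent change, which keeps them
distinguishable from weak binders. Reference draws are normal, followed by
a deterministic rescaling of their deviations (sample mean preserved)
whenever the realised best/mean ratio would make a stratum unconstructible
— without it, the moderate and nonbinder strata become infeasible with
small probability at any seed. Activity labels are assigned among the
shortlisted chemicals at a configurable rate, with a deterministic count
of label flips emulating classifier error.

What the generator does *not* emulate: realistic force-field energetics,
pose geometry, score–structure correlation (scores are independent of the
generated SMILES), or learned activity boundaries. Passing the recovery
tests therefore demonstrates that the decision logic is implemented
exactly as specified — not that the pipeline would reproduce any
particular experimental screening outcome.

Toy protein–ligand complexes are written with exact coordinates at PDB
precision, so the planted contact list is the ground truth for the
fingerprint detectors, including under random rigid-body transforms.

## Numerical choices and degenerate inputs

* Boundary placement: an average percent change of exactly 0 is moderate
  (strong requires strictly more than 0); exactly −10 is weak. Shortlist
  comparisons use non-strict inequalities, so a candidate equal to the
  bound, or to the best reference itself, passes.
* A zero reference mean makes the percent change undefined and is an
  error, as are non-negative best reference scores in the shortlist rule.
* BMU ties resolve to the lower row-major unit index; activity-overlay
  ties resolve to `inactive`; empty units are empty, not inactive.
* SOM codebooks serialise to JSON with 17 significant digits so reloaded
  models resolve distance ties identically.
* `r_squared` requires at least three finite pairs and non-zero variance;
  potencies are used as provided, with an explicit flag for log10
  transformation, whose state is the caller's record.

## Problem sizes used by the test suite

The suite verifies curation on 500-entry libraries (30% decoys), triage
recovery on 1000 chemicals × 10 receptors, map properties on 500 random
2048-bit fingerprints (50 epochs) and three planted clusters on a 6×6
grid, interaction-fingerprint recovery across 50 rigid-body transforms,
and end-to-end determinism of two full pipeline runs on a 100-entry
fixture. These sizes exercise every code path at a scale a laptop handles
in about a minute.

## Known limitations

* The package ingests scores and labels; it cannot assess their quality,
  and the triage output is only as good as those inputs.
* The taxonomy is a practical subset of PFAS terminology (13 rules), not
  an exhaustive nomenclature; polymers are out of scope.
* Interaction typing covers hydrophobic contacts and hydrogen bonds only
  — no π-stacking, salt bridges or halogen bonds.
* The SOM emulates the usual batch toolkit behaviour; it does not
  reproduce any specific published map layout, and map appearance depends
  on the seed and grid size.
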