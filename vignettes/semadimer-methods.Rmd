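---
title: "Methods: structural accounting of semaphorin dimerization"
author: "semadimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural accounting of semaphorin dimerization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semadimer)
```

## The scientific problem

Insect class 1 and class 2 semaphorins are axon-guidance ligands whose sema
domains (seven-bladed beta-propellers) engage plexin receptors as dimers. The
structural questions this package operationalises are:

* how large is a semaphorin homodimer interface, and how is it partitioned
  between the sema domain, the C-terminal Ig-like domain, and N-linked
  glycans;
* whether a given ectodomain is covalently locked into a dimer by an
  interchain disulfide bond (and which cysteine is responsible, or which
  substitution removes it);
* how similar two paralogues are in sequence (percent identity) and in
  structure (core rmsd over trimmed C-alpha equivalences), how mobile the
  Ig-like domain is (hinge angle), and how rigid the fold is across an
  ensemble (per-residue RMSF);
* which positions in the (transferred) plexin-binding site have
  class-specific residue chemistry and therefore plausibly set receptor
  specificity;
* how tightly a semaphorin binds its plexin (apparent Kd from a titration);
* and what oligomeric state a measured molar mass implies.

Every stage is a pure function of explicit inputs, so the same code path runs
on deposited crystal structures and on the package's synthetic generators.

## Interface accounting

Solvent-accessible surface area is computed by the Shrake–Rupley method: each
heavy atom carries a Chothia-style radius (C 1.87, N 1.65, O 1.40, S 1.85 Å;
overridable) inflated by a 1.4 Å water probe, and a deterministic Fibonacci
lattice (default 960 points per atom) is tested against all overlapping
neighbour spheres. Waters and hydrogens are excluded; glycan and ligand heavy
atoms are included. The lattice is fixed in the laboratory frame; passing the
molecule's rotation as `orientation` co-rotates the lattice and makes the
result exactly invariant, a convention the tests exercise. With the fixed
lattice, re-orienting a molecule moves totals by well under 0.5% at 960
points.

Buried surface area between groups A and B is
`SASA(A) + SASA(B) − SASA(A∪B)`, i.e. the *sum over both partners*, not the
halved "interface area" — the per-component contributions of a full partition
then sum to 100% by construction. A residue is an interface residue when it
loses more than 0.1 Å² (interface membership for the receptor-site transfer
uses a more conservative 1 Å²; sensitivity to 0.1/1/5 Å² can be probed by
changing a single argument). Glycans attached to a chain (see below) travel
with that chain's group, which is what makes a "glycan share of the buried
surface" well defined.

Contacts are typed by distance only, because crystal structures carry no
hydrogens: disulfide (Cys SG–SG ≤ 2.3 Å), salt bridge (Asp/Glu carboxylate O
to Lys/Arg/His basic N ≤ 4.0 Å), hydrogen bond (N/O pairs ≤ 3.5 Å),
remaining heavy-atom pairs ≤ 4.0 Å as nonbonded; each pair is reported once
under its most specific type.

## Glycan attachment

A sugar residue (codes NAG, NDG, BMA, MAN, FUC, GAL; extendable) is rooted at
an asparagine when one of its carbons lies within 2.0 Å of the Asn side-chain
ND2, and further sugars chain through O–C links within 1.8 Å. The walk only
regroups atoms — coordinates never change. A sugar reachable from two
different Asn roots is a hard error (it would make the per-chain partition
ambiguous); sugars reachable from none are reclassified as free ligands and
excluded from glycan-share arithmetic.

## Superposition, hinge and RMSF

Rigid superposition is the Kabsch SVD solution with reflection correction.
Residue equivalences between two structures come from a global sequence
alignment of their amino-acid content, then the fit is trimmed iteratively:
pairs deviating by more than `max(2 × rmsd, 3.5 Å)` are discarded and the fit
repeated (at most 10 cycles). The surviving pairs define the *core rmsd* and
the "over N C-alpha atoms" count. The 2.0 multiplier and the 3.5 Å floor are
package choices — published core-rmsd figures rarely state their trimming
schedule — and both are arguments; the floor dominates for well-superposing
pairs, which keeps the core honest for rmsd values below ~1.75 Å.

Hinge angles superpose the two conformers on an anchor selection (e.g.
sema+PSI), then Kabsch-fit the mobile selection (e.g. the Ig-like domain);
the residual rotation angle `acos((tr(R)−1)/2)` is the hinge. The result is
invariant under any global rigid motion of either model, which is tested.

Ensemble RMSF superposes every frame on the evolving mean structure (two
fit→mean iterations), then takes per-residue C-alpha fluctuations around the
mean. The rigid-body fit absorbs 6 of the 3N coordinate degrees of freedom,
deflating RMSF by roughly `sqrt(1 − 2/N)`; at the ensemble sizes used here
that is a ≤2.5% effect, which the recovery test tolerance accommodates.
Values are reported in Å, or nm on request.

## Sequence layer

Pairwise alignment is an affine-gap global (Gotoh) dynamic programme over
BLOSUM62 with gap open 10 and extension 0.5; a gap of length L costs
`open + extend·(L−1)`. Percent identity divides identical aligned pairs by
gap-free aligned pairs (an alignment-length denominator is available — the
literature rarely states which convention produced a printed identity, so
both are exposed). The small progressive MSA seeds with the most similar
pair and adds sequences by best identity to the profile (ties broken by
lexicographic id, making column structure reproducible under input
reordering); profile columns score as the mean substitution score over
non-gap letters.

Sequon scanning finds every N-X(≠P)-[S/T] motif, overlapping occurrences
included, in the protein's own numbering. Residue chemistry uses a fixed
five-class partition (hydrophobic AVLIMFWY, polar STNQCH, positive KR,
negative DE, special GP). Histidine sits with the polar class because it is
predominantly neutral at physiological pH; a `reclassify` argument moves it
if a charged treatment is wanted.

## Specificity hot-spots

The receptor-binding site is transferred from a reference ligand–receptor
complex: reference-ligand residues burying > 1 Å² against the receptor are
mapped through the residue pairing of a trimmed superposition of the
reference ligand onto each query. A hot-spot is an alignment column, touched
by at least one transferred interface, where residue chemistry is *uniform
within each class but different between classes*. Uniformity means identical
chemistry class, not identical residue — with any within-class sequence
variation at all, requiring identical residues would call essentially
nothing, while requiring only a majority would call far more than a curated
set; the chemistry-class rule is the middle ground this package commits to.
Calls are labelled as hydrophobic/polar swaps or charge swaps and reported in
a chosen reference member's numbering.

## Structure-based tree

The pairwise metric is `D = rmsd_core / coverage` with
`coverage = n_matched / min(len_a, len_b)`, symmetrised by averaging both
superposition directions. Published structure-tree software often uses
likelihood-based scores whose exact form is not reproducible from a paper;
this surrogate is declared openly and is validated only at the topology
level (planted classes must come out monophyletic; additive and ultrametric
matrices must reconstruct exactly), never on branch lengths. Tree building
itself is standard neighbour-joining and UPGMA (via `ape` and `phangorn`),
with Newick output.

## Binding model

Titrations are fitted with the exact 1:1 mass-action solution including
ligand depletion,

`f = ((R + L + Kd) − sqrt((R + L + Kd)² − 4·R·L)) / (2R)`,

because the labelled-species concentration in thermophoresis experiments can
sit near the Kd of a tight binder (single-digit nM), where the simple
hyperbola is biased. The signal model `S = s_free + (s_bound − s_free)·f` is
linear in its endpoints, so the fit profiles them out analytically and
searches only log-Kd (25-point grid spanning `[min(L)/100, max(L)·100]`,
then golden-section refinement). This makes the estimate exactly invariant
to affine rescaling of the signal and fast enough for dense bootstrap use.
Uncertainty is a case-resampling bootstrap (default 200 resamples,
seed-controlled). "No measurable binding" is declared when the lower 2.5%
bootstrap bound on Kd exceeds the largest titrated concentration, *or* when
the fitted amplitude is indistinguishable from zero (within 2 bootstrap
s.d.) — a flat titration constrains no Kd at all, so the amplitude condition
is what actually recognises the flat class-crossed-pairing case.

## Oligomeric state

Theoretical construct mass is the average-isotope protein mass (residue
masses plus one water) plus 1.7 kDa per occupied N-glycosylation site — a
typical paucimannose-type increment for kifunensine-free HEK material; the
increment is an argument and is logged. The copy number `n` minimises the
relative deviation `|m_obs − n·m_theor| / (n·m_theor)` over n = 1..6, and a
verdict is only issued when that deviation is within 15%. The tolerance is
deliberately wide: glycoform heterogeneity alone moves observed masses by
several percent (a 75 kDa observation against a 70 kDa theoretical monomer
is a ~7% deviation and still an unambiguous monomer). Heterodimer checks
compare the observation against the sum of the two component masses.

## What the synthetic generators emulate

The generators provide, under a single integer seed each:

* `make_toy_domain` — a compact, self-avoiding C-alpha trace (3.8 Å steps,
  backbone bends of 100–150°, non-adjacent C-alpha pairs ≥ 6 Å) with ideal
  backbone stubs (N, CA, C, O, CB) and a cysteine-free random sequence.
  These are geometry carriers, not folded proteins: no secondary structure,
  no Ramachandran statistics, no packing energetics. They are sufficient —
  and intended only — for area, contact, and superposition arithmetic,
  which is geometry-only.
* `make_c2_dimer` — a two-fold symmetric dimer with at least 20 interchain
  heavy-atom contacts within 4.5 Å, optionally planting the two features the
  dimerization analysis keys on: an interchain disulfide (surface residue
  pair mutated to Cys, SG atoms 2.05 Å apart) and a three-sugar NAG-NAG-BMA
  glycan on a surface Asn of each chain placed so that ≥ 5 glycan atoms sit
  within 4 Å of the partner chain without clashing.
* `make_structure_family` / `make_sequence_family` — families with planted
  class structure: a rigid sub-domain shift between classes plus Gaussian
  coordinate noise; sequences identical up to class-specific chemistry at
  planted positions plus optional background substitutions.
* `make_titration` — two-fold dilution series from 1000×Kd downwards
  (16 points by default) with multiplicative Gaussian noise; the labelled
  species sits at 5 nM, which is deliberately *not* negligible against the
  tightest preset so the depletion model is actually exercised.
* `make_molar_mass_obs` — masses scattered around integer multiples of a
  monomer mass.

Because the toy structures lack real protein features, a passing test shows
that the *arithmetic* (areas, partitions, distances, angles, recoveries) is
correct, not that biological conclusions transfer to any particular real
structure; conversely the planted features are constructed to be
unambiguous, so any recovery failure is a genuine code defect.

## Problem sizes and numerical choices

The shipped tests run 40-residue domains (about 450 atoms per dimer),
240–960 sphere points, 100-seed × 5-preset Kd recovery with 200 bootstrap
resamples, 500-frame RMSF ensembles, and exhaustive alignment enumeration
for sequence pairs up to length 8 — sizes chosen so the whole suite
completes in a few minutes while every oracle remains exact or
statistically sharp. Ties in alternate-location resolution keep the first
record; NJ tie-breaking follows `ape`; selections use author residue
numbering with inclusive ranges throughout.

## Known limitations

* mmCIF support covers the canonical `atom_site` loop (reading via `bio3d`,
  writing a minimal canonical loop); exotic categories are ignored.
* No symmetry expansion: interfaces are computed on the chains present in
  the model, so lattice-contact analysis is out of scope.
* Hydrogen-bond calls are distance-only and will over-call at grazing
  geometries.
* The structural-distance surrogate is not calibrated against any published
  structure-tree score; only topology-level statements should be read from
  the trees.
* Reproductions that require deposited crystal structures (interface sizes,
  hinge angles, paralogue rmsd values of the real semaphorins) run only
  where the public structure archive is reachable; the corresponding test
  states this explicitly when the files cannot be obtained.
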