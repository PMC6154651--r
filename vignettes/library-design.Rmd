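---
title: "Designing a diverse triterpenoid 3-O-ester library"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing a diverse triterpenoid 3-O-ester library}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esterlib)
```

## Overview

`esterlib` implements the in-silico half of a scaffold-derivatization
campaign: starting from a large catalogue of carboxylic acids, it curates
the catalogue down to drug-like, chemically well-behaved building blocks,
selects a structurally diverse subset by fingerprint clustering, and
enumerates the corresponding 3-*O*-esters of oleanolic acid with exact mass
bookkeeping, ready for external docking. This vignette documents the model
behind each stage, the conventions and defaults, and the design choices
that were genuinely open.

## The molecular model

Molecules are hydrogen-suppressed graphs: heavy atoms carry element,
formal charge, an implicit-hydrogen count and an aromaticity flag; bonds
carry integer orders. Structure input (SMILES line format and SDF V2000)
is parsed through OpenBabel via ChemmineOB, one record at a time so that a
malformed record is reported with its line number instead of corrupting
the batch. Implicit hydrogens are assigned by a default-valence model:
the smallest allowed valence state that accommodates the bond-order sum is
filled with hydrogens, with charges shifting the allowed valence for
N/P/O/S/Se and reducing it for charged carbon. Stereochemistry is parsed
but ignored throughout — the pipeline is two-dimensional.

**Aromaticity.** Input bonds arrive kekulized; the package applies one
documented Hückel-style perception scheme per SSSR ring: an atom is
sp2-eligible when it is B/C/N/O/S/Se/P without triple bonds; it contributes
one π electron when double-bonded to a ring atom, zero when its double bond
is exocyclic (a ring carbonyl), and two when it is N/O/S/Se with only single
bonds; a ring is aromatic when every member is eligible and the total is
4n + 2. This handles benzenoids, azines, five-membered heteroaromatics and
fused bicyclics correctly and deliberately leaves borderline systems
(azulene-type non-alternants, quinones) non-aromatic. Records whose rings
cannot be kekulized at all are rejected to the parse report.

**Ring perception.** Ring count is the smallest set of smallest rings:
candidate rings are the shortest cycles through every cyclic bond, accepted
greedily in size order under GF(2) linear independence until the circuit
rank E − V + C is reached.

**Masses.** Monoisotopic masses and standard atomic weights are pinned in a
versioned in-package table (H 1.007825, C 12 exactly, N 14.003074,
O 15.994915, S 31.972071, Na 22.989770, …), so every printed mass is
bit-stable. ESI adduct deltas are derived from the same table:
[M−H]⁻ = M − 1.007276, [M+H]⁺ = M + 1.007276, [M+Na]⁺ = M + (Na − e⁻).
Predicted m/z values are monoisotopic and singly charged; because
low-resolution instruments report values that straddle the monoisotopic and
average masses, the product table also carries the average mass as a
diagnostic, and comparisons against low-resolution measurements are made at
one decimal place.

## Descriptors and the drug-likeness filter

The six filter descriptors follow the Rule-of-5 lineage, with the exact
conventions fixed here because descriptor names alone underdetermine them:

* **HBD** — number of O–H plus N–H hydrogens (Lipinski count).
* **HBA** — number of nitrogen plus oxygen atoms.
* **Rotatable bonds** — non-ring single bonds between two non-terminal
  heavy atoms, excluding amide C–N. No further exclusions: bonds to nitrile
  or trifluoromethyl carbons count, which matters only for molecules near
  the threshold and is applied uniformly on both the filter and the
  generator side.
* **Rings** — SSSR size; **aromatic rings** — SSSR rings entirely aromatic
  under the scheme above.
* **MW** — average (standard-atomic-weight) mass, the convention catalogue
  software prints.

Defaults (`filter_criteria()`): MW ≤ 200 u, HBD ≤ 4, HBA ≤ 8, rotatable
≤ 7, rings ≤ 2, aromatic rings ≤ 2. The MW ceiling is deliberately far
below the classical 500 u because the scaffold contributes ~456 u to every
final ester. A molecule is removed once but tallied under every rule it
violates, so funnel tallies are diagnostic rather than additive.

## Salt handling and structural alerts

Multi-fragment records (salts, mixtures) are rejected whole — the campaign
this mirrors removed salts rather than desalting them — and survivors must
contain at least one protonated carboxylic-acid group. The alert catalogue
ships as an editable TSV (`inst/extdata/structural_alerts.tsv`) with three
rule kinds:

* **SMARTS** rows (epoxide, aziridine, disulfide, azo, nitrogen oxides,
  β-lactam, aminonitrile, thionitrile, gem-dicarboxylic, quaternary
  ammonium) matched through OpenBabel;
* an **element scan** for boron, selenium and silicon;
* a built-in **chain rule** for long-chain fatty acids, which no practical
  SMARTS expresses cleanly: an acid is flagged when an unbranched,
  acyclic, all-single-bond carbon chain of at least 8 carbons (counted from
  the α-carbon) runs from the carboxyl group to a terminal methyl.
  Heteroatoms, branches and rings break the chain, so methoxy-capped or
  branched chains of the same length pass. The boundary case is therefore
  nonanoic acid (flagged) versus octanoic acid (passed).

"Ion-exchange resin" entries cannot be expressed on small-molecule graphs;
they are approximated by the quaternary-ammonium alert plus the fact that
repeat-unit records fail to parse and land in the rejects report. The test
suite checks every SMARTS row against an independent brute-force subgraph
oracle on a 30-molecule panel.

## Fingerprints, similarity, clustering

Fingerprints are functional-class circular fingerprints in the FCFP_4
family: radius 2 (diameter 4), folded to 1024 bits. The initial atom
invariant is the six-bit pharmacophore class vector — H-bond acceptor,
H-bond donor, positively ionizable, negatively ionizable, aromatic,
halogen — each class defined by a documented substructure rule (e.g.
"positively ionizable" is a formal cation or a non-aromatic all-single-bond
amine not adjacent to a carbonyl). Each Morgan iteration hashes the atom's
identifier with the sorted (bond order, neighbour identifier) pairs through
a pinned 32-bit mixing function (polynomial accumulation modulo 2³¹ − 1,
exact in double arithmetic), and all identifiers from all iterations are
folded modulo the bit length. The representation is invariant under atom
renumbering by construction; bit-compatibility with any vendor
implementation of FCFP_4 is explicitly not a goal.

Similarity is the Tanimoto coefficient on bit sets, with two empty
fingerprints defined as identical; 1 − *T* is a metric, which the suite
verifies on 10⁴ random triples.

**Clustering.** The reference campaign reports only a cluster count
(*k* = 285), not an algorithm, so the package uses the standard
diversity-selection pairing: MaxMin medoid seeding (first medoid drawn
uniformly under the stage seed; each next medoid maximizes the minimum
Tanimoto distance to those chosen) followed by nearest-medoid assignment.
Ties break toward the lexicographically smallest molecule id, all work is
done in canonical id order, and medoids always own their cluster, so the
partition is deterministic given (inputs, k, seed), invariant to input
order, and has exactly min(n, k) non-empty clusters. Whether the original
285 was a requested count or emerged from a similarity cutoff is unknowable
from the record; the package treats the count as configuration (`k`) and
additionally exposes a threshold mode (`cluster_threshold`) in which
seeding stops when the largest remaining minimum distance falls below the
cutoff and the count is emergent. Representative selection draws one
molecule per cluster uniformly under its own seed, over id-sorted members
so the draw is also order-independent.

## Ester enumeration

The scaffold ships as a SMILES fixture with its esterifiable hydroxyl
located structurally: the unique oxygen bearing exactly one hydrogen and a
single bond to a carbon with no carbonyl — which identifies the 3β-OH of
oleanolic acid unambiguously, since the only other O–H belongs to the
C-28 carboxyl. (An atom-map annotation was considered instead, but the
OpenBabel SDF bridge does not preserve atom maps, so structural location
plus an explicit `site` override is the robust choice.) Esterification is a
graph edit: the acid must carry exactly one protonated carboxyl (acids with
zero or several are routed to a rejects report, never silently dropped);
the hydroxyl oxygen of the acid is deleted, the scaffold oxygen loses its
hydrogen and gains a bond to the carbonyl carbon. Formula and monoisotopic
mass are recomputed from the product graph and must satisfy
formula(product) = formula(scaffold) + formula(acid) − H2O exactly, with
monoisotopic conservation to 1e-6 u — asserted for every enumerated
product. Side-chain nucleophiles on the acid are ignored: competing
reactivity is chemistry, not enumeration.

## External docking scores

Docking is delegated to an external engine; the package defines the
adapter contract (ligand SMILES/SDF out, CSV of `ligand_id, pki,
is_control` in) and records the engine configuration (receptor PDB code,
grid dimensions, runs per ligand) verbatim in the run manifest. pKi is
treated as an opaque monotone score: ranking is descending with
lexicographic id tie-breaks, controls stay flagged, and a validation check
warns unless every control outranks every library compound — the same
logic used to sanity-check a docking setup against its positive control.

## The synthetic acid library

The generator emulates the role of a commercial catalogue extract: a large
set of mostly mono-carboxylic organic acids with controllable property
distributions and known contamination. Records are built from a fragment
grammar — a COOH head plus aromatic/aliphatic ring or chain bodies with
substituents — so each record's descriptor labels are assembled from frozen
per-fragment constants (formula, HBD/HBA/rotatable increments) rather than
computed by the pipeline; label agreement with `compute_properties()` is
therefore a genuine end-to-end test, verified exactly over whole libraries.
Spiked motifs (one fixed structure set per structural alert, salts,
di-acids) are inserted at exact counts, `round(rate × n)`. In-range records
are tuned by rejection sampling within the grammar; `fraction_property_pass`
fixes the share of clean records that satisfy the default criteria, realized
against a fixed violator pool that covers each filter rule. Defaults
(1% per alert motif, 2% salts, 2% di-acids, 70% property pass) give a
funnel with every stage populated. Salt records carry only the salt flag
and carboxyl count; their descriptor labels are `NA` because salts leave
the funnel before properties are computed.

What the generator does **not** emulate: the real catalogue's chemical
distribution, its scale by default (tens of thousands of records are
supported but not default), or manual curation judgement. Consequently the
historical funnel counts of the original campaign (34,895 → 6,106 → 4,454)
are not reproducible quantities; what is reproducible — and tested — is the
*contract* at each stage: realized funnel = expected funnel exactly, k
non-empty clusters with one representative each, one ester per
representative mono-acid.

## Seeds, determinism, problem sizes

One root seed fans out to per-stage seeds (generation, cluster seeding,
representative draw) by fixed offsets recorded in the manifest, so any
stage can be rerun independently. All randomness flows through these
seeds; reruns of `run_pipeline()` with the same configuration are
byte-identical, and the test suite asserts this file by file. The shipped
validation runs use a 1,000-acid curated library clustered at k = 285 for
the diversity contract, a 500-record default-contamination library for the
funnel contract, 10⁴ random triples for the metric property and
100 permutations × 20 molecules for renumbering invariance — sizes chosen
to exercise every code path at desk scale while keeping a full check run
in the order of a minute.

## Known limitations

* Aromaticity perception is per-ring Hückel; non-alternant fused systems
  are treated as non-aromatic.
* The alert set reflects the original campaign's exclusion list, not a
  modern PAINS-style battery; there is no pKa or ionization modelling.
* Fingerprints are not bit-compatible with vendor FCFP_4 implementations
  (hash and class definitions are pinned locally instead).
* Esterification assumes the declared hydroxyl is the only reacting site;
  protecting-group strategy and yields are out of scope.
* Docking energies are never computed; only external score tables are
  ranked.
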