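# esterlib

Diversity-driven design of triterpenoid 3-*O*-ester libraries in R.

## The problem

Semi-synthetic modification of natural-product scaffolds is a standard route
to new nuclear-receptor ligands. A typical campaign acylates one position of
the scaffold — here the 3β-hydroxyl of oleanolic acid (OA, C30H48O3, a
pentacyclic triterpene with known FXR-modulating activity) — with carboxylic
acids drawn from a commercial catalogue. Because tens of thousands of acids
are available and only a few hundred esters can be docked or synthesized, the
catalogue must be funnelled:

1. **Curation** — remove salts and non-acids; apply a customized Rule-of-5
   filter (MW ≤ 200 u, HBD ≤ 4, HBA ≤ 8, rotatable bonds ≤ 7, rings ≤ 2,
   aromatic rings ≤ 2, thresholds chosen so the final esters stay drug-like
   given that the scaffold itself weighs ~456 u); then remove reactive
   (epoxide, aziridine, disulfide, azo, N-oxide, β-lactam, amino-/thio-nitrile)
   and non-druglike (long-chain fatty acids, gem-dicarboxylic acids, B/Se/Si,
   quaternary ammonium) chemotypes via a structural-alert catalogue.
2. **Diversity selection** — encode each survivor as a functional-class
   circular fingerprint (FCFP_4 style: Morgan iterations over the six
   pharmacophoric atom classes), measure similarity with the Tanimoto
   coefficient *T* = *c* / (*a* + *b* − *c*), partition into *k* clusters
   (the reference campaign used *k* = 285) by MaxMin medoid seeding, and
   draw one representative acid per cluster at random.
3. **Enumeration** — condense every representative onto the declared
   scaffold hydroxyl (loss of one H2O), with exact formula/monoisotopic-mass
   bookkeeping and predicted ESI adduct m/z ([M−H]⁻, [M+H]⁺, [M+Na]⁺).
4. **Ranking** — ingest externally produced docking scores (pKi) and rank
   candidates against a flagged positive control. The docking engine itself
   is out of scope; its configuration is recorded as provenance.

Because the original acid catalogue is proprietary, the package ships a
seeded synthetic acid-library generator built from a fragment grammar. Every
generated record carries ground-truth labels (descriptor values, alert
names, salt flag, carboxyl count) computed from frozen per-fragment
constants, so the whole funnel can be validated end to end against exact
expected counts.

## Worked example

```r
library(esterlib)

site <- oa_scaffold()                 # bundled OA structure + 3β-OH site
site$scaffold
#> <Molecule OA> C30H48O3, 33 heavy atoms, 37 bonds  CC1(C)CC[C@@]2(...)C(O)=O

acid <- parse_structures("OC(=O)c1cc(-c2ccccc2)no1 2a", "smiles")$molecules[[1]]
compute_properties(acid)
#> <properties 2a> C10H7NO3  MW 189.17 (mono 189.0426)  HBD 1  HBA 4  rot 2  rings 2 (aromatic 2)

esterify(site, acid)
#> <ester_product OA_O_2a> C40H53NO5  MW 627.87 (mono 627.3924)
#>    [M-H]-   m/z 626.3851
#>    [M+H]+   m/z 628.3997
#>    [M+Na]+  m/z 650.3816
```

The predicted deprotonated ion, 626.4 at one decimal, is what a
low-resolution ESI-MS measurement of this ester reports. A full synthetic
run:

```r
cfg <- pipeline_config(synthetic_n = 500, k = 50, seed = 1)
res <- run_pipeline(cfg, "demo-out")
res$funnel
#> <funnel_report>
#>   strip_salts               500 ->    490
#>   druglike_filter           490 ->    364
#>   structural_alerts         364 ->    304
res$counts$clusters    # 50 non-empty clusters
res$counts$products    # 50 enumerated 3-O-esters
```

Every stage writes plain-text artifacts (`funnel.tsv`, `clusters.tsv`,
`products.csv`, …) plus a JSON manifest; a rerun with the same configuration
reproduces them byte-identically. A thin command-line wrapper lives at
`inst/scripts/esterlib-cli.R` (subcommands `run`, `simulate`, `filter`,
`rank`).

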