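# metallominer

Rule-based detection of **NRP metallophore biosynthetic gene clusters
(BGCs)** in annotated bacterial genomes.

Siderophores and other metallophores — secreted small molecules that
chelate scarce environmental metal ions — are mostly non-ribosomal
peptides (NRPs). Their gene clusters look like any other NRPS cluster
until you notice the genes that build the *chelating* substructures:
catechol (2,3-DHB), salicylate, hydroxamates, β-hydroxyaspartate,
β-hydroxyhistidine, graminine, Dmaq, and the pyoverdine chromophore.
Telling metallophore NRPS clusters apart from the rest has traditionally
required expert manual curation, which does not scale to thousands of
genomes. `metallominer` automates it for anyone doing secondary-metabolite
genome mining: it evaluates a boolean detection rule over calibrated
profile-HMM domain hits and classifies every candidate NRPS region.

## The rule at the core

A region is called an NRP metallophore BGC iff

```
VibH_like or Cy_tandem or
(cds(Condensation and AMP-binding) and (
    (IBH_Asp and not SBH_Asp) or IBH_His or TBH_Asp or
    CyanoBH_Asp1 or CyanoBH_Asp2 or
    IPL or SalSyn or (EntA and EntC) or
    (GrbD and GrbE) or (FbnL and FbnM) or PvdO or PvdP or
    (Orn_monoox and not (KtzT or MetRS-like)) or
    Lys_monoox or VbsL))
```

with two-scope semantics: a bare identifier is true if *any* gene in the
region has a significant hit (bitscore ≥ the profile's registry cutoff),
while `cds(...)` must be satisfied by a *single* gene — the NRPS signature
"a gene containing at least one condensation and one adenylation domain".
`not` identifiers are region-wide vetoes (piperazate/hydrazine pathways
against the hydroxamate branch, a competing hydroxylase clade against
IBH_Asp). VibH-like and tandem-Cy condensation subtypes trigger on their
own, which is what catches Type II (non-/semi-modular) NRPS systems.

Alongside the chelator rule the package implements the transporter-based
classifier (metallophore iff ≥ 2 distinct families among Pfam PF00593,
PF01032, PF01497 hit the region) and their either/or ensemble, plus
precision/recall/F1 benchmarking (`confusion()`, `compute_metrics()`),
completeness-stratified censuses (`census()`, `census_percent()`),
chelator-combination counts (`combination_counts()`), bitscore-cutoff
calibration (`choose_cutoff()`), and a deterministic synthetic-genome
generator with planted ground truth (`synth_genome()`, `benchmark_set()`).

## Worked example

Generate a small synthetic benchmark (8 planted clusters, one per contig),
run the full pipeline on its files, and score the result against the
generator's ground truth:

```r
library(metallominer)

d <- file.path(tempdir(), "demo")
bench <- benchmark_set(8, seed = 42, dir = d)     # genome.gbk, hits.tsv, truth.tsv

contigs <- read_genbank(file.path(d, "genome.gbk"))
hits    <- read_domain_hits(file.path(d, "hits.tsv"), dialect = "tsv")
det     <- detect(contigs, hits)                  # default registry + rule
summary(det)
#> Regions: 8 (7 complete, 1 partial)
#> Chelator rule positive:  4
#> Transporter rule positive: 5
#> Ensemble positive:       5
#> Chelator groups: catechol=2, beta-OHAsp=1, hydroxamate=1, NRPS-domain-marker=1, pyoverdine-chromophore=1
```

Eight regions were assembled around their NRPS anchor genes; one planted
on a contig edge is flagged partial. Four regions satisfy the chelator
rule; a fifth — a "cheater" locus that kept siderophore transporters but
lost chelator biosynthesis — is caught only by the transporter method, so
the ensemble finds five. The chelator-combination tally keys each positive
region by its sorted group tuple (the pyoverdine-like cluster carries the
characteristic three-group combination):

```r
combination_counts(det)
#> beta-OHAsp;hydroxamate;pyoverdine-chromophore
#>                                             1
#>                                      catechol
#>                                             2
#>                            NRPS-domain-marker
#>                                             1

truth <- read_truth_labels(file.path(d, "truth.tsv"))
evaluate_detection(det, truth, "chelator")$metrics
#> precision 1.00  recall 1.00  F1 1.00
```

On clean synthetic genomes the chelator rule recovers the planted truth
exactly — hit scores are planted at 1.5× the cutoffs, so this validates
the engine, not real-world accuracy (see the methods vignette,
`vignettes/detection-methods.Rmd`). `write_outputs(det, "out/")` writes
GFF3, TSV and JSON; a thin command-line wrapper with `detect`, `evaluate`,
`calibrate` and `simulate` subcommands lives at
`inst/cli/metallominer.R`.

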