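---
title: "Detecting NRP metallophore gene clusters: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting NRP metallophore gene clusters: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metallominer)
```

## The problem and the approach

Most non-ribosomal peptide (NRP) metallophores — siderophores and related
metal chelators — carry one of a small set of chelating substructures:
2,3-dihydroxybenzoate (catechol), salicylate, hydroxamates,
β-hydroxyaspartate, β-hydroxyhistidine, graminine, Dmaq, or the pyoverdine
chromophore. Each has a known biosynthetic pathway with characteristic
enzymes, so the presence of chelator biosynthesis genes inside an NRPS
(non-ribosomal peptide synthetase) gene cluster is a strong marker that the
cluster encodes a metallophore. `metallominer` formalises this as a boolean
detection rule over profile-HMM domain hits:

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

The rule language has three pieces of semantics worth spelling out:

* **Region scope.** A bare identifier is true if *any* gene in the
  candidate region has a significant hit to that profile. Marker pairs such
  as `EntA and EntC` may sit on different genes.
* **Gene scope.** `cds(Condensation and AMP-binding)` is true only if a
  *single* gene carries both a condensation and an adenylation domain —
  the minimal signature of a modular NRPS. Two genes carrying one domain
  each do not qualify.
* **Negative constraints.** `not` identifiers veto a branch. KtzT
  (piperazate biosynthesis) and MetRS-like (hydrazine pathways) veto the
  ornithine-monooxygenase hydroxamate branch; SBH_Asp (a syringomycin-family
  hydroxylase clade) vetoes IBH_Asp. Negative constraints are
  *region-scoped*: a veto gene anywhere in the region suppresses the
  branch. No intra-region distance window is applied, which intentionally
  reproduces the known failure mode that a veto gene located very far away
  in the same region still suppresses detection, and a veto gene outside
  the region does not rescue a false positive.

The first two disjuncts let metallophore-specific condensation-domain
subtypes (VibH-like stand-alone condensation enzymes and tandem
heterocyclization domains) trigger detection on their own. These "Type II"
(non- or semi-modular) NRPS systems would otherwise be missed entirely
because they lack the single-gene condensation + adenylation signature.

One textual repair was needed: the published form of the rule omits an
`or` between `(Orn_monoox and not (KtzT or MetRS-like))` and
`Lys_monoox`, which would make it syntactically invalid. The bundled
canonical rule inserts the `or`, consistent with the prose description of
ornithine and lysine monooxygenases as alternative hydroxamate markers.

## Two more classifiers

Besides the chelator rule, each region is classified by a
**transporter-based criterion**: a region is called a metallophore BGC if
at least two *distinct* families among the three siderophore-associated
Pfam transporter families — PF00593 (TonB-dependent receptor), PF01032
(FecCD-domain permease), PF01497 (periplasmic binding protein) — hit genes
in the region. Multiple genes hitting the same family count once. The
**either/or ensemble** is the logical OR of the two methods; by
construction its positive set is a superset of each component's, so its
recall can never be below either component's recall.

The two methods disagree in an instructive way on "cheater" loci that have
kept metallophore transporters (to pirate other strains' siderophores) next
to an NRPS fragment but have lost chelator biosynthesis. These are
transporter-positive and chelator-negative, and the synthetic-fixture
generator plants them deliberately (see below).

## From hits to regions

Detection consumes an annotated genome (GenBank), a raw domain-hit table
(HMMER3 `--domtblout` or a simple TSV), and a *profile registry* mapping
each profile name to a bitscore significance cutoff, a chelator category,
and a role. All hits are retained at read time; `apply_cutoffs()` is the
single explicit filtering step (a hit survives iff `bitscore >= cutoff`,
inclusive), so one scan can be re-analysed under different registries.

Candidate regions are assembled around **anchor genes**: genes carrying
both core NRPS domains, or a standalone Type II marker. Anchors within
`merge_distance` of each other (default 20 kb, the usual NRPS-region
convention) share a region; the merged anchor span is extended by
`neighborhood` (default 20 kb) on both sides and clamped to the contig.
Clusters whose extended spans would overlap are merged as well, so regions
on a contig are always pairwise disjoint. Both distances are configurable
because no published values pin them down; none of the package's
benchmark-arithmetic results depend on them.

A region is **complete** iff its extension was *not* truncated by a contig
boundary (pre-clamp start ≥ 0 and pre-clamp end ≤ contig length, both
inclusive). This is a concrete, testable proxy for "not on a contig edge";
fragmented draft genomes produce partial regions whose gene content — and
hence classification — is unreliable, which is why census results are
stratified by completeness.

## Chelator-group profiles and census arithmetic

When the rule fires, the *triggering identifiers* — profiles that occur
positively in the rule and are true on a satisfied path — are mapped
through the registry's `category` column to chelator groups. Identifiers
on vetoed branches never trigger, so a vetoed ornithine monooxygenase
contributes no hydroxamate claim even if another branch fires. VibH-like
and tandem-Cy hits map to a `NRPS-domain-marker` pseudo-group: the region
is detected by metallophore-specific NRPS domains rather than by chelator
biosynthesis, and may use chelator genes encoded elsewhere in the genome.
In `combination_counts()` that pseudo-group is kept as its own key only
when it is a region's sole evidence; alongside real chelator groups it is
dropped from the combination key, so combination tallies describe chelator
chemistry only.

Benchmark metrics use the standard definitions: precision `tp/(tp+fp)`,
recall `tp/(tp+fn)`, and F1 as their harmonic mean
`2·P·R/(P+R)`. Degenerate denominators yield 0 plus a flag rather than
`NaN` so that batch benchmarking never crashes. Reported values are
rounded half-up (base R's `round()` rounds half to even): precision and
recall to two decimals or whole percent, F1 to two decimals. Census
percentages are `100·positive/total` rounded half-up to the nearest whole
percent, keeping one decimal below 10% so that small strata are not
flattened to a single digit.

## Cutoff calibration

`choose_cutoff()` is a deterministic stand-in for the judgement call made
when profile HMMs are built: given labeled positive and negative bitscore
distributions for a profile, it returns the midpoint cutoff
`(max(negative) + min(positive))/2` when the distributions separate, half
the lowest positive score when there are no negatives, and an
`inseparable` flag otherwise. The midpoint maximises the margin
symmetrically and is scale-consistent (scaling all scores by *c* scales
the cutoff by *c*). The inseparable branch corresponds to the
human-in-the-loop step of augmenting the profile's seed alignment with
low-scoring true hits and rebuilding — outside this package's scope. The
bundled registry ships illustrative round cutoffs; they are placeholders
for profile-specific calibrated values, and every package result that
involves them is invariant to their exact magnitudes because synthetic hit
scores are planted *relative* to the cutoffs.

## The synthetic-fixture generator

Real positive controls would require genome downloads and an HMM scan, so
the package generates its own test substrate. `synth_genome()` emits a
GenBank genome, a matching hit table, and ground-truth labels for planted
cluster archetypes, one cluster per contig:

* **enterobactin** — EntC + EntA + an NRPS core gene + all three
  transporter families; catechol, both methods positive.
* **pyoverdine** — PvdP + Orn_monoox + TBH_Asp + NRPS core + two
  transporter families; the characteristic three-group combination
  (chromophore + hydroxamate + β-OHAsp).
* **type2** — a tandem-Cy gene with transporters and no NRPS core;
  detected via the `NRPS-domain-marker` route alone.
* **cheater** — NRPS core + all three transporter families, no chelator
  genes; transporter-positive, chelator-negative by design.
* **himastatin_veto** — Orn_monoox + KtzT + NRPS core; the hydroxamate
  branch is vetoed, nothing else fires.
* **syringomycin_excl** — IBH_Asp + SBH_Asp + NRPS core; excluded by the
  competing-profile constraint.
* **nrps_decoy** — a plain NRPS with no chelator or transporter genes.

Planted hits score 1.5× the registry cutoff; scattered decoy genes carry
no hits or subthreshold hits at 0.5× (probing the inclusive boundary).
Geometry is fixed: 1.2 kb genes with 0.2 kb spacing, interior clusters
placed ~25 kb into a contig sized so both neighborhood extensions fit,
edge-truncated clusters placed 2 kb from the left contig edge so the
extension clamps and the region is flagged partial. Template expectations
are re-validated against the actual rule and registry at generation time,
and generation is byte-deterministic given the seed.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: biologically realistic sequence content (hit
tables carry the signal; sequences are filler), borderline bitscores from
genuinely ambiguous homologs, chelator genes located outside the region,
overlapping or nested BGCs, and annotation noise in the CDS calls.
Synthetic recovery being perfect is a statement about the engine's
correctness, not about field performance; the published curated benchmark
(97% precision, 78% recall for the chelator rule) is the realistic anchor,
and the package reproduces that arithmetic from the published confusion
counts rather than re-deriving the curation.

## Problem sizes and numerical choices

The default test and acceptance workloads use benchmarks of 40–60 planted
clusters per seed and a few hundred random rule/assignment cases for the
truth-table and round-trip properties — comfortably exercising every code
path while keeping a full run in well under a minute. Ties and degenerate
inputs are handled explicitly: cutoff comparison is inclusive (`>=`),
region completeness is inclusive at exact-fit boundaries, an empty region
never satisfies any rule, empty inputs produce valid empty outputs
(header-only GFF3/TSV), and JSON serialisation uses sorted keys so outputs
are byte-stable.

Internal coordinates are 0-based half-open everywhere; GenBank and GFF3
(1-based inclusive) are converted only at the file boundary, making the
round-trip an identity that the tests assert. Compound (`join`) CDS
locations collapse to their outermost bounds — introns are irrelevant for
bacterial CDSs in practice.

## Known limitations

* The chelator rule only detects pathways with dedicated marker enzymes;
  chelators built by core NRPS/PKS chemistry (thiazolines,
  5-alkylsalicylate) and newly described groups (5-aminosalicylate,
  2-naphthoate) are invisible to it, as are clusters whose chelator genes
  reside elsewhere in the genome.
* Region formation approximates, but does not replicate, any particular
  annotation pipeline's internals; partial-region counts are therefore not
  comparable across tools, which is why only percentage arithmetic on
  published stratum counts is reproduced.
* The transporter criterion uses three broad Pfam families and inherits
  their false positives (e.g. vitamin B12 import loci).
* Distinguishing siderophores from zincophores and other metallophore
  classes would require regulatory-element evidence beyond gene content.
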