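---
title: "Estimating eukaryotic genome quality with clade-specific single copy markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating eukaryotic genome quality with clade-specific single copy markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magqc)
```

## The model

A single copy marker gene (SCMG) is a protein family expected exactly
once per genome within some clade. If a clade's reference genomes carry a
set $S$ of such families, a draft genome of that clade can be scored by
scanning its (predicted) proteins against the family profile HMMs:

$$\text{completeness} = 100\cdot\frac{|\{p \in S : c_p \ge 1\}|}{|S|},
\qquad
\text{contamination} = 100\cdot\frac{|\{p \in S : c_p \ge 2\}|}{|S|},$$

where $c_p$ is the number of distinct query proteins matching profile
$p$ above its bit-score threshold. Both are fractions of the *set*, so a
duplicated profile is also a found one and contamination can never
exceed completeness — an invariant the test suite fuzzes. Contamination
counts a duplicated profile once regardless of its copy number: the
statistic is "fraction of duplicated markers", not total extra copies;
the per-profile counts are retained in the report for anyone who wants
the latter.

Because no family is single copy across all microbial eukaryotes, the
set $S$ must be clade-specific, and for a query of unknown lineage it is
chosen automatically in a two-stage procedure described below.

## Threshold calibration

Profile HMM scores for true family members and for paralogs or
domain-level matches overlap; a per-profile noise cutoff separates them.
For each profile we scan all distinct observed bit scores and keep the
one maximising the number of reference genomes with *exactly one*
surviving hit. Only observed scores need trying: any cutoff strictly
between two observed values classifies every hit identically to one of
them. When several cutoffs attain the maximum we keep the **largest**.
The published description does not fix the tie rule; stringency is the
natural choice because the entire point of the cutoff is paralog
separation, and every tied value retains the same number of single-copy
genomes anyway. The calibration set is taxonomically balanced (at most
30 genomes per major sub-clade, drawn round-robin across the phyla
beneath it with a seeded shuffle) so deeply sequenced clades do not
dominate the cutoffs.

An open question in the published description is whether the objective
counts genomes with exactly one surviving hit or penalises multi-copy
genomes as well; we implement the literal reading (count of single-hit
genomes), which the exhaustive-scan oracle in the tests pins down.

## Clade set mining and the greedy reference set

With thresholds applied, the reference corpus becomes a genome × profile
copy-count matrix (distinct proteins only: a protein matched repeatedly
by the same profile counts once). For every internal node of the
reference tree whose clade holds at least `min_species = 3` genomes, a
profile qualifies when its *single-copy prevalence* — the fraction of
clade genomes with exactly one copy, not at least one — reaches
`prevalence_cutoff = 0.98`; a marker set is emitted when at least
`min_profiles = 20` profiles qualify. The species floor and the profile
floor are applied jointly; both are configuration parameters
(`db_config()`).

The initial placement stage needs probes before any clade is known, so a
small *reference set* of overlapping single copy markers is grown
greedily: repeatedly add the profile that is single copy in the most
genomes still covered fewer than `min_cover = 3` times, breaking ties
lexicographically, until every genome reaches the floor or no profile
helps. Three is the coverage floor actually attained by the published
database (each species covered 3–34 times); we do not impose an upper
cap, reading the observed maximum as incidental. On infeasible inputs
the best-effort set is returned along with the under-covered genomes
rather than failing, since a partially covered corpus is still usable.
The classical $1 + \ln n$ greedy set-cover guarantee is checked against
an exhaustive optimum on small instances in the tests.

## Set selection for a query

Query proteins hitting the reference set are placed on the reference
tree. Real phylogenetic placements arrive as jplace (version 3)
documents; the support value is the posterior probability when the
document declares one, else the likelihood weight ratio (jplace dialects
differ, and the posterior is what the placement step is described as
maximising). Per protein the top-support placement is kept; support ties
break toward the *rootward* location, the conservative reading, since a
deeper claim should need positive evidence. When no placement tool is
available, the built-in fallback places each protein on the leaf of the
reference genome whose marker for the protein's best profile scores
highest, with support 1.0 — a nearest-reference heuristic, clearly
documented as such, that keeps the pipeline runnable end to end.

Candidate sets are every set whose clade contains at least one placement
plus, for the LCA of all placements, the nearest ancestor owning a set
(the "highest possible ancestor" ascent). The winner maximises the
number of encapsulated placements; coverage ties break toward the
deeper, more specific node — more specific sets contain more markers and
mirror the method's stated preference for specificity — and residual
ties by set identifier, making the choice total and deterministic. The
coverage fraction is always reported and a warning is raised when it is
below 1, or when fewer than 20% (configurable) of reference profiles
produced placements at all: such genomes deserve closer manual analysis,
but the method reports rather than refuses.

## Lineage, unassessed fraction, uniformity

The reported lineage is the *strict* consensus of the chosen set's
species lineages: the longest rank prefix on which every species agrees,
stopping at the first disagreement. The published description says only
"consensus"; strictness is the conservative reading (a majority variant
would claim more precision than the evidence supports).

Marker-based scores are blind to contigs without markers, so the report
includes the fraction of genome length on marker-free contigs. The
marker-uniformity diagnostic samples non-overlapping random 5-kb
fragments — implemented as a random draw without replacement from the
5-kb windows tiling each contig, since overlapping draws would recover
the same markers twice and inflate the statistic — and reports the
Pearson correlation between cumulative sampled length and distinct
markers recovered. Uniformly spread markers give $r \ge 0.95$ on a
10-Mb genome with 200 markers; clustered markers score visibly lower.

## The simulator and the synthetic corpus

Benchmark genomes are produced by stepping along chromosomes with
fragment lengths $\max(2000,\ 100\cdot\mathrm{Pois}(100))$ bp. Read
literally, a Poisson(100) step with a 2000 bp floor is degenerate (the
floor always binds); we therefore scale draws by a `step_unit` of 100 bp,
giving 2–20 kb fragments — the contig size range of real metagenome
assemblies — while `step_unit = 1` recovers the literal reading.
Fragments are kept independently with probability `target_fraction`;
contaminants are fragmented identically and subsampled to
`contamination_fraction` *of the contaminant genome's length* (the same
size-fraction logic as completeness; the truth ledger stores raw bp so
any other denominator can be recomputed). Random-DNA contamination draws
i.i.d. bases at a configurable GC content; having no genome of its own,
its total length is set equal to the target's. Coordinates are 0-based
half-open throughout, and every fragment's source and label are written
to the FASTA headers and the truth ledger.

The synthetic reference corpus (`synthesize_reference_fixture()`) draws
each genome × profile cell single copy with probability $1-d$, absent
with probability $d(1-r)$ and duplicated otherwise ($d$ = dropout, $r$ =
duplication rate), then emits a hit table whose above-threshold scores
reproduce the matrix exactly, plus sub-threshold noise hits that
exercise thresholding without changing counts. Lineages are derived from
the fixture tree's own ancestor paths, so consensus-lineage behaviour is
structurally consistent. Parameter-recovery experiments use genomes with
one 1-bp marker locus per profile placed uniformly at random: a point
locus survives fragmentation if and only if its fragment survives,
giving recovery experiments an exactly binomial truth model (in
particular, a fully retained genome scores exactly 100% complete).

What the fixtures deliberately do *not* model: gene prediction error
(the dominant error source on real MAGs — proteins are taken as given),
sequence-level homology (hit tables are generated, not scanned),
placement uncertainty (fallback placements have support 1.0), and
assembly chimerism beyond whole-fragment mixing. Passing tests therefore
validate the *statistics and the selection logic*, not HMM scanning or
phylogenetics; on real data those upstream steps contribute additional
error.

## Problem sizes and numerical choices

The test suite and acceptance script run at desk scale: corpora of 8–20
genomes with 15–100 profiles, simulated genomes of 1–10 Mb, 50 seeds per
completeness level and 10 per contamination level — sizes chosen so the
binomial error bands are tight enough to be informative while the whole
suite stays fast. All randomness flows through explicit integer seeds
(`withr::local_seed`), making every pipeline stage bit-reproducible;
database directories contain no timestamps, so rebuilds are
byte-identical and are verified as such. Thresholds compare with `>=`
(a hit exactly at the cutoff passes). Degenerate inputs — empty hit
tables, empty sets, genomes shorter than one sampling fragment, clades
with missing genomes — fail early with typed, named errors; the two
conditions a batch caller must distinguish ("no applicable marker set",
"too few markers") carry their own condition classes and distinct CLI
exit codes.

## Known limitations

The fallback placement engine is a heuristic, not a phylogenetic method;
with it, set choice degrades gracefully but placements carry no real
uncertainty. Clades thinly represented in the reference corpus get few
or no sets, and queries from them fall back to rootward, less specific
sets — the same behaviour the underlying method exhibits with sparse
training data. Contamination from a clade sharing no marker families
with the chosen set is invisible to the score (the unassessed fraction
and uniformity diagnostics are the partial mitigations). Gene
prediction is out of scope by design: accuracy on real genomes is
bounded by the protein predictions fed in.
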