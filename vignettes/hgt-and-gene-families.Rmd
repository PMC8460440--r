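---
title: "Staged HGT detection and gene-family statistics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged HGT detection and gene-family statistics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(potworm)
```

This vignette is the package's own account of the science it implements:
the models, the assumptions behind them, the tunable parameters, what the
synthetic-data generators do and do not emulate, and the choices made where
the design was genuinely open.

## The staged HGT detection model

Horizontal gene transfer into an animal genome is easy to claim and hard to
defend: most apparent transfers in draft genomes are contamination or
annotation artifacts. The pipeline therefore demands three independent
kinds of evidence in sequence.

**1. Homology asymmetry (h-score).** Each gene's homology hits are grouped
by source database — metazoa excluding annelids, annelids, plants, bacteria,
archaea, protists, fungi — and collapsed to per-group best bitscores
(`summarize_best_hits()`). The h-score is the best non-metazoan bitscore
minus the best metazoan bitscore. Bitscores are database-size independent,
so the difference is comparable across genes. A gene is a *candidate* when
`h >= 30` and its best non-metazoan bitscore is `>= 100` (both inclusive;
`filter_candidates()`). The non-metazoan bitscore floor keeps genes with no
strong homology anywhere out of the candidate set.

A gene with no metazoan hit gets a metazoan bitscore of 0, the natural
lower bound, so `h` stays defined and equals the non-metazoan bitscore.
Annelid-database hits represent vertical inheritance in an annelid focal
genome: they are counted on the metazoan side of the clade test and
excluded from the non-metazoan best hit. Because this is a judgement call,
`annelida_nonmetazoan = TRUE` inverts it for sensitivity analysis.

**2. Genomic-context linkage.** True transfers are embedded in the host
genome; contaminating sequences are not. `check_context_linkage()` requires
a *native* neighbour — an annotated protein-coding gene that is not itself a
candidate, immediately adjacent in per-scaffold gene order (order index
± 1) — and at least one mapped long read overlapping both the candidate span
and the neighbour span by at least 100 bp each, i.e. one molecule spanning
the junction. "Immediately adjacent" is the strictest neighbour definition
computable from an annotation alone; the 100-bp overlap floor makes a
few-bp graze insufficient while remaining far below any long-read length.
Both are configurable (`hgt_config()`).

**3. Bitscore confirmation, then phylogeny.** A linkage-passing candidate
whose best metazoan bitscore is strictly below 50 has essentially no
metazoan homology to explain away and is confirmed outright
(`classify_by_bitscore()`). At or above 50, a gene tree of the candidate
plus its top database hits decides: the smallest clade containing the
candidate — the subtree of its parent node — must contain no metazoan leaf
(`clade_test()`). Trees are used as rooted as parsed; aLRT/bootstrap
support values are parsed but ignored, since no support threshold is part
of the procedure. Candidates that need a tree but have none supplied are
reported `phylo_missing` and never counted as confirmed.

**Origin and enrichment.** A confirmed gene's origin is the taxon group of
its best non-metazoan hit (ties broken by lower e-value, then subject id).
Percentages are rounded half-away-from-zero to one decimal, matching how
such breakdowns are printed. GO enrichment of the confirmed set
(`enrich_go()`) is a one-sided hypergeometric test with Benjamini–Hochberg
correction within each namespace at `q <= 0.05`; the enrichment method is
an artifact choice, documented as such, because no canonical method is
attached to this pipeline.

All iteration is ordered by gene id, so a pipeline run is reproducible bit
for bit.

## Gene-family expansion and contraction

For each orthogroup, each species' gene count is standardised against the
family's cross-species mean and standard deviation; `z >= 2` is a
significant expansion, `z <= -2` a contraction (`family_zscores()`).
Decisions made where the formula's prose leaves room:

* **Sample sd (denominator n − 1)** is the default; it is the conservative
  choice, and `sd_mode = "population"` is available and pinned by tests.
  The difference matters: the vector (20, 2, 2, 2, 2) has focal
  `z = 4/√5 ≈ 1.79` under the sample sd (not called) and exactly 2.0 under
  the population sd (called).
* **All species enter the mean/sd**, zeros included — the standardisation
  is "from all species"; `species_scope = "representing"` restricts to
  species with at least one gene.
* **Eligibility**: the family must be represented by the focal species
  (count ≥ 1) and by at least three other species. Ineligible families are
  reported, never called.
* **sd = 0 families** (constant counts) have undefined z and are reported
  `undefined_sd`, never expanded or contracted.

A consequence worth knowing: with the sample sd over *n* species,
`|z| <= (n − 1)/√n` for any count vector. With 9 species the single-outlier
maximum is `8/3 ≈ 2.67`; with 5 or fewer species `|z| >= 2` is unreachable,
so the family generator refuses to plant expansions in matrices that small.

`lineage_specific_families()` returns focal-only families;
`shared_families()` implements both "at least one gene in every listed
species" and, with `exclusive = TRUE`, proper Venn-region semantics.
`rank_expansions()` orders expansions by focal gene count (descending),
breaking ties by z then orthogroup id — the ordering used for printed
top-expansion tables.

## Assembly statistics and the mitochondrial screen

`compute_assembly_stats()` filters scaffolds below 1 kb by default (the
convention for reporting gapless assemblies), then applies the de facto
standard N50 rule: cumulative length in descending order, `>=` half-total
tie rule. GC excludes ambiguity codes from numerator and denominator, so
N-padding cannot dilute it, while `total_bp` counts every base.
`compute_genome_fractions()` computes gene/exon/intron/repeat fractions on
unions of spans, so overlapping annotations are counted once; since exons
are validated to lie within gene spans, the intron fraction is exactly the
gene fraction minus the exon fraction.

Assemblies often retain scaffolds that are fragmented copies of the
separately assembled mitochondrial genome. The screen
(`screen_mito_fragments()`) is an exact k-mer containment test: the
fraction of a scaffold's 31-mer positions whose canonical (strand-collapsed)
31-mer occurs in the circularised mitochondrial sequence. At k = 31 a chance
match in a random sequence is negligible (4^31 ≈ 4.6 × 10^18), so genuine
fragments sit near containment 1 and unrelated scaffolds near 0; the 0.5
flagging threshold splits a bimodal statistic and is deliberately
uncritical. Wrap-around k-mers are included because the mitochondrial
genome is circular. Windows containing ambiguity codes can never match and
count against containment.

## The synthetic-data generators

The generators exist so that every stage of every analysis can be exercised,
with known truth, from a seed — no downloads, no fixtures on disk.

`generate_hgt_fixture()` plants a chosen number of genes in each latent
stage class. Bitscores are drawn uniformly inside class-specific windows
separated from every decision threshold (30, 100, 50) by at least the
spec's `bitscore_margin` (default 5), so stage recovery is exact and
threshold boundary behaviour is tested separately with exact values.
Linkage failures come in two alternating sub-modes: a candidate alone on
its scaffold, and a candidate with native neighbours whose junctions no
read bridges. Trees for tree-confirmable genes give the candidate a
donor-group sibling; tree-rejected genes get a metazoan sibling. One RNG is
derived from the seed with separate sub-streams for layout, scores, reads
and trees, so adding a file type cannot shift existing output. The
`hgt_paper_stages_spec()` preset plants the reference survey profile
(33/5/27/40 across the stage classes plus 45 background genes, donors
19/8/4/1) — the composition 19/8/4/1 is the unique 4-part composition of 32
whose one-decimal percentages are 59.4/25.0/12.5/3.1.

`generate_family_counts_fixture()` plants expanded, contracted,
lineage-specific and neutral orthogroup rows. Planted outlier rows are
drawn with cross-species noise and *verified* against `family_zscores()`
before emission, falling back to the deterministic single-outlier pattern
(whose z is exactly `±(n − 1)/√n`) if the noise washes the signal out.
Requests that violate the analytic bound are refused with an error rather
than silently weakened.

`generate_genome_fixture()` emits an assembly, gene models and a
mitochondrial sequence; planted fragment scaffolds carry a verbatim
substring of the circularised mitochondrial sequence covering 60% of the
scaffold, padded with random sequence.

**What the generators do not emulate** — and hence what passing tests do not
show about real data: sequence evolution (bitscores are drawn, not computed
from alignments), e-value statistics beyond rank consistency with
bitscores, read errors and mapping ambiguity, isoform structure (the
pipeline operates at the unit given in the hit table's `query_id`; callers
must pre-collapse transcript isoforms to genes), and realistic genome scale.
The genome fixture uses kilobase-scale scaffolds and a higher gene density
than a real 500-Mbp genome, which exercises the statistics without
multi-minute test times; the assembly statistics themselves are
scale-free (N50/L50/GC are pure functions of lengths and composition).

## Numerical and interface choices

* Coordinates are format-native per table and declared per column: gene
  models are 1-based inclusive (as in GFF3), read intervals 0-based
  half-open (as in PAF/BED). Conversion happens in exactly one place, the
  overlap computation of the linkage test. This trades a single uniform
  convention for zero conversions at the parse boundary.
* Origin percentages round half away from zero at one decimal; base R's
  `round()` rounds half to even, which disagrees exactly at printed
  boundary values such as 59.375 → 59.4.
* Hit tables are never deduplicated on read; best-hit selection is an
  explicit, tested operation.
* FASTA record ids truncate at the first whitespace (NCBI convention),
  matching GFF3 seqid usage.
* Collinear duplicated blocks classify as `inter_scaffold` across
  scaffolds, otherwise `palindrome` (paired genes on opposite strands) or
  `tandem` (same strand); with mixed pair orientations the majority decides
  and ties fall to palindrome.
* Problem sizes in the test suite are desk scale: 1,000 random length sets
  for the N50 oracle, all ~32,000 labelled rooted topologies with up to 6
  leaves for the clade test, 10,000 random count vectors for the z bound,
  and 100 random fixture specifications each for the HGT and family
  recovery properties.

## Known limitations

* The pipeline trusts its inputs' gene units; transcript-level hit tables
  must be collapsed to genes upstream.
* The linkage rule requires an *immediately* adjacent native neighbour; a
  candidate flanked by two other candidates fails even if a native gene
  sits two positions away. This is the strictest reading and is
  intentional.
* The clade test uses the tree as rooted as parsed; an unrooted or
  mis-rooted tree changes the parent clade. No support filtering is
  applied.
* Shared/lineage-specific family counts depend entirely on the upstream
  orthology clustering; the package reproduces the set logic, not the
  clustering.
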