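---
title: "Methods: interval-permutation enrichment of Mendelian disease annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interval-permutation enrichment of Mendelian disease annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mendelprior)
```

# Overview

`mendelprior` links GWAS loci to Mendelian disease biology in three stages:
interval definition around lead variants, intersection with an integrated
Mendelian gene–disease knowledge base, and enrichment testing of
disease-phenotype ontology terms under a permutation null that respects
genomic structure. This vignette records the model, its assumptions, the
parameters that matter, and the design decisions taken where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

# The knowledge base

Gene–disease associations arrive as one table per source (OMIM-like,
Orphanet-like, DECIPHER-like, Genomics England panel-like labels).
Integration merges rows sharing a `(gene_id, disease_id)` key; the `sources`
field keeps full provenance, and the highest-priority source
(OMIM > Orphanet > DECIPHER > GE) supplies the displayed disease name. An
optional alias table maps member disease ids to a shared series id and
merging then happens on the aliased key — this approximates
phenotypic-series-level deduplication while keeping series resolution
pluggable, since no authoritative rule exists for it. Identifiers are
opaque, case-sensitive strings throughout; no symbol-resolution service is
built in.

Short disease descriptions are attached by fixed priority
OMIM > Orphanet > Uniprot > DO (the order in which the four description
sources are conventionally listed; absence is legal and common). Ontology
terms are attached per disease as the **union** over sources; source order
affects only the provenance log (how many diseases gained terms exclusively
from non-primary sources), never the final sets. Unknown or obsolete term
ids are dropped with a logged warning rather than failing the run, because
real ontology dumps are version-skewed relative to annotation files.

Canonical transcripts follow the APPRIS rule: the unique principal isoform
if exactly one exists, otherwise the longest transcript, with ties broken by
the lexicographically smallest transcript id (a deterministic, arbitrary
tie-break; ties are rare in practice but must not depend on input order).

Two points the upstream data sources leave open were decided as follows:
Genomics England panel confidence filtering happens *before* ingestion (the
reader accepts a pre-filtered table), and conflicting disease names across
sources are resolved by keeping the first-priority source's name.

# Ontologies

Ontologies are read from OBO 1.2; only `is_a` edges participate in
subsumption, matching standard enrichment practice for HPO and DO (whose
primary hierarchy is `is_a`). The graph must be acyclic and closed; obsolete
terms are retained but flagged and excluded from closures and slims.

A gene's annotation is the ancestor closure of the union of the direct
terms of all its diseases. Propagation happens **before** testing; testing
unpropagated sets is possible by building the annotation directly with
`gene_annotation()` from explicit term→gene sets (the same entry point used
for GMT-style pathway collections). The DAG root is kept in closures but
excluded from enrichment reporting by default — it annotates every termed
gene and is uninformative. Slims are either supplied as term lists or built
as the direct non-obsolete children of a chosen root term;
`map_to_slim()` rolls a term set up to the slim via closure intersection.

# Interval definition

Internal coordinates are 1-based inclusive; BED input/output converts
to/from 0-based half-open exactly at the file boundary. Three routes:

* **Fixed flanks** — `[pos − flank_left, pos + flank_right]`, each flank at
  most 10 Mbp. Intervals are clipped at chromosome ends rather than
  rejected (the clip is visible in the run log); a position outside its
  chromosome is an error naming the record.
* **LD boundaries** — from a per-index-variant proxy table (LDproxy-style
  columns `variant_id, chrom, pos, r2, dprime`; a file-based stand-in for a
  remote LD service, so runs are reproducible offline). The interval spans
  the most distant upstream/downstream proxies meeting the threshold;
  proxies outside the 1 Mbp window centred on the SNP are ignored; the
  index always qualifies, so the interval always contains it. A missing
  proxy table degrades to a 1-bp interval with a warning instead of
  aborting a multi-locus run. Population choice is simply a label selecting
  an LD-source directory.
* **User intervals** — BED, TSV or `chrom:start-end` text.

Optional hotspot extension moves each boundary outward to the nearest
recombination-map entry with rate **strictly** greater than 3 cM/Mb (at or
left of the start; at or right of the end). The map entry's own position is
used as the new boundary — hotspots are reported as points in HapMap-style
maps, and any interval-valued definition would need a width convention the
data does not provide. The operation never shrinks an interval and is
idempotent.

Validation caps: at most 10,000 intervals, each at most 20 Mbp. Overlapping
intervals from different lead SNPs are deliberately **not** merged; shared
genes are handled by gene collapsing in the enrichment engine, and keeping
loci separate preserves the per-locus structure of the input (at the cost
that one signal tagged by several lead SNPs counts multiple times, which is
a property of the input, not of the test).

# Overlap and gene collapsing

Gene regions are canonical transcript spans optionally extended up to
20 kbp per side. Extension is strand-aware by default ("upstream" is
transcription-relative, which is the conventional reading for regulatory
regions); `strand_aware = FALSE` gives the strand-agnostic alternative.
Interval/region intersection requires at least one shared base — touching
end-to-start in inclusive coordinates is not overlap. The engine is
`IRanges::findOverlaps` behind these contracts; every behaviour is pinned
to brute-force all-pairs oracles in the test suite, so the library is an
implementation detail, not the specification. Variants are anchored at
their single `pos` even for indels; multi-base variant spans are out of
scope.

Background gene regions that mutually overlap are collapsed into maximal
clusters (union of overlap chains). Clusters, not genes, are the unit of
confounder matching below: tightly packed paralog arrays would otherwise be
trivially "hit" by any relocation landing nearby, and collapsing is what
prevents them from dominating the null. Collapsing is restricted to
background (Mendelian) genes because the enrichment background is all
Mendelian disease genes.

# The enrichment test

## Observed statistic

Gene mode counts distinct annotated background genes across all intervals;
interval mode counts intervals containing at least one such gene. Gene mode
has more power when several related genes cluster within loci; interval
mode is robust to one locus containing many genes of the same term.

## The relocation null

Each interval, independently, is relocated to a uniformly random
same-length position whose background-cluster count equals the original's
(± `match_tolerance`, default 0). This conditions the null on the two
dominant genomic confounders of interval-based gene-set statistics —
interval length and local gene density/size — which, if ignored, inflate
family-wise type-I error dramatically. SNP-density matching would require a
variant-position map and is deliberately not a default.

Rather than rejection sampling, the implementation enumerates the valid
placement set exactly: on each chromosome the cluster count of a length-L
window is a piecewise-constant step function of its start (each cluster
contributes +1 on one contiguous start range), so the matched set is a
union of integer ranges, sampled uniformly by weight. This realizes the
stated distribution ("uniform among matching positions") with no rejection
failures; if the matched set is empty at the configured tolerance the
tolerance is relaxed by 1 with a logged note, and an error naming the
interval is raised only if no placement exists at any tolerance.

Per-interval RNG substreams are derived from the master seed and a hash of
the interval's **label**, so results are identical under reordering of the
input intervals. Intervals sharing a label share a substream — labels are
expected to be unique (they are variant ids or coordinate strings).

## Estimators

With R₁ first-level replicates (default 5,000),
`empirical_p = (1 + exceedances) / (R₁ + 1)` — never zero, bounded below by
`1/(R₁+1)`. Terms with genome-wide gene counts outside
`[min_term_size, max_term_size]` (defaults 2 and 2,000) are excluded, as is
the DAG root.

Correction uses a min-p bootstrap with R₂ fresh pseudo-experiments (default
1,000): each bootstrap replicate relocates all intervals anew, its per-term
p-values are computed against the *first-level* null distributions, and the
minimum over terms forms the reference distribution. Fresh draws (rather
than reusing first-level relocations) keep the two levels independent; the
cost is R₂ extra relocation rounds, which the vectorized engine absorbs.
An interval overlapping zero background genes is kept: it contributes 0 to
every statistic and relocates within gene deserts (k = 0), which is the
faithful matched behaviour.

Results are ranked by empirical p ascending, then number of overlapping
genes descending, then term id — the same comparator drives the report
table and the top-terms figure, whose point size encodes the gene ratio
(genes found in intervals / all Mendelian genes annotated with the term)
and whose colour encodes empirical p (any monotone colour map satisfies the
contract; a red-to-blue ramp is used).

# The synthetic data generator

`generate_fixture()` emits a complete input bundle — toy genome,
transcripts with APPRIS flags, four-source association tables with
overlapping provenance, description tables, an is_a ontology with
per-source disease–term tables, ClinVar-like variants, LD proxy tables
(exponential r² decay with multiplicative noise; D′ ≥ r² row-wise),
HapMap-style recombination map with hotspots at fixed spacing, and test
intervals — plus a ground-truth manifest. Identical seeds give
byte-identical bundles.

The default world is the calibration world: one 10 Mbp chromosome, 60
genes, 10 terms of 4–8 genes under a single root, 8 intervals of 100 kbp.
For calibration runs the termless-disease fraction is set to 0 so realized
term sizes are exactly 4–8; elsewhere the default is 0.1, reflecting that a
substantial minority of real gene–disease entries carry no ontology
annotation. Multi-gene diseases are drawn from the termless pool only, so
the manifest's term membership is exactly what annotation recomputes.

Planted signal works by *interval placement*: `effect × n_target_loci`
intervals are centred on member genes of the planted term, which is how a
real GWAS signal would manifest (loci landing on phenotypically related
genes), rather than by inflating term sizes. Null bundles assign term
labels to genes independently of position and of the intervals, so every
term's null hypothesis is true by construction.

What the generator does **not** emulate: realistic LD structure (no
population-genetic model), chromosome-scale gene-density gradients,
correlated term memberships between related ontology branches, and real
identifier vocabularies. A green calibration therefore establishes that the
test is calibrated *for the confounders the null matches* on a genome of
this shape — not that it corrects biases absent from the simulation (e.g.
SNP-density artefacts).

# Numerical and reporting choices

* All string ordering uses C-locale radix sort; tables are written with
  fixed formatting (`\n` endings, no quoting, no scientific notation), so
  identical seed + config gives byte-identical text outputs on one
  platform.
* Config files are JSON. Output inventory per run: `mendelprior.log` (every
  config value actually used, plus warnings), `input_file.bed` (0-based
  echo of validated input), `disease_overlap.txt` (one row per interval ×
  gene × disease; the full column set beyond the canonical
  interval/gene/disease/link columns is artifact-defined and documented in
  the writer), `variant_overlap.txt`, and per ontology `*.out.inrich`,
  `*.out.inrich.parsed`, `*.top_terms.tsv` and a best-effort `.png` that
  never fails the run.
* CLI exit codes: 0 success, 2 validation error, 3 data error, 4 internal
  error.
* Defaults R₁ = 5,000 and R₂ = 1,000 suit real analyses; the test suite and
  acceptance script use R₁ = 500, R₂ = 200 (calibration) and R₁ = 2,000
  (exact-null agreement), which keeps the full suite around two minutes
  while leaving Monte-Carlo error well inside the asserted tolerances.

# Known limitations

* No LD computation from genotypes, no genome-build conversion, no live
  database adapters — these are documented integration points, not
  features.
* Confounder matching covers interval length and gene-cluster density
  only; SNP density requires an optional variant map not bundled here.
* The gene-mode statistic counts distinct genes across intervals, so when
  two input intervals overlap the same gene the "gene-mode ≥ interval-mode"
  intuition can fail; with non-overlapping loci it always holds.
* Interval-mode power degrades when one locus contains many same-term
  genes, by design.
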