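---
title: "Managing and comparing microbial genome collections"
author: "genomekeeper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing and comparing microbial genome collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genomekeeper)
```

`genomekeeper` manages a collection of annotated microbial genomes in a
single embedded store and supports comparative analysis anchored on
precomputed ortholog groups. This vignette explains the methods and the
design choices behind each stage; the README shows the worked example.

## The store

All entities — genomes, contigs, genes, deduplicated proteins, taxonomy,
strains, samples, metadata triples, operons, regulons, binding sites,
ortholog-group memberships, functional labels, gene annotations, tool
configurations and job records — live in one store file. The store is
implemented as serialized R tables behind an atomic write-rename: every
mutating call either commits completely or leaves the previous file
intact. A magic header and a schema version make corrupt files and
stores written by a newer schema fail cleanly. Several independent store
files on one host are the intended way to keep separate projects
separate; there is no shared registry.

`store_audit()` checks referential integrity after any operation
sequence: genes within contig bounds, CDS protein hashes resolvable,
operon members on one contig and strand with exact spans, site sequences
matching their intervals, and every persisted protein label present in
the label table.

## Import and protein deduplication

GenBank flat files are parsed directly (LOCUS records become contigs;
multi-record files become multi-contig genomes). Coordinates are
converted once at the boundary: GenBank and GFF3 are 1-based inclusive,
everything internal is 0-based half-open, which keeps interval
arithmetic uniform and confines the conversion to the parser and the
exporters.

For each CDS the protein sequence is taken from `/translation` when
present, otherwise re-derived from the spliced nucleotide sequence with
translation table 11 (the bacterial/archaeal code; `/transl_table` is
honored when given) and the trailing stop stripped. Features with fuzzy
(`<`/`>`) endpoints are imported with a warning and never re-translated:
guessing truncated proteins would poison the dedup table. CDS with
internal stops or non-multiple-of-three spans keep their gene record but
get no protein.

Each protein is keyed by the MD5 digest of its amino-acid sequence. The
hash is computed over the amino-acid rather than the nucleotide sequence
so that synonymous differences between genomes still deduplicate. On
import, a hash already present store-wide reuses the existing record;
the import report exposes the novel/known split. This split is what
makes collection updates cheap: everything downstream that is expensive
is only ever run on novel hashes.

## Incremental ortholog-group assignment

Orthology is not inferred de novo — all-against-all approaches are
quadratic in the collection and get slower with every update. Instead,
proteins are assigned to precomputed ortholog groups, possibly at
several taxonomic levels, from a reference table (TSV, keyed by protein
MD5 or raw sequence). `assign_orthologs()` looks up **only hashes that
the store has never seen**: hashes with existing assignments are
skipped, hashes previously found absent from the reference are recorded
and not retried unless `retry_unassigned` is set. The reference index
carries an instrumented lookup counter so this contract is testable:
during any assignment run the counter advances exactly once per novel
hash, independent of store size, and a second run performs zero lookups
and zero writes.

A real external mapper can stand in for the table through
`run_mapper_plugin()`: it receives a FASTA of novel proteins only and
must emit the same reference dialect; a failing tool leaves the store
untouched.

When a protein maps to groups at several taxonomic levels, neighborhood
queries need one level. The default is the anchor's most specific
assignment, operationalized as the level whose group has the fewest
member proteins store-wide (ties broken by level name). This is a
deliberate choice — nothing in the data dictates it — and it can be
overridden per call with `og_level`.

## Operon calling

The built-in predictor is a transparent heuristic: maximal runs of two
or more consecutive same-strand CDS in which every intergenic gap
(`next start − previous end`) is at most `max_gap` become operons.
`max_gap` defaults to 150 bp, a conventional prokaryotic intergenic
threshold; overlapping same-strand genes (negative gap) count as gap 0
and join; singletons are never operons. The rule is monotone: raising
`max_gap` never removes genes from operon coverage. An external
predictor can replace the heuristic through the operon plugin contract
(TSV of `operon_name`, `genome`, `contig`, comma-separated
`locus_tags`); plugin output *replaces* previous predictions for the
genome rather than merging, so re-annotation is idempotent — merge
semantics would make repeated runs order-dependent.

## Annotation pipeline

Tools are registered with a command template (`{input_faa}`,
`{input_fna}`, `{input_gff}`, `{output_tsv}`, `{workdir}`, plus one
placeholder per configured parameter) and an execution-environment
label. Rendering is fixed-string placeholder substitution only — no
shell interpolation of values. By default commands are prefixed with
`conda run -n <env_name>`; `no_env = TRUE` runs plain scripts, which is
what the test suite's mock tools use. Jobs run sequentially, one per
(genome, tool): inputs are exported to a work directory, the tool runs,
and its output TSV is validated and imported atomically — a failed job
changes nothing for that pair and does not abort the rest. The
annotation exchange format is fixed by this package as six tab-separated
columns (`locus_tag`, `genome`, `source`, `key`, `value`, `note`);
anyone exchanging annotation files with other systems should note that
this column set is this package's contract. Duplicate annotations (same
gene, source, key, value) are counted as skipped, never imported twice.

## Neighborhood comparison

Given an anchor CDS with an ortholog family, candidates are all store
proteins of that family — restricting to the family rather than scanning
the whole store keeps the cost linear in family size and mirrors the
ortholog-centric design. Similarity is the global pairwise alignment
score under BLOSUM62 with affine gaps (open 11, extend 1: a gap of
length L costs 11 + L). Scores are ranked descending, ties broken by
(genome, locus tag), the anchor always first, truncated to `max_n`,
which must lie in 10–200. Distances for the guide tree are
`1 − S(a,b) / min(S(a,a), S(b,b))`, clamped into [0, 1]; a self or
identical hit has distance 0. Neighbor joining builds the tree, negative
branch lengths are clamped to zero, the tree is midpoint-rooted, and
children are ordered smaller-subtree-first with lexicographic
tie-breaks, so the serialized Newick and the row order are
deterministic and identical.

Each row shows every gene overlapping a symmetric window (default 10 kb)
around the hit gene's midpoint. Rows whose hit gene lies on the minus
strand are mirrored (coordinates reflected about the center, strands
flipped) so the anchor family always points rightward — the standard
synteny-view convention. Colors are assigned to families in order of
first appearance scanning rows top-down, left-to-right, with the
anchor's family fixed at color 0; unassigned genes get no color. The
functional profile tallies COG category letters over all genes of all
rows; a multi-letter category such as "KT" increments K and T once each,
and genes without a category count under "unclassified", so the total is
the sum of the entries (which can exceed the gene count when multi-letter
categories are present — the per-letter rule takes precedence).

Conserved-operon and conserved-regulon queries intersect
ortholog-group sets at a single taxonomic level (default: the level
annotating the most proteins store-wide; comparing across levels at once
would double-count families annotated at several levels). Regulon
comparison additionally requires the regulator genes, when present on
both sides, to share a group.

## Sequence search

The internal search is a documented seed-and-extend with fixed
parameters rather than a wrapper around an external aligner: exact
k-mer seeds (nucleotide k = 11 searched on both strands, protein k = 4),
ungapped extension in both directions terminated when the running score
drops 20 below its maximum, nucleotide scoring +1/−2, protein BLOSUM62.
Overlapping hits on the same diagonal are merged by extending the first
seed and skipping seeds it covers. Results report raw score and percent
identity only — no E-values, no gapped extension, no translated
searches. Any exact stored substring of at least seed length is
guaranteed to surface at 100% identity, and reverse-complement queries
return the same forward-strand subject intervals with the strand
flipped.

## Synthetic collections and what the tests show

The generator plants ortholog families by mutating a family-ancestor
protein at a per-residue substitution rate (default 5%) and
back-translating with uniform codon choice from the seeded generator, so
truth tables (gene-to-family map, operon membership, identity
percentages) are exact by construction and the whole output is
byte-identical for a given seed. Operons are planted as tight
same-strand runs (gaps 5–50 bp) separated by 200–400 bp from everything
else, so the 150 bp rule recovers them exactly. The default desk-scale
conditions — 10 genomes × 200 genes, half the gene complement from a
shared family pool, operons of 4, 3 and 2 genes — exercise cross-genome
dedup, incremental mapping and conserved neighborhoods at sizes the full
suite processes in about a minute.

What passing tests do **not** show: real genomes have fuzzy and
pseudogenized features, rearranged neighborhoods, horizontally
transferred genes, paralogs within a genome, and families whose members
differ by indels rather than substitutions only. The generator models
none of these, so the tests certify the contracts (dedup arithmetic,
lookup counts, coordinate conversions, rule-based operon calls, tree and
color determinism), not biological accuracy of the heuristics on real
data.

## Numerical and degenerate-input choices

* Alignment scores are integers; ranking ties are always broken
  lexicographically, never by float comparison.
* Normalized distances are clamped into [0, 1]; unrelated family members
  with negative alignment scores therefore saturate at 1.
* Single-leaf and two-leaf guide trees are built directly (neighbor
  joining needs ≥ 3); identical sequences yield all-zero distances and a
  zero-length tree.
* Empty metadata files import 0 rows; an all-bad file is an error with a
  row-level report.
* Deleting a genome removes proteins (and their assignments) only when
  no remaining gene references them.
* All sorting of identifiers uses byte order (locale-independent), which
  is what makes exports byte-reproducible across systems.

## Static site export

`export_site()` writes `genomes.json`, `sunburst.json`, per-genome
track files plus `genes.json` / `operons.json` / `regulons.json`, and a
minimal `index.html`. Schemas are intentionally flat: `genomes.json` is
a list of objects with `genome_id`, `strain`, `taxon_id`, `taxon_name`
and entity counts; `sunburst.json` is the recursive
`name`/`rank`/`taxon_id`/`count`/`children` node tree whose child counts
sum to each parent's count; the per-genome JSON files carry the same
fields as the store tables. `site_audit()` re-reads an exported tree and
verifies cross-file consistency, and the export is deterministic, so two
exports of the same store are byte-identical.
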