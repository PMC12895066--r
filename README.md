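# genomekeeper

`genomekeeper` is an R toolkit for managing and comparatively analyzing
collections of annotated microbial genomes, aimed at groups who maintain
project-scale genome sets (isolate collections, MAG panels) and want
annotation, ortholog-aware comparison and export to static browser
artifacts without standing up a database server or a web stack.

## What it does

* **Incremental import.** GenBank flat files (as produced by Prokka, Bakta
  or NCBI-style exports) are parsed into an embedded single-file store.
  Every protein sequence is keyed by its MD5 content hash: a CDS whose
  hash already exists store-wide reuses the existing protein record, so a
  growing collection stores each distinct protein exactly once.
* **Incremental ortholog-group mapping.** Proteins are assigned to
  precomputed ortholog groups (with KEGG ortholog/pathway, EC, GO and COG
  category labels) from a reference table. Only hashes *new to the store*
  are ever looked up — update cost scales with the number of novel
  sequences, not with collection size. All-against-all orthology
  inference, which is quadratic in the collection, is deliberately out of
  scope.
* **Operon prediction.** A transparent distance/strand heuristic: maximal
  runs of ≥ 2 same-strand adjacent CDS with intergenic gaps ≤ `max_gap`
  (150 bp default), or an external predictor through the plugin contract.
* **Annotation pipeline.** Registered tools with per-tool configuration
  run sequentially per genome from rendered command templates (optionally
  inside a named conda environment) and must emit a 6-column tab-separated
  annotation file (`locus_tag`, `genome`, `source`, `key`, `value`,
  `note`) that is validated and imported atomically per job.
* **Neighborhood comparison.** For an anchor gene, the 10–200 most similar
  proteins of its ortholog family are ranked by global alignment score
  (BLOSUM62, affine gaps open 11 / extend 1), arranged by a
  midpoint-rooted neighbor-joining guide tree over normalized distances
  `1 − S / min(S_self(query), S_self(hit))`, and drawn as rows of
  family-colored gene arrows with a COG-category functional profile.
* **Search.** Text search over gene names, products, annotations and
  classifications (exact-identifier for K numbers, GO terms, EC numbers),
  genome/strain/taxonomy/metadata search, and an internal seed-and-extend
  sequence search (nucleotide k = 11 on both strands, protein k = 4,
  ungapped X-drop 20) reporting raw score and percent identity.
* **Exports.** Per-genome FASTA + GFF3 + protein FASTA track files, a
  taxonomy sunburst, and a static JSON/HTML site for the whole collection.
* **Synthetic collections.** A deterministic generator plants ortholog
  families, operons and taxonomy with exact truth tables, used throughout
  the tests.

## Worked example

```r
library(genomekeeper)

dir <- tempfile()
synth_collection(collection_spec(n_genomes = 3, genes_per_genome = 20,
                                 operon_sizes = c(3L, 2L), seed = 7), dir)

st <- open_store(tempfile(fileext = ".gkdb"), create = TRUE)
import_collection(st, dir)
#> genome GEN001: 1 contigs, 20 genes (20 CDS), 20 new / 0 reused proteins
#> genome GEN002: 1 contigs, 20 genes (20 CDS), 20 new / 0 reused proteins
#> genome GEN003: 1 contigs, 20 genes (20 CDS), 19 new / 1 reused proteins

ref <- load_reference(file.path(dir, "reference.tsv"))
assign_orthologs(st, ref, "GEN001")
#> genome GEN001: 20 proteins, 0 already known, 20 assigned, 0 unassigned
assign_orthologs(st, ref, "GEN003")
#> genome GEN003: 20 proteins, 1 already known, 19 assigned, 0 unassigned

predict_operons(st, "GEN001")
#> [1] 2

v <- build_neighborhood(st, "GEN001:GEN001_0001", max_n = 10,
                        window_bp = 6000)
v
#> <neighborhood> anchor GEN001:GEN001_0001, family OG0001@Bacteria, 3 rows, 13 colors
```

The import lines show the protein dedup at work: one of GEN003's proteins
is byte-identical to a protein already in the store, so it is reused and —
in the ortholog step — skipped rather than looked up again (`1 already
known`). `predict_operons` finds the two planted operons. The
neighborhood view holds one row per genome carrying the anchor's family,
ordered by the guide tree; 13 distinct families receive colors, the
anchor's family always color 0.

A thin command-line front end over the same functions ships at
`inst/cli/genomekeeper.R` (subcommands `synth`, `init`, `import`,
`taxonomy`, `orthologs`, `operons`, `annotate`, `search`, `seqsearch`,
`neighborhood`, `export`, `export-site`, `delete`; every subcommand takes
`--db PATH`).

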