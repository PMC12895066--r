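# Deterministic synthetic genome collections with planted ortholog families
# and operons. Families are generated by mutating a family-ancestor protein
# at a per-residue substitution rate; coding sequences are back-translated
# with uniform codon choice from the seeded generator, so truth-table
# identity percentages and the dedup arithmetic are exact by construction.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
COG_CATS <- c("C", "E", "G", "H", "J", "K", "L", "M", "P", "T")

#' Define a synthetic-collection specification
#'
#' Defaults are the desk-scale study conditions used throughout the test
#' suite: 10 genomes of 200 genes, half the gene complement drawn from a
#' shared ortholog-group pool (so cross-genome protein deduplication and
#' conserved neighborhoods are exercised), planted operons of 4, 3 and 2
#' genes per genome, and a 5% per-residue substitution rate within families.
#'
#' @param n_genomes number of genomes.
#' @param genes_per_genome protein-coding genes per genome.
#' @param og_pool_size number of ortholog families in the pool.
#' @param shared_og_fraction fraction of each genome's genes drawn from the
#'   shared family pool (families present in every genome).
#' @param operon_sizes integer vector of planted operon sizes (each >= 2),
#'   planted at the start of every genome using shared families so operon
#'   conservation is exact.
#' @param mutation_rate per-residue substitution probability for family
#'   members relative to the family ancestor.
#' @param seed integer seed; the same seed yields byte-identical output.
#' @return a `collection_spec` list.
#' @export
collection_spec <- function(n_genomes = 10, genes_per_genome = 200,
                            og_pool_size = 2 * genes_per_genome,
                            shared_og_fraction = 0.5,
                            operon_sizes = c(4L, 3L, 2L),
                            mutation_rate = 0.05, seed = 1L) {
  spec <- list(n_genomes = as.integer(n_genomes),
               genes_per_genome = as.integer(genes_per_genome),
               og_pool_size = as.integer(og_pool_size),
               shared_og_fraction = shared_og_fraction,
               operon_sizes = as.integer(operon_sizes),
               mutation_rate = mutation_rate, seed = as.integer(seed))
  n_shared <- round(spec$shared_og_fraction * spec$genes_per_genome)
  if (n_shared > spec$og_pool_size)
    stop("unsatisfiable spec: shared_og_fraction * genes_per_genome exceeds og_pool_size")
  if (spec$genes_per_genome > spec$og_pool_size)
    stop("unsatisfiable spec: genes_per_genome exceeds og_pool_size")
  if (any(spec$operon_sizes < 2))
    stop("unsatisfiable spec: operon sizes must be >= 2")
  if (sum(spec$operon_sizes) > n_shared)
    stop("unsatisfiable spec: operons need more shared families than available")
  if (spec$mutation_rate < 0 || spec$mutation_rate > 1)
    stop("unsatisfiable spec: mutation_rate outside [0, 1]")
  class(spec) <- "collection_spec"
  spec
}

mutate_protein <- function(aa, rate) {
  if (rate <= 0) return(aa)
  ch <- strsplit(aa, "", fixed = TRUE)[[1]]
  n <- length(ch)
  hit <- which(stats::runif(n) < rate)
  hit <- hit[hit > 1L]  # keep the initiator methionine
  for (i in hit) ch[i] <- sample(setdiff(AA20, ch[i]), 1L)
  paste(ch, collapse = "")
}

back_translate <- function(aa, codon_choices) {
  ch <- strsplit(aa, "", fixed = TRUE)[[1]]
  codons <- vapply(ch, function(a) {
    opts <- codon_choices[[a]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1))
  paste0(paste(codons, collapse = ""), sample(c("TAA", "TGA", "TAG"), 1L))
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

#' Generate a synthetic genome collection
#'
#' Writes one GenBank file per genome (coding sequences consistent with
#' their `/translation` qualifiers under translation table 11), a taxonomy
#' TSV, an ortholog-reference TSV covering every planted protein variant
#' with KEGG/EC/GO/COG labels, truth tables (gene-to-family assignments with
#' identity percentages, and operon memberships), and a JSON manifest. All
#' output is deterministic for a given seed.
#'
#' @param spec a [collection_spec()].
#' @param outdir output directory (created).
#' @return the manifest (list), invisibly readable from
#'   `file.path(outdir, "manifest.json")`.
#' @export
synth_collection <- function(spec, outdir) {
  stopifnot(inherits(spec, "collection_spec"))
  dir.create(file.path(outdir, "genomes"), recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  code <- Biostrings::getGeneticCode("11")
  codon_choices <- split(names(code), code)
  n_pool <- spec$og_pool_size
  og_ids <- sprintf("OG%04d", seq_len(n_pool))
  anc_len <- sample(60:90, n_pool, replace = TRUE)
  ancestors <- vapply(anc_len, function(L)
    paste0("M", paste(sample(AA20, L - 1L, replace = TRUE), collapse = "")),
    character(1))
  pathways <- sprintf("map%05d", seq(10, 80, by = 10))
  og_labels <- data.frame(
    og_id = og_ids,
    kegg_ko = sprintf("K%05d", seq_len(n_pool)),
    kegg_pathway = sample(pathways, n_pool, replace = TRUE),
    ec = ifelse(seq_len(n_pool) %% 2 == 0,
                sprintf("%d.%d.%d.%d", sample(1:6, n_pool, replace = TRUE),
                        sample(1:9, n_pool, replace = TRUE),
                        sample(1:9, n_pool, replace = TRUE),
                        sample(1:99, n_pool, replace = TRUE)), ""),
    go = sprintf("GO:%07d", seq_len(n_pool) * 13L),
    cog_category = vapply(seq_len(n_pool), function(i)
      paste(sample(COG_CATS, sample(1:2, 1L)), collapse = ""), character(1)),
    stringsAsFactors = FALSE)

  n_shared <- round(spec$shared_og_fraction * spec$genes_per_genome)
  shared_idx <- seq_len(n_shared)
  planted <- sum(spec$operon_sizes)

  # taxonomy: root -> Bacteria -> phylum -> 3 genera -> one species per
  # genome pair (adjacent genomes share a species)
  n_species <- ceiling(spec$n_genomes / 2)
  genus_of_species <- ((seq_len(n_species) - 1L) %% 3L) + 1L
  taxa <- rbind(
    data.frame(taxon_id = "2", name = "Bacteria", rank = "superkingdom",
               parent_id = "1", stringsAsFactors = FALSE),
    data.frame(taxon_id = "1224", name = "Synthoproteobacteria", rank = "phylum",
               parent_id = "2", stringsAsFactors = FALSE),
    data.frame(taxon_id = as.character(100 + 1:3),
               name = paste0("Synthogenus", c("A", "B", "C")), rank = "genus",
               parent_id = "1224", stringsAsFactors = FALSE),
    data.frame(taxon_id = as.character(2000 + seq_len(n_species)),
               name = sprintf("Synthogenus%s species%d",
                              c("A", "B", "C")[genus_of_species],
                              seq_len(n_species)),
               rank = "species",
               parent_id = as.character(100 + genus_of_species),
               stringsAsFactors = FALSE))

  genome_ids <- sprintf("GEN%03d", seq_len(spec$n_genomes))
  truth_genes <- list()
  truth_operons <- list()
  ref_rows <- list()
  seen_hash <- character(0)
  all_hashes <- character(0)
  gb_files <- character(0)

  for (gi in seq_len(spec$n_genomes)) {
    gid <- genome_ids[gi]
    sp_idx <- ceiling(gi / 2)
    taxon_id <- as.character(2000 + sp_idx)
    organism <- taxa$name[taxa$taxon_id == taxon_id]

    extra_shared <- setdiff(shared_idx, seq_len(planted))
    n_specific <- spec$genes_per_genome - n_shared
    specific <- if (n_specific > 0)
      sample(setdiff(seq_len(n_pool), shared_idx), n_specific) else integer(0)
    tail_ogs <- c(extra_shared, specific)
    tail_ogs <- tail_ogs[sample.int(length(tail_ogs))]
    gene_ogs <- c(seq_len(planted), tail_ogs)

    prots <- vapply(gene_ogs, function(oi)
      mutate_protein(ancestors[oi], spec$mutation_rate), character(1))
    cds <- vapply(prots, back_translate, character(1),
                  codon_choices = codon_choices)

    # layout: planted operons first (tight same-strand runs), then singletons
    n_genes <- length(gene_ogs)
    strand <- integer(n_genes)
    op_of_gene <- integer(n_genes)
    pos <- 1L
    for (k in seq_along(spec$operon_sizes)) {
      sz <- spec$operon_sizes[k]
      strand[pos:(pos + sz - 1L)] <- sample(c(1L, -1L), 1L)
      op_of_gene[pos:(pos + sz - 1L)] <- k
      pos <- pos + sz
    }
    if (pos <= n_genes)
      strand[pos:n_genes] <- sample(c(1L, -1L), n_genes - pos + 1L,
                                    replace = TRUE)

    cursor <- sample(100:200, 1L)
    seq_parts <- list(rand_dna(cursor))
    starts <- ends <- integer(n_genes)
    for (j in seq_len(n_genes)) {
      nt <- cds[j]
      placed <- if (strand[j] == 1L) nt else rev_comp(nt)
      starts[j] <- cursor
      ends[j] <- cursor + nchar(nt)
      seq_parts[[length(seq_parts) + 1L]] <- placed
      in_operon <- j < n_genes && op_of_gene[j] != 0L &&
        op_of_gene[j + 1L] == op_of_gene[j]
      gap <- if (in_operon) sample(5:50, 1L) else sample(200:400, 1L)
      seq_parts[[length(seq_parts) + 1L]] <- rand_dna(gap)
      cursor <- ends[j] + gap
    }
    contig_seq <- paste(unlist(seq_parts), collapse = "")
    contig_id <- paste0(gid, "_c1")
    tags <- sprintf("%s_%04d", gid, seq_len(n_genes))
    ident <- vapply(seq_len(n_genes), function(j) {
      a <- strsplit(ancestors[gene_ogs[j]], "", fixed = TRUE)[[1]]
      b <- strsplit(prots[j], "", fixed = TRUE)[[1]]
      100 * sum(a == b) / length(a)
    }, numeric(1))

    genes <- data.frame(
      gene_id = paste0(gid, ":", tags), genome_id = gid,
      contig_id = contig_id, locus_tag = tags, start = starts, end = ends,
      strand = strand, feature_type = "CDS", name = NA_character_,
      function_text = sprintf("%s family protein", og_ids[gene_ogs]),
      protein_seq = unname(prots), stringsAsFactors = FALSE)
    record <- structure(list(
      genome_id = gid,
      contigs = data.frame(contig_id = contig_id, length = nchar(contig_seq),
                           sequence = contig_seq, stringsAsFactors = FALSE),
      genes = genes,
      source_taxon = list(name = organism, taxon_id = taxon_id),
      warnings = character(0)), class = "genome_record")
    gbf <- file.path(outdir, "genomes", paste0(gid, ".gbk"))
    write_genbank(record, gbf)
    gb_files <- c(gb_files, gbf)

    hashes <- md5_strings(unname(prots))
    all_hashes <- c(all_hashes, hashes)
    truth_genes[[gi]] <- data.frame(
      genome = gid, contig = contig_id, locus_tag = tags,
      start = starts, end = ends, strand = strand,
      og_id = og_ids[gene_ogs], protein_hash = hashes,
      identity_pct = sprintf("%.2f", ident), stringsAsFactors = FALSE)
    for (k in seq_along(spec$operon_sizes)) {
      mem <- tags[op_of_gene == k]
      truth_operons[[length(truth_operons) + 1L]] <- data.frame(
        genome = gid, contig = contig_id, operon_index = k,
        locus_tags = paste(mem, collapse = ","), stringsAsFactors = FALSE)
    }
    novel <- !hashes %in% seen_hash
    if (any(novel)) {
      lab <- og_labels[gene_ogs[novel], ]
      ref_rows[[length(ref_rows) + 1L]] <- data.frame(
        protein_md5 = hashes[novel], protein_seq = unname(prots)[novel],
        og_id = og_ids[gene_ogs[novel]], level = "Bacteria",
        kegg_ko = lab$kegg_ko, kegg_pathway = lab$kegg_pathway, ec = lab$ec,
        go = lab$go, cog_category = lab$cog_category, stringsAsFactors = FALSE)
      seen_hash <- c(seen_hash, hashes[novel])
    }
  }

  ref <- do.call(rbind, ref_rows)
  # exercise both reference key columns: every 7th row is keyed by sequence
  by_seq <- seq_len(nrow(ref)) %% 7L == 0L
  ref$protein_md5[by_seq] <- ""
  ref$protein_seq[!by_seq] <- ""

  tax_path <- file.path(outdir, "taxonomy.tsv")
  write_tsv_plain(taxa, tax_path)
  ref_path <- file.path(outdir, "reference.tsv")
  write_tsv_plain(ref, ref_path)
  tg <- do.call(rbind, truth_genes)
  tg_path <- file.path(outdir, "truth_genes.tsv")
  write_tsv_plain(tg, tg_path)
  to <- do.call(rbind, truth_operons)
  to_path <- file.path(outdir, "truth_operons.tsv")
  write_tsv_plain(to, to_path)

  manifest <- list(
    seed = spec$seed, n_genomes = spec$n_genomes,
    genes_per_genome = spec$genes_per_genome,
    shared_og_fraction = spec$shared_og_fraction,
    mutation_rate = spec$mutation_rate,
    operon_sizes = as.list(spec$operon_sizes),
    n_genes_total = nrow(tg),
    n_distinct_proteins = length(unique(all_hashes)),
    n_reference_entries = length(unique(seen_hash)),
    genome_files = as.list(file.path("genomes", paste0(genome_ids, ".gbk"))),
    taxonomy = "taxonomy.tsv", reference = "reference.tsv",
    truth_genes = "truth_genes.tsv", truth_operons = "truth_operons.tsv")
  write_json_file(manifest, file.path(outdir, "manifest.json"))
  invisible(manifest)
}

write_tsv_plain <- function(df, path) {
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(unname(as.list(df)), sep = "\t")))
  write_lines_lf(lines, path)
}

#' Import a synthetic collection into a store
#'
#' Convenience wrapper: loads the taxonomy and imports every genome file of
#' a generated collection directory in manifest order (or a given order).
#'
#' @param store a `gk_store` handle.
#' @param dir collection directory produced by [synth_collection()].
#' @param order optional permutation of genome file indices.
#' @return list of import reports.
#' @export
import_collection <- function(store, dir, order = NULL) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  load_taxonomy(store, file.path(dir, manifest$taxonomy))
  files <- file.path(dir, unlist(manifest$genome_files))
  if (!is.null(order)) files <- files[order]
  invisible(lapply(files, function(f) import_genome(store, parse_genbank(f))))
}
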