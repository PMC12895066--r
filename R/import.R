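#' Import a parsed genome into a store
#'
#' Persists contigs and genes atomically and deduplicates proteins by content
#' hash: a CDS whose protein hash already exists store-wide reuses the
#' existing protein record, otherwise a new record is created. The genome's
#' taxonomy hint is resolved against the taxonomy table by taxon_id first,
#' then by exact organism name; unresolved genomes are attached to the
#' "unclassified" node with a warning.
#'
#' @param store a `gk_store` handle.
#' @param record a `genome_record` from [parse_genbank()].
#' @param genome_id override for the genome identifier.
#' @param strain optional strain name; created if absent from the store.
#' @param sample optional sample name; created if absent from the store.
#' @return an `import_report` with `genome_id`, `n_contigs`, `n_genes`,
#'   `n_cds`, `n_new_proteins`, `n_reused_proteins` and `warnings`.
#' @export
import_genome <- function(store, record, genome_id = record$genome_id,
                          strain = NULL, sample = NULL) {
  t <- store$tables
  if (genome_id %in% t$genomes$genome_id)
    stop("duplicate genome_id: ", genome_id)
  warnings <- record$warnings

  genes <- record$genes
  if (nrow(genes)) {
    genes$genome_id <- genome_id
    genes$gene_id <- paste0(genome_id, ":", genes$locus_tag)
  }
  cds <- genes$feature_type == "CDS"
  with_prot <- cds & !is.na(genes$protein_hash)
  uniq_hash <- unique(genes$protein_hash[with_prot])
  new_hash <- setdiff(uniq_hash, t$proteins$protein_hash)
  if (length(new_hash)) {
    seqs <- genes$protein_seq[with_prot][match(new_hash,
                                               genes$protein_hash[with_prot])]
    t$proteins <- rbind(t$proteins, data.frame(
      protein_hash = new_hash, sequence = seqs, length = nchar(seqs),
      stringsAsFactors = FALSE))
  }
  n_new <- sum(genes$protein_hash[with_prot] %in% new_hash)
  n_reused <- sum(with_prot) - n_new

  # taxonomy resolution: id first, then exact name
  taxon_id <- "0"
  hint <- record$source_taxon
  if (!is.na(hint$taxon_id) && hint$taxon_id %in% t$taxa$taxon_id) {
    taxon_id <- hint$taxon_id
  } else if (!is.na(hint$name) && hint$name %in% t$taxa$name) {
    taxon_id <- t$taxa$taxon_id[match(hint$name, t$taxa$name)]
  } else {
    warnings <- c(warnings, sprintf(
      "taxonomy hint (%s, %s) unresolved; genome attached to 'unclassified'",
      hint$name, hint$taxon_id))
  }

  strain_id <- NA_character_
  if (!is.null(strain)) {
    hit <- t$strains$strain_id[t$strains$name == strain]
    if (length(hit)) strain_id <- hit[1] else {
      strain_id <- strain
      t$strains <- rbind(t$strains, data.frame(
        strain_id = strain, name = strain, taxon_id = taxon_id,
        stringsAsFactors = FALSE))
    }
  }
  sample_id <- NA_character_
  if (!is.null(sample)) {
    hit <- t$samples$sample_id[t$samples$name == sample]
    if (length(hit)) sample_id <- hit[1] else {
      sample_id <- sample
      t$samples <- rbind(t$samples, data.frame(
        sample_id = sample, name = sample, description = "",
        stringsAsFactors = FALSE))
    }
  }

  ctg <- record$contigs
  ctg$genome_id <- genome_id
  t$contigs <- rbind(t$contigs, ctg[, c("genome_id", "contig_id", "length",
                                        "sequence")])
  t$genes <- rbind(t$genes, genes[, setdiff(names(t$genes), character(0))])
  t$genomes <- rbind(t$genomes, data.frame(
    genome_id = genome_id, strain_id = strain_id, sample_id = sample_id,
    taxon_id = taxon_id, source_file = NA_character_, stringsAsFactors = FALSE))
  store_commit(store, t)

  structure(list(genome_id = genome_id, n_contigs = nrow(ctg),
                 n_genes = nrow(genes), n_cds = sum(cds),
                 n_new_proteins = n_new, n_reused_proteins = n_reused,
                 warnings = warnings),
            class = "import_report")
}

#' @export
print.import_report <- function(x, ...) {
  cat(sprintf("genome %s: %d contigs, %d genes (%d CDS), %d new / %d reused proteins\n",
              x$genome_id, x$n_contigs, x$n_genes, x$n_cds,
              x$n_new_proteins, x$n_reused_proteins))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

gff_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

#' Export genome browser-track files
#'
#' Writes, for one genome, a nucleotide FASTA of its contigs (`genome.fna`),
#' a GFF3 feature file (`genome.gff3`, version 3 header, 1-based inclusive
#' coordinates, attributes ID / locus_tag / product) and a protein FASTA
#' (`proteins.faa`) with headers `genome_id|locus_tag|protein_hash`. Output
#' is deterministic: contigs ordered by id, genes by start position.
#'
#' @param store a `gk_store` handle.
#' @param genome_id genome to export.
#' @param outdir output directory (created if needed).
#' @return named character vector of the three file paths.
#' @export
export_tracks <- function(store, genome_id, outdir) {
  t <- store$tables
  if (!genome_id %in% t$genomes$genome_id) stop("not found: genome ", genome_id)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ctg <- t$contigs[t$contigs$genome_id == genome_id, ]
  ctg <- ctg[order_c(ctg$contig_id), ]
  fna <- file.path(outdir, "genome.fna")
  dna <- Biostrings::DNAStringSet(stats::setNames(ctg$sequence, ctg$contig_id))
  Biostrings::writeXStringSet(dna, fna, width = 70L)

  g <- t$genes[t$genes$genome_id == genome_id, ]
  gff <- file.path(outdir, "genome.gff3")
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", ctg$contig_id, ctg$length))
  for (cid in ctg$contig_id) {
    gc <- g[g$contig_id == cid, , drop = FALSE]
    gc <- gc[order_c(gc$start, gc$locus_tag), , drop = FALSE]
    for (i in seq_len(nrow(gc))) {
      r <- gc[i, ]
      attrs <- sprintf("ID=%s;locus_tag=%s", gff_escape(r$gene_id),
                       gff_escape(r$locus_tag))
      if (!is.na(r$function_text))
        attrs <- paste0(attrs, ";product=", gff_escape(r$function_text))
      lines <- c(lines, paste(
        cid, "genomekeeper", r$feature_type, r$start + 1L, r$end, ".",
        if (r$strand == 1L) "+" else "-",
        if (r$feature_type == "CDS") "0" else ".", attrs, sep = "\t"))
    }
  }
  write_lines_lf(lines, gff)

  faa <- file.path(outdir, "proteins.faa")
  cds <- g[g$feature_type == "CDS" & !is.na(g$protein_hash), , drop = FALSE]
  cds <- cds[order_c(cds$contig_id, cds$start, cds$locus_tag), , drop = FALSE]
  seqs <- t$proteins$sequence[match(cds$protein_hash, t$proteins$protein_hash)]
  aa <- Biostrings::AAStringSet(stats::setNames(
    seqs, sprintf("%s|%s|%s", genome_id, cds$locus_tag, cds$protein_hash)))
  Biostrings::writeXStringSet(aa, faa, width = 70L)
  c(fna = fna, gff3 = gff, faa = faa)
}
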