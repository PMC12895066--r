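#' Export static site artifacts for a collection
#'
#' Writes a deterministic, serveable summary of the store: `genomes.json`
#' (one entry per genome with strain, taxon and entity counts),
#' `sunburst.json` (the taxonomy overview of [taxonomy_sunburst()]), one
#' directory per genome containing the browser-track files of
#' [export_tracks()] plus `genes.json`, `operons.json` and `regulons.json`,
#' and a minimal static `index.html` linking them.
#'
#' @param store a `gk_store` handle (must contain at least one genome).
#' @param outdir output directory.
#' @return the manifest list (files written), invisibly.
#' @export
export_site <- function(store, outdir) {
  t <- store$tables
  if (!nrow(t$genomes)) stop("nothing to export: store has no genomes")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gids <- sort_c(t$genomes$genome_id)
  tax_names <- stats::setNames(t$taxa$name, t$taxa$taxon_id)

  genomes <- lapply(gids, function(gid) {
    gm <- t$genomes[t$genomes$genome_id == gid, ]
    g <- t$genes[t$genes$genome_id == gid, ]
    list(genome_id = gid,
         strain = if (is.na(gm$strain_id)) NULL else gm$strain_id,
         taxon_id = gm$taxon_id,
         taxon_name = unname(tax_names[gm$taxon_id]),
         n_contigs = sum(t$contigs$genome_id == gid),
         n_genes = nrow(g),
         n_cds = sum(g$feature_type == "CDS"),
         n_operons = sum(t$operons$genome_id == gid))
  })
  write_json_file(genomes, file.path(outdir, "genomes.json"))
  write_json_file(taxonomy_sunburst(store), file.path(outdir, "sunburst.json"))

  files <- c("genomes.json", "sunburst.json")
  for (gid in gids) {
    gdir <- file.path(outdir, gid)
    export_tracks(store, gid, gdir)
    g <- t$genes[t$genes$genome_id == gid, ]
    g <- g[order_c(g$contig_id, g$start, g$locus_tag), ]
    genes_js <- lapply(seq_len(nrow(g)), function(i) {
      r <- g[i, ]
      list(gene_id = r$gene_id, contig_id = r$contig_id,
           locus_tag = r$locus_tag, start = r$start, end = r$end,
           strand = r$strand, feature_type = r$feature_type,
           product = if (is.na(r$function_text)) NULL else r$function_text)
    })
    write_json_file(genes_js, file.path(gdir, "genes.json"))
    ops <- t$operons[t$operons$genome_id == gid, ]
    ops <- ops[order_c(ops$operon_id), ]
    ops_js <- lapply(seq_len(nrow(ops)), function(i) {
      r <- ops[i, ]
      og <- t$operon_genes[t$operon_genes$operon_id == r$operon_id, ]
      list(operon_id = r$operon_id, contig_id = r$contig_id,
           start = r$start, end = r$end, strand = r$strand,
           gene_ids = as.list(og$gene_id[order(og$pos)]))
    })
    write_json_file(ops_js, file.path(gdir, "operons.json"))
    regs <- t$regulons[t$regulons$genome_id == gid, ]
    regs <- regs[order_c(regs$regulon_id), ]
    regs_js <- lapply(seq_len(nrow(regs)), function(i) {
      r <- regs[i, ]
      list(regulon_id = r$regulon_id, name = r$name,
           regulator_gene_id = if (is.na(r$regulator_gene_id)) NULL
           else r$regulator_gene_id,
           target_gene_ids = as.list(sort_c(
             t$regulon_targets$gene_id[t$regulon_targets$regulon_id ==
                                         r$regulon_id])))
    })
    write_json_file(regs_js, file.path(gdir, "regulons.json"))
    files <- c(files, file.path(gid, c("genome.fna", "genome.gff3",
                                       "proteins.faa", "genes.json",
                                       "operons.json", "regulons.json")))
  }

  html <- c("<!DOCTYPE html>", "<html><head><title>Genome collection</title></head><body>",
            "<h1>Genome collection</h1>",
            "<p><a href=\"genomes.json\">genomes.json</a> | <a href=\"sunburst.json\">sunburst.json</a></p>",
            "<ul>",
            sprintf("<li><a href=\"%s/genes.json\">%s</a></li>", gids, gids),
            "</ul>", "</body></html>")
  write_lines_lf(html, file.path(outdir, "index.html"))
  files <- c(files, "index.html")
  invisible(list(outdir = outdir, files = files))
}

#' Audit cross-file consistency of an exported site
#'
#' Checks that every gene id referenced from each genome's `operons.json`
#' and `regulons.json` exists in that genome's `genes.json`, and that the
#' sunburst root count equals the number of entries in `genomes.json`.
#'
#' @param outdir directory written by [export_site()].
#' @return character vector of problems; empty when consistent.
#' @export
site_audit <- function(outdir) {
  bad <- character(0)
  genomes <- jsonlite::fromJSON(file.path(outdir, "genomes.json"),
                                simplifyVector = FALSE)
  sb <- jsonlite::fromJSON(file.path(outdir, "sunburst.json"),
                           simplifyVector = FALSE)
  if (sb$count != length(genomes))
    bad <- c(bad, "sunburst root count != number of genomes")
  for (gm in genomes) {
    gdir <- file.path(outdir, gm$genome_id)
    genes <- jsonlite::fromJSON(file.path(gdir, "genes.json"),
                                simplifyVector = FALSE)
    ids <- vapply(genes, `[[`, character(1), "gene_id")
    ops <- jsonlite::fromJSON(file.path(gdir, "operons.json"),
                              simplifyVector = FALSE)
    for (op in ops) {
      miss <- setdiff(unlist(op$gene_ids), ids)
      if (length(miss))
        bad <- c(bad, sprintf("%s: operon %s references unknown gene %s",
                              gm$genome_id, op$operon_id, miss[1]))
    }
    regs <- jsonlite::fromJSON(file.path(gdir, "regulons.json"),
                               simplifyVector = FALSE)
    for (rg in regs) {
      miss <- setdiff(unlist(rg$target_gene_ids), ids)
      if (length(miss))
        bad <- c(bad, sprintf("%s: regulon %s references unknown gene %s",
                              gm$genome_id, rg$regulon_id, miss[1]))
    }
  }
  bad
}
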