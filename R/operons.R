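#' Call operons on one contig with a distance/strand heuristic
#'
#' Maximal runs of two or more consecutive same-strand CDS genes in which
#' every intergenic gap (next start minus previous end) is at most `max_gap`
#' base pairs become operons. Singletons are never operons. Overlapping
#' same-strand genes (negative gap) are treated as gap 0 and joined.
#'
#' @param genes data frame of genes on one contig, sorted by `start`, with
#'   columns `gene_id`, `contig_id`, `start`, `end`, `strand`,
#'   `feature_type` (only CDS rows are considered).
#' @param max_gap maximum intergenic distance in bp (default 150).
#' @param genome_id genome identifier used in operon ids.
#' @return data frame with one row per operon: `operon_id`, `contig_id`,
#'   `start`, `end`, `strand`, `n_genes`, and a `gene_ids` list column of
#'   member gene ids ordered by start.
#' @examples
#' g <- data.frame(gene_id = c("g:a", "g:b"), contig_id = "c1",
#'                 start = c(0L, 310L), end = c(300L, 600L),
#'                 strand = c(1L, 1L), feature_type = "CDS")
#' call_operons(g, max_gap = 150)
#' @export
call_operons <- function(genes, max_gap = 150L, genome_id = "genome") {
  if (is.unsorted(genes$start)) stop("input not sorted")
  g <- genes[genes$feature_type == "CDS", , drop = FALSE]
  n <- nrow(g)
  empty <- data.frame(operon_id = character(), contig_id = character(),
                      start = integer(), end = integer(), strand = integer(),
                      n_genes = integer(), stringsAsFactors = FALSE)
  empty$gene_ids <- list()
  if (n < 2) return(empty)
  if (length(unique(g$contig_id)) > 1) stop("genes must lie on one contig")
  gap <- pmax(g$start[-1] - g$end[-n], 0L)
  linked <- g$strand[-1] == g$strand[-n] & gap <= max_gap
  run_id <- cumsum(c(TRUE, !linked))
  out <- empty
  idx <- 0L
  for (r in split(seq_len(n), run_id)) {
    if (length(r) < 2) next
    idx <- idx + 1L
    row <- data.frame(
      operon_id = sprintf("%s:%s:%d", genome_id, g$contig_id[r[1]], idx),
      contig_id = g$contig_id[r[1]],
      start = min(g$start[r]), end = max(g$end[r]),
      strand = g$strand[r[1]], n_genes = length(r), stringsAsFactors = FALSE)
    row$gene_ids <- list(g$gene_id[r])
    out <- rbind(out, row)
  }
  out
}

persist_operons <- function(store, genome_id, operons) {
  t <- store$tables
  old <- t$operons$operon_id[t$operons$genome_id == genome_id]
  t$operons <- t$operons[!t$operons$operon_id %in% old, ]
  t$operon_genes <- t$operon_genes[!t$operon_genes$operon_id %in% old, ]
  if (nrow(operons)) {
    t$operons <- rbind(t$operons, data.frame(
      operon_id = operons$operon_id, genome_id = genome_id,
      contig_id = operons$contig_id, start = operons$start,
      end = operons$end, strand = operons$strand, stringsAsFactors = FALSE))
    for (i in seq_len(nrow(operons))) {
      ids <- operons$gene_ids[[i]]
      t$operon_genes <- rbind(t$operon_genes, data.frame(
        operon_id = operons$operon_id[i], gene_id = ids,
        pos = seq_along(ids), stringsAsFactors = FALSE))
    }
  }
  store_commit(store, t)
  nrow(operons)
}

#' Predict and store operons for a genome
#'
#' Runs [call_operons()] on every contig of the genome and persists the
#' result, replacing any previously stored operons of that genome.
#'
#' @param store a `gk_store` handle.
#' @param genome_id genome to process.
#' @param max_gap maximum intergenic distance in bp.
#' @return number of operons stored.
#' @export
predict_operons <- function(store, genome_id, max_gap = 150L) {
  t <- store$tables
  if (!genome_id %in% t$genomes$genome_id) stop("not found: genome ", genome_id)
  all_ops <- list()
  for (cid in sort_c(unique(t$genes$contig_id[t$genes$genome_id == genome_id]))) {
    g <- t$genes[t$genes$genome_id == genome_id & t$genes$contig_id == cid, ]
    g <- g[order_c(g$start, g$locus_tag), ]
    all_ops[[length(all_ops) + 1L]] <- call_operons(g, max_gap, genome_id)
  }
  ops <- do.call(rbind, all_ops)
  # re-number across contigs for unique ids
  if (nrow(ops)) ops$operon_id <- sprintf("%s:%s:%d", genome_id,
                                          ops$contig_id, seq_len(nrow(ops)))
  persist_operons(store, genome_id, ops)
}

#' Import operons from an external predictor tool
#'
#' Renders and runs the tool's command (see [register_tool()]); the tool must
#' emit a TSV with columns `operon_name`, `genome`, `contig`, `locus_tags`
#' (comma-separated). Rows with unknown locus tags or fewer than two members
#' are skipped with a report; stored operons for the genome are replaced, not
#' merged. On tool failure the store is unchanged.
#'
#' @param store a `gk_store` handle.
#' @param tool tool configuration.
#' @param genome_id genome to process.
#' @param workdir scratch directory.
#' @param no_env run without environment activation prefix.
#' @return number of operons imported; attribute `"skipped"` lists rejected
#'   rows.
#' @export
run_operon_plugin <- function(store, tool, genome_id,
                              workdir = tempfile("operons"), no_env = TRUE) {
  t <- store$tables
  if (!genome_id %in% t$genomes$genome_id) stop("not found: genome ", genome_id)
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  paths <- export_tracks(store, genome_id, workdir)
  out_tsv <- file.path(workdir, "operons.tsv")
  status <- run_tool_command(tool, list(input_fna = paths[["fna"]],
                                        input_gff = paths[["gff3"]],
                                        input_faa = paths[["faa"]],
                                        output_tsv = out_tsv, workdir = workdir),
                             log = file.path(workdir, "operons.log"),
                             no_env = no_env)
  if (status != 0 || !file.exists(out_tsv))
    stop("operon tool failed (exit ", status, "); store unchanged")
  df <- read_tsv_chr(out_tsv)
  need <- c("operon_name", "genome", "contig", "locus_tags")
  if (is.null(df)) df <- data.frame(operon_name = character(),
                                    genome = character(), contig = character(),
                                    locus_tags = character())
  if (!all(need %in% names(df))) stop("operon TSV missing columns; store unchanged")
  skipped <- character(0)
  ops <- list()
  g <- t$genes[t$genes$genome_id == genome_id, ]
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (r$genome != genome_id) {
      skipped <- c(skipped, sprintf("row %d: genome mismatch", i)); next
    }
    tags <- trimws(strsplit(r$locus_tags, ",", fixed = TRUE)[[1]])
    mem <- g[g$locus_tag %in% tags & g$contig_id == r$contig, ]
    if (length(tags) < 2 || nrow(mem) != length(tags)) {
      skipped <- c(skipped, sprintf("row %d: needs >=2 known locus tags", i)); next
    }
    if (length(unique(mem$strand)) != 1) {
      skipped <- c(skipped, sprintf("row %d: mixed strands", i)); next
    }
    mem <- mem[order_c(mem$start), ]
    row <- data.frame(operon_id = sprintf("%s:%s:%d", genome_id, r$contig,
                                          length(ops) + 1L),
                      contig_id = r$contig, start = min(mem$start),
                      end = max(mem$end), strand = mem$strand[1],
                      n_genes = nrow(mem), stringsAsFactors = FALSE)
    row$gene_ids <- list(mem$gene_id)
    ops[[length(ops) + 1L]] <- row
  }
  ops <- if (length(ops)) do.call(rbind, ops) else call_operons(
    data.frame(gene_id = character(), contig_id = character(),
               start = integer(), end = integer(), strand = integer(),
               feature_type = character()), genome_id = genome_id)
  n <- persist_operons(store, genome_id, ops)
  attr(n, "skipped") <- skipped
  n
}
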