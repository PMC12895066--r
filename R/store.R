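STORE_MAGIC <- "genomekeeper-store"
STORE_SCHEMA_VERSION <- 1L

empty_tables <- function() {
  list(
    genomes = data.frame(genome_id = character(), strain_id = character(),
                         sample_id = character(), taxon_id = character(),
                         source_file = character(), stringsAsFactors = FALSE),
    contigs = data.frame(genome_id = character(), contig_id = character(),
                         length = integer(), sequence = character(),
                         stringsAsFactors = FALSE),
    genes = data.frame(gene_id = character(), genome_id = character(),
                       contig_id = character(), locus_tag = character(),
                       start = integer(), end = integer(), strand = integer(),
                       feature_type = character(), name = character(),
                       function_text = character(), protein_hash = character(),
                       stringsAsFactors = FALSE),
    proteins = data.frame(protein_hash = character(), sequence = character(),
                          length = integer(), stringsAsFactors = FALSE),
    strains = data.frame(strain_id = character(), name = character(),
                         taxon_id = character(), stringsAsFactors = FALSE),
    samples = data.frame(sample_id = character(), name = character(),
                         description = character(), stringsAsFactors = FALSE),
    metadata = data.frame(kind = character(), entity_id = character(),
                          key = character(), source = character(),
                          value = character(), stringsAsFactors = FALSE),
    taxa = data.frame(taxon_id = c("1", "0"),
                      name = c("root", "unclassified"),
                      rank = c("no rank", "no rank"),
                      parent_id = c("", "1"), stringsAsFactors = FALSE),
    operons = data.frame(operon_id = character(), genome_id = character(),
                         contig_id = character(), start = integer(),
                         end = integer(), strand = integer(),
                         stringsAsFactors = FALSE),
    operon_genes = data.frame(operon_id = character(), gene_id = character(),
                              pos = integer(), stringsAsFactors = FALSE),
    regulons = data.frame(regulon_id = character(), name = character(),
                          genome_id = character(),
                          regulator_gene_id = character(),
                          stringsAsFactors = FALSE),
    regulon_targets = data.frame(regulon_id = character(),
                                 gene_id = character(),
                                 stringsAsFactors = FALSE),
    sites = data.frame(site_id = character(), regulon_id = character(),
                       genome_id = character(), contig_id = character(),
                       start = integer(), end = integer(), strand = integer(),
                       sequence = character(), stringsAsFactors = FALSE),
    og_groups = data.frame(og_id = character(), level = character(),
                           description = character(), stringsAsFactors = FALSE),
    og_members = data.frame(protein_hash = character(), og_id = character(),
                            level = character(), stringsAsFactors = FALSE),
    labels = data.frame(scheme = character(), value = character(),
                        description = character(), stringsAsFactors = FALSE),
    protein_labels = data.frame(protein_hash = character(), scheme = character(),
                                value = character(), stringsAsFactors = FALSE),
    unassigned = data.frame(protein_hash = character(), stringsAsFactors = FALSE),
    annotations = data.frame(gene_id = character(), source = character(),
                             key = character(), value = character(),
                             note = character(), stringsAsFactors = FALSE),
    tools = data.frame(name = character(), env_name = character(),
                       command_template = character(), params = character(),
                       enabled = logical(), stringsAsFactors = FALSE),
    jobs = data.frame(job_id = character(), tool = character(),
                      genome_id = character(), status = character(),
                      log_path = character(), n_imported = integer(),
                      stringsAsFactors = FALSE)
  )
}

#' Open or create a genome collection store
#'
#' The store is a single file holding all entities of a genome collection:
#' genomes, contigs, genes, deduplicated proteins, taxonomy, strains, samples,
#' metadata, operons, regulons, binding sites, ortholog-group assignments,
#' functional labels, gene annotations, tool configurations and job records.
#' Every mutating operation is atomic per call: the updated store is written
#' to a temporary file and renamed over the old one, so a failure mid-call
#' leaves the previous state intact.
#'
#' @param path path of the store file.
#' @param create if `TRUE`, create a fresh empty store at `path`.
#' @return a `gk_store` handle.
#' @examples
#' st <- open_store(tempfile(), create = TRUE)
#' store_counts(st)["genomes"]
#' @export
open_store <- function(path, create = FALSE) {
  if (create) {
    h <- new.env(parent = emptyenv())
    h$path <- path
    h$schema_version <- STORE_SCHEMA_VERSION
    h$tables <- empty_tables()
    class(h) <- "gk_store"
    store_save(h)
    return(h)
  }
  if (!file.exists(path)) stop("invalid store: file does not exist: ", path)
  obj <- tryCatch(readRDS(path), error = function(e) NULL)
  if (is.null(obj) || !is.list(obj) || !identical(obj$magic, STORE_MAGIC))
    stop("invalid store: ", path)
  if (obj$schema_version > STORE_SCHEMA_VERSION)
    stop("unsupported schema: store has schema_version ", obj$schema_version,
         ", this build supports up to ", STORE_SCHEMA_VERSION)
  h <- new.env(parent = emptyenv())
  h$path <- path
  h$schema_version <- obj$schema_version
  h$tables <- obj$tables
  class(h) <- "gk_store"
  h
}

store_save <- function(store) {
  tmp <- paste0(store$path, ".tmp")
  saveRDS(list(magic = STORE_MAGIC, schema_version = store$schema_version,
               tables = store$tables), tmp)
  if (!file.rename(tmp, store$path)) stop("failed to write store file")
  invisible(store)
}

# commit a modified table list atomically (all-or-nothing per operation)
store_commit <- function(store, tables) {
  old <- store$tables
  store$tables <- tables
  ok <- FALSE
  tryCatch({ store_save(store); ok <- TRUE },
           finally = if (!ok) store$tables <- old)
  invisible(store)
}

#' @export
print.gk_store <- function(x, ...) {
  n <- store_counts(x)
  cat("<genome collection store> ", x$path, "\n", sep = "")
  cat(sprintf("  genomes: %d  genes: %d  proteins: %d  operons: %d\n",
              n[["genomes"]], n[["genes"]], n[["proteins"]], n[["operons"]]))
  invisible(x)
}

#' Entity counts of a store
#'
#' @param store a `gk_store` handle.
#' @return named integer vector of row counts per entity table.
#' @export
store_counts <- function(store) {
  vapply(store$tables, nrow, integer(1))
}

#' Add a strain entry
#'
#' @param store a `gk_store` handle.
#' @param strain_id unique strain identifier.
#' @param name display name (defaults to `strain_id`).
#' @param taxon_id taxon of the strain (default `"0"`, unclassified).
#' @return the store, invisibly.
#' @export
add_strain <- function(store, strain_id, name = strain_id, taxon_id = "0") {
  t <- store$tables
  if (strain_id %in% t$strains$strain_id) stop("strain_id already exists: ", strain_id)
  t$strains <- rbind(t$strains, data.frame(strain_id = strain_id, name = name,
                                           taxon_id = taxon_id,
                                           stringsAsFactors = FALSE))
  store_commit(store, t)
}

#' Add a sample entry
#'
#' @param store a `gk_store` handle.
#' @param sample_id unique sample identifier.
#' @param name display name.
#' @param description free-text description.
#' @return the store, invisibly.
#' @export
add_sample <- function(store, sample_id, name = sample_id, description = "") {
  t <- store$tables
  if (sample_id %in% t$samples$sample_id) stop("sample_id already exists: ", sample_id)
  t$samples <- rbind(t$samples, data.frame(sample_id = sample_id, name = name,
                                           description = description,
                                           stringsAsFactors = FALSE))
  store_commit(store, t)
}

#' Load a taxonomy table into the store
#'
#' Accepts a tab-separated file with columns `taxon_id`, `name`, `rank`,
#' `parent_id` (NCBI-style numeric identifiers as text; full NCBI dumps
#' re-formatted this way are accepted but never required). Parent chains must
#' terminate at the root node "1".
#'
#' @param store a `gk_store` handle.
#' @param tsv path to the taxonomy TSV.
#' @return number of taxa loaded, invisibly.
#' @export
load_taxonomy <- function(store, tsv) {
  df <- read_tsv_chr(tsv)
  need <- c("taxon_id", "name", "rank", "parent_id")
  if (is.null(df) || !all(need %in% names(df)))
    stop("taxonomy TSV must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  t <- store$tables
  df <- df[!df$taxon_id %in% t$taxa$taxon_id, , drop = FALSE]
  if (anyDuplicated(df$taxon_id)) stop("duplicate taxon_id in taxonomy TSV")
  t$taxa <- rbind(t$taxa, df)
  # validate parent chains: every parent exists, chains terminate at root
  pmap <- stats::setNames(t$taxa$parent_id, t$taxa$taxon_id)
  for (id in df$taxon_id) {
    seen <- character(0)
    cur <- id
    while (cur != "1" && cur != "") {
      if (cur %in% seen) stop("taxonomy cycle at taxon ", id)
      seen <- c(seen, cur)
      if (!cur %in% names(pmap)) stop("taxon ", id, " has missing ancestor ", cur)
      cur <- pmap[[cur]]
    }
  }
  store_commit(store, t)
  invisible(nrow(df))
}

# lineage taxon_ids from a taxon up to (excluding) root ""
taxon_lineage <- function(store, taxon_id) {
  pmap <- stats::setNames(store$tables$taxa$parent_id, store$tables$taxa$taxon_id)
  out <- character(0)
  cur <- taxon_id
  while (!is.na(cur) && nzchar(cur) && cur %in% names(pmap)) {
    out <- c(out, cur)
    if (cur == "1") break
    cur <- pmap[[cur]]
  }
  rev(out)
}

#' Bulk-import strain or sample metadata
#'
#' Reads a tab-separated file with columns `entity_name`, `key`, `source`,
#' `value` and attaches (key, source, value) triples to matching strains or
#' samples. Rows naming unknown entities or with malformed content are
#' collected in the skipped report; valid rows are still imported unless all
#' rows are bad.
#'
#' @param store a `gk_store` handle.
#' @param kind `"strain"` or `"sample"`.
#' @param tsv path to the metadata TSV (UTF-8, header required, `#` comments
#'   ignored).
#' @return number of rows imported; attribute `"skipped"` holds a character
#'   vector describing rows that were not imported.
#' @export
bulk_import_metadata <- function(store, kind = c("strain", "sample"), tsv) {
  kind <- match.arg(kind)
  df <- read_tsv_chr(tsv)
  if (is.null(df)) {
    res <- 0L
    attr(res, "skipped") <- character(0)
    return(res)
  }
  need <- c("entity_name", "key", "source", "value")
  if (!all(need %in% names(df)))
    stop("metadata TSV must have columns: ", paste(need, collapse = ", "))
  t <- store$tables
  known <- if (kind == "strain") {
    stats::setNames(t$strains$strain_id, t$strains$name)
  } else {
    stats::setNames(t$samples$sample_id, t$samples$name)
  }
  # entity ids are also accepted as names
  known <- c(known, stats::setNames(unname(known), unname(known)))
  skipped <- character(0)
  rows <- list()
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (!nzchar(r$key)) {
      skipped <- c(skipped, sprintf("row %d: empty metadata key", i))
    } else if (!r$entity_name %in% names(known)) {
      skipped <- c(skipped, sprintf("row %d: unknown %s '%s'", i, kind, r$entity_name))
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        kind = kind, entity_id = unname(known[[r$entity_name]]),
        key = r$key, source = r$source, value = r$value,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows) && nrow(df) > 0)
    stop("all rows failed: ", paste(skipped, collapse = "; "))
  if (length(rows)) {
    t$metadata <- rbind(t$metadata, do.call(rbind, rows))
    store_commit(store, t)
  }
  res <- length(rows)
  attr(res, "skipped") <- skipped
  res
}

#' Bulk-import regulons
#'
#' Reads a tab-separated file with columns `regulon_name`, `genome`,
#' `regulator_locus_tag`, `target_locus_tag`, `site_contig`, `site_start`,
#' `site_end`, `site_strand`, `site_sequence` (the site columns may be empty
#' per row). Rows sharing (regulon_name, genome) accumulate into one regulon;
#' rows naming unknown genomes or locus tags are skipped with a report.
#'
#' @param store a `gk_store` handle.
#' @param tsv path to the regulon TSV.
#' @return number of rows imported; attribute `"skipped"` lists skipped rows.
#' @export
bulk_import_regulons <- function(store, tsv) {
  df <- read_tsv_chr(tsv)
  need <- c("regulon_name", "genome", "regulator_locus_tag", "target_locus_tag")
  if (is.null(df) || !all(need %in% names(df)))
    stop("regulon TSV must have columns: ", paste(need, collapse = ", "))
  site_cols <- c("site_contig", "site_start", "site_end", "site_strand",
                 "site_sequence")
  for (sc in site_cols) if (!sc %in% names(df)) df[[sc]] <- ""
  t <- store$tables
  skipped <- character(0)
  n_ok <- 0L
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (!r$genome %in% t$genomes$genome_id) {
      skipped <- c(skipped, sprintf("row %d: unknown genome '%s'", i, r$genome))
      next
    }
    gsel <- t$genes[t$genes$genome_id == r$genome, ]
    tgt <- gsel$gene_id[gsel$locus_tag == r$target_locus_tag]
    if (!length(tgt)) {
      skipped <- c(skipped, sprintf("row %d: unknown locus_tag '%s' in genome '%s'",
                                    i, r$target_locus_tag, r$genome))
      next
    }
    reg_gene <- NA_character_
    if (nzchar(r$regulator_locus_tag)) {
      rg <- gsel$gene_id[gsel$locus_tag == r$regulator_locus_tag]
      if (!length(rg)) {
        skipped <- c(skipped, sprintf("row %d: unknown regulator locus_tag '%s'",
                                      i, r$regulator_locus_tag))
        next
      }
      reg_gene <- rg[1]
    }
    rid <- paste0(r$regulon_name, ":", r$genome)
    if (!rid %in% t$regulons$regulon_id) {
      t$regulons <- rbind(t$regulons, data.frame(
        regulon_id = rid, name = r$regulon_name, genome_id = r$genome,
        regulator_gene_id = reg_gene, stringsAsFactors = FALSE))
    } else if (!is.na(reg_gene)) {
      t$regulons$regulator_gene_id[t$regulons$regulon_id == rid] <- reg_gene
    }
    if (!tgt[1] %in% t$regulon_targets$gene_id[t$regulon_targets$regulon_id == rid]) {
      t$regulon_targets <- rbind(t$regulon_targets, data.frame(
        regulon_id = rid, gene_id = tgt[1], stringsAsFactors = FALSE))
    }
    if (nzchar(r$site_contig)) {
      st <- suppressWarnings(as.integer(r$site_start))
      en <- suppressWarnings(as.integer(r$site_end))
      csel <- t$contigs[t$contigs$genome_id == r$genome &
                          t$contigs$contig_id == r$site_contig, ]
      if (!nrow(csel) || is.na(st) || is.na(en) || st < 0 || st >= en ||
          en > csel$length[1] || nchar(r$site_sequence) != en - st) {
        skipped <- c(skipped, sprintf("row %d: invalid site definition", i))
        next
      }
      sid <- sprintf("%s:site%03d", rid,
                     sum(t$sites$regulon_id == rid) + 1L)
      t$sites <- rbind(t$sites, data.frame(
        site_id = sid, regulon_id = rid, genome_id = r$genome,
        contig_id = r$site_contig, start = st, end = en,
        strand = as.integer(r$site_strand), sequence = r$site_sequence,
        stringsAsFactors = FALSE))
    }
    n_ok <- n_ok + 1L
  }
  if (n_ok > 0) store_commit(store, t)
  res <- n_ok
  attr(res, "skipped") <- skipped
  res
}

#' Taxonomic sunburst of the genome collection
#'
#' Builds the hierarchical node tree behind a sunburst overview of the
#' collection: each node carries its taxon name, rank and the number of
#' genomes in its subtree. Genomes without a resolvable taxon are grouped
#' under an "unclassified" node attached to the root.
#'
#' @param store a `gk_store` handle.
#' @return nested list: `name`, `rank`, `taxon_id`, `count`, `children`.
#' @export
taxonomy_sunburst <- function(store) {
  t <- store$tables
  tax_ids <- t$genomes$taxon_id
  tax_ids[is.na(tax_ids) | !nzchar(tax_ids) |
            !tax_ids %in% t$taxa$taxon_id] <- "0"
  # per-taxon subtree genome counts via lineage tally
  counts <- new.env(parent = emptyenv())
  bump <- function(id) assign(id, (get0(id, envir = counts) %||% 0L) + 1L,
                              envir = counts)
  for (id in tax_ids) {
    lin <- taxon_lineage(store, id)
    if (!length(lin)) lin <- c("1", "0")
    for (a in lin) bump(a)
    if (!"1" %in% lin) bump("1")
  }
  kids <- split(t$taxa$taxon_id, t$taxa$parent_id)
  build <- function(id) {
    row <- t$taxa[t$taxa$taxon_id == id, ]
    ch <- sort_c(kids[[id]] %||% character(0))
    ch <- ch[vapply(ch, function(c) (get0(c, envir = counts) %||% 0L) > 0L,
                    logical(1))]
    list(name = row$name, rank = row$rank, taxon_id = id,
         count = get0(id, envir = counts) %||% 0L,
         children = lapply(ch, build))
  }
  root <- build("1")
  root$count <- length(tax_ids)
  root
}

#' Delete a genome and everything that belongs to it
#'
#' Removes the genome with its contigs, genes, operons, regulons, sites and
#' annotations. Protein records still referenced by genes of other genomes
#' are retained; orphaned protein records are removed together with their
#' ortholog-group memberships and labels.
#'
#' @param store a `gk_store` handle.
#' @param genome_id genome to delete.
#' @return named integer vector of removed entity counts.
#' @export
delete_genome <- function(store, genome_id) {
  t <- store$tables
  if (!genome_id %in% t$genomes$genome_id) stop("not found: genome ", genome_id)
  report <- c(genomes = 0L, contigs = 0L, genes = 0L, proteins = 0L,
              operons = 0L, regulons = 0L, sites = 0L, annotations = 0L)
  gsel <- t$genes$genome_id == genome_id
  gone_genes <- t$genes$gene_id[gsel]
  report["genes"] <- sum(gsel)
  report["contigs"] <- sum(t$contigs$genome_id == genome_id)
  report["genomes"] <- 1L
  ops <- t$operons$operon_id[t$operons$genome_id == genome_id]
  report["operons"] <- length(ops)
  regs <- t$regulons$regulon_id[t$regulons$genome_id == genome_id]
  report["regulons"] <- length(regs)
  report["sites"] <- sum(t$sites$genome_id == genome_id)
  report["annotations"] <- sum(t$annotations$gene_id %in% gone_genes)

  t$genes <- t$genes[!gsel, ]
  t$contigs <- t$contigs[t$contigs$genome_id != genome_id, ]
  t$genomes <- t$genomes[t$genomes$genome_id != genome_id, ]
  t$operons <- t$operons[!t$operons$operon_id %in% ops, ]
  t$operon_genes <- t$operon_genes[!t$operon_genes$operon_id %in% ops, ]
  t$regulons <- t$regulons[!t$regulons$regulon_id %in% regs, ]
  t$regulon_targets <- t$regulon_targets[!t$regulon_targets$regulon_id %in% regs, ]
  t$sites <- t$sites[t$sites$genome_id != genome_id, ]
  t$annotations <- t$annotations[!t$annotations$gene_id %in% gone_genes, ]

  live <- unique(t$genes$protein_hash[!is.na(t$genes$protein_hash)])
  orphan <- t$proteins$protein_hash[!t$proteins$protein_hash %in% live]
  report["proteins"] <- length(orphan)
  t$proteins <- t$proteins[!t$proteins$protein_hash %in% orphan, ]
  t$og_members <- t$og_members[!t$og_members$protein_hash %in% orphan, ]
  t$protein_labels <- t$protein_labels[!t$protein_labels$protein_hash %in% orphan, ]
  t$unassigned <- t$unassigned[!t$unassigned$protein_hash %in% orphan, , drop = FALSE]
  store_commit(store, t)
  report
}

#' Audit referential integrity of a store
#'
#' Checks that every gene references an existing contig within bounds, every
#' CDS protein hash has a protein record, operon and regulon members exist
#' and satisfy the operon invariants (same contig and strand, >= 2 genes,
#' span = member span), sites lie within their contigs with sequence length
#' equal to their span, and every persisted protein label exists in the label
#' table.
#'
#' @param store a `gk_store` handle.
#' @return character vector of problems; empty when the store is consistent.
#' @export
store_audit <- function(store) {
  t <- store$tables
  bad <- character(0)
  ckey <- paste(t$contigs$genome_id, t$contigs$contig_id)
  gkey <- paste(t$genes$genome_id, t$genes$contig_id)
  miss <- !gkey %in% ckey
  if (any(miss)) bad <- c(bad, sprintf("gene %s references missing contig",
                                       t$genes$gene_id[miss]))
  clen <- stats::setNames(t$contigs$length, ckey)
  inb <- !miss & (t$genes$start < 0 | t$genes$start >= t$genes$end |
                    t$genes$end > clen[gkey])
  if (any(inb)) bad <- c(bad, sprintf("gene %s out of contig bounds",
                                      t$genes$gene_id[inb]))
  cds <- t$genes[t$genes$feature_type == "CDS" & !is.na(t$genes$protein_hash), ]
  mp <- !cds$protein_hash %in% t$proteins$protein_hash
  if (any(mp)) bad <- c(bad, sprintf("gene %s references missing protein",
                                     cds$gene_id[mp]))
  for (oid in t$operons$operon_id) {
    o <- t$operons[t$operons$operon_id == oid, ]
    mem <- t$operon_genes$gene_id[t$operon_genes$operon_id == oid]
    g <- t$genes[t$genes$gene_id %in% mem, ]
    if (length(mem) < 2) bad <- c(bad, sprintf("operon %s has < 2 genes", oid))
    if (nrow(g) != length(mem))
      bad <- c(bad, sprintf("operon %s references missing genes", oid))
    else {
      if (any(g$contig_id != o$contig_id) || any(g$strand != o$strand))
        bad <- c(bad, sprintf("operon %s members off-contig or off-strand", oid))
      if (nrow(g) && (min(g$start) != o$start || max(g$end) != o$end))
        bad <- c(bad, sprintf("operon %s span mismatch", oid))
    }
  }
  mt <- !t$regulon_targets$gene_id %in% t$genes$gene_id
  if (any(mt)) bad <- c(bad, sprintf("regulon %s references missing gene",
                                     t$regulon_targets$regulon_id[mt]))
  for (i in seq_len(nrow(t$sites))) {
    s <- t$sites[i, ]
    cl <- clen[paste(s$genome_id, s$contig_id)]
    if (is.na(cl) || s$start < 0 || s$start >= s$end || s$end > cl ||
        nchar(s$sequence) != s$end - s$start)
      bad <- c(bad, sprintf("site %s invalid", s$site_id))
  }
  lk <- paste(t$protein_labels$scheme, t$protein_labels$value)
  ml <- !lk %in% paste(t$labels$scheme, t$labels$value)
  if (any(ml)) bad <- c(bad, sprintf("protein label %s missing from label table",
                                     lk[ml]))
  ao <- !t$annotations$gene_id %in% t$genes$gene_id
  if (any(ao)) bad <- c(bad, "annotation references missing gene")
  bad
}
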