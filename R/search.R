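# Text search over annotations and an internal seed-and-extend sequence
# search over stored contigs and proteins. The sequence search finds exact
# k-mer seeds (nucleotide k = 11, both strands; protein k = 4), extends them
# ungapped in both directions until the running score drops 20 below its
# maximum, merges overlapping hits on the same diagonal, and reports raw
# score and percent identity (no E-value statistics).

CLASS_FIELDS <- c(KEGG_ortholog = "KEGG_ortholog", KEGG_pathway = "KEGG_pathway",
                  GO = "GO", EC = "EC")

#' Search genes by name, function or classification
#'
#' Name and function fields use case-insensitive substring matching;
#' classification fields (`KEGG_ortholog`, `KEGG_pathway`, `GO`, `EC`) use
#' exact identifier matching so that "K1" never matches "K12345". `field =
#' "any"` unions all fields. Gene annotations imported from tools are
#' searched as part of the function field.
#'
#' @param store a `gk_store` handle.
#' @param query non-empty query string.
#' @param scope `"all"` or a genome id to restrict the search.
#' @param field one of `"name"`, `"function"`, `"KEGG_ortholog"`,
#'   `"KEGG_pathway"`, `"GO"`, `"EC"`, `"any"`.
#' @return data frame of gene summaries sorted by (genome_id, contig_id,
#'   start).
#' @export
search_genes <- function(store, query, scope = "all",
                         field = c("any", "name", "function", "KEGG_ortholog",
                                   "KEGG_pathway", "GO", "EC")) {
  field <- match.arg(field)
  if (!nzchar(query)) stop("empty query")
  t <- store$tables
  g <- t$genes
  if (!identical(scope, "all")) {
    if (!scope %in% t$genomes$genome_id) stop("not found: genome ", scope)
    g <- g[g$genome_id == scope, ]
  }
  subs <- function(x) !is.na(x) & grepl(tolower(query), tolower(x), fixed = TRUE)
  keep <- rep(FALSE, nrow(g))
  if (field %in% c("name", "any")) keep <- keep | subs(g$name)
  if (field %in% c("function", "any")) {
    keep <- keep | subs(g$function_text)
    ann <- t$annotations[subs(t$annotations$value) | subs(t$annotations$key), ]
    keep <- keep | g$gene_id %in% ann$gene_id
  }
  if (field %in% names(CLASS_FIELDS) || field == "any") {
    schemes <- if (field == "any") unname(CLASS_FIELDS) else field
    pl <- t$protein_labels[t$protein_labels$scheme %in% schemes &
                             t$protein_labels$value == query, ]
    keep <- keep | (!is.na(g$protein_hash) & g$protein_hash %in% pl$protein_hash)
  }
  res <- g[keep, c("gene_id", "genome_id", "contig_id", "locus_tag", "start",
                   "end", "strand", "feature_type", "name", "function_text")]
  res <- res[order_c(res$genome_id, res$contig_id, res$start), ]
  rownames(res) <- NULL
  res
}

#' Search genomes and strains
#'
#' Substring search (case-insensitive) across genome names, strain names,
#' taxonomy lineage names, and strain metadata values; each result states
#' which field matched.
#'
#' @param store a `gk_store` handle.
#' @param query query string.
#' @return data frame with `genome_id`, `matched_field`, `matched_value`.
#' @export
search_genomes <- function(store, query) {
  t <- store$tables
  hit <- function(x) !is.na(x) & grepl(tolower(query), tolower(x), fixed = TRUE)
  res <- list()
  add <- function(gid, field, value)
    res[[length(res) + 1L]] <<- data.frame(genome_id = gid,
                                           matched_field = field,
                                           matched_value = value,
                                           stringsAsFactors = FALSE)
  tax_names <- stats::setNames(t$taxa$name, t$taxa$taxon_id)
  for (i in seq_len(nrow(t$genomes))) {
    gm <- t$genomes[i, ]
    if (hit(gm$genome_id)) add(gm$genome_id, "genome_name", gm$genome_id)
    if (!is.na(gm$strain_id)) {
      sn <- t$strains$name[t$strains$strain_id == gm$strain_id]
      if (length(sn) && hit(sn)) add(gm$genome_id, "strain_name", sn)
      md <- t$metadata[t$metadata$kind == "strain" &
                         t$metadata$entity_id == gm$strain_id, ]
      mv <- md$value[hit(md$value)]
      if (length(mv)) add(gm$genome_id, "metadata", mv[1])
    }
    lin <- taxon_lineage(store, gm$taxon_id)
    ln <- tax_names[lin]
    ln <- ln[hit(ln)]
    if (length(ln)) add(gm$genome_id, "taxonomy", unname(ln[length(ln)]))
  }
  out <- if (length(res)) unique(do.call(rbind, res)) else
    data.frame(genome_id = character(), matched_field = character(),
               matched_value = character(), stringsAsFactors = FALSE)
  out <- out[order_c(out$genome_id, out$matched_field), ]
  rownames(out) <- NULL
  out
}

#' List genes of a KEGG pathway in a genome
#'
#' Groups the genome's genes labeled with the pathway by their KEGG ortholog
#' labels.
#'
#' @param store a `gk_store` handle.
#' @param genome_id genome of interest.
#' @param pathway_id KEGG pathway identifier (exact match).
#' @return data frame (`kegg_ortholog`, `gene_id`, `locus_tag`); genes in a
#'   pathway without a KEGG-ortholog label appear with `kegg_ortholog = NA`.
#' @export
list_pathway_genes <- function(store, genome_id, pathway_id) {
  t <- store$tables
  if (!genome_id %in% t$genomes$genome_id) stop("not found: genome ", genome_id)
  g <- t$genes[t$genes$genome_id == genome_id & !is.na(t$genes$protein_hash), ]
  pw <- t$protein_labels[t$protein_labels$scheme == "KEGG_pathway" &
                           t$protein_labels$value == pathway_id, ]
  g <- g[g$protein_hash %in% pw$protein_hash, ]
  ko <- t$protein_labels[t$protein_labels$scheme == "KEGG_ortholog", ]
  res <- list()
  for (i in seq_len(nrow(g))) {
    kos <- ko$value[ko$protein_hash == g$protein_hash[i]]
    if (!length(kos)) kos <- NA_character_
    res[[length(res) + 1L]] <- data.frame(
      kegg_ortholog = kos, gene_id = g$gene_id[i], locus_tag = g$locus_tag[i],
      stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(kegg_ortholog = character(), gene_id = character(),
               locus_tag = character(), stringsAsFactors = FALSE)
  out <- out[order_c(out$kegg_ortholog, out$gene_id), ]
  rownames(out) <- NULL
  out
}

# ---- seed-and-extend sequence search --------------------------------------

nt_score <- function(a, b) ifelse(a == b & a != "N", 1L, -2L)

# ungapped X-drop extension over precomputed per-position scores
extend_hit <- function(qc, sc, qpos, spos, score_vec_fun, xdrop) {
  ql <- length(qc); sl <- length(sc)
  # rightward from the seed start (inclusive)
  len_r <- min(ql - qpos + 1L, sl - spos + 1L)
  sr <- score_vec_fun(qc[qpos:(qpos + len_r - 1L)], sc[spos:(spos + len_r - 1L)])
  cum <- cumsum(sr)
  best <- cummax(cum)
  stop_at <- which(best - cum > xdrop)[1]
  lim <- if (is.na(stop_at)) len_r else stop_at - 1L
  r_ext <- which.max(cum[seq_len(lim)])
  r_score <- cum[r_ext]
  # leftward from just before the seed
  l_ext <- 0L; l_score <- 0
  len_l <- min(qpos - 1L, spos - 1L)
  if (len_l > 0) {
    sl_v <- score_vec_fun(qc[(qpos - 1L):(qpos - len_l)],
                          sc[(spos - 1L):(spos - len_l)])
    cum <- cumsum(sl_v)
    best <- cummax(cum)
    stop_at <- which(best - cum > xdrop)[1]
    lim <- if (is.na(stop_at)) len_l else stop_at - 1L
    if (lim > 0) {
      l_ext <- which.max(cum[seq_len(lim)])
      l_score <- cum[l_ext]
      if (l_score <= 0) { l_ext <- 0L; l_score <- 0 }
    }
  }
  q0 <- qpos - l_ext; q1 <- qpos + r_ext - 1L
  s0 <- spos - l_ext; s1 <- spos + r_ext - 1L
  matches <- sum(qc[q0:q1] == sc[s0:s1])
  list(query_start = q0 - 1L, query_end = q1, subject_start = s0 - 1L,
       subject_end = s1, score = l_score + r_score, matches = matches,
       length = q1 - q0 + 1L)
}

search_one_subject <- function(subject, query, k, score_vec_fun, xdrop) {
  qn <- nchar(query)
  if (qn < k) return(NULL)
  qc <- strsplit(query, "", fixed = TRUE)[[1]]
  sc <- strsplit(subject, "", fixed = TRUE)[[1]]
  seeds <- list()
  for (i in seq_len(qn - k + 1L)) {
    kmer <- substr(query, i, i + k - 1L)
    m <- gregexpr(kmer, subject, fixed = TRUE)[[1]]
    if (m[1] == -1) next
    for (p in as.integer(m)) seeds[[length(seeds) + 1L]] <- c(qpos = i, spos = p)
  }
  if (!length(seeds)) return(NULL)
  sd <- do.call(rbind, seeds)
  diag <- sd[, "spos"] - sd[, "qpos"]
  hits <- list()
  for (d in sort(unique(diag))) {
    grp <- sd[diag == d, , drop = FALSE]
    grp <- grp[order(grp[, "spos"]), , drop = FALSE]
    covered_end <- -1L
    for (r in seq_len(nrow(grp))) {
      if (grp[r, "spos"] <= covered_end) next
      h <- extend_hit(qc, sc, grp[r, "qpos"], grp[r, "spos"],
                      score_vec_fun, xdrop)
      covered_end <- h$subject_end
      hits[[length(hits) + 1L]] <- h
    }
  }
  hits
}

#' Seed-and-extend sequence search over the store
#'
#' Searches the query against stored contigs (`mode = "nucleotide"`, both
#' strands, seed k = 11, match +1 / mismatch -2) or stored protein sequences
#' (`mode = "protein"`, seed k = 4, BLOSUM62). Seeds are extended ungapped in
#' both directions with an X-drop of 20; hits below `min_identity_pct` are
#' dropped and results are ranked by score descending, ties by subject id.
#' Coordinates are 0-based half-open; reverse-strand nucleotide hits report
#' the forward-strand subject interval with `strand = -1`.
#'
#' @param store a `gk_store` handle.
#' @param query query sequence (alphabet must match the mode).
#' @param mode `"nucleotide"` or `"protein"`.
#' @param min_identity_pct minimum percent identity (default 80).
#' @param max_hits maximum hits returned (default 50).
#' @return data frame of hits: `subject_id`, `genome_id`, `subject_start`,
#'   `subject_end`, `query_start`, `query_end`, `strand`, `matches`,
#'   `length`, `identity_pct`, `score`.
#' @export
seq_search <- function(store, query, mode = c("nucleotide", "protein"),
                       min_identity_pct = 80, max_hits = 50) {
  mode <- match.arg(mode)
  query <- toupper(query)
  t <- store$tables
  if (mode == "nucleotide") {
    k <- 11L
    if (grepl("[^ACGTN]", query)) stop("alphabet mismatch: not a DNA sequence")
    score_fun <- nt_score
  } else {
    k <- 4L
    if (grepl("[^ACDEFGHIKLMNPQRSTVWYXBZUO*]", query))
      stop("alphabet mismatch: not a protein sequence")
    b62 <- get_blosum62()
    score_fun <- function(a, b) {
      a[!a %in% rownames(b62)] <- "X"; b[!b %in% rownames(b62)] <- "X"
      b62[cbind(a, b)]
    }
  }
  if (nchar(query) < k) stop("query shorter than seed length ", k)
  out <- list()
  add_hits <- function(hits, sid, gid, strand, qlen) {
    for (h in hits) {
      if (strand == -1L) {
        qs <- qlen - h$query_end; qe <- qlen - h$query_start
        h$query_start <- qs; h$query_end <- qe
      }
      out[[length(out) + 1L]] <<- data.frame(
        subject_id = sid, genome_id = gid, subject_start = h$subject_start,
        subject_end = h$subject_end, query_start = h$query_start,
        query_end = h$query_end, strand = strand, matches = h$matches,
        length = h$length, identity_pct = 100 * h$matches / h$length,
        score = h$score, stringsAsFactors = FALSE)
    }
  }
  if (mode == "nucleotide") {
    rcq <- rev_comp(query)
    for (i in seq_len(nrow(t$contigs))) {
      ctg <- t$contigs[i, ]
      sid <- paste0(ctg$genome_id, ":", ctg$contig_id)
      add_hits(search_one_subject(ctg$sequence, query, k, score_fun, 20L) %||% list(),
               sid, ctg$genome_id, 1L, nchar(query))
      add_hits(search_one_subject(ctg$sequence, rcq, k, score_fun, 20L) %||% list(),
               sid, ctg$genome_id, -1L, nchar(query))
    }
  } else {
    for (i in seq_len(nrow(t$proteins))) {
      pr <- t$proteins[i, ]
      add_hits(search_one_subject(pr$sequence, query, k, score_fun, 20L) %||% list(),
               pr$protein_hash, NA_character_, 0L, nchar(query))
    }
  }
  res <- if (length(out)) unique(do.call(rbind, out)) else
    data.frame(subject_id = character(), genome_id = character(),
               subject_start = integer(), subject_end = integer(),
               query_start = integer(), query_end = integer(),
               strand = integer(), matches = integer(), length = integer(),
               identity_pct = numeric(), score = numeric(),
               stringsAsFactors = FALSE)
  res <- res[res$identity_pct >= min_identity_pct, , drop = FALSE]
  res <- res[order_c(-res$score, res$subject_id, res$subject_start), , drop = FALSE]
  res <- utils::head(res, max_hits)
  rownames(res) <- NULL
  res
}
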