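# Ortholog-anchored comparative analysis. Similarity between family members
# is scored by global pairwise alignment (BLOSUM62, affine gaps: open 11,
# extend 1, so a gap of length L costs 11 + L) and converted to a normalized
# distance 1 - score / min(self_score(query), self_score(hit)), clamped to
# [0, 1]. Rows of a neighborhood view are ordered by a midpoint-rooted
# neighbor-joining guide tree over those distances.

align_score <- function(a, b) {
  mat <- get_blosum62()
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = mat, gapOpening = 11, gapExtension = 1,
    type = "global", scoreOnly = TRUE))
}

.blosum_cache <- new.env(parent = emptyenv())
get_blosum62 <- function() {
  if (is.null(.blosum_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum_cache$m <- e$BLOSUM62
  }
  .blosum_cache$m
}

norm_distance <- function(score, self_a, self_b) {
  d <- 1 - score / min(self_a, self_b)
  min(max(d, 0), 1)
}

# pick the OG level for an anchor: the most specific assignment, taken as the
# level whose group has the fewest member proteins store-wide (ties by level
# name, byte order)
pick_og_level <- function(store, anchor_ogs) {
  t <- store$tables
  sizes <- vapply(seq_len(nrow(anchor_ogs)), function(i) {
    sum(t$og_members$og_id == anchor_ogs$og_id[i] &
          t$og_members$level == anchor_ogs$level[i])
  }, integer(1))
  anchor_ogs[order_c(sizes, anchor_ogs$level)[1], ]
}

#' Rank proteins most similar to an anchor gene
#'
#' Candidates are all store proteins sharing the anchor's ortholog group at
#' the chosen taxonomic level (the anchor's most specific assignment by
#' default). Each candidate is scored by global alignment against the anchor
#' and ranked by score descending, ties broken by (genome_id, locus_tag);
#' the anchor itself is always rank 1. `max_n` must lie in [10, 200].
#'
#' @param store a `gk_store` handle.
#' @param anchor_gene gene id (`"genome_id:locus_tag"`).
#' @param max_n maximum number of hits returned, in \[10, 200\].
#' @param og_level taxonomic level of the ortholog group to use; `NULL`
#'   picks the anchor's most specific assignment.
#' @return data frame of hits (`gene_id`, `genome_id`, `locus_tag`,
#'   `protein_hash`, `score`, `normalized_distance`) with attributes
#'   `og_id`, `og_level`, `self_scores`.
#' @export
similar_proteins <- function(store, anchor_gene, max_n = 50, og_level = NULL) {
  if (max_n < 10 || max_n > 200) stop("max_n must be in [10, 200]")
  t <- store$tables
  a <- t$genes[t$genes$gene_id == anchor_gene, ]
  if (!nrow(a)) stop("not found: gene ", anchor_gene)
  if (a$feature_type != "CDS" || is.na(a$protein_hash))
    stop("no ortholog family: anchor is not a protein-coding gene")
  ogs <- t$og_members[t$og_members$protein_hash == a$protein_hash, ]
  if (!is.null(og_level)) ogs <- ogs[ogs$level == og_level, ]
  if (!nrow(ogs)) stop("no ortholog family: anchor protein has no OG assignment")
  og <- pick_og_level(store, ogs)
  fam_hashes <- t$og_members$protein_hash[t$og_members$og_id == og$og_id &
                                            t$og_members$level == og$level]
  cand <- t$genes[t$genes$feature_type == "CDS" &
                    !is.na(t$genes$protein_hash) &
                    t$genes$protein_hash %in% fam_hashes, ]
  seqs <- stats::setNames(
    t$proteins$sequence[match(unique(cand$protein_hash), t$proteins$protein_hash)],
    unique(cand$protein_hash))
  aseq <- seqs[[a$protein_hash]]
  self <- vapply(seqs, function(s) align_score(s, s), numeric(1))
  score_by_hash <- vapply(names(seqs), function(h) {
    if (h == a$protein_hash) self[[h]] else align_score(aseq, seqs[[h]])
  }, numeric(1))
  hits <- data.frame(gene_id = cand$gene_id, genome_id = cand$genome_id,
                     locus_tag = cand$locus_tag,
                     protein_hash = cand$protein_hash,
                     score = score_by_hash[cand$protein_hash],
                     stringsAsFactors = FALSE)
  hits$normalized_distance <- mapply(function(s, h)
    norm_distance(s, self[[a$protein_hash]], self[[h]]),
    hits$score, hits$protein_hash)
  is_anchor <- hits$gene_id == anchor_gene
  hits <- rbind(hits[is_anchor, ],
                hits[!is_anchor, ][order_c(-hits$score[!is_anchor],
                                           hits$genome_id[!is_anchor],
                                           hits$locus_tag[!is_anchor]), ])
  hits <- utils::head(hits, max_n)
  rownames(hits) <- NULL
  attr(hits, "og_id") <- og$og_id
  attr(hits, "og_level") <- og$level
  attr(hits, "self_scores") <- self
  hits
}

# ---- guide tree -----------------------------------------------------------

fmt_len <- function(x) sprintf("%.6g", max(x, 0))

# deterministic ladderized newick from a rooted ape tree: children ordered by
# (subtree leaf count, smallest leaf label); returns newick + leaf order
serialize_tree <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  elen <- stats::setNames(tree$edge.length, tree$edge[, 2])
  rec <- function(node) {
    if (node <= ntip) {
      lab <- tree$tip.label[node]
      return(list(str = lab, n = 1L, mn = lab, leaves = lab))
    }
    ch <- lapply(kids[[as.character(node)]], rec)
    ord <- order_c(vapply(ch, `[[`, integer(1), "n"),
                   vapply(ch, `[[`, character(1), "mn"))
    ch <- ch[ord]
    ids <- kids[[as.character(node)]][ord]
    parts <- vapply(seq_along(ch), function(i)
      paste0(ch[[i]]$str, ":", fmt_len(elen[[as.character(ids[i])]])),
      character(1))
    list(str = paste0("(", paste(parts, collapse = ","), ")"),
         n = sum(vapply(ch, `[[`, integer(1), "n")),
         mn = min(vapply(ch, `[[`, character(1), "mn")),
         leaves = unlist(lapply(ch, `[[`, "leaves")))
  }
  root <- ntip + 1L
  r <- rec(root)
  list(newick = paste0(r$str, ";"), leaf_order = r$leaves)
}

#' Build a guide tree over similarity hits
#'
#' Neighbor-joining on the pairwise normalized-distance matrix, negative
#' branch lengths clamped to zero, rooted at the midpoint, and ladderized
#' deterministically (smaller subtree first, ties by smallest leaf label).
#' One and two leaves are handled directly.
#'
#' @param labels leaf labels.
#' @param D symmetric distance matrix (dimnames = labels) or `NULL` when a
#'   single leaf.
#' @return list with `newick` (serialized tree; leaf order in the string is
#'   the display order) and `leaf_order`.
#' @export
guide_tree <- function(labels, D = NULL) {
  n <- length(labels)
  if (n == 1) return(list(newick = paste0("(", labels, ":0);"),
                          leaf_order = labels))
  D <- D[labels, labels, drop = FALSE]
  if (n == 2) {
    ord <- sort_c(labels)
    h <- fmt_len(D[1, 2] / 2)
    return(list(newick = sprintf("(%s:%s,%s:%s);", ord[1], h, ord[2], h),
                leaf_order = ord))
  }
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr <- phangorn::midpoint(tr)
  tr$edge.length[tr$edge.length < 0] <- 0
  serialize_tree(tr)
}

# ---- neighborhood assembly ------------------------------------------------

#' Assemble an ortholog-anchored gene neighborhood view
#'
#' One row per similarity hit: every gene overlapping a symmetric window of
#' `window_bp` base pairs around the hit gene's midpoint, on the hit's
#' contig. Rows whose hit gene lies on the minus strand are mirrored so the
#' hit gene always points rightward. Rows are ordered by the guide tree's
#' leaf order; genes are colored by ortholog group at the anchor's level in
#' order of first appearance scanning rows top-down, left-to-right (the
#' anchor's group is always color 0; genes without a group get no color).
#'
#' @param store a `gk_store` handle.
#' @param anchor_gene gene id of the anchor.
#' @param max_n maximum hits, in \[10, 200\].
#' @param window_bp window width in bp (default 10000).
#' @param og_level taxonomic level override, as in [similar_proteins()].
#' @return a `neighborhood_view`: `anchor_gene_id`, `og_id`, `og_level`,
#'   `window_bp`, `tree` (newick), `leaf_order`, `hits`, and `rows` — a list
#'   (one element per hit, in tree order) of gene tables with `locus_tag`,
#'   `start`, `end`, `strand`, `og_id`, `color_index`.
#' @export
build_neighborhood <- function(store, anchor_gene, max_n = 50,
                               window_bp = 10000L, og_level = NULL) {
  t <- store$tables
  hits <- similar_proteins(store, anchor_gene, max_n, og_level)
  level <- attr(hits, "og_level")
  anchor_og <- attr(hits, "og_id")
  labels <- sprintf("%s|%s", hits$genome_id, hits$locus_tag)

  # pairwise distances among hit proteins (cached per distinct hash pair)
  self <- attr(hits, "self_scores")
  uh <- unique(hits$protein_hash)
  seqs <- stats::setNames(
    t$proteins$sequence[match(uh, t$proteins$protein_hash)], uh)
  Dh <- matrix(0, length(uh), length(uh), dimnames = list(uh, uh))
  if (length(uh) > 1) {
    for (i in seq_len(length(uh) - 1)) for (j in (i + 1):length(uh)) {
      s <- align_score(seqs[[uh[i]]], seqs[[uh[j]]])
      Dh[i, j] <- Dh[j, i] <- norm_distance(s, self[[uh[i]]], self[[uh[j]]])
    }
  }
  D <- Dh[hits$protein_hash, hits$protein_hash, drop = FALSE]
  dimnames(D) <- list(labels, labels)
  tree <- guide_tree(labels, D)

  og_of_hash <- t$og_members[t$og_members$level == level, ]
  row_for <- function(k) {
    hg <- t$genes[t$genes$gene_id == hits$gene_id[k], ]
    center <- (hg$start + hg$end) %/% 2L
    w0 <- center - window_bp %/% 2L
    w1 <- center + window_bp %/% 2L
    g <- t$genes[t$genes$genome_id == hg$genome_id &
                   t$genes$contig_id == hg$contig_id &
                   t$genes$start < w1 & t$genes$end > w0, , drop = FALSE]
    if (hg$strand == -1L) {
      ns <- 2L * center - g$end
      ne <- 2L * center - g$start
      g$start <- ns; g$end <- ne; g$strand <- -g$strand
    }
    g <- g[order_c(g$start, g$locus_tag), , drop = FALSE]
    g$og_id <- og_of_hash$og_id[match(g$protein_hash, og_of_hash$protein_hash)]
    g[, c("gene_id", "locus_tag", "start", "end", "strand", "og_id")]
  }
  rows <- lapply(match(tree$leaf_order, labels), row_for)
  names(rows) <- tree$leaf_order

  color_map <- stats::setNames(0L, anchor_og)
  for (r in rows) for (og in r$og_id) {
    if (!is.na(og) && !og %in% names(color_map))
      color_map[og] <- length(color_map)
  }
  rows <- lapply(rows, function(r) {
    r$color_index <- unname(color_map[r$og_id])
    r
  })
  structure(list(anchor_gene_id = anchor_gene, og_id = anchor_og,
                 og_level = level, window_bp = window_bp,
                 tree = tree$newick, leaf_order = tree$leaf_order,
                 hits = hits, rows = rows, color_map = color_map),
            class = "neighborhood_view")
}

#' @export
print.neighborhood_view <- function(x, ...) {
  cat(sprintf("<neighborhood> anchor %s, family %s@%s, %d rows, %d colors\n",
              x$anchor_gene_id, x$og_id, x$og_level, length(x$rows),
              length(x$color_map)))
  invisible(x)
}

#' Functional profile of a neighborhood
#'
#' Tallies COG functional-category labels over all genes of all rows of a
#' neighborhood view. Multi-letter categories count once per letter; genes
#' without a category label count under "unclassified".
#'
#' @param view a `neighborhood_view`.
#' @param store the store the view was built from.
#' @return list with `entries` (data frame: `category`, `count`, sorted by
#'   count descending then category) and `total` = sum of counts.
#' @export
functional_profile <- function(view, store) {
  t <- store$tables
  cogs <- t$protein_labels[t$protein_labels$scheme == "COG_category", ]
  counts <- new.env(parent = emptyenv())
  bump <- function(k) assign(k, (get0(k, envir = counts) %||% 0L) + 1L,
                             envir = counts)
  for (r in view$rows) {
    hashes <- t$genes$protein_hash[match(r$gene_id, t$genes$gene_id)]
    for (h in hashes) {
      vals <- if (is.na(h)) character(0) else cogs$value[cogs$protein_hash == h]
      letters <- unique(unlist(strsplit(vals, "", fixed = TRUE)))
      if (!length(letters)) bump("unclassified")
      else for (L in letters) bump(L)
    }
  }
  cats <- ls(counts)
  entries <- data.frame(category = cats,
                        count = vapply(cats, get, integer(1), envir = counts),
                        stringsAsFactors = FALSE)
  entries <- entries[order_c(-entries$count, entries$category), ]
  rownames(entries) <- NULL
  list(entries = entries, total = sum(entries$count))
}

# OG id set of a gene set at one level
og_set_of_genes <- function(store, gene_ids, level) {
  t <- store$tables
  hashes <- t$genes$protein_hash[match(gene_ids, t$genes$gene_id)]
  m <- t$og_members[t$og_members$level == level &
                      t$og_members$protein_hash %in% hashes, ]
  unique(m$og_id)
}

default_og_level <- function(store) {
  t <- store$tables
  if (!nrow(t$og_members)) stop("no ortholog assignments in store")
  tab <- table(t$og_members$level)
  names(tab)[order_c(-as.integer(tab), names(tab))][1]
}

#' Find operons conserved across genomes
#'
#' Ranks operons of other genomes by the number of ortholog groups (at one
#' taxonomic level) shared with the query operon's member genes.
#'
#' @param store a `gk_store` handle.
#' @param operon_id query operon.
#' @param min_shared minimum number of shared groups (default 2).
#' @param og_level taxonomic level; `NULL` uses the level annotating the
#'   most proteins store-wide.
#' @return data frame (`operon_id`, `genome_id`, `n_shared_ogs`) ranked by
#'   `n_shared_ogs` descending, ties by genome_id.
#' @export
conserved_operons <- function(store, operon_id, min_shared = 2,
                              og_level = NULL) {
  t <- store$tables
  q <- t$operons[t$operons$operon_id == operon_id, ]
  if (!nrow(q)) stop("not found: operon ", operon_id)
  level <- og_level %||% default_og_level(store)
  qset <- og_set_of_genes(
    store, t$operon_genes$gene_id[t$operon_genes$operon_id == operon_id], level)
  others <- t$operons[t$operons$genome_id != q$genome_id, ]
  res <- data.frame(operon_id = character(), genome_id = character(),
                    n_shared_ogs = integer(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(others))) {
    oset <- og_set_of_genes(
      store, t$operon_genes$gene_id[t$operon_genes$operon_id == others$operon_id[i]],
      level)
    ns <- length(intersect(qset, oset))
    if (ns >= min_shared)
      res <- rbind(res, data.frame(operon_id = others$operon_id[i],
                                   genome_id = others$genome_id[i],
                                   n_shared_ogs = ns, stringsAsFactors = FALSE))
  }
  res <- res[order_c(-res$n_shared_ogs, res$genome_id), ]
  rownames(res) <- NULL
  res
}

#' Find regulons conserved across genomes
#'
#' As [conserved_operons()], intersecting target-gene ortholog-group sets;
#' additionally, when both the query and the candidate regulon have a
#' regulator gene, the regulators must share an ortholog group.
#'
#' @inheritParams conserved_operons
#' @param regulon_id query regulon.
#' @return data frame (`regulon_id`, `genome_id`, `n_shared_target_ogs`).
#' @export
conserved_regulons <- function(store, regulon_id, min_shared = 2,
                               og_level = NULL) {
  t <- store$tables
  q <- t$regulons[t$regulons$regulon_id == regulon_id, ]
  if (!nrow(q)) stop("not found: regulon ", regulon_id)
  level <- og_level %||% default_og_level(store)
  qset <- og_set_of_genes(
    store, t$regulon_targets$gene_id[t$regulon_targets$regulon_id == regulon_id],
    level)
  qreg <- if (!is.na(q$regulator_gene_id))
    og_set_of_genes(store, q$regulator_gene_id, level) else NULL
  others <- t$regulons[t$regulons$genome_id != q$genome_id, ]
  res <- data.frame(regulon_id = character(), genome_id = character(),
                    n_shared_target_ogs = integer(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(others))) {
    o <- others[i, ]
    oset <- og_set_of_genes(
      store, t$regulon_targets$gene_id[t$regulon_targets$regulon_id == o$regulon_id],
      level)
    ns <- length(intersect(qset, oset))
    if (ns < min_shared) next
    if (!is.null(qreg) && !is.na(o$regulator_gene_id)) {
      oreg <- og_set_of_genes(store, o$regulator_gene_id, level)
      if (!length(intersect(qreg, oreg))) next
    }
    res <- rbind(res, data.frame(regulon_id = o$regulon_id,
                                 genome_id = o$genome_id,
                                 n_shared_target_ogs = ns,
                                 stringsAsFactors = FALSE))
  }
  res <- res[order_c(-res$n_shared_target_ogs, res$genome_id), ]
  rownames(res) <- NULL
  res
}

#' Serialize a neighborhood view to JSON-ready structures
#'
#' Writes `view.json` (rows with colors), `tree.nwk` and `profile.json`
#' into `outdir`, plus a standalone SVG rendering of the gene arrows.
#'
#' @param view a `neighborhood_view`.
#' @param store the originating store.
#' @param outdir output directory.
#' @return named vector of file paths.
#' @export
export_neighborhood <- function(view, store, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  vj <- list(anchor_gene_id = view$anchor_gene_id, og_id = view$og_id,
             og_level = view$og_level, window_bp = view$window_bp,
             leaf_order = as.list(view$leaf_order),
             rows = lapply(view$leaf_order, function(lb) {
               r <- view$rows[[lb]]
               list(label = lb, genes = lapply(seq_len(nrow(r)), function(i)
                 list(locus_tag = r$locus_tag[i], start = r$start[i],
                      end = r$end[i], strand = r$strand[i],
                      og_id = if (is.na(r$og_id[i])) NULL else r$og_id[i],
                      color_index = if (is.na(r$color_index[i])) NULL
                      else r$color_index[i])))
             }))
  vpath <- file.path(outdir, "view.json")
  write_json_file(vj, vpath)
  tpath <- file.path(outdir, "tree.nwk")
  write_lines_lf(view$tree, tpath)
  prof <- functional_profile(view, store)
  ppath <- file.path(outdir, "profile.json")
  write_json_file(list(total = prof$total, entries = prof$entries), ppath)
  spath <- file.path(outdir, "view.svg")
  write_lines_lf(neighborhood_svg(view), spath)
  c(view = vpath, tree = tpath, profile = ppath, svg = spath)
}

# minimal standalone SVG: one lane of OG-colored arrows per row in tree order
neighborhood_svg <- function(view) {
  pal <- c("#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd", "#8c564b",
           "#e377c2", "#7f7f7f", "#bcbd22", "#17becf")
  lane_h <- 28L
  width <- 900L
  rows <- view$leaf_order
  svg <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                   width, lane_h * length(rows) + 10L))
  for (k in seq_along(rows)) {
    r <- view$rows[[rows[k]]]
    if (!nrow(r)) next
    x0 <- min(r$start); x1 <- max(r$end)
    sc <- (width - 160L) / max(1L, x1 - x0)
    y <- (k - 1L) * lane_h + 5L
    svg <- c(svg, sprintf('<text x="2" y="%d" font-size="9">%s</text>',
                          y + 12L, rows[k]))
    for (i in seq_len(nrow(r))) {
      gx <- 150L + (r$start[i] - x0) * sc
      gw <- max(2, (r$end[i] - r$start[i]) * sc)
      col <- if (is.na(r$color_index[i])) "#dddddd"
      else pal[(r$color_index[i] %% length(pal)) + 1L]
      marker <- if (r$strand[i] == 1L) "" else " transform=\"scale(1,1)\""
      svg <- c(svg, sprintf(
        '<rect x="%.1f" y="%d" width="%.1f" height="14" fill="%s"><title>%s (%s)</title></rect>%s',
        gx, y, gw, col, r$locus_tag[i],
        if (is.na(r$og_id[i])) "-" else r$og_id[i], marker))
    }
  }
  c(svg, "</svg>")
}
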