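# independent oracles used by the tests; deliberately written as plain
# brute-force implementations, separate from the package code paths

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gotoh affine-gap global alignment score: a gap of length L costs
# open + L * ext (first gapped residue pays open + ext)
oracle_align_score <- function(a, b, open = 11, ext = 1) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  mat <- e$BLOSUM62
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- mat[A[i], B[j]]
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# brute-force operon finder: enumerate all windows of consecutive CDS genes,
# keep those that satisfy the rule and are maximal
oracle_operons <- function(genes, max_gap = 150L) {
  g <- genes[genes$feature_type == "CDS", , drop = FALSE]
  g <- g[order(g$start), , drop = FALSE]
  n <- nrow(g)
  ok_pair <- function(i, j) g$strand[i] == g$strand[j] &&
    max(g$start[j] - g$end[i], 0L) <= max_gap
  ok_window <- function(i, j) {
    if (j - i < 1) return(FALSE)
    all(vapply(i:(j - 1), function(k) ok_pair(k, k + 1), logical(1)))
  }
  out <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i || !ok_window(i, j)) next
    left_max <- i == 1 || !ok_pair(i - 1, i)
    right_max <- j == n || !ok_pair(j, j + 1)
    if (left_max && right_max)
      out[[length(out) + 1L]] <- g$gene_id[i:j]
  }
  out
}

random_gene_layout <- function(n_genes, seed) {
  set.seed(seed)
  starts <- integer(n_genes)
  ends <- integer(n_genes)
  pos <- 0L
  for (i in seq_len(n_genes)) {
    gap <- sample(c(-30:0, 1:300), 1)          # overlaps allowed
    len <- sample(90:900, 1)
    starts[i] <- max(pos + gap, if (i == 1) 0L else starts[i - 1] + 1L)
    ends[i] <- starts[i] + len
    pos <- ends[i]
  }
  data.frame(gene_id = sprintf("g:t%03d", seq_len(n_genes)),
             contig_id = "c1", start = starts, end = ends,
             strand = sample(c(1L, -1L), n_genes, replace = TRUE),
             feature_type = "CDS", stringsAsFactors = FALSE)
}

# brute-force check that a tree's pairwise path lengths reproduce a distance
# matrix (additivity check for NJ recovery tests)
tree_path_distances <- function(newick) {
  tr <- ape::read.tree(text = newick)
  d <- ape::cophenetic.phylo(tr)
  d[order(rownames(d)), order(colnames(d))]
}

# mock annotation tool: one "domain" annotation per protein in the input FASTA
write_mock_annotator <- function(path, source_name = "mocktool") {
  writeLines(c(
    "#!/usr/bin/env bash",
    "faa=\"$1\"; out=\"$2\"",
    "printf 'locus_tag\\tgenome\\tsource\\tkey\\tvalue\\tnote\\n' > \"$out\"",
    paste0("grep '^>' \"$faa\" | sed 's/^>//' | awk -F'|' '{print $2\"\\t\"$1\"\\t",
           source_name, "\\tdomain\\tDOM\"NR\"\\t-\"}' >> \"$out\"")),
    path)
  Sys.chmod(path, "0755")
  path
}
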