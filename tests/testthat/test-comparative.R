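test_that("alignment scores and ranking match an independent affine-gap DP", {
  set.seed(7)
  base <- paste(c("M", sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K",
                                "L", "N", "P", "Q", "R", "S", "T", "V", "W",
                                "Y"), 49, replace = TRUE)), collapse = "")
  mutate_n <- function(s, n) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(2:length(ch), n)
    for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "D", "E"), ch[i]), 1)
    paste(ch, collapse = "")
  }
  fam <- c(base, vapply(c(1, 3, 5, 8, 12, 20, 30), mutate_n, character(1),
                        s = base))
  for (s in fam)
    expect_equal(genomekeeper:::align_score(base, s),
                 oracle_align_score(base, s), info = s)
  # gapped pair exercises the affine penalty
  gapped <- paste0(substr(base, 1, 20), substr(base, 26, 50))
  expect_equal(genomekeeper:::align_score(base, gapped),
               oracle_align_score(base, gapped))
  # ranking by package score equals ranking by oracle score
  pk <- vapply(fam, function(s) genomekeeper:::align_score(base, s), numeric(1))
  or <- vapply(fam, function(s) oracle_align_score(base, s), numeric(1))
  expect_equal(order(-pk), order(-or))
})

test_that("similar_proteins ranks family members, anchor first, bounds enforced", {
  st <- small_store()
  tg <- truth_genes(small_collection())
  a <- tg[tg$genome == "GEN001" & tg$og_id == "OG0001", ][1, ]
  anchor <- paste0("GEN001:", a$locus_tag)
  hits <- similar_proteins(st, anchor, max_n = 10)
  expect_equal(hits$gene_id[1], anchor)
  expect_equal(hits$normalized_distance[1], 0)
  expect_equal(nrow(hits), 5L)  # one OG0001 member per genome
  expect_true(all(diff(hits$score[-1]) <= 0))
  expect_true(all(hits$normalized_distance >= 0 & hits$normalized_distance <= 1))
  # hits are exactly the planted family members
  expect_setequal(hits$gene_id,
                  paste0(tg$genome[tg$og_id == "OG0001"], ":",
                         tg$locus_tag[tg$og_id == "OG0001"]))
  expect_error(similar_proteins(st, anchor, max_n = 5), "max_n")
  expect_error(similar_proteins(st, anchor, max_n = 500), "max_n")
  # anchor without OG assignment
  st2 <- fresh_store()
  import_collection(st2, small_collection()$dir, order = 1L)
  expect_error(similar_proteins(st2, anchor, max_n = 10), "no ortholog family")
})

test_that("neighbor joining recovers additive 4- and 5-leaf trees exactly", {
  # planted additive tree: ((A:1,B:2):1.5,(C:1,D:3)) as unrooted distances
  D4 <- matrix(c(0, 3, 3.5, 5.5,
                 3, 0, 4.5, 6.5,
                 3.5, 4.5, 0, 4,
                 5.5, 6.5, 4, 0), 4, 4,
               dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- guide_tree(c("A", "B", "C", "D"), D4)
  got <- tree_path_distances(tr$newick)
  expect_equal(got[c("A", "B", "C", "D"), c("A", "B", "C", "D")], D4,
               tolerance = 1e-6)
  # topology: {A,B} vs {C,D} split (brute force over the three topologies
  # reduces to checking the path-length matrix, which is unique per topology)
  expect_equal(tr$leaf_order, sort(tr$leaf_order))

  # additive 5-leaf caterpillar
  lbl <- c("L1", "L2", "L3", "L4", "L5")
  edge <- c(L1 = 1, L2 = 2, L3 = 1.5, L4 = 2.5, L5 = 3)
  spine <- c(0, 1, 2)   # internal nodes n1-n2-n3
  pos <- c(L1 = 0, L2 = 0, L3 = 1, L4 = 2, L5 = 2)
  D5 <- matrix(0, 5, 5, dimnames = list(lbl, lbl))
  for (i in 1:4) for (j in (i + 1):5) {
    d <- edge[lbl[i]] + edge[lbl[j]] + abs(spine[pos[lbl[i]] + 1] -
                                             spine[pos[lbl[j]] + 1])
    D5[i, j] <- D5[j, i] <- d
  }
  tr5 <- guide_tree(lbl, D5)
  got5 <- tree_path_distances(tr5$newick)
  expect_equal(got5[lbl, lbl], D5, tolerance = 1e-6)
})

test_that("guide tree degenerate cases and deterministic leaf order", {
  one <- guide_tree("X")
  expect_equal(one$leaf_order, "X")
  two <- guide_tree(c("B", "A"), matrix(c(0, 0.4, 0.4, 0), 2, 2,
                                        dimnames = list(c("B", "A"), c("B", "A"))))
  expect_equal(two$leaf_order, c("A", "B"))
  expect_match(two$newick, "A:0.2,B:0.2")
  # identical sequences: all-zero distances give zero path lengths
  lbl <- c("a", "b", "c", "d")
  Z <- matrix(0, 4, 4, dimnames = list(lbl, lbl))
  trz <- guide_tree(lbl, Z)
  expect_true(all(tree_path_distances(trz$newick) == 0))
  # newick leaf sequence equals the reported leaf order
  from_newick <- regmatches(trz$newick, gregexpr("[a-d]", trz$newick))[[1]]
  expect_equal(from_newick, trz$leaf_order)
})

test_that("neighborhood rows follow the tree, colors are consistent, minus anchors mirror", {
  st <- small_store()
  coll <- small_collection()
  tg <- truth_genes(coll)
  a <- tg[tg$genome == "GEN001" & tg$og_id == "OG0002", ][1, ]
  anchor <- paste0("GEN001:", a$locus_tag)
  v <- build_neighborhood(st, anchor, max_n = 10, window_bp = 6000)
  expect_equal(length(v$rows), 5L)
  expect_equal(names(v$rows), v$leaf_order)
  # newick leaf sequence equals row order
  leaves <- regmatches(v$tree, gregexpr("GEN[0-9]+\\|[A-Za-z0-9_]+", v$tree))[[1]]
  expect_equal(leaves, v$leaf_order)

  # color map: bijection over assigned colors, anchor family color 0
  expect_equal(unname(v$color_map[v$og_id]), 0L)
  expect_equal(anyDuplicated(v$color_map), 0L)
  expect_equal(sort(unname(v$color_map)), seq_along(v$color_map) - 1L)
  # planted conserved neighborhood: OG0001..OG0004 get one shared color each
  for (og in sprintf("OG%04d", 1:4)) {
    cols <- unlist(lapply(v$rows, function(r) r$color_index[r$og_id == og]))
    expect_equal(length(unique(cols)), 1L, info = og)
    expect_length(cols, 5L)
  }
  # per-row: the hit gene points rightward after reorientation
  for (lb in v$leaf_order) {
    r <- v$rows[[lb]]
    hit_tag <- sub("^.*\\|", "", lb)
    expect_equal(r$strand[r$locus_tag == hit_tag], 1L, info = lb)
  }
  # idempotence: second build yields identical serialization
  v2 <- build_neighborhood(st, anchor, max_n = 10, window_bp = 6000)
  expect_identical(v$tree, v2$tree)
  expect_identical(v$rows, v2$rows)
})

test_that("functional profile counts letters and the unclassified bucket", {
  st <- small_store()
  tg <- truth_genes(small_collection())
  a <- tg[tg$genome == "GEN001" & tg$og_id == "OG0001", ][1, ]
  v <- build_neighborhood(st, paste0("GEN001:", a$locus_tag),
                          max_n = 10, window_bp = 6000)
  prof <- functional_profile(v, st)
  expect_equal(sum(prof$entries$count), prof$total)

  # independent tally from the truth table and the reference labels
  ref <- utils::read.delim(file.path(small_collection()$dir, "reference.tsv"),
                           colClasses = "character")
  key <- ref$protein_md5
  key[key == ""] <- protein_hash(toupper(ref$protein_seq[key == ""]))
  cog_of <- stats::setNames(ref$cog_category, key)
  want <- new.env(parent = emptyenv())
  for (lb in v$leaf_order) {
    r <- v$rows[[lb]]
    gid <- sub("\\|.*$", "", lb)
    for (tag in r$locus_tag) {
      h <- tg$protein_hash[tg$genome == gid & tg$locus_tag == tag]
      letters <- unique(strsplit(cog_of[[h]], "")[[1]])
      for (L in letters)
        assign(L, (get0(L, envir = want) %||% 0L) + 1L, envir = want)
    }
  }
  for (cat in prof$entries$category) {
    if (cat == "unclassified") next
    expect_equal(prof$entries$count[prof$entries$category == cat],
                 get0(cat, envir = want), info = cat)
  }
})

test_that("conserved operons and regulons match brute-force OG-set intersection", {
  st <- small_store()
  coll <- small_collection()
  to <- truth_operons(coll)
  tg <- truth_genes(coll)
  og_of <- stats::setNames(tg$og_id, paste0(tg$genome, ":", tg$locus_tag))
  op1 <- st$tables$operons$operon_id[st$tables$operons$genome_id == "GEN001"][1]

  res <- conserved_operons(st, op1, min_shared = 2)
  # brute force over all operons of other genomes
  qset <- unique(og_of[st$tables$operon_genes$gene_id[
    st$tables$operon_genes$operon_id == op1]])
  others <- st$tables$operons[st$tables$operons$genome_id != "GEN001", ]
  want <- do.call(rbind, lapply(seq_len(nrow(others)), function(i) {
    oset <- unique(og_of[st$tables$operon_genes$gene_id[
      st$tables$operon_genes$operon_id == others$operon_id[i]]])
    data.frame(operon_id = others$operon_id[i],
               n = length(intersect(qset, oset)), stringsAsFactors = FALSE)
  }))
  want <- want[want$n >= 2, ]
  expect_setequal(res$operon_id, want$operon_id)
  expect_equal(res$n_shared_ogs,
               want$n[match(res$operon_id, want$operon_id)])
  expect_true(all(diff(res$n_shared_ogs) <= 0))
  # the planted 4-gene operon is conserved in all other genomes
  expect_equal(sum(res$n_shared_ogs == 4), 4L)
  # a bound higher than the operon size returns nothing
  expect_equal(nrow(conserved_operons(st, op1, min_shared = 5)), 0L)
  expect_error(conserved_operons(st, "nope"), "not found")
})

test_that("conserved regulons require regulator agreement when both present", {
  st <- small_store()
  coll <- small_collection()
  tg <- truth_genes(coll)
  # plant identical regulons (same OG targets) in GEN001 and GEN002 and a
  # decoy in GEN003 whose regulator comes from a different family
  mk_rows <- function(gid, reg_og, name) {
    g <- tg[tg$genome == gid, ]
    reg <- g$locus_tag[g$og_id == reg_og][1]
    targ <- g$locus_tag[g$og_id %in% c("OG0002", "OG0003")]
    sprintf("%s\t%s\t%s\t%s\t\t\t\t\t", name, gid, reg, targ)
  }
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(paste("regulon_name", "genome", "regulator_locus_tag",
                     "target_locus_tag", "site_contig", "site_start",
                     "site_end", "site_strand", "site_sequence", sep = "\t"),
               mk_rows("GEN001", "OG0010", "RegC"),
               mk_rows("GEN002", "OG0010", "RegC"),
               mk_rows("GEN003", "OG0011", "RegC")), tsv)
  n <- bulk_import_regulons(st, tsv)
  expect_equal(as.integer(n), 6L)
  res <- conserved_regulons(st, "RegC:GEN001", min_shared = 2)
  expect_true("RegC:GEN002" %in% res$regulon_id)
  expect_false("RegC:GEN003" %in% res$regulon_id)  # regulator OG differs
  expect_equal(res$n_shared_target_ogs[res$regulon_id == "RegC:GEN002"], 2L)
})

test_that("neighborhood export writes consistent JSON, newick and SVG", {
  st <- small_store()
  tg <- truth_genes(small_collection())
  a <- tg[tg$genome == "GEN002" & tg$og_id == "OG0003", ][1, ]
  v <- build_neighborhood(st, paste0("GEN002:", a$locus_tag),
                          max_n = 10, window_bp = 5000)
  out <- tempfile()
  paths <- export_neighborhood(v, st, out)
  expect_true(all(file.exists(paths)))
  vj <- jsonlite::fromJSON(paths[["view"]], simplifyVector = FALSE)
  expect_equal(length(vj$rows), length(v$rows))
  expect_equal(unlist(vj$leaf_order), v$leaf_order)
  expect_identical(readLines(paths[["tree"]]), v$tree)
})
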