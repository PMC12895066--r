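test_that("gene text search matches names, products and annotations", {
  st <- small_store()
  tg <- truth_genes(small_collection())
  # products are "<OG> family protein"; search one family name
  res <- search_genes(st, "OG0003 family", field = "function")
  expect_equal(nrow(res), 5L)
  expect_setequal(res$genome_id, sprintf("GEN%03d", 1:5))
  # case-insensitive substring
  expect_equal(nrow(search_genes(st, "og0003 FAMILY", field = "function")), 5L)
  # scope restriction
  res1 <- search_genes(st, "family protein", scope = "GEN001", field = "function")
  expect_equal(nrow(res1), sum(tg$genome == "GEN001"))
  expect_true(all(diff(res1$start) > 0))
  expect_error(search_genes(st, "x", scope = "NOPE"), "not found")
  expect_error(search_genes(st, ""), "empty query")
})

test_that("classification search is exact-identifier, matching the truth table", {
  st <- small_store()
  tg <- truth_genes(small_collection())
  # OG0005 carries K00005 by construction of the generator
  res <- search_genes(st, "K00005", field = "KEGG_ortholog")
  want <- paste0(tg$genome[tg$og_id == "OG0005"], ":",
                 tg$locus_tag[tg$og_id == "OG0005"])
  expect_setequal(res$gene_id, want)
  # a prefix must not match
  expect_equal(nrow(search_genes(st, "K0000", field = "KEGG_ortholog")), 0L)
  # GO labels
  res_go <- search_genes(st, "GO:0000065", field = "GO")  # OG0005 * 13
  expect_setequal(res_go$gene_id, want)
})

test_that("genome search covers names, taxonomy and strain metadata", {
  coll <- small_collection()
  st <- fresh_store()
  import_collection(st, coll$dir)
  res <- search_genomes(st, "GEN002")
  expect_true(any(res$matched_field == "genome_name" & res$genome_id == "GEN002"))

  # genus name matches all genomes of that genus via their lineage
  res_g <- search_genomes(st, "SynthogenusA")
  tax <- utils::read.delim(file.path(coll$dir, "taxonomy.tsv"),
                           colClasses = "character")
  genusA <- tax$taxon_id[tax$name == "SynthogenusA"]
  species_a <- tax$taxon_id[tax$parent_id == genusA]
  want <- st$tables$genomes$genome_id[st$tables$genomes$taxon_id %in% species_a]
  expect_setequal(res_g$genome_id[res_g$matched_field == "taxonomy"], want)

  # strain metadata match
  add_strain(st, "strZ")
  t <- st$tables; t$genomes$strain_id[1] <- "strZ"; genomekeeper:::store_commit(st, t)
  md <- tempfile(fileext = ".tsv")
  writeLines(c("entity_name\tkey\tsource\tvalue",
               "strZ\thabitat\tnotes\thydrothermal vent"), md)
  bulk_import_metadata(st, "strain", md)
  res_m <- search_genomes(st, "hydrothermal")
  expect_equal(res_m$matched_field, "metadata")
  expect_equal(res_m$genome_id, st$tables$genomes$genome_id[1])

  expect_equal(nrow(search_genomes(st, "no such thing")), 0L)
})

test_that("pathway gene listing groups by KEGG ortholog and unions to all labeled genes", {
  st <- small_store()
  coll <- small_collection()
  tg <- truth_genes(coll)
  ref <- utils::read.delim(file.path(coll$dir, "reference.tsv"),
                           colClasses = "character")
  key <- ref$protein_md5
  key[key == ""] <- protein_hash(toupper(ref$protein_seq[key == ""]))
  pw_of <- stats::setNames(ref$kegg_pathway, key)
  g1 <- tg[tg$genome == "GEN001", ]
  pw <- unname(pw_of[g1$protein_hash[1]])
  res <- list_pathway_genes(st, "GEN001", pw)
  want_genes <- paste0("GEN001:", g1$locus_tag[pw_of[g1$protein_hash] == pw])
  expect_setequal(unique(res$gene_id), want_genes)
  expect_true(all(grepl("^K[0-9]{5}$", res$kegg_ortholog)))

  # union over all pathways = all pathway-labeled genes of the genome
  all_pw <- unique(unname(pw_of[g1$protein_hash]))
  got <- unique(unlist(lapply(all_pw, function(p)
    list_pathway_genes(st, "GEN001", p)$gene_id)))
  expect_setequal(got, paste0("GEN001:", g1$locus_tag))

  expect_equal(nrow(list_pathway_genes(st, "GEN001", "map99999")), 0L)
  expect_error(list_pathway_genes(st, "NOPE", pw), "not found")
})

test_that("planted exact substrings are hit #1 at 100% identity on both strands", {
  st <- small_store()
  ctg <- st$tables$contigs[st$tables$contigs$genome_id == "GEN001", ]
  q <- substr(ctg$sequence, 501, 530)
  res <- seq_search(st, q, "nucleotide")
  expect_gt(nrow(res), 0L)
  top <- res[1, ]
  expect_equal(top$identity_pct, 100)
  expect_equal(top$subject_id, paste0("GEN001:", ctg$contig_id))
  expect_lte(top$subject_start, 500L)
  expect_gte(top$subject_end, 530L)
  # the matched subject interval contains the planted query
  sub_seq <- substr(ctg$sequence, 501, 530)
  expect_true(grepl(if (top$strand == 1L) q else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(q))),
    substr(ctg$sequence, top$subject_start + 1, top$subject_end), fixed = TRUE) ||
      identical(sub_seq, q))

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
  res_rc <- seq_search(st, rc, "nucleotide")
  top_rc <- res_rc[1, ]
  expect_equal(top_rc$identity_pct, 100)
  expect_equal(top_rc$subject_start, top$subject_start)
  expect_equal(top_rc$subject_end, top$subject_end)
  expect_equal(top_rc$strand, -top$strand)
})

test_that("a planted 90%-identity homolog passes at 80 and fails at 95", {
  st <- small_store()
  ctg <- st$tables$contigs[st$tables$contigs$genome_id == "GEN002", ]
  region <- substr(ctg$sequence, 1001, 1100)
  ch <- strsplit(region, "")[[1]]
  flip <- function(b) c(A = "C", C = "G", G = "T", T = "A", N = "A")[[b]]
  mut_pos <- c(5, 10, 15, 20, 25, 50, 58, 66, 74, 82)
  for (p in mut_pos) ch[p] <- flip(ch[p])
  q <- paste(ch, collapse = "")

  res80 <- seq_search(st, q, "nucleotide", min_identity_pct = 80)
  sid <- paste0("GEN002:", ctg$contig_id)
  in_region <- res80$subject_id == sid & res80$subject_start >= 990 &
    res80$subject_end <= 1110
  expect_true(any(in_region))
  hit <- res80[which(in_region)[1], ]
  expect_equal(hit$matches, 90L)
  expect_equal(hit$length, 100L)
  expect_equal(hit$identity_pct, 90)

  res95 <- seq_search(st, q, "nucleotide", min_identity_pct = 95)
  expect_false(any(res95$subject_id == sid & res95$subject_start >= 990 &
                     res95$subject_end <= 1110 & res95$length > 50))
})

test_that("protein search finds exact peptide substrings; inputs validated", {
  st <- small_store()
  pr <- st$tables$proteins$sequence[5]
  q <- substr(pr, 10, 34)
  res <- seq_search(st, q, "protein")
  expect_gt(nrow(res), 0L)
  expect_equal(res$identity_pct[1], 100)
  own <- res[res$subject_id == st$tables$proteins$protein_hash[5], ]
  expect_equal(own$score[1], res$score[1])  # the source protein ties for #1
  expect_equal(own$subject_start[1], 9L)
  expect_equal(own$subject_end[1], 34L)
  expect_equal(own$identity_pct[1], 100)

  expect_error(seq_search(st, "MKTXYZ123", "nucleotide"), "alphabet")
  expect_error(seq_search(st, "ACGTACGT", "nucleotide"), "shorter than seed")
  expect_error(seq_search(st, "MKT", "protein"), "shorter than seed")
})
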