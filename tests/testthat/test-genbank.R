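test_that("coordinate conventions: 1-based inclusive becomes 0-based half-open", {
  rec <- parse_genbank(write_mini_genbank(tempfile(fileext = ".gbk"),
                                          location = "1..9",
                                          translation = "MKT"))
  g <- rec$genes
  expect_equal(nrow(g), 1L)
  expect_equal(g$start, 0L)
  expect_equal(g$end, 9L)
  expect_equal(g$strand, 1L)
  expect_equal(g$protein_seq, "MKT")

  rec2 <- parse_genbank(write_mini_genbank(tempfile(fileext = ".gbk"),
                                           location = "complement(1..9)"))
  expect_equal(rec2$genes$start, 0L)
  expect_equal(rec2$genes$end, 9L)
  expect_equal(rec2$genes$strand, -1L)
})

test_that("missing /translation is re-derived with the bacterial code, stop stripped", {
  p <- write_mini_genbank(tempfile(fileext = ".gbk"), location = "1..12",
                          translation = NULL,
                          sequence = "atgaaaacctaacctgtgcagt")
  rec <- parse_genbank(p)
  expect_equal(rec$genes$protein_seq, "MKT")
  expect_false(is.na(rec$genes$protein_hash))

  # minus strand: the coding sequence is the reverse complement
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGAAAACCTAA")))
  p2 <- write_mini_genbank(tempfile(fileext = ".gbk"),
                           location = "complement(1..12)",
                           translation = NULL,
                           sequence = tolower(paste0(rc, "cctgtgcagt")))
  expect_equal(parse_genbank(p2)$genes$protein_seq, "MKT")
})

test_that("fuzzy endpoints import with a warning and no re-derived translation", {
  p <- write_mini_genbank(tempfile(fileext = ".gbk"), location = "<1..12",
                          translation = NULL)
  rec <- parse_genbank(p)
  expect_equal(nrow(rec$genes), 1L)
  expect_true(is.na(rec$genes$protein_seq))
  expect_true(any(grepl("fuzzy", rec$warnings)))
})

test_that("join locations splice and organism/taxon hints are captured", {
  seq <- "atgaaagggacctaacgtacgt"
  lines <- c("LOCUS       ctgJ 22 bp    DNA     linear   BCT 01-JAN-2000",
             "FEATURES             Location/Qualifiers",
             "     source          1..22",
             '                     /organism="Synthogenus testii"',
             '                     /db_xref="taxon:2001"',
             "     CDS             join(1..6,10..15)",
             '                     /locus_tag="J_0001"',
             "ORIGIN",
             sprintf("%9d %s", 1, seq), "//")
  p <- tempfile(fileext = ".gbk")
  writeLines(lines, p)
  rec <- parse_genbank(p)
  spliced <- paste0(substr(toupper(seq), 1, 6), substr(toupper(seq), 10, 15))
  expect_equal(rec$genes$protein_seq,
               genomekeeper:::translate_cds(spliced))
  expect_equal(rec$genes$start, 0L)
  expect_equal(rec$genes$end, 15L)
  expect_equal(rec$source_taxon$name, "Synthogenus testii")
  expect_equal(rec$source_taxon$taxon_id, "2001")
})

test_that("unreadable or non-GenBank input is a parse failure", {
  expect_error(parse_genbank(tempfile()), "parse failure")
  p <- tempfile()
  writeLines(c("this is", "not genbank"), p)
  expect_error(parse_genbank(p), "parse failure")
})

test_that("protein_hash is the MD5 of the sequence bytes", {
  # reference digests computed with an RFC 1321 implementation
  expect_equal(protein_hash("A"), "7fc56270e7a70fa81a5935b72eacbe29")
  expect_equal(protein_hash("MKT"), protein_hash("MKT"))
  expect_false(protein_hash("MKT") == protein_hash("MKV"))
  expect_error(protein_hash(""), "empty protein")
})

test_that("import deduplicates proteins by hash within and across genomes", {
  coll <- small_collection()
  st <- fresh_store()
  f1 <- file.path(coll$dir, "genomes", "GEN001.gbk")
  rep1 <- import_genome(st, parse_genbank(f1))
  expect_equal(rep1$n_new_proteins + rep1$n_reused_proteins, rep1$n_cds)
  expect_equal(rep1$n_reused_proteins, 0L)

  # identical file under a new id: everything is reused
  rep2 <- import_genome(st, parse_genbank(f1), genome_id = "GEN001bis")
  expect_equal(rep2$n_new_proteins, 0L)
  expect_equal(rep2$n_reused_proteins, rep1$n_cds)

  # duplicate id rejected, store unchanged
  before <- store_counts(st)
  expect_error(import_genome(st, parse_genbank(f1)), "duplicate genome_id")
  expect_identical(store_counts(st), before)

  # store-wide protein count equals distinct translations (truth table)
  tg <- truth_genes(coll)
  st2 <- fresh_store()
  import_collection(st2, coll$dir)
  expect_equal(nrow(st2$tables$proteins), length(unique(tg$protein_hash)))
})

test_that("import order does not change the protein hash set or gene tables", {
  coll <- small_collection()
  a <- fresh_store()
  import_collection(a, coll$dir, order = 1:5)
  b <- fresh_store()
  import_collection(b, coll$dir, order = 5:1)
  expect_setequal(a$tables$proteins$protein_hash, b$tables$proteins$protein_hash)
  ga <- a$tables$genes[order(a$tables$genes$gene_id), ]
  gb <- b$tables$genes[order(b$tables$genes$gene_id), ]
  rownames(ga) <- rownames(gb) <- NULL
  expect_identical(ga, gb)
})

test_that("export_tracks writes GFF3/FASTA with 1-based coordinates, deterministically", {
  st <- fresh_store()
  rec <- parse_genbank(write_mini_genbank(tempfile(fileext = ".gbk"),
                                          location = "1..9"))
  import_genome(st, rec, genome_id = "mini")
  out1 <- tempfile(); out2 <- tempfile()
  p1 <- export_tracks(st, "mini", out1)
  gff <- readLines(p1[["gff3"]])
  row <- strsplit(grep("\tCDS\t", gff, value = TRUE), "\t")[[1]]
  expect_equal(as.integer(row[4]), 1L)   # 0-based 0 -> GFF 1
  expect_equal(as.integer(row[5]), 9L)
  expect_equal(row[7], "+")
  faa <- readLines(p1[["faa"]])
  expect_match(faa[1], "^>mini\\|MINI_0001\\|[0-9a-f]{32}$")

  p2 <- export_tracks(st, "mini", out2)
  for (k in names(p1))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  expect_error(export_tracks(st, "nope", tempfile()), "not found")
})

test_that("parse -> export -> re-parse is identity on gene coordinates", {
  skip_if_not_installed("rtracklayer")
  coll <- small_collection()
  st <- fresh_store()
  import_collection(st, coll$dir)
  for (gid in c("GEN001", "GEN004")) {
    out <- file.path(tempdir(), paste0("tracks_", gid))
    paths <- export_tracks(st, gid, out)
    gr <- rtracklayer::import(paths[["gff3"]])
    got <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      strand = ifelse(as.character(GenomicRanges::strand(gr)) == "+",
                                      1L, -1L),
                      locus_tag = gr$locus_tag, stringsAsFactors = FALSE)
    got <- got[order(got$locus_tag), ]
    want <- st$tables$genes[st$tables$genes$genome_id == gid,
                            c("contig_id", "start", "end", "strand", "locus_tag")]
    want <- want[order(want$locus_tag), ]
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$strand, want$strand)
    expect_equal(got$contig, want$contig_id)
  }
})
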