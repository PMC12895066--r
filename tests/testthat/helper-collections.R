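# shared synthetic collections, generated once per test run

.coll_cache <- new.env()

cached_collection <- function(name, spec) {
  if (is.null(.coll_cache[[name]])) {
    dir <- file.path(tempdir(), paste0("gkcoll_", name))
    unlink(dir, recursive = TRUE)
    manifest <- synth_collection(spec, dir)
    .coll_cache[[name]] <- list(dir = dir, manifest = manifest, spec = spec)
  }
  .coll_cache[[name]]
}

# the default desk-scale study collection: 10 genomes x 200 genes
default_collection <- function() {
  cached_collection("default", collection_spec(seed = 1L))
}

# small 5-genome collection with a planted conserved 4-gene neighborhood
small_collection <- function() {
  cached_collection("small", collection_spec(
    n_genomes = 5, genes_per_genome = 30, operon_sizes = c(4L, 3L),
    seed = 42L))
}

truth_genes <- function(coll) {
  utils::read.delim(file.path(coll$dir, "truth_genes.tsv"),
                    colClasses = "character")
}

truth_operons <- function(coll) {
  utils::read.delim(file.path(coll$dir, "truth_operons.tsv"),
                    colClasses = "character")
}

fresh_store <- function() {
  open_store(tempfile(fileext = ".gkdb"), create = TRUE)
}

# store with the small collection imported and orthologs assigned
.small_store_path <- NULL
small_store <- function() {
  if (is.null(.coll_cache$small_store_path)) {
    coll <- small_collection()
    st <- fresh_store()
    import_collection(st, coll$dir)
    ref <- load_reference(file.path(coll$dir, "reference.tsv"))
    for (g in sprintf("GEN%03d", 1:5)) assign_orthologs(st, ref, g)
    for (g in sprintf("GEN%03d", 1:5)) predict_operons(st, g)
    .coll_cache$small_store_path <- st$path
  }
  open_store(.coll_cache$small_store_path)
}

# a hand-built single-CDS GenBank file (1-based inclusive coordinates)
write_mini_genbank <- function(path, location = "1..9",
                               translation = "MKT",
                               sequence = "atgaaaacctaacctgtgcagt") {
  qual <- if (is.null(translation)) character(0) else
    sprintf('                     /translation="%s"', translation)
  lines <- c(
    sprintf("LOCUS       ctg1 %d bp    DNA     linear   BCT 01-JAN-2000",
            nchar(sequence)),
    "DEFINITION  mini.",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(sequence)),
    '                     /organism="Synthogenus sp."',
    sprintf("     CDS             %s", location),
    '                     /locus_tag="MINI_0001"',
    '                     /product="test protein"',
    qual,
    "ORIGIN",
    sprintf("%9d %s", 1, sequence),
    "//")
  writeLines(lines, path)
  path
}
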