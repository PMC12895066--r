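# Incremental ortholog-group assignment. The expensive external aligner of a
# production deployment is replaced by exact hash lookup against a precomputed
# reference table; the architectural property preserved is that only proteins
# whose hash is new to the store are ever looked up, so update cost scales
# with the number of novel sequences, not with collection size.

REF_SCHEMES <- c(kegg_ko = "KEGG_ortholog", kegg_pathway = "KEGG_pathway",
                 ec = "EC", go = "GO", cog_category = "COG_category")

#' Load a precomputed ortholog-group reference table
#'
#' The reference is a tab-separated file with columns `protein_md5` and/or
#' `protein_seq` (at least one per row), `og_id`, `level`, and the label
#' columns `kegg_ko`, `kegg_pathway`, `ec`, `go`, `cog_category`
#' (comma-separated multi-values, empty allowed). Rows keyed by sequence have
#' their MD5 computed on load. A protein may carry ortholog groups at several
#' taxonomic levels (one row per level); duplicate keys with conflicting
#' og_id at the same level are rejected.
#'
#' @param tsv path to the reference TSV.
#' @return a `reference_index` with `n_entries` distinct proteins and an
#'   instrumented lookup counter (see [ref_lookup_count()]).
#' @export
load_reference <- function(tsv) {
  df <- read_tsv_chr(tsv)
  if (is.null(df) || (!"protein_md5" %in% names(df) && !"protein_seq" %in% names(df)))
    stop("invalid reference: need protein_md5 or protein_seq column")
  if (!all(c("og_id", "level") %in% names(df)))
    stop("invalid reference: need og_id and level columns")
  for (col in c("protein_md5", "protein_seq", names(REF_SCHEMES)))
    if (!col %in% names(df)) df[[col]] <- ""
  key <- df$protein_md5
  need_seq <- !nzchar(key)
  if (any(need_seq)) {
    if (any(!nzchar(df$protein_seq[need_seq])))
      stop("invalid reference: row ", which(need_seq & !nzchar(df$protein_seq))[1],
           " has neither protein_md5 nor protein_seq")
    key[need_seq] <- md5_strings(toupper(df$protein_seq[need_seq]))
  }
  ref <- new.env(parent = emptyenv())
  ref$by_key <- new.env(parent = emptyenv())
  ref$lookups <- 0L
  for (i in seq_len(nrow(df))) {
    k <- key[i]
    entry <- get0(k, envir = ref$by_key) %||%
      list(og = data.frame(og_id = character(), level = character(),
                           stringsAsFactors = FALSE),
           labels = data.frame(scheme = character(), value = character(),
                               stringsAsFactors = FALSE))
    prev <- entry$og$og_id[entry$og$level == df$level[i]]
    if (length(prev) && any(prev != df$og_id[i]))
      stop("invalid reference: row ", i, " conflicts with earlier og_id for ",
           k, " at level ", df$level[i])
    entry$og <- unique(rbind(entry$og, data.frame(
      og_id = df$og_id[i], level = df$level[i], stringsAsFactors = FALSE)))
    for (col in names(REF_SCHEMES)) {
      vals <- strsplit(df[[col]][i], ",", fixed = TRUE)[[1]]
      vals <- trimws(vals[nzchar(trimws(vals))])
      if (length(vals))
        entry$labels <- unique(rbind(entry$labels, data.frame(
          scheme = REF_SCHEMES[[col]], value = vals, stringsAsFactors = FALSE)))
    }
    assign(k, entry, envir = ref$by_key)
  }
  ref$n_entries <- length(ls(ref$by_key))
  class(ref) <- "reference_index"
  ref
}

ref_lookup <- function(ref, hash) {
  ref$lookups <- ref$lookups + 1L
  get0(hash, envir = ref$by_key)
}

#' Reference lookup counter
#'
#' Number of reference lookups performed so far, or reset the counter.
#' The counter instruments the incremental-update property: during
#' [assign_orthologs()] it advances once per *novel* protein hash, never in
#' proportion to the store size.
#'
#' @param ref a `reference_index`.
#' @param reset if `TRUE`, reset the counter to zero.
#' @return the (pre-reset) lookup count.
#' @export
ref_lookup_count <- function(ref, reset = FALSE) {
  n <- ref$lookups
  if (reset) ref$lookups <- 0L
  n
}

# persist assignments for a set of hashes; returns n_assigned / n_unassigned
persist_assignments <- function(t, hashes, lookup_fun) {
  n_assigned <- 0L
  n_unassigned <- 0L
  for (h in hashes) {
    entry <- lookup_fun(h)
    if (is.null(entry)) {
      n_unassigned <- n_unassigned + 1L
      t$unassigned <- rbind(t$unassigned,
                            data.frame(protein_hash = h, stringsAsFactors = FALSE))
      next
    }
    n_assigned <- n_assigned + 1L
    og_new <- entry$og[!paste(entry$og$og_id, entry$og$level) %in%
                         paste(t$og_groups$og_id, t$og_groups$level), , drop = FALSE]
    if (nrow(og_new))
      t$og_groups <- rbind(t$og_groups, data.frame(
        og_id = og_new$og_id, level = og_new$level,
        description = NA_character_, stringsAsFactors = FALSE))
    t$og_members <- rbind(t$og_members, data.frame(
      protein_hash = h, og_id = entry$og$og_id, level = entry$og$level,
      stringsAsFactors = FALSE))
    if (nrow(entry$labels)) {
      lab_new <- entry$labels[!paste(entry$labels$scheme, entry$labels$value) %in%
                                paste(t$labels$scheme, t$labels$value), , drop = FALSE]
      if (nrow(lab_new))
        t$labels <- rbind(t$labels, data.frame(
          scheme = lab_new$scheme, value = lab_new$value,
          description = NA_character_, stringsAsFactors = FALSE))
      t$protein_labels <- rbind(t$protein_labels, data.frame(
        protein_hash = h, scheme = entry$labels$scheme,
        value = entry$labels$value, stringsAsFactors = FALSE))
    }
  }
  list(tables = t, n_assigned = n_assigned, n_unassigned = n_unassigned)
}

#' Assign ortholog groups and functional labels to a genome's proteins
#'
#' For each distinct protein of the genome: hashes that already carry
#' assignments (or were previously looked up and found absent) are skipped;
#' only novel hashes are looked up in the reference. Assignments are
#' store-wide per protein hash and therefore shared across genomes.
#'
#' @param store a `gk_store` handle.
#' @param ref a `reference_index` from [load_reference()].
#' @param genome_id genome whose proteins to assign.
#' @param retry_unassigned re-look-up hashes previously recorded as absent
#'   from the reference.
#' @return a `mapping_report`: `n_proteins_considered`, `n_skipped_known`,
#'   `n_assigned`, `n_unassigned`.
#' @export
assign_orthologs <- function(store, ref, genome_id, retry_unassigned = FALSE) {
  t <- store$tables
  if (!genome_id %in% t$genomes$genome_id) stop("not found: genome ", genome_id)
  g <- t$genes[t$genes$genome_id == genome_id & t$genes$feature_type == "CDS", ]
  hashes <- unique(g$protein_hash[!is.na(g$protein_hash)])
  known <- unique(t$og_members$protein_hash)
  seen_absent <- t$unassigned$protein_hash
  skip <- hashes %in% known
  n_skipped <- sum(skip)
  pending <- hashes[!skip]
  prior_absent <- 0L
  if (!retry_unassigned) {
    was_absent <- pending %in% seen_absent
    prior_absent <- sum(was_absent)
    pending <- pending[!was_absent]
  } else {
    t$unassigned <- t$unassigned[!t$unassigned$protein_hash %in% pending, ,
                                 drop = FALSE]
  }
  res <- persist_assignments(t, pending, function(h) ref_lookup(ref, h))
  if (res$n_assigned + res$n_unassigned > 0) store_commit(store, res$tables)
  structure(list(genome_id = genome_id,
                 n_proteins_considered = length(hashes),
                 n_skipped_known = n_skipped,
                 n_assigned = res$n_assigned,
                 n_unassigned = res$n_unassigned + prior_absent),
            class = "mapping_report")
}

#' @export
print.mapping_report <- function(x, ...) {
  cat(sprintf("genome %s: %d proteins, %d already known, %d assigned, %d unassigned\n",
              x$genome_id, x$n_proteins_considered, x$n_skipped_known,
              x$n_assigned, x$n_unassigned))
  invisible(x)
}

#' Run an external ortholog-mapper tool on novel proteins
#'
#' Writes a FASTA of the genome's novel proteins (headers are protein
#' hashes), renders and executes the tool's command template (see
#' [register_tool()]), and imports the emitted TSV, which must follow the
#' reference-table dialect of [load_reference()]. On failure the store is
#' left unchanged.
#'
#' @param store a `gk_store` handle.
#' @param tool a tool configuration (from [register_tool()] or a list with
#'   `name`, `env_name`, `command_template`).
#' @param genome_id genome whose novel proteins to map.
#' @param workdir scratch directory for inputs/outputs.
#' @param no_env if `TRUE`, run the command without an environment
#'   activation prefix.
#' @return a `mapping_report` as for [assign_orthologs()].
#' @export
run_mapper_plugin <- function(store, tool, genome_id,
                              workdir = tempfile("mapper"), no_env = TRUE) {
  t <- store$tables
  if (!genome_id %in% t$genomes$genome_id) stop("not found: genome ", genome_id)
  g <- t$genes[t$genes$genome_id == genome_id & t$genes$feature_type == "CDS", ]
  hashes <- unique(g$protein_hash[!is.na(g$protein_hash)])
  known <- unique(c(t$og_members$protein_hash, t$unassigned$protein_hash))
  novel <- setdiff(hashes, known)
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  faa <- file.path(workdir, "novel_proteins.faa")
  seqs <- t$proteins$sequence[match(novel, t$proteins$protein_hash)]
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(stats::setNames(seqs, novel)), faa, width = 70L)
  out_tsv <- file.path(workdir, "mapper_output.tsv")
  status <- run_tool_command(tool, list(input_faa = faa, output_tsv = out_tsv,
                                        workdir = workdir),
                             log = file.path(workdir, "mapper.log"),
                             no_env = no_env)
  if (status != 0 || !file.exists(out_tsv))
    stop("mapper tool failed (exit ", status, "); store unchanged")
  emitted <- tryCatch(load_reference(out_tsv),
                      error = function(e) stop("mapper output unparseable: ",
                                               conditionMessage(e)))
  res <- persist_assignments(t, novel,
                             function(h) get0(h, envir = emitted$by_key))
  store_commit(store, res$tables)
  structure(list(genome_id = genome_id, n_proteins_considered = length(hashes),
                 n_skipped_known = length(hashes) - length(novel),
                 n_assigned = res$n_assigned, n_unassigned = res$n_unassigned),
            class = "mapping_report")
}
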