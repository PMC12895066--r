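# Plugin-based annotation pipeline. Each registered tool runs from a rendered
# bash command; its output must be a 6-column tab-separated annotation file
# (locus_tag, genome, source, key, value, note) that is validated and
# imported atomically per job.

ANNOT_COLUMNS <- c("locus_tag", "genome", "source", "key", "value", "note")

render_template <- function(template, vars) {
  # placeholder substitution only (fixed-string), never shell interpolation
  for (k in names(vars))
    template <- gsub(paste0("{", k, "}"), vars[[k]], template, fixed = TRUE)
  template
}

run_tool_command <- function(tool, vars, log, no_env = FALSE,
                             env_prefix = "conda run -n {env_name}") {
  params <- tool$params %||% list()
  cmd <- render_template(tool$command_template, c(vars, params))
  if (!no_env && nzchar(tool$env_name %||% ""))
    cmd <- paste(render_template(env_prefix, list(env_name = tool$env_name)), cmd)
  script <- file.path(dirname(log), "run.sh")
  write_lines_lf(c("#!/usr/bin/env bash", "set -o pipefail", cmd), script)
  status <- suppressWarnings(system2("bash", script, stdout = log, stderr = log))
  status
}

#' Register an annotation tool
#'
#' Stores the tool's configuration: a command template with placeholders
#' `{input_faa}`, `{input_fna}`, `{input_gff}`, `{output_tsv}`, `{workdir}`
#' (plus one placeholder per configuration parameter), the name of its
#' execution environment, and parameters. Re-registering under the same name
#' overwrites the previous configuration. Templates without `{output_tsv}`
#' are rejected.
#'
#' @param store a `gk_store` handle.
#' @param name unique tool name.
#' @param command_template shell command template.
#' @param env_name execution-environment label (used by the activation
#'   prefix, e.g. a conda environment name).
#' @param params named list of configuration parameters.
#' @param enabled whether the tool participates in pipeline runs.
#' @return the stored configuration, invisibly.
#' @export
register_tool <- function(store, name, command_template, env_name = "",
                          params = list(), enabled = TRUE) {
  if (!grepl("{output_tsv}", command_template, fixed = TRUE))
    stop("command_template must contain {output_tsv}")
  t <- store$tables
  t$tools <- t$tools[t$tools$name != name, ]
  t$tools <- rbind(t$tools, data.frame(
    name = name, env_name = env_name, command_template = command_template,
    params = as.character(jsonlite::toJSON(params, auto_unbox = TRUE)),
    enabled = enabled, stringsAsFactors = FALSE))
  store_commit(store, t)
  invisible(get_tool(store, name))
}

#' Retrieve a registered tool configuration
#'
#' @param store a `gk_store` handle.
#' @param name tool name.
#' @return list with `name`, `env_name`, `command_template`, `params`,
#'   `enabled`.
#' @export
get_tool <- function(store, name) {
  r <- store$tables$tools[store$tables$tools$name == name, ]
  if (!nrow(r)) stop("not found: tool ", name)
  list(name = r$name, env_name = r$env_name,
       command_template = r$command_template,
       params = jsonlite::fromJSON(r$params), enabled = r$enabled)
}

#' Validate an annotation TSV against the import contract
#'
#' The contract is a UTF-8 tab-separated file with header columns
#' `locus_tag`, `genome`, `source`, `key`, `value`, `note` (`#` comment
#' lines ignored). Checks the header, that every row names a known genome
#' and locus tag, and that key and value are non-empty.
#'
#' @param tsv path to the annotation TSV.
#' @param store a `gk_store` handle.
#' @return character vector of per-row diagnostics; empty means valid.
#' @export
validate_annotation_tsv <- function(tsv, store) {
  df <- tryCatch(read_tsv_chr(tsv), error = function(e) NULL)
  if (is.null(df)) {
    if (!file.exists(tsv)) return("fatal: file not readable")
    return(character(0))  # empty file: nothing to import, nothing invalid
  }
  if (!identical(sort_c(names(df)), sort_c(ANNOT_COLUMNS)))
    return(sprintf("fatal: header must be: %s",
                   paste(ANNOT_COLUMNS, collapse = ", ")))
  t <- store$tables
  diags <- character(0)
  gene_key <- paste(t$genes$genome_id, t$genes$locus_tag)
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (!r$genome %in% t$genomes$genome_id)
      diags <- c(diags, sprintf("row %d: unknown genome '%s'", i, r$genome))
    else if (!paste(r$genome, r$locus_tag) %in% gene_key)
      diags <- c(diags, sprintf("row %d: unknown locus_tag '%s' in genome '%s'",
                                i, r$locus_tag, r$genome))
    else if (!nzchar(r$key) || !nzchar(r$value))
      diags <- c(diags, sprintf("row %d: empty key or value", i))
  }
  diags
}

#' Import gene annotations from a TSV
#'
#' Imports rows satisfying the contract of [validate_annotation_tsv()].
#' Duplicate annotations — same (gene, source, key, value) — are counted as
#' skipped, not errors, so re-importing a file adds nothing.
#'
#' @param store a `gk_store` handle.
#' @param tsv path to the annotation TSV.
#' @param skip_bad_rows if `TRUE`, import valid rows even when some rows
#'   fail validation; otherwise any diagnostic aborts the import.
#' @return number of rows imported; attribute `"skipped"` counts duplicates
#'   and (when `skip_bad_rows`) invalid rows.
#' @export
import_annotation_tsv <- function(store, tsv, skip_bad_rows = FALSE) {
  diags <- validate_annotation_tsv(tsv, store)
  if (length(diags) && (!skip_bad_rows || any(grepl("^fatal", diags))))
    stop("annotation TSV invalid: ", paste(diags, collapse = "; "))
  df <- read_tsv_chr(tsv)
  if (is.null(df)) {
    res <- 0L; attr(res, "skipped") <- 0L; return(res)
  }
  bad_rows <- as.integer(sub("^row (\\d+):.*$", "\\1",
                             diags[grepl("^row", diags)]))
  t <- store$tables
  gid <- paste0(df$genome, ":", df$locus_tag)
  existing <- paste(t$annotations$gene_id, t$annotations$source,
                    t$annotations$key, t$annotations$value)
  n_imported <- 0L
  n_skipped <- 0L
  for (i in seq_len(nrow(df))) {
    if (i %in% bad_rows) { n_skipped <- n_skipped + 1L; next }
    key <- paste(gid[i], df$source[i], df$key[i], df$value[i])
    if (key %in% existing) { n_skipped <- n_skipped + 1L; next }
    existing <- c(existing, key)
    t$annotations <- rbind(t$annotations, data.frame(
      gene_id = gid[i], source = df$source[i], key = df$key[i],
      value = df$value[i], note = df$note[i], stringsAsFactors = FALSE))
    n_imported <- n_imported + 1L
  }
  if (n_imported > 0) store_commit(store, t)
  res <- n_imported
  attr(res, "skipped") <- n_skipped
  res
}

#' Run the annotation pipeline
#'
#' For each (genome, tool) pair in order: writes the tool inputs (protein
#' FASTA, nucleotide FASTA, GFF3) to a work directory, renders and executes
#' the tool command (optionally prefixed with an environment activation
#' line), validates the emitted annotation TSV and imports it atomically. A
#' failing job leaves the store unchanged for that job and does not abort
#' the remaining jobs. A job record is persisted either way.
#'
#' @param store a `gk_store` handle.
#' @param genome_ids genomes to annotate.
#' @param tools names of registered, enabled tools to run.
#' @param workdir_root scratch root; one subdirectory per job.
#' @param no_env if `TRUE`, run commands without environment activation
#'   (plain scripts, as in tests).
#' @param env_prefix activation prefix template (default
#'   `"conda run -n {env_name}"`).
#' @return data frame of job records (`job_id`, `tool`, `genome_id`,
#'   `status`, `log_path`, `n_imported`).
#' @export
run_pipeline <- function(store, genome_ids, tools,
                         workdir_root = tempfile("pipeline"),
                         no_env = FALSE,
                         env_prefix = "conda run -n {env_name}") {
  t0 <- store$tables
  missing <- setdiff(genome_ids, t0$genomes$genome_id)
  if (length(missing)) stop("not found: genome ", missing[1])
  cfgs <- lapply(tools, function(nm) get_tool(store, nm))
  cfgs <- Filter(function(cf) isTRUE(cf$enabled), cfgs)
  dir.create(workdir_root, recursive = TRUE, showWarnings = FALSE)
  jobs <- list()
  for (cf in cfgs) {
    for (gid in genome_ids) {
      job_id <- sprintf("job%05d", nrow(store$tables$jobs) + length(jobs) + 1L)
      wd <- file.path(workdir_root, paste0(cf$name, "_", gid))
      dir.create(wd, recursive = TRUE, showWarnings = FALSE)
      log <- file.path(wd, "job.log")
      paths <- export_tracks(store, gid, wd)
      out_tsv <- file.path(wd, "annotations.tsv")
      status <- run_tool_command(cf, list(input_faa = paths[["faa"]],
                                          input_fna = paths[["fna"]],
                                          input_gff = paths[["gff3"]],
                                          output_tsv = out_tsv, workdir = wd),
                                 log = log, no_env = no_env,
                                 env_prefix = env_prefix)
      n_imp <- NA_integer_
      st <- "failed"
      if (status == 0 && file.exists(out_tsv)) {
        diags <- validate_annotation_tsv(out_tsv, store)
        if (!length(diags)) {
          n_imp <- as.integer(import_annotation_tsv(store, out_tsv))
          st <- "done"
        } else {
          cat(diags, file = log, sep = "\n", append = TRUE)
        }
      }
      jobs[[length(jobs) + 1L]] <- data.frame(
        job_id = job_id, tool = cf$name, genome_id = gid, status = st,
        log_path = log, n_imported = n_imp, stringsAsFactors = FALSE)
      tt <- store$tables
      tt$jobs <- rbind(tt$jobs, jobs[[length(jobs)]])
      store_commit(store, tt)
    }
  }
  if (length(jobs)) do.call(rbind, jobs) else store$tables$jobs[0, ]
}
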