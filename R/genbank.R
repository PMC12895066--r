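# GenBank flat-file I/O. Column conventions of the format: feature keys start
# at column 6, locations and qualifiers at column 22; coordinates are 1-based
# inclusive and are converted to 0-based half-open on parse.

parse_location <- function(loc) {
  s <- gsub("\\s", "", loc)
  strand <- 1L
  while (grepl("^complement\\(", s)) {
    strand <- -strand
    s <- sub("^complement\\((.*)\\)$", "\\1", s)
  }
  if (grepl("^(join|order)\\(", s)) s <- sub("^(join|order)\\((.*)\\)$", "\\2", s)
  fuzzy <- grepl("[<>]", s)
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  st <- en <- integer(length(parts))
  for (i in seq_along(parts)) {
    p <- gsub("[<>]", "", parts[i])
    p <- sub("^complement\\((.*)\\)$", "\\1", p)
    if (grepl("\\.\\.", p)) {
      ab <- strsplit(p, "..", fixed = TRUE)[[1]]
      st[i] <- as.integer(ab[1]); en[i] <- as.integer(ab[2])
    } else {
      st[i] <- en[i] <- as.integer(p)
    }
  }
  if (anyNA(st) || anyNA(en) || any(st > en)) stop("unparseable location: ", loc)
  list(start = min(st) - 1L, end = max(en), strand = strand, fuzzy = fuzzy,
       parts = data.frame(start = st - 1L, end = en))
}

parse_qualifiers <- function(qlines) {
  # qlines: trimmed feature-block lines after the location line
  quals <- list()
  cur_key <- NULL
  cur_val <- NULL
  flush <- function() {
    if (!is.null(cur_key)) {
      v <- cur_val
      if (grepl('^"', v)) v <- gsub('"', "", v)
      quals[[length(quals) + 1L]] <<- list(key = cur_key, value = v)
    }
  }
  for (ln in qlines) {
    if (grepl("^/", ln)) {
      flush()
      m <- regmatches(ln, regexec("^/([A-Za-z0-9_]+)(=(.*))?$", ln))[[1]]
      cur_key <- m[2]
      cur_val <- if (length(m) >= 4 && nzchar(m[3])) m[4] else "true"
    } else if (!is.null(cur_key)) {
      # continuation: translations concatenate without a space, prose with one
      sep <- if (identical(cur_key, "translation")) "" else " "
      cur_val <- paste(cur_val, ln, sep = sep)
    }
  }
  flush()
  quals
}

qual_get <- function(quals, key) {
  for (q in quals) if (identical(q$key, key)) return(q$value)
  NULL
}

parse_genbank_record <- function(lines, warnings_env) {
  locus <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  contig_id <- locus[2]
  fstart <- which(grepl("^FEATURES", lines))[1]
  ostart <- which(grepl("^ORIGIN", lines))[1]
  if (is.na(ostart)) stop("parse failure: no ORIGIN in record ", contig_id)
  seq_lines <- lines[(ostart + 1L):length(lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("parse failure: empty sequence in ", contig_id)

  features <- list()
  if (!is.na(fstart)) {
    flines <- lines[(fstart + 1L):(ostart - 1L)]
    idx <- integer(0)
    for (i in seq_along(flines)) {
      ln <- flines[i]
      if (nchar(ln) >= 6 && substr(ln, 1, 5) == "     " &&
          substr(ln, 6, 6) != " ") idx <- c(idx, i)
    }
    idx <- c(idx, length(flines) + 1L)
    for (k in seq_len(length(idx) - 1L)) {
      block <- flines[idx[k]:(idx[k + 1L] - 1L)]
      head <- strsplit(trimws(block[1]), "\\s+")[[1]]
      ftype <- head[1]
      loc <- paste(head[-1], collapse = "")
      rest <- trimws(block[-1])
      # location may continue before the first qualifier line
      j <- 1L
      while (j <= length(rest) && !grepl("^/", rest[j])) {
        loc <- paste0(loc, rest[j]); j <- j + 1L
      }
      quals <- parse_qualifiers(rest[seq_along(rest) >= j])
      features[[length(features) + 1L]] <- list(type = ftype, location = loc,
                                                quals = quals)
    }
  }
  list(contig_id = contig_id, sequence = sequence, features = features)
}

#' Parse a GenBank flat file into a genome record
#'
#' Reads one or more LOCUS records (multi-record files become multi-contig
#' genomes). CDS features yield genes whose protein sequence is taken from
#' the `/translation` qualifier when present and otherwise translated from
#' the spliced nucleotide sequence with the bacterial code (translation table
#' 11, or the `/transl_table` qualifier when given); a trailing stop is
#' stripped. 1-based inclusive GenBank coordinates are converted to 0-based
#' half-open. `join()` locations are supported; features with fuzzy (`<`/`>`)
#' endpoints are imported with a warning and no translation re-derivation.
#' The `/organism` qualifier and `/db_xref="taxon:N"` of the source feature
#' are captured as a taxonomy hint.
#'
#' @param path path to a GenBank flat file.
#' @param genome_id identifier for the genome; defaults to the file stem.
#' @return a `genome_record` list with elements `genome_id`, `contigs`
#'   (data frame: contig_id, length, sequence), `genes` (data frame with
#'   0-based half-open coordinates, strand +/-1, feature_type, protein
#'   sequence and hash for CDS), `source_taxon` (list: name, taxon_id) and
#'   `warnings`.
#' @examples
#' gb <- system.file("extdata", "mini_genome.gbk", package = "genomekeeper")
#' rec <- parse_genbank(gb)
#' rec$genes[, c("locus_tag", "start", "end", "strand")]
#' @export
parse_genbank <- function(path, genome_id = NULL) {
  if (!file.exists(path)) stop("parse failure: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(grepl("^LOCUS", lines)))
    stop("parse failure: not a GenBank flat file: ", path)
  genome_id <- genome_id %||% sub("\\.(gb|gbk|gbff|genbank)$", "", basename(path))
  rec_bounds <- which(grepl("^//\\s*$", lines))
  starts <- which(grepl("^LOCUS", lines))
  warnings <- character(0)
  contigs <- list()
  genes <- list()
  taxon <- list(name = NA_character_, taxon_id = NA_character_)
  for (ri in seq_along(starts)) {
    endl <- rec_bounds[rec_bounds > starts[ri]][1]
    if (is.na(endl)) endl <- length(lines) + 1L
    rec <- parse_genbank_record(lines[starts[ri]:(endl - 1L)], NULL)
    contigs[[ri]] <- data.frame(contig_id = rec$contig_id,
                                length = nchar(rec$sequence),
                                sequence = rec$sequence,
                                stringsAsFactors = FALSE)
    feat_i <- 0L
    seen_tags <- character(0)
    for (f in rec$features) {
      if (f$type == "source") {
        org <- qual_get(f$quals, "organism")
        if (!is.null(org) && is.na(taxon$name)) taxon$name <- org
        for (q in f$quals) {
          if (identical(q$key, "db_xref") && grepl("^taxon:", q$value))
            taxon$taxon_id <- sub("^taxon:", "", q$value)
        }
        next
      }
      if (f$type %in% c("gene", "misc_feature", "repeat_region")) next
      ftype <- if (f$type %in% c("CDS", "tRNA", "rRNA")) f$type else "other"
      loc <- tryCatch(parse_location(f$location), error = function(e) NULL)
      if (is.null(loc)) {
        warnings <- c(warnings, sprintf("%s: skipped feature with location '%s'",
                                        rec$contig_id, f$location))
        next
      }
      feat_i <- feat_i + 1L
      tag <- qual_get(f$quals, "locus_tag") %||%
        sprintf("%s_f%04d", rec$contig_id, feat_i)
      if (ftype == "other" && tag %in% seen_tags) next
      seen_tags <- c(seen_tags, tag)
      prot <- NA_character_
      if (ftype == "CDS") {
        tr <- qual_get(f$quals, "translation")
        if (!is.null(tr)) {
          prot <- sub("\\*$", "", toupper(tr))
        } else if (loc$fuzzy) {
          warnings <- c(warnings, sprintf("%s: fuzzy CDS %s imported without protein",
                                          rec$contig_id, tag))
        } else {
          nt <- paste(substring(rec$sequence, loc$parts$start + 1L,
                                loc$parts$end), collapse = "")
          if (loc$strand == -1L) nt <- rev_comp(nt)
          tbl <- qual_get(f$quals, "transl_table") %||% "11"
          if (nchar(nt) %% 3 != 0 || nchar(nt) < 6) {
            warnings <- c(warnings, sprintf("%s: CDS %s has no clean coding sequence",
                                            rec$contig_id, tag))
          } else {
            aa <- translate_cds(nt, tbl)
            if (grepl("\\*", aa)) {
              warnings <- c(warnings, sprintf("%s: CDS %s has internal stop; protein omitted",
                                              rec$contig_id, tag))
            } else prot <- aa
          }
        }
        if (!is.na(prot) && loc$fuzzy)
          warnings <- c(warnings, sprintf("%s: fuzzy CDS %s kept with declared translation",
                                          rec$contig_id, tag))
      }
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = paste0(genome_id, ":", tag), genome_id = genome_id,
        contig_id = rec$contig_id, locus_tag = tag,
        start = loc$start, end = loc$end, strand = loc$strand,
        feature_type = ftype,
        name = qual_get(f$quals, "gene") %||% NA_character_,
        function_text = qual_get(f$quals, "product") %||% NA_character_,
        protein_seq = prot, stringsAsFactors = FALSE)
    }
  }
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(), genome_id = character(),
               contig_id = character(), locus_tag = character(),
               start = integer(), end = integer(), strand = integer(),
               feature_type = character(), name = character(),
               function_text = character(), protein_seq = character(),
               stringsAsFactors = FALSE)
  genes$protein_hash <- NA_character_
  has_prot <- !is.na(genes$protein_seq)
  if (any(has_prot)) genes$protein_hash[has_prot] <- md5_strings(genes$protein_seq[has_prot])
  structure(list(genome_id = genome_id,
                 contigs = do.call(rbind, contigs),
                 genes = genes, source_taxon = taxon, warnings = warnings),
            class = "genome_record")
}

# --- writer (used by the synthetic-collection generator and examples) ------

format_origin <- function(seq) {
  n <- nchar(seq)
  out <- character(0)
  for (off in seq(1L, n, by = 60L)) {
    chunk <- substring(seq, off, min(off + 59L, n))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", off, paste(blocks, collapse = " ")))
  }
  out
}

wrap_qual <- function(text, width = 58L) {
  out <- character(0)
  while (nchar(text) > width) {
    out <- c(out, substr(text, 1, width))
    text <- substr(text, width + 1L, nchar(text))
  }
  c(out, text)
}

#' Write a genome record as a GenBank flat file
#'
#' Serializes contigs and genes (0-based half-open coordinates converted back
#' to 1-based inclusive) with `/locus_tag`, `/product`, `/translation` and
#' `/transl_table=11` qualifiers, plus a source feature carrying the organism
#' name and taxon cross-reference.
#'
#' @param record a `genome_record` as returned by [parse_genbank()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  out <- character(0)
  for (ci in seq_len(nrow(record$contigs))) {
    ctg <- record$contigs[ci, ]
    out <- c(out, sprintf("LOCUS       %s %d bp    DNA     linear   BCT 01-JAN-2000",
                          ctg$contig_id, ctg$length),
             sprintf("DEFINITION  %s.", record$genome_id),
             "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", ctg$length))
    if (!is.na(record$source_taxon$name))
      out <- c(out, sprintf('                     /organism="%s"',
                            record$source_taxon$name))
    if (!is.na(record$source_taxon$taxon_id))
      out <- c(out, sprintf('                     /db_xref="taxon:%s"',
                            record$source_taxon$taxon_id))
    g <- record$genes[record$genes$contig_id == ctg$contig_id, , drop = FALSE]
    g <- g[order_c(g$start, g$locus_tag), , drop = FALSE]
    for (gi in seq_len(nrow(g))) {
      r <- g[gi, ]
      loc <- sprintf("%d..%d", r$start + 1L, r$end)
      if (r$strand == -1L) loc <- sprintf("complement(%s)", loc)
      out <- c(out, sprintf("     %-15s %s", r$feature_type, loc),
               sprintf('                     /locus_tag="%s"', r$locus_tag))
      if (!is.na(r$name))
        out <- c(out, sprintf('                     /gene="%s"', r$name))
      if (!is.na(r$function_text))
        out <- c(out, sprintf('                     /product="%s"', r$function_text))
      if (r$feature_type == "CDS" && !is.na(r$protein_seq)) {
        out <- c(out, "                     /transl_table=11")
        tl <- wrap_qual(sprintf('/translation="%s"', r$protein_seq))
        out <- c(out, paste0("                     ", tl))
      }
    }
    out <- c(out, "ORIGIN", format_origin(tolower(ctg$sequence)), "//")
  }
  write_lines_lf(out, path)
  invisible(path)
}
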