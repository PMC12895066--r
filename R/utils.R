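`%||%` <- function(a, b) if (is.null(a)) b else a

#' MD5 digest of character strings
#'
#' Computes the lowercase hexadecimal MD5 digest of the UTF-8 bytes of each
#' input string. Used to key deduplicated protein records.
#'
#' @param x character vector of non-empty strings.
#' @return character vector of 32-hex-character digests.
#' @keywords internal
md5_strings <- function(x) {
  stopifnot(is.character(x))
  if (!length(x)) return(character(0))
  dir <- tempfile("md5batch")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  files <- file.path(dir, sprintf("s%07d", seq_along(x)))
  for (i in seq_along(x)) {
    writeBin(charToRaw(enc2utf8(x[i])), files[i])
  }
  unname(tools::md5sum(files))
}

#' Hash a protein sequence
#'
#' Content hash used store-wide to deduplicate protein records: the lowercase
#' hex MD5 digest of the amino-acid sequence (uppercase, no stop character).
#'
#' @param sequence character vector of amino-acid sequences.
#' @return character vector of 32-hex-character digests.
#' @examples
#' protein_hash("MKT")
#' @export
protein_hash <- function(sequence) {
  if (!is.character(sequence) || any(is.na(sequence)) || any(!nzchar(sequence)))
    stop("empty protein")
  md5_strings(sequence)
}

# locale-independent sort / order (byte order, stable)
sort_c <- function(x) sort(x, method = "radix")
order_c <- function(...) order(..., method = "radix")

# read a TSV with '#' comment lines ignored; returns data.frame of characters
read_tsv_chr <- function(path, header = TRUE) {
  if (!file.exists(path)) stop("cannot open file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(NULL)
  con <- textConnection(lines)
  on.exit(close(con))
  utils::read.delim(con, header = header, colClasses = "character",
                    check.names = FALSE, quote = "", na.strings = NULL)
}

write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
}

# deterministic JSON writer used by exports
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
}

rev_comp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# translate a CDS nucleotide string with the given translation table
translate_cds <- function(nt, table = "11") {
  code <- Biostrings::getGeneticCode(as.character(table))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                           genetic.code = code,
                                           if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}
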