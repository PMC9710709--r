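#' Read sequences from FASTA or FASTQ
#'
#' Format (FASTA vs FASTQ) and compression (plain vs gzip) are auto-detected
#' from the file content.  Sequences are uppercased; record ids are the
#' header up to the first whitespace, de-duplicated with a numeric suffix and
#' a warning when repeated.
#'
#' @param path input file.
#' @return named character vector of sequences, in file order.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  con <- gzfile(path, "rb")
  first <- tryCatch(rawToChar(readBin(con, "raw", 1L)),
                    error = function(e) "")
  close(con)
  if (!length(first) || !nzchar(first))
    stop("empty or unreadable input: ", path)
  fmt <- if (first == ">") "fasta" else if (first == "@") "fastq" else
    stop("unrecognized sequence format (expected FASTA or FASTQ): ", path)
  set <- Biostrings::readDNAStringSet(path, format = fmt)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    warning("duplicate record ids in ", path, "; de-duplicating with suffixes")
    ids <- make.unique(ids, sep = "_")
  }
  stats::setNames(unname(seqs), ids)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output file (gzipped iff the name ends in `.gz`).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write sequences as FASTQ (constant placeholder qualities)
#'
#' @inheritParams write_fasta
#' @export
write_fastq <- function(seqs, path) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  for (k in seq_along(seqs)) {
    writeLines(c(paste0("@", names(seqs)[k]), seqs[[k]], "+",
                 strrep("I", nchar(seqs[[k]]))), con)
  }
  invisible(path)
}

#' Write an SFS table as TSV
#'
#' Columns `sequence`, `count`, `canonical`, in the table's deterministic
#' order (descending count, then sequence).
#'
#' @param table an `sfs_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sfs_tsv <- function(table, path) {
  stopifnot(inherits(table, "sfs_table"))
  utils::write.table(as.data.frame(table)[c("sequence", "count", "canonical")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an SFS table written by [write_sfs_tsv()]
#'
#' @param path TSV file.
#' @return an `sfs_table`.
#' @export
read_sfs_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "character"))
  as_sfs_table(df, tau = NULL)
}

#' Write an SFS table as FASTA
#'
#' Headers are `>sfs_<rank>#<count>` in table order.
#'
#' @inheritParams write_sfs_tsv
#' @export
write_sfs_fasta <- function(table, path) {
  stopifnot(inherits(table, "sfs_table"))
  seqs <- stats::setNames(table$sequence,
                          sprintf("sfs_%d#%d", seq_len(nrow(table)),
                                  table$count))
  write_fasta(seqs, path)
}

# BED-like per-emission file: target_id, begin, end, sequence (0-based,
# half-open).
write_emissions_tsv <- function(emissions, path) {
  utils::write.table(emissions[c("target_id", "begin", "end", "sequence")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_emissions_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
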