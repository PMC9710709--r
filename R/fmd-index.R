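#' Build an FMD-index over a DNA string collection
#'
#' Indexes a collection of DNA strings together with (by default) the reverse
#' complement of every string, supporting constant-time backward and forward
#' bi-interval extension.  Sequences are uppercased and split at maximal runs
#' of non-A/C/G/T characters into fragments before indexing; a sequence left
#' with no A/C/G/T content is skipped with a warning.
#'
#' @param sequences character vector of DNA sequences (optionally named).
#' @param strand_mode `"both"` (default) indexes each string and its reverse
#'   complement, the FMD construction; `"single"` indexes only the given
#'   strands (a plain bidirectional FM-index), useful when reverse-complement
#'   membership must not interfere, e.g. when studying the edit-distance
#'   bound of the relaxed search on a plain string pair.
#' @return an object of class `FMDIndex`.
#' @seealso [occurs()], [init_interval()], [backward_extension()],
#'   [forward_extension()], [save_index()]
#' @export
#' @examples
#' idx <- build_index(c("ACGTACGT", "TTTTACGT"))
#' occurs(idx, "GTAC")
build_index <- function(sequences, strand_mode = c("both", "single")) {
  strand_mode <- match.arg(strand_mode)
  if (length(sequences) == 0L) stop("nothing to index")
  frag <- dna_fragments(sequences)
  kept <- if (is.null(frag)) integer(0) else unique(frag$seq_index)
  dropped <- setdiff(seq_along(sequences), kept)
  if (length(dropped)) {
    warning(length(dropped), " sequence(s) with no A/C/G/T content skipped: ",
            paste(utils::head(if (is.null(names(sequences)))
              as.character(dropped) else names(sequences)[dropped], 5L),
              collapse = ", "))
  }
  if (is.null(frag) || nrow(frag) == 0L) stop("nothing to index")
  raw <- cpp_build_fmd(frag$fragment, strand_mode == "both")
  new_fmd_index(raw, n_input = length(kept))
}

new_fmd_index <- function(raw, n_input) {
  counts <- cpp_symbol_counts(raw$bwt)
  idx <- list(
    bwt = raw$bwt,
    occ = raw$occ,
    rbwt = raw$rbwt,
    rocc = raw$rocc,
    C = as.integer(c(0L, cumsum(counts))),
    strand_mode = raw$strand_mode,
    n_sequences = raw$n_sequences,
    n_input = n_input
  )
  class(idx) <- "FMDIndex"
  idx
}

#' @export
print.FMDIndex <- function(x, ...) {
  cat("FMDIndex:", x$n_sequences, "indexed fragments from", x$n_input,
      "input sequence(s);", length(x$bwt), "BWT symbols; strand mode:",
      x$strand_mode, "\n")
  invisible(x)
}

assert_index <- function(index) {
  if (!inherits(index, "FMDIndex")) stop("not an FMDIndex object")
  invisible(index)
}

sym_code <- function(symbol) {
  code <- match(symbol, c("A", "C", "G", "T"))
  if (length(symbol) != 1L || is.na(code))
    stop("invalid symbol (expected one of A, C, G, T)")
  code
}

#' Bi-interval of a single character
#'
#' Initializes the bi-interval `[i, j, l]` of a length-1 string: `i` is the
#' start of the Q-interval in the generalized suffix array, `j` the start of
#' the paired (reverse-complement) interval and `l` the shared width, i.e.
#' the number of occurrences across the indexed text.
#'
#' @param index an [FMDIndex][build_index].
#' @param symbol a single character, one of `A`, `C`, `G`, `T`.
#' @return a named integer vector `c(i, j, l)` of class `bi_interval`.
#' @export
init_interval <- function(index, symbol) {
  assert_index(index)
  bi(cpp_init(unclass(index), sym_code(symbol)))
}

bi <- function(v) {
  v <- as.integer(v)
  names(v) <- c("i", "j", "l")
  class(v) <- "bi_interval"
  v
}

#' @export
print.bi_interval <- function(x, ...) {
  cat(sprintf("bi-interval [i=%d, j=%d, l=%d]\n", x[["i"]], x[["j"]], x[["l"]]))
  invisible(x)
}

#' Width of a bi-interval
#'
#' The shared width `l`, equal to the number of occurrences of the
#' represented string in the indexed text (0 means absent).
#'
#' @param interval a `bi_interval`.
#' @return integer occurrence count.
#' @export
interval_width <- function(interval) {
  stopifnot(inherits(interval, "bi_interval"))
  interval[["l"]]
}

#' Backward (prepend) extension of a bi-interval
#'
#' Turns the bi-interval of a string `Q` into the bi-interval of `sigma Q`.
#' The width can only shrink; extending an empty interval stays empty.
#'
#' @inheritParams init_interval
#' @param interval the `bi_interval` of `Q`.
#' @param symbol the character `sigma` to prepend.
#' @return the `bi_interval` of `sigma Q`.
#' @export
backward_extension <- function(index, interval, symbol) {
  assert_index(index)
  stopifnot(inherits(interval, "bi_interval"))
  bi(cpp_extend(unclass(index), unclass(interval), sym_code(symbol), FALSE))
}

#' Forward (append) extension of a bi-interval
#'
#' Turns the bi-interval of a string `Q` into the bi-interval of `Q sigma`,
#' implemented as a backward extension of the complement symbol on the paired
#' interval with the two interval roles swapped.
#'
#' @inheritParams backward_extension
#' @return the `bi_interval` of `Q sigma`.
#' @export
forward_extension <- function(index, interval, symbol) {
  assert_index(index)
  stopifnot(inherits(interval, "bi_interval"))
  bi(cpp_extend(unclass(index), unclass(interval), sym_code(symbol), TRUE))
}

#' Substring membership in the indexed collection
#'
#' @inheritParams init_interval
#' @param s a non-empty A/C/G/T string.
#' @return `TRUE` iff `s` occurs in some indexed string (or a reverse
#'   complement when `strand_mode = "both"`).
#' @export
occurs <- function(index, s) {
  count_occurrences(index, s) > 0L
}

#' Occurrence count of a string in the index
#'
#' The width of the final bi-interval after chained backward extensions over
#' `s`; counts overlapping occurrences over all indexed strings (and reverse
#' complements when `strand_mode = "both"`).
#'
#' @inheritParams occurs
#' @return non-negative integer.
#' @export
count_occurrences <- function(index, s) {
  assert_index(index)
  assert_acgt(toupper(s), "query")
  cpp_match_width(unclass(index), toupper(s))
}

INDEX_MAGIC <- "SFSTIDX1"
INDEX_VERSION <- 1L

#' Serialize an FMD-index to a file
#'
#' Single binary file with a versioned magic header; [load_index()] restores
#' an index answering every query identically.
#'
#' @param index an [FMDIndex][build_index].
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
save_index <- function(index, path) {
  assert_index(index)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(INDEX_MAGIC), con)
  meta <- c(INDEX_VERSION,
            if (index$strand_mode == "both") 1L else 0L,
            index$n_sequences, index$n_input,
            length(index$bwt),
            if (is.null(index$rbwt)) 0L else length(index$rbwt))
  writeBin(as.integer(meta), con, size = 4L, endian = "little")
  writeBin(index$bwt, con)
  if (!is.null(index$rbwt)) writeBin(index$rbwt, con)
  invisible(path)
}

#' Load a serialized FMD-index
#'
#' @param path file written by [save_index()].
#' @return an [FMDIndex][build_index].
#' @export
load_index <- function(path) {
  if (!file.exists(path)) stop("index file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", nchar(INDEX_MAGIC)))
  if (!identical(magic, INDEX_MAGIC))
    stop("not an sfstools index file (bad magic): ", path)
  meta <- readBin(con, "integer", 6L, size = 4L, endian = "little")
  if (length(meta) < 6L) stop("corrupt index file (truncated header): ", path)
  if (meta[1] != INDEX_VERSION)
    stop("unsupported index file version ", meta[1], ": ", path)
  bwt <- readBin(con, "raw", meta[5])
  if (length(bwt) != meta[5]) stop("corrupt index file (truncated): ", path)
  raw <- list(bwt = bwt, occ = cpp_occ_build(bwt),
              strand_mode = if (meta[2] == 1L) "both" else "single",
              n_sequences = meta[3], rbwt = NULL, rocc = NULL)
  if (meta[6] > 0L) {
    rbwt <- readBin(con, "raw", meta[6])
    if (length(rbwt) != meta[6]) stop("corrupt index file (truncated): ", path)
    raw$rbwt <- rbwt
    raw$rocc <- cpp_occ_build(rbwt)
  }
  new_fmd_index(raw, n_input = meta[4])
}
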