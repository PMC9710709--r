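#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA strings (A/C/G/T and IUPAC codes).
#' @return character vector of reverse complements, names dropped.
#' @export
#' @examples
#' rc(c("ACGT", "AAAC"))
rc <- function(x) {
  if (!length(x)) return(character(0))
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

#' Canonical form of DNA strings
#'
#' The lexicographic minimum of a string and its reverse complement; used as
#' the strand-agnostic key when counting specific strings.
#'
#' @param x character vector of A/C/G/T strings.
#' @return character vector of canonical forms.
#' @export
canonical_sequence <- function(x) {
  if (!length(x)) return(character(0))
  r <- rc(x)
  ifelse(x <= r, x, r)
}

# Split sequences into maximal A/C/G/T-only fragments (uppercasing first).
# Returns a data.frame with one row per fragment: seq_index, id, offset
# (0-based start of the fragment on the original sequence) and fragment.
dna_fragments <- function(sequences, ids = names(sequences)) {
  if (is.null(ids)) ids <- paste0("seq_", seq_along(sequences))
  up <- toupper(sequences)
  m <- gregexpr("[ACGT]+", up)
  out <- lapply(seq_along(up), function(k) {
    starts <- m[[k]]
    if (starts[1] == -1L) return(NULL)
    lens <- attr(starts, "match.length")
    data.frame(seq_index = k, id = ids[k], offset = as.integer(starts) - 1L,
               fragment = substring(up[k], starts, starts + lens - 1L),
               stringsAsFactors = FALSE)
  })
  out <- Filter(Negate(is.null), out)
  if (!length(out)) return(NULL)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

assert_acgt <- function(x, what = "sequence") {
  if (length(x) != 1L || is.na(x) || !nzchar(x))
    stop("empty ", what, call. = FALSE)
  if (grepl("[^ACGT]", x))
    stop("invalid symbol in ", what, " (expected A/C/G/T only)", call. = FALSE)
  invisible(x)
}

# Seeded evaluation that restores the caller's RNG state afterwards, so all
# simulator randomness flows from explicit seed arguments.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic substream seeds derived from one user seed (kept < 2^31).
substream_seed <- function(seed, stream) {
  offs <- c(genome = 11L, variants = 23L, reads = 37L, errors = 53L)
  if (!stream %in% names(offs)) stop("unknown seed substream: ", stream)
  (as.integer(seed) %% 1000000000L) * 2L + offs[[stream]]
}
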