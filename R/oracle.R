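#' Brute-force specific-string oracle
#'
#' Reference solver for the substring-free sample-specific string problem on
#' small instances, used to validate the index-based search.  It enumerates
#' every substring of the references (plus reverse complements when
#' `strand_mode = "both"`) into a hash set, takes the substrings of `t`
#' absent from that set, and keeps the minimal ones: a string is in the
#' solution iff it is absent while both of its one-shorter substrings occur
#' in the references (length-1 absent strings are always minimal).
#'
#' @param t target A/C/G/T string.
#' @param refs character vector of reference A/C/G/T strings.
#' @param strand_mode `"both"` or `"single"`, matching [build_index()].
#' @param max_total size guard on `nchar(t) + sum(nchar(refs))`; the oracle
#'   is cubic and test-only.
#' @return sorted character vector: the distinct `t`-specific strings.
#' @export
#' @examples
#' oracle_sfs("ACGT", c("ACG", "CGT"), strand_mode = "single")
oracle_sfs <- function(t, refs, strand_mode = c("both", "single"),
                       max_total = 2000L) {
  strand_mode <- match.arg(strand_mode)
  t <- toupper(t)
  assert_acgt(t, "target")
  total <- nchar(t) + sum(nchar(refs))
  if (total > max_total)
    stop("instance too large for the brute-force oracle (", total, " > ",
         max_total, " characters)")
  universe <- substring_universe(refs, strand_mode, cap = nchar(t))
  cand <- unique(all_substrings(t, nchar(t)))
  absent <- cand[!(cand %in% universe)]
  if (!length(absent)) return(character(0))
  len <- nchar(absent)
  left <- substr(absent, 1L, len - 1L)
  right <- substr(absent, 2L, len)
  minimal <- len == 1L | (!(left %in% absent) & !(right %in% absent))
  sort(absent[minimal])
}

#' Brute-force occurrence count
#'
#' Sliding-window occurrence count of `q` over all reference strings (plus
#' reverse complements when `strand_mode = "both"`); overlapping occurrences
#' count individually, matching suffix-array interval width semantics.
#'
#' @param q query A/C/G/T string.
#' @inheritParams oracle_sfs
#' @return non-negative integer.
#' @export
oracle_occurrence_count <- function(q, refs, strand_mode = c("both", "single")) {
  strand_mode <- match.arg(strand_mode)
  q <- toupper(q)
  assert_acgt(q, "query")
  refs2 <- if (strand_mode == "both") c(refs, rc(refs)) else refs
  m <- nchar(q)
  sum(vapply(refs2, function(s) {
    n <- nchar(s)
    if (m > n) return(0L)
    starts <- seq_len(n - m + 1L)
    sum(substring(s, starts, starts + m - 1L) == q)
  }, integer(1)))
}

# All substrings of one string up to length `cap` (with duplicates).
all_substrings <- function(x, cap) {
  n <- nchar(x)
  if (n == 0L) return(character(0))
  unlist(lapply(seq_len(min(cap, n)), function(len) {
    starts <- seq_len(n - len + 1L)
    substring(x, starts, starts + len - 1L)
  }), use.names = FALSE)
}

substring_universe <- function(refs, strand_mode, cap) {
  refs2 <- if (strand_mode == "both") c(refs, rc(toupper(refs)))
           else toupper(refs)
  unique(unlist(lapply(refs2, all_substrings, cap = cap), use.names = FALSE))
}

# Independent second construction used by the property tests: for each start
# position of t, binary-search the shortest prefix absent from the references
# (absence decided by fixed-string grepl, not the hash set), then drop
# candidates whose interval properly contains another candidate's interval.
oracle_sfs_per_start <- function(t, refs, strand_mode = c("both", "single")) {
  strand_mode <- match.arg(strand_mode)
  t <- toupper(t)
  refs2 <- if (strand_mode == "both") c(toupper(refs), rc(toupper(refs)))
           else toupper(refs)
  present <- function(s) any(grepl(s, refs2, fixed = TRUE))
  n <- nchar(t)
  b <- integer(0); e <- integer(0)
  for (start in seq_len(n)) {
    maxlen <- n - start + 1L
    if (present(substring(t, start, start + maxlen - 1L))) next
    lo <- 1L; hi <- maxlen # shortest absent prefix length in [lo, hi]
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (present(substring(t, start, start + mid - 1L))) lo <- mid + 1L
      else hi <- mid
    }
    b <- c(b, start); e <- c(e, start + lo - 1L)
  }
  if (!length(b)) return(character(0))
  dominated <- vapply(seq_along(b), function(k)
    any(b >= b[k] & e <= e[k] & (b > b[k] | e < e[k])), logical(1))
  sort(unique(substring(t, b[!dominated], e[!dominated])))
}
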