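# Shared fixtures and independent mini-oracles for the test suite.
# Everything here is deliberately naive: scans, dynamic programming and hash
# sets that do not share any code path with the index-based implementation.

BASES <- c("A", "C", "G", "T")

rnd_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

rnd_collection <- function(max_strings = 6L, max_len = 100L, min_len = 5L) {
  k <- sample.int(max_strings, 1L)
  vapply(seq_len(k), function(i) rnd_dna(sample(min_len:max_len, 1L)),
         character(1))
}

rc_naive <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# Sliding-window occurrence count over a set of strings (overlaps counted).
naive_count <- function(q, strings) {
  m <- nchar(q)
  sum(vapply(strings, function(s) {
    n <- nchar(s)
    if (m > n) return(0L)
    starts <- seq_len(n - m + 1L)
    sum(substring(s, starts, starts + m - 1L) == q)
  }, integer(1)))
}

indexed_strings <- function(refs, strand_mode) {
  if (strand_mode == "both") c(refs, vapply(refs, rc_naive, character(1)))
  else refs
}

# Quadratic DP Levenshtein, the oracle for edit_distance().
naive_edit <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  d <- matrix(0L, length(x) + 1L, length(y) + 1L)
  d[, 1] <- 0:length(x)
  d[1, ] <- 0:length(y)
  for (i in seq_along(x)) {
    for (j in seq_along(y)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (x[i] != y[j]))
    }
  }
  d[length(x) + 1L, length(y) + 1L]
}

# Plant k isolated substitutions into r, spaced widely enough that each is
# its own edit and its own relaxed emission (used for tightness cases).
plant_substitutions <- function(r, k, min_gap = 25L) {
  n <- nchar(r)
  pos <- round(seq(min_gap, n - min_gap, length.out = k))
  stopifnot(all(diff(pos) >= min_gap))
  t <- strsplit(r, "", fixed = TRUE)[[1]]
  for (p in pos) t[p] <- sample(setdiff(BASES, t[p]), 1L)
  paste(t, collapse = "")
}

expect_sfs_invariants <- function(emissions, t, index) {
  # specificity: each emission is a substring of t at its interval and is
  # absent from the index
  if (!nrow(emissions)) return(invisible(NULL))
  expect_identical(substring(t, emissions$begin + 1L, emissions$end),
                   emissions$sequence)
  expect_false(any(vapply(unique(emissions$sequence),
                          function(s) occurs(index, s), logical(1))))
}
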