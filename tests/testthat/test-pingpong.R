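test_that("exact search on spec'd tiny instances", {
  for (mode in c("both", "single")) {
    idx <- build_index("ACGT", strand_mode = mode)
    expect_identical(nrow(ping_pong_exact("ACGT", idx)), 0L)
  }
  single <- build_index("TTTT", strand_mode = "single")
  expect_setequal(unique(ping_pong_exact("ACGT", single)$sequence),
                  c("A", "C", "G"))
  both <- build_index("TTTT", strand_mode = "both")
  expect_setequal(unique(ping_pong_exact("ACGT", both)$sequence),
                  c("C", "G"))
  expect_error(ping_pong_exact("", both), "empty")
  expect_error(ping_pong_exact("ACNGT", both), "invalid symbol")
})

test_that("exact search equals the brute-force oracle on random instances", {
  set.seed(31)
  for (it in 1:60) {
    t <- rnd_dna(sample(10:150, 1L))
    refs <- rnd_collection(max_strings = 8L, max_len = 150L, min_len = 8L)
    mode <- if (it %% 2L) "both" else "single"
    idx <- build_index(refs, strand_mode = mode)
    em <- ping_pong_exact(t, idx)
    expect_identical(sort(unique(em$sequence)),
                     oracle_sfs(t, refs, strand_mode = mode))
    expect_sfs_invariants(em, t, idx)
    # per-start uniqueness: no two emissions share a begin position
    expect_false(anyDuplicated(em$begin) > 0L)
    # substring-freeness of the distinct output
    u <- unique(em$sequence)
    for (s in u) {
      expect_false(any(vapply(setdiff(u, s), grepl, logical(1), x = s,
                              fixed = TRUE)))
    }
  }
})

test_that("relaxed search: specific, disjoint, within the exact solution", {
  set.seed(32)
  for (it in 1:50) {
    t <- rnd_dna(sample(10:150, 1L))
    refs <- rnd_collection(max_strings = 6L, max_len = 150L, min_len = 8L)
    mode <- if (it %% 2L) "both" else "single"
    idx <- build_index(refs, strand_mode = mode)
    em <- ping_pong_relaxed(t, idx)
    expect_sfs_invariants(em, t, idx)
    full <- oracle_sfs(t, refs, strand_mode = mode)
    expect_true(all(em$sequence %in% full))
    if (nrow(em) > 1L) {
      o <- order(em$begin)
      expect_true(all(em$end[o][-nrow(em)] <= em$begin[o][-1]))
    }
    # extension budget: at most two index queries per symbol
    expect_lte(attr(em, "n_extensions"), 2L * nchar(t))
  }
})

test_that("relaxed output size is bounded by the edit distance", {
  set.seed(33)
  for (it in 1:40) {
    r <- rnd_dna(sample(50:300, 1L))
    # mutate r lightly so the pair stays related
    t <- r
    for (dummy in seq_len(sample.int(6L, 1L))) {
      p <- sample.int(nchar(t), 1L)
      t <- paste0(substr(t, 1, p - 1L),
                  sample(BASES, 1L), substr(t, p + 1L, nchar(t)))
    }
    idx <- build_index(r, strand_mode = "single")
    em <- ping_pong_relaxed(t, idx)
    expect_lte(nrow(em), edit_distance(t, r))
  }
})

test_that("edit_distance matches the DP oracle", {
  expect_identical(edit_distance("ACGT", "ACGT"), 0L)
  expect_identical(edit_distance("ACGT", "ACGA"), 1L)
  expect_identical(edit_distance("", "ACG"), 3L)
  set.seed(34)
  for (it in 1:30) {
    a <- rnd_dna(sample.int(40L, 1L))
    b <- rnd_dna(sample.int(40L, 1L))
    expect_identical(edit_distance(a, b), naive_edit(a, b))
  }
})

test_that("search_collection tabulates canonically and additively", {
  set.seed(35)
  t <- rnd_dna(60)
  refs <- rnd_collection(max_strings = 4L, max_len = 60L)
  idx <- build_index(refs, strand_mode = "both")
  one <- search_collection(c(a = t), idx)
  expect_s3_class(one, "sfs_table")
  if (nrow(one)) {
    expect_true(all(one$canonical == canonical_sequence(one$sequence)))
    # same read twice: every count doubles
    two <- search_collection(c(a = t, b = t), idx)
    expect_identical(two$canonical, one$canonical)
    expect_identical(two$count, 2L * one$count)
    # a read plus its reverse complement: counts double via canonicalization
    rcpair <- search_collection(c(a = t, b = rc(t)), idx)
    expect_identical(rcpair[order(rcpair$canonical), ]$count,
                     2L * one[order(one$canonical), ]$count)
  }
  # chunked processing is invisible in the output
  four <- search_collection(setNames(rep(t, 5), letters[1:5]), idx,
                            chunks = 4L)
  seq_ <- search_collection(setNames(rep(t, 5), letters[1:5]), idx,
                            chunks = 1L)
  expect_identical(four, seq_)
  # targets with non-ACGT runs are split with original coordinates kept
  spiky <- paste0(substr(t, 1, 20), "NN", substr(t, 21, 60))
  em <- attr(search_collection(c(s = spiky), idx, keep_emissions = TRUE),
             "emissions")
  if (nrow(em)) {
    expect_identical(substring(spiky, em$begin + 1L, em$end), em$sequence)
  }
  expect_error(search_collection(character(0), idx), "empty")
})

test_that("abundance filtering and aggregation", {
  tab <- sfstools:::as_sfs_table(data.frame(
    sequence = c("AAAC", "GGGT"), count = c(7L, 4L),
    canonical = canonical_sequence(c("AAAC", "GGGT")),
    stringsAsFactors = FALSE))
  expect_identical(filter_by_abundance(tab, 5)$sequence, "AAAC")
  expect_identical(nrow(filter_by_abundance(tab, 8)), 0L)
  t1 <- filter_by_abundance(tab, 1)
  expect_identical(t1$sequence, tab$sequence)
  expect_identical(t1$count, tab$count)
  expect_error(filter_by_abundance(tab, 0), "positive")
  merged <- aggregate_tables(tab, tab)
  expect_identical(sort(merged$count), c(8L, 14L))
  expect_identical(aggregate_tables(tab, tab, tau = 10L)$count, 14L)
})

test_that("deterministic output ordering: count desc, then sequence", {
  tab <- sfstools:::as_sfs_table(data.frame(
    sequence = c("TTTG", "AAAC", "CCCA"), count = c(3L, 5L, 3L),
    canonical = canonical_sequence(c("TTTG", "AAAC", "CCCA")),
    stringsAsFactors = FALSE))
  expect_identical(tab$sequence, c("AAAC", "CCCA", "TTTG"))
})
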