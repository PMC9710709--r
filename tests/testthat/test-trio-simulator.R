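test_that("genome generation is seeded and roughly uniform", {
  expect_error(generate_genome(100), "at least 1000")
  g1 <- generate_genome(5000, seed = 1)
  expect_identical(g1, generate_genome(5000, seed = 1))
  expect_false(identical(g1, generate_genome(5000, seed = 2)))
  big <- generate_genome(100000, seed = 3)
  comp <- table(strsplit(big, "", fixed = TRUE)[[1]]) / nchar(big)
  expect_true(all(abs(comp - 0.25) < 0.02))
})

test_that("trio construction: counts, conservation, disjointness", {
  g <- generate_genome(30000, seed = 5)
  trio <- make_trio(g, n_inherited = 12, n_denovo = 21,
                    sv_size_range = c(50, 200), seed = 5)
  vars <- trio$variants
  dn <- vars[vars$origin == "de_novo", ]
  # de novo kinds equally divided (21 -> 7/7/7)
  expect_identical(sort(as.integer(table(dn$kind))), c(7L, 7L, 7L))
  expect_identical(sum(vars$origin != "de_novo"), 12L)

  # length conservation per haplotype: + insertions - deletions
  plc <- trio$placements
  for (nm in names(trio$haplotypes)) {
    p <- plc[plc$haplotype == nm, ]
    v <- vars[match(p$variant_id, vars$variant_id), ]
    delta <- sum(ifelse(v$kind == "insertion", v$length,
                        ifelse(v$kind == "deletion", -v$length, 0L)))
    expect_identical(nchar(trio$haplotypes[[nm]]), nchar(g) + delta)
  }

  # truth-set disjointness on each haplotype (assert, don't assume)
  for (nm in unique(plc$haplotype)) {
    p <- plc[plc$haplotype == nm, ]
    p <- p[order(p$hap_start), ]
    if (nrow(p) > 1L) {
      expect_true(all(p$hap_end[-nrow(p)] <= p$hap_start[-1]))
    }
  }

  # de novo variants sit on child haplotypes only
  expect_true(all(grepl("^child_", plc$haplotype[plc$origin == "de_novo"])))

  # seeded determinism
  trio2 <- make_trio(g, n_inherited = 12, n_denovo = 21,
                     sv_size_range = c(50, 200), seed = 5)
  expect_identical(trio$haplotypes, trio2$haplotypes)
})

test_that("without recombination the child copies a parent outside de novo SVs", {
  g <- generate_genome(20000, seed = 6)
  trio <- make_trio(g, n_inherited = 8, n_denovo = 6,
                    sv_size_range = c(50, 150), seed = 6)
  # strip de novo intervals from a child haplotype: the remainder must be a
  # subsequence reconstruction of one parental haplotype
  for (side in 1:2) {
    nm <- paste0("child_", side)
    child <- trio$haplotypes[[nm]]
    plc <- trio$placements
    dn <- plc[plc$haplotype == nm & plc$origin == "de_novo", ]
    dn <- dn[order(dn$hap_start), ]
    keep <- character(0)
    cur <- 0L
    for (k in seq_len(nrow(dn))) {
      keep <- c(keep, substr(child, cur + 1L, dn$hap_start[k]))
      cur <- dn$hap_end[k]
    }
    keep <- c(keep, substr(child, cur + 1L, nchar(child)))
    stripped <- paste(keep, collapse = "")
    parents <- trio$haplotypes[grep(
      if (side == 1L) "^father" else "^mother", names(trio$haplotypes))]
    # stripping de novo insertions restores parental content; deletions and
    # inversions leave scars, so require exact identity only when none occurred
    if (all(dn$kind == "insertion") || nrow(dn) == 0L) {
      expect_true(stripped %in% parents)
    } else {
      # at minimum, large flanks around the first variant match a parent
      expect_true(any(vapply(parents, function(p)
        identical(substr(p, 1, dn$hap_start[1]),
                  substr(stripped, 1, dn$hap_start[1])), logical(1))))
    }
  }
})

test_that("liftover round-trips outside variant intervals", {
  g <- generate_genome(20000, seed = 7)
  trio <- make_trio(g, n_inherited = 10, n_denovo = 9, seed = 7,
                    sv_size_range = c(50, 150))
  set.seed(7)
  for (nm in names(trio$haplotypes)) {
    hl <- nchar(trio$haplotypes[[nm]])
    pos <- sample.int(hl, 200L) - 1L
    ref <- hap_to_ref(trio, nm, pos)
    ok <- !is.na(ref)
    expect_gt(sum(ok), 0L)
    back <- ref_to_hap(trio, nm, ref[ok])
    expect_identical(back, pos[ok])
  }
  expect_error(hap_to_ref(trio, "nope", 1L), "unknown haplotype")
})

test_that("read simulation: determinism, coverage, exact slices", {
  hap <- c(h1 = generate_genome(100000, seed = 8))
  reads <- simulate_reads(hap, coverage = 20, seed = 8)
  reads2 <- simulate_reads(hap, coverage = 20, seed = 8)
  expect_identical(reads, reads2)
  # realized coverage within 5% of requested
  expect_lt(abs(sum(nchar(reads$sequence)) / 1e5 - 20) / 20, 0.05)
  # error-free reads are exact haplotype slices (up to reverse complement)
  set.seed(8)
  for (k in sample.int(nrow(reads), 25L)) {
    slice <- substr(hap[[1]], reads$hap_begin[k] + 1L, reads$hap_end[k])
    if (reads$strand[k] == "-") slice <- rc(slice)
    expect_identical(reads$sequence[k], slice)
  }
  expect_identical(sum(reads$errors_injected), 0L)
  # error injection actually perturbs sequences at roughly the right rate
  noisy <- simulate_reads(hap, coverage = 5, error_rate = 0.01, seed = 9)
  expect_gt(sum(noisy$errors_injected), 0L)
  rate <- sum(noisy$errors_injected) / sum(noisy$hap_end - noisy$hap_begin)
  expect_lt(abs(rate - 0.01), 0.005)
  expect_error(simulate_reads(hap, coverage = 0), "positive")
  expect_error(simulate_reads(hap, coverage = 5, error_rate = 0.5),
               "error_rate")
})

test_that("variant_overlap decides coverage by lifted coordinates", {
  g <- generate_genome(20000, seed = 10)
  trio <- make_trio(g, n_inherited = 0, n_denovo = 3,
                    sv_size_range = c(60, 120), seed = 10)
  plc <- trio$placements[trio$placements$origin == "de_novo", ]
  ins <- plc[plc$kind == "insertion", ][1, ]
  hap <- trio$haplotypes[[ins$haplotype]]
  # fabricate a read covering the insertion and an emission inside it
  rb <- max(0L, ins$hap_start - 100L)
  re <- min(nchar(hap), ins$hap_end + 100L)
  read <- data.frame(read_id = "r1", haplotype = ins$haplotype,
                     hap_begin = rb, hap_end = re, strand = "+",
                     errors_injected = 0L,
                     sequence = substr(hap, rb + 1L, re),
                     stringsAsFactors = FALSE)
  emission <- data.frame(sequence = substr(read$sequence,
                                           ins$hap_start - rb + 1L,
                                           ins$hap_start - rb + 10L),
                         target_id = "r1", begin = ins$hap_start - rb,
                         end = ins$hap_start - rb + 10L,
                         stringsAsFactors = FALSE)
  hit <- variant_overlap(emission, read, trio)
  expect_true(ins$variant_id %in% hit$variant_id)
  # an emission in an unvaried region overlaps nothing
  far <- data.frame(sequence = substr(read$sequence, 1, 5), target_id = "r1",
                    begin = 0L, end = 5L, stringsAsFactors = FALSE)
  if (ins$hap_start - rb > 5L) {
    expect_identical(nrow(variant_overlap(far, read, trio)), 0L)
  }
  # mismatched read errors out
  expect_error(variant_overlap(emission, transform(read, read_id = "r2"),
                               trio), "mismatch")
  # deletion junction: an emission spanning the junction point is a hit
  del <- plc[plc$kind == "deletion", ][1, ]
  hapd <- trio$haplotypes[[del$haplotype]]
  rb <- max(0L, del$hap_start - 50L)
  re <- min(nchar(hapd), del$hap_start + 50L)
  readd <- data.frame(read_id = "rd", haplotype = del$haplotype,
                      hap_begin = rb, hap_end = re, strand = "+",
                      errors_injected = 0L,
                      sequence = substr(hapd, rb + 1L, re),
                      stringsAsFactors = FALSE)
  emd <- data.frame(sequence = substr(readd$sequence,
                                      del$hap_start - rb - 4L,
                                      del$hap_start - rb + 5L),
                    target_id = "rd", begin = del$hap_start - rb - 5L,
                    end = del$hap_start - rb + 5L, stringsAsFactors = FALSE)
  expect_true(del$variant_id %in% variant_overlap(emd, readd, trio)$variant_id)
})
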