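#' Ping-Pong search: specific strings of one target
#'
#' Enumerates, for a single target string `t`, the substring-free set of
#' `t`-specific strings: substrings of `t` that do not occur anywhere in the
#' indexed reference collection, none of which has a proper substring with
#' the same property.  The search alternates backward extensions (finding the
#' left-maximal match ending at the current position, extended one base left)
#' and forward extensions (trimming it to the shortest absent prefix).  In
#' exact mode the search resumes from the saved pre-failure interval, so
#' consecutive solutions may overlap on `t` and every viable start position
#' is visited (quadratic worst case).  In relaxed mode it restarts one
#' position left of each emission: emissions become pairwise disjoint, the
#' scan is linear (at most two extension queries per symbol of `t`) and the
#' number of emissions is bounded by the edit distance between target and
#' reference.
#'
#' @param t a non-empty A/C/G/T target string (pre-split at non-ACGT runs;
#'   see [search_collection()] for the splitting front end).
#' @param index an [FMDIndex][build_index] of the reference collection.
#' @param target_id identifier recorded in the output rows.
#' @return a data.frame with columns `sequence`, `target_id`, `begin`, `end`
#'   (0-based half-open interval on `t`), one row per emission event in
#'   right-to-left discovery order.  Attribute `n_extensions` carries the
#'   instrumented count of extension operations performed.
#' @export
#' @examples
#' idx <- build_index("TTTT", strand_mode = "single")
#' ping_pong_exact("ACGT", idx)$sequence
ping_pong_exact <- function(t, index, target_id = "target") {
  ping_pong_run(t, index, target_id, relaxed = FALSE)
}

#' Relaxed Ping-Pong search
#'
#' @inheritParams ping_pong_exact
#' @return as [ping_pong_exact()]; emission intervals are pairwise disjoint.
#' @export
ping_pong_relaxed <- function(t, index, target_id = "target") {
  ping_pong_run(t, index, target_id, relaxed = TRUE)
}

ping_pong_run <- function(t, index, target_id, relaxed) {
  assert_index(index)
  t <- toupper(t)
  assert_acgt(t, "target")
  res <- cpp_pingpong(unclass(index), t, relaxed)
  begin <- res$begin
  end <- res$end + 1L # inclusive -> half-open
  out <- data.frame(
    sequence = if (length(begin)) substring(t, begin + 1L, end)
               else character(0),
    target_id = rep_len(as.character(target_id), length(begin)),
    begin = begin, end = end, stringsAsFactors = FALSE)
  attr(out, "n_extensions") <- res$n_extensions
  out
}

#' Search a target collection and tabulate specific strings
#'
#' Runs the Ping-Pong search independently on every target (specific strings
#' of a collection are the union of the per-target solutions), splitting each
#' target at non-A/C/G/T runs first, and aggregates emission counts keyed by
#' the canonical (strand-collapsed) sequence.  Results are independent of
#' processing order and of the number of chunks, so parallel orchestration
#' cannot change the output.
#'
#' @param targets character vector of target sequences (optionally named;
#'   names become target ids).
#' @param index an [FMDIndex][build_index] of the references.
#' @param mode `"exact"` or `"relaxed"`.
#' @param tau optional abundance cutoff applied via [filter_by_abundance()].
#' @param keep_emissions if `TRUE`, the per-emission table (with target ids
#'   and 0-based half-open coordinates) is attached as attribute
#'   `"emissions"`.
#' @param chunks split the targets into this many chunks processed
#'   independently and merged; provided to exercise the determinism contract
#'   of parallel orchestration (the merge is order-insensitive).
#' @return a data.frame of class `sfs_table` with columns `sequence` (most
#'   frequently observed orientation, ties broken lexicographically),
#'   `count` (total emission events) and `canonical`, ordered by descending
#'   count then sequence.  Attributes: `tau`, `mode`, optionally `emissions`.
#' @export
search_collection <- function(targets, index, mode = c("exact", "relaxed"),
                              tau = NULL, keep_emissions = FALSE,
                              chunks = 1L) {
  mode <- match.arg(mode)
  assert_index(index)
  if (length(targets) == 0L) stop("empty target collection")
  ids <- names(targets)
  if (is.null(ids)) ids <- paste0("target_", seq_along(targets))
  frag <- dna_fragments(targets, ids)
  emissions <- list()
  if (!is.null(frag) && nrow(frag) > 0L) {
    groups <- split(seq_len(nrow(frag)),
                    rep_len(seq_len(max(1L, chunks)), nrow(frag)))
    for (g in groups) {
      for (k in g) {
        em <- ping_pong_run(frag$fragment[k], index, frag$id[k],
                            relaxed = (mode == "relaxed"))
        if (nrow(em)) {
          em$begin <- em$begin + frag$offset[k]
          em$end <- em$end + frag$offset[k]
          emissions[[length(emissions) + 1L]] <- em
        }
      }
    }
  }
  emissions <- if (length(emissions)) {
    do.call(rbind, c(emissions, list(make.row.names = FALSE)))
  } else {
    data.frame(sequence = character(0), target_id = character(0),
               begin = integer(0), end = integer(0), stringsAsFactors = FALSE)
  }
  tab <- tabulate_emissions(emissions, mode = mode)
  if (keep_emissions) attr(tab, "emissions") <- emissions
  if (!is.null(tau)) tab <- filter_by_abundance(tab, tau)
  tab
}

# Aggregate an emission table into a canonical-keyed sfs_table.
tabulate_emissions <- function(emissions, mode = NA_character_) {
  if (nrow(emissions) == 0L) {
    tab <- data.frame(sequence = character(0), count = integer(0),
                      canonical = character(0), stringsAsFactors = FALSE)
    return(as_sfs_table(tab, tau = NULL, mode = mode))
  }
  canon <- canonical_sequence(emissions$sequence)
  count <- tapply(canon, canon, length)
  # representative orientation: the most frequent observed spelling per key
  # (at most two spellings map to one canonical: s and rc(s))
  pair <- table(paste(canon, emissions$sequence, sep = "\1"))
  parts <- strsplit(names(pair), "\1", fixed = TRUE)
  po <- data.frame(canon = vapply(parts, `[`, "", 1L),
                   seq = vapply(parts, `[`, "", 2L),
                   n = as.integer(pair), stringsAsFactors = FALSE)
  po <- po[order(po$canon, -po$n, po$seq), , drop = FALSE]
  po <- po[!duplicated(po$canon), , drop = FALSE]
  rep_seq <- stats::setNames(po$seq, po$canon)
  tab <- data.frame(sequence = unname(rep_seq[names(count)]),
                    count = as.integer(count),
                    canonical = names(count), stringsAsFactors = FALSE)
  as_sfs_table(tab, tau = NULL, mode = mode)
}

as_sfs_table <- function(tab, tau = NULL, mode = NA_character_,
                         emissions = NULL) {
  ord <- order(-tab$count, tab$sequence)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("sfs_table", "data.frame")
  attr(tab, "tau") <- tau
  attr(tab, "mode") <- mode
  if (!is.null(emissions)) attr(tab, "emissions") <- emissions
  tab
}

#' @export
print.sfs_table <- function(x, ...) {
  tau <- attr(x, "tau")
  cat("SFS table:", nrow(x), "canonical specific string(s), total count",
      sum(x$count),
      if (!is.null(tau)) paste0("(tau = ", tau, ")") else "(unfiltered)", "\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Abundance filtering of an SFS table
#'
#' Retains entries seen at least `tau` times, the post-processing step that
#' removes specific strings arising from sequencing errors.
#'
#' @param table an `sfs_table` from [search_collection()] or
#'   [aggregate_tables()].
#' @param tau positive integer cutoff; entries with `count >= tau` survive.
#' @return the filtered `sfs_table` (attached emissions, if any, are filtered
#'   to the surviving canonical sequences).
#' @export
filter_by_abundance <- function(table, tau) {
  stopifnot(inherits(table, "sfs_table"))
  if (length(tau) != 1L || is.na(tau) || tau < 1)
    stop("tau must be a positive integer (>= 1)")
  tau <- as.integer(tau)
  keep <- table$count >= tau
  em <- attr(table, "emissions")
  out <- as.data.frame(table)[keep, , drop = FALSE]
  if (!is.null(em)) {
    em <- em[canonical_sequence(em$sequence) %in% out$canonical, , drop = FALSE]
    rownames(em) <- NULL
  }
  as_sfs_table(out, tau = tau, mode = attr(table, "mode"), emissions = em)
}

#' Merge SFS tables from independent batches
#'
#' Canonical-keyed, order-insensitive merge: counts of identical canonical
#' sequences are summed (the post-processing combine step for parallel or
#' batched runs).
#'
#' @param ... `sfs_table` objects (or a single list of them).
#' @param tau optional abundance cutoff applied after merging.
#' @return a merged `sfs_table`.
#' @export
aggregate_tables <- function(..., tau = NULL) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]]) && !is.data.frame(tabs[[1]]))
    tabs <- tabs[[1]]
  if (!length(tabs)) stop("no tables to aggregate")
  all <- do.call(rbind, lapply(tabs, function(tb) {
    stopifnot(inherits(tb, "sfs_table"))
    as.data.frame(tb)[c("sequence", "count", "canonical")]
  }))
  count <- tapply(all$count, all$canonical, sum)
  # representative: highest-count spelling wins, ties lexicographic
  rep_seq <- vapply(names(count), function(k) {
    sub <- all[all$canonical == k, , drop = FALSE]
    agg <- tapply(sub$count, sub$sequence, sum)
    names(agg)[order(-agg, names(agg))][1]
  }, character(1))
  tab <- data.frame(sequence = unname(rep_seq), count = as.integer(count),
                    canonical = names(count), stringsAsFactors = FALSE)
  tab <- as_sfs_table(tab, tau = NULL, mode = NA_character_)
  if (!is.null(tau)) tab <- filter_by_abundance(tab, tau)
  tab
}

#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions and substitutions
#' transforming `a` into `b`; the upper bound on the relaxed Ping-Pong output
#' size for a string pair.
#'
#' @param a,b character strings.
#' @return non-negative integer.
#' @export
#' @examples
#' edit_distance("ACGT", "ACGA")
edit_distance <- function(a, b) {
  as.integer(utils::adist(a, b))
}
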