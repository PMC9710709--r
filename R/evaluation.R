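#' Precision and recall of specific strings against a simulated truth set
#'
#' Evaluates child-specific string emissions against the de novo variants of
#' a coordinate-tracked trio simulation, without any alignment: each
#' emission's read interval is lifted to haplotype coordinates and
#' intersected (breakpoints inclusive) with the truth placements.  Recall is
#' the fraction of de novo variants covered by at least one retained
#' emission; precision is the fraction of retained emissions covering at
#' least one de novo variant.  Precision is computed per emission occurrence;
#' a per-distinct-sequence precision is reported alongside.
#'
#' @param emissions emission table (columns `sequence`, `target_id`, `begin`,
#'   `end`), e.g. the `"emissions"` attribute of
#'   [search_collection()]`(..., keep_emissions = TRUE)`.
#' @param trio the [TrioSim][make_trio] providing truth and liftover.
#' @param reads the [simulate_reads()] table the targets came from.
#' @param tau optional abundance cutoff: emissions whose canonical sequence
#'   occurs fewer than `tau` times (over all of `emissions`) are dropped
#'   before scoring.
#' @return an object of class `sfs_eval_report`: counts, `precision`,
#'   `recall`, `precision_distinct` and a per-kind breakdown.
#' @export
evaluate_simulation <- function(emissions, trio, reads, tau = NULL) {
  stopifnot(is.data.frame(emissions), inherits(trio, "TrioSim"))
  n_total <- nrow(emissions)
  retained <- emissions
  if (!is.null(tau) && n_total > 0L) {
    canon <- canonical_sequence(emissions$sequence)
    counts <- table(canon)
    retained <- emissions[counts[canon] >= tau, , drop = FALSE]
  }
  denovo <- trio$placements[trio$placements$origin == "de_novo", , drop = FALSE]
  n_var <- nrow(denovo)
  kinds <- sort(unique(denovo$kind))

  if (nrow(retained) == 0L) {
    warning("no emissions to evaluate; precision undefined")
    report <- list(n_sfs_total = n_total, n_sfs_after_tau = 0L,
                   n_sfs_covering = 0L, n_variants_total = n_var,
                   n_variants_covered = 0L, precision = NaN,
                   precision_distinct = NaN, recall = 0,
                   tau = tau,
                   by_kind = data.frame(kind = kinds,
                                        n = as.integer(table(denovo$kind)[kinds]),
                                        covered = 0L))
    class(report) <- "sfs_eval_report"
    return(report)
  }

  lifted <- lift_emissions(retained, reads)
  covering <- logical(nrow(retained))
  var_covered <- logical(n_var)
  for (v in seq_len(n_var)) {
    hit <- lifted$haplotype == denovo$haplotype[v] &
      lifted$hap_begin <= denovo$hap_end[v] &
      lifted$hap_end >= denovo$hap_start[v]
    covering <- covering | hit
    var_covered[v] <- any(hit)
  }
  canon <- canonical_sequence(retained$sequence)
  distinct_cover <- tapply(covering, canon, any)
  by_kind <- data.frame(
    kind = kinds,
    n = as.integer(table(denovo$kind)[kinds]),
    covered = vapply(kinds, function(k)
      sum(var_covered[denovo$kind == k]), integer(1)))
  report <- list(
    n_sfs_total = n_total,
    n_sfs_after_tau = nrow(retained),
    n_sfs_covering = sum(covering),
    n_variants_total = n_var,
    n_variants_covered = sum(var_covered),
    precision = sum(covering) / nrow(retained),
    precision_distinct = mean(distinct_cover),
    recall = if (n_var > 0L) sum(var_covered) / n_var else NaN,
    tau = tau,
    by_kind = by_kind)
  class(report) <- "sfs_eval_report"
  report
}

#' @export
print.sfs_eval_report <- function(x, ...) {
  cat("SFS evaluation report\n")
  cat(sprintf("  emissions: %d total, %d after tau filter (tau = %s)\n",
              x$n_sfs_total, x$n_sfs_after_tau,
              if (is.null(x$tau)) "none" else x$tau))
  cat(sprintf("  precision: %.4f (%d / %d emissions cover a de novo variant)\n",
              x$precision, x$n_sfs_covering, x$n_sfs_after_tau))
  cat(sprintf("  recall:    %.4f (%d / %d de novo variants covered)\n",
              x$recall, x$n_variants_covered, x$n_variants_total))
  if (nrow(x$by_kind)) {
    cat("  by kind:\n")
    for (k in seq_len(nrow(x$by_kind)))
      cat(sprintf("    %-10s %d / %d covered\n", x$by_kind$kind[k],
                  x$by_kind$covered[k], x$by_kind$n[k]))
  }
  invisible(x)
}

#' Descriptive summary of an SFS table
#'
#' @param table an `sfs_table`.
#' @return list with totals and quantiles of the length and abundance
#'   distributions of the canonical specific strings.
#' @export
summarize_table <- function(table) {
  stopifnot(inherits(table, "sfs_table"))
  qs <- c(0, 0.25, 0.5, 0.75, 1)
  len <- nchar(table$sequence)
  list(
    n_strings = nrow(table),
    total_count = sum(table$count),
    tau = attr(table, "tau"),
    length_quantiles = if (nrow(table)) stats::quantile(len, qs) else
      stats::setNames(rep(NA_real_, 5L), paste0(qs * 100, "%")),
    count_quantiles = if (nrow(table)) stats::quantile(table$count, qs) else
      stats::setNames(rep(NA_real_, 5L), paste0(qs * 100, "%")))
}
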