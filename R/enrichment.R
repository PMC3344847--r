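# Gene-set enrichment machinery: single-selection Fisher exact tests and a
# threshold-free scan over partitions of a ranked list.

#' Two-sided Fisher exact p for 2x2 tables
#'
#' Exact hypergeometric two-sided p-value: the sum of all point
#' probabilities not exceeding the observed one (relative tie tolerance
#' 1 + 1e-7, the usual convention). Tables are parameterized as draws:
#' `x` in-set genes among `k` selected from a background holding `m` in-set
#' and `n` out-set genes. Vectorized over tables.
#'
#' @param x in-set members of the selection.
#' @param m in-set background size.
#' @param n out-set background size.
#' @param k selection size.
#' @return numeric vector of p-values in (0, 1].
#' @export
fisher_exact_p <- function(x, m, n, k) {
  len <- max(length(x), length(m), length(n), length(k))
  x <- rep_len(as.integer(x), len); m <- rep_len(as.integer(m), len)
  n <- rep_len(as.integer(n), len); k <- rep_len(as.integer(k), len)
  .fisher_p_cpp(x, m, n, k)
}

.enrich_table <- function(selected, background, sets, alternative) {
  n_bg <- length(background)
  n_sel <- length(selected)
  in_bg <- lapply(sets, intersect, background)
  empty <- lengths(in_bg) == 0L
  if (any(empty))
    log_msg(sprintf("skipped %d set(s) with no members in the background",
                    sum(empty)))
  in_bg <- in_bg[!empty]
  if (length(in_bg) == 0L) return(NULL)
  a <- vapply(in_bg, function(s) length(intersect(s, selected)), 1L)
  m <- lengths(in_bg)
  b <- m - a                 # in set, not selected
  c_ <- n_sel - a            # selected, out of set
  d <- n_bg - m - c_
  p <- if (alternative == "greater")
    phyper(a - 1L, m, n_bg - m, n_sel, lower.tail = FALSE)
  else fisher_exact_p(a, m, n_bg - m, n_sel)
  or <- (a * d) / (b * c_)   # sample odds ratio; Inf/NaN allowed on empty margins
  data.frame(set_id = names(in_bg), a = a, b = b, c = c_, d = d,
             odds_ratio = or, p = p, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Single-selection gene-set enrichment (Fisher exact)
#'
#' Tests each gene set for over/under-representation of a selected gene
#' list against a background, in the style of classical term-enrichment
#' tools. Sets are intersected with the background first; sets left empty
#' are skipped. P-values are Benjamini-Hochberg adjusted across sets.
#'
#' @param selected character vector of selected gene ids (must be a subset
#'   of `background`).
#' @param background character vector of all measured gene ids.
#' @param collection named list of gene sets (see [read_gmt()]).
#' @param alternative `"two.sided"` (default; depletion and enrichment both
#'   detected, direction read off the odds ratio) or `"greater"`
#'   (enrichment only).
#' @return data frame sorted by p: `set_id`, counts `a` (in-set selected),
#'   `b` (in-set unselected), `c` (out-set selected), `d` (out-set
#'   unselected), `odds_ratio`, `p`, `p_adj`.
#' @export
fisher_term_enrichment <- function(selected, background, collection,
                                   alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(background) > 0L)
  background <- unique(background)
  selected <- unique(selected)
  stray <- setdiff(selected, background)
  if (length(stray) > 0L)
    stop("selected ids absent from the background: ",
         paste(head(stray, 10L), collapse = ", "), call. = FALSE)
  res <- .enrich_table(selected, background, collection, alternative)
  if (is.null(res)) return(res)
  res$p_adj <- p.adjust(res$p, "BH")
  res[order(res$p), , drop = FALSE]
}

#' Threshold-free enrichment scan over a ranked gene list
#'
#' Instead of one arbitrary selection cutoff, scans the ranking: for
#' partition k of `n_partitions`, the top `ceiling(k * n / (n_partitions +
#' 1))` genes form the selection and the full list the background, and each
#' gene set is Fisher-tested at every partition. P-values are
#' Benjamini-Hochberg adjusted across all (set, partition) results, and the
#' minimum adjusted p per set, with its partition, is summarized.
#'
#' @param ranked_ids character vector of unique gene ids, best-ranked
#'   first (e.g. decreasing translation efficiency).
#' @param collection named list of gene sets.
#' @param n_partitions number of list partitions scanned (default 30, the
#'   classical choice for this style of scan).
#' @param alternative passed to the per-partition Fisher test.
#' @return list with `results` (all set x partition rows: `partition`,
#'   `n_selected`, set counts, `p`, `p_adj`) and `summary` (per set: the
#'   minimal adjusted p and the partition attaining it).
#' @export
ranked_partition_scan <- function(ranked_ids, collection, n_partitions = 30,
                                  alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (anyDuplicated(ranked_ids))
    stop("ranked list contains duplicate ids", call. = FALSE)
  n <- length(ranked_ids)
  stopifnot(n_partitions >= 1L, n_partitions < n)
  res <- do.call(rbind, lapply(seq_len(n_partitions), function(k) {
    n_sel <- ceiling(k * n / (n_partitions + 1))
    r <- .enrich_table(ranked_ids[seq_len(n_sel)], ranked_ids, collection,
                       alternative)
    if (is.null(r)) return(NULL)
    cbind(data.frame(partition = k, n_selected = n_sel), r)
  }))
  if (is.null(res)) return(list(results = NULL, summary = NULL))
  res$p_adj <- p.adjust(res$p, "BH")
  best <- do.call(rbind, lapply(split(res, res$set_id), function(d) {
    i <- which.min(d$p_adj)
    data.frame(set_id = d$set_id[i], best_partition = d$partition[i],
               n_selected = d$n_selected[i], a = d$a[i],
               odds_ratio = d$odds_ratio[i], p = d$p[i], p_adj = d$p_adj[i],
               stringsAsFactors = FALSE)
  }))
  rownames(best) <- NULL
  list(results = res, summary = best[order(best$p_adj), , drop = FALSE])
}
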