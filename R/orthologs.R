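# Cross-species agreement of translation efficiencies via an ortholog table,
# stratified by abundance.

#' Pair two translatomes through an ortholog table
#'
#' Joins per-gene expression tables of two species on an ortholog pair list.
#' Pairs are deduplicated first; only pairs with both genes measured are
#' retained; one-to-many ortholog mappings are expanded to all combinations
#' (the count of expanded pairs is reported).
#'
#' @param pairs data frame with columns `id_a`, `id_b` (gene ids in species
#'   A and B).
#' @param expr_a,expr_b expression tables (`gene_id`, `M`, `A`) for the two
#'   species.
#' @return data frame with one row per resolvable pair: `id_a`, `id_b`,
#'   `te_a`, `te_b`, `a_a`, `a_b`.
#' @export
pair_translatomes <- function(pairs, expr_a, expr_b) {
  assert_cols(pairs, c("id_a", "id_b"), "ortholog table")
  assert_cols(expr_a, c("gene_id", "M", "A"), "species A expression")
  assert_cols(expr_b, c("gene_id", "M", "A"), "species B expression")
  stopifnot(all(nzchar(pairs$id_a)), all(nzchar(pairs$id_b)))
  dup <- duplicated(pairs[, c("id_a", "id_b")])
  if (any(dup)) {
    log_msg(sprintf("deduplicated %d repeated ortholog pair(s)", sum(dup)))
    pairs <- pairs[!dup, , drop = FALSE]
  }
  ia <- match(pairs$id_a, expr_a$gene_id)
  ib <- match(pairs$id_b, expr_b$gene_id)
  keep <- !is.na(ia) & !is.na(ib)
  out <- data.frame(
    id_a = pairs$id_a[keep], id_b = pairs$id_b[keep],
    te_a = expr_a$M[ia[keep]], te_b = expr_b$M[ib[keep]],
    a_a = expr_a$A[ia[keep]], a_b = expr_b$A[ib[keep]],
    stringsAsFactors = FALSE
  )
  n_multi <- sum(duplicated(out$id_a)) + sum(duplicated(out$id_b))
  if (n_multi > 0L)
    log_msg(sprintf("one-to-many orthology expanded into %d extra row(s)", n_multi))
  log_msg(sprintf("%d of %d ortholog pairs resolvable in both translatomes",
                  nrow(out), nrow(pairs)))
  out
}

#' Ortholog TE agreement stratified by abundance
#'
#' For each abundance cutoff, keeps pairs where both species' A values reach
#' the cutoff (`min(a_a, a_b) >= cutoff`, the conservative reading of an
#' abundance restriction applied to a pair) and computes the Pearson
#' correlation of the two species' M values.
#'
#' @param paired output of [pair_translatomes()].
#' @param a_cutoffs ascending numeric vector of abundance cutoffs; use
#'   `-Inf` for the unrestricted stratum.
#' @return data frame per stratum: `a_cutoff`, `n`, `r`, `r_squared`.
#'   Strata with fewer than 3 pairs get `NA` correlations.
#' @export
stratified_correlation <- function(paired, a_cutoffs) {
  assert_cols(paired, c("te_a", "te_b", "a_a", "a_b"), "paired table")
  stopifnot(!is.unsorted(a_cutoffs))
  amin <- pmin(paired$a_a, paired$a_b)
  do.call(rbind, lapply(a_cutoffs, function(cut) {
    sel <- amin >= cut
    n <- sum(sel)
    r <- if (n >= 3L) cor(paired$te_a[sel], paired$te_b[sel]) else NA_real_
    data.frame(a_cutoff = cut, n = n, r = r, r_squared = r^2)
  }))
}
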