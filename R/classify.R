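# Stress translation-change scoring, S/R/I class calling, calibration-marker
# percentile placement, and translatome-transcriptome coordination.

#' Thresholds for stress translation classes
#'
#' Bundles the log2-scale cutoffs that define the three stress translation
#' classes and the coordination analysis:
#' sensitive (S): translation change `<= s_delta`;
#' resistant (R): `M >= r_level` in both conditions;
#' inducible (I): control `M <= i_control_max` and change `>= i_delta`.
#' `venn_translation_delta` and `abundance_delta` are the |change| cutoffs
#' used for "changed translation" / "changed abundance" in the coordination
#' analysis (deliberately separate from `s_delta`).
#'
#' @param s_delta maximum translation change for S calls (default -0.8).
#' @param r_level minimum M in both conditions for R calls (default 0.8).
#' @param i_control_max maximum control M for I calls (default 0).
#' @param i_delta minimum translation change for I calls (default 1).
#' @param venn_translation_delta |dM| cutoff for "changed translation"
#'   (default 1).
#' @param abundance_delta |dA| cutoff for "changed abundance" (default 1).
#' @return list of class `"class_thresholds"`.
#' @export
class_thresholds <- function(s_delta = -0.8, r_level = 0.8, i_control_max = 0,
                             i_delta = 1, venn_translation_delta = 1,
                             abundance_delta = 1) {
  th <- list(s_delta = s_delta, r_level = r_level,
             i_control_max = i_control_max, i_delta = i_delta,
             venn_translation_delta = venn_translation_delta,
             abundance_delta = abundance_delta)
  if (!all(vapply(th, is.finite, TRUE)))
    stop("all thresholds must be finite", call. = FALSE)
  if (s_delta >= 0) stop("s_delta must be negative", call. = FALSE)
  if (r_level <= 0) stop("r_level must be positive", call. = FALSE)
  if (i_delta <= 0) stop("i_delta must be positive", call. = FALSE)
  if (i_control_max >= r_level)
    stop("i_control_max must be below r_level (keeps I and R disjoint)",
         call. = FALSE)
  structure(th, class = "class_thresholds")
}

#' Pair control and stress expression into translation-change entries
#'
#' Joins two per-gene expression tables (same layout as
#' [summarize_expression()] output) on `gene_id` and computes the stress
#' translation change `delta_te = te_stress - te_control` and abundance
#' change `delta_a`. Genes present in only one condition are dropped with a
#' reported count.
#'
#' @param control,stress expression tables for the two conditions.
#' @return data frame with one row per shared gene: `gene_id`, `te_control`,
#'   `te_stress`, `delta_te`, `a_control`, `a_stress`, `delta_a`,
#'   `class_label` (initialized to `"U"`).
#' @export
compute_translation_change <- function(control, stress) {
  assert_cols(control, c("gene_id", "M", "A"), "control expression")
  assert_cols(stress, c("gene_id", "M", "A"), "stress expression")
  shared <- intersect(control$gene_id, stress$gene_id)
  dropped <- (nrow(control) - length(shared)) + (nrow(stress) - length(shared))
  if (dropped > 0L)
    log_msg(sprintf("%d record(s) present in only one condition were dropped",
                    dropped))
  if (length(shared) == 0L) {
    warning("no genes shared between conditions", call. = FALSE)
  }
  ic <- match(shared, control$gene_id)
  is <- match(shared, stress$gene_id)
  data.frame(
    gene_id = shared,
    te_control = control$M[ic],
    te_stress = stress$M[is],
    delta_te = stress$M[is] - control$M[ic],
    a_control = control$A[ic],
    a_stress = stress$A[is],
    delta_a = stress$A[is] - control$A[ic],
    class_label = rep("U", length(shared)),
    stringsAsFactors = FALSE
  )
}

#' Assign stress translation classes
#'
#' Applies the class rules in fixed precedence I, then R, then S (any gene
#' matching no rule is U, unclassified). Evaluating R before S means a gene
#' whose translation falls but stays at a high absolute level (e.g. M from
#' 3.0 to 1.0) is called resistant: the R class is defined by maintained
#' polysome engagement, not by the size of the change.
#'
#' @param entries data frame with `te_control` and `te_stress` columns (the
#'   output of [compute_translation_change()]), or a numeric vector of
#'   control M values (with `te_stress` supplied separately).
#' @param thresholds a [class_thresholds()] object.
#' @param te_stress stress M values when `entries` is a numeric vector.
#' @return for a data-frame input, the data frame with `class_label` filled
#'   in; for vector input, a character vector of labels in
#'   `c("S","R","I","U")`.
#' @export
classify_translation <- function(entries, thresholds = class_thresholds(),
                                 te_stress = NULL) {
  stopifnot(inherits(thresholds, "class_thresholds"))
  if (is.data.frame(entries)) {
    assert_cols(entries, c("te_control", "te_stress"), "translatome entries")
    entries$class_label <- classify_translation(entries$te_control, thresholds,
                                                entries$te_stress)
    return(entries)
  }
  tc <- entries
  ts <- te_stress
  stopifnot(length(tc) == length(ts), all(is.finite(tc)), all(is.finite(ts)))
  delta <- ts - tc
  lab <- rep("U", length(tc))
  is_i <- tc <= thresholds$i_control_max & delta >= thresholds$i_delta
  is_r <- !is_i & tc >= thresholds$r_level & ts >= thresholds$r_level
  is_s <- !is_i & !is_r & delta <= thresholds$s_delta
  lab[is_s] <- "S"; lab[is_r] <- "R"; lab[is_i] <- "I"
  lab
}

#' Percentile placement of calibration markers
#'
#' Places marker genes on the distribution of translation efficiencies using
#' midrank percentiles (`(midrank - 0.5) / n * 100`), so ties share a rank
#' and the placement is invariant to permutation of equal values.
#'
#' @param te named numeric vector of M values (names are gene ids).
#' @param markers character vector of marker gene ids.
#' @return data frame `gene_id`, `te`, `percentile`; markers absent from the
#'   distribution are reported with `NA` values rather than an error.
#' @export
percentile_placement <- function(te, markers) {
  stopifnot(!is.null(names(te)), length(te) > 0L)
  n <- length(te)
  pct <- (rank(te, ties.method = "average") - 0.5) / n * 100
  idx <- match(markers, names(te))
  missing <- is.na(idx)
  if (any(missing))
    log_msg("marker(s) absent from the distribution: ",
            paste(markers[missing], collapse = ", "))
  data.frame(
    gene_id = markers,
    te = ifelse(missing, NA_real_, te[idx]),
    percentile = ifelse(missing, NA_real_, pct[idx]),
    stringsAsFactors = FALSE
  )
}

#' Coordination between translation and abundance changes under stress
#'
#' Quantifies how far stress-induced translation changes are mirrored by
#' abundance changes: (i) Venn counts of genes with changed translation only
#' (`|delta_te| >= venn_translation_delta`), changed abundance only
#' (`|delta_a| >= abundance_delta`), or both; (ii) per translation class
#' (S, R, I), how many genes went up or down in abundance; (iii) among genes
#' whose abundance went up, the share that were translationally induced
#' (`delta_te >= i_delta`) or repressed (`delta_te <= s_delta`).
#'
#' @param entries classified translatome table (see
#'   [classify_translation()]); must have finite `delta_te` and `delta_a`.
#' @param thresholds a [class_thresholds()] object.
#' @return list of class `"coordination_report"` with elements `venn`,
#'   `per_class`, `abundance_up`, `thresholds` and `precedence`.
#' @export
coordination_analysis <- function(entries, thresholds = class_thresholds()) {
  assert_cols(entries, c("delta_te", "delta_a", "class_label"), "entries")
  stopifnot(all(is.finite(entries$delta_te)), all(is.finite(entries$delta_a)))
  tr_chg <- abs(entries$delta_te) >= thresholds$venn_translation_delta
  ab_chg <- abs(entries$delta_a) >= thresholds$abundance_delta
  venn <- c(translation_only = sum(tr_chg & !ab_chg),
            abundance_only = sum(!tr_chg & ab_chg),
            both = sum(tr_chg & ab_chg))
  up <- entries$delta_a >= thresholds$abundance_delta
  dn <- entries$delta_a <= -thresholds$abundance_delta
  per_class <- do.call(rbind, lapply(c("S", "R", "I"), function(cl) {
    sel <- entries$class_label == cl
    n <- sum(sel)
    data.frame(class = cl, n = n,
               n_abundance_up = sum(sel & up),
               pct_abundance_up = if (n > 0) 100 * sum(sel & up) / n else NA_real_,
               n_abundance_down = sum(sel & dn),
               pct_abundance_down = if (n > 0) 100 * sum(sel & dn) / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
  n_up <- sum(up)
  abundance_up <- data.frame(
    n = n_up,
    pct_translation_up = if (n_up > 0)
      100 * sum(up & entries$delta_te >= thresholds$i_delta) / n_up else NA_real_,
    pct_translation_down = if (n_up > 0)
      100 * sum(up & entries$delta_te <= thresholds$s_delta) / n_up else NA_real_
  )
  structure(list(venn = venn, per_class = per_class,
                 abundance_up = abundance_up,
                 thresholds = unclass(thresholds),
                 precedence = "I > R > S (ties resolved toward maintained engagement)"),
            class = "coordination_report")
}

#' Mean and SD of translation efficiency over a gene subset
#'
#' Summary used for curated panels (e.g. the most abundant proteins): mean
#' and sample SD of control and stress M over the listed genes.
#'
#' @param entries translatome table (see [compute_translation_change()]).
#' @param ids gene ids of the subset.
#' @param subset_name label used in error messages.
#' @return one-row data frame: `n`, `mean_control`, `sd_control`,
#'   `mean_stress`, `sd_stress`.
#' @export
subset_summary <- function(entries, ids, subset_name = "subset") {
  assert_cols(entries, c("gene_id", "te_control", "te_stress"), "entries")
  sel <- entries$gene_id %in% ids
  if (!any(sel))
    stop(sprintf("no genes of '%s' found in the translatome table", subset_name),
         call. = FALSE)
  data.frame(
    n = sum(sel),
    mean_control = mean(entries$te_control[sel]),
    sd_control = sd(entries$te_control[sel]),
    mean_stress = mean(entries$te_stress[sel]),
    sd_stress = sd(entries$te_stress[sel])
  )
}

#' @export
print.coordination_report <- function(x, ...) {
  cat("Translation/abundance coordination report\n")
  cat(sprintf("  changed translation only: %d\n", x$venn[["translation_only"]]))
  cat(sprintf("  changed abundance only:   %d\n", x$venn[["abundance_only"]]))
  cat(sprintf("  changed both:             %d\n", x$venn[["both"]]))
  cat("  per-class abundance changes:\n")
  print(x$per_class, row.names = FALSE)
  cat(sprintf("  among %d abundance-up genes: %.1f%% induced, %.1f%% repressed\n",
              x$abundance_up$n, x$abundance_up$pct_translation_up,
              x$abundance_up$pct_translation_down))
  invisible(x)
}
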