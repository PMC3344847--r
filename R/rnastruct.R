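# Equilibrium base-pair probabilities (McCaskill partition-function
# recursion under a pair-weight model) and positional BPP profiles anchored
# at the start / stop codons.

#' Default Boltzmann weights per base-pair type
#'
#' Order-of-magnitude equilibrium weights reflecting the stability ranking
#' GC > AU > GU of Watson-Crick and wobble pairs; the model carries no
#' stacking or loop terms, so only the ratios matter.
#'
#' @return named numeric vector with elements `GC`, `AU`, `GU`.
#' @export
default_pair_weights <- function() c(GC = 6, AU = 2, GU = 1)

.base_codes <- c(A = 0L, C = 1L, G = 2L, U = 3L, T = 3L)

.weight_matrix <- function(pair_weights) {
  w <- matrix(0, 4, 4)  # A C G U
  w[1, 4] <- w[4, 1] <- pair_weights[["AU"]]
  w[2, 3] <- w[3, 2] <- pair_weights[["GC"]]
  w[3, 4] <- w[4, 3] <- pair_weights[["GU"]]
  w
}

#' Base-pair probability matrix of a sequence
#'
#' Computes p(i, j), the equilibrium probability that bases i and j pair,
#' over the Boltzmann ensemble of all nested secondary structures. Allowed
#' pairs are AU/UA, GC/CG and GU/UG with one configurable weight per pair
#' type; hairpin loops must contain at least `min_loop` unpaired bases. The
#' inside-outside recursion is exact for this model (no sampling).
#'
#' @param sequence character scalar over A, C, G, U/T (case-insensitive).
#' @param pair_weights named numeric vector with elements `GC`, `AU`, `GU`
#'   (see [default_pair_weights()]).
#' @param min_loop minimum number of unpaired bases in a hairpin loop
#'   (default 3).
#' @return object of class `"bpp_matrix"`: list with `n`, symmetric matrix
#'   `p`, and the normalized `sequence`. Sequences shorter than
#'   `min_loop + 2` return an all-zero matrix with a warning.
#' @export
pair_probabilities <- function(sequence, pair_weights = default_pair_weights(),
                               min_loop = 3) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  codes <- .base_codes[chars]
  if (anyNA(codes)) {
    bad <- which(is.na(codes))
    stop("invalid character(s) at position(s): ",
         paste(head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  n <- length(codes)
  if (n < min_loop + 2L) {
    warning("sequence shorter than min_loop + 2; no pairing possible",
            call. = FALSE)
    return(structure(list(n = n, p = matrix(0, n, n), sequence = s),
                     class = "bpp_matrix"))
  }
  p <- .mccaskill_cpp(unname(codes), .weight_matrix(pair_weights),
                      as.integer(min_loop))
  structure(list(n = n, p = p, sequence = s), class = "bpp_matrix")
}

#' Per-position marginal pairing probability
#'
#' @param bpp a `"bpp_matrix"` object.
#' @return numeric vector: for each base, the probability of being paired
#'   with any partner (row sums of the pair matrix).
#' @export
bpp_marginal <- function(bpp) {
  stopifnot(inherits(bpp, "bpp_matrix"))
  rowSums(bpp$p)
}

#' Export / import a sparse base-pair probability matrix
#'
#' Plain-text exchange format (1-based `i`, `j`, `p` for i < j with p > 0),
#' allowing profiles to be built from probabilities computed by an external
#' thermodynamic folder.
#'
#' @param bpp a `"bpp_matrix"` object.
#' @param path file path.
#' @return `write_bpp` returns `path` invisibly; `read_bpp` a
#'   `"bpp_matrix"`.
#' @export
write_bpp <- function(bpp, path) {
  stopifnot(inherits(bpp, "bpp_matrix"))
  idx <- which(upper.tri(bpp$p) & bpp$p > 0, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1L], j = idx[, 2L], p = bpp$p[idx])
  df <- df[order(df$i, df$j), , drop = FALSE]
  writeLines(c(sprintf("# n=%d", bpp$n), "i\tj\tp",
               sprintf("%d\t%d\t%.10g", df$i, df$j, df$p)), path)
  invisible(path)
}

#' @param n sequence length (read from the header when absent).
#' @rdname write_bpp
#' @export
read_bpp <- function(path, n = NULL) {
  first <- readLines(path, n = 1L)
  if (is.null(n)) {
    if (!grepl("^# n=", first)) stop("missing length header; supply n", call. = FALSE)
    n <- as.integer(sub("^# n=", "", first))
  }
  df <- read.delim(path, comment.char = "#")
  p <- matrix(0, n, n)
  p[cbind(df$i, df$j)] <- df$p
  p[cbind(df$j, df$i)] <- df$p
  structure(list(n = n, p = p, sequence = NA_character_), class = "bpp_matrix")
}

# map window offsets to 1-based sequence positions; +1 is the A of the
# initiator AUG (anchor "start") or the first base of the stop codon
# (anchor "stop"); there is no offset 0.
.anchor_positions <- function(annotation_row, anchor, window) {
  base <- if (anchor == "start") annotation_row$cds_start + 1L
          else annotation_row$cds_end - 2L
  ifelse(window > 0L, base + window - 1L, base + window)
}

#' Positional base-pair probability profile around start or stop codons
#'
#' For each transcript, folds the region spanned by the window plus a flank
#' on each side (truncated at the transcript ends) and records the marginal
#' pairing probability at every window offset; offsets are counted with +1
#' at the A of the initiator AUG, or at the first base of the stop codon,
#' and no offset 0. The two groups are then compared per position with a
#' two-sided Welch t test (uncorrected p plus Benjamini-Hochberg adjusted).
#'
#' @param annotations annotation table from [parse_annotation()].
#' @param groups named list of exactly two transcript-id vectors.
#' @param anchor `"start"` or `"stop"`.
#' @param window integer offsets (no 0), e.g. `c(-20:-1, 1:50)`.
#' @param flank folding context added on each side of the window (default
#'   50 nt).
#' @param pair_weights,min_loop passed to [pair_probabilities()].
#' @param p_flag per-position significance threshold (default 0.05,
#'   uncorrected, with BH-adjusted values also reported).
#' @return data frame per offset: `offset`, group means and sizes, `p`,
#'   `p_adj`, `significant`; transcripts whose window falls outside the
#'   sequence are excluded with a reported count.
#' @export
positional_bpp_profile <- function(annotations, groups,
                                   anchor = c("start", "stop"),
                                   window = c(-20:-1, 1:50), flank = 50,
                                   pair_weights = default_pair_weights(),
                                   min_loop = 3, p_flag = 0.05) {
  anchor <- match.arg(anchor)
  stopifnot(is.list(groups), length(groups) == 2L, !is.null(names(groups)))
  if (any(window == 0L)) stop("window offsets use +1/-1 around the anchor; 0 is not a position",
                              call. = FALSE)
  window <- sort(as.integer(window))

  profile_one <- function(row) {
    pos <- .anchor_positions(row, anchor, window)
    len <- nchar(row$sequence)
    if (min(pos) < 1L || max(pos) > len) return(NULL)
    lo <- max(1L, min(pos) - flank)
    hi <- min(len, max(pos) + flank)
    bpp <- suppressWarnings(
      pair_probabilities(substr(row$sequence, lo, hi), pair_weights, min_loop))
    bpp_marginal(bpp)[pos - lo + 1L]
  }

  group_mats <- lapply(groups, function(ids) {
    sel <- annotations[annotations$transcript_id %in% ids, , drop = FALSE]
    prof <- lapply(seq_len(nrow(sel)), function(i) profile_one(sel[i, , drop = FALSE]))
    skipped <- sum(vapply(prof, is.null, TRUE))
    if (skipped > 0L)
      log_msg(sprintf("excluded %d transcript(s) with the window outside the sequence",
                      skipped))
    do.call(rbind, prof[!vapply(prof, is.null, TRUE)])
  })

  ga <- group_mats[[1L]]; gb <- group_mats[[2L]]
  p <- vapply(seq_along(window), function(i) {
    if (is.null(ga) || is.null(gb) || nrow(ga) < 2L || nrow(gb) < 2L) return(NA_real_)
    if (sd(ga[, i]) == 0 && sd(gb[, i]) == 0) return(NA_real_)
    t.test(ga[, i], gb[, i])$p.value
  }, 1)
  out <- data.frame(
    offset = window,
    mean_a = if (is.null(ga)) NA_real_ else colMeans(ga),
    mean_b = if (is.null(gb)) NA_real_ else colMeans(gb),
    n_a = if (is.null(ga)) 0L else nrow(ga),
    n_b = if (is.null(gb)) 0L else nrow(gb),
    p = p,
    p_adj = p.adjust(p, "BH"),
    significant = !is.na(p) & p < p_flag
  )
  names(out)[2:3] <- paste0("mean_", names(groups))
  names(out)[4:5] <- paste0("n_", names(groups))
  attr(out, "anchor") <- anchor
  out
}
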