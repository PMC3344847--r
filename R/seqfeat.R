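# Transcript annotation parsing and the mRNA sequence-feature inventory:
# region lengths, G+C, upstream AUG counts and initiator context, compared
# across translation groups.

.norm_seq <- function(s) {
  s <- toupper(s)
  gsub("U", "T", s, fixed = TRUE)
}

#' Parse transcript sequences and CDS coordinates into annotations
#'
#' Combines transcript sequences with a CDS coordinate table into validated
#' annotations. Coordinates are 0-based half-open on the sense strand and
#' include the start and stop codons. Sequences are uppercased and U is
#' normalized to T. Transcripts violating the coordinate invariants are
#' rejected individually (with reasons collected in the `"rejected"`
#' attribute), not fatally.
#'
#' @param sequences a named character vector of transcript sequences, a
#'   `Biostrings::DNAStringSet`/`RNAStringSet`, or the path to a FASTA file.
#' @param cds data frame with columns `transcript_id`, `cds_start`,
#'   `cds_end`.
#' @param check_frame require the CDS length to be divisible by 3
#'   (default `TRUE`).
#' @return data frame of accepted annotations: `transcript_id`, `sequence`,
#'   `cds_start`, `cds_end`, with attribute `"rejected"` (data frame of
#'   `transcript_id`, `reason`).
#' @export
parse_annotation <- function(sequences, cds, check_frame = TRUE) {
  if (is.character(sequences) && length(sequences) == 1L && file.exists(sequences))
    sequences <- Biostrings::readDNAStringSet(sequences)
  if (methods::is(sequences, "XStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  # FASTA headers may carry descriptions after the id
  names(sequences) <- sub("\\s.*$", "", names(sequences))
  sequences <- vapply(sequences, .norm_seq, "")
  assert_cols(cds, c("transcript_id", "cds_start", "cds_end"), "CDS table")

  reasons <- character(0); rejected_ids <- character(0)
  keep <- logical(nrow(cds))
  for (i in seq_len(nrow(cds))) {
    id <- cds$transcript_id[i]
    s <- if (id %in% names(sequences)) sequences[[id]] else NA_character_
    reason <- NULL
    if (is.na(s)) reason <- "no FASTA record"
    else {
      len <- nchar(s)
      st <- cds$cds_start[i]; en <- cds$cds_end[i]
      if (grepl("[^ACGTN]", s)) reason <- "invalid characters in sequence"
      else if (!(st >= 0 && st < en && en <= len)) reason <- "CDS outside sequence"
      else if (check_frame && (en - st) %% 3L != 0L) reason <- "CDS length not divisible by 3"
    }
    if (is.null(reason)) keep[i] <- TRUE
    else { rejected_ids <- c(rejected_ids, id); reasons <- c(reasons, reason) }
  }
  if (length(rejected_ids) > 0L)
    warning(sprintf("rejected %d transcript(s): %s", length(rejected_ids),
                    paste(unique(reasons), collapse = "; ")), call. = FALSE)
  out <- data.frame(
    transcript_id = cds$transcript_id[keep],
    sequence = unname(sequences[cds$transcript_id[keep]]),
    cds_start = as.integer(cds$cds_start[keep]),
    cds_end = as.integer(cds$cds_end[keep]),
    stringsAsFactors = FALSE
  )
  attr(out, "rejected") <- data.frame(transcript_id = rejected_ids,
                                      reason = reasons,
                                      stringsAsFactors = FALSE)
  out
}

.gc_percent <- function(region) {
  n_gc <- nchar(gsub("[^GC]", "", region))
  n_acgt <- nchar(gsub("[^ACGT]", "", region))
  ifelse(n_acgt > 0L, 100 * n_gc / n_acgt, NA_real_)
}

.count_uaug <- function(utr5) {
  # every ATG whose three bases lie entirely in the 5'UTR, overlaps included
  hits <- gregexpr("(?=ATG)", utr5, perl = TRUE)
  vapply(hits, function(h) if (h[1L] == -1L) 0L else length(h), 1L)
}

#' Extract the sequence-feature vector of each transcript
#'
#' Computes, per transcript: CDS / 5'UTR / 3'UTR lengths and G+C percentages
#' (Ns excluded from both numerator and denominator; `NA` for empty
#' regions), the number of upstream AUG triplets fully contained in the
#' 5'UTR (all positions scanned, overlapping occurrences counted), and
#' whether the initiator context carries a purine at position -3
#' (`NA` = unknown when the 5'UTR is shorter than 3 nt).
#'
#' @param annotations annotation table from [parse_annotation()].
#' @return data frame with one row per transcript: `transcript_id`,
#'   `cds_len`, `cds_gc`, `utr5_len`, `utr5_gc`, `utr3_len`, `utr3_gc`,
#'   `n_uaug`, `start_context_purine`.
#' @export
extract_features <- function(annotations) {
  assert_cols(annotations, c("transcript_id", "sequence", "cds_start", "cds_end"),
              "annotations")
  s <- annotations$sequence
  st <- annotations$cds_start
  en <- annotations$cds_end
  len <- nchar(s)
  utr5 <- substr(s, 1L, st)                     # st == utr5 length (0-based start)
  cdsr <- substr(s, st + 1L, en)
  utr3 <- substr(s, en + 1L, len)
  minus3 <- ifelse(st >= 3L, substr(s, st - 2L, st - 2L), NA_character_)
  data.frame(
    transcript_id = annotations$transcript_id,
    cds_len = en - st,
    cds_gc = .gc_percent(cdsr),
    utr5_len = st,
    utr5_gc = .gc_percent(utr5),
    utr3_len = len - en,
    utr3_gc = .gc_percent(utr3),
    n_uaug = .count_uaug(utr5),
    start_context_purine = ifelse(is.na(minus3), NA, minus3 %in% c("A", "G")),
    stringsAsFactors = FALSE
  )
}

#' Build the translation groups used in the feature report
#'
#' High and Low groups are cut on control translation efficiency
#' (`M >= m_high`, `M <= m_low`); R and I come from the class labels.
#'
#' @param entries classified translatome table.
#' @param m_high,m_low control-M cutoffs for the High / Low groups
#'   (defaults 2 and -1.5).
#' @return named list of gene-id vectors (`High`, `Low`, `R`, `I`).
#' @export
translation_groups <- function(entries, m_high = 2, m_low = -1.5) {
  assert_cols(entries, c("gene_id", "te_control", "class_label"), "entries")
  list(High = entries$gene_id[entries$te_control >= m_high],
       Low = entries$gene_id[entries$te_control <= m_low],
       R = entries$gene_id[entries$class_label == "R"],
       I = entries$gene_id[entries$class_label == "I"])
}

#' Compare sequence features across translation groups
#'
#' Applies the selection filter (by default abundance `A >= 5.5` and both
#' UTRs at least 10 nt, so the UTR-derived features are defined), then
#' reports for the whole filtered set (`Total`) and for each group: medians
#' of the region lengths, means of the G+C percentages, the frequency of a
#' purine at -3 (RnnAUG), and the percentage of transcripts with at least
#' k upstream AUGs (k = 1..5). Continuous features are tested group vs
#' complement with a two-sided Welch t test; proportions with a Fisher
#' exact test (a deliberate departure from t tests on binary indicators).
#'
#' @param features feature table from [extract_features()].
#' @param groups named list of transcript-id vectors (see
#'   [translation_groups()]).
#' @param a_values named numeric vector of abundance (A) per transcript.
#' @param a_min,utr5_min,utr3_min selection filter (defaults 5.5, 10, 10).
#' @param p_flag significance flag threshold (default 0.005).
#' @return long data frame: `feature`, `statistic`, `group`, `n`, `value`,
#'   `p`, `significant`; `Total` rows carry no test.
#' @export
class_feature_report <- function(features, groups, a_values,
                                 a_min = 5.5, utr5_min = 10, utr3_min = 10,
                                 p_flag = 0.005) {
  assert_cols(features, c("transcript_id", "cds_len", "utr5_len", "utr3_len"),
              "features")
  stopifnot(!is.null(names(a_values)))
  a <- a_values[features$transcript_id]
  keep <- !is.na(a) & a >= a_min & features$utr5_len >= utr5_min &
    features$utr3_len >= utr3_min
  log_msg(sprintf("feature-report filter: kept %d of %d transcripts",
                  sum(keep), nrow(features)))
  f <- features[keep, , drop = FALSE]

  continuous <- list(
    cds_len = list(stat = "median"), utr5_len = list(stat = "median"),
    utr3_len = list(stat = "median"), cds_gc = list(stat = "mean"),
    utr5_gc = list(stat = "mean"), utr3_gc = list(stat = "mean"))
  rows <- list()
  add_row <- function(feature, statistic, group, n, value, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      feature = feature, statistic = statistic, group = group, n = n,
      value = value, p = p,
      significant = !is.na(p) & p < p_flag, stringsAsFactors = FALSE)
  }
  group_sel <- c(list(Total = rep(TRUE, nrow(f))),
                 lapply(groups, function(ids) f$transcript_id %in% ids))

  for (feat in names(continuous)) {
    stat_name <- continuous[[feat]]$stat
    stat_fun <- if (stat_name == "median") median else mean
    v <- f[[feat]]
    for (g in names(group_sel)) {
      sel <- group_sel[[g]] & !is.na(v)
      n <- sum(sel)
      val <- if (n > 0) stat_fun(v[sel]) else NA_real_
      p <- NA_real_
      if (g != "Total" && n >= 2L && sum(!sel & !is.na(v)) >= 2L)
        p <- tryCatch(t.test(v[sel], v[!sel & !is.na(v)])$p.value,
                      error = function(e) NA_real_)   # constant features
      add_row(feat, stat_name, g, n, val, p)
    }
  }

  binary <- c(list(rnnaug = f$start_context_purine),
              setNames(lapply(1:5, function(k) f$n_uaug >= k),
                       paste0("uaug_ge", 1:5)))
  for (feat in names(binary)) {
    v <- binary[[feat]]
    is_freq <- feat == "rnnaug"   # reported as frequency, uAUG rows as %
    for (g in names(group_sel)) {
      sel <- group_sel[[g]] & !is.na(v)
      n <- sum(sel)
      val <- if (n > 0) mean(v[sel]) * (if (is_freq) 1 else 100) else NA_real_
      p <- NA_real_
      out <- !sel & !is.na(v) & group_sel[["Total"]]
      if (g != "Total" && n >= 2L && sum(out) >= 2L) {
        tab <- c(sum(v[sel]), n - sum(v[sel]), sum(v[out]), sum(out) - sum(v[out]))
        p <- fisher_exact_p(tab[1L], tab[1L] + tab[3L], tab[2L] + tab[4L],
                            tab[1L] + tab[2L])
      }
      add_row(feat, if (is_freq) "frequency" else "percent", g, n, val, p)
    }
  }
  do.call(rbind, rows)
}
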