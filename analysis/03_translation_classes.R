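#!/usr/bin/env Rscript
# Score stress-induced translation changes, call the S/R/I classes, place
# calibration markers on the control TE distribution, and quantify
# translation/abundance coordination.

suppressMessages(library(translatome))
th <- class_thresholds()   # S: drop >= 0.8; R: M >= 0.8 both; I: M <= 0, gain >= 1

for (tag in c("jurkat", "nih3t3")) {
  ec <- read.delim(sprintf("results/%s_expression_control.tsv", tag))
  es <- read.delim(sprintf("results/%s_expression_stress.tsv", tag))
  entries <- classify_translation(compute_translation_change(ec, es), th)
  write_tsv(entries, sprintf("results/%s_translatome.tsv", tag))

  cls <- table(entries$class_label)
  message(sprintf("%s: %d genes | S %d (%.1f%%)  R %d (%.1f%%)  I %d (%.1f%%)",
                  tag, nrow(entries),
                  cls["S"], 100 * cls["S"] / nrow(entries),
                  cls["R"], 100 * cls["R"] / nrow(entries),
                  cls["I"], 100 * cls["I"] / nrow(entries)))

  # calibration-marker placement: the most repressed and the most engaged
  # transcripts play the roles of the classical low/high-TE markers
  te <- setNames(entries$te_control, entries$gene_id)
  markers <- c(names(sort(te))[1:2], names(sort(te, decreasing = TRUE))[1:2])
  mk <- percentile_placement(te, markers)
  write_tsv(mk, sprintf("results/%s_marker_percentiles.tsv", tag))

  coord <- coordination_analysis(entries, th)
  jsonlite::write_json(unclass(coord),
                       sprintf("results/%s_coordination.json", tag),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  message(sprintf(
    "  coordination: %d translation-only, %d abundance-only, %d both",
    coord$venn[["translation_only"]], coord$venn[["abundance_only"]],
    coord$venn[["both"]]))
  i_row <- coord$per_class[coord$per_class$class == "I", ]
  message(sprintf("  %.0f%% of I-class mRNAs also increased in abundance",
                  i_row$pct_abundance_up))

  # the abundant-protein panel: most-abundant truth transcripts measured here
  truth <- read.delim(sprintf("results/%s_truth.tsv", tag))
  panel <- head(truth$transcript_id[order(-truth$abundance)], 46)
  ss <- subset_summary(entries, panel, "abundant-protein panel")
  write_tsv(ss, sprintf("results/%s_abundant_panel.tsv", tag))
  message(sprintf(
    "  abundant panel (n=%d): control %.2f +/- %.2f -> stress %.2f +/- %.2f",
    ss$n, ss$mean_control, ss$sd_control, ss$mean_stress, ss$sd_stress))
}
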