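#!/usr/bin/env Rscript
# Sequence-feature anatomy of the translation groups: region lengths, G+C,
# upstream AUG burden and initiator context, compared group vs complement
# (filter: A >= 5.5 and both UTRs >= 10 nt).

suppressMessages(library(translatome))

for (tag in c("jurkat", "nih3t3")) {
  ann <- read.delim(sprintf("results/%s_cds.tsv", tag))
  entries <- read.delim(sprintf("results/%s_translatome.tsv", tag))
  feats <- extract_features(ann)
  rep <- class_feature_report(
    feats, translation_groups(entries),
    setNames(entries$a_control, entries$gene_id))
  write_tsv(rep, sprintf("results/%s_feature_report.tsv", tag))

  pick <- function(f, g, what = "value")
    rep[[what]][rep$feature == f & rep$group == g]
  message(sprintf("%s feature report (n filtered = %d):", tag,
                  pick("cds_len", "Total", "n")))
  message(sprintf("  uAUG>=1: total %.1f%%, I class %.1f%% (p=%.2g)",
                  pick("uaug_ge1", "Total"), pick("uaug_ge1", "I"),
                  pick("uaug_ge1", "I", "p")))
  message(sprintf("  CDS length median: total %.0f nt, I class %.0f nt (p=%.2g)",
                  pick("cds_len", "Total"), pick("cds_len", "I"),
                  pick("cds_len", "I", "p")))
  message(sprintf("  5'UTR G+C mean: total %.1f%%, I class %.1f%%",
                  pick("utr5_gc", "Total"), pick("utr5_gc", "I")))
}
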