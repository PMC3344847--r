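#!/usr/bin/env Rscript
# Functional enrichment: Fisher exact tests of each translation class
# against the gene-set collection, and a threshold-free scan over the list
# ranked by stress translation change.

suppressMessages(library(translatome))

tag <- "nih3t3"
entries <- read.delim(sprintf("results/%s_translatome.tsv", tag))
sets <- read_gmt("results/gene_sets.gmt")
bg <- entries$gene_id

cls_enr <- do.call(rbind, lapply(c("S", "R", "I"), function(cl) {
  sel <- entries$gene_id[entries$class_label == cl]
  cbind(class = cl, fisher_term_enrichment(sel, bg, sets))
}))
write_tsv(cls_enr, sprintf("results/%s_class_enrichment.tsv", tag))
top <- cls_enr[cls_enr$p_adj < 0.01, c("class", "set_id", "odds_ratio", "p_adj")]
message("class enrichments with adjusted p < 0.01:")
for (i in seq_len(nrow(top)))
  message(sprintf("  %s: %-28s OR %.1f, p_adj %.2g", top$class[i],
                  top$set_id[i], top$odds_ratio[i], top$p_adj[i]))

ranked <- entries$gene_id[order(entries$delta_te, decreasing = TRUE)]
scan <- ranked_partition_scan(ranked, sets, n_partitions = 30)
write_tsv(scan$summary, sprintf("results/%s_ranked_scan.tsv", tag))
best <- head(scan$summary, 3)
message("ranked-scan (by stress translation change) top sets:")
for (i in seq_len(nrow(best)))
  message(sprintf("  %-28s best partition %d (top %d), p_adj %.2g",
                  best$set_id[i], best$best_partition[i], best$n_selected[i],
                  best$p_adj[i]))
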