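#!/usr/bin/env Rscript
# Generate the synthetic polysome-profiling study: two cell-line-like
# presets (human-leukemia-like and mouse-fibroblast-like), each with a
# control and a stress condition, plus transcript annotations, an ortholog
# pairing and a gene-set collection. Everything downstream reads from
# results/.

suppressMessages(library(translatome))
seed <- 20260921L
dir.create("results", showWarnings = FALSE)

for (preset in c("jurkat_like", "nih3t3_like")) {
  cfg <- sim_preset(preset, seed = seed, n_genes = 2000)
  sim <- suppressWarnings(simulate_transcriptome(cfg))
  tag <- sub("_like", "", preset)
  write_tsv(sim$truth, sprintf("results/%s_truth.tsv", tag))
  write_tsv(sim$annotations, sprintf("results/%s_cds.tsv", tag)[1])
  # annotations double as FASTA for external tools
  writeLines(paste0(">", sim$annotations$transcript_id, "\n",
                    sim$annotations$sequence),
             sprintf("results/%s_transcripts.fasta", tag))
  for (cond in c("control", "stress")) {
    probes <- simulate_arrays(sim$truth, cfg, cond,
                              seed + match(cond, c("control", "stress")))
    write_tsv(probes, sprintf("results/%s_probes_%s.tsv", tag, cond))
  }
  message(sprintf(
    "%s: %d transcripts; realized P:FM mass ratio %.3f (control) / %.3f (stress)",
    preset, nrow(sim$truth),
    realized_mass_ratio(sim$truth, "control"),
    realized_mass_ratio(sim$truth, "stress")))
}

sets <- simulate_gene_sets(
  suppressWarnings(simulate_transcriptome(
    sim_preset("nih3t3_like", seed = seed, n_genes = 2000)))$truth,
  seed = seed + 9L)
write_gmt(sets, "results/gene_sets.gmt")
message(sprintf("wrote %d gene sets (3 coupled to translation classes)",
                length(sets)))
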