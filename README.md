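# translatome

Analysis of **translation efficiency from polysome-profiling two-channel
microarrays**, for researchers studying translational control — in
particular how the translatome is remodeled when stress (e.g. ER stress
with eIF2α phosphorylation) halts general initiation.

Polysome profiling splits cellular mRNA into a polysome pool **P**
(actively translated) and a free+monosome pool **FM**. With P labeled
green (Cy3) and FM red (Cy5), each transcript's translation efficiency is

```
M = log2(P / FM),        A = 1/2 · log2(R·G)   (abundance proxy)
```

and a transcript engaging polysomes with probability φ has
`M = log2(φ/(1−φ))`. On top of this statistic the package implements:

* **arrayio** — probe-table input, background correction (`none`, `half`,
  `normexp` with moment-matching and closed-form conditional expectation),
  per-gene M/A summarization over replicate probes, abundance filtering;
* **translation classes** — stress change `ΔM = M_stress − M_control` and
  the three classes, called with precedence I > R > S:
  sensitive (`ΔM ≤ −0.8`), resistant (`M ≥ 0.8` in both conditions),
  inducible (`M_control ≤ 0` and `ΔM ≥ 1`); calibration-marker midrank
  percentiles; translation-vs-abundance coordination (Venn counts and
  per-class percentages);
* **orthologs** — cross-species TE agreement through an ortholog table,
  Pearson r stratified by `min(A_a, A_b)`;
* **seqfeat** — 5'UTR/CDS/3'UTR lengths, G+C, upstream-AUG counts and
  initiator `RnnAUG` context, with Welch-t / Fisher group comparisons;
* **rnastruct** — equilibrium base-pair probabilities by a McCaskill-style
  inside–outside partition-function recursion (C++; per-pair-type
  Boltzmann weights, min hairpin loop 3) and positional BPP profiles
  anchored at start/stop codons;
* **enrichment** — Fisher exact term enrichment and a threshold-free scan
  over partitions of a ranked gene list, with BH adjustment;
* **simdata** — a calibrated synthetic study generator (ground-truth TE,
  classes, features, sequences, and two-channel intensities) so the whole
  pipeline is testable end to end;
* **pipeline** — `run_full_pipeline()` driving all stages from one config.

## Worked example

```r
library(translatome)

cfg <- sim_config(seed = 1, n_genes = 2000)        # synthetic stress study
sim <- simulate_transcriptome(cfg)
ec  <- filter_by_abundance(summarize_expression(background_correct(
         simulate_arrays(sim$truth, cfg, "control", 101), "half")), 4)
es  <- filter_by_abundance(summarize_expression(background_correct(
         simulate_arrays(sim$truth, cfg, "stress", 202), "half")), 4)
entries <- classify_translation(compute_translation_change(ec, es))
table(entries$class_label)
#>
#>   I   R   S   U
#> 133 205 991 469
coordination_analysis(entries)
#> Translation/abundance coordination report
#>   changed translation only: 926
#>   changed abundance only:   84
#>   changed both:             201
#>   per-class abundance changes:
#>  class   n n_abundance_up pct_abundance_up ...
#>      S 991             34              3.4
#>      R 205             41             20.0
#>      I 133             25             18.8
#>   among 138 abundance-up genes: 21.0% induced, 29.7% repressed
```

About half of the genes are stress-sensitive (S), a minority keeps
translating (R), and a small inducible group (I) gains engagement — and
far more genes change in translation than in abundance, the hallmark of a
translation-dominated acute stress response. Because the generator's truth
is recorded, recovery can be quantified: with log-normal intensity noise
(sd 0.25) and 3 probes per gene, the pipeline recovers true TE with
Pearson r ≈ 0.95 and calls S/R/I with balanced accuracy ≈ 0.96.

The `analysis/` directory holds the full workflow as numbered scripts
(simulate → preprocess → classify → orthologs → features → structure →
enrichment); each is a thin narrative driver over the package functions
and writes its tables under `results/`:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

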