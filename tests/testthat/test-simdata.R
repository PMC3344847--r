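test_that("the generator is deterministic given its config", {
  cfg <- sim_config(seed = 91, n_genes = 150)
  # small populations can need a calibration shift beyond the class margin;
  # the generator warns and re-checks labels, which is fine here
  s1 <- suppressWarnings(simulate_transcriptome(cfg))
  s2 <- suppressWarnings(simulate_transcriptome(cfg))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$annotations, s2$annotations)
  a1 <- simulate_arrays(s1$truth, cfg, "control", seed = 5)
  a2 <- simulate_arrays(s2$truth, cfg, "control", seed = 5)
  expect_identical(a1, a2)
  expect_false(identical(a1$green_fg,
                         simulate_arrays(s1$truth, cfg, "control", 6)$green_fg))
  expect_error(sim_config(), "seed")
})

test_that("realized class counts sit inside binomial 99% bounds", {
  mix <- c(S = 0.5, R = 0.13, I = 0.08)
  cfg <- sim_config(seed = 92, n_genes = 2000, class_mix = mix,
                    with_sequences = FALSE)
  tr <- simulate_transcriptome(cfg)$truth
  for (cl in names(mix)) {
    n <- sum(tr$true_class == cl)
    expect_gt(n, qbinom(0.005, 2000, mix[[cl]]))
    expect_lt(n, qbinom(0.995, 2000, mix[[cl]]))
  }
})

test_that("truth labels are class-consistent and margins respected", {
  cfg <- sim_config(seed = 93, n_genes = 1000, with_sequences = FALSE)
  tr <- simulate_transcriptome(cfg)$truth
  th <- cfg$thresholds
  expect_equal(classify_translation(tr$te_control, th, tr$te_stress),
               tr$true_class)
  expect_true(all(tr$delta_te[tr$true_class == "S"] <= th$s_delta))
  expect_true(all(tr$te_control[tr$true_class == "R"] >= th$r_level &
                    tr$te_stress[tr$true_class == "R"] >= th$r_level))
  expect_true(all(tr$te_control[tr$true_class == "I"] <= th$i_control_max &
                    tr$delta_te[tr$true_class == "I"] >= th$i_delta))
  expect_true(all(tr$phi_control > 0 & tr$phi_control < 1))
})

test_that("polysome mass ratios match the configured presets within 2%", {
  cfg <- sim_config(seed = 94, n_genes = 2000, with_sequences = FALSE)
  tr <- simulate_transcriptome(cfg)$truth
  expect_lt(abs(realized_mass_ratio(tr, "control") / cfg$mass_ratio_control - 1),
            0.02)
  expect_lt(abs(realized_mass_ratio(tr, "stress") / cfg$mass_ratio_stress - 1),
            0.02)
  for (p in c("jurkat_like", "nih3t3_like")) {
    cfgp <- sim_preset(p, seed = 95, n_genes = 2000, with_sequences = FALSE)
    trp <- suppressWarnings(simulate_transcriptome(cfgp)$truth)
    expect_lt(abs(realized_mass_ratio(trp, "control") / cfgp$mass_ratio_control - 1),
              0.02)
    expect_lt(abs(realized_mass_ratio(trp, "stress") / cfgp$mass_ratio_stress - 1),
              0.02)
  }
})

test_that("inducible transcripts carry more upstream AUGs than sensitive ones", {
  cfg <- sim_config(seed = 96, n_genes = 1500, with_sequences = FALSE)
  tr <- simulate_transcriptome(cfg)$truth
  expect_gt(mean(tr$n_uaug[tr$true_class == "I"]),
            mean(tr$n_uaug[tr$true_class == "S"]))
  expect_gt(median(tr$cds_len[tr$true_class == "I"]),
            median(tr$cds_len[tr$true_class == "S"]))
})

test_that("stress abundance changes are rare, mostly upward and class-coupled", {
  cfg <- sim_config(seed = 191, n_genes = 4000, with_sequences = FALSE)
  tr <- simulate_transcriptome(cfg)$truth
  chg <- abs(tr$delta_log2_abundance) >= 1
  expect_true(all(abs(tr$delta_log2_abundance[chg]) >= 1))
  expect_gt(mean(tr$delta_log2_abundance[chg] > 0), 0.8)   # mostly induction
  up_i <- mean(tr$delta_log2_abundance[tr$true_class == "I"] >= 1)
  up_s <- mean(tr$delta_log2_abundance[tr$true_class == "S"] >= 1)
  expect_gt(up_i, up_s)
  expect_equal(tr$abundance_stress, tr$abundance * 2^tr$delta_log2_abundance)
})

test_that("synthesized sequences realize the recorded features exactly", {
  cfg <- sim_config(seed = 97, n_genes = 250)
  sim <- suppressWarnings(simulate_transcriptome(cfg))   # small-n calibration
  f <- extract_features(sim$annotations)
  expect_identical(f$n_uaug, sim$truth$n_uaug)
  expect_equal(f$utr5_len, sim$truth$utr5_len)
  expect_equal(f$cds_len, sim$truth$cds_len)
  expect_equal(f$utr5_len + f$cds_len + f$utr3_len,
               nchar(sim$annotations$sequence))
  expect_identical(f$start_context_purine, sim$truth$start_context_purine)
  # CDS starts with AUG and ends with a stop codon, no in-frame stops inside
  for (g in sample(nrow(sim$truth), 20)) {
    cds <- substr(sim$annotations$sequence[g], sim$truth$utr5_len[g] + 1,
                  sim$truth$utr5_len[g] + sim$truth$cds_len[g])
    expect_equal(substr(cds, 1, 3), "ATG")
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("array expectations follow the generative closed form", {
  cfg <- sim_config(seed = 98, n_genes = 50, noise_sd = 0, bg_mean = 0,
                    bg_sd = 0, probes_per_gene = 1, with_sequences = FALSE)
  tr <- suppressWarnings(simulate_transcriptome(cfg))$truth
  pr <- simulate_arrays(tr, cfg, "control", seed = 1)
  # phi = 1/2 gives equal channels; doubling abundance raises A by 1, not M
  expect_equal(pr$green_fg / pr$red_fg, tr$phi_control / (1 - tr$phi_control))
  tr2 <- tr; tr2$abundance <- 2 * tr$abundance
  pr2 <- simulate_arrays(tr2, cfg, "control", seed = 1)
  e1 <- summarize_expression(background_correct(pr, "none"))
  e2 <- summarize_expression(background_correct(pr2, "none"))
  expect_equal(e2$M, e1$M, tolerance = 1e-12)
  expect_equal(e2$A, e1$A + 1, tolerance = 1e-12)
})

test_that("unequal channel gains bias M by exactly log2(P/FM)", {
  cfg <- sim_config(seed = 99, n_genes = 40, noise_sd = 0, bg_mean = 0,
                    bg_sd = 0, probes_per_gene = 1, gains = c(P = 3, FM = 1),
                    with_sequences = FALSE)
  tr <- suppressWarnings(simulate_transcriptome(cfg))$truth
  e <- summarize_expression(background_correct(
    simulate_arrays(tr, cfg, "control", 1), "none"))
  idx <- match(e$gene_id, tr$transcript_id)
  expect_equal(e$M, tr$te_control[idx] + log2(3), tolerance = 1e-9)
})

test_that("paired-translatome and gene-set generators expose their couplings", {
  ps <- simulate_paired_translatomes(800, seed = 100)
  expect_gt(nrow(ps$pairs), 800)                  # extra unmatched + multi rows
  expect_equal(nrow(ps$expr_a), 800)
  sets <- simulate_gene_sets(
    suppressWarnings(simulate_transcriptome(
      sim_config(seed = 101, n_genes = 400, with_sequences = FALSE)))$truth,
    seed = 7)
  expect_true(all(lengths(sets) > 0))
  expect_true("induced_tf_regulon" %in% names(sets))
})
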