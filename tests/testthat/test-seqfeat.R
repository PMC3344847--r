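test_that("annotations partition a transcript into UTR5/CDS/UTR3", {
  seqs <- c(t1 = paste(rep("ACGTA", 6), collapse = ""))   # 30 nt
  cds <- data.frame(transcript_id = "t1", cds_start = 6, cds_end = 15)
  ann <- parse_annotation(seqs, cds)
  f <- extract_features(ann)
  expect_equal(f$utr5_len, 6)
  expect_equal(f$cds_len, 9)
  expect_equal(f$utr3_len, 15)
  expect_equal(f$utr5_len + f$cds_len + f$utr3_len, nchar(seqs[["t1"]]))
})

test_that("invalid coordinates reject the transcript, not the batch", {
  seqs <- c(ok = strrep("ACG", 10), bad = strrep("ACG", 4))
  cds <- data.frame(transcript_id = c("ok", "bad", "ghost"),
                    cds_start = c(3, 3, 0), cds_end = c(12, 99, 3))
  expect_warning(ann <- parse_annotation(seqs, cds), "rejected")
  expect_equal(ann$transcript_id, "ok")
  rej <- attr(ann, "rejected")
  expect_setequal(rej$transcript_id, c("bad", "ghost"))
  # out-of-frame CDS rejected only when frame checking is on
  cds2 <- data.frame(transcript_id = "ok", cds_start = 3, cds_end = 13)
  expect_warning(a2 <- parse_annotation(seqs, cds2), "divisible")
  expect_equal(nrow(a2), 0L)
  expect_equal(nrow(parse_annotation(seqs, cds2, check_frame = FALSE)), 1L)
})

test_that("lowercase and RNA alphabets are normalized", {
  seqs <- c(t1 = "gcaaccaugGCGUGAacguacguacguacg")
  cds <- data.frame(transcript_id = "t1", cds_start = 6, cds_end = 15)
  ann <- parse_annotation(seqs, cds)
  expect_equal(substr(ann$sequence, 1, 9), "GCAACCATG")
  expect_false(grepl("U", ann$sequence))
})

test_that("feature vectors match hand computation", {
  seqs <- c(t1 = paste0("GCAACC", "ATGGCGTGA", "TTTTT"))
  cds <- data.frame(transcript_id = "t1", cds_start = 6, cds_end = 15)
  f <- extract_features(parse_annotation(seqs, cds))
  expect_equal(f$utr5_len, 6)
  expect_equal(f$utr5_gc, 100 * 4 / 6, tolerance = 1e-12)
  expect_equal(f$n_uaug, 0L)
  expect_true(f$start_context_purine)             # -3 base is 'A'

  seqs2 <- c(t2 = paste0("ATGATG", "ATGGCGTGA", "AA"))
  f2 <- extract_features(parse_annotation(
    seqs2, data.frame(transcript_id = "t2", cds_start = 6, cds_end = 15)))
  expect_equal(f2$n_uaug, 2L)

  seqs3 <- c(t3 = paste0("CG", "ATGTAA", "A"))
  f3 <- extract_features(parse_annotation(
    seqs3, data.frame(transcript_id = "t3", cds_start = 2, cds_end = 8)))
  expect_true(is.na(f3$start_context_purine))     # UTR too short for -3
})

test_that("overlapping upstream AUGs and region GC match brute-force scans", {
  set.seed(61)
  for (r in 1:300) {
    utr5_len <- sample(0:60, 1)
    s <- random_transcript(utr5_len, sample(3:10, 1), sample(0:30, 1))
    ann <- data.frame(transcript_id = "t", sequence = s,
                      cds_start = utr5_len,
                      cds_end = nchar(s) - (nchar(s) - utr5_len) %% 3)
    ann$cds_end <- utr5_len + ((nchar(s) - utr5_len) %/% 3) * 3
    f <- extract_features(ann)
    utr5 <- substr(s, 1, utr5_len)
    expect_identical(f$n_uaug, oracle_count_uaug(utr5))
    if (utr5_len > 0) {
      gc <- sum(strsplit(utr5, "")[[1]] %in% c("G", "C")) / utr5_len * 100
      expect_equal(f$utr5_gc, gc)
    }
  }
  # Ns are excluded from GC numerator and denominator
  fN <- extract_features(data.frame(transcript_id = "t", sequence = "GCNNATGTAA",
                                    cds_start = 4, cds_end = 10))
  expect_equal(fN$utr5_gc, 100)
})

test_that("feature extraction is pure", {
  set.seed(62)
  s <- random_transcript(25, 12, 30)
  ann <- data.frame(transcript_id = "t", sequence = s, cds_start = 25,
                    cds_end = 25 + 36)
  expect_identical(extract_features(ann), extract_features(ann))
})

test_that("a large location shift is detected at extreme significance", {
  set.seed(63)
  n <- 500
  base <- data.frame(
    transcript_id = paste0("t", 1:(2 * n)),
    cds_len = c(rnorm(n, 1500, 100), rnorm(n, 2500, 100)),
    utr5_len = rep(150, 2 * n), utr3_len = rep(500, 2 * n),
    cds_gc = 50, utr5_gc = 60, utr3_gc = 45,
    n_uaug = rpois(2 * n, 0.5), start_context_purine = TRUE)
  a_values <- setNames(rep(8, 2 * n), base$transcript_id)
  groups <- list(Shifted = base$transcript_id[(n + 1):(2 * n)])
  suppressMessages(
    rep <- class_feature_report(base, groups, a_values, a_min = 0,
                                utr5_min = 0, utr3_min = 0))
  p_cds <- rep$p[rep$feature == "cds_len" & rep$group == "Shifted"]
  expect_lt(p_cds, 1e-10)
  expect_true(rep$significant[rep$feature == "cds_len" & rep$group == "Shifted"])
  # sanity: the closed-form Welch statistic gives the same p
  x <- base$cds_len[(n + 1):(2 * n)]; y <- base$cds_len[1:n]
  tt <- (mean(x) - mean(y)) / sqrt(var(x) / n + var(y) / n)
  expect_gt(abs(tt), 80)
})

test_that("the selection filter and medians populate the report", {
  feats <- data.frame(
    transcript_id = paste0("t", 1:5),
    cds_len = c(300, 600, 900, 1200, 1500),
    utr5_len = c(5, 20, 30, 40, 50),      # t1 fails utr5 filter
    utr3_len = c(100, 5, 100, 100, 100),  # t2 fails utr3 filter
    cds_gc = 50, utr5_gc = 60, utr3_gc = 45,
    n_uaug = c(0, 1, 2, 0, 5), start_context_purine = c(TRUE, TRUE, FALSE, TRUE, NA))
  a_values <- setNames(rep(6, 5), feats$transcript_id)
  suppressMessages(
    rep <- class_feature_report(feats, list(G = c("t3", "t4")), a_values))
  total_n <- rep$n[rep$feature == "cds_len" & rep$group == "Total"]
  expect_equal(total_n, 3L)                               # t1, t2 filtered out
  expect_equal(rep$value[rep$feature == "cds_len" & rep$group == "Total"], 1200)
  expect_equal(rep$value[rep$feature == "uaug_ge1" & rep$group == "Total"],
               100 * 2 / 3)
  expect_equal(rep$value[rep$feature == "rnnaug" & rep$group == "G"], 0.5)
})

test_that("p-values are null-uniform when groups are exchangeable", {
  set.seed(64)
  pvals <- replicate(120, {
    feats <- data.frame(
      transcript_id = paste0("t", 1:80),
      cds_len = rnorm(80, 1200, 300), utr5_len = 150, utr3_len = 400,
      cds_gc = rnorm(80, 52, 4), utr5_gc = 60, utr3_gc = 45,
      n_uaug = 0L, start_context_purine = TRUE)
    a_values <- setNames(rep(8, 80), feats$transcript_id)
    groups <- list(G = sample(feats$transcript_id, 40))
    suppressMessages(
      rep <- class_feature_report(feats, groups, a_values, a_min = 0,
                                  utr5_min = 0, utr3_min = 0))
    rep$p[rep$feature == "cds_len" & rep$group == "G"]
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  expect_lt(mean(pvals < 0.05), 0.12)
})
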