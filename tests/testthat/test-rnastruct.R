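test_that("sequences without allowed pairs give an all-zero matrix", {
  bp <- pair_probabilities("AAAAAAA")
  expect_equal(bp$p, matrix(0, 7, 7))
  expect_warning(short <- pair_probabilities("ACG"), "min_loop")
  expect_equal(short$p, matrix(0, 3, 3))
  expect_error(pair_probabilities("ACGXU"), "position")
})

test_that("dynamic programming equals exhaustive structure enumeration", {
  set.seed(71)
  pw <- default_pair_weights()
  for (r in 1:40) {
    n <- sample(5:14, 1)
    s <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
    bp <- pair_probabilities(s)
    expect_lt(max(abs(bp$p - oracle_enum_bpp(s, pw))), 1e-9)
  }
  # and under a different weight setting
  pw2 <- c(GC = 11, AU = 0.7, GU = 0.2)
  for (r in 1:10) {
    s <- paste(sample(c("A", "C", "G", "U"), 12, replace = TRUE), collapse = "")
    expect_lt(max(abs(pair_probabilities(s, pw2)$p - oracle_enum_bpp(s, pw2))),
              1e-9)
  }
})

test_that("a strongly weighted GC stem closes with high probability", {
  bp <- pair_probabilities("GGGAAAACCC", pair_weights = c(GC = 200, AU = 2, GU = 1))
  expect_gt(bp$p[1, 10], 0.9)
  expect_gt(bp$p[2, 9], 0.9)
  expect_gt(bp$p[3, 8], 0.9)
})

test_that("probability-matrix invariants hold on random sequences", {
  set.seed(72)
  for (r in 1:20) {
    n <- sample(10:30, 1)
    s <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
    bp <- pair_probabilities(s)
    expect_true(all(rowSums(bp$p) <= 1 + 1e-9))          # marginal bound
    expect_equal(bp$p, t(bp$p))                          # symmetry
    band <- row(bp$p) < col(bp$p) & col(bp$p) - row(bp$p) <= 3
    expect_true(all(bp$p[band] == 0))                    # min_loop exclusion
    # reversal: the reverse complement pairs (n+1-j, n+1-i); wobble pairs
    # break the mapping (GU complements to AC), so check Watson-Crick only
    wc <- c(GC = 6, AU = 2, GU = 0)
    bp_wc <- pair_probabilities(s, wc)
    chars <- chartr("ACGU", "UGCA", s)
    rc <- paste(rev(strsplit(chars, "")[[1]]), collapse = "")
    bp_rc <- pair_probabilities(rc, wc)
    expect_equal(bp_rc$p, bp_wc$p[n:1, n:1], tolerance = 1e-12)
  }
})

test_that("raising the GC weight never weakens an isolated GC helix", {
  s <- "GGGGAAAACCCC"
  probs <- vapply(c(1, 2, 4, 8, 16, 32), function(w)
    pair_probabilities(s, c(GC = w, AU = 2, GU = 1))$p[1, 12], 1)
  expect_true(all(diff(probs) >= -1e-12))
})

test_that("sparse import/export round-trips the matrix", {
  set.seed(73)
  s <- paste(sample(c("A", "C", "G", "U"), 25, replace = TRUE), collapse = "")
  bp <- pair_probabilities(s)
  f <- tempfile()
  write_bpp(bp, f)
  bp2 <- read_bpp(f)
  expect_equal(bp2$p, bp$p, tolerance = 1e-9)
})

test_that("profiles have the window's shape and honor the anchor convention", {
  set.seed(74)
  seqs <- vapply(1:6, function(i) random_transcript(30, 40, 40), "")
  ann <- data.frame(transcript_id = paste0("t", 1:6), sequence = seqs,
                    cds_start = 30, cds_end = 150)
  groups <- list(hi = paste0("t", 1:3), lo = paste0("t", 4:6))
  win <- c(-10:-1, 1:40)
  prof <- positional_bpp_profile(ann, groups, "start", win, flank = 15)
  expect_equal(nrow(prof), length(win))
  expect_equal(prof$offset, win)
  expect_true(all(prof$mean_hi >= 0 & prof$mean_hi <= 1))
  prof_stop <- positional_bpp_profile(ann, groups, "stop", c(-5:-1, 1:10),
                                      flank = 15)
  expect_equal(nrow(prof_stop), 15)

  # windows that leave the sequence exclude the transcript
  wide <- c(-40:-1, 1:40)
  suppressMessages(
    prof_w <- positional_bpp_profile(ann, groups, "start", wide, flank = 5))
  expect_true(all(prof_w$n_hi == 0))
})

test_that("a designed downstream helix separates groups; shuffled controls do not", {
  set.seed(75)
  # A/T elsewhere keeps the stem the only G/C material, so the pair-weight
  # ensemble concentrates on the designed helix rather than on scattered
  # background partners
  make_tx <- function(with_helix) {
    utr5 <- paste(sample(c("A", "T"), 20, replace = TRUE), collapse = "")
    stem5 <- "GGCGCCGCC"                       # CDS offsets +18..+26
    loop <- "ATAA"
    stem3 <- "GGCGGCGCC"                       # reverse complement of stem5
    if (!with_helix) {
      reg <- strsplit(paste0(stem5, loop, stem3), "")[[1]]
      sh <- paste(sample(reg), collapse = "")
      stem5 <- substr(sh, 1, 9); loop <- substr(sh, 10, 13)
      stem3 <- substr(sh, 14, 22)
    }
    pre <- paste(sample(c("A", "T"), 14, replace = TRUE), collapse = "")
    post <- paste(sample(c("A", "T"), 45, replace = TRUE), collapse = "")
    cds <- paste0("ATG", pre, stem5, loop, stem3, post, "TAA")
    paste0(utr5, cds)
  }
  n <- 40
  seqs <- c(vapply(1:n, function(i) make_tx(TRUE), ""),
            vapply(1:n, function(i) make_tx(FALSE), ""))
  ann <- data.frame(transcript_id = paste0("t", 1:(2 * n)), sequence = seqs,
                    cds_start = 20, cds_end = nchar(seqs))
  groups <- list(helix = paste0("t", 1:n), shuffled = paste0("t", (n + 1):(2 * n)))
  prof <- positional_bpp_profile(ann, groups, "start", window = 1:45, flank = 20)
  sel <- prof$offset %in% 18:26
  expect_true(all(prof$mean_helix[sel] > prof$mean_shuffled[sel]))
  expect_true(all(prof$p[sel] < 0.05))
})

test_that("identical groups stay near the nominal false-positive rate", {
  set.seed(76)
  seqs <- vapply(1:60, function(i) random_transcript(25, 30, 25), "")
  ann <- data.frame(transcript_id = paste0("t", 1:60), sequence = seqs,
                    cds_start = 25, cds_end = 115)
  groups <- list(a = paste0("t", 1:30), b = paste0("t", 31:60))
  prof <- positional_bpp_profile(ann, groups, "start", c(-10:-1, 1:30),
                                 flank = 20)
  expect_lt(mean(prof$significant, na.rm = TRUE), 0.2)
})
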