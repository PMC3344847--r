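# Synthetic polysome-profiling study generator: ground-truth translation
# states, transcript sequences with coupled features, and two-channel probe
# intensities, so every pipeline stage is testable without any download.
#
# The generative model inverts the pipeline's statistic: a transcript with
# true translation efficiency te engages polysomes with probability
# phi = 2^te / (1 + 2^te), and the two dye channels measure abundance*phi
# (green / polysome) and abundance*(1-phi) (red / free+monosome), up to
# gains, multiplicative log-normal noise and additive background.

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
.phi <- function(te) 2^te / (1 + 2^te)

#' Configuration of a synthetic polysome-profiling study
#'
#' Defaults describe a stress experiment with a severe, abundance-biased
#' translational shutdown: half of the genes lose at least 0.8 log2 units of
#' polysome engagement, a resistant minority keeps translating at high
#' levels, and a small inducible group is de-repressed. Polysome:free
#' RNA mass ratios per condition (2:1 control, 1:3 stress by default) are
#' enforced exactly by a global calibration shift of the drawn efficiencies.
#'
#' @param seed integer seed (mandatory; the generator is fully
#'   deterministic given the config).
#' @param n_genes number of transcripts.
#' @param class_mix named proportions for `S`, `R`, `I` (the remainder is
#'   unclassified `U`); must sum to at most 1.
#' @param probes_per_gene replicate probes per transcript.
#' @param noise_sd sd of the multiplicative log-normal intensity noise
#'   (natural-log scale).
#' @param bg_mean,bg_sd additive background level and spread (intensity
#'   units).
#' @param mass_ratio_control,mass_ratio_stress target polysome:free total
#'   RNA mass ratios.
#' @param gains named vector `c(P=, FM=)` of per-unit-mass channel gains;
#'   unequal gains bias the M estimate by `log2(P/FM)`, which is the point
#'   of exposing them.
#' @param gain_mode `"proportional"` hybridizes each pool proportionally to
#'   its true mass (the unbiased convention); `"fixed_total"` rescales the
#'   channel totals to the configured mass ratio regardless of the realized
#'   one.
#' @param abundance_meanlog2,abundance_sdlog2 log2-normal abundance
#'   distribution.
#' @param abundance_class_coupling logistic coefficient tying the
#'   probability of being stress-sensitive to (standardized) log abundance.
#' @param s_drop_coupling extra stress drop, in log2 units per positive
#'   standardized log-abundance unit, for sensitive transcripts.
#' @param abundance_up_prob named per-class probabilities that a
#'   transcript's abundance responds to stress; nine in ten responders go
#'   up by at least 1 log2 unit (transcriptional induction), the rest down.
#' @param s_drop_mean mean of the exponential tail of the sensitive-class
#'   stress drop beyond the boundary (log2 units).
#' @param te_level additive offset of the control efficiency level (log2),
#'   used by presets to represent cell lines with globally slower
#'   translation.
#' @param margin log2 slack kept between every drawn efficiency and its
#'   class decision boundary, so the calibration shift cannot flip truth
#'   labels.
#' @param thresholds a [class_thresholds()] object defining the boundaries.
#' @param with_sequences also synthesize transcript sequences with coupled
#'   features (uAUG counts, G+C, lengths).
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(seed, n_genes = 2000,
                       class_mix = c(S = 0.5, R = 0.13, I = 0.08),
                       probes_per_gene = 3, noise_sd = 0.25,
                       bg_mean = 40, bg_sd = 6,
                       mass_ratio_control = 2, mass_ratio_stress = 1 / 3,
                       gains = c(P = 1, FM = 1),
                       gain_mode = c("proportional", "fixed_total"),
                       abundance_meanlog2 = 8, abundance_sdlog2 = 2,
                       abundance_class_coupling = 1.6, s_drop_coupling = 1.0,
                       abundance_up_prob = c(S = 0.04, R = 0.20, I = 0.28,
                                             U = 0.08),
                       s_drop_mean = 1.6, te_level = 0, margin = 0.2,
                       thresholds = class_thresholds(),
                       with_sequences = TRUE) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(all(c("S", "R", "I") %in% names(class_mix)),
            sum(class_mix) <= 1, all(class_mix >= 0),
            n_genes >= 10, probes_per_gene >= 1, noise_sd >= 0,
            all(c("S", "R", "I", "U") %in% names(abundance_up_prob)),
            all(abundance_up_prob >= 0 & abundance_up_prob <= 0.9),
            inherits(thresholds, "class_thresholds"))
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    class_mix = class_mix[c("S", "R", "I")],
    probes_per_gene = as.integer(probes_per_gene), noise_sd = noise_sd,
    bg_mean = bg_mean, bg_sd = bg_sd,
    mass_ratio_control = mass_ratio_control,
    mass_ratio_stress = mass_ratio_stress,
    gains = gains, gain_mode = match.arg(gain_mode),
    abundance_meanlog2 = abundance_meanlog2,
    abundance_sdlog2 = abundance_sdlog2,
    abundance_class_coupling = abundance_class_coupling,
    abundance_up_prob = abundance_up_prob,
    s_drop_coupling = s_drop_coupling, s_drop_mean = s_drop_mean,
    te_level = te_level, margin = margin,
    thresholds = thresholds, with_sequences = with_sequences
  ), class = "sim_config")
}

#' Preset study configurations
#'
#' `"jurkat_like"`: polysome:free mass 2:1 in control, 1:3 under stress,
#' with a large resistant class and a small inducible one.
#' `"nih3t3_like"`: 1.5:1 control mass ratio, small resistant and larger
#' inducible classes.
#'
#' @param name preset name.
#' @param seed integer seed.
#' @param ... overrides passed on to [sim_config()].
#' @return a `"sim_config"` object.
#' @export
sim_preset <- function(name = c("jurkat_like", "nih3t3_like"), seed, ...) {
  name <- match.arg(name)
  args <- switch(name,
    jurkat_like = list(mass_ratio_control = 2,
                       class_mix = c(S = 0.45, R = 0.13, I = 0.015)),
    nih3t3_like = list(mass_ratio_control = 1.5, te_level = -0.45,
                       s_drop_mean = 1.1,
                       class_mix = c(S = 0.45, R = 0.04, I = 0.08)))
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, c(list(seed = seed), args))
}

# class-conditional efficiency draws. All constraints are kept `m` log2
# units inside the decision boundaries of `th` so that the global
# calibration shift (bounded by m) cannot flip a truth label.
.draw_te <- function(cls, th, m, z, s_drop_coupling, level = 0,
                     s_drop_mean = 1.6) {
  n <- length(z)
  te_c <- numeric(n); delta <- numeric(n)
  i <- which(cls == "S")
  if (length(i)) {
    repeat {
      te_c[i] <- rnorm(length(i), 1.2 + level, 0.78)
      delta[i] <- -(abs(th$s_delta) + m) - rexp(length(i), 1 / s_drop_mean) -
        s_drop_coupling * pmax(z[i], 0)
      bad <- te_c[i] < th$i_control_max + m |
        te_c[i] + delta[i] > th$r_level - m
      if (!any(bad)) break
      i <- i[bad]
    }
  }
  i <- which(cls == "R")
  if (length(i)) {
    te_c[i] <- th$r_level + m + 0.1 + abs(rnorm(length(i), 0, 0.9))
    delta[i] <- (th$r_level + m + 0.1 + abs(rnorm(length(i), 0, 0.9))) - te_c[i]
  }
  i <- which(cls == "I")
  if (length(i)) {
    te_c[i] <- th$i_control_max - m - 0.15 - abs(rnorm(length(i), 0, 0.8))
    delta[i] <- th$i_delta + m + 0.2 + rexp(length(i), 1 / 1.2)
  }
  i <- which(cls == "U")
  if (length(i)) {
    repeat {
      te_c[i] <- rnorm(length(i), 0.5 + level, 0.62)
      delta[i] <- rnorm(length(i), -0.22, 0.22)
      te_s <- te_c[i] + delta[i]
      bad <- delta[i] <= th$s_delta + m |
        (te_c[i] <= th$i_control_max + m & delta[i] >= th$i_delta - m) |
        (te_c[i] >= th$r_level - m & te_s >= th$r_level - m)
      if (!any(bad)) break
      i <- i[bad]
    }
  }
  list(te_c = te_c, delta = delta)
}

# global additive shift of efficiencies matching the abundance-weighted
# polysome:free mass ratio to its target
.calibrate_shift <- function(te, abundance, target) {
  f <- function(d) {
    phi <- .phi(te + d)
    sum(abundance * phi) / sum(abundance * (1 - phi)) - target
  }
  uniroot(f, c(-4, 4), extendInt = "yes", tol = 1e-10)$root
}

#' Simulate a ground-truth transcriptome
#'
#' Draws per-transcript abundance, translation class, control efficiency and
#' stress shift, then applies a per-condition global shift so the
#' abundance-weighted polysome:free mass ratios match the configured
#' targets exactly. Stress sensitivity and the size of the stress drop both
#' increase with abundance (abundant messages carry most of the ribosome
#' load and are hit hardest), which is what lets the stress-side mass ratio
#' collapse while only about half of the genes cross the sensitive cutoff.
#' Optionally synthesizes transcript sequences whose upstream-AUG counts,
#' lengths and G+C track the translation state.
#'
#' @param config a [sim_config()] object.
#' @return list with `truth` (per-transcript ground truth), `annotations`
#'   (sequence + CDS table, or `NULL`), and `config`.
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  th <- config$thresholds
  n <- config$n_genes
  mix <- config$class_mix
  ids <- sprintf("G%05d", seq_len(n))

  log2a <- rnorm(n, config$abundance_meanlog2, config$abundance_sdlog2)
  abundance <- 2^log2a
  z <- as.numeric(scale(log2a))

  # class assignment; P(S) rises with abundance, marginal proportions kept
  kap <- config$abundance_class_coupling
  off <- uniroot(function(b) mean(plogis(b + kap * z)) - mix[["S"]],
                 c(-15, 15), tol = 1e-10)$root
  p_s <- plogis(off + kap * z)
  scale_ri <- (1 - p_s) / (1 - mix[["S"]])
  p_r <- mix[["R"]] * scale_ri
  p_i <- mix[["I"]] * scale_ri
  u <- runif(n)
  cls <- ifelse(u < p_s, "S",
         ifelse(u < p_s + p_r, "R",
         ifelse(u < p_s + p_r + p_i, "I", "U")))

  d <- .draw_te(cls, th, config$margin, z, config$s_drop_coupling, config$te_level,
                config$s_drop_mean)
  te_c <- d$te_c; delta <- d$delta

  # transcriptional side of the stress response: abundance changes are rare,
  # mostly upward, and concentrated in the inducible and resistant classes
  p_up <- config$abundance_up_prob[cls]
  chg <- runif(n) < p_up / 0.9          # 90% of changed genes go up
  up <- chg & (runif(n) < 0.9)
  dla <- numeric(n)
  dla[chg] <- (1 + rexp(sum(chg), 1 / 0.6)) * ifelse(up[chg], 1, -1)
  abundance_stress <- abundance * 2^dla

  dc <- .calibrate_shift(te_c, abundance, config$mass_ratio_control)
  ds <- .calibrate_shift(te_c + delta, abundance_stress,
                         config$mass_ratio_stress)
  te_c <- te_c + dc
  delta <- delta + ds - dc
  if (max(abs(c(dc, ds))) > config$margin)
    warning(sprintf(
      "calibration shift (%.2f, %.2f) exceeds the class margin %.2f; truth labels re-checked",
      dc, ds, config$margin), call. = FALSE)

  # genes whose label the shift flipped are redrawn directly in final space
  viol <- which(classify_translation(te_c, th, te_c + delta) != cls)
  if (length(viol) > 0L) {
    rd <- .draw_te(cls[viol], th, config$margin, z[viol], config$s_drop_coupling, config$te_level,
                config$s_drop_mean)
    te_c[viol] <- rd$te_c; delta[viol] <- rd$delta
  }
  stopifnot(all(classify_translation(te_c, th, te_c + delta) == cls))

  te_s <- te_c + delta
  tcl <- .clamp(te_c, -2, 2)
  is_i <- cls == "I"
  utr5_len <- pmin(pmax(round(rlnorm(n, log(140), 0.8) *
                                ifelse(is_i, 1.45, ifelse(cls == "R", 1.35, 1))),
                        3L), 3000L)
  cds_len <- 3L * pmax(round(rlnorm(n, log(1250 / 3) +
                                      ifelse(is_i, log(1.8),
                                             ifelse(cls == "R", log(1.25), 0)),
                                    0.75)), 35L)
  utr3_len <- pmax(round(rlnorm(n, log(800), 0.9) * ifelse(is_i, 1.9, 1)), 5L)
  utr5_gc <- .clamp(65 + 1.2 * tcl - 3.5 * is_i + rnorm(n, 0, 5), 35, 85)
  cds_gc <- .clamp(53 + 0.8 * tcl - 3 * is_i + rnorm(n, 0, 4), 35, 72)
  utr3_gc <- .clamp(44 - 3 * is_i + rnorm(n, 0, 5), 25, 65)
  lambda <- 0.55 * exp(-0.35 * tcl) * (1 + 0.5 * is_i)
  uaug_cap <- ifelse(utr5_len >= 12L, (utr5_len - 12L) %/% 3L + 1L, 0L)
  n_uaug <- as.integer(pmin(rpois(n, lambda), uaug_cap, 8L))
  purine <- ifelse(utr5_len >= 3L,
                   rbinom(n, 1L, 0.87 - 0.03 * is_i) == 1L, NA)

  truth <- data.frame(
    transcript_id = ids, abundance = abundance,
    abundance_stress = abundance_stress, log2_abundance = log2a,
    delta_log2_abundance = dla,
    true_class = cls, te_control = te_c, te_stress = te_s, delta_te = delta,
    phi_control = .phi(te_c), phi_stress = .phi(te_s),
    utr5_len = utr5_len, cds_len = cds_len, utr3_len = utr3_len,
    utr5_gc = utr5_gc, cds_gc = cds_gc, utr3_gc = utr3_gc,
    n_uaug = n_uaug, start_context_purine = purine,
    stringsAsFactors = FALSE
  )
  annotations <- if (config$with_sequences) .build_sequences(truth) else NULL
  list(truth = truth, annotations = annotations, config = config)
}

.random_bases <- function(k, gc) {
  sample(c("G", "C", "A", "T"), k, replace = TRUE,
         prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
}

.scrub_atg <- function(v) {
  k <- length(v)
  if (k < 3L) return(v)
  hit <- which(v[seq_len(k - 2L)] == "A" & v[seq_len(k - 2L) + 1L] == "T" &
                 v[seq_len(k - 2L) + 2L] == "G")
  if (length(hit)) v[hit + 1L] <- "C"
  v
}

.build_utr5 <- function(len, gc, n_uaug, purine) {
  v <- .scrub_atg(.random_bases(len, gc))
  if (n_uaug > 0L) {
    blocks <- seq(1L, len - 11L, by = 3L)   # keep the last bases plant-free
    at <- sort(blocks[sample.int(length(blocks), n_uaug)])
    for (p in at) v[p:(p + 2L)] <- c("A", "T", "G")
  }
  if (len >= 3L && !is.na(purine))
    v[len - 2L] <- if (purine) sample(c("A", "G"), 1L) else sample(c("C", "T"), 1L)
  # the context base may have recreated an AUG near the 3' end; repair
  if (len >= 3L) {
    k <- len
    hit <- which(v[seq_len(k - 2L)] == "A" & v[seq_len(k - 2L) + 1L] == "T" &
                   v[seq_len(k - 2L) + 2L] == "G")
    planted <- if (n_uaug > 0L) at else integer(0)
    for (q in setdiff(hit, planted)) {
      if (q + 1L != k - 2L) v[q + 1L] <- "C" else v[q] <- "C"
    }
  }
  v
}

.build_cds <- function(len, gc) {
  n_codon <- len %/% 3L
  stops <- c("TAA", "TAG", "TGA")
  inner <- matrix(.random_bases(3L * (n_codon - 2L), gc), nrow = 3L)
  repeat {
    cod <- paste0(inner[1L, ], inner[2L, ], inner[3L, ])
    bad <- cod %in% stops
    if (!any(bad)) break
    inner[, bad] <- .random_bases(3L * sum(bad), gc)
  }
  c("A", "T", "G", as.vector(inner),
    strsplit(sample(stops, 1L), "")[[1L]])
}

.build_sequences <- function(truth) {
  n <- nrow(truth)
  seqs <- character(n)
  for (g in seq_len(n)) {
    utr5 <- .build_utr5(truth$utr5_len[g], truth$utr5_gc[g] / 100,
                        truth$n_uaug[g], truth$start_context_purine[g])
    cds <- .build_cds(truth$cds_len[g], truth$cds_gc[g] / 100)
    utr3 <- .random_bases(truth$utr3_len[g], truth$utr3_gc[g] / 100)
    seqs[g] <- paste(c(utr5, cds, utr3), collapse = "")
  }
  data.frame(
    transcript_id = truth$transcript_id, sequence = seqs,
    cds_start = truth$utr5_len, cds_end = truth$utr5_len + truth$cds_len,
    stringsAsFactors = FALSE
  )
}

#' Simulate two-channel probe intensities for one condition
#'
#' Expected signals are `abundance * phi * gain_P` (green, polysome) and
#' `abundance * (1 - phi) * gain_FM` (red, free+monosome) with the
#' condition's engagement `phi`; each replicate probe gets independent
#' multiplicative log-normal noise and additive normal background, and the
#' per-probe background columns carry the background level itself (a local
#' background estimate).
#'
#' @param truth truth table from [simulate_transcriptome()].
#' @param config the study's [sim_config()].
#' @param condition `"control"` or `"stress"`.
#' @param seed seed for the array-level noise (separate from the
#'   transcriptome seed so conditions get independent noise).
#' @return probe table in the layout of [read_probe_table()].
#' @export
simulate_arrays <- function(truth, config, condition = c("control", "stress"),
                            seed) {
  stopifnot(inherits(config, "sim_config"))
  condition <- match.arg(condition)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(as.integer(seed))
  phi <- if (condition == "control") truth$phi_control else truth$phi_stress
  a <- if (condition == "control" || is.null(truth$abundance_stress))
    truth$abundance else truth$abundance_stress
  mu_g <- a * phi * config$gains[["P"]]
  mu_r <- a * (1 - phi) * config$gains[["FM"]]
  if (config$gain_mode == "fixed_total") {
    target <- if (condition == "control") config$mass_ratio_control
              else config$mass_ratio_stress
    mu_g <- mu_g * target / (sum(mu_g) / sum(mu_r))
  }
  k <- config$probes_per_gene
  np <- nrow(truth) * k
  gi <- rep(seq_len(nrow(truth)), each = k)
  noise <- function(mu) mu * exp(rnorm(np, 0, config$noise_sd))
  bg_g <- pmax(rnorm(np, config$bg_mean, config$bg_sd), 0)
  bg_r <- pmax(rnorm(np, config$bg_mean, config$bg_sd), 0)
  # the reported background is a local estimate, not the true level
  est <- function(b) if (config$bg_sd > 0)
    pmax(b + rnorm(np, 0, config$bg_sd / 3), 0) else b
  data.frame(
    probe_id = paste0(truth$transcript_id[gi], "_p", rep(seq_len(k), nrow(truth))),
    gene_id = truth$transcript_id[gi],
    green_fg = noise(mu_g[gi]) + bg_g,
    green_bg = est(bg_g),
    red_fg = noise(mu_r[gi]) + bg_r,
    red_bg = est(bg_r),
    condition = condition,
    stringsAsFactors = FALSE
  )
}

#' Realized polysome:free RNA mass ratio of a simulated transcriptome
#'
#' @param truth truth table from [simulate_transcriptome()].
#' @param condition `"control"` or `"stress"`.
#' @return the abundance-weighted ratio `sum(a*phi) / sum(a*(1-phi))`.
#' @export
realized_mass_ratio <- function(truth, condition = c("control", "stress")) {
  condition <- match.arg(condition)
  phi <- if (condition == "control") truth$phi_control else truth$phi_stress
  a <- if (condition == "control" || is.null(truth$abundance_stress))
    truth$abundance else truth$abundance_stress
  sum(a * phi) / sum(a * (1 - phi))
}

#' Simulate paired translatomes of two species with abundance-dependent
#' agreement
#'
#' Generates ortholog-paired expression tables where both species share a
#' latent efficiency and the idiosyncratic noise shrinks with abundance, so
#' the cross-species correlation rises across abundance strata. A few
#' unresolvable and one-to-many ortholog rows are included to exercise the
#' pairing logic.
#'
#' @param n_pairs number of ortholog pairs.
#' @param seed integer seed.
#' @param noise_base idiosyncratic sd at average abundance.
#' @param noise_coupling exponential decay of that sd per standardized
#'   log-abundance unit.
#' @param frac_unmatched fraction of pairs whose ids are absent from the
#'   expression tables.
#' @param frac_multi fraction of extra duplicated-id (one-to-many) rows.
#' @return list with `pairs`, `expr_a`, `expr_b`.
#' @export
simulate_paired_translatomes <- function(n_pairs = 5000, seed,
                                         noise_base = 0.9,
                                         noise_coupling = 0.45,
                                         frac_unmatched = 0.05,
                                         frac_multi = 0.03) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(as.integer(seed))
  log2a <- rnorm(n_pairs, 8, 2)
  z <- as.numeric(scale(log2a))
  shared <- rnorm(n_pairs, 0.8, 1.0) + 0.15 * z
  sd_e <- pmax(noise_base * exp(-noise_coupling * z), 0.05)
  te_a <- shared + rnorm(n_pairs, 0, sd_e)
  te_b <- shared + rnorm(n_pairs, 0, sd_e)
  id_a <- sprintf("HsG%05d", seq_len(n_pairs))
  id_b <- sprintf("MmG%05d", seq_len(n_pairs))
  expr_a <- data.frame(gene_id = id_a, M = te_a,
                       A = log2a + rnorm(n_pairs, 0, 0.3),
                       stringsAsFactors = FALSE)
  expr_b <- data.frame(gene_id = id_b, M = te_b,
                       A = log2a + rnorm(n_pairs, 0, 0.3),
                       stringsAsFactors = FALSE)
  pairs <- data.frame(id_a = id_a, id_b = id_b, stringsAsFactors = FALSE)
  n_un <- round(frac_unmatched * n_pairs)
  if (n_un > 0L)
    pairs <- rbind(pairs, data.frame(
      id_a = sprintf("HsX%05d", seq_len(n_un)),
      id_b = sprintf("MmX%05d", seq_len(n_un))))
  n_mu <- round(frac_multi * n_pairs)
  if (n_mu > 0L) {
    i <- sample(n_pairs, n_mu)
    j <- sample(n_pairs, n_mu)
    pairs <- rbind(pairs, data.frame(id_a = id_a[i], id_b = id_b[j]))
  }
  list(pairs = pairs, expr_a = expr_a, expr_b = expr_b)
}

#' Simulate a gene-set collection coupled to the translation classes
#'
#' Builds random gene sets plus, optionally, sets concentrated in the
#' inducible, resistant and sensitive classes (mimicking coherent
#' functional programs such as stress-response transcription factors), for
#' exercising the enrichment machinery with known positives.
#'
#' @param truth truth table from [simulate_transcriptome()].
#' @param seed integer seed.
#' @param n_random number of uncoupled random sets.
#' @param size_range set-size range.
#' @param coupled also generate the three class-coupled sets.
#' @return named list of gene sets with a `"descriptions"` attribute.
#' @export
simulate_gene_sets <- function(truth, seed, n_random = 25,
                               size_range = c(15, 80), coupled = TRUE) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(as.integer(seed))
  ids <- truth$transcript_id
  sets <- list()
  desc <- character(0)
  take <- function(pool, n) sample(pool, min(n, length(pool)))
  if (coupled) {
    i_ids <- ids[truth$true_class == "I"]
    r_ids <- ids[truth$true_class == "R"]
    s_ids <- ids[truth$true_class == "S"]
    sets$induced_tf_regulon <- unique(c(take(i_ids, 32), take(ids, 8)))
    sets$resistant_chaperone_core <- unique(c(take(r_ids, 32), take(ids, 8)))
    sets$sensitive_housekeeping <- unique(c(take(s_ids, 48), take(ids, 12)))
    desc <- c(induced_tf_regulon = "stress-inducible transcription-factor program",
              resistant_chaperone_core = "arrest-resistant chaperone/repair program",
              sensitive_housekeeping = "stress-sensitive housekeeping program")
  }
  for (j in seq_len(n_random)) {
    nm <- sprintf("random_set_%02d", j)
    sets[[nm]] <- take(ids, sample(size_range[1L]:size_range[2L], 1L))
    desc[nm] <- "uncoupled random set"
  }
  attr(sets, "descriptions") <- desc
  sets
}
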