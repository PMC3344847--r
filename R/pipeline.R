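# End-to-end orchestration: config -> arrays -> expression -> classes ->
# downstream analyses, with bookkeeping that makes a rerun reproducible.

.default_stages <- c("simulate", "preprocess", "classify", "orthologs",
                     "features", "bpp", "enrich")

#' Assemble (or read) a pipeline run configuration
#'
#' A run configuration is a plain nested list; YAML files with the same
#' structure are accepted. Recognized fields: `seed` (mandatory), `stages`
#' (subset of simulate, preprocess, classify, orthologs, features, bpp,
#' enrich), `inputs` (paths: `probe_control`, `probe_stress`, `fasta`,
#' `cds`, `orthologs`, `gmt`; all optional when simulation is enabled),
#' `sim` (arguments for [sim_config()], or `preset` naming a
#' [sim_preset()]), and `methods` (`background_method`, `a_min`,
#' `thresholds` as arguments for [class_thresholds()], `markers`,
#' `a_cutoffs`, `n_partitions`, `bpp` window settings, `feature_filter`).
#'
#' @param config path to a YAML file or a list.
#' @return validated config list of class `"run_config"`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config field 'seed' is required", call. = FALSE)
  config$stages <- config$stages %||% .default_stages
  bad <- setdiff(config$stages, .default_stages)
  if (length(bad) > 0L)
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  config$inputs <- config$inputs %||% list()
  for (f in names(config$inputs)) {
    p <- config$inputs[[f]]
    if (!is.null(p) && !file.exists(p))
      stop(sprintf("config inputs$%s: path '%s' does not exist", f, p),
           call. = FALSE)
  }
  simulating <- "simulate" %in% config$stages
  if (!simulating && is.null(config$inputs$probe_control))
    stop("config field 'inputs$probe_control' is required when the simulate stage is disabled",
         call. = FALSE)
  if ("enrich" %in% config$stages && !simulating && is.null(config$inputs$gmt))
    stop("config field 'inputs$gmt' is required for the enrich stage",
         call. = FALSE)
  config$methods <- config$methods %||% list()
  structure(config, class = c("run_config", "list"))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (simulate, preprocess, classify,
#' then the independent downstream analyses), writing every module's table
#' under `out_dir` plus a `run_summary.json` with versions, seed,
#' thresholds and the gene counts at each filter boundary. Identical config
#' and inputs yield identical outputs; on a stage failure the error names
#' the stage and the outputs of completed stages remain on disk.
#'
#' @param config a [run_config()] (or anything it accepts).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results of each stage.
#' @export
run_full_pipeline <- function(config, out_dir) {
  config <- run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  enabled <- function(s) s %in% config$stages
  m <- config$methods
  th <- do.call(class_thresholds, m$thresholds %||% list())
  seed <- as.integer(config$seed)
  summary <- list(
    package_version = as.character(utils::packageVersion("translatome")),
    r_version = R.version.string, seed = seed,
    stages = config$stages, thresholds = unclass(th), counts = list())

  sim <- NULL
  if (enabled("simulate")) {
    sim <- .stage("simulate", {
      sim_args <- config$sim %||% list()
      cfg <- if (!is.null(sim_args$preset)) {
        do.call(sim_preset, c(list(name = sim_args$preset, seed = seed),
                              sim_args[setdiff(names(sim_args), "preset")]))
      } else do.call(sim_config, c(list(seed = seed), sim_args))
      simulate_transcriptome(cfg)
    })
    res$sim <- sim
    write_tsv(sim$truth, file.path(out_dir, "sim_truth.tsv"))
    summary$counts$n_genes_simulated <- nrow(sim$truth)
  }

  probes <- .stage("preprocess", {
    if (!is.null(config$inputs$probe_control)) {
      list(control = read_probe_table(config$inputs$probe_control,
                                      condition = "control"),
           stress = read_probe_table(config$inputs$probe_stress,
                                     condition = "stress"))
    } else {
      if (is.null(sim)) stop("no probe input and simulation disabled")
      list(control = simulate_arrays(sim$truth, sim$config, "control", seed + 1L),
           stress = simulate_arrays(sim$truth, sim$config, "stress", seed + 2L))
    }
  })
  expr <- .stage("preprocess", {
    method <- m$background_method %||% "half"
    a_min <- m$a_min %||% 4
    lapply(probes, function(p) {
      filter_by_abundance(summarize_expression(background_correct(p, method)),
                          a_min)
    })
  })
  res$expression <- expr
  write_tsv(expr$control, file.path(out_dir, "expression_control.tsv"))
  write_tsv(expr$stress, file.path(out_dir, "expression_stress.tsv"))
  summary$counts$n_probes <- vapply(probes, nrow, 1L)
  summary$counts$n_genes_after_filter <- vapply(expr, nrow, 1L)

  entries <- NULL
  if (enabled("classify")) {
    entries <- .stage("classify", {
      e <- classify_translation(
        compute_translation_change(expr$control, expr$stress), th)
      write_tsv(e, file.path(out_dir, "translatome.tsv"))
      coord <- coordination_analysis(e, th)
      jsonlite::write_json(unclass(coord), file.path(out_dir, "coordination.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      if (!is.null(m$markers)) {
        mk <- percentile_placement(setNames(e$te_control, e$gene_id), m$markers)
        write_tsv(mk, file.path(out_dir, "marker_percentiles.tsv"))
      }
      e
    })
    res$entries <- entries
    summary$counts$class_sizes <- as.list(table(entries$class_label))
  }

  if (enabled("orthologs")) {
    res$orthologs <- .stage("orthologs", {
      if (!is.null(config$inputs$orthologs)) {
        pr <- read.delim(config$inputs$orthologs, stringsAsFactors = FALSE)
        names(pr)[1:2] <- c("id_a", "id_b")
        paired <- pair_translatomes(pr, expr$control, expr$stress)
      } else {
        ps <- simulate_paired_translatomes(5000, seed = seed + 3L)
        paired <- pair_translatomes(ps$pairs, ps$expr_a, ps$expr_b)
      }
      strata <- stratified_correlation(paired, m$a_cutoffs %||% c(-Inf, 6, 8, 10))
      write_tsv(paired, file.path(out_dir, "ortholog_pairs.tsv"))
      write_tsv(strata, file.path(out_dir, "ortholog_strata.tsv"))
      list(paired = paired, strata = strata)
    })
  }

  ann <- NULL
  if (enabled("features") || enabled("bpp")) {
    ann <- .stage("features", {
      if (!is.null(config$inputs$fasta)) {
        parse_annotation(config$inputs$fasta,
                         read.delim(config$inputs$cds, stringsAsFactors = FALSE))
      } else if (!is.null(sim) && !is.null(sim$annotations)) {
        sim$annotations
      } else stop("no annotation input available")
    })
  }

  if (enabled("features")) {
    res$features <- .stage("features", {
      if (is.null(entries)) stop("features stage needs the classify stage")
      feats <- extract_features(ann)
      ff <- m$feature_filter %||% list()
      rep <- class_feature_report(
        feats, translation_groups(entries),
        setNames(entries$a_control, entries$gene_id),
        a_min = ff$a_min %||% 5.5, utr5_min = ff$utr5_min %||% 10,
        utr3_min = ff$utr3_min %||% 10)
      write_tsv(rep, file.path(out_dir, "feature_report.tsv"))
      rep
    })
  }

  if (enabled("bpp")) {
    res$bpp <- .stage("bpp", {
      if (is.null(entries)) stop("bpp stage needs the classify stage")
      bp <- m$bpp %||% list()
      n_per <- bp$n_per_group %||% 40
      groups <- translation_groups(entries,
                                   m_high = bp$m_high %||% 2,
                                   m_low = bp$m_low %||% -1.5)
      gsel <- list(High = head(groups$High, n_per), Low = head(groups$Low, n_per))
      prof <- positional_bpp_profile(
        ann, gsel, anchor = bp$anchor %||% "start",
        window = bp$window %||% c(-20:-1, 1:50), flank = bp$flank %||% 50)
      write_tsv(prof, file.path(out_dir, "bpp_profile.tsv"))
      prof
    })
  }

  if (enabled("enrich")) {
    res$enrich <- .stage("enrich", {
      if (is.null(entries)) stop("enrich stage needs the classify stage")
      sets <- if (!is.null(config$inputs$gmt)) read_gmt(config$inputs$gmt)
              else simulate_gene_sets(sim$truth, seed = seed + 4L)
      bg <- entries$gene_id
      cls_enr <- do.call(rbind, lapply(c("S", "R", "I"), function(cl) {
        sel <- entries$gene_id[entries$class_label == cl]
        if (length(sel) == 0L) return(NULL)
        cbind(class = cl, fisher_term_enrichment(sel, bg, sets))
      }))
      ranked <- entries$gene_id[order(entries$te_control, decreasing = TRUE)]
      scan <- ranked_partition_scan(ranked, sets,
                                    n_partitions = m$n_partitions %||% 30)
      write_tsv(cls_enr, file.path(out_dir, "class_enrichment.tsv"))
      write_tsv(scan$summary, file.path(out_dir, "ranked_scan_summary.tsv"))
      list(classes = cls_enr, scan = scan)
    })
  }

  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
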