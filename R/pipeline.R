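#' Pipeline run configuration
#'
#' Collects input paths, every threshold of the filter cascade, and the
#' output directory for a reproducible [run_pipeline()] invocation. The
#' config is serialized verbatim (YAML) into the output directory so a
#' run can be audited and repeated.
#'
#' @param mirna,mrna,annotation,predictions Paths to the canonical TSV
#'   inputs (see [read_expression_matrix()] and friends).
#' @param detection Optional path to a detection matrix for the miRNA
#'   panel; when absent, calls are derived from intensities at
#'   `detect_quantile`.
#' @param mirna_annotation Optional path to a miRNA family/cluster table.
#' @param qpcr Optional path to a Ct table; enables the validation arm.
#' @param out_dir Output directory.
#' @param input_scale Scale of the stored expression values.
#' @param normalize Quantile-normalize both panels before analysis.
#' @param frac_bone,frac_cell_line,presence_combine Presence-rule
#'   parameters (detectable in at least `frac_bone` of bones and/or
#'   `frac_cell_line` of cell lines).
#' @param alpha BH-adjusted significance cut-off.
#' @param fc_threshold Absolute fold-change flag threshold.
#' @param r_threshold Anti-correlation threshold (strict `<`).
#' @param pct_threshold Conservation threshold (weak `>=`; missing kept).
#' @param min_mirnas Minimum distinct miRNAs per multi-miRNA target.
#' @param correlation_group Sample group over which pair correlations are
#'   computed.
#' @param reference_assays,calibrator_group,sig,trend_hi qPCR-arm
#'   parameters.
#' @param detect_quantile Fallback detection quantile.
#' @param seed Integer seed recorded with the run (the analysis itself is
#'   deterministic).
#' @return A `run_config` list.
#' @export
run_config <- function(mirna, mrna, annotation, predictions,
                       detection = NULL, mirna_annotation = NULL,
                       qpcr = NULL, out_dir = "osteomir_run",
                       input_scale = "log2", normalize = TRUE,
                       frac_bone = 0.75, frac_cell_line = 0.25,
                       presence_combine = "or", alpha = 0.05,
                       fc_threshold = 2, r_threshold = -0.5,
                       pct_threshold = 0.4, min_mirnas = 2,
                       correlation_group = "cell_line",
                       reference_assays = c("RNU44", "RNU6B"),
                       calibrator_group = "bone", sig = 0.05,
                       trend_hi = 0.15, detect_quantile = 0.25, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(alpha >= 0, alpha <= 1, pct_threshold >= 0, pct_threshold <= 1,
            r_threshold >= -1, r_threshold <= 1, min_mirnas >= 1,
            sig >= 0, sig <= 1, trend_hi >= sig)
  structure(cfg, class = "run_config")
}

#' Run the integrated miRNA-mRNA analysis on in-memory tables
#'
#' The full filter cascade on already-loaded data: presence filtering
#' and miRNA differential expression (cell lines vs bone), mRNA
#' differential expression in both the cell-line and clinical contrasts,
#' hypergeometric overlap of the two mRNA hit sets, sample clustering,
#' prediction-constrained candidate pairing, anti-correlation screening
#' over the cell-line samples, conservation (P_CT) filtering, and
#' multi-miRNA target grouping -- with a stage audit recording the count
#' entering and surviving every stage.
#'
#' @param mirna,mrna [expression_table()]s on the log2 scale.
#' @param annotation Sample annotation.
#' @param predictions Prediction tibble.
#' @param detection Optional [detection_table()] for the miRNA panel.
#' @param mirna_annotation Optional miRNA family/cluster tibble.
#' @param qpcr_tbl Optional Ct tibble.
#' @param config A [run_config()] supplying thresholds (paths ignored).
#' @return A list of class `osteomir_result`: `audit`, `de_mirna`,
#'   `de_mrna_cl`, `de_mrna_clin`, `overlap`, `mirna_tree`, `pairs`
#'   (with stage flags), `multi_targets`, `family_summary`, and -- when
#'   `qpcr_tbl` is given -- `rq` and `qpcr_tests`.
#' @export
analyze_cohort <- function(mirna, mrna, annotation, predictions,
                           detection = NULL, mirna_annotation = NULL,
                           qpcr_tbl = NULL, config = run_config(".", ".", ".", ".")) {
  cfg <- config
  audit <- list()
  note <- function(stage, n_in, n_out, params = "") {
    audit[[length(audit) + 1]] <<- tibble::tibble(
      stage = stage, n_in = n_in, n_out = n_out, parameters = params)
  }

  if (expr_scale(mirna) == "raw") mirna <- log2_transform(mirna)
  if (expr_scale(mrna) == "raw") mrna <- log2_transform(mrna)
  if (isTRUE(cfg$normalize)) {
    mirna <- quantile_normalize(mirna)
    mrna <- quantile_normalize(mrna)
  }
  if (is.null(detection)) {
    detection <- detection_from_intensity(mirna, cfg$detect_quantile)
  }
  rule <- presence_rule("bone", cfg$frac_bone, "cell_line",
                        cfg$frac_cell_line, cfg$presence_combine)

  retained <- presence_filter(detection, annotation, rule)
  note("presence_filter", nrow(mirna), length(retained),
       sprintf("bone>=%.2f and/or cell_line>=%.2f", cfg$frac_bone,
               cfg$frac_cell_line))

  de_mirna <- differential_features(mirna, annotation, "cell_line", "bone",
                                    d = detection, rule = rule,
                                    alpha = cfg$alpha,
                                    fc_threshold = cfg$fc_threshold)
  de_mirna_ids <- de_mirna$feature_id[de_mirna$significant]
  note("mirna_diffexpr", length(retained), length(de_mirna_ids),
       sprintf("BH alpha=%.3g, cell_line vs bone", cfg$alpha))

  fam <- NULL
  if (!is.null(mirna_annotation)) {
    fam <- annotate_families(de_mirna, mirna_annotation)
    de_mirna <- fam$records
  }

  de_mrna_cl <- differential_features(mrna, annotation, "cell_line", "bone",
                                      rule = NULL, alpha = cfg$alpha,
                                      fc_threshold = cfg$fc_threshold)
  de_mrna_clin <- differential_features(mrna, annotation, "clinical", "bone",
                                        rule = NULL, alpha = cfg$alpha,
                                        fc_threshold = cfg$fc_threshold)
  cl_ids <- de_mrna_cl$feature_id[de_mrna_cl$significant]
  clin_ids <- de_mrna_clin$feature_id[de_mrna_clin$significant]
  note("mrna_diffexpr_cell_line", nrow(mrna), length(cl_ids),
       sprintf("BH alpha=%.3g", cfg$alpha))
  note("mrna_diffexpr_clinical", nrow(mrna), length(clin_ids),
       sprintf("BH alpha=%.3g", cfg$alpha))

  overlap <- hypergeometric_overlap(cl_ids, clin_ids, expr_features(mrna))

  tree <- cluster_samples(abs_pearson_distance(
    mirna[mirna$feature_id %in% retained,
          c("feature_id",
            intersect(expr_samples(mirna),
                      annotation$sample_id[annotation$group %in%
                                             c("cell_line", "bone")]))]
  ))

  # transcript-level hits mapped to gene symbols through the prediction
  # table (only predicted genes can pair anyway)
  tx_map <- dplyr::distinct(predictions, .data$transcript_id,
                            .data$gene_symbol)
  gene_hits <- function(tx_ids) {
    unique(tx_map$gene_symbol[tx_map$transcript_id %in% tx_ids])
  }
  cand <- candidate_pairs(de_mirna_ids, predictions,
                          gene_hits(cl_ids), gene_hits(clin_ids))
  note("candidate_pairs", nrow(predictions), nrow(cand),
       "DE miRNA x predicted target significant in both cohorts")

  corr_samples <- annotation$sample_id[annotation$group == cfg$correlation_group]
  pairs <- pair_correlations(cand, mirna, mrna, samples = corr_samples)
  anti <- anticorrelation_filter(pairs, cfg$r_threshold)
  note("anticorrelation_filter", nrow(pairs), nrow(anti),
       sprintf("r < %.2f over %s samples", cfg$r_threshold,
               cfg$correlation_group))
  cons <- conservation_filter(anti, cfg$pct_threshold)
  note("conservation_filter", nrow(anti), nrow(cons),
       sprintf("P_CT >= %.2f or missing (star strands kept)",
               cfg$pct_threshold))
  multi <- multi_mirna_targets(cons, cfg$min_mirnas)
  note("multi_mirna_targets", dplyr::n_distinct(cons$gene_symbol),
       nrow(multi), sprintf(">= %d distinct miRNAs per gene",
                            cfg$min_mirnas))

  res <- list(
    audit = dplyr::bind_rows(audit),
    de_mirna = de_mirna, de_mrna_cl = de_mrna_cl,
    de_mrna_clin = de_mrna_clin, overlap = overlap, mirna_tree = tree,
    pairs = cons, pairs_all = pairs, multi_targets = multi,
    family_summary = if (is.null(fam)) NULL else fam$summary,
    config = cfg
  )

  if (!is.null(qpcr_tbl)) {
    imp <- impute_undetected(qpcr_tbl)
    rel <- ddct(imp, cfg$reference_assays, annotation,
                calibrator_group = cfg$calibrator_group)
    tests <- qpcr_group_tests(rel, "clinical", "bone", sig = cfg$sig,
                              trend_hi = cfg$trend_hi)
    note("qpcr_tests", dplyr::n_distinct(rel$assay_id),
         sum(tests$band == "significant"),
         sprintf("Mann-Whitney, significant p<%.2g, trend [%.2g, %.2g]",
                 cfg$sig, cfg$sig, cfg$trend_hi))
    res$rq <- rel
    res$qpcr_tests <- tests
    res$audit <- dplyr::bind_rows(audit)
  }
  structure(res, class = "osteomir_result")
}

#' @export
print.osteomir_result <- function(x, ...) {
  cat("Integrated miRNA-mRNA analysis\n")
  print(x$audit, n = Inf)
  invisible(x)
}

#' Run the pipeline from a file-based configuration
#'
#' Reads every input named in the config, executes [analyze_cohort()],
#' and writes per-stage TSV outputs, a Newick sample tree, the stage
#' audit and a verbatim copy of the configuration into the output
#' directory. Identical inputs and configuration produce byte-identical
#' outputs.
#'
#' @param config A [run_config()].
#' @return The [analyze_cohort()] result, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  inputs <- list(
    mirna = read_expression_matrix(cfg$mirna, scale = cfg$input_scale),
    mrna = read_expression_matrix(cfg$mrna, scale = cfg$input_scale),
    annotation = read_sample_annotation(cfg$annotation),
    predictions = read_targetscan_predictions(cfg$predictions),
    detection = if (!is.null(cfg$detection)) read_detection_matrix(cfg$detection),
    mirna_annotation = if (!is.null(cfg$mirna_annotation)) {
      readr::read_tsv(cfg$mirna_annotation,
                      col_types = readr::cols(.default = "c"))
    },
    qpcr_tbl = if (!is.null(cfg$qpcr)) read_qpcr_table(cfg$qpcr)
  )
  res <- analyze_cohort(inputs$mirna, inputs$mrna, inputs$annotation,
                        inputs$predictions, detection = inputs$detection,
                        mirna_annotation = inputs$mirna_annotation,
                        qpcr_tbl = inputs$qpcr_tbl, config = cfg)

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(cfg$out_dir, f)
  readr::write_tsv(res$audit, p("audit.tsv"))
  readr::write_tsv(res$de_mirna, p("de_mirna.tsv"), na = "")
  readr::write_tsv(res$de_mrna_cl, p("de_mrna_cell_line.tsv"), na = "")
  readr::write_tsv(res$de_mrna_clin, p("de_mrna_clinical.tsv"), na = "")
  readr::write_tsv(res$pairs, p("pairs.tsv"), na = "")
  readr::write_tsv(res$multi_targets, p("multi_mirna_targets.tsv"), na = "")
  readr::write_tsv(tidy(res$overlap), p("mrna_overlap.tsv"))
  write_newick(res$mirna_tree, p("mirna_samples.nwk"))
  if (!is.null(res$rq)) {
    readr::write_tsv(res$rq, p("qpcr_rq.tsv"))
    readr::write_tsv(res$qpcr_tests, p("qpcr_tests.tsv"))
  }
  writeLines(yaml::as.yaml(unclass(cfg)), p("config.yaml"))
  invisible(res)
}

#' Volcano plot of a differential-expression table
#'
#' @param de Output of [differential_features()].
#' @param alpha Significance line.
#' @return A ggplot of -log10 adjusted p against the log2 group
#'   difference, significant features highlighted.
#' @export
plot_volcano <- function(de, alpha = 0.05) {
  df <- dplyr::mutate(de, log2_diff = .data$log2_mean_a - .data$log2_mean_b)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_diff,
                                   y = -log10(pmax(.data$p_adj, 1e-300)),
                                   color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2,
                        linewidth = 0.3) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "red3",
                                           `FALSE` = "grey55")) +
    ggplot2::labs(x = "log2 group difference", y = "-log10 adjusted p",
                  color = "significant") +
    ggplot2::theme_minimal()
}
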