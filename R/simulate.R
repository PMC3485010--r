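#' Simulation configuration
#'
#' Defines a synthetic two-panel study with the structure the analysis
#' assumes: four sample arms (osteosarcoma cell lines, normal bones,
#' clinical tumors, osteoblast cultures), planted differentially
#' expressed miRNAs -- some co-regulated through shared family/cluster
#' latent factors -- planted negatively coupled miRNA-to-target mRNA
#' pairs hidden among decoy predictions carrying conservation (P_CT)
#' scores, and passenger-strand miRNAs without P_CT. Defaults mirror the
#' emulated study design: 19 cell lines against 4 bones, a clinical arm
#' at half the cell-line effect (the "intermediate expression" gradient),
#' and strong planted effects (4 log2 units) over Gaussian log2-scale
#' noise -- sized so the 4-sample bone reference still yields adequate
#' power in every contrast.
#'
#' @param n_cell_lines,n_bone,n_clinical,n_osteoblast Arm sizes.
#' @param n_mirna,n_mrna Panel sizes.
#' @param n_de_mirna Number of planted differentially expressed miRNAs.
#' @param de_log2_effect Cell-line shift of planted miRNAs, log2 units
#'   (random sign per miRNA); clinical arm gets half of it, osteoblasts
#'   the full shift.
#' @param n_true_pairs Planted miRNA-target couplings, assigned to the
#'   first `n_true_pairs` planted miRNAs; miRNAs sharing a family or
#'   cluster co-target one gene (the multi-miRNA target pattern), which
#'   responds to the mean deviation of its regulators.
#' @param coupling_slope log2 mRNA change per log2 miRNA deviation for
#'   true pairs; must be negative.
#' @param noise_sd Gaussian noise sd on the log2 scale, applied to both
#'   panels.
#' @param n_de_mrna_extra Additional differentially expressed mRNAs with
#'   no miRNA coupling (decoy targets that survive the dual-cohort
#'   significance screen).
#' @param n_decoy_predictions Prediction rows with zero true coupling.
#' @param pct_true_range,pct_decoy_range Uniform P_CT ranges for true and
#'   decoy predictions.
#' @param frac_star Fraction of miRNAs labelled as passenger ("star")
#'   strands; their predictions carry no P_CT.
#' @param cluster_latent_ratio Sd of each cluster/family shared latent
#'   factor, as a multiple of `noise_sd` (so zero-noise configurations
#'   stay exactly deterministic).
#' @param detect_quantile Global intensity quantile under which a well is
#'   called not-detected.
#' @param n_qpcr_assays Planted DE miRNAs carried into the qPCR arm.
#' @param qpcr_noise_sd Ct noise sd (cycles).
#' @param frac_undetected_qpcr Fraction of target wells emitted as
#'   undetected (the highest-Ct wells).
#' @param seed Integer seed; all randomness derives from it.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_cell_lines = 19, n_bone = 4, n_clinical = 20,
                              n_osteoblast = 5, n_mirna = 200, n_mrna = 400,
                              n_de_mirna = 15, de_log2_effect = 4,
                              n_true_pairs = 15, coupling_slope = -2,
                              noise_sd = 0.5, n_de_mrna_extra = 40,
                              n_decoy_predictions = 100,
                              pct_true_range = c(0.6, 0.95),
                              pct_decoy_range = c(0.05, 0.7),
                              frac_star = 0.1, cluster_latent_ratio = 1.2,
                              detect_quantile = 0.25, n_qpcr_assays = 8,
                              qpcr_noise_sd = 0.3,
                              frac_undetected_qpcr = 0.05, seed = 1) {
  cfg <- as.list(environment())
  counts <- cfg[c("n_cell_lines", "n_bone", "n_clinical", "n_osteoblast",
                  "n_mirna", "n_mrna", "n_de_mirna", "n_true_pairs",
                  "n_de_mrna_extra", "n_decoy_predictions")]
  if (any(unlist(counts) < 0)) stop("counts must be >= 0", call. = FALSE)
  if (n_de_mirna > n_mirna) stop("n_de_mirna > n_mirna", call. = FALSE)
  if (n_true_pairs > n_de_mirna) {
    stop("n_true_pairs > n_de_mirna (one planted coupling per DE miRNA)",
         call. = FALSE)
  }
  if (n_true_pairs + n_de_mrna_extra > n_mrna) {
    stop("mRNA panel too small for planted genes", call. = FALSE)
  }
  if (n_true_pairs > 0 && coupling_slope >= 0) {
    stop("coupling_slope must be negative for planted pairs", call. = FALSE)
  }
  if (frac_star < 0 || frac_star > 1 || frac_undetected_qpcr < 0 ||
      frac_undetected_qpcr > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "simulation_config")
}

group_shift_mult <- c(cell_line = 1, clinical = 0.5, bone = 0, osteoblast = 1)

#' Simulate a synthetic two-panel cohort
#'
#' Generates miRNA and mRNA log2 expression tables, detection calls,
#' sample annotation, a TargetScan-style prediction table (true
#' couplings plus decoys), a miRNA family/cluster annotation, and a
#' ground-truth manifest. Deterministic under a fixed config: two calls
#' give identical output.
#'
#' The generative model, per feature and sample, is
#' `log2 intensity = baseline + planted shift x arm multiplier +
#' shared cluster factor + N(0, noise_sd)`, with arm multipliers 1
#' (cell line), 1 (osteoblast), 0.5 (clinical) and 0 (bone). A true
#' pair's target gene follows
#' `baseline + coupling_slope x (miRNA deviation) + N(0, noise_sd)`;
#' decoy predictions have zero coupling.
#'
#' @param config A [simulation_config()].
#' @return A list: `mirna`, `mrna` ([expression_table()]s), `detection`
#'   ([detection_table()] for the miRNA panel), `annotation`,
#'   `predictions`, `mirna_annotation`, `truth`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  c_ <- config
  withr::with_seed(c_$seed, {
    ann <- sample_annotation(
      c(sprintf("CL%02d", seq_len(c_$n_cell_lines)),
        sprintf("BO%02d", seq_len(c_$n_bone)),
        sprintf("TU%02d", seq_len(c_$n_clinical)),
        sprintf("OB%02d", seq_len(c_$n_osteoblast))),
      rep(c("cell_line", "bone", "clinical", "osteoblast"),
          c(c_$n_cell_lines, c_$n_bone, c_$n_clinical, c_$n_osteoblast))
    )
    n_s <- nrow(ann)
    mult <- unname(group_shift_mult[ann$group])

    # --- miRNA panel ------------------------------------------------------
    mirna_ids <- sprintf("miR-%03d", seq_len(c_$n_mirna))
    star_idx <- sort(sample.int(c_$n_mirna, round(c_$frac_star * c_$n_mirna)))
    mirna_ids[star_idx] <- paste0(mirna_ids[star_idx], "*")
    de_idx <- sort(sample.int(c_$n_mirna, c_$n_de_mirna))
    baseline_mi <- stats::runif(c_$n_mirna, 7, 13)
    baseline_mi[de_idx] <- stats::runif(c_$n_de_mirna, 9, 12)
    effect <- numeric(c_$n_mirna)
    effect[de_idx] <- sample(c(-1, 1), c_$n_de_mirna, replace = TRUE) *
      c_$de_log2_effect

    # family / cluster structure among the planted miRNAs: two seed
    # families of three and two polycistronic clusters of two (when the
    # planted set is large enough); cluster members share a latent factor
    fam <- rep(NA_character_, c_$n_mirna)
    clus <- rep(NA_character_, c_$n_mirna)
    grp_defs <- list(c("family", "fam-1", 3), c("family", "fam-2", 3),
                     c("cluster", "clus-1", 2), c("cluster", "clus-2", 2))
    used <- 0
    for (g in grp_defs) {
      size <- as.integer(g[[3]])
      if (used + size > c_$n_de_mirna) break
      members <- de_idx[(used + 1):(used + size)]
      if (g[[1]] == "family") fam[members] <- g[[2]] else clus[members] <- g[[2]]
      # co-regulated groups share one shift direction
      effect[members] <- effect[members[1]]
      used <- used + size
    }
    latent_sd <- c_$cluster_latent_ratio * c_$noise_sd
    latent_groups <- stats::na.omit(unique(c(fam, clus)))
    latent <- matrix(0, c_$n_mirna, n_s)
    for (lg in latent_groups) {
      members <- which(fam %in% lg | clus %in% lg)
      f <- stats::rnorm(n_s, 0, latent_sd)
      latent[members, ] <- rep(f, each = length(members))
    }

    mi <- baseline_mi + outer(effect, mult) + latent +
      matrix(stats::rnorm(c_$n_mirna * n_s, 0, c_$noise_sd), c_$n_mirna)
    dimnames(mi) <- list(mirna_ids, ann$sample_id)

    # --- mRNA panel -------------------------------------------------------
    gene_ids <- sprintf("GENE%03d", seq_len(c_$n_mrna))
    tx_ids <- sprintf("NM_%06d", seq_len(c_$n_mrna))
    baseline_mr <- stats::runif(c_$n_mrna, 7, 13)
    mr <- baseline_mr +
      matrix(stats::rnorm(c_$n_mrna * n_s, 0, c_$noise_sd), c_$n_mrna)
    # planted targets: miRNAs sharing a family or cluster co-target one
    # gene (the multi-miRNA pattern); the gene responds to the mean
    # deviation of its regulators. Singleton DE miRNAs get their own gene.
    paired_idx <- de_idx[seq_len(c_$n_true_pairs)]
    grp_key <- dplyr::coalesce(fam[paired_idx], clus[paired_idx],
                               as.character(paired_idx))
    gene_groups <- split(paired_idx, factor(grp_key, levels = unique(grp_key)))
    for (j in seq_along(gene_groups)) {
      members <- gene_groups[[j]]
      dev <- colMeans(mi[members, , drop = FALSE] - baseline_mi[members])
      mr[j, ] <- mr[j, ] + c_$coupling_slope * dev
    }
    n_genes <- length(gene_groups)
    # extra DE genes without coupling, same arm gradient
    extra_idx <- n_genes + seq_len(c_$n_de_mrna_extra)
    extra_effect <- sample(c(-1, 1), c_$n_de_mrna_extra, replace = TRUE) *
      c_$de_log2_effect
    mr[extra_idx, ] <- mr[extra_idx, ] + outer(extra_effect, mult)
    # host genes tracking each cluster's latent factor
    host <- rep(NA_character_, c_$n_mirna)
    clus_ids <- stats::na.omit(unique(clus))
    host_idx <- c_$n_true_pairs + c_$n_de_mrna_extra + seq_along(clus_ids)
    for (h in seq_along(clus_ids)) {
      members <- which(clus %in% clus_ids[h])
      gene_ids[host_idx[h]] <- sprintf("HOST%02d", h)
      mr[host_idx[h], ] <- mr[host_idx[h], ] + latent[members[1], ]
      host[members] <- gene_ids[host_idx[h]]
    }
    dimnames(mr) <- list(tx_ids, ann$sample_id)

    mirna_x <- expression_table(mi, scale = "log2")
    mrna_x <- expression_table(mr, scale = "log2")
    detection <- detection_from_intensity(mirna_x, c_$detect_quantile)

    # --- predictions: true couplings + decoys -----------------------------
    pair_gene_idx <- rep(seq_len(n_genes), lengths(gene_groups))
    true_pred <- tibble::tibble(
      mirna_id = mirna_ids[paired_idx],
      family_id = dplyr::coalesce(fam[paired_idx], clus[paired_idx],
                                  mirna_ids[paired_idx]),
      gene_symbol = gene_ids[pair_gene_idx],
      transcript_id = tx_ids[pair_gene_idx],
      pct = stats::runif(c_$n_true_pairs, c_$pct_true_range[1],
                         c_$pct_true_range[2]),
      truth = "true_pair"
    )
    n_dec <- c_$n_decoy_predictions
    dec_mirna_idx <- c(
      sample(de_idx, ceiling(n_dec / 2), replace = TRUE),
      sample(setdiff(seq_len(c_$n_mirna), de_idx), floor(n_dec / 2),
             replace = TRUE)
    )
    decoy_gene_pool <- c(extra_idx, setdiff(seq_len(c_$n_mrna),
                                            c(seq_len(n_genes),
                                              extra_idx, host_idx)))
    dec_gene_idx <- c(
      sample(extra_idx, ceiling(n_dec / 4), replace = TRUE),
      sample(decoy_gene_pool, n_dec - ceiling(n_dec / 4), replace = TRUE)
    )
    decoy_pred <- tibble::tibble(
      mirna_id = mirna_ids[dec_mirna_idx],
      family_id = mirna_ids[dec_mirna_idx],
      gene_symbol = gene_ids[dec_gene_idx],
      transcript_id = tx_ids[dec_gene_idx],
      pct = stats::runif(n_dec, c_$pct_decoy_range[1], c_$pct_decoy_range[2]),
      truth = "decoy"
    ) |>
      dplyr::anti_join(true_pred, by = c("mirna_id", "gene_symbol")) |>
      dplyr::distinct(.data$mirna_id, .data$gene_symbol, .keep_all = TRUE)
    predictions <- dplyr::bind_rows(true_pred, decoy_pred) |>
      dplyr::mutate(star_strand = endsWith(.data$mirna_id, "*"),
                    pct = ifelse(.data$star_strand, NA_real_, .data$pct))

    mirna_annotation <- tibble::tibble(
      mirna_id = mirna_ids, family_id = fam, cluster_id = clus,
      host_gene = host
    )

    truth <- list(
      de_mirna = tibble::tibble(
        mirna_id = mirna_ids[de_idx],
        effect = !!effect[de_idx],
        direction = ifelse(!!effect[de_idx] > 0, "up", "down")
      ),
      true_pairs = tibble::tibble(
        mirna_id = mirna_ids[paired_idx],
        gene_symbol = gene_ids[pair_gene_idx],
        transcript_id = tx_ids[pair_gene_idx],
        slope = c_$coupling_slope
      ),
      de_mrna = tibble::tibble(
        gene_symbol = gene_ids[c(seq_len(n_genes), extra_idx)],
        transcript_id = tx_ids[c(seq_len(n_genes), extra_idx)],
        coupled = c(rep(TRUE, n_genes),
                    rep(FALSE, c_$n_de_mrna_extra))
      ),
      group_shift = tidyr::expand_grid(
        mirna_id = mirna_ids[de_idx],
        group = names(group_shift_mult)
      ) |>
        dplyr::mutate(shift = unname(effect[de_idx][match(.data$mirna_id,
                                                          mirna_ids[de_idx])] *
                                       group_shift_mult[.data$group]))
    )
    list(mirna = mirna_x, mrna = mrna_x, detection = detection,
         annotation = ann, predictions = predictions,
         mirna_annotation = mirna_annotation, truth = truth,
         config = config)
  })
}

#' Simulate a qPCR Ct table from cohort ground truth
#'
#' Emits well-level Ct values for the planted DE miRNA assays plus two
#' group-invariant endogenous reference assays (RNU44, RNU6B) over the
#' clinical, bone and osteoblast arms -- the validation design. Each
#' target well is `Ct = assay base - planted group shift + N(0,
#' qpcr_noise_sd)`, so relative expression recovered by [ddct()] against
#' the bone calibrator equals `2^shift` exactly when noise is zero. The
#' configured fraction of highest-Ct (lowest-expression) target wells is
#' emitted as undetected.
#'
#' @param config A [simulation_config()].
#' @param truth Ground-truth manifest from [simulate_cohort()].
#' @return A Ct tibble (`sample_id`, `assay_id`, `ct`, `undetected`).
#' @export
simulate_qpcr <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"))
  c_ <- config
  withr::with_seed(c_$seed + 1L, {
    ann <- sample_annotation(
      c(sprintf("TU%02d", seq_len(c_$n_clinical)),
        sprintf("BO%02d", seq_len(c_$n_bone)),
        sprintf("OB%02d", seq_len(c_$n_osteoblast))),
      rep(c("clinical", "bone", "osteoblast"),
          c(c_$n_clinical, c_$n_bone, c_$n_osteoblast))
    )
    assays <- utils::head(truth$de_mirna$mirna_id, c_$n_qpcr_assays)
    shifts <- truth$group_shift |>
      dplyr::filter(.data$mirna_id %in% assays)
    base <- stats::runif(length(assays), 24, 30)
    names(base) <- assays
    tb <- tidyr::expand_grid(sample_id = ann$sample_id, assay_id = assays) |>
      dplyr::left_join(ann, by = "sample_id") |>
      dplyr::left_join(shifts, by = c(assay_id = "mirna_id", "group")) |>
      dplyr::mutate(ct = base[.data$assay_id] - .data$shift +
                      stats::rnorm(dplyr::n(), 0, c_$qpcr_noise_sd))
    ref_base <- c(RNU44 = stats::runif(1, 18, 21), RNU6B = stats::runif(1, 18, 21))
    refs <- tidyr::expand_grid(sample_id = ann$sample_id,
                               assay_id = names(ref_base)) |>
      dplyr::mutate(ct = ref_base[.data$assay_id] +
                      stats::rnorm(dplyr::n(), 0, c_$qpcr_noise_sd))
    n_undet <- floor(c_$frac_undetected_qpcr * nrow(tb))
    undet_rows <- if (n_undet > 0) order(tb$ct, decreasing = TRUE)[seq_len(n_undet)]
                  else integer(0)
    out <- dplyr::bind_rows(
      tb |>
        dplyr::mutate(undetected = dplyr::row_number() %in% undet_rows,
                      ct = ifelse(.data$undetected, NA_real_, .data$ct)) |>
        dplyr::select("sample_id", "assay_id", "ct", "undetected"),
      dplyr::mutate(refs, undetected = FALSE)
    )
    dplyr::arrange(out, .data$sample_id, .data$assay_id)
  })
}

#' Write a simulated cohort to a directory of canonical TSV files
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Files: `mirna.tsv`, `mrna.tsv`,
#'   `detection.tsv`, `annotation.tsv`, `predictions.tsv`,
#'   `mirna_annotation.tsv`, `truth_*.tsv`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_expression_matrix(cohort$mirna, p("mirna.tsv"))
  write_expression_matrix(cohort$mrna, p("mrna.tsv"))
  write_expression_matrix(cohort$detection, p("detection.tsv"))
  write_sample_annotation(cohort$annotation, p("annotation.tsv"))
  write_targetscan_predictions(cohort$predictions, p("predictions.tsv"))
  readr::write_tsv(cohort$mirna_annotation, p("mirna_annotation.tsv"), na = "")
  readr::write_tsv(cohort$truth$de_mirna, p("truth_de_mirna.tsv"), na = "")
  readr::write_tsv(cohort$truth$true_pairs, p("truth_pairs.tsv"), na = "")
  readr::write_tsv(cohort$truth$de_mrna, p("truth_de_mrna.tsv"), na = "")
  invisible(dir)
}
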