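test_that("configuration validation rejects impossible designs", {
  expect_error(simulation_config(n_mirna = -1), "counts")
  expect_error(simulation_config(n_de_mirna = 10, n_true_pairs = 11),
               "n_true_pairs")
  expect_error(simulation_config(coupling_slope = 0.5), "negative")
  expect_error(simulation_config(frac_star = 1.5), "\\[0, 1\\]")
  expect_error(simulation_config(n_mrna = 20, n_true_pairs = 10,
                                 n_de_mirna = 10, n_de_mrna_extra = 15),
               "panel too small")
})

test_that("cohorts are byte-identical under a fixed seed", {
  cfg <- simulation_config(seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$mirna, b$mirna)
  expect_identical(a$mrna, b$mrna)
  expect_identical(a$predictions, b$predictions)
  expect_identical(a$truth, b$truth)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(a, d1)
  write_cohort(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  c2 <- simulate_cohort(simulation_config(seed = 10))
  expect_false(identical(expr_matrix(a$mirna), expr_matrix(c2$mirna)))
})

test_that("the ground-truth manifest is consistent with the emitted tables", {
  co <- simulate_cohort(simulation_config(seed = 12))
  expect_true(all(co$truth$de_mirna$mirna_id %in% expr_features(co$mirna)))
  expect_true(all(co$truth$true_pairs$transcript_id %in% expr_features(co$mrna)))
  key <- function(x) paste(x$mirna_id, x$gene_symbol)
  preds_true <- co$predictions[co$predictions$truth == "true_pair", ]
  expect_setequal(key(co$truth$true_pairs), key(preds_true))
  expect_true(all(is.na(preds_true$pct[preds_true$star_strand])))
  expect_true(all(preds_true$pct[!preds_true$star_strand] >= 0.6))
  # family/cluster co-members co-target one gene
  fam_members <- co$mirna_annotation$mirna_id[!is.na(co$mirna_annotation$family_id)]
  fam_pairs <- co$truth$true_pairs[co$truth$true_pairs$mirna_id %in% fam_members, ]
  expect_lt(dplyr::n_distinct(fam_pairs$gene_symbol),
            nrow(fam_pairs))
})

test_that("zero-noise cohorts reduce to exact closed forms", {
  cfg <- simulation_config(seed = 4, noise_sd = 0, de_log2_effect = 2,
                           coupling_slope = -1)
  co <- simulate_cohort(cfg)
  fc <- fold_change(co$mirna, co$annotation)
  planted <- fc$fold_change[fc$feature_id %in% co$truth$de_mirna$mirna_id]
  expect_true(all(abs(planted) == 4))
  # perfect linear coupling: r of every true pair is exactly -1
  pairs <- candidate_pairs(co$truth$de_mirna$mirna_id, co$predictions,
                           co$truth$de_mrna$gene_symbol,
                           co$truth$de_mrna$gene_symbol)
  pairs <- pairs[paste(pairs$mirna_id, pairs$gene_symbol) %in%
                   paste(co$truth$true_pairs$mirna_id,
                         co$truth$true_pairs$gene_symbol), ]
  r <- pair_correlations(pairs, co$mirna, co$mrna)
  expect_equal(r$r, rep(-1, nrow(r)), tolerance = 1e-12)
})

test_that("detection calls follow the configured global quantile", {
  co <- simulate_cohort(simulation_config(seed = 8, detect_quantile = 0.25))
  det <- as.matrix(co$detection[-1])
  expect_equal(mean(!det), 0.25, tolerance = 0.01)
})

test_that("simulated qPCR tables invert to the planted relative expression", {
  cfg <- simulation_config(seed = 6, qpcr_noise_sd = 0,
                           frac_undetected_qpcr = 0)
  co <- simulate_cohort(cfg)
  qp <- simulate_qpcr(cfg, co$truth)
  expect_false(any(qp$undetected))
  rel <- ddct(qp, c("RNU44", "RNU6B"), co$annotation,
              calibrator_group = "bone")
  want <- co$truth$group_shift
  got <- dplyr::left_join(rel, want,
                          by = c(assay_id = "mirna_id", "group"))
  expect_equal(got$rq, 2^got$shift, tolerance = 1e-12)
  # fixed seed reproducibility, undetected fraction honored
  qp2 <- simulate_qpcr(cfg, co$truth)
  expect_identical(qp, qp2)
  cfg3 <- simulation_config(seed = 6, frac_undetected_qpcr = 0.1)
  qp3 <- simulate_qpcr(cfg3, simulate_cohort(cfg3)$truth)
  n_target_wells <- sum(!qp3$assay_id %in% c("RNU44", "RNU6B"))
  expect_equal(sum(qp3$undetected), floor(0.1 * n_target_wells))
})
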