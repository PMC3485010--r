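test_that("candidate pairs require a DE miRNA and dual-cohort gene significance", {
  preds <- tibble::tibble(
    mirna_id = c("miR-1", "miR-2", "miR-3", "miR-9"),
    family_id = "fam",
    gene_symbol = c("G1", "G2", "G3", "G1"),
    transcript_id = paste0("NM_", 1:4),
    pct = 0.8, star_strand = FALSE
  )
  out <- candidate_pairs(c("miR-1", "miR-2", "miR-3"), preds,
                         de_mrnas_cl = c("G1", "G2", "G3"),
                         de_mrnas_clin = c("G1", "G2"))
  expect_equal(nrow(out), 2)          # G3 significant in one cohort only
  expect_setequal(out$gene_symbol, c("G1", "G2"))
  expect_true(all(out$predicted & out$cohort_confirmed))
  expect_equal(nrow(candidate_pairs(character(), preds, "G1", "G1")), 0)
  expect_warning(candidate_pairs("miR-1", preds[0, ], "G1", "G1"),
                 "empty prediction table")
})

test_that("pair correlations agree with the two-pass Pearson oracle", {
  withr::local_seed(17)
  n <- 19
  mi <- matrix(rnorm(5 * n), 5,
               dimnames = list(sprintf("miR-%02d", 1:5), sprintf("CL%02d", 1:n)))
  mr <- matrix(rnorm(5 * n), 5,
               dimnames = list(sprintf("NM_%d", 1:5), sprintf("CL%02d", 1:n)))
  pairs <- tibble::tibble(
    mirna_id = rownames(mi), gene_symbol = sprintf("G%d", 1:5),
    transcript_id = rownames(mr), pct = 0.5, star_strand = FALSE,
    r = NA_real_, predicted = TRUE, cohort_confirmed = TRUE
  )
  out <- pair_correlations(pairs, expression_table(mi, scale = "log2"),
                           expression_table(mr, scale = "log2"))
  for (i in 1:5) {
    expect_equal(out$r[out$mirna_id == rownames(mi)[i]],
                 oracle_pearson(mi[i, ], mr[i, ]), tolerance = 1e-12)
  }
  # exact anti-proportionality gives r = -1
  mr2 <- mr
  mr2[1, ] <- -2 * mi[1, ] + 7
  out2 <- pair_correlations(pairs, expression_table(mi, scale = "log2"),
                            expression_table(mr2, scale = "log2"))
  expect_equal(out2$r[out2$mirna_id == rownames(mi)[1]], -1)
  expect_error(
    pair_correlations(pairs, expression_table(mi[, 1:2], scale = "log2"),
                      expression_table(mr[, 1:2], scale = "log2")),
    "at least 3 overlapping samples")
})

test_that("decoy pair correlations center near zero", {
  withr::local_seed(23)
  n <- 19
  mi <- matrix(rnorm(100 * n), 100,
               dimnames = list(sprintf("miR-%03d", 1:100), sprintf("CL%02d", 1:n)))
  mr <- matrix(rnorm(100 * n), 100,
               dimnames = list(sprintf("NM_%03d", 1:100), sprintf("CL%02d", 1:n)))
  pairs <- tibble::tibble(
    mirna_id = rownames(mi), gene_symbol = sprintf("G%d", 1:100),
    transcript_id = rownames(mr), pct = 0.5, star_strand = FALSE,
    r = NA_real_, predicted = TRUE, cohort_confirmed = TRUE
  )
  out <- pair_correlations(pairs, expression_table(mi, scale = "log2"),
                           expression_table(mr, scale = "log2"))
  expect_lt(abs(mean(out$r)), 0.15)
})

test_that("anti-correlation and conservation filters use the documented boundaries", {
  p <- toy_pairs(r = c(-0.51, -0.5, -0.49, 0.9, -1))
  kept <- anticorrelation_filter(p)
  expect_setequal(kept$r, c(-0.51, -1))
  expect_equal(nrow(anticorrelation_filter(p, r_threshold = -1)), 0)

  q <- toy_pairs(r = rep(-0.9, 4), pct = c(0.39, 0.40, NA, 1))
  q$star_strand <- c(FALSE, FALSE, TRUE, FALSE)
  kept_q <- conservation_filter(q)
  expect_setequal(kept_q$pct, c(0.40, NA, 1))
  expect_true(any(kept_q$star_strand))
  all_one <- toy_pairs(r = rep(-0.9, 3), pct = 1)
  expect_equal(nrow(conservation_filter(all_one)), 3)
})

test_that("multi-miRNA target grouping keeps genes with enough distinct regulators", {
  p <- toy_pairs(r = c(-0.8, -0.7, -0.6, -0.9, -0.85, -0.75, -0.65),
                 mirna = c("miR-29a", "miR-29b", "miR-9", "miR-17",
                           "miR-20b", "miR-9*", "miR-92a"),
                 gene = c("CPEB3", "CPEB3", "TGFBR2", "PTEN", "PTEN",
                          "PTEN", "PTEN"))
  g <- multi_mirna_targets(p)
  expect_equal(g$gene_symbol, c("CPEB3", "PTEN"))
  expect_equal(g$n_mirnas, c(2, 4))
  expect_equal(g$mirna_ids[1], "miR-29a, miR-29b")
  expect_equal(nrow(multi_mirna_targets(p, min_mirnas = 3)), 1)
})

test_that("hypergeometric overlap matches exact enumeration and the worked example", {
  u <- sprintf("g%02d", 1:10)
  res <- hypergeometric_overlap(u[1:4], u[c(1:4, 10)], u)
  expect_equal(res$n_overlap, 4)
  expect_equal(res$p, 5 / 210, tolerance = 1e-12)
  expect_equal(res$log10_p, log10(5 / 210), tolerance = 1e-9)
  expect_equal(hypergeometric_overlap(u, u[3:7], u)$log10_p, 0)
  expect_equal(hypergeometric_overlap(u[1:3], u[4:6], u)$p, 1)
  expect_error(hypergeometric_overlap(c(u[1], "zz"), u[1:2], u), "subsets")

  withr::local_seed(19)
  for (i in 1:40) {
    n <- sample(5:60, 1)
    uni <- sprintf("e%02d", seq_len(n))
    a <- sample(uni, sample(1:n, 1))
    b <- sample(uni, sample(1:n, 1))
    got <- hypergeometric_overlap(a, b, uni)
    want <- oracle_hyper_upper(length(intersect(a, b)), length(a),
                               length(b), n)
    expect_equal(got$log10_p, log10(want), tolerance = 1e-8)
  }
})

test_that("overlap p-values far below double underflow stay finite in log space", {
  uni <- sprintf("g%05d", 1:5000)
  res <- hypergeometric_overlap(uni[1:2500], uni[1:2500], uni)
  expect_true(is.finite(res$log10_p))
  expect_lt(res$log10_p, -1000)
  # independent check against R's log-space hypergeometric tail
  want <- stats::phyper(2499, 2500, 2500, 2500, lower.tail = FALSE,
                        log.p = TRUE) / log(10)
  expect_equal(res$log10_p, want, tolerance = 1e-6)
})

test_that("correlate_features computes paired Pearson r over shared samples", {
  withr::local_seed(29)
  a <- matrix(rnorm(3 * 10), 3,
              dimnames = list(c("miR-106b", "miR-93", "miR-25"),
                              sprintf("s%02d", 1:10)))
  b <- rbind(MCM7 = a["miR-106b", ] * 1.5 + rnorm(10, 0, 0.1),
             OTHER = rnorm(10))
  colnames(b) <- colnames(a)
  out <- correlate_features(expression_table(a, scale = "log2"),
                            expression_table(b, scale = "log2"),
                            data.frame(id_a = c("miR-106b", "miR-93"),
                                       id_b = c("MCM7", "OTHER")))
  expect_equal(out$r[1], oracle_pearson(a["miR-106b", ], b["MCM7", ]),
               tolerance = 1e-12)
  ident <- correlate_features(expression_table(a, scale = "log2"),
                              expression_table(a, scale = "log2"),
                              data.frame(id_a = "miR-93", id_b = "miR-93"))
  expect_equal(ident$r, 1)
})

test_that("the filter cascade is monotone on a simulated cohort", {
  co <- simulate_cohort(simulation_config(seed = 3))
  res <- analyze_cohort(co$mirna, co$mrna, co$annotation, co$predictions,
                        detection = co$detection,
                        config = run_config(".", ".", ".", ".",
                                            normalize = FALSE))
  aud <- res$audit
  filt <- aud[aud$stage %in% c("anticorrelation_filter",
                               "conservation_filter"), ]
  expect_true(all(filt$n_out <= filt$n_in))
  key <- function(p) paste(p$mirna_id, p$gene_symbol)
  expect_true(all(key(res$pairs) %in% key(res$pairs_all)))
})
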