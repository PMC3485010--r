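make_two_group <- function(a, b, feature = "f1") {
  samples <- c(sprintf("a%d", seq_along(a)), sprintf("b%d", seq_along(b)))
  ann <- sample_annotation(samples,
                           rep(c("cell_line", "bone"), c(length(a), length(b))))
  x <- expression_table(matrix(c(a, b), 1,
                               dimnames = list(feature, samples)),
                        scale = "log2")
  list(x = x, ann = ann)
}

test_that("group t-test handles identical, separated, and degenerate groups", {
  g <- make_two_group(c(1, 2, 3), c(1, 2, 3))
  r <- group_t_test(g$x, g$ann)
  expect_equal(r$t_stat, 0)
  expect_equal(r$p_raw, 1)
  g2 <- make_two_group(c(0, 0) + c(1e-9, -1e-9), c(10, 10) + c(1e-9, -1e-9))
  expect_lt(group_t_test(g2$x, g2$ann)$p_raw, 1e-6)
  # exactly constant groups: p = 1 convention at equal means, 0 otherwise
  g3 <- make_two_group(c(5, 5, 5), c(5, 5))
  expect_equal(group_t_test(g3$x, g3$ann)$p_raw, 1)
  g4 <- make_two_group(c(5, 5, 5), c(7, 7))
  expect_equal(group_t_test(g4$x, g4$ann)$p_raw, 0)
  g5 <- make_two_group(c(1, 2), 3)
  expect_error(group_t_test(g5$x, g5$ann), "at least 2 samples")
})

test_that("Welch variant matches the textbook formula oracle", {
  a <- c(1, 2, 3, 4)
  b <- c(3, 4, 5, 6)
  g <- make_two_group(a, b)
  r <- group_t_test(g$x, g$ann, var_equal = FALSE)
  o <- oracle_welch(a, b)
  expect_equal(r$t_stat, o$t, tolerance = 1e-12)
  expect_equal(r$p_raw, o$p, tolerance = 1e-12)
})

test_that("BH adjustment reproduces hand examples and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("BH adjustment equals the definition-based oracle on random vectors", {
  withr::local_seed(11)
  for (i in 1:1000) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("signed fold changes follow the ratio convention and antisymmetry", {
  g <- make_two_group(c(5, 5), c(3, 3))
  expect_equal(fold_change(g$x, g$ann)$fold_change, 4)
  g2 <- make_two_group(c(3, 3), c(5, 5))
  expect_equal(fold_change(g2$x, g2$ann)$fold_change, -4)
  g3 <- make_two_group(c(4, 4), c(4, 4))
  expect_equal(fold_change(g3$x, g3$ann)$fold_change, 1)
  withr::local_seed(3)
  for (i in 1:20) {
    a <- rnorm(4)
    b <- rnorm(3)
    fab <- fold_change(make_two_group(a, b)$x, make_two_group(a, b)$ann)
    fba <- fold_change(make_two_group(b, a)$x,
                       sample_annotation(
                         c(sprintf("a%d", 1:3), sprintf("b%d", 1:4)),
                         rep(c("cell_line", "bone"), c(3, 4))))
    expect_equal(fab$fold_change, -fba$fold_change, tolerance = 1e-12)
    expect_gte(abs(fab$fold_change), 1)
  }
})

test_that("differential_features recovers planted miRNAs with few false calls", {
  # 20 planted of 200, moderate noise; median over repeated cohorts
  res <- sapply(1:15, function(s) {
    co <- simulate_cohort(simulation_config(seed = s, n_de_mirna = 20,
                                            n_true_pairs = 15,
                                            noise_sd = 0.3))
    de <- differential_features(co$mirna, co$annotation, d = co$detection)
    hits <- de$feature_id[de$significant]
    c(tp = sum(co$truth$de_mirna$mirna_id %in% hits),
      fp = sum(!hits %in% co$truth$de_mirna$mirna_id))
  })
  expect_gte(median(res["tp", ]), 18)
  expect_lte(median(res["fp", ]), 1)
})

test_that("differential_features honors degenerate thresholds and exact zero noise", {
  co <- simulate_cohort(simulation_config(seed = 5, noise_sd = 0,
                                          de_log2_effect = 2))
  de <- differential_features(co$mirna, co$annotation, d = co$detection,
                              alpha = 0)
  expect_equal(sum(de$significant), 0)
  planted <- de[de$feature_id %in% co$truth$de_mirna$mirna_id, ]
  expect_true(all(abs(planted$fold_change) == 4))
})

test_that("family annotation counts shared families and clusters", {
  rec <- tibble::tibble(
    feature_id = sprintf("m%d", 1:6),
    significant = TRUE
  )
  ann <- tibble::tibble(
    mirna_id = sprintf("m%d", 1:6),
    family_id = c("famA", "famA", "famB", "famB", NA, NA),
    cluster_id = NA_character_
  )
  out <- annotate_families(rec, ann)
  expect_equal(out$summary$n_shared_family_or_cluster, 4)
  expect_equal(out$summary$n_in_family, 4)
  # cluster-mates count too
  ann2 <- tibble::tibble(mirna_id = c("m1", "m2"), family_id = NA_character_,
                         cluster_id = "miR-17-92")
  out2 <- annotate_families(rec[1:2, ], ann2)
  expect_equal(out2$summary$n_shared_family_or_cluster, 2)
  # no annotation: zero counts
  out3 <- annotate_families(rec, tibble::tibble(mirna_id = character(),
                                                family_id = character(),
                                                cluster_id = character()))
  expect_equal(out3$summary$n_shared_family_or_cluster, 0)
  expect_equal(out3$summary$n_in_family, 0)
})
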