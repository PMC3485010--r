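#' Per-feature two-group t-tests
#'
#' Two-sided two-sample t-test for every feature of a log2-scale
#' expression table, comparing group A against group B. The
#' pooled-variance (Student) test is the default: with a reference arm
#' of only 4 bones, the Welch-Satterthwaite degrees of freedom collapse
#' to ~4, which both starves the test of power and makes its far-tail
#' p-values unreliable under FDR thresholds near 10^-3; on log2
#' microarray intensities with comparable group variances the pooled
#' test is well calibrated. Welch's unequal-variance test is available
#' via `var_equal = FALSE`.
#'
#' Degenerate features (zero variance in both groups) cannot be tested:
#' with equal group means they get `t = 0, p = 1` by convention, keeping
#' the downstream FDR adjustment well defined; with unequal means the
#' limit `t = +/-Inf, p = 0` is reported.
#'
#' @param x An [expression_table()] on the log2 scale.
#' @param ann Sample annotation.
#' @param group_a,group_b Group labels to compare (A minus B).
#' @param var_equal Pooled-variance test (default); `FALSE` gives
#'   Welch's unequal-variance test.
#' @return A tibble with columns `feature_id`, `t_stat`, `p_raw`.
#' @export
group_t_test <- function(x, ann, group_a = "cell_line", group_b = "bone",
                         var_equal = TRUE) {
  m <- expr_matrix(x)
  ia <- intersect(colnames(m), samples_in_group(ann, group_a))
  ib <- intersect(colnames(m), samples_in_group(ann, group_b))
  if (length(ia) < 2 || length(ib) < 2) {
    stop("both groups need at least 2 samples (", group_a, ": ", length(ia),
         ", ", group_b, ": ", length(ib), ")", call. = FALSE)
  }
  res <- apply(m, 1, function(row) {
    a <- row[ia]
    b <- row[ib]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      d <- mean(a) - mean(b)
      if (d == 0) return(c(0, 1))
      return(c(sign(d) * Inf, 0))
    }
    tt <- stats::t.test(a, b, var.equal = var_equal)
    c(unname(tt$statistic), tt$p.value)
  })
  tibble::tibble(feature_id = rownames(m), t_stat = unname(res[1, ]),
                 p_raw = unname(res[2, ]))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: sort ascending, take `p_i * m / i`, enforce
#' monotonicity from the largest rank down, cap at 1, return in input
#' order (delegated to [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] and be non-missing", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Signed fold changes between two groups
#'
#' On the log2 scale the group-mean difference `D = mean_A - mean_B` is
#' converted to the field's signed ratio convention: `2^D` when `D >= 0`,
#' `-2^(-D)` when `D < 0`. Equal means give `+1`; the magnitude is always
#' `>= 1`.
#'
#' @inheritParams group_t_test
#' @return A tibble with `feature_id`, `log2_mean_a`, `log2_mean_b`,
#'   `fold_change`.
#' @export
fold_change <- function(x, ann, group_a = "cell_line", group_b = "bone") {
  m <- expr_matrix(x)
  ia <- intersect(colnames(m), samples_in_group(ann, group_a))
  ib <- intersect(colnames(m), samples_in_group(ann, group_b))
  ma <- rowMeans(m[, ia, drop = FALSE])
  mb <- rowMeans(m[, ib, drop = FALSE])
  d <- ma - mb
  tibble::tibble(
    feature_id = rownames(m),
    log2_mean_a = unname(ma),
    log2_mean_b = unname(mb),
    fold_change = unname(ifelse(d >= 0, 2^d, -(2^(-d))))
  )
}

#' Two-group differential expression with presence filtering
#'
#' The full differential-expression stage: apply the presence filter,
#' t-test the retained features, BH-adjust within the retained set
#' (filtering precedes testing, so the multiplicity burden reflects only
#' the analyzable features), and report signed fold changes plus detected
#' counts per group. Features detected in few samples of one group are
#' flagged `fc_overestimated`: their group mean leans on near-background
#' wells, so the ratio can overstate the true change.
#'
#' @inheritParams group_t_test
#' @param d Optional [detection_table()]; when absent, detection calls are
#'   derived with [detection_from_intensity()] at `detect_quantile`.
#' @param rule A [presence_rule()]; `NULL` skips presence filtering.
#' @param alpha BH-adjusted significance cut-off (default 0.05,
#'   inclusive); `alpha = 0` marks nothing significant, even exact-zero
#'   p-values.
#' @param fc_threshold Absolute fold-change threshold for the `twofold`
#'   flag (default 2, strict `>`).
#' @param detect_quantile Fallback detection quantile.
#' @return A tibble of per-feature records: `feature_id`, `t_stat`,
#'   `p_raw`, `p_adj`, `log2_mean_a`, `log2_mean_b`, `fold_change`,
#'   `presence_a`, `presence_b`, `significant`, `twofold`,
#'   `fc_overestimated`.
#' @export
differential_features <- function(x, ann, group_a = "cell_line",
                                  group_b = "bone", d = NULL,
                                  rule = presence_rule(), alpha = 0.05,
                                  fc_threshold = 2, detect_quantile = 0.25,
                                  var_equal = TRUE) {
  if (is.null(d)) d <- detection_from_intensity(x, detect_quantile)
  keep <- if (is.null(rule)) expr_features(x) else presence_filter(d, ann, rule)
  xs <- x[match(keep, x$feature_id), ]
  dm <- as.matrix(d[setdiff(names(d), "feature_id")])
  rownames(dm) <- d$feature_id
  ia <- intersect(expr_samples(x), samples_in_group(ann, group_a))
  ib <- intersect(expr_samples(x), samples_in_group(ann, group_b))
  pres_a <- rowSums(dm[keep, ia, drop = FALSE])
  pres_b <- rowSums(dm[keep, ib, drop = FALSE])
  tt <- group_t_test(xs, ann, group_a, group_b, var_equal = var_equal)
  fc <- fold_change(xs, ann, group_a, group_b)
  dplyr::left_join(tt, fc, by = "feature_id") |>
    dplyr::mutate(
      p_adj = bh_adjust(.data$p_raw),
      presence_a = unname(pres_a),
      presence_b = unname(pres_b),
      significant = alpha > 0 & .data$p_adj <= alpha,
      twofold = abs(.data$fold_change) > fc_threshold,
      fc_overestimated = pmin(pres_a / length(ia), pres_b / length(ib)) < 0.5
    ) |>
    dplyr::relocate("p_adj", .after = "p_raw")
}

#' Annotate differential hits with miRNA family and cluster membership
#'
#' Tags each record with its family, genomic cluster and host gene (when
#' annotated) and summarizes co-regulation: how many significant hits
#' carry any family tag, and how many share a family or polycistronic
#' cluster with at least one other significant hit -- the hallmark of
#' co-transcribed or seed-sharing miRNAs moving together.
#'
#' @param records Output of [differential_features()].
#' @param mirna_annotation Tibble with `mirna_id`, `family_id`,
#'   `cluster_id`, `host_gene` (missing entries allowed).
#' @return A list with `records` (annotated tibble) and `summary`
#'   (one-row tibble: `n_significant`, `n_in_family`,
#'   `n_shared_family_or_cluster`).
#' @export
annotate_families <- function(records, mirna_annotation) {
  ann <- tibble::as_tibble(mirna_annotation)
  rec <- dplyr::left_join(
    records,
    dplyr::select(ann, "mirna_id", "family_id", "cluster_id",
                  dplyr::any_of("host_gene")),
    by = c(feature_id = "mirna_id")
  )
  sig <- dplyr::filter(rec, .data$significant)
  shared_ids <- function(col) {
    tab <- table(sig[[col]][!is.na(sig[[col]])])
    sig$feature_id[!is.na(sig[[col]]) & sig[[col]] %in% names(tab)[tab >= 2]]
  }
  shared <- union(shared_ids("family_id"), shared_ids("cluster_id"))
  list(
    records = rec,
    summary = tibble::tibble(
      n_significant = nrow(sig),
      n_in_family = sum(!is.na(sig$family_id)),
      n_shared_family_or_cluster = length(shared)
    )
  )
}
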