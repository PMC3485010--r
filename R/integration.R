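#' Build candidate miRNA-mRNA pairs
#'
#' Crosses the differentially expressed miRNAs with their predicted
#' targets and keeps only pairs whose target gene is significantly
#' changed in *both* the cell-line and the clinical contrast -- requiring
#' dual-cohort confirmation screens out in-vitro artifacts before any
#' correlation is computed.
#'
#' @param de_mirnas Character vector of differentially expressed miRNA
#'   ids.
#' @param predictions Prediction tibble
#'   ([read_targetscan_predictions()] shape).
#' @param de_mrnas_cl,de_mrnas_clin Gene symbols significant in the
#'   cell-line and clinical contrasts respectively.
#' @return A pair tibble: `mirna_id`, `gene_symbol`, `transcript_id`,
#'   `pct`, `star_strand`, `r` (NA until [pair_correlations()]), and the
#'   stage flags `predicted`, `cohort_confirmed`.
#' @export
candidate_pairs <- function(de_mirnas, predictions, de_mrnas_cl,
                            de_mrnas_clin) {
  if (nrow(predictions) == 0) {
    warning("empty prediction table: no candidate pairs")
  }
  common <- intersect(de_mrnas_cl, de_mrnas_clin)
  predictions |>
    dplyr::filter(.data$mirna_id %in% de_mirnas,
                  .data$gene_symbol %in% common) |>
    dplyr::distinct(.data$mirna_id, .data$transcript_id, .keep_all = TRUE) |>
    dplyr::mutate(r = NA_real_, predicted = TRUE, cohort_confirmed = TRUE) |>
    dplyr::select("mirna_id", "gene_symbol", "transcript_id", "pct",
                  "star_strand", "r", "predicted", "cohort_confirmed")
}

#' Compute pairwise miRNA-target correlations
#'
#' Fills each pair's Pearson `r` between the miRNA's and the target's
#' expression across a sample subset -- by default the osteosarcoma cell
#' lines, where co-measurement of both panels is complete. When a gene is
#' represented by several probes/transcripts, the most anti-correlated
#' probe represents the gene (`collapse = "min_r"`, most favorable to
#' detection); `collapse = "none"` keeps every probe as its own pair.
#'
#' @param pairs Pair tibble from [candidate_pairs()].
#' @param mirna_x,mrna_x Expression tables. mRNA features may be keyed by
#'   `gene_symbol` or `transcript_id`.
#' @param samples Sample ids to correlate over (default: all shared
#'   samples); at least 3 required.
#' @param collapse `"min_r"` or `"none"`.
#' @return The pair tibble with `r` filled (one row per gene per miRNA
#'   under `"min_r"`).
#' @export
pair_correlations <- function(pairs, mirna_x, mrna_x, samples = NULL,
                              collapse = c("min_r", "none")) {
  collapse <- match.arg(collapse)
  shared <- intersect(expr_samples(mirna_x), expr_samples(mrna_x))
  if (!is.null(samples)) shared <- intersect(samples, shared)
  if (length(shared) < 3) {
    stop("need at least 3 overlapping samples, got ", length(shared),
         call. = FALSE)
  }
  mi <- expr_matrix(mirna_x)[, shared, drop = FALSE]
  mr <- expr_matrix(mrna_x)[, shared, drop = FALSE]
  key <- if (all(pairs$transcript_id %in% rownames(mr))) "transcript_id"
         else "gene_symbol"
  out <- pairs |>
    dplyr::filter(.data$mirna_id %in% rownames(mi),
                  .data[[key]] %in% rownames(mr)) |>
    dplyr::mutate(r = purrr::map2_dbl(.data$mirna_id, .data[[key]],
                                      function(a, b) {
      stats::cor(mi[a, ], mr[b, ])
    }))
  if (collapse == "min_r") {
    out <- out |>
      dplyr::group_by(.data$mirna_id, .data$gene_symbol) |>
      dplyr::slice_min(.data$r, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  out
}

#' Anti-correlation filter
#'
#' Keeps pairs whose Pearson `r` lies strictly below the threshold
#' (default `-0.5`): a pair at exactly `r = -0.5` is dropped.
#'
#' @param pairs Pair tibble with `r` filled.
#' @param r_threshold Strict upper bound on `r` (default `-0.5`).
#' @return Filtered pairs with an `anticorrelated` flag column.
#' @export
anticorrelation_filter <- function(pairs, r_threshold = -0.5) {
  pairs |>
    dplyr::filter(!is.na(.data$r), .data$r < r_threshold) |>
    dplyr::mutate(anticorrelated = TRUE)
}

#' Conservation (P_CT) filter
#'
#' Drops pairs whose probability of preferentially conserved targeting is
#' below the threshold (default 0.4, kept at the boundary). Pairs with
#' *missing* P_CT are retained: passenger-strand (star) miRNAs have no
#' conserved-targeting probability, and excluding them for lack of a
#' score would silently discard that arm of the analysis.
#'
#' @param pairs Pair tibble.
#' @param pct_threshold Minimum P_CT retained (weak inequality).
#' @return Filtered pairs with a `conserved` flag column.
#' @export
conservation_filter <- function(pairs, pct_threshold = 0.4) {
  pairs |>
    dplyr::filter(is.na(.data$pct) | .data$pct >= pct_threshold) |>
    dplyr::mutate(conserved = TRUE)
}

#' Group genes targeted by multiple miRNAs
#'
#' Genes inversely correlated with at least `min_mirnas` distinct miRNAs
#' -- often members of one seed family -- are the strongest target
#' candidates, since several independent regulators point at them.
#'
#' @param pairs Filtered pair tibble.
#' @param min_mirnas Minimum distinct miRNAs per gene (default 2).
#' @return A tibble ordered by gene symbol: `gene_symbol`, `n_mirnas`,
#'   `mirna_ids` (comma-separated, sorted), `mean_r`.
#' @export
multi_mirna_targets <- function(pairs, min_mirnas = 2) {
  pairs |>
    dplyr::group_by(.data$gene_symbol) |>
    dplyr::summarise(
      n_mirnas = dplyr::n_distinct(.data$mirna_id),
      mirna_ids = paste(sort(unique(.data$mirna_id)), collapse = ", "),
      mean_r = mean(.data$r),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_mirnas >= min_mirnas) |>
    dplyr::arrange(.data$gene_symbol)
}

#' Hypergeometric overlap test for two gene sets
#'
#' Upper-tail probability of observing at least the seen intersection of
#' two sets drawn from a common universe. The tail is accumulated in log
#' space from log-gamma binomial coefficients, so overlaps whose p-value
#' underflows double precision (below ~1e-308, and the study's reported
#' `< 1e-1000` regime) remain exactly representable as `log10_p`.
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector of all eligible elements.
#' @return An `overlap_test` object; see [tidy()] / [glance()]. Fields:
#'   `n_universe`, `n_set_a`, `n_set_b`, `n_overlap`, `log10_p`, `p`.
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("both sets must be subsets of the universe", call. = FALSE)
  }
  n <- length(universe)
  ka <- length(set_a)
  kb <- length(set_b)
  k <- length(intersect(set_a, set_b))
  log_p <- log_hyper_upper(k, ka, kb, n)
  structure(list(n_universe = n, n_set_a = ka, n_set_b = kb, n_overlap = k,
                 log10_p = log_p / log(10), p = exp(log_p)),
            class = "overlap_test")
}

# log P(X >= k), X ~ Hypergeometric(n_a successes, n - n_a failures,
# n_b draws), via log-gamma terms and a log-sum-exp accumulation
log_hyper_upper <- function(k, n_a, n_b, n) {
  if (k <= 0) return(0)
  lchoose_ <- function(a, b) lgamma(a + 1) - lgamma(b + 1) - lgamma(a - b + 1)
  kmax <- min(n_a, n_b)
  i <- k:kmax
  terms <- lchoose_(n_a, i) + lchoose_(n - n_a, n_b - i) - lchoose_(n, n_b)
  m <- max(terms)
  min(0, m + log(sum(exp(terms - m))))
}

#' @export
print.overlap_test <- function(x, ...) {
  cat("Hypergeometric overlap test\n")
  cat("  |A| =", x$n_set_a, " |B| =", x$n_set_b, " overlap =", x$n_overlap,
      " universe =", x$n_universe, "\n")
  cat("  upper-tail log10(p) =", format(x$log10_p, digits = 6), "\n")
  invisible(x)
}

#' @export
tidy.overlap_test <- function(x, ...) {
  tibble::tibble(n_universe = x$n_universe, n_set_a = x$n_set_a,
                 n_set_b = x$n_set_b, n_overlap = x$n_overlap,
                 log10_p = x$log10_p, p = x$p)
}

#' @export
glance.overlap_test <- function(x, ...) tidy(x)

#' Pearson correlation for given feature pairs across two matrices
#'
#' Generic paired correlation over shared samples, used e.g. for
#' miRNA-versus-host-gene expression (intronic miRNA clusters track the
#' transcription of the gene carrying them) and guide-versus-star-strand
#' comparisons.
#'
#' @param x_a,x_b Expression tables.
#' @param id_pairs Two-column data frame (`id_a`, `id_b`) of feature ids
#'   to correlate.
#' @param samples Optional sample subset; at least 3 shared samples
#'   required.
#' @return `id_pairs` with an `r` column.
#' @export
correlate_features <- function(x_a, x_b, id_pairs, samples = NULL) {
  shared <- intersect(expr_samples(x_a), expr_samples(x_b))
  if (!is.null(samples)) shared <- intersect(samples, shared)
  if (length(shared) < 3) {
    stop("need at least 3 overlapping samples, got ", length(shared),
         call. = FALSE)
  }
  ma <- expr_matrix(x_a)[, shared, drop = FALSE]
  mb <- expr_matrix(x_b)[, shared, drop = FALSE]
  ids <- tibble::as_tibble(id_pairs)
  names(ids)[1:2] <- c("id_a", "id_b")
  ids$r <- purrr::map2_dbl(ids$id_a, ids$id_b,
                           function(a, b) stats::cor(ma[a, ], mb[b, ]))
  ids
}

#' Scatter plot for one miRNA-target pair
#'
#' @param mirna_x,mrna_x Expression tables.
#' @param mirna_id,gene_id Feature ids to plot (gene keyed as in the
#'   mRNA table).
#' @param ann Optional sample annotation used to color points by group.
#' @param samples Optional sample subset.
#' @return A ggplot scatter of target against miRNA log2 expression.
#' @export
plot_pair <- function(mirna_x, mrna_x, mirna_id, gene_id, ann = NULL,
                      samples = NULL) {
  shared <- intersect(expr_samples(mirna_x), expr_samples(mrna_x))
  if (!is.null(samples)) shared <- intersect(samples, shared)
  df <- tibble::tibble(
    sample_id = shared,
    mirna = expr_matrix(mirna_x)[mirna_id, shared],
    mrna = expr_matrix(mrna_x)[gene_id, shared]
  )
  if (!is.null(ann)) df <- dplyr::left_join(df, ann, by = "sample_id")
  r <- stats::cor(df$mirna, df$mrna)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mirna, y = .data$mrna)) +
    ggplot2::geom_point(if (!is.null(ann)) ggplot2::aes(color = .data$group)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, color = "grey40") +
    ggplot2::labs(
      x = paste(mirna_id, "(log2)"), y = paste(gene_id, "(log2)"),
      title = sprintf("%s vs %s  (r = %.2f)", mirna_id, gene_id, r)
    ) +
    ggplot2::theme_minimal()
  p
}
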