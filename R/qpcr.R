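#' Impute undetected qPCR wells
#'
#' Wells where amplification never crossed the threshold are set to a
#' ceiling cycle number (default Ct = 40, the instrument's last cycle),
#' the standard convention for "expression below detection". The number
#' of imputed wells per assay is attached as the `"imputed"` attribute.
#'
#' @param ct_tbl Ct tibble from [read_qpcr_table()] or [simulate_qpcr()].
#' @param ceiling Ct value assigned to undetected wells.
#' @return The table with undetected wells numeric at `ceiling`.
#' @export
impute_undetected <- function(ct_tbl, ceiling = 40) {
  out <- ct_tbl |>
    dplyr::mutate(ct = ifelse(.data$undetected, ceiling, .data$ct))
  counts <- ct_tbl |>
    dplyr::filter(.data$undetected) |>
    dplyr::count(.data$assay_id, name = "n_imputed")
  attr(out, "imputed") <- counts
  out
}

#' Relative quantification by the comparative Ct (2^-ddCt) method
#'
#' Per sample, `dCt = Ct_target - mean(Ct of the reference assays)`
#' (dual endogenous references, e.g. RNU44 and RNU6B, combined by
#' arithmetic mean on the Ct scale); `ddCt = dCt - mean(dCt over the
#' calibrator group)`; the relative quantity is `RQ = 2^-ddCt`, i.e.
#' expression relative to the calibrator group's mean level. Technical
#' replicates (duplicate sample/assay rows) are averaged on the Ct scale
#' first. Undetected wells must be imputed beforehand
#' ([impute_undetected()]).
#'
#' @param ct_tbl Ct tibble with no undetected wells remaining.
#' @param reference_assays Assay ids of the endogenous references; every
#'   sample must have all of them measured.
#' @param ann Sample annotation.
#' @param calibrator_group Group whose mean dCt anchors ddCt = 0
#'   (default `"bone"`).
#' @return A tibble: `sample_id`, `assay_id`, `group`, `delta_ct`,
#'   `ddct`, `rq`.
#' @export
ddct <- function(ct_tbl, reference_assays, ann, calibrator_group = "bone") {
  if (anyNA(ct_tbl$ct)) {
    stop("undetected wells present; run impute_undetected() first",
         call. = FALSE)
  }
  tb <- ct_tbl |>
    dplyr::group_by(.data$sample_id, .data$assay_id) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
  refs <- tb |>
    dplyr::filter(.data$assay_id %in% reference_assays) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(ref_ct = mean(.data$ct), n_ref = dplyr::n(),
                     .groups = "drop")
  missing_ref <- tb |>
    dplyr::distinct(.data$sample_id) |>
    dplyr::left_join(refs, by = "sample_id") |>
    dplyr::filter(is.na(.data$ref_ct) | .data$n_ref < length(reference_assays))
  if (nrow(missing_ref) > 0) {
    stop("missing reference assay well(s) for sample(s): ",
         paste(missing_ref$sample_id, collapse = ", "), call. = FALSE)
  }
  rel <- tb |>
    dplyr::filter(!.data$assay_id %in% reference_assays) |>
    dplyr::left_join(refs, by = "sample_id") |>
    dplyr::left_join(ann[c("sample_id", "group")], by = "sample_id") |>
    dplyr::mutate(delta_ct = .data$ct - .data$ref_ct)
  cal <- rel |>
    dplyr::filter(.data$group == calibrator_group) |>
    dplyr::group_by(.data$assay_id) |>
    dplyr::summarise(cal_dct = mean(.data$delta_ct), .groups = "drop")
  if (nrow(cal) == 0) {
    stop("calibrator group '", calibrator_group, "' is empty", call. = FALSE)
  }
  rel |>
    dplyr::left_join(cal, by = "assay_id") |>
    dplyr::mutate(ddct = .data$delta_ct - .data$cal_dct,
                  rq = 2^(-.data$ddct)) |>
    dplyr::select("sample_id", "assay_id", "group", "delta_ct", "ddct", "rq")
}

#' Mann-Whitney U test for two groups
#'
#' Exact two-sided p by full enumeration of the U distribution when both
#' groups are small (`min(n, m) <= exact_max`) and the data are tie-free;
#' otherwise the normal approximation with tie and continuity correction.
#' The method actually used is recorded in the result.
#'
#' @param a,b Numeric vectors (both nonempty).
#' @param exact_max Largest smaller-group size for which the exact
#'   distribution is used.
#' @return A `mw_test` list: `u_stat`, `p`, `method`, `n_a`, `n_b`.
#' @export
mann_whitney <- function(a, b, exact_max = 8) {
  if (length(a) == 0 || length(b) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- !ties && min(length(a), length(b)) <= exact_max
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = use_exact,
                                            correct = TRUE))
  structure(list(u_stat = unname(wt$statistic), p = min(1, wt$p.value),
                 method = if (use_exact) "exact" else "normal_approx",
                 n_a = length(a), n_b = length(b)),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g, p = %.4g (%s; n = %d vs %d)\n",
              x$u_stat, x$p, x$method, x$n_a, x$n_b))
  invisible(x)
}

#' @export
tidy.mw_test <- function(x, ...) {
  tibble::tibble(u_stat = x$u_stat, p = x$p, method = x$method,
                 n_a = x$n_a, n_b = x$n_b)
}

#' @export
glance.mw_test <- function(x, ...) tidy(x)

#' Per-assay group comparison with significance/trend banding
#'
#' Runs [mann_whitney()] per assay between two sample groups on the
#' relative quantities (or dCt values) and assigns each p-value to a
#' band: `significant` when `p < sig` (strict), `trend` when
#' `sig <= p <= trend_hi` (the closed interval), otherwise `ns`. No
#' multiplicity adjustment is applied across assays by default, matching
#' common qPCR validation reporting; `adjust = "BH"` turns it on.
#'
#' @param rel Output of [ddct()].
#' @param group_a,group_b Groups to compare.
#' @param value `"rq"` (default) or `"delta_ct"`.
#' @param sig Significance cut-off (default 0.05).
#' @param trend_hi Upper edge of the trend band (default 0.15).
#' @param adjust `"none"` (default) or `"BH"` (bands then use adjusted
#'   p).
#' @return A tibble: `assay_id`, `group_a`, `group_b`, `u_stat`, `p`,
#'   `method`, `band`.
#' @export
qpcr_group_tests <- function(rel, group_a = "clinical", group_b = "bone",
                             value = c("rq", "delta_ct"), sig = 0.05,
                             trend_hi = 0.15, adjust = c("none", "BH")) {
  value <- match.arg(value)
  adjust <- match.arg(adjust)
  res <- rel |>
    dplyr::group_by(.data$assay_id) |>
    dplyr::group_modify(function(df, key) {
      va <- df[[value]][df$group == group_a]
      vb <- df[[value]][df$group == group_b]
      tidy(mann_whitney(va, vb))[c("u_stat", "p", "method")]
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(group_a = group_a, group_b = group_b,
                  .after = "assay_id")
  if (adjust == "BH") res$p <- bh_adjust(res$p)
  band_results(res, sig = sig, trend_hi = trend_hi)
}

#' Assign p-value bands
#'
#' @param results Tibble with a `p` column.
#' @param sig,trend_hi Band edges; `significant` is `p < sig` (strict),
#'   `trend` is the closed interval `[sig, trend_hi]`.
#' @return `results` with a `band` factor column.
#' @export
band_results <- function(results, sig = 0.05, trend_hi = 0.15) {
  results |>
    dplyr::mutate(band = factor(
      dplyr::case_when(
        .data$p < sig ~ "significant",
        .data$p <= trend_hi ~ "trend",
        TRUE ~ "ns"
      ),
      levels = c("significant", "trend", "ns")
    ))
}

#' Strip plot of relative expression by group
#'
#' @param rel Output of [ddct()].
#' @param assays Optional subset of assay ids.
#' @return A ggplot of per-sample RQ (log scale) by group, one facet per
#'   assay.
#' @export
plot_rq <- function(rel, assays = NULL) {
  df <- if (is.null(assays)) rel else dplyr::filter(rel, .data$assay_id %in% assays)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$rq)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.5, linewidth = 0.3, color = "red3") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~assay_id, scales = "free_y") +
    ggplot2::labs(x = NULL, y = expression(2^{-Delta*Delta*Ct})) +
    ggplot2::theme_minimal()
}
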