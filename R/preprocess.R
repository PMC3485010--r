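#' Log2-transform an expression table
#'
#' @param x An [expression_table()] on the raw intensity scale.
#' @param offset Non-negative pseudo-intensity added before taking logs;
#'   every `value + offset` must be strictly positive.
#' @return The table with `values = log2(value + offset)` and scale
#'   `"log2"`.
#' @export
log2_transform <- function(x, offset = 0) {
  stopifnot(offset >= 0)
  if (expr_scale(x) != "raw") {
    stop("input is already on the log2 scale", call. = FALSE)
  }
  m <- expr_matrix(x)
  bad <- which(m + offset <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-positive intensity at feature '", rownames(m)[bad[1, 1]],
         "', sample '", colnames(m)[bad[1, 2]], "' (offset ", offset, ")",
         call. = FALSE)
  }
  expression_table(log2(m + offset), scale = "log2")
}

#' Quantile-normalize an expression table
#'
#' Forces every sample column to share one reference distribution: the
#' vector of cross-sample rank means. Within-column ordering is preserved;
#' tied values receive the mean of the rank-mean values at the tied ranks,
#' so the result is deterministic and idempotent.
#'
#' @param x An [expression_table()] on the log2 scale with no missing
#'   values (impute or drop incomplete rows first, by explicit choice).
#' @return The normalized table; a single-column table is returned
#'   unchanged with a message.
#' @export
quantile_normalize <- function(x) {
  if (expr_scale(x) != "log2") {
    stop("quantile normalization expects log2-scale values", call. = FALSE)
  }
  m <- expr_matrix(x)
  if (anyNA(m)) stop("missing values present; handle them first", call. = FALSE)
  if (ncol(m) == 1) {
    message("single-column matrix: quantile normalization is a no-op")
    return(x)
  }
  ref <- rowMeans(apply(m, 2, sort))
  cs <- c(0, cumsum(ref))
  out <- apply(m, 2, function(col) {
    # tied values span ranks [rmin, rmax]; they all receive the mean of
    # the reference values over that span
    rmin <- rank(col, ties.method = "min")
    rmax <- rank(col, ties.method = "max")
    (cs[rmax + 1] - cs[rmin]) / (rmax - rmin + 1)
  })
  dimnames(out) <- dimnames(m)
  expression_table(out, scale = "log2")
}

#' Presence rule
#'
#' Encodes the group-wise detection filter "detectable in at least
#' `frac_a` of group A and/or `frac_b` of group B". Fractions are turned
#' into integer count thresholds by ceiling, matching the "at least"
#' semantics (e.g. 25% of 19 cell lines requires detection in
#' `ceiling(4.75) = 5` of them).
#'
#' @param group_a,group_b Group labels (see [sample_annotation()]).
#' @param frac_a,frac_b Required detected fractions in `[0, 1]`.
#' @param combine `"or"` (either group suffices, the default) or `"and"`.
#' @return A `presence_rule` list.
#' @export
presence_rule <- function(group_a = "bone", frac_a = 0.75,
                          group_b = "cell_line", frac_b = 0.25,
                          combine = c("or", "and")) {
  stopifnot(frac_a >= 0, frac_a <= 1, frac_b >= 0, frac_b <= 1)
  structure(list(group_a = group_a, frac_a = frac_a, group_b = group_b,
                 frac_b = frac_b, combine = match.arg(combine)),
            class = "presence_rule")
}

#' Apply a group-wise presence filter
#'
#' A feature is retained when its detected count reaches the rule's
#' thresholds: `detected in group_a >= ceiling(frac_a * n_a)` OR/AND
#' `detected in group_b >= ceiling(frac_b * n_b)`.
#'
#' @param d A [detection_table()].
#' @param ann Sample annotation covering the detection table's samples.
#' @param rule A [presence_rule()].
#' @return Character vector of retained feature ids, in input order.
#' @export
presence_filter <- function(d, ann, rule = presence_rule()) {
  m <- as.matrix(d[setdiff(names(d), "feature_id")])
  rownames(m) <- d$feature_id
  count_in <- function(group, frac) {
    ids <- intersect(colnames(m), ann$sample_id[ann$group == group])
    if (length(ids) == 0) {
      stop("no samples in group '", group, "'", call. = FALSE)
    }
    list(n = rowSums(m[, ids, drop = FALSE], na.rm = TRUE),
         thr = ceiling(frac * length(ids)))
  }
  a <- count_in(rule$group_a, rule$frac_a)
  b <- count_in(rule$group_b, rule$frac_b)
  pass <- if (rule$combine == "or") {
    a$n >= a$thr | b$n >= b$thr
  } else {
    a$n >= a$thr & b$n >= b$thr
  }
  rownames(m)[pass]
}

#' Derive detection calls from intensities
#'
#' When vendor detection flags are unavailable, a feature is called
#' detected in a sample when its intensity exceeds a global quantile of
#' all values in the matrix.
#'
#' @param x An [expression_table()].
#' @param quantile Global quantile used as the detection threshold.
#' @return A [detection_table()] with the same axes as `x`.
#' @export
detection_from_intensity <- function(x, quantile = 0.25) {
  m <- expr_matrix(x)
  thr <- stats::quantile(m, probs = quantile, na.rm = TRUE, names = FALSE)
  detection_table(m > thr)
}
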