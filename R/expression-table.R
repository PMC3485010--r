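#' Expression tables
#'
#' The pipeline's central container is a *wide tibble*: the first column,
#' `feature_id`, holds unique feature identifiers (miRNA or mRNA probe ids)
#' and every remaining column is one sample's numeric intensities. The
#' measurement scale ("raw" intensity or "log2" intensity) travels with the
#' table as the `"scale"` attribute so downstream stages can refuse to, say,
#' quantile-normalize raw intensities.
#'
#' @param x A data frame whose first column is `feature_id` and whose
#'   remaining columns are numeric sample intensities, or a numeric matrix
#'   with rownames (features) and colnames (samples).
#' @param scale Measurement scale, `"raw"` or `"log2"`.
#' @return A tibble of class `expr_tbl` with a `"scale"` attribute.
#' @examples
#' m <- matrix(1:4, 2, dimnames = list(c("A", "B"), c("s1", "s2")))
#' expression_table(m, scale = "raw")
#' @export
expression_table <- function(x, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (is.matrix(x)) {
    stopifnot(!is.null(rownames(x)), !is.null(colnames(x)))
    x <- dplyr::bind_cols(tibble::tibble(feature_id = rownames(x)),
                          tibble::as_tibble(x, .name_repair = "minimal"))
  }
  x <- tibble::as_tibble(x)
  if (names(x)[1] != "feature_id") {
    names(x)[1] <- "feature_id"
  }
  x$feature_id <- as.character(x$feature_id)
  dup <- unique(x$feature_id[duplicated(x$feature_id)])
  if (length(dup) > 0) {
    stop("duplicated feature ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  sdup <- unique(names(x)[-1][duplicated(names(x)[-1])])
  if (length(sdup) > 0) {
    stop("duplicated sample ids: ", paste(sdup, collapse = ", "), call. = FALSE)
  }
  bad <- names(x)[-1][!vapply(x[-1], is.numeric, logical(1))]
  if (length(bad) > 0) {
    stop("non-numeric sample columns: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (scale == "log2" && any(!is.finite(as.matrix(x[-1])) & !is.na(as.matrix(x[-1])))) {
    stop("log2-scale expression values must be finite (missing values NA)",
         call. = FALSE)
  }
  structure(x, scale = scale, class = c("expr_tbl", class(x)))
}

#' @rdname expression_table
#' @export
expr_scale <- function(x) attr(x, "scale") %||% "raw"

#' @rdname expression_table
#' @export
expr_features <- function(x) x$feature_id

#' @rdname expression_table
#' @export
expr_samples <- function(x) setdiff(names(x), "feature_id")

#' Extract the numeric feature-by-sample matrix from an expression table
#'
#' @param x An [expression_table()] (or any wide tibble with a `feature_id`
#'   first column).
#' @return A numeric matrix with feature rownames and sample colnames.
#' @export
expr_matrix <- function(x) {
  m <- as.matrix(x[setdiff(names(x), "feature_id")])
  rownames(m) <- x$feature_id
  m
}

#' Detection-call tables
#'
#' A detection table mirrors the shape of its companion expression table but
#' holds logical detected/not-detected calls (array software's
#' above-background flags). Axes must match the companion exactly when both
#' are used together.
#'
#' @param x Data frame (first column `feature_id`, logical sample columns)
#'   or logical matrix with dimnames.
#' @return A tibble of class `detect_tbl`.
#' @export
detection_table <- function(x) {
  if (is.matrix(x)) {
    stopifnot(!is.null(rownames(x)), !is.null(colnames(x)))
    x <- dplyr::bind_cols(tibble::tibble(feature_id = rownames(x)),
                          tibble::as_tibble(x, .name_repair = "minimal"))
  }
  x <- tibble::as_tibble(x)
  names(x)[1] <- "feature_id"
  x$feature_id <- as.character(x$feature_id)
  x[-1] <- lapply(x[-1], function(v) as.logical(v))
  structure(x, class = c("detect_tbl", class(x)))
}

#' Sample annotation tables
#'
#' Maps each sample id to its study group -- osteosarcoma cell line, normal
#' bone, clinical tumor sample, or osteoblast culture -- plus a free-form
#' cohort tag. Every sample appearing in a group-wise operation must have
#' exactly one annotation row.
#'
#' @param sample_id Character vector of sample ids.
#' @param group Group label per sample; one of `"cell_line"`, `"bone"`,
#'   `"clinical"`, `"osteoblast"`.
#' @param cohort Optional cohort tag (defaults to the group label).
#' @return A tibble with columns `sample_id`, `group`, `cohort`.
#' @export
sample_annotation <- function(sample_id, group, cohort = group) {
  group <- as.character(group)
  ok <- group %in% c("cell_line", "bone", "clinical", "osteoblast")
  if (!all(ok)) {
    stop("unknown group label(s): ", paste(unique(group[!ok]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_id)) {
    stop("duplicated sample ids in annotation", call. = FALSE)
  }
  tibble::tibble(sample_id = as.character(sample_id), group = group,
                 cohort = as.character(cohort))
}

# group labels -> sample ids, with validation that every requested sample
# is annotated exactly once
samples_in_group <- function(ann, group, samples = NULL) {
  ids <- ann$sample_id[ann$group == group]
  if (!is.null(samples)) ids <- intersect(samples, ids)
  ids
}

`%||%` <- function(a, b) if (is.null(a)) b else a
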