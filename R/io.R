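#' Read and write expression matrices
#'
#' The canonical on-disk dialect is UTF-8 tab-separated text with a `.`
#' decimal mark: the first header cell is the literal `feature_id`, the
#' remaining header cells are sample ids, and each following row is one
#' feature. Empty cells are missing values. Files written by
#' [write_expression_matrix()] round-trip byte-identically.
#'
#' @param path Path to a tab-separated expression file.
#' @param scale Measurement scale of the stored values (`"raw"` or
#'   `"log2"`); recorded on the returned table, never used to transform.
#' @return An [expression_table()].
#' @export
read_expression_matrix <- function(path, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  tb <- read_tsv_strict(path, first_col = "character")
  expression_table(tb, scale = scale)
}

#' @rdname read_expression_matrix
#' @param x An [expression_table()] (or detection/annotation tibble for the
#'   companion writers).
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(names(x)[1] == "feature_id")
  readr::write_tsv(tibble::as_tibble(x), path, na = "")
  invisible(path)
}

#' Read a detection-call matrix
#'
#' Same dialect as [read_expression_matrix()] but with a logical body
#' (`TRUE`/`FALSE` or `0`/`1`).
#'
#' @inheritParams read_expression_matrix
#' @return A [detection_table()].
#' @export
read_detection_matrix <- function(path) {
  tb <- read_tsv_strict(path, first_col = "character")
  detection_table(tb)
}

#' Read and write sample annotation tables
#'
#' Tab-separated with columns `sample_id`, `group`, `cohort`.
#'
#' @inheritParams read_expression_matrix
#' @return A [sample_annotation()] tibble.
#' @export
read_sample_annotation <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  require_columns(tb, c("sample_id", "group"), path)
  sample_annotation(tb$sample_id, tb$group,
                    cohort = tb$cohort %||% tb$group)
}

#' @rdname read_sample_annotation
#' @param x Annotation tibble.
#' @export
write_sample_annotation <- function(x, path) {
  readr::write_tsv(x, path, na = "")
  invisible(path)
}

#' Read a TargetScan-style prediction table
#'
#' Tab-separated with named header columns `mirna_id`, `family_id`,
#' `gene_symbol`, `transcript_id` and `pct` (the column may also be named
#' `P_CT`; case is ignored). An empty P_CT cell yields a missing value --
#' the convention for passenger ("star") strands, for which no conserved
#' targeting probability is defined. The star-strand flag is derived from
#' the trailing `*` of the miRNA id.
#'
#' @inheritParams read_expression_matrix
#' @return A tibble with columns `mirna_id`, `family_id`, `gene_symbol`,
#'   `transcript_id`, `pct`, `star_strand`.
#' @export
read_targetscan_predictions <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  names(tb)[tolower(names(tb)) %in% c("pct", "p_ct")] <- "pct"
  require_columns(tb, c("mirna_id", "family_id", "gene_symbol",
                        "transcript_id", "pct"), path)
  pct <- suppressWarnings(as.numeric(tb$pct))
  bad <- which(!is.na(pct) & (pct < 0 | pct > 1))
  if (length(bad) > 0) {
    stop("P_CT outside [0, 1] on data row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    mirna_id = tb$mirna_id,
    family_id = tb$family_id,
    gene_symbol = tb$gene_symbol,
    transcript_id = tb$transcript_id,
    pct = pct,
    star_strand = endsWith(tb$mirna_id, "*")
  )
}

#' @rdname read_targetscan_predictions
#' @param x Prediction tibble.
#' @export
write_targetscan_predictions <- function(x, path) {
  readr::write_tsv(dplyr::select(x, -dplyr::any_of("star_strand")), path,
                   na = "")
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' Long tab-separated format with columns `sample_id`, `assay_id`, `ct`.
#' The sentinel `Undetermined` (any case) marks wells where no
#' amplification crossed the threshold; it is parsed as an explicit
#' undetected flag, never as a number. Imputation to a ceiling cycle is a
#' separate, downstream choice ([impute_undetected()]).
#'
#' @inheritParams read_expression_matrix
#' @return A tibble with columns `sample_id`, `assay_id`, `ct` (NA when
#'   undetected) and `undetected`.
#' @export
read_qpcr_table <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  require_columns(tb, c("sample_id", "assay_id", "ct"), path)
  undet <- tolower(trimws(tb$ct)) %in% "undetermined"
  ct <- suppressWarnings(as.numeric(tb$ct))
  ct[undet] <- NA_real_
  unparsed <- which(!undet & is.na(ct) & !(is.na(tb$ct) | tb$ct == ""))
  if (length(unparsed) > 0) {
    stop("unparseable Ct value on data row(s) ",
         paste(unparsed, collapse = ", "), call. = FALSE)
  }
  if (any(ct < 0, na.rm = TRUE)) {
    stop("negative Ct value(s) on data row(s) ",
         paste(which(ct < 0), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(sample_id = tb$sample_id, assay_id = tb$assay_id,
                 ct = ct, undetected = undet)
}

#' @rdname read_qpcr_table
#' @param x Ct tibble as returned by [read_qpcr_table()].
#' @export
write_qpcr_table <- function(x, path) {
  out <- tibble::tibble(
    sample_id = x$sample_id, assay_id = x$assay_id,
    ct = ifelse(x$undetected, "Undetermined", format_num(x$ct))
  )
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Read a GEO series-matrix file
#'
#' Convenience reader for the GEO `series_matrix.txt` text format: a
#' key-value header block followed by an expression body delimited by
#' `!series_matrix_table_begin` / `!series_matrix_table_end`. Sample titles
#' from the `!Sample_title` header line are used as sample ids when
#' present; otherwise the body header accessions are kept. Intended for
#' reproducing accession-based results; the core pipeline only depends on
#' the canonical TSV dialect.
#'
#' @inheritParams read_expression_matrix
#' @return An [expression_table()].
#' @export
read_series_matrix <- function(path, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  lines <- readr::read_lines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1 || length(end) != 1 || end <= beg + 1) {
    stop("missing or malformed series-matrix table delimiters in ", path,
         call. = FALSE)
  }
  body <- lines[(beg + 1):(end - 1)]
  tb <- readr::read_tsv(I(body), col_types = readr::cols(.default = "c"))
  names(tb)[1] <- "feature_id"
  tb$feature_id <- gsub('^"|"$', "", tb$feature_id)
  tb[-1] <- lapply(tb[-1], as.numeric)
  title_line <- grep("^!Sample_title\t", lines, value = TRUE)
  if (length(title_line) == 1) {
    titles <- strsplit(title_line, "\t")[[1]][-1]
    titles <- gsub('^"|"$', "", titles)
    if (length(titles) == ncol(tb) - 1 && !anyDuplicated(titles)) {
      names(tb)[-1] <- titles
    }
  }
  expression_table(tb, scale = scale)
}

# strict TSV reader for the canonical matrix dialect: rejects ragged rows,
# names the offending line
read_tsv_strict <- function(path, first_col = "character") {
  lines <- readr::read_lines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) < 1) stop("empty file: ", path, call. = FALSE)
  widths <- lengths(regmatches(lines, gregexpr("\t", lines)))
  if (length(unique(widths)) > 1) {
    bad <- which(widths != widths[1])[1]
    stop("ragged row on line ", bad, " of ", path, call. = FALSE)
  }
  tb <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_guess()),
    na = ""
  ))
  prob <- readr::problems(tb)
  if (nrow(prob) > 0) {
    stop("parse error on line ", prob$row[1] + 1, " of ", path, call. = FALSE)
  }
  tb[[1]] <- as.character(tb[[1]])
  tb
}

require_columns <- function(tb, cols, path) {
  missing <- setdiff(cols, names(tb))
  if (length(missing) > 0) {
    stop("missing column(s) ", paste(missing, collapse = ", "), " in ", path,
         call. = FALSE)
  }
  invisible(tb)
}

format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else format(v, digits = 15, scientific = FALSE)
  }, character(1))
  out
}
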