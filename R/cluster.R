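#' Absolute-Pearson sample dissimilarity
#'
#' `d(i, j) = 1 - |r(i, j)|` with `r` the Pearson correlation between the
#' two samples' expression profiles. The absolute value makes strongly
#' anti-correlated profiles as close as correlated ones -- the "Pearson's
#' correlation absolute" metric of array clustering software. A signed
#' variant (`1 - r`, range `[0, 2]`) is available.
#'
#' @param x An [expression_table()] with at least two features.
#' @param absolute Use `1 - |r|` (default) rather than `1 - r`.
#' @return A symmetric sample-by-sample dissimilarity matrix with zero
#'   diagonal.
#' @export
abs_pearson_distance <- function(x, absolute = TRUE) {
  m <- expr_matrix(x)
  if (nrow(m) < 2) stop("need at least 2 features", call. = FALSE)
  v <- apply(m, 2, stats::var)
  if (any(v == 0)) {
    stop("zero-variance sample(s): ",
         paste(colnames(m)[v == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(m)
  d <- if (absolute) 1 - abs(r) else 1 - r
  d[d < 0] <- 0  # guard tiny negative rounding
  diag(d) <- 0
  d
}

#' Hierarchical clustering of samples (UPGMA)
#'
#' Average-linkage (UPGMA) agglomeration on a precomputed dissimilarity:
#' at each step the two clusters with the smallest unweighted mean of
#' inter-cluster pairwise dissimilarities are merged. Complete linkage is
#' available behind a flag. Samples are ordered lexicographically before
#' clustering so exact ties merge deterministically.
#'
#' @param d Dissimilarity matrix from [abs_pearson_distance()] (or any
#'   symmetric matrix with dimnames).
#' @param linkage `"average"` (default) or `"complete"`.
#' @return An object of class `sample_clustering` wrapping the
#'   [stats::hclust()] tree.
#' @export
cluster_samples <- function(d, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  ord <- order(rownames(d))
  hc <- stats::hclust(stats::as.dist(d[ord, ord]), method = linkage)
  structure(list(hclust = hc, linkage = linkage), class = "sample_clustering")
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat("Sample clustering (", x$linkage, " linkage, ",
      length(x$hclust$labels), " samples)\n", sep = "")
  invisible(x)
}

#' Export a clustering as a Newick tree
#'
#' Branch lengths follow the ultrametric convention: every leaf sits at
#' depth `merge height / 2` below its ancestor, so two leaves merged at
#' height 0.4 serialize as `(A:0.2,B:0.2);`. Parsing the string back
#' recovers topology and heights.
#'
#' @param tree A `sample_clustering`.
#' @param path Optional file path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL) {
  if (!inherits(tree, "sample_clustering") || length(tree$hclust$labels) < 2) {
    stop("need a sample_clustering with at least 2 leaves", call. = FALSE)
  }
  phy <- ape::as.phylo(tree$hclust)
  s <- ape::write.tree(phy)
  if (is.null(path)) return(s)
  readr::write_lines(s, path)
  invisible(s)
}

#' Read a Newick tree
#'
#' @param path File path or a Newick string.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  if (file.exists(path)) ape::read.tree(path) else ape::read.tree(text = path)
}

#' Compare two sample partitions
#'
#' Cuts two clusterings into `k` groups each and reports the (adjusted)
#' Rand agreement between the induced partitions -- used to quantify, not
#' assert, whether e.g. the miRNA-based and mRNA-based sample trees find
#' the same main classes.
#'
#' @param tree_a,tree_b `sample_clustering` objects over the same samples.
#' @param k Number of groups to cut each tree into.
#' @return One-row tibble with `k`, `rand`, `adjusted_rand`.
#' @export
clustering_concordance <- function(tree_a, tree_b, k = 2) {
  ca <- stats::cutree(tree_a$hclust, k = k)
  cb <- stats::cutree(tree_b$hclust, k = k)
  common <- intersect(names(ca), names(cb))
  stopifnot(length(common) >= 2)
  ca <- ca[common]
  cb <- cb[common]
  tab <- table(ca, cb)
  n <- length(common)
  sum_comb <- function(v) sum(choose(v, 2))
  a <- sum_comb(as.vector(tab))
  b1 <- sum_comb(rowSums(tab))
  b2 <- sum_comb(colSums(tab))
  total <- choose(n, 2)
  rand <- (total + 2 * a - b1 - b2) / total
  expected <- b1 * b2 / total
  ari <- (a - expected) / ((b1 + b2) / 2 - expected)
  tibble::tibble(k = k, rand = rand, adjusted_rand = ari)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Dendrogram plot of a sample clustering
#'
#' @param object A `sample_clustering`.
#' @param ... Unused.
#' @return A ggplot dendrogram with sample labels.
#' @export
autoplot.sample_clustering <- function(object, ...) {
  hc <- object$hclust
  n <- length(hc$labels)
  # x position of each leaf in plotting order, then of each merged node
  leaf_x <- match(seq_len(n), hc$order)
  node_x <- numeric(nrow(hc$merge))
  node_h <- hc$height
  pos <- function(id) if (id < 0) c(leaf_x[-id], 0) else c(node_x[id], node_h[id])
  segs <- purrr::map_dfr(seq_len(nrow(hc$merge)), function(i) {
    l <- pos(hc$merge[i, 1])
    r <- pos(hc$merge[i, 2])
    node_x[i] <<- mean(c(l[1], r[1]))
    h <- node_h[i]
    tibble::tibble(
      x = c(l[1], r[1], l[1]), xend = c(l[1], r[1], r[1]),
      y = c(l[2], r[2], h), yend = c(h, h, h)
    )
  })
  labs <- tibble::tibble(x = leaf_x, label = hc$labels)
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = labs,
                       ggplot2::aes(x = .data$x, y = 0, label = .data$label),
                       angle = 90, hjust = 1.1, size = 3) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.25, 0.05))) +
    ggplot2::labs(x = NULL, y = "dissimilarity (1 - |r|)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' @export
tidy.sample_clustering <- function(x, ...) {
  hc <- x$hclust
  tibble::tibble(
    step = seq_along(hc$height),
    left = hc$merge[, 1],
    right = hc$merge[, 2],
    height = hc$height
  )
}

#' @export
glance.sample_clustering <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$hclust$labels),
    linkage = x$linkage,
    max_height = max(x$hclust$height)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
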