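# Independent brute-force oracles. These deliberately avoid the code paths
# (and, where possible, the base functions) used by the implementation.

# definition-based BH step-up: adj_(i) = min_{j >= i} p_(j) * m / j, capped
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- vapply(seq_len(m), function(i) {
    min(1, min(sorted[i:m] * m / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# textbook two-pass Pearson correlation
oracle_pearson <- function(x, y) {
  dx <- x - sum(x) / length(x)
  dy <- y - sum(y) / length(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# hand Welch t-test
oracle_welch <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

# naive O(n^3) UPGMA; returns the cophenetic distance matrix (merge heights
# between every leaf pair), which pins both topology and heights
oracle_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  labs <- rownames(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = list(labs, labs))
  active <- rep(TRUE, n)
  while (sum(active) > 1) {
    idx <- which(active)
    best <- c(NA, NA)
    bestv <- Inf
    for (i in idx) {
      for (j in idx) {
        if (i < j) {
          v <- mean(d[clusters[[i]], clusters[[j]]])
          if (v < bestv) {
            bestv <- v
            best <- c(i, j)
          }
        }
      }
    }
    coph[clusters[[best[1]]], clusters[[best[2]]]] <- bestv
    coph[clusters[[best[2]]], clusters[[best[1]]]] <- bestv
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    active[best[2]] <- FALSE
  }
  coph
}

# hypergeometric upper tail by direct term summation with choose()
oracle_hyper_upper <- function(k, ka, kb, n) {
  if (k <= 0) return(1)
  i <- k:min(ka, kb)
  sum(choose(ka, i) * choose(n - ka, kb - i)) / choose(n, kb)
}

# exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled ranks to group a
oracle_mw_p <- function(a, b) {
  ab <- c(a, b)
  n <- length(a)
  rk <- rank(ab)
  u_obs <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(length(ab), n)
  us <- apply(combos, 2, function(ix) sum(rk[ix])) - n * (n + 1) / 2
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# small expression fixture: features x samples matrix wrapped as a table
toy_expr <- function(values, features, samples, scale = "log2") {
  m <- matrix(values, nrow = length(features), byrow = TRUE,
              dimnames = list(features, samples))
  expression_table(m, scale = scale)
}

# minimal pair tibble for filter-stage tests
toy_pairs <- function(r, pct = NA_real_, star = FALSE,
                      mirna = sprintf("miR-%02d", seq_along(r)),
                      gene = sprintf("G%02d", seq_along(r))) {
  tibble::tibble(
    mirna_id = mirna, gene_symbol = gene,
    transcript_id = paste0("NM_", seq_along(r)),
    pct = rep_len(pct, length(r)), star_strand = rep_len(star, length(r)),
    r = r, predicted = TRUE, cohort_confirmed = TRUE
  )
}
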