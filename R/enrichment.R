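#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' observing at least `k` members of a size-`K` set in a size-`n` draw from
#' a universe of `N`. Evaluated through the stable log-space tail of
#' [stats::phyper].
#'
#' @param k observed overlap.
#' @param K size of the annotated set.
#' @param n size of the drawn set.
#' @param N universe size.
#' @return p-value in (0, 1].
#' @export
hypergeomUpper <- function(k, K, n, N) {
  if (any(K > N) || any(n > N)) stopf("K and n must not exceed N")
  if (any(k > pmin(K, n))) stopf("k must not exceed min(K, n)")
  if (any(k < 0)) stopf("k must be >= 0")
  exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

# Lower tail P(X <= k), for under-representation.
hypergeomLower <- function(k, K, n, N) {
  exp(phyper(k, K, N - K, n, lower.tail = TRUE, log.p = TRUE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} m * p_(j) / j`, clipped
#' at 1.
#'
#' @param pvals numeric p-values in \[0, 1\].
#' @return adjusted q-values, same order as input.
#' @export
bhAdjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Co-association matrix between two gene-set collections
#'
#' For every pair (A, B) tests the overlap `k = |A n B|` against the
#' hypergeometric null over the shared universe. Over-represented pairs
#' (k at or above expectation `K*n/N`) are scored with the upper tail,
#' under-represented pairs with the lower tail; BH correction is applied
#' across all cells of the matrix.
#'
#' @param sets_a,sets_b [GeneSets-class] collections.
#' @param universe character vector of gene ids (shared universe).
#' @return data.frame with one row per (A, B) pair: `set_a`, `set_b`,
#'   `N`, `K`, `n`, `k`, `p`, `q`, `direction`.
#' @export
coassociationMatrix <- function(sets_a, sets_b, universe) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0L) stopf("universe is empty")
  pairs <- expand.grid(set_a = names(sets_a), set_b = names(sets_b),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    A <- intersect(sets_a[[pairs$set_a[i]]], universe)
    B <- intersect(sets_b[[pairs$set_b[i]]], universe)
    k <- length(intersect(A, B)); K <- length(A); n <- length(B)
    expect <- K * n / N
    over <- k >= expect
    p <- if (over) hypergeomUpper(k, K, n, N) else hypergeomLower(k, K, n, N)
    data.frame(set_a = pairs$set_a[i], set_b = pairs$set_b[i], N = N, K = K,
               n = n, k = k, p = p,
               direction = if (over) "over" else "under")
  })
  out <- do.call(rbind, rows)
  out$q <- bhAdjust(out$p)
  out[c("set_a", "set_b", "N", "K", "n", "k", "p", "q", "direction")]
}

#' Term enrichment of a query gene set
#'
#' Upper-tail hypergeometric enrichment of `query` in every term of
#' `annotations`, BH-corrected across terms.
#'
#' @param query character vector of gene ids.
#' @param annotations a [GeneSets-class] of term -> genes.
#' @param universe character vector of gene ids.
#' @return data.frame sorted by `q`: `term`, `N`, `K`, `n`, `k`, `p`, `q`.
#' @export
termEnrichment <- function(query, annotations, universe) {
  universe <- unique(universe)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warnf("dropping %d query gene(s) outside the universe", length(outside))
    query <- intersect(query, universe)
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(names(annotations), function(tm) {
    term_genes <- intersect(annotations[[tm]], universe)
    K <- length(term_genes)
    k <- length(intersect(term_genes, query))
    data.frame(term = tm, N = N, K = K, n = n, k = k,
               p = hypergeomUpper(k, K, n, N))
  })
  out <- do.call(rbind, rows)
  out$q <- bhAdjust(out$p)
  out[order(out$q, out$p, out$term), ]
}

#' Average-linkage clustering of an enrichment matrix
#'
#' UPGMA (average linkage) hierarchical clustering of rows and columns on
#' Euclidean distances, as used to organise enrichment heatmaps. Intended
#' input is a matrix of `-log10(q)` values (floor q at 1e-300 before
#' taking logs).
#'
#' @param mat numeric matrix.
#' @return list with `row_order`, `col_order` (leaf orderings) and
#'   `row_hclust`, `col_hclust` (or NULL when a dimension has < 2 entries).
#' @export
clusterMatrix <- function(mat) {
  if (!all(is.finite(mat))) stopf("matrix must be finite; floor q at 1e-300")
  one_way <- function(m) {
    if (nrow(m) < 2L) return(list(order = seq_len(nrow(m)), hclust = NULL))
    hc <- hclust(dist(m), method = "average")
    list(order = hc$order, hclust = hc)
  }
  r <- one_way(mat)
  cl <- one_way(t(mat))
  list(row_order = r$order, col_order = cl$order,
       row_hclust = r$hclust, col_hclust = cl$hclust)
}

#' Membership-pattern overlap counts
#'
#' Counts, for every membership pattern over up to 6 sets, the number of
#' genes showing exactly that pattern (the numbers behind an Euler
#' diagram). All `2^s - 1` non-null patterns are reported, including empty
#' ones; counts sum to the size of the union.
#'
#' @param gs a [GeneSets-class] with at most 6 sets.
#' @return named integer vector; names are 0/1 pattern strings ordered as
#'   `names(gs)`.
#' @export
overlapCounts <- function(gs) {
  s <- length(gs)
  if (s > 6L) stopf("at most 6 sets supported")
  genes <- unique(unlist(gs@sets, use.names = FALSE))
  memb <- vapply(names(gs), function(nm) genes %in% gs[[nm]], logical(length(genes)))
  if (length(genes) == 1L) memb <- matrix(memb, nrow = 1L)
  pat <- apply(memb, 1L, function(b) paste(as.integer(b), collapse = ""))
  all_pat <- apply(expand.grid(rep(list(0:1), s))[-1, , drop = FALSE], 1L,
                   paste, collapse = "")
  counts <- table(factor(pat, levels = all_pat))
  out <- as.integer(counts)
  names(out) <- all_pat
  out
}
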