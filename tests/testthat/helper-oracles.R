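# Independent brute-force oracles used across test files. These deliberately
# avoid the package's own code paths.

# Upper-tail hypergeometric by exhaustive enumeration of all C(N, n) draws.
bf_hypergeom_upper <- function(k, K, n, N) {
  if (n == 0L) return(as.numeric(k <= 0))
  draws <- combn(N, n)
  in_K <- draws <= K                      # label genes 1..K as the K-set
  mean(colSums(in_K) >= k)
}

# AUC as the fraction of concordant (pos, neg) score pairs, ties counting 1/2.
bf_auc <- function(scores, labels) {
  pos <- scores[labels == "pos" | labels == TRUE]
  neg <- scores[!(labels == "pos" | labels == TRUE)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# IUPAC consensus window count by explicit window-by-window enumeration.
bf_motif_count <- function(seq, consensus) {
  codes <- list(A = "A", C = "C", G = "G", U = "U",
                R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"),
                W = c("A", "U"), K = c("G", "U"), M = c("A", "C"),
                B = c("C", "G", "U"), D = c("A", "G", "U"),
                H = c("A", "C", "U"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "U"))
  s <- strsplit(seq, "")[[1]]
  m <- strsplit(consensus, "")[[1]]
  L <- length(m); n <- length(s)
  if (n < L) return(0L)
  hits <- 0L
  for (i in seq_len(n - L + 1L)) {
    ok <- TRUE
    for (j in seq_len(L)) {
      if (!s[i + j - 1L] %in% codes[[m[j]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- hits + 1L
  }
  hits
}

# BH step-up by the textbook formula.
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Random in-frame ORF (AUG ... stop) of k internal codons.
random_orf <- function(k) {
  sense <- setdiff(gsub("T", "U", names(Biostrings::GENETIC_CODE)),
                   c("UAA", "UAG", "UGA"))
  paste0("AUG", paste(sample(sense, k, replace = TRUE), collapse = ""), "UAA")
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                                collapse = "")

# Small PolysomeSet from a gene x cell mean matrix plus iid noise.
make_ps <- function(n_genes, reps = 3, sigma = 0.25, delta = 0,
                    regulon = integer(0), with_total = TRUE) {
  fractions <- if (with_total) c("total", "monosome", "polysome")
               else c("monosome", "polysome")
  design <- expand.grid(replicate = seq_len(reps), fraction = fractions,
                        condition = c("control", "stress"),
                        stringsAsFactors = FALSE)
  base <- rnorm(n_genes, 8, 1)
  mat <- sapply(seq_len(nrow(design)), function(j) {
    mu <- base +
      delta * (design$condition[j] == "stress") *
        (design$fraction[j] == "polysome") *
        (seq_len(n_genes) %in% regulon)
    mu + rnorm(n_genes, 0, sigma)
  })
  rownames(mat) <- sprintf("g%04d", seq_len(n_genes))
  PolysomeSet(mat, design$condition, design$fraction, design$replicate)
}
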