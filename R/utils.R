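#' @importFrom stats median p.adjust pf phyper cor wilcox.test rnorm runif
#'   rlnorm hclust dist as.dendrogram order.dendrogram setNames quantile
#' @importFrom utils read.delim write.table
NULL

# Evaluate `expr` under a locally-seeded RNG, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Deterministic child seeds derived from one master seed (kept below 2^31).
derive_seed <- function(seed, k) {
  ((as.integer(seed) %% 1000003L) * 1009L + 97L * as.integer(k)) %% 2000000011L
}

geom_mean <- function(x) exp(mean(log(x)))

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
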