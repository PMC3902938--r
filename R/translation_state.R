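#' Per-gene translation states and their stress-induced change
#'
#' The translation state (ts) of a gene under one condition is the mean
#' log2 polysome intensity minus the mean log2 monosome intensity; the
#' change in translation state is `delta = ts_stress - ts_control`, i.e.
#' the log2 of the ratio of the two polysome:monosome ratios (of geometric
#' means over replicates). `|delta| > 1` marks a 2-fold change in absolute
#' ratios.
#'
#' @param ps a [PolysomeSet-class].
#' @return data.frame with columns `gene`, `ts_control`, `ts_stress`,
#'   `delta`. Genes lacking a complete monosome+polysome design are
#'   excluded, with their ids in attribute `excluded`.
#' @export
computeTranslationStates <- function(ps) {
  a <- assay(ps, "log2intensity")
  cd <- colData(ps)
  mean_cell <- function(cond, frac) {
    sel <- cd$condition == cond & cd$fraction == frac
    rowMeans(a[, sel, drop = FALSE])
  }
  ts_c <- mean_cell("control", "polysome") - mean_cell("control", "monosome")
  ts_s <- mean_cell("stress", "polysome") - mean_cell("stress", "monosome")
  ok <- is.finite(ts_c) & is.finite(ts_s)
  out <- data.frame(gene = rownames(a)[ok], ts_control = ts_c[ok],
                    ts_stress = ts_s[ok], delta = (ts_s - ts_c)[ok],
                    row.names = NULL)
  attr(out, "excluded") <- rownames(a)[!ok]
  out
}

#' Condition x fraction interaction test
#'
#' Fits, per gene, the two-factor linear model
#' `log2 intensity ~ condition * fraction` over the monosome and polysome
#' arrays and tests the interaction coefficient — the term measuring a
#' stress-dependent shift between fractions, i.e. a change in translation
#' state. With `moderation = TRUE` the per-gene residual variance is shrunk
#' toward the across-gene mean with `prior_df` pseudo-replicates
#' (empirical-Bayes style), stabilising small-replicate designs; the
#' moderated statistic is F on (1, df + prior_df) degrees of freedom.
#'
#' @param ps a [PolysomeSet-class] with >= 2 replicates per
#'   (condition, fraction) cell.
#' @param moderation shrink residual variances (default TRUE).
#' @param prior_df prior degrees of freedom for the shrinkage (default 4).
#' @return data.frame with columns `gene`, `effect` (interaction
#'   coefficient, equal to delta), `F`, `p_interaction`.
#' @export
interactionTest <- function(ps, moderation = TRUE, prior_df = 4) {
  a <- assay(ps, "log2intensity")
  cd <- colData(ps)
  sel <- cd$fraction %in% c("monosome", "polysome")
  Y <- a[, sel, drop = FALSE]
  cond <- factor(cd$condition[sel], levels = c("control", "stress"))
  frac <- factor(cd$fraction[sel], levels = c("monosome", "polysome"))
  cells <- table(cond, frac)
  if (any(cells < 2L))
    stopf("interaction test needs >= 2 replicates per (condition, fraction) cell")
  X <- stats::model.matrix(~ cond * frac)
  n <- nrow(X); pX <- ncol(X)
  df <- n - pX
  if (df < 1L) stopf("zero residual degrees of freedom; need >= 2 replicates")
  keep <- rowSums(is.na(Y)) == 0L
  Y <- Y[keep, , drop = FALSE]
  XtXi <- solve(crossprod(X))
  B <- Y %*% X %*% XtXi                    # genes x coefficients
  fit <- B %*% t(X)
  rss <- rowSums((Y - fit)^2)
  s2 <- rss / df
  j <- which(colnames(X) == "condstress:fracpolysome")
  v <- XtXi[j, j]
  eff <- B[, j]
  if (moderation) {
    s2_0 <- mean(s2)
    s2_post <- (prior_df * s2_0 + df * s2) / (prior_df + df)
    Fstat <- eff^2 / (v * s2_post)
    p <- pf(Fstat, 1, df + prior_df, lower.tail = FALSE)
  } else {
    Fstat <- eff^2 / (v * s2)
    p <- pf(Fstat, 1, df, lower.tail = FALSE)
  }
  data.frame(gene = rownames(Y), effect = eff, F = Fstat, p_interaction = p,
             row.names = NULL)
}

#' Classify transcripts by translational response
#'
#' A transcript is translationally up-regulated when its change in
#' translation state exceeds `tau` (default 1.0, a 2-fold change in absolute
#' ratios) with BH-adjusted interaction p-value at most `alpha` (default
#' 0.01); down-regulated symmetrically; everything else is unchanged.
#' Both inequalities on delta are strict.
#'
#' @param states output of [computeTranslationStates()].
#' @param pvals output of [interactionTest()] (matched by gene).
#' @param tau change-in-translation-state threshold (> 0).
#' @param alpha adjusted-p threshold in (0, 1).
#' @return data.frame of translation calls: `gene`, `ts_control`,
#'   `ts_stress`, `delta`, `p_interaction`, `q_interaction`, `label`.
#' @export
classifyTranscripts <- function(states, pvals, tau = 1.0, alpha = 0.01) {
  if (tau <= 0) stopf("tau must be > 0")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  m <- merge(states, pvals[c("gene", "p_interaction")], by = "gene",
             sort = FALSE)
  m$q_interaction <- bhAdjust(m$p_interaction)
  m$label <- "unchanged"
  m$label[m$delta >  tau & m$q_interaction <= alpha] <- "up"
  m$label[m$delta < -tau & m$q_interaction <= alpha] <- "down"
  m[order(m$gene), c("gene", "ts_control", "ts_stress", "delta",
                     "p_interaction", "q_interaction", "label")]
}

#' One-stop translation calls from a PolysomeSet
#'
#' @inheritParams interactionTest
#' @inheritParams classifyTranscripts
#' @return translation-call data.frame (see [classifyTranscripts()]).
#' @export
translationCalls <- function(ps, tau = 1.0, alpha = 0.01, moderation = TRUE,
                             prior_df = 4) {
  states <- computeTranslationStates(ps)
  pvals <- interactionTest(ps, moderation = moderation, prior_df = prior_df)
  classifyTranscripts(states, pvals, tau = tau, alpha = alpha)
}

#' Potentiation: transcriptional vs translational change
#'
#' Correlates the transcriptional change (mean log2 total-fraction intensity,
#' stress minus control) with the change in translation state, and compares
#' stress transcript levels of the up and down classes against the unchanged
#' class by Wilcoxon rank-sum tests.
#'
#' @param ps a [PolysomeSet-class].
#' @param calls translation-call data.frame.
#' @return list with `r` (Pearson correlation), `txn_change` (named vector),
#'   and `rank_sum` (data.frame comparing up/down vs unchanged stress
#'   transcript levels).
#' @export
potentiationCorrelation <- function(ps, calls) {
  a <- assay(ps, "log2intensity")
  cd <- colData(ps)
  tot <- function(cond) {
    sel <- cd$condition == cond & cd$fraction == "total"
    rowMeans(a[, sel, drop = FALSE])
  }
  t_c <- tot("control"); t_s <- tot("stress")
  txn <- (t_s - t_c)[calls$gene]
  ok <- is.finite(txn)
  if (sum(ok) < 3L) stopf("need >= 3 genes with total-fraction data")
  r <- cor(txn[ok], calls$delta[ok])
  level_s <- t_s[calls$gene]
  unchanged <- level_s[calls$label == "unchanged" & is.finite(level_s)]
  cmp <- lapply(c(up = "up", down = "down"), function(cls) {
    x <- level_s[calls$label == cls & is.finite(level_s)]
    if (length(x) < 2L || length(unchanged) < 2L)
      return(data.frame(class = cls, n = length(x), W = NA_real_,
                        p = NA_real_))
    wt <- wilcox.test(x, unchanged, exact = FALSE)
    data.frame(class = cls, n = length(x), W = unname(wt$statistic),
               p = wt$p.value)
  })
  list(r = r, txn_change = txn, rank_sum = do.call(rbind, c(cmp, make.row.names = FALSE)))
}
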