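test_that("translation states follow the log-ratio-of-ratios definition", {
  # all intensities equal -> everything zero
  mat <- matrix(5, 2, 12, dimnames = list(c("g1", "g2"), NULL))
  design <- expand.grid(replicate = 1:3,
                        fraction = c("monosome", "polysome"),
                        condition = c("control", "stress"),
                        stringsAsFactors = FALSE)
  ps <- PolysomeSet(mat, design$condition, design$fraction, design$replicate)
  st <- computeTranslationStates(ps)
  expect_equal(st$ts_control, c(0, 0))
  expect_equal(st$delta, c(0, 0))

  # stress polysome shifted down by 1 log2 unit -> delta = -1
  mat2 <- mat
  mat2[, design$condition == "stress" & design$fraction == "polysome"] <- 4
  ps2 <- PolysomeSet(mat2, design$condition, design$fraction, design$replicate)
  expect_equal(computeTranslationStates(ps2)$delta, c(-1, -1))

  # random replicates: delta equals the log2 ratio of ratios of per-condition
  # geometric means, recomputed by brute force
  withr::local_seed(11)
  mat3 <- matrix(rnorm(24, 8, 1), 2, 12, dimnames = list(c("g1", "g2"), NULL))
  ps3 <- PolysomeSet(mat3, design$condition, design$fraction, design$replicate)
  st3 <- computeTranslationStates(ps3)
  for (g in 1:2) {
    gm <- function(cond, frac)
      2^mean(mat3[g, design$condition == cond & design$fraction == frac])
    expected <- log2((gm("stress", "polysome") / gm("stress", "monosome")) /
                       (gm("control", "polysome") / gm("control", "monosome")))
    expect_equal(st3$delta[g], expected, tolerance = 1e-12)
  }
})

test_that("delta is invariant under per-condition array rescaling", {
  withr::local_seed(3)
  ps <- make_ps(20, with_total = FALSE)
  a <- SummarizedExperiment::assay(ps)
  cd <- SummarizedExperiment::colData(ps)
  a2 <- a
  a2[, cd$condition == "stress"] <- a2[, cd$condition == "stress"] + 1.7
  ps2 <- PolysomeSet(a2, cd$condition, cd$fraction, cd$replicate)
  expect_equal(computeTranslationStates(ps)$delta,
               computeTranslationStates(ps2)$delta, tolerance = 1e-12)
})

test_that("unmoderated interaction test matches the textbook two-way ANOVA", {
  withr::local_seed(5)
  ps <- make_ps(25, reps = 3, with_total = FALSE)
  res <- interactionTest(ps, moderation = FALSE)
  a <- SummarizedExperiment::assay(ps)
  cd <- SummarizedExperiment::colData(ps)
  for (g in sample(rownames(a), 5)) {
    d <- data.frame(y = a[g, ], cond = cd$condition, frac = cd$fraction)
    p_lm <- anova(lm(y ~ cond * frac, data = d))["cond:frac", "Pr(>F)"]
    expect_equal(res$p_interaction[res$gene == g], p_lm, tolerance = 1e-10)
  }
})

test_that("interaction test errors without replication", {
  mat <- matrix(rnorm(8), 2, 4, dimnames = list(c("g1", "g2"), NULL))
  ps <- PolysomeSet(mat, rep(c("control", "stress"), each = 2),
                    rep(c("monosome", "polysome"), 2), rep(1L, 4))
  expect_error(interactionTest(ps), ">= 2 replicates")
})

test_that("null interaction p-values are uniform and calibrated", {
  withr::local_seed(202)
  ps <- make_ps(10000, reps = 3, sigma = 0.3, with_total = FALSE)
  p <- interactionTest(ps, moderation = FALSE)$p_interaction
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
  expect_gt(mean(p < 0.05), 0.04)
  expect_lt(mean(p < 0.05), 0.06)
})

test_that("a planted interaction of 2 log2 units is detected with high power", {
  withr::local_seed(303)
  ps <- make_ps(2000, reps = 3, sigma = 0.25, delta = 2, regulon = 1:2000,
                with_total = FALSE)
  p <- interactionTest(ps, moderation = FALSE)$p_interaction
  expect_gte(mean(p < 0.01), 0.99)
})

test_that("moderation shrinks variances but preserves strong signals", {
  withr::local_seed(17)
  ps <- make_ps(500, reps = 3, sigma = 0.25, delta = 2, regulon = 1:100,
                with_total = FALSE)
  p_mod <- interactionTest(ps, moderation = TRUE)
  expect_true(all(p_mod$p_interaction[1:100] < 0.01))
  expect_equal(nrow(p_mod), 500)
})

test_that("classification respects strict thresholds and partitions genes", {
  states <- data.frame(gene = c("a", "b", "c", "d"),
                       ts_control = 0, ts_stress = 0,
                       delta = c(0, -1.5, 1.0, 2.0))
  pvals <- data.frame(gene = c("a", "b", "c", "d"),
                      p_interaction = c(1, 1e-4, 1e-4, 1e-4))
  calls <- classifyTranscripts(states, pvals, tau = 1.0, alpha = 0.01)
  expect_equal(calls$label[calls$gene == "a"], "unchanged")
  expect_equal(calls$label[calls$gene == "b"], "down")
  expect_equal(calls$label[calls$gene == "c"], "unchanged") # delta not > tau
  expect_equal(calls$label[calls$gene == "d"], "up")
  expect_equal(sum(table(calls$label)), nrow(calls))
  expect_error(classifyTranscripts(states, pvals, tau = 0), "tau")
  expect_error(classifyTranscripts(states, pvals, alpha = 1.5), "alpha")
})

test_that("potentiation correlation is exact in the self-correlated case", {
  withr::local_seed(23)
  ps <- make_ps(200, with_total = TRUE)
  calls <- translationCalls(ps, tau = 0.5, alpha = 0.5)
  # replace txn change with delta itself: r must be 1 by construction
  a <- SummarizedExperiment::assay(ps)
  cd <- SummarizedExperiment::colData(ps)
  a2 <- a
  a2[, cd$condition == "stress" & cd$fraction == "total"] <-
    a[calls$gene, cd$condition == "control" & cd$fraction == "total"] +
    calls$delta
  ps2 <- PolysomeSet(a2, cd$condition, cd$fraction, cd$replicate)
  pc <- potentiationCorrelation(ps2, calls)
  expect_equal(pc$r, 1, tolerance = 1e-9)
})

test_that("independent transcriptional and translational changes decorrelate", {
  withr::local_seed(29)
  ps <- make_ps(5000, with_total = TRUE)
  calls <- translationCalls(ps, tau = 0.5, alpha = 0.99)
  pc <- potentiationCorrelation(ps, calls)
  expect_lt(abs(pc$r), 0.05)
})

test_that("rank-sum comparisons on identical level distributions are rarely significant", {
  withr::local_seed(31)
  hits <- 0L
  for (i in 1:100) {
    ps <- make_ps(200, reps = 2, with_total = TRUE)
    calls <- data.frame(gene = rownames(SummarizedExperiment::assay(ps)),
                        ts_control = 0, ts_stress = 0, delta = rnorm(200),
                        label = sample(rep(c("up", "unchanged"), each = 100)))
    pc <- potentiationCorrelation(ps, calls)
    if (pc$rank_sum$p[pc$rank_sum$class == "up"] > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 94L)
})
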