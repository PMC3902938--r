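test_that("hypergeometric upper tail matches exact combinatorics", {
  expect_equal(hypergeomUpper(0, 5, 4, 10), 1.0)
  expect_equal(hypergeomUpper(4, 5, 4, 10), 5 / 210, tolerance = 1e-12)
  withr::local_seed(83)
  for (i in 1:30) {
    N <- sample(4:12, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeomUpper(k, K, n, N), bf_hypergeom_upper(k, K, n, N),
                 tolerance = 1e-12)
  }
  expect_error(hypergeomUpper(6, 5, 4, 10), "min")
  expect_error(hypergeomUpper(2, 11, 4, 10), "exceed N")
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(bhAdjust(0.04), 0.04)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  withr::local_seed(89)
  for (i in 1:50) {
    p <- runif(sample(2:40, 1))
    q <- bhAdjust(p)
    expect_equal(q, bf_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-15))   # monotone in p rank
    # BH rejections contain Bonferroni rejections
    expect_true(all(q[p <= 0.05 / length(p)] <= 0.05))
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("co-association flags planted overlap and under-representation", {
  universe <- paste0("g", 1:100)
  a <- GeneSets(list(A = universe[1:10]), universe)
  expect_equal(
    coassociationMatrix(a, GeneSets(list(B = universe[1:10]), universe),
                        universe)$direction, "over")
  self <- coassociationMatrix(a, a, universe)
  expect_equal(self$k, 10L)
  expect_lt(self$p, 1e-3)
  # fully disjoint large sets sit below expectation
  b <- GeneSets(list(B = universe[41:100]), universe)
  res <- coassociationMatrix(a, b, universe)
  expect_equal(res$direction, "under")
  expect_equal(res$k, 0L)
  expect_error(coassociationMatrix(a, b, character(0)), "empty")
})

test_that("a Puf3-like target set co-associates with the planted down class", {
  p <- simulationParams(n_genes = 400, regulon_size = 60, seed = 17)
  tx <- simulateTranscriptome(p)
  ex <- simulateExpression(tx$truth, p)
  calls <- translationCalls(ex)
  sets <- simulateGeneSets(tx$truth, p)
  classes <- GeneSets(split(calls$gene, calls$label), universe = calls$gene)
  co <- coassociationMatrix(sets$rbp, classes, calls$gene)
  hit <- co[co$set_a == "Puf3_targets" & co$set_b == "down", ]
  expect_equal(hit$direction, "over")
  expect_lt(hit$q, 0.01)
})

test_that("term enrichment recovers an exact query and reports raw overlaps", {
  universe <- paste0("g", 1:60)
  ann <- GeneSets(list(t1 = universe[1:10], t2 = universe[11:30],
                       t3 = universe[21:50]), universe)
  res <- termEnrichment(universe[1:10], ann, universe)
  expect_equal(res$term[1], "t1")
  expect_equal(res$k[res$term == "t2"],
               length(intersect(universe[1:10], universe[11:30])))
  expect_warning(res2 <- termEnrichment(c("g1", "zz"), ann, universe),
                 "outside the universe")
  expect_equal(res2$n[1], 1L)
  # random queries of matched size are rarely enriched
  withr::local_seed(97)
  wins <- 0L
  for (i in 1:50) {
    q <- sample(universe, 10)
    if (min(termEnrichment(q, ann, universe)$q) > 0.05) wins <- wins + 1L
  }
  expect_gte(wins, 45L)
})

test_that("average-linkage clustering follows hand-traced merges", {
  m <- matrix(c(0, 1, 10), 3, 1)
  rownames(m) <- c("p0", "p1", "p10")
  cl <- clusterMatrix(m)
  hc <- cl$row_hclust
  # {0,1} merge first at height 1; 10 joins at mean distance 9.5
  expect_equal(hc$height, c(1, 9.5))
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))
  # identical rows merge at distance zero
  m2 <- rbind(a = c(1, 2), b = c(1, 2), c = c(5, 9))
  expect_equal(clusterMatrix(m2)$row_hclust$height[1], 0)
  # permutation changes labels, not merge heights
  perm <- c(3, 1, 2)
  expect_equal(clusterMatrix(m[perm, , drop = FALSE])$row_hclust$height,
               hc$height)
  expect_equal(clusterMatrix(m[1, , drop = FALSE])$row_order, 1L)
  expect_error(clusterMatrix(matrix(c(1, Inf), 1, 2)), "finite")
})

test_that("overlap counts enumerate every membership pattern", {
  gs <- GeneSets(list(A = paste0("g", 1:3), B = paste0("h", 1:4)))
  oc <- overlapCounts(gs)
  expect_equal(oc[["10"]], 3L)
  expect_equal(oc[["01"]], 4L)
  expect_equal(oc[["11"]], 0L)
  gs2 <- GeneSets(list(A = paste0("g", 1:3), B = paste0("g", 1:3)))
  oc2 <- overlapCounts(gs2)
  expect_equal(oc2[["11"]], 3L)
  expect_equal(oc2[["10"]] + oc2[["01"]], 0L)
  # brute-force per-gene tabulation on random sets
  withr::local_seed(101)
  sets <- lapply(1:4, function(i) sample(paste0("g", 1:40), sample(5:20, 1)))
  names(sets) <- LETTERS[1:4]
  oc3 <- overlapCounts(GeneSets(sets))
  genes <- unique(unlist(sets))
  expect_equal(sum(oc3), length(genes))
  for (pat in names(oc3)) {
    bits <- as.integer(strsplit(pat, "")[[1]])
    want <- sum(vapply(genes, function(g)
      all((g %in% sets[[1]]) == bits[1], (g %in% sets[[2]]) == bits[2],
          (g %in% sets[[3]]) == bits[3], (g %in% sets[[4]]) == bits[4]),
      logical(1)))
    expect_equal(unname(oc3[pat]), want)
  }
  expect_error(overlapCounts(GeneSets(setNames(rep(list("g1"), 7),
                                               letters[1:7]))), "6 sets")
})
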