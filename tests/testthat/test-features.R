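make_tiny_ts <- function() {
  seqs <- Biostrings::RNAStringSet(c(
    g1 = paste0("ACGUACGUACGUACGUACGUACGUACGUAC",      # 30 nt 5'UTR
                "AUGGCUGCCAAAGGGUUUCCCACUAGCUAA",      # 30 nt ORF
                "UUUCCCGGGAAA"),                       # 12 nt 3'UTR
    g2 = paste0("AAAAAAAAAAAA", "AUGUCUUAA", "CCCCCCCCCCCC")))
  regions <- data.frame(transcript_id = c("g1", "g2"),
                        utr5_len = c(30L, 12L), orf_len = c(30L, 9L),
                        utr3_len = c(12L, 12L))
  assembleTranscripts(seqs, regions)
}

test_that("assembly splits regions conservatively and enforces ORF rules", {
  ts <- make_tiny_ts()
  expect_equal(length(ts), 2L)
  joined <- paste0(as.character(transcriptRegion(ts, "utr5")),
                   as.character(transcriptRegion(ts, "orf")),
                   as.character(transcriptRegion(ts, "utr3")))
  expect_equal(unname(nchar(joined)), c(72L, 33L))
  expect_equal(as.character(transcriptRegion(ts, "orf")[["g2"]]), "AUGUCUUAA")
  # not starting with AUG -> dropped with warning, or error on demand
  bad <- Biostrings::RNAStringSet(c(gX = paste0("ACGUACGUACGU",
                                                "CUGGCUUAA", "ACGUACGUACGU")))
  reg <- data.frame(transcript_id = "gX", utr5_len = 12L, orf_len = 9L,
                    utr3_len = 12L)
  expect_warning(tsX <- assembleTranscripts(bad, reg), "AUG")
  expect_equal(length(tsX), 0L)
  expect_equal(attr(tsX, "dropped"), "gX")
  expect_error(assembleTranscripts(bad, reg, on_invalid = "error"), "AUG")
  # internal stop codon is rejected
  bad2 <- Biostrings::RNAStringSet(c(gY = paste0("ACGUACGUACGU",
                                                 "AUGUAAGCUUAA",
                                                 "ACGUACGUACGU")))
  reg2 <- data.frame(transcript_id = "gY", utr5_len = 12L, orf_len = 12L,
                     utr3_len = 12L)
  expect_warning(tsY <- assembleTranscripts(bad2, reg2), "internal stop")
  expect_equal(length(tsY), 0L)
})

test_that("base composition matches hand counts and normalises to one", {
  ts <- make_tiny_ts()
  comp <- compositionFeatures(ts)
  # ORF of g2 is AUGUCUUAA: A=3, U=4, G=1, C=1 over 9
  expect_equal(comp["g2", "pct_A_orf"], 3 / 9)
  expect_equal(comp["g2", "pct_U_orf"], 4 / 9)
  expect_equal(comp["g2", "pct_G_orf"], 1 / 9)
  expect_equal(comp["g2", "pct_C_orf"], 1 / 9)
  expect_equal(comp["g2", "length_orf"], 9)
  expect_equal(comp["g2", "pct_A_utr5"], 1)        # all-A 5'UTR
  withr::local_seed(13)
  for (rg in c("utr5", "orf", "utr3")) {
    sums <- rowSums(comp[, paste0("pct_", c("A", "C", "G", "U"), "_", rg)])
    expect_equal(unname(sums), rep(1, 2), tolerance = 1e-12)
  }
})

test_that("CAI follows the geometric-mean definition", {
  # two-codon ORF with weights 0.25 and 1.0 -> geometric mean 0.5
  w <- buildCaiWeights(Biostrings::RNAStringSet(c(r = random_orf(5))))
  w[] <- 1; w["GCU"] <- 0.25; w["GCC"] <- 1.0
  tab <- codonWeightTable(w)
  expect_equal(unname(cai(c(x = "GCUGCC"), tab)), 0.5)
  # all-maximal ORF -> exactly 1
  expect_equal(unname(cai(c(x = "GCCGCCGCC"), tab)), 1.0)
  # invariant under codon order permutation
  withr::local_seed(19)
  orf <- random_orf(30)
  cods <- substring(orf, seq(1, nchar(orf) - 2, 3), seq(3, nchar(orf), 3))
  perm <- c(cods[1], sample(cods[-c(1, length(cods))]), cods[length(cods)])
  wr <- buildCaiWeights(Biostrings::RNAStringSet(c(r = random_orf(200))))
  tabr <- codonWeightTable(wr)
  expect_equal(cai(c(a = orf), tabr),
               cai(c(a = paste(perm, collapse = "")), tabr),
               tolerance = 1e-12)
})

test_that("fop counts optimal codons among degenerate families", {
  w <- buildCaiWeights(Biostrings::RNAStringSet(c(r = random_orf(5))))
  w[] <- 0.5; w["GCU"] <- 1; w["AAA"] <- 1
  tab <- codonWeightTable(w)
  expect_equal(unname(fop(c(x = "GCUGCUGCU"), tab)), 1.0)
  expect_equal(unname(fop(c(x = "GCUGCC"), tab)), 0.5)
  # brute-force count on random ORFs
  withr::local_seed(37)
  wr <- buildCaiWeights(Biostrings::RNAStringSet(c(r = random_orf(300))))
  tabr <- codonWeightTable(wr)
  fams <- split(names(Biostrings::GENETIC_CODE), Biostrings::GENETIC_CODE)
  names(fams) <- NULL
  for (i in 1:20) {
    orf <- random_orf(40)
    cods <- substring(orf, seq(1, nchar(orf) - 2, 3), seq(3, nchar(orf), 3))
    gc_map <- Biostrings::GENETIC_CODE
    names(gc_map) <- gsub("T", "U", names(gc_map))
    aa <- gc_map[cods]
    in_multi <- aa %in% names(table(gc_map)[table(gc_map) > 1]) & aa != "*"
    expected <- sum(cods %in% tabr$optimal & in_multi) / sum(in_multi)
    expect_equal(unname(fop(c(x = orf), tabr)), expected)
  }
})

test_that("tAI reproduces the toy hand computation", {
  # two anticodons, Watson-Crick only, copy numbers 2:1 -> weights 1 and 0.5
  s_strict <- c(WC = 0, "G:U" = 1, "I:C" = 1, "I:A" = 1, "U:G" = 1)
  w <- buildTaiWeights(c(AAU = 2, GAU = 1), s = s_strict)
  expect_equal(unname(w["AUU"]), 1.0)     # read by AAU (2 copies)
  expect_equal(unname(w["AUC"]), 0.5)     # read by GAU (1 copy)
  tab <- codonWeightTable(setNames(rep(1, length(w)), names(w)), tai_w = w)
  # one codon of each -> geometric mean sqrt(0.5)
  expect_equal(unname(tai(c(x = "AUUAUC"), tab)), sqrt(0.5), tolerance = 1e-12)
  # single-codon ORF on the best codon -> 1
  expect_equal(unname(tai(c(x = "AUU"), tab)), 1.0)
  # order invariance
  expect_equal(tai(c(a = "AUUAUCAUU"), tab), tai(c(a = "AUUAUUAUC"), tab))
})

test_that("tAI wobble discounting follows the stated pairing rules", {
  # single Gly tRNA with anticodon GCC reads GGC (WC) and GGU (G:U wobble)
  w <- buildTaiWeights(c(GCC = 10))
  expect_equal(unname(w["GGU"] / w["GGC"]), 1 - 0.41, tolerance = 1e-12)
})

test_that("amino-acid composition sums to one and flags internal stops", {
  aa <- aaComposition(Biostrings::RNAStringSet(c(x = "AUGUCUUAA")))
  expect_equal(unname(aa[1, "M"]), 0.5)
  expect_equal(unname(aa[1, "S"]), 0.5)
  expect_equal(unname(rowSums(aa)), 1, tolerance = 1e-12)
  aa2 <- aaComposition(Biostrings::RNAStringSet(c(x = "AUGAUGAUG")))
  expect_equal(unname(aa2[1, "M"]), 1)
  withr::local_seed(43)
  aa3 <- aaComposition(Biostrings::RNAStringSet(
    setNames(vapply(1:10, function(i) random_orf(50), character(1)),
             paste0("r", 1:10))))
  expect_equal(unname(rowSums(aa3)), rep(1, 10), tolerance = 1e-12)
  expect_error(aaComposition(Biostrings::RNAStringSet(c(x = "AUGUAAGCUUAA"))),
               "internal stop")
})

test_that("start-context features detect upstream AUGs, uORFs and stops", {
  seqs <- Biostrings::RNAStringSet(c(
    no_aug = paste0("CCCCCCCCCCCC", "AUGGCUUAA", "ACGUACGUACGU"),
    uorf   = paste0("CCAUGUAACCCC", "AUGGCUUAA", "ACGUACGUACGU"),
    aug_only = paste0("CCCCCCAUGCCC", "AUGGCUUAA", "ACGUACGUACGU")))
  regions <- data.frame(transcript_id = names(seqs), utr5_len = 12L,
                        orf_len = 9L, utr3_len = 12L)
  ts <- assembleTranscripts(seqs, regions)
  sc <- startContextFeatures(ts)
  expect_equal(unname(sc["no_aug", c("uaug_count", "uorf_present")]), c(0, 0))
  expect_equal(unname(sc["uorf", c("uaug_count", "uorf_present",
                                   "utr5_stop_present")]), c(1, 1, 1))
  expect_equal(unname(sc["aug_only", c("uaug_count", "uorf_present")]), c(1, 0))
  # GC windows: all-C before start -> 1
  expect_equal(unname(sc["no_aug", "gc_before_start"]), 1)
})

test_that("AUG-CAI(r) is maximal on the reference consensus context", {
  # identical transcripts: every observed base is the positional maximum
  seqs <- Biostrings::RNAStringSet(
    setNames(rep(paste0("ACGUACGUACGA", "AUGGCUUAA", "ACGUACGUACGU"), 5),
             paste0("g", 1:5)))
  regions <- data.frame(transcript_id = names(seqs), utr5_len = 12L,
                        orf_len = 9L, utr3_len = 12L)
  ts <- assembleTranscripts(seqs, regions)
  sc <- startContextFeatures(ts)
  expect_equal(unname(sc[, "aug_cai_r"]), rep(1, 5), tolerance = 1e-12)
})

test_that("motif scanning matches IUPAC semantics and the window oracle", {
  m <- MotifModel("Puf3_3utr", "CYUGUAAAUA", region = "utr3")
  expect_equal(scanMotif(c(a = "CCUGUAAAUA"), m), 1)   # Y matches C
  expect_equal(scanMotif(c(a = "CAUGUAAAUA"), m), 0)   # A not in Y
  expect_equal(scanMotif(c(a = "CC"), m), 0)           # shorter than motif
  withr::local_seed(47)
  seqs <- vapply(1:200, function(i) random_rna(200), character(1))
  got <- scanMotif(setNames(seqs, paste0("s", 1:200)),
                   MotifModel("puf", "UGUAHAUA", region = "utr3"))
  want <- vapply(seqs, bf_motif_count, numeric(1), consensus = "UGUAHAUA",
                 USE.NAMES = FALSE)
  expect_equal(got, want)
})

test_that("PWM scoring returns the best window log-odds", {
  pwm <- matrix(c(0.97, 0.01, 0.01, 0.01), 4, 4,
                dimnames = list(c("A", "C", "G", "U"), NULL))
  m <- MotifModel("pA", pwm = pwm, region = "utr3", scoring = "max_log_odds")
  s <- scanMotif(c(x = "GGGAAAAGGG"), m)
  expect_equal(s, 4 * log2(0.97 / 0.25), tolerance = 1e-9)
  expect_equal(scanMotif(c(x = "GG"), m), -1e6)
})

test_that("folding proxy reproduces hand-traced structures", {
  expect_equal(foldEnergy("AAAAAAAA"), 0)
  # three-pair helix with two stacks at unit bonuses
  expect_equal(foldEnergy("GGGAAACCC"), -5)
  expect_equal(foldEnergy("GGGAAACCC", pair_bonus = 2, stack_bonus = 0.5), -7)
  expect_equal(foldEnergy("ACGUACG"), 0)  # below the 8 nt floor
  # extension with the reverse complement of a prefix never loses structure
  withr::local_seed(53)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  for (i in 1:20) {
    s <- random_rna(sample(8:12, 1))
    k <- sample(3:6, 1)
    pre <- strsplit(substr(s, 1, k), "")[[1]]
    ext <- paste0(s, paste(rev(comp[pre]), collapse = ""))
    expect_lte(foldEnergy(ext, window = Inf), foldEnergy(s, window = Inf))
  }
})

test_that("the default schema builds exactly 77 ordered features", {
  schema <- defaultFeatureSchema()
  expect_equal(length(schema), 77L)
  expect_false(anyDuplicated(featureNames(schema)) > 0)
  ts <- make_tiny_ts()
  fm <- buildFeatureMatrix(ts)
  expect_equal(ncol(featureValues(fm)), 77L)
  expect_equal(colnames(featureValues(fm)), featureNames(schema))
  # compositional and index features live in [0, 1]
  vals <- featureValues(fm)
  unit_cols <- c(grep("^pct_|^aa_", colnames(vals), value = TRUE),
                 "cai", "fop", "tai", "aug_cai_r",
                 "gc_before_start", "gc_after_start")
  expect_true(all(vals[, unit_cols] >= 0 & vals[, unit_cols] <= 1))
})

test_that("a reduced schema and shuffled input preserve column contracts", {
  ts <- make_tiny_ts()
  panel <- defaultMotifPanel()
  schema <- defaultFeatureSchema(panel)
  comp_only <- new("FeatureSchema",
                   entries = schema@entries[schema@entries$op == "composition", ],
                   version = "comp-15")
  fm <- buildFeatureMatrix(ts, schema = comp_only)
  expect_equal(ncol(featureValues(fm)), 15L)
  # shuffled transcript order: same columns, same per-gene values
  ts_rev <- new("TranscriptSet", utr5 = ts@utr5[2:1], orf = ts@orf[2:1],
                utr3 = ts@utr3[2:1])
  fm_rev <- buildFeatureMatrix(ts_rev, schema = comp_only)
  expect_equal(featureValues(fm_rev)["g1", ], featureValues(fm)["g1", ])
  # schema referencing a motif absent from the panel is an error
  bad <- schema
  bad@entries$name[bad@entries$op == "motif"][1] <- "NotInPanel_3utr"
  expect_error(buildFeatureMatrix(ts, panel = panel, schema = bad),
               "absent from panel")
})

test_that("feature building is a pure function of its inputs", {
  withr::local_seed(59)
  p <- simulationParams(n_genes = 40, regulon_size = 8, seed = 99)
  tx <- simulateTranscriptome(p)
  ex <- simulateExpression(tx$truth, p)
  ts <- assembleTranscripts(tx$sequences, tx$regions)
  f1 <- buildFeatureMatrix(ts, expression = ex)
  f2 <- buildFeatureMatrix(ts, expression = ex)
  expect_identical(featureValues(f1), featureValues(f2))
})
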