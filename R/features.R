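#' Assemble transcripts from sequences and a region table
#'
#' Splits each full-length transcript into 5'UTR, ORF and 3'UTR using the
#' region-length table, and enforces the ORF invariants (starts AUG, ends
#' with a stop codon, codon multiple, no internal stop).
#'
#' @param seqs `RNAStringSet` of full transcripts.
#' @param regions region data.frame (see [readRegionTable()]).
#' @param on_invalid `"drop"` (warn and drop offending transcripts) or
#'   `"error"`.
#' @return a [TranscriptSet-class]; dropped ids in attribute `dropped`.
#' @export
assembleTranscripts <- function(seqs, regions, on_invalid = c("drop", "error")) {
  on_invalid <- match.arg(on_invalid)
  ids <- intersect(regions$transcript_id, names(seqs))
  miss <- setdiff(regions$transcript_id, names(seqs))
  if (length(miss))
    warnf("%d region row(s) without a sequence (e.g. %s)", length(miss), miss[1])
  reg <- regions[match(ids, regions$transcript_id), ]
  sq <- seqs[ids]
  total <- reg$utr5_len + reg$orf_len + reg$utr3_len
  bad_len <- Biostrings::width(sq) != total
  ch <- as.character(sq)
  u5 <- substr(ch, 1L, reg$utr5_len)
  orf <- substr(ch, reg$utr5_len + 1L, reg$utr5_len + reg$orf_len)
  u3 <- substr(ch, reg$utr5_len + reg$orf_len + 1L, total)
  starts_aug <- substr(orf, 1L, 3L) == "AUG"
  last <- substr(orf, nchar(orf) - 2L, nchar(orf))
  ends_stop <- last %in% STOP_CODONS
  n_stop <- function(s) {
    cc <- codonCounts(Biostrings::RNAStringSet(s))
    rowSums(cc[, STOP_CODONS, drop = FALSE])
  }
  internal <- n_stop(orf) - as.integer(ends_stop) > 0L
  bad <- bad_len | !starts_aug | !ends_stop | internal
  if (any(bad)) {
    why <- ifelse(bad_len, "length mismatch",
           ifelse(!starts_aug, "ORF does not start with AUG",
           ifelse(!ends_stop, "ORF does not end with a stop codon",
                  "internal stop codon")))
    msg <- sprintf("%d transcript(s) failed assembly (e.g. %s: %s)",
                   sum(bad), ids[bad][1], why[bad][1])
    if (on_invalid == "error") stopf("%s", msg)
    warnf("%s", msg)
  }
  keep <- !bad
  mk <- function(x) {
    out <- Biostrings::RNAStringSet(x[keep]); names(out) <- ids[keep]; out
  }
  ts <- new("TranscriptSet", utr5 = mk(u5), orf = mk(orf), utr3 = mk(u3))
  validObject(ts)
  attr(ts, "dropped") <- ids[bad]
  ts
}

#' Base composition and length features per region
#'
#' @param ts a [TranscriptSet-class].
#' @return matrix, transcripts x 15: region lengths (3) and per-region
#'   A/C/G/U fractions (12). N bases are excluded from denominators; empty
#'   regions yield 0 fractions.
#' @export
compositionFeatures <- function(ts) {
  blocks <- lapply(c(utr5 = "utr5", orf = "orf", utr3 = "utr3"), function(rg) {
    x <- transcriptRegion(ts, rg)
    af <- Biostrings::alphabetFrequency(x)[, c("A", "C", "G", "U"), drop = FALSE]
    den <- rowSums(af)
    frac <- sweep(af, 1L, pmax(den, 1L), "/")
    colnames(frac) <- paste0("pct_", c("A", "C", "G", "U"), "_", rg)
    cbind(setNames(data.frame(Biostrings::width(x)), paste0("length_", rg)),
          frac)
  })
  out <- as.matrix(do.call(cbind, unname(blocks)))
  rownames(out) <- names(ts)
  out[, c(paste0("length_", c("utr5", "orf", "utr3")),
          as.vector(outer(c("pct_A_", "pct_C_", "pct_G_", "pct_U_"),
                          c("utr5", "orf", "utr3"), paste0))),
      drop = FALSE]
}

#' Scan a sequence set with one motif model
#'
#' Consensus motifs are matched with IUPAC semantics (a window matches when
#' every base belongs to the consensus position's class); the count score is
#' the number of matching windows, overlaps included, forward strand only.
#' PWM scoring returns the maximum over windows of the summed
#' `log2(p(base)/0.25)`; sequences shorter than the motif score 0 (count)
#' or the documented floor `-1e6` (max_log_odds).
#'
#' @param seqs `RNAStringSet` (or character vector).
#' @param motif a [MotifModel-class].
#' @return numeric vector of scores, one per sequence.
#' @export
scanMotif <- function(seqs, motif) {
  seqs <- .as_rna_set(seqs)
  L <- motifWidth(motif)
  if (motif@scoring == "count") {
    if (length(motif@pwm)) stopf("count scoring requires a consensus motif")
    pat <- Biostrings::RNAString(motif@consensus)
    out <- Biostrings::vcountPattern(pat, seqs,
                                     fixed = c(pattern = FALSE, subject = TRUE))
    out[Biostrings::width(seqs) < L] <- 0L
    as.numeric(out)
  } else {
    pwm <- motif@pwm
    if (!length(pwm)) {
      pwm <- .consensus_to_pwm(motif@consensus)
    }
    lo <- log2(pmax(pwm, 1e-6) / 0.25)
    ch <- as.character(seqs)
    vapply(ch, function(s) {
      n <- nchar(s)
      if (n < L) return(-1e6)
      b <- strsplit(s, "")[[1]]
      idx <- match(b, c("A", "C", "G", "U"))
      best <- -Inf
      for (i in seq_len(n - L + 1L)) {
        cols <- idx[i:(i + L - 1L)]
        if (anyNA(cols)) next
        best <- max(best, sum(lo[cbind(cols, seq_len(L))]))
      }
      if (is.finite(best)) best else -1e6
    }, numeric(1), USE.NAMES = FALSE)
  }
}

.consensus_to_pwm <- function(consensus) {
  cols <- strsplit(consensus, "")[[1]]
  pwm <- vapply(cols, function(code) {
    allowed <- strsplit(IUPAC_CODES[[code]], "")[[1]]
    p <- setNames(numeric(4), c("A", "C", "G", "U"))
    p[allowed] <- 1 / length(allowed)
    p
  }, numeric(4))
  rownames(pwm) <- c("A", "C", "G", "U")
  pwm
}

#' Folding-energy proxy per sequence
#'
#' Deterministic maximum base-pairing dynamic program (Watson-Crick + GU
#' wobble, minimum hairpin loop 3 nt) scored with a bonus per pair
#' (`pair_bonus`, default 1) plus a bonus per directly stacked pair
#' (`stack_bonus`, default 1); the reported pseudo-energy is the negated
#' score, so lower means more structured. Folding is evaluated on the
#' leading `window` nt of each sequence (structure near the region start;
#' keeps cost linear in transcript number). Sequences shorter than 8 nt
#' score 0.
#'
#' @param seqs `RNAStringSet` or character vector.
#' @param window cap on folded length in nt (default 100); `Inf` folds the
#'   whole sequence.
#' @param pair_bonus,stack_bonus,min_loop scoring constants.
#' @return numeric vector of pseudo-energies (<= 0).
#' @export
foldEnergy <- function(seqs, window = 100L, pair_bonus = 1.0,
                       stack_bonus = 1.0, min_loop = 3L) {
  ch <- toupper(as.character(seqs))
  ch <- gsub("T", "U", ch)
  if (is.finite(window)) ch <- substr(ch, 1L, window)
  out <- numeric(length(ch))
  long <- nchar(ch) >= 8L
  if (any(long))
    out[long] <- .fold_energy_cpp(ch[long], pair_bonus, stack_bonus,
                                  as.integer(min_loop))
  out
}

#' Positional base frequencies of the start-codon context
#'
#' Builds the -6..+3 positional nucleotide frequency table (AUG occupying
#' +1..+3) from a reference transcript set, for the AUG-CAI(r) context
#' score.
#'
#' @param ts a [TranscriptSet-class] (the reference set).
#' @return 4 x 9 matrix of frequencies (rows A,C,G,U; columns -6..+3),
#'   columns summing to 1.
#' @export
buildStartContextTable <- function(ts) {
  u5 <- as.character(transcriptRegion(ts, "utr5"))
  orf <- as.character(transcriptRegion(ts, "orf"))
  up <- vapply(u5, function(s) {
    n <- nchar(s)
    paste0(strrep("N", max(0L, 6L - n)), substr(s, max(1L, n - 5L), n))
  }, character(1), USE.NAMES = FALSE)
  ctx <- paste0(up, substr(orf, 1L, 3L))
  mat <- matrix(0, 4, 9, dimnames = list(c("A", "C", "G", "U"),
                                         as.character(c(-6:-1, 1:3))))
  for (pos in 1:9) {
    b <- substr(ctx, pos, pos)
    tab <- table(factor(b, levels = c("A", "C", "G", "U")))
    if (sum(tab) > 0) mat[, pos] <- as.numeric(tab) / sum(tab)
  }
  mat
}

#' Start-codon context features
#'
#' Six features per transcript: the AUG-CAI(r) context score (geometric mean
#' over -6..+3 positions of `f(base)/f_max(position)` under a reference
#' positional-frequency table), GC fraction in the window before the AUG and
#' after it (AUG excluded), the number of upstream AUGs in the 5'UTR, the
#' presence of an upstream ORF (an upstream AUG with an in-frame stop wholly
#' within the 5'UTR), and the presence of any stop codon in the 5'UTR (any
#' frame). Windows truncate at region boundaries.
#'
#' @param ts a [TranscriptSet-class].
#' @param context_table 4 x 9 positional frequency table
#'   (see [buildStartContextTable()]); defaults to one built from `ts`.
#' @param window GC window size in nt (default 30).
#' @return matrix, transcripts x 6.
#' @export
startContextFeatures <- function(ts, context_table = NULL, window = 30L) {
  if (is.null(context_table)) context_table <- buildStartContextTable(ts)
  u5 <- as.character(transcriptRegion(ts, "utr5"))
  orf <- as.character(transcriptRegion(ts, "orf"))
  n5 <- nchar(u5)
  gc_frac <- function(s) {
    n <- nchar(s)
    ifelse(n == 0L, 0,
           (nchar(gsub("[^GC]", "", s))) / pmax(n, 1L))
  }
  before <- substr(u5, pmax(1L, n5 - window + 1L), n5)
  after <- substr(orf, 4L, 3L + window)
  fmax <- apply(context_table, 2L, max)
  ctx_up <- substr(u5, pmax(1L, n5 - 5L), n5)
  aug_cai_r <- vapply(seq_along(u5), function(i) {
    bases <- c(strsplit(ctx_up[i], "")[[1]], strsplit(substr(orf[i], 1, 3), "")[[1]])
    offset <- 9L - length(bases)
    ratios <- numeric(0)
    for (k in seq_along(bases)) {
      pos <- offset + k
      b <- bases[k]
      if (!b %in% rownames(context_table)) next
      f <- context_table[b, pos]
      ratios <- c(ratios, max(f, 1e-6) / max(fmax[pos], 1e-6))
    }
    if (!length(ratios)) return(NA_real_)
    geom_mean(ratios)
  }, numeric(1))
  count_aug <- vapply(u5, function(s) {
    if (nchar(s) < 3L) return(0L)
    hits <- gregexpr("(?=AUG)", s, perl = TRUE)[[1]]
    sum(hits > 0)
  }, integer(1), USE.NAMES = FALSE)
  uorf <- vapply(u5, .has_uorf, logical(1), USE.NAMES = FALSE)
  ustop <- vapply(u5, function(s)
    any(vapply(STOP_CODONS, function(sc) grepl(sc, s, fixed = TRUE),
               logical(1))), logical(1), USE.NAMES = FALSE)
  out <- cbind(aug_cai_r = aug_cai_r,
               gc_before_start = gc_frac(before),
               gc_after_start = gc_frac(after),
               uaug_count = as.numeric(count_aug),
               uorf_present = as.numeric(uorf),
               utr5_stop_present = as.numeric(ustop))
  rownames(out) <- names(ts)
  out
}

.has_uorf <- function(u5) {
  n <- nchar(u5)
  if (n < 6L) return(FALSE)
  starts <- gregexpr("(?=AUG)", u5, perl = TRUE)[[1]]
  starts <- starts[starts > 0]
  for (st in starts) {
    pos <- st + 3L
    while (pos + 2L <= n) {
      if (substr(u5, pos, pos + 2L) %in% STOP_CODONS) return(TRUE)
      pos <- pos + 3L
    }
  }
  FALSE
}

#' The default 77-feature schema
#'
#' Region lengths (3), per-region base composition (12), GC windows around
#' the start codon (2), folding-energy proxy per region (3), CAI, fop, tAI
#' and AUG-CAI(r) (4), amino-acid composition (20), upstream-AUG count,
#' uORF presence and 5'UTR stop presence (3), transcript levels in control
#' and stress (2), and one column per motif-panel entry (28 by default).
#'
#' @param panel list of [MotifModel-class] (default [defaultMotifPanel()]).
#' @return a [FeatureSchema-class] of length 49 + number of panel entries
#'   (77 with the default panel).
#' @export
defaultFeatureSchema <- function(panel = defaultMotifPanel()) {
  e <- function(name, op, region = NA_character_, param = NA_character_)
    data.frame(name = name, op = op, region = region, param = param)
  rg <- c("utr5", "orf", "utr3")
  entries <- rbind(
    e(paste0("length_", rg), "composition", rg),
    e(as.vector(outer(c("pct_A_", "pct_C_", "pct_G_", "pct_U_"), rg, paste0)),
      "composition", rep(rg, each = 4)),
    e(c("gc_before_start", "gc_after_start"), "start_context"),
    e(paste0("fold_energy_", rg), "fold", rg),
    e("cai", "cai", "orf"), e("fop", "fop", "orf"), e("tai", "tai", "orf"),
    e("aug_cai_r", "start_context"),
    e(paste0("aa_", sort(unique(rna_genetic_code()[rna_genetic_code() != "*"]))),
      "aa", "orf"),
    e(c("uaug_count", "uorf_present", "utr5_stop_present"), "start_context"),
    e(c("transcript_level_control", "transcript_level_stress"), "expression"),
    e(vapply(panel, function(m) m@name, character(1)), "motif",
      vapply(panel, function(m) m@region, character(1)))
  )
  rownames(entries) <- NULL
  new("FeatureSchema", entries = entries, version = "default-77")
}

#' Build the per-transcript feature matrix
#'
#' Computes every feature of `schema` for every transcript in `ts`.
#' Transcript-level features are the mean log2 total-fraction intensity per
#' condition from `expression`. The CAI reference set (and start-context
#' reference) defaults to the top decile of transcripts by control
#' transcript level (or all transcripts when no expression is supplied).
#' Missing values (e.g. transcripts absent from the expression matrix) are
#' imputed with the per-feature median and flagged in the `imputed` slot.
#'
#' @param ts a [TranscriptSet-class].
#' @param expression optional [PolysomeSet-class].
#' @param panel motif panel (list of [MotifModel-class]).
#' @param schema a [FeatureSchema-class]; default [defaultFeatureSchema()].
#' @param weights optional [codonWeightTable()]; by default CAI weights come
#'   from the reference decile and tAI weights from the bundled tables.
#' @param fold_window folded window per region in nt (see [foldEnergy()]).
#' @param gc_window GC window around the start codon in nt.
#' @return a [FeatureMatrix-class].
#' @export
buildFeatureMatrix <- function(ts, expression = NULL, panel = defaultMotifPanel(),
                               schema = defaultFeatureSchema(panel),
                               weights = NULL, fold_window = 100L,
                               gc_window = 30L) {
  ids <- names(ts)
  n <- length(ids)
  expr_block <- matrix(NA_real_, n, 2,
                       dimnames = list(ids, c("transcript_level_control",
                                              "transcript_level_stress")))
  if (!is.null(expression)) {
    a <- assay(expression, "log2intensity")
    cd <- colData(expression)
    for (cond in c("control", "stress")) {
      sel <- cd$condition == cond & cd$fraction == "total"
      lv <- rowMeans(a[, sel, drop = FALSE])
      hit <- intersect(ids, names(lv))
      expr_block[hit, paste0("transcript_level_", cond)] <- lv[hit]
    }
  }
  ref_ids <- ids
  lvl <- expr_block[, "transcript_level_control"]
  if (any(is.finite(lvl))) {
    thr <- quantile(lvl, 0.9, na.rm = TRUE)
    cand <- ids[!is.na(lvl) & lvl >= thr]
    if (length(cand) >= 10L) ref_ids <- cand
  }
  ref_ts <- new("TranscriptSet",
                utr5 = ts@utr5[ref_ids], orf = ts@orf[ref_ids],
                utr3 = ts@utr3[ref_ids])
  if (is.null(weights)) weights <- defaultCodonWeights(transcriptRegion(ref_ts, "orf"))
  ops <- unique(schema@entries$op)
  blocks <- list()
  if ("composition" %in% ops) blocks$composition <- compositionFeatures(ts)
  if ("start_context" %in% ops)
    blocks$start_context <- startContextFeatures(
      ts, context_table = buildStartContextTable(ref_ts), window = gc_window)
  if ("fold" %in% ops) {
    fe <- vapply(c("utr5", "orf", "utr3"), function(rg)
      foldEnergy(transcriptRegion(ts, rg), window = fold_window), numeric(n))
    if (n == 1L) fe <- matrix(fe, nrow = 1L,
                              dimnames = list(ids, c("utr5", "orf", "utr3")))
    colnames(fe) <- paste0("fold_energy_", c("utr5", "orf", "utr3"))
    blocks$fold <- fe
  }
  orfs <- transcriptRegion(ts, "orf")
  if ("cai" %in% ops) blocks$cai <- cbind(cai = cai(orfs, weights))
  if ("fop" %in% ops) blocks$fop <- cbind(fop = fop(orfs, weights))
  if ("tai" %in% ops) blocks$tai <- cbind(tai = tai(orfs, weights))
  if ("aa" %in% ops) {
    aam <- aaComposition(orfs)
    colnames(aam) <- paste0("aa_", colnames(aam))
    blocks$aa <- aam
  }
  if ("expression" %in% ops) blocks$expression <- expr_block
  if ("motif" %in% ops) {
    want <- schema@entries$name[schema@entries$op == "motif"]
    absent <- setdiff(want, vapply(panel, function(m) m@name, character(1)))
    if (length(absent)) stopf("schema references motif absent from panel: %s",
                              absent[1])
    mm <- vapply(panel, function(m)
      scanMotif(transcriptRegion(ts, if (m@region == "any") "orf" else m@region), m),
      numeric(n))
    if (n == 1L) mm <- matrix(mm, nrow = 1L,
                              dimnames = list(ids, names(panel)))
    blocks$motif <- mm
  }
  all_cols <- do.call(cbind, unname(blocks))
  rownames(all_cols) <- ids
  missing_cols <- setdiff(schema@entries$name, colnames(all_cols))
  if (length(missing_cols)) stopf("schema feature not computable: %s",
                                  missing_cols[1])
  vals <- all_cols[, schema@entries$name, drop = FALSE]
  imputed <- is.na(vals)
  if (any(imputed)) {
    med <- apply(vals, 2L, median, na.rm = TRUE)
    med[is.na(med)] <- 0
    for (jj in which(colSums(imputed) > 0L))
      vals[imputed[, jj], jj] <- med[jj]
  }
  new("FeatureMatrix", values = vals, imputed = imputed, schema = schema)
}

#' Write a feature matrix (and its schema) to disk
#' @param fm a `FeatureMatrix`
#' @param path output TSV (gene column + one column per feature)
#' @param schema_path optional JSON schema dump
#' @param header_comment optional `# ...` first line
#' @export
writeFeatureMatrix <- function(fm, path, schema_path = NULL,
                               header_comment = NULL) {
  df <- data.frame(gene = rownames(fm@values), fm@values, check.names = FALSE)
  con <- file(path, "w")
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  if (!is.null(schema_path))
    jsonlite::write_json(fm@schema@entries, schema_path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  invisible(path)
}
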