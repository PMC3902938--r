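#' @importFrom Biostrings trinucleotideFrequency alphabetFrequency width
NULL

# RNA-space genetic code, derived from the standard code table.
rna_genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- gsub("T", "U", names(gc))
  gc
}

STOP_CODONS <- c("UAA", "UAG", "UGA")

# Synonymous-family map: list aa -> codons (stops excluded).
codon_families <- function() {
  gc <- rna_genetic_code()
  gc <- gc[gc != "*"]
  split(names(gc), gc)
}

#' Codon usage counts for a set of ORFs
#'
#' @param orfs an `RNAStringSet` of in-frame ORFs.
#' @return integer matrix, ORFs x 64 codons (in-frame positions only).
#' @export
codonCounts <- function(orfs) {
  m <- trinucleotideFrequency(orfs, step = 3)
  colnames(m) <- gsub("T", "U", colnames(m))
  rownames(m) <- names(orfs)
  m
}

#' Build CAI relative-adaptiveness weights from a reference ORF set
#'
#' Relative synonymous codon usage in the reference set, scaled so the most
#' used codon of every family has weight 1. A 0.5 pseudocount keeps unused
#' codons off zero.
#'
#' @param reference_orfs `RNAStringSet` of reference ORFs.
#' @return named numeric vector of weights over the 61 sense codons.
#' @export
buildCaiWeights <- function(reference_orfs) {
  counts <- colSums(codonCounts(reference_orfs)) + 0.5
  counts <- counts[setdiff(names(counts), STOP_CODONS)]
  w <- counts
  for (fam in codon_families()) w[fam] <- counts[fam] / max(counts[fam])
  w
}

#' Codon weight table bundling CAI, fop and tAI weights
#'
#' @param cai_w named CAI weights per sense codon (max 1 within each family).
#' @param tai_w named tAI weights per sense codon, in (0, 1].
#' @return list with elements `cai_w`, `tai_w`, `optimal` (the fop optimal
#'   codon set: weight-1 codons of families with a synonymous choice).
#' @export
codonWeightTable <- function(cai_w, tai_w = NULL) {
  stopifnot(!is.null(names(cai_w)))
  fams <- codon_families()
  multi <- unlist(fams[lengths(fams) > 1L], use.names = FALSE)
  optimal <- intersect(names(cai_w)[cai_w >= 1 - 1e-12], multi)
  list(cai_w = cai_w, tai_w = tai_w, optimal = optimal)
}

# Codons excluded from the CAI geometric mean: stops plus single-codon
# families (AUG, UGG), per the standard definition.
cai_excluded <- function() {
  fams <- codon_families()
  c(STOP_CODONS, unlist(fams[lengths(fams) == 1L], use.names = FALSE))
}

#' Codon adaptation index
#'
#' Geometric mean of relative adaptiveness over the ORF's codons, excluding
#' the stop codon and the single-codon families (AUG, UGG).
#'
#' @param orfs `RNAStringSet` of ORFs (or a single character string).
#' @param weights a [codonWeightTable()].
#' @return numeric vector in (0, 1], one value per ORF.
#' @export
cai <- function(orfs, weights) {
  .index_geomean(orfs, weights$cai_w, exclude = cai_excluded())
}

#' Frequency of optimal codons
#'
#' Fraction of optimal codons among codons belonging to families with a
#' synonymous alternative.
#'
#' @inheritParams cai
#' @return numeric vector in \[0, 1\].
#' @export
fop <- function(orfs, weights) {
  orfs <- .as_rna_set(orfs)
  cc <- codonCounts(orfs)
  fams <- codon_families()
  multi <- unlist(fams[lengths(fams) > 1L], use.names = FALSE)
  denom <- rowSums(cc[, multi, drop = FALSE])
  num <- rowSums(cc[, weights$optimal, drop = FALSE])
  ifelse(denom > 0, num / denom, NA_real_)
}

#' tRNA adaptation index
#'
#' Geometric mean of normalised tRNA-availability weights over the ORF's
#' codons (stop excluded).
#'
#' @inheritParams cai
#' @return numeric vector in (0, 1].
#' @export
tai <- function(orfs, weights) {
  if (is.null(weights$tai_w)) stopf("weight table has no tAI weights")
  .index_geomean(orfs, weights$tai_w, exclude = STOP_CODONS)
}

.as_rna_set <- function(x) {
  if (is.character(x)) Biostrings::RNAStringSet(setNames(x, names(x)))
  else x
}

.index_geomean <- function(orfs, w, exclude) {
  orfs <- .as_rna_set(orfs)
  cc <- codonCounts(orfs)
  keep <- setdiff(colnames(cc), exclude)
  keep <- intersect(keep, names(w))
  cc <- cc[, keep, drop = FALSE]
  lw <- log(w[keep])
  n <- rowSums(cc)
  out <- exp(as.vector(cc %*% lw) / n)
  out[n == 0] <- NA_real_
  out
}

#' Build tAI codon weights from tRNA gene copy numbers
#'
#' Each codon's absolute weight sums the contributions of its Watson-Crick
#' anticodon and its wobble anticodon, discounted by the pairing-specific
#' selective constraints `s`; weights are scaled by the maximum, and codons
#' with no recognising tRNA are imputed with the geometric mean of the
#' non-zero weights (standard convention).
#'
#' @param tgcn named numeric vector: anticodon (5'->3', RNA) -> gene copy
#'   number.
#' @param s named penalties for the wobble pairings, defaults
#'   `c(WC = 0, "G:U" = 0.41, "I:C" = 0.28, "I:A" = 0.9999, "U:G" = 0.68)`.
#' @return named numeric vector of weights over the 61 sense codons.
#' @export
buildTaiWeights <- function(tgcn,
                            s = c(WC = 0, "G:U" = 0.41, "I:C" = 0.28,
                                  "I:A" = 0.9999, "U:G" = 0.68)) {
  codons <- setdiff(gsub("T", "U", names(Biostrings::GENETIC_CODE)), STOP_CODONS)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  gcn <- function(ac) if (ac %in% names(tgcn)) unname(tgcn[[ac]]) else 0
  W <- setNames(numeric(length(codons)), codons)
  for (cod in codons) {
    b <- strsplit(cod, "")[[1]]
    body <- paste0(comp[b[2]], comp[b[1]])   # anticodon positions 2-3
    wc_ac <- paste0(comp[b[3]], body)        # Watson-Crick anticodon
    W[cod] <- switch(b[3],
      U = (1 - s[["WC"]])    * gcn(wc_ac) + (1 - s[["G:U"]]) * gcn(paste0("G", body)),
      C = (1 - s[["WC"]])    * gcn(wc_ac) + (1 - s[["I:C"]]) * gcn(paste0("A", body)),
      A = (1 - s[["WC"]])    * gcn(wc_ac) + (1 - s[["I:A"]]) * gcn(paste0("A", body)),
      G = (1 - s[["WC"]])    * gcn(wc_ac) + (1 - s[["U:G"]]) * gcn(paste0("U", body)))
  }
  w <- W / max(W)
  zero <- w == 0
  if (any(zero)) w[zero] <- geom_mean(w[!zero])
  w
}

#' The bundled yeast tRNA gene copy number table (reconstruction)
#'
#' Approximate S. cerevisiae tRNA gene copy numbers by anticodon. This is a
#' reconstruction assembled for default use; substitute measured copy
#' numbers for production analyses.
#'
#' @return named numeric vector anticodon -> copy number.
#' @export
defaultTrnaCopyNumbers <- function() {
  path <- system.file("extdata", "trna_gcn_yeast_reconstruction.tsv",
                      package = "translatomeRF", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  setNames(df$gene_copy_number, df$anticodon)
}

#' Default codon weight table
#'
#' CAI weights from a caller-supplied reference ORF set and tAI weights from
#' the bundled tRNA copy-number reconstruction.
#'
#' @param reference_orfs `RNAStringSet` used as the CAI reference set.
#' @return a [codonWeightTable()].
#' @export
defaultCodonWeights <- function(reference_orfs) {
  codonWeightTable(cai_w = buildCaiWeights(reference_orfs),
                   tai_w = buildTaiWeights(defaultTrnaCopyNumbers()))
}

#' Amino-acid composition of translated ORFs
#'
#' @param orfs `RNAStringSet` of valid ORFs (no internal stop).
#' @return matrix, ORFs x 20 amino acids (one-letter, alphabetical),
#'   rows summing to 1.
#' @export
aaComposition <- function(orfs) {
  orfs <- .as_rna_set(orfs)
  cc <- codonCounts(orfs)
  gc <- rna_genetic_code()
  internal <- cc[, STOP_CODONS, drop = FALSE]
  # stop codons are legal only as the final codon
  n_stop <- rowSums(internal)
  last <- substr(as.character(orfs), width(orfs) - 2L, width(orfs))
  if (any(n_stop - as.integer(last %in% STOP_CODONS) > 0L))
    stopf("internal stop codon in ORF '%s'",
          names(orfs)[which(n_stop - (last %in% STOP_CODONS) > 0L)[1]])
  aas <- sort(unique(gc[gc != "*"]))
  memb <- vapply(aas, function(a) as.numeric(gc[colnames(cc)] == a),
                 numeric(ncol(cc)))
  memb[is.na(memb)] <- 0
  counts <- cc %*% memb
  sweep(counts, 1L, pmax(rowSums(counts), 1L), "/")
}
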