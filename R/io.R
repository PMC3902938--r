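#' Read transcript sequences from FASTA
#'
#' Sequences are normalised to the RNA alphabet (T becomes U) on read; the
#' package works in RNA space throughout because binding-site models such as
#' the Puf3p element are RNA motifs.
#'
#' @param path FASTA file.
#' @return A [Biostrings::RNAStringSet], one entry per record, input order
#'   preserved.
#' @export
readTranscriptFasta <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) return(Biostrings::RNAStringSet())
  ids <- sub("\\s.*$", "", names(raw))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stopf("duplicate sequence id: %s", dup[1])
  seqs <- toupper(as.character(raw))
  empty <- !nzchar(seqs)
  if (any(empty)) stopf("empty sequence for id: %s", ids[empty][1])
  seqs <- gsub("T", "U", seqs)
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGUN]", seqs[[i]])
    if (bad > 0)
      stopf("non-IUPAC character '%s' in '%s' at position %d",
            substr(seqs[[i]], bad, bad), ids[i], bad)
  }
  out <- Biostrings::RNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write an RNAStringSet to FASTA
#' @param x RNAStringSet
#' @param path output file
#' @export
writeTranscriptFasta <- function(x, path) {
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a transcript region table
#'
#' Tab-delimited file with columns `transcript_id`, `utr5_len`, `orf_len`,
#' `utr3_len` (transcript-local lengths in nt). Rows violating the region
#' invariants (ORF shorter than 3 nt or not a codon multiple, negative
#' lengths, or — under `require_utrs = TRUE` — an absent 5' or 3' UTR) are
#' dropped with a warning; mRNAs without measured UTRs are excluded from the
#' analysis rather than padded.
#'
#' @param path TSV file.
#' @param require_utrs drop transcripts with a zero-length UTR (default TRUE).
#' @return data.frame with the retained rows and attributes `n_excluded`
#'   and `excluded_ids`.
#' @export
readRegionTable <- function(path, require_utrs = TRUE) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("transcript_id", "utr5_len", "orf_len", "utr3_len")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stopf("region table missing column(s): %s",
                          paste(miss, collapse = ", "))
  df <- df[need]
  for (col in need[-1]) df[[col]] <- as.integer(df[[col]])
  bad_neg <- df$utr5_len < 0L | df$orf_len < 0L | df$utr3_len < 0L
  bad_orf <- df$orf_len < 3L | df$orf_len %% 3L != 0L
  bad_utr <- if (require_utrs) df$utr5_len == 0L | df$utr3_len == 0L
             else rep(FALSE, nrow(df))
  drop <- bad_neg | bad_orf | bad_utr
  if (any(drop))
    warnf("dropping %d region row(s) violating invariants (e.g. %s)",
          sum(drop), df$transcript_id[drop][1])
  out <- df[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(drop)
  attr(out, "excluded_ids") <- df$transcript_id[drop]
  out
}

#' Write a region table
#' @param regions data.frame as returned by [readRegionTable()]
#' @param path output TSV
#' @export
writeRegionTable <- function(regions, path) write_tsv(regions, path)

#' Read a long-format expression table into a PolysomeSet
#'
#' Expects columns `gene`, `condition`, `fraction`, `replicate`,
#' `log2_intensity`.
#'
#' @param path TSV file.
#' @return a [PolysomeSet-class]; genes missing any (condition, fraction)
#'   cell are retained but flagged via [incompleteGenes()].
#' @export
readExpressionTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "condition", "fraction", "replicate", "log2_intensity")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stopf("expression table missing column(s): %s",
                          paste(miss, collapse = ", "))
  suppressWarnings(v <- as.numeric(df$log2_intensity))
  if (anyNA(v) && any(is.na(v) & !is.na(df$log2_intensity)))
    stopf("non-numeric intensity at row %d",
          which(is.na(v) & !is.na(df$log2_intensity))[1])
  df$log2_intensity <- v
  key <- paste(df$gene, df$condition, df$fraction, df$replicate)
  if (anyDuplicated(key))
    stopf("duplicate (gene, condition, fraction, replicate) at row %d",
          which(duplicated(key))[1])
  col_key <- unique(df[c("condition", "fraction", "replicate")])
  col_key <- col_key[order(col_key$condition, col_key$fraction, col_key$replicate), ]
  genes <- unique(df$gene)
  mat <- matrix(NA_real_, length(genes), nrow(col_key),
                dimnames = list(genes, NULL))
  idx_col <- match(paste(df$condition, df$fraction, df$replicate),
                   paste(col_key$condition, col_key$fraction, col_key$replicate))
  mat[cbind(match(df$gene, genes), idx_col)] <- df$log2_intensity
  PolysomeSet(mat, col_key$condition, col_key$fraction, col_key$replicate)
}

#' Write a PolysomeSet as a long-format TSV
#' @param ps a `PolysomeSet`
#' @param path output TSV
#' @export
writeExpressionTable <- function(ps, path) {
  a <- assay(ps, "log2intensity")
  cd <- colData(ps)
  df <- data.frame(
    gene = rep(rownames(a), times = ncol(a)),
    condition = rep(cd$condition, each = nrow(a)),
    fraction = rep(cd$fraction, each = nrow(a)),
    replicate = rep(cd$replicate, each = nrow(a)),
    log2_intensity = as.vector(a))
  df <- df[!is.na(df$log2_intensity), ]
  write_tsv(df, path)
}

#' Read a motif panel
#'
#' Tab-delimited with columns `name`, `motif`, `target_region`, `scoring`.
#' `motif` is either an IUPAC consensus or `pwm:<id>` referencing a sidecar
#' file of stacked 4-row probability matrices (rows labelled `<id>_A` ..
#' `<id>_U`).
#'
#' @param path panel TSV.
#' @param pwm_path optional sidecar TSV of PWMs.
#' @return list of [MotifModel-class] objects.
#' @export
readMotifPanel <- function(path, pwm_path = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "motif", "target_region", "scoring")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stopf("motif panel missing column(s): %s",
                          paste(miss, collapse = ", "))
  pwms <- if (!is.null(pwm_path)) .read_pwm_sidecar(pwm_path) else list()
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    m <- df$motif[i]
    if (startsWith(m, "pwm:")) {
      id <- sub("^pwm:", "", m)
      if (is.null(pwms[[id]])) stopf("PWM '%s' not found in sidecar", id)
      out[[i]] <- MotifModel(df$name[i], pwm = pwms[[id]],
                             region = df$target_region[i],
                             scoring = df$scoring[i])
    } else {
      out[[i]] <- MotifModel(df$name[i], consensus = m,
                             region = df$target_region[i],
                             scoring = df$scoring[i])
    }
  }
  names(out) <- df$name
  out
}

.read_pwm_sidecar <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  ids <- unique(sub("_[ACGU]$", "", df[[1]]))
  out <- list()
  for (id in ids) {
    rows <- df[match(paste0(id, "_", c("A", "C", "G", "U")), df[[1]]), -1]
    pwm <- as.matrix(rows)
    dimnames(pwm) <- list(c("A", "C", "G", "U"), NULL)
    out[[id]] <- pwm
  }
  out
}

#' The default 28-entry RNA-binding-protein motif panel
#'
#' A reconstruction of a yeast RBP binding-site panel: each entry is an
#' IUPAC consensus with a target region, scanned in count mode. The
#' `Puf3_3utr` entry carries the canonical Puf3p element CYUGUAAAUA. The
#' panel file (`inst/extdata/motif_panel_default.tsv`) is the single source
#' of truth for the 28 motif columns of the default feature schema and can
#' be replaced by the user.
#'
#' @return list of 28 [MotifModel-class] objects.
#' @export
defaultMotifPanel <- function() {
  readMotifPanel(system.file("extdata", "motif_panel_default.tsv",
                             package = "translatomeRF", mustWork = TRUE))
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, then member ids, tab-separated).
#' @param universe optional declared universe; members outside it are dropped
#'   with a warning.
#' @return a [GeneSets-class] collection. Empty sets are dropped with a
#'   warning; duplicate set names are an error.
#' @export
readGeneSets <- function(path, universe = character(0)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(nm)) stopf("duplicate set name: %s", nm[duplicated(nm)][1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- nm
  if (length(universe)) {
    for (i in seq_along(sets)) {
      out <- setdiff(sets[[i]], universe)
      if (length(out)) {
        warnf("set '%s': dropping %d member(s) outside universe",
              nm[i], length(out))
        sets[[i]] <- intersect(sets[[i]], universe)
      }
    }
  }
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warnf("dropping %d empty set(s)", sum(empty))
    sets <- sets[!empty]
  }
  GeneSets(sets, universe)
}

#' Write gene sets to a GMT file
#' @param gs a `GeneSets`
#' @param path output GMT
#' @export
writeGeneSets <- function(gs, path) {
  lines <- vapply(names(gs), function(nm)
    paste(c(nm, "na", gs[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
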