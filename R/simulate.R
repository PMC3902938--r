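#' Simulation parameters with planted ground truth
#'
#' Defines the synthetic study conditions: a transcriptome in which a
#' designated regulon carries a Puf3-like element in its 3'UTRs and is
#' translationally repressed under stress through a condition x fraction
#' interaction of size `delta` in the stress/polysome cell.
#'
#' @param n_genes number of transcripts (default 3000).
#' @param regulon_size size of the planted regulon (default 400).
#' @param delta planted interaction effect in log2 units (default -2:
#'   polysome association halved twice over under stress).
#' @param sigma per-observation Gaussian noise SD in log2 units
#'   (default 0.25).
#' @param replicates arrays per (condition, fraction) cell (default 3).
#' @param plant_rate probability a regulon 3'UTR receives a planted motif
#'   (default 0.9).
#' @param background_rate same for background genes (default 0.05).
#' @param rho fraction of the simulated RBP target set drawn from the
#'   regulon (default 0.7).
#' @param motif IUPAC consensus planted in 3'UTRs (default the Puf3p
#'   element CYUGUAAAUA).
#' @param utr5_meanlog,utr5_sdlog,utr3_meanlog,utr3_sdlog log-normal
#'   parameters of UTR lengths in nt (defaults give yeast-like medians of
#'   ~70 and ~120 nt).
#' @param orf_meanlog,orf_sdlog log-normal parameters of ORF length in
#'   codons (median ~350 codons).
#' @param codon_tiers per-tier probability that a codon position uses the
#'   family's optimal codon (spreads CAI/tAI/fop across genes).
#' @param baseline_mean,baseline_sd per-gene baseline log2 intensity.
#' @param condition_effect additive stress shift (log2).
#' @param fraction_effects named additive shifts for total/monosome/polysome.
#' @param total_shift_sd SD of the per-gene transcriptional (total-fraction)
#'   stress shift.
#' @param n_decoy_sets,decoy_size decoy RBP target sets; `decoy_size`
#'   defaults to 250 genes, capped at a third of the universe.
#' @param n_terms,term_size flat term annotation; the first term draws 60%
#'   of its members from the regulon; `term_size` defaults to 120 genes,
#'   capped at a third of the universe.
#' @param seed master seed.
#' @return list of class `SimulationParams`.
#' @export
simulationParams <- function(n_genes = 3000L, regulon_size = 400L,
                             delta = -2, sigma = 0.25, replicates = 3L,
                             plant_rate = 0.9, background_rate = 0.05,
                             rho = 0.7, motif = "CYUGUAAAUA",
                             utr5_meanlog = log(70), utr5_sdlog = 0.5,
                             utr3_meanlog = log(120), utr3_sdlog = 0.5,
                             orf_meanlog = log(350), orf_sdlog = 0.45,
                             codon_tiers = c(0.25, 0.5, 0.85),
                             baseline_mean = 8, baseline_sd = 1,
                             condition_effect = 0.2,
                             fraction_effects = c(total = 1, monosome = 0,
                                                  polysome = 0.5),
                             total_shift_sd = 0.5,
                             n_decoy_sets = 8L, decoy_size = NULL,
                             n_terms = 15L, term_size = NULL, seed = 1L) {
  if (is.null(decoy_size)) decoy_size <- min(250L, n_genes %/% 3L)
  if (is.null(term_size)) term_size <- min(120L, n_genes %/% 3L)
  p <- as.list(environment())
  if (p$regulon_size >= p$n_genes) stopf("regulon_size must be < n_genes")
  if (p$sigma <= 0) stopf("sigma must be > 0")
  for (r in c(p$plant_rate, p$background_rate, p$rho))
    if (r < 0 || r > 1) stopf("rates must lie in [0, 1]")
  if (p$decoy_size > p$n_genes || p$term_size > p$n_genes)
    stopf("requested set size larger than the gene universe")
  structure(p, class = "SimulationParams")
}

.sample_iupac <- function(consensus) {
  paste(vapply(strsplit(consensus, "")[[1]], function(code) {
    allowed <- strsplit(IUPAC_CODES[[code]], "")[[1]]
    if (length(allowed) == 1L) allowed else sample(allowed, 1L)
  }, character(1)), collapse = "")
}

#' Simulate a transcriptome with a planted motif regulon
#'
#' UTRs are i.i.d. uniform over ACGU; ORFs are built codon-wise, choosing
#' each family's optimal codon with a per-gene tier probability (so CAI,
#' fop and tAI vary between genes). Regulon 3'UTRs receive one concrete
#' instance of the consensus (IUPAC degeneracy sampled) at `plant_rate`,
#' background 3'UTRs at `background_rate`. Chance motif matches are
#' recorded in the truth, not scrubbed.
#'
#' @param params a [simulationParams()].
#' @return list with `sequences` (full-transcript `RNAStringSet`),
#'   `regions` (region data.frame) and `truth` (regulon membership, planted
#'   positions, per-gene true delta, codon tiers).
#' @export
simulateTranscriptome <- function(params) {
  p <- params
  with_seed(derive_seed(p$seed, 1L), {
    ids <- sprintf("g%04d", seq_len(p$n_genes))
    mlen <- nchar(p$motif)
    min_utr <- max(12L, mlen + 2L)
    u5_len <- pmax(min_utr, round(rlnorm(p$n_genes, p$utr5_meanlog, p$utr5_sdlog)))
    u3_len <- pmax(min_utr, round(rlnorm(p$n_genes, p$utr3_meanlog, p$utr3_sdlog)))
    n_codons <- pmax(50L, round(rlnorm(p$n_genes, p$orf_meanlog, p$orf_sdlog)))
    bases <- c("A", "C", "G", "U")
    rand_seq <- function(lens) {
      vapply(lens, function(L)
        paste(sample(bases, L, replace = TRUE), collapse = ""), character(1))
    }
    u5 <- rand_seq(u5_len)
    u3 <- rand_seq(u3_len)
    tier <- sample(seq_along(p$codon_tiers), p$n_genes, replace = TRUE)
    fams <- codon_families()
    optimal <- vapply(fams, `[`, character(1), 1L)
    orf <- vapply(seq_len(p$n_genes), function(i) {
      k <- n_codons[i] - 2L      # minus start and stop
      aa <- sample(names(fams), k, replace = TRUE)
      use_opt <- runif(k) < p$codon_tiers[tier[i]]
      cods <- ifelse(use_opt, optimal[aa],
                     vapply(aa, function(a) sample(fams[[a]], 1L), character(1)))
      paste0("AUG", paste(cods, collapse = ""), sample(STOP_CODONS, 1L))
    }, character(1))
    regulon <- sort(sample(ids, p$regulon_size))
    plant <- runif(p$n_genes) < ifelse(ids %in% regulon,
                                       p$plant_rate, p$background_rate)
    planted <- data.frame(gene = character(0), position = integer(0),
                          instance = character(0))
    for (i in which(plant)) {
      inst <- .sample_iupac(p$motif)
      pos <- sample(nchar(u3[i]) - mlen + 1L, 1L)
      substr(u3[i], pos, pos + mlen - 1L) <- inst
      planted <- rbind(planted, data.frame(gene = ids[i], position = pos,
                                           instance = inst))
    }
    seqs <- Biostrings::RNAStringSet(paste0(u5, orf, u3))
    names(seqs) <- ids
    regions <- data.frame(transcript_id = ids, utr5_len = nchar(u5),
                          orf_len = nchar(orf), utr3_len = nchar(u3))
    chance <- Biostrings::vcountPattern(
      Biostrings::RNAString(p$motif), Biostrings::RNAStringSet(setNames(u3, ids)),
      fixed = c(pattern = FALSE, subject = TRUE))
    truth <- list(
      regulon = regulon,
      planted = planted,
      motif_hits = setNames(as.integer(chance), ids),
      true_delta = setNames(ifelse(ids %in% regulon, p$delta, 0), ids),
      tier = setNames(tier, ids),
      params = unclass(p)[setdiff(names(p), "fraction_effects")])
    list(sequences = seqs, regions = regions, truth = truth)
  })
}

#' Simulate the polysome-profiling expression matrix
#'
#' log2 intensity = gene baseline + fraction effect + condition effect
#' + `delta` for regulon genes in the stress/polysome cell (the interaction
#' the two-factor ANOVA tests) + an independent per-gene transcriptional
#' stress shift in the total fraction + Gaussian noise.
#'
#' @param truth truth component of [simulateTranscriptome()].
#' @param params the same [simulationParams()].
#' @return a [PolysomeSet-class].
#' @export
simulateExpression <- function(truth, params) {
  p <- params
  with_seed(derive_seed(p$seed, 2L), {
    ids <- names(truth$true_delta)
    ng <- length(ids)
    design <- expand.grid(replicate = seq_len(p$replicates),
                          fraction = c("total", "monosome", "polysome"),
                          condition = c("control", "stress"),
                          stringsAsFactors = FALSE)
    baseline <- rnorm(ng, p$baseline_mean, p$baseline_sd)
    txn_shift <- rnorm(ng, 0, p$total_shift_sd)
    mat <- matrix(NA_real_, ng, nrow(design), dimnames = list(ids, NULL))
    for (j in seq_len(nrow(design))) {
      mu <- baseline + p$fraction_effects[[design$fraction[j]]] +
        p$condition_effect * (design$condition[j] == "stress") +
        truth$true_delta * (design$condition[j] == "stress") *
          (design$fraction[j] == "polysome") +
        txn_shift * (design$condition[j] == "stress") *
          (design$fraction[j] == "total")
      mat[, j] <- mu + rnorm(ng, 0, p$sigma)
    }
    PolysomeSet(mat, design$condition, design$fraction, design$replicate)
  })
}

#' Simulate RBP target sets and term annotations
#'
#' Builds a "Puf3-like" target set sharing fraction `rho` of its members
#' with the regulon, `n_decoy_sets` decoy RBP target sets drawn uniformly,
#' and a flat term annotation in which the first term is enriched in the
#' regulon.
#'
#' @inheritParams simulateExpression
#' @return list with `rbp` and `terms`, both [GeneSets-class] over the
#'   full gene universe.
#' @export
simulateGeneSets <- function(truth, params) {
  p <- params
  with_seed(derive_seed(p$seed, 3L), {
    ids <- names(truth$true_delta)
    regulon <- truth$regulon
    size <- min(p$regulon_size, length(ids) - 1L)
    n_in <- round(p$rho * size)
    if (size > length(ids)) stopf("requested set larger than universe")
    n_in <- min(n_in, length(regulon))
    n_out <- min(size - n_in, length(ids) - length(regulon))
    puf3_like <- c(sample(regulon, n_in),
                   sample(setdiff(ids, regulon), n_out))
    decoy_size <- min(p$decoy_size, length(ids))
    rbp <- c(list(Puf3_targets = sort(puf3_like)),
             setNames(lapply(seq_len(p$n_decoy_sets), function(i)
               sort(sample(ids, decoy_size))),
               sprintf("RBP_decoy_%02d", seq_len(p$n_decoy_sets))))
    terms <- setNames(vector("list", p$n_terms),
                      sprintf("term_%02d", seq_len(p$n_terms)))
    term_size <- min(p$term_size, length(ids))
    n_from_reg <- min(round(0.6 * term_size), length(regulon))
    terms[[1]] <- sort(c(sample(regulon, n_from_reg),
                         sample(setdiff(ids, regulon),
                                min(term_size - n_from_reg,
                                    length(ids) - length(regulon)))))
    for (i in seq_len(p$n_terms)[-1])
      terms[[i]] <- sort(sample(ids, term_size))
    list(rbp = GeneSets(rbp, universe = ids),
         terms = GeneSets(terms, universe = ids))
  })
}

#' Export (and reload) the planted ground truth
#'
#' Writes machine-readable truth as JSON plus a GMT carrying the regulon.
#'
#' @param truth truth list from [simulateTranscriptome()].
#' @param path output JSON path; a `.gmt` with the same stem is written
#'   alongside.
#' @export
exportTruth <- function(truth, path) {
  out <- list(regulon = truth$regulon, planted = truth$planted,
              motif_hits = as.list(truth$motif_hits),
              true_delta = as.list(truth$true_delta),
              tier = as.list(truth$tier))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  gmt <- sub("\\.json$", ".gmt", path)
  writeGeneSets(GeneSets(list(regulon = truth$regulon)), gmt)
  invisible(path)
}

#' @rdname exportTruth
#' @return `loadTruth` returns the truth list (regulon, planted positions,
#'   motif hit counts, true deltas, codon tiers).
#' @export
loadTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$regulon <- as.character(x$regulon)
  x$true_delta <- unlist(x$true_delta)
  x$motif_hits <- unlist(x$motif_hits)
  x$tier <- unlist(x$tier)
  x
}
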