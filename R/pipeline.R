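#' Pipeline configuration
#'
#' Either `inputs` (paths to FASTA, region table, expression table, motif
#' panel, optional gene sets / terms GMTs) or `simulate` (a
#' [simulationParams()]) must be supplied — not both.
#'
#' @param inputs named list of input paths: `fasta`, `regions`,
#'   `expression`, optional `panel`, `gene_sets`, `terms`.
#' @param simulate a [simulationParams()] block.
#' @param tau change-in-translation-state threshold (default 1.0).
#' @param alpha adjusted-p threshold (default 0.01).
#' @param forest a [forestConfig()].
#' @param outdir output directory.
#' @param seed master seed; overrides the seeds in `simulate`/`forest`.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(inputs = NULL, simulate = NULL, tau = 1.0,
                           alpha = 0.01, forest = forestConfig(),
                           outdir = tempfile("translatomeRF_run_"),
                           seed = 1L) {
  if (is.null(inputs) == is.null(simulate))
    stopf("supply exactly one of 'inputs' or 'simulate'")
  if (tau <= 0) stopf("tau must be > 0")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  seed <- as.integer(seed)
  if (!is.null(simulate)) simulate$seed <- seed
  forest$seed <- seed
  structure(list(inputs = inputs, simulate = simulate, tau = tau,
                 alpha = alpha, forest = forest, outdir = outdir,
                 seed = seed),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipelineConfig()] arguments; a `simulate`
#' mapping is passed to [simulationParams()], a `forest` mapping to
#' [forestConfig()].
#'
#' @param path YAML file.
#' @param seed,outdir optional overrides of the file's values.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path, seed = NULL, outdir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(seed)) y$seed <- seed
  if (!is.null(outdir)) y$outdir <- outdir
  sim <- if (!is.null(y$simulate)) do.call(simulationParams, y$simulate)
  fst <- if (!is.null(y$forest)) do.call(forestConfig, y$forest)
         else forestConfig()
  pipelineConfig(inputs = y$inputs, simulate = sim,
                 tau = y$tau %||% 1.0, alpha = y$alpha %||% 0.01,
                 forest = fst,
                 outdir = y$outdir %||% tempfile("translatomeRF_run_"),
                 seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.tsv_with_seed <- function(df, path, seed) {
  con <- file(path, "w")
  writeLines(sprintf("# translatomeRF seed=%d", seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: simulate (or load) inputs; translation-state calling
#' and classification; feature-matrix construction; one one-vs-rest forest
#' per response class (up and down); RBP co-association and term
#' enrichment. All outputs are TSV/JSON files under `config$outdir`; the
#' same config and seed reproduce them byte-identically.
#'
#' @param config a [pipelineConfig()].
#' @return (invisibly) the run report: per-stage counts, forest reports,
#'   enrichment tables, and the output file index.
#' @export
runPipeline <- function(config) {
  cfg <- config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = cfg$seed, stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  truth <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- stage("simulate", {
      tx <- simulateTranscriptome(cfg$simulate)
      expr <- simulateExpression(tx$truth, cfg$simulate)
      gsets <- simulateGeneSets(tx$truth, cfg$simulate)
      writeTranscriptFasta(tx$sequences, file.path(cfg$outdir, "transcripts.fa"))
      .tsv_with_seed(tx$regions, file.path(cfg$outdir, "regions.tsv"), cfg$seed)
      writeExpressionTable(expr, file.path(cfg$outdir, "expression.tsv"))
      exportTruth(tx$truth, file.path(cfg$outdir, "truth.json"))
      list(seqs = tx$sequences, regions = tx$regions, expr = expr,
           rbp = gsets$rbp, terms = gsets$terms, truth = tx$truth)
    })
    seqs <- sim$seqs; regions <- sim$regions; expr <- sim$expr
    rbp <- sim$rbp; terms <- sim$terms; truth <- sim$truth
    panel <- defaultMotifPanel()
  } else {
    inp <- cfg$inputs
    seqs <- stage("load", readTranscriptFasta(inp$fasta))
    regions <- stage("load", readRegionTable(inp$regions))
    expr <- stage("load", readExpressionTable(inp$expression))
    panel <- stage("load", if (!is.null(inp$panel)) readMotifPanel(inp$panel)
                           else defaultMotifPanel())
    rbp <- if (!is.null(inp$gene_sets)) stage("load", readGeneSets(inp$gene_sets))
    terms <- if (!is.null(inp$terms)) stage("load", readGeneSets(inp$terms))
    common <- intersect(regions$transcript_id, rownames(assay(expr)))
    if (!length(common))
      stopf("stage 'load' failed: no gene ids shared between regions (%s...) %s",
            regions$transcript_id[1], "and expression matrix")
  }
  report$stages$input <- list(n_sequences = length(seqs),
                              n_regions = nrow(regions),
                              n_regions_excluded = attr(regions, "n_excluded") %||% 0L)

  calls <- stage("translation_state", translationCalls(expr, tau = cfg$tau,
                                                       alpha = cfg$alpha))
  .tsv_with_seed(calls, file.path(cfg$outdir, "translation_calls.tsv"), cfg$seed)
  report$stages$translation_state <- as.list(table(calls$label))

  ts <- stage("features", assembleTranscripts(seqs, regions))
  fm <- stage("features", buildFeatureMatrix(ts, expression = expr,
                                             panel = panel))
  writeFeatureMatrix(fm, file.path(cfg$outdir, "feature_matrix.tsv"),
                     schema_path = file.path(cfg$outdir, "schema.json"),
                     header_comment = sprintf("translatomeRF seed=%d", cfg$seed))
  report$stages$features <- list(n_transcripts = length(ts),
                                 n_features = length(featureSchema(fm)),
                                 n_dropped = length(attr(ts, "dropped")))

  X <- featureValues(fm)
  calls_f <- calls[calls$gene %in% rownames(X), ]
  X <- X[calls_f$gene, , drop = FALSE]
  report$forest <- list()
  for (positive in c("up", "down")) {
    if (!any(calls_f$label == positive)) {
      report$forest[[positive]] <- list(skipped = "empty positive class")
      next
    }
    y <- makeBinaryLabels(calls_f, positive)
    rep_i <- stage("forest", forestReport(X, y, cfg$forest, positive = positive))
    .tsv_with_seed(rep_i$roc_points,
                   file.path(cfg$outdir, sprintf("roc_points_%s.tsv", positive)),
                   cfg$seed)
    .tsv_with_seed(rep_i$importance,
                   file.path(cfg$outdir, sprintf("importance_%s.tsv", positive)),
                   cfg$seed)
    jsonlite::write_json(
      rep_i[c("positive", "best", "oob_error", "confusion", "auc", "n", "seed")],
      file.path(cfg$outdir, sprintf("forest_report_%s.json", positive)),
      auto_unbox = TRUE, digits = NA)
    report$forest[[positive]] <- rep_i
  }

  universe <- calls_f$gene
  classes <- GeneSets(split(calls_f$gene, calls_f$label), universe = universe)
  enr <- NULL
  if (!is.null(rbp)) {
    enr <- stage("enrichment", coassociationMatrix(rbp, classes, universe))
    .tsv_with_seed(enr, file.path(cfg$outdir, "enrichment.tsv"), cfg$seed)
  }
  term_enr <- NULL
  if (!is.null(terms) && any(calls_f$label == "down")) {
    term_enr <- stage("enrichment",
                      termEnrichment(calls_f$gene[calls_f$label == "down"],
                                     terms, universe))
    .tsv_with_seed(term_enr, file.path(cfg$outdir, "term_enrichment.tsv"),
                   cfg$seed)
  }
  report$enrichment <- list(coassociation = enr, terms = term_enr)
  report$truth <- truth
  writeRunReport(report, file.path(cfg$outdir, "run_report.json"))
  invisible(report)
}

#' Write the consolidated run report
#'
#' JSON report plus a human-readable text summary with the confusion-matrix
#' block (TP/FP/TN/FN, AUC, top-3 features with effect signs) per response
#' class.
#'
#' @param report run-report list from [runPipeline()].
#' @param path JSON output path; a `.txt` summary with the same stem is
#'   written alongside.
#' @export
writeRunReport <- function(report, path) {
  slim <- report
  slim$truth <- NULL
  for (cls in names(slim$forest)) {
    f <- slim$forest[[cls]]
    if (!is.null(f$roc_points)) {
      f$roc_points <- NULL
      f$importance <- f$importance[seq_len(min(10L, nrow(f$importance))), ]
      slim$forest[[cls]] <- f
    }
  }
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  txt <- sub("\\.json$", ".txt", path)
  lines <- c(sprintf("translatomeRF run (seed=%d)", report$seed),
             sprintf("classes: %s",
                     paste(names(report$stages$translation_state),
                           unlist(report$stages$translation_state),
                           sep = "=", collapse = " ")))
  for (cls in names(report$forest)) {
    f <- report$forest[[cls]]
    if (!is.null(f$skipped)) {
      lines <- c(lines, sprintf("[%s] skipped: %s", cls, f$skipped))
      next
    }
    top3 <- f$importance[1:3, ]
    lines <- c(lines,
      sprintf("[%s] TP=%d FP=%d TN=%d FN=%d AUC=%.3f",
              cls, f$confusion$TP, f$confusion$FP, f$confusion$TN,
              f$confusion$FN, f$auc),
      sprintf("  top3: %s",
              paste(sprintf("%s (%s)", top3$feature, top3$effect),
                    collapse = ", ")))
  }
  if (is.null(report$enrichment$coassociation))
    lines <- c(lines, "[enrichment] skipped")
  writeLines(lines, txt)
  invisible(path)
}
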