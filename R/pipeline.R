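#' Verification percentages stratified by support and length
#'
#' The anti-contamination argument: if candidate HGT transcripts were
#' host contamination they would not be recoverable from the parasite's
#' genomic reads, so their verification percentage should fall below the
#' VGT percentage — overall and within every bootstrap-support and
#' transcript-length stratum. This function builds those tables.
#'
#' @param verification Data.frame from \code{\link{verifyTranscripts}}.
#' @param classifications Data.frame from \code{\link{classifyAll}}.
#' @param lengths Named integer vector of transcript lengths.
#' @param supportBins Breaks for support bins (default decade bins
#'   50..100).
#' @param lengthQuantiles Number of length strata (default 4).
#' @return List of two data.frames, \code{bySupport} and \code{byLength},
#'   each with category, bin, n, nVerified, percent (NA for empty bins).
#' @export
reportVerificationStratified <- function(verification, classifications,
                                         lengths,
                                         supportBins = seq(50, 100, by = 10),
                                         lengthQuantiles = 4) {
  m <- merge(verification,
             classifications[c("transcript", "category", "support")],
             by = "transcript")
  m <- m[m$category %in% c("VGT", "HGT"), , drop = FALSE]
  m$length <- unname(lengths[m$transcript])
  sBin <- cut(m$support, breaks = supportBins, right = FALSE,
              include.lowest = TRUE)
  qs <- unique(stats::quantile(m$length,
                               probs = seq(0, 1, length.out =
                                             lengthQuantiles + 1)))
  lBin <- cut(m$length, breaks = qs, include.lowest = TRUE)
  tab <- function(bin) {
    do.call(rbind, lapply(levels(bin), function(b) {
      do.call(rbind, lapply(c("VGT", "HGT"), function(cat) {
        idx <- !is.na(bin) & bin == b & m$category == cat
        n <- sum(idx); v <- sum(m$verified[idx])
        data.frame(category = cat, bin = b, n = n, nVerified = v,
                   percent = if (n) 100 * v / n else NA_real_,
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  list(bySupport = tab(sBin), byLength = tab(lBin))
}

#' Run the full analysis pipeline on a simulated study
#'
#' Orchestrates simulate -> classify (parasite, host side and
#' control-taxon backgrounds, plus the threshold sweep) -> verify
#' (fragment mapping, stratified tables, introns, divergence) -> express
#' -> rates -> coding affinity, and assembles one report. Each stage is
#' executed in dependency order; a failure aborts with the failing stage
#' named.
#'
#' @param cfg A \code{\link{simulationConfig}}.
#' @param classifier A \code{\link{classifierConfig}} (default: parasite
#'   side).
#' @param outDir Optional directory; when given, all tables are written
#'   there as TSV/JSON together with a run manifest.
#' @param sim Optional pre-built study (from \code{\link{simulateStudy}});
#'   when supplied, \code{cfg} is ignored for generation.
#' @return A list report with elements \code{classification},
#'   \code{sweep}, \code{controls}, \code{rates}, \code{verification},
#'   \code{stratified}, \code{introns}, \code{divergence},
#'   \code{expression}, \code{coding} and \code{truth}.
#' @export
runPipeline <- function(cfg = simulationConfig(),
                        classifier = classifierConfig(),
                        outDir = NULL, sim = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  sim <- stage("simulate", sim %||% simulateStudy(cfg))
  k <- sim$config@fragmentSize
  l <- sim$config@readLength

  cls <- stage("classify", classifyAll(sim$clusters, classifier))
  sweep <- stage("classify",
                 sweepThresholds(cls$classifications, classifier))
  controls <- stage("classify", lapply(
    stats::setNames(, c("Manihot", "Ricinus")), function(g)
      classifyAll(sim$clusters,
                  controlConfig(g, bsThreshold = classifier@bsThreshold))))

  filtered <- filterClusters(sim$clusters, classifier)
  rates <- stage("rates",
                 compareRates(cls$classifications, filtered, classifier))

  focalTx <- stage("verify", {
    if (is.null(sim$transcripts))
      stop("transcripts missing (simulate with sequences = TRUE, or ",
           "supply a transcripts FASTA)")
    sim$transcripts[names(sim$transcripts) %in%
                      cls$classifications$transcript]
  })
  verification <- stage("verify",
                        verifyTranscripts(focalTx, sim$gdnaReads, k = k))
  lengths <- stats::setNames(Biostrings::width(sim$transcripts),
                             names(sim$transcripts))
  stratified <- stage("verify",
                      reportVerificationStratified(verification,
                                                   cls$classifications,
                                                   lengths))
  introns <- stage("verify", detectIntrons(sim$gdnaReads, focalTx, k = k))
  divergence <- stage("verify", .hgtHostDivergence(sim, cls))

  N <- stage("express", countMappedReads(sim$cdnaReads, focalTx, k = k))
  exprRec <- stage("express", if (sum(N) > 0)
    expressionRecords(N, lengths, k = k, l = k) else NULL)
  exprCmp <- stage("express", if (!is.null(exprRec))
    compareExpression(exprRec, cls$classifications) else NULL)

  coding <- stage("coding", .codingStage(sim, cls, exprRec))

  report <- list(config = sim$config, classification = cls, sweep = sweep,
                 controls = lapply(controls, `[[`, "summary"),
                 rates = rates, verification = verification,
                 stratified = stratified, introns = introns,
                 divergence = divergence,
                 expression = list(records = exprRec,
                                   comparison = exprCmp),
                 coding = coding, truth = sim$truth)
  if (!is.null(outDir)) .writeReport(report, outDir)
  report
}

# Divergence between each classified-HGT parasite transcript and the host
# clade member of the same cluster, when present.
.hgtHostDivergence <- function(sim, cls) {
  hgtIds <- cls$classifications$transcript[
    cls$classifications$category == "HGT"]
  rows <- list()
  for (id in hgtIds) {
    cid <- sub("_[^_]+$", "", id)
    host <- paste0(cid, "_Tetrastigma")
    partner <- if (host %in% names(sim$transcripts)) host
               else paste0(cid, "_Vitis")
    if (!(partner %in% names(sim$transcripts))) next
    rows[[length(rows) + 1L]] <- data.frame(
      transcript = id, partner = partner,
      divergence = pairwiseDivergence(sim$transcripts[[id]],
                                      sim$transcripts[[partner]]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(transcript = character(), partner = character(),
                      divergence = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# Coding-property stage: affinity of focal VGTs and of the two control
# genomes' transcripts, host-like rates, exact binomial test (null = the
# larger control rate) and the expression-affinity correlation.
.codingStage <- function(sim, cls, exprRec) {
  vgtIds <- cls$classifications$transcript[
    cls$classifications$category == "VGT"]
  focalCalls <- affinityCalls(sim$clusters, vgtIds)
  controlCalls <- lapply(stats::setNames(, c("Manihot", "Ricinus")),
    function(g) {
      rel <- setdiff(c("Manihot", "Ricinus"), g)
      ids <- unlist(lapply(sim$clusters, function(cl)
        names(genomeOf(cl))[genomeOf(cl) == g]))
      affinityCalls(sim$clusters, ids, relativeSide = rel)
    })
  rates <- affinityRates(c(list(focal = focalCalls), controlCalls))
  ctrl <- rates$hostLikePercent[rates$genome %in% c("Manihot", "Ricinus")]
  p0 <- max(ctrl, na.rm = TRUE) / 100
  binom <- if (nrow(focalCalls) && p0 > 0 && p0 < 1)
    list(k = sum(focalCalls$label == "host-like"), n = nrow(focalCalls),
         p0 = p0,
         p = exactBinomialTest(sum(focalCalls$label == "host-like"),
                               nrow(focalCalls), p0))
    else NULL
  corr <- if (!is.null(exprRec) && nrow(focalCalls) >= 3)
    tryCatch(expressionAffinityCorrelation(focalCalls, exprRec),
             error = function(e) NULL) else NULL
  list(focalCalls = focalCalls, controlCalls = controlCalls,
       rates = rates, binomial = binom, correlation = corr)
}

.writeReport <- function(report, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeTSV(report$classification$classifications,
           file.path(outDir, "classifications.tsv"))
  writeTSV(report$classification$summary,
           file.path(outDir, "classification_summary.tsv"))
  writeTSV(report$sweep, file.path(outDir, "threshold_sweep.tsv"))
  writeTSV(report$verification, file.path(outDir, "verification.tsv"))
  writeTSV(report$introns, file.path(outDir, "intron_calls.tsv"))
  writeTSV(report$divergence, file.path(outDir, "divergence.tsv"))
  if (!is.null(report$expression$records))
    writeTSV(report$expression$records, file.path(outDir, "expression.tsv"))
  writeTSV(report$coding$rates, file.path(outDir, "affinity_rates.tsv"))
  manifest <- list(
    seed = report$config@seed,
    nClusters = report$config@nClusters,
    rateProxy = report$rates$rateProxy,
    files = list.files(outDir),
    rows = list(classifications =
                  nrow(report$classification$classifications),
                verification = nrow(report$verification),
                introns = nrow(report$introns)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}
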