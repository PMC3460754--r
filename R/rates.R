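#' Terminal branch length of a tip (substitution-rate proxy)
#'
#' The rate proxy used throughout is the focal tip's terminal branch
#' length from the per-cluster tree (substitutions/site). Root-to-tip
#' distance is available via \code{rootToTip = TRUE}; every report states
#' which proxy was used.
#'
#' @param st A \code{SupportTree} with branch lengths.
#' @param tip Tip label.
#' @param rootToTip Use the root-to-tip path length instead (requires a
#'   rooted tree).
#' @return Non-negative numeric.
#' @export
extractRate <- function(st, tip, rootToTip = FALSE) {
  phy <- treePhylo(st)
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  ti <- match(tip, phy$tip.label)
  if (is.na(ti)) stop("tip not in tree: ", tip)
  if (!rootToTip)
    return(phy$edge.length[match(ti, phy$edge[, 2])])
  if (!ape::is.rooted(phy)) stop("root-to-tip distance needs a rooted tree")
  ntip <- length(phy$tip.label)
  d <- 0; nd <- ti
  while (nd != ntip + 1L) {
    e <- match(nd, phy$edge[, 2])
    d <- d + phy$edge.length[e]
    nd <- phy$edge[e, 1]
  }
  d
}

#' Welch's two-sample t test
#'
#' Unequal-variance t test:
#' t = (mean_a - mean_b) / sqrt(s2_a/n_a + s2_b/n_b), with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#' Computed via \code{stats::t.test(var.equal = FALSE)}. The degenerate
#' case of two constant, equal samples is defined as t = 0, p = 1.
#'
#' @param a,b Numeric vectors (each length >= 2, finite variance).
#' @return List with \code{t}, \code{df}, \code{p}.
#' @export
welchTTest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 observations")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    stop("both variances are zero with unequal means; t is infinite")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Compare substitution rates between HGT and VGT transcripts
#'
#' Builds per-transcript rate records (terminal branch lengths of the
#' focal tip and of its homologous sister-lineage tips) and reports
#' boxplot-style group summaries plus Welch tests: focal HGT vs focal
#' VGT, and focal vs partner within each category. The partner rate is
#' the mean terminal branch length over the sister-set tips belonging to
#' the category's reference genomes.
#'
#' @param classifications Data.frame from \code{\link{classifyAll}}.
#' @param clusters The (filtered) cluster list the classifications came
#'   from.
#' @param cfg The \code{\link{classifierConfig}} used.
#' @return List with \code{records} (transcript, category, rate,
#'   partnerRate), \code{summaries} (n, median, q1, q3 per group),
#'   \code{tests} (list of Welch results; comparisons with a group of
#'   < 2 members are skipped with a log message) and \code{rateProxy}.
#' @export
compareRates <- function(classifications, clusters, cfg) {
  byId <- stats::setNames(clusters,
                          vapply(clusters, clusterId, character(1)))
  rows <- list()
  resolved <- classifications[classifications$category %in% c("VGT", "HGT"), ]
  for (i in seq_len(nrow(resolved))) {
    r <- resolved[i, ]
    cl <- byId[[r$cluster]]
    if (is.null(cl)) next
    st <- clusterTree(cl)
    rate <- extractRate(st, r$transcript)
    partnerGenomes <- if (r$category == "HGT") cfg@transferSet
                      else cfg@relativeSet
    tg <- tipGenome(st)
    sisters <- intersect(strsplit(r$sisterGenomes, ",")[[1]], partnerGenomes)
    partnerTips <- names(tg)[tg %in% sisters]
    partnerRate <- if (length(partnerTips))
      mean(vapply(partnerTips, function(tp) extractRate(st, tp),
                  numeric(1))) else NA_real_
    rows[[length(rows) + 1L]] <-
      data.frame(transcript = r$transcript, category = r$category,
                 rate = rate, partnerRate = partnerRate,
                 stringsAsFactors = FALSE)
  }
  records <- if (length(rows)) do.call(rbind, rows)
    else data.frame(transcript = character(), category = character(),
                    rate = numeric(), partnerRate = numeric())
  summaries <- do.call(rbind, lapply(split(records$rate, records$category),
    function(x) data.frame(n = length(x), median = stats::median(x),
                           q1 = unname(stats::quantile(x, 0.25)),
                           q3 = unname(stats::quantile(x, 0.75)))))
  tests <- list()
  hgt <- records$rate[records$category == "HGT"]
  vgt <- records$rate[records$category == "VGT"]
  if (length(hgt) >= 2 && length(vgt) >= 2)
    tests$hgt_vs_vgt <- welchTTest(hgt, vgt)
  else .log("rates", "HGT-vs-VGT comparison skipped: a group has < 2 members")
  for (cat in c("HGT", "VGT")) {
    sub <- records[records$category == cat & !is.na(records$partnerRate), ]
    nm <- paste0(tolower(cat), "_vs_partner")
    if (nrow(sub) >= 2)
      tests[[nm]] <- welchTTest(sub$rate, sub$partnerRate)
    else .log("rates", nm, " skipped: fewer than 2 paired records")
  }
  list(records = records, summaries = summaries, tests = tests,
       rateProxy = "terminal branch length")
}
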