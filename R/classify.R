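#' Filter clusters by the taxon-retention rule
#'
#' A cluster is retained iff its genome set contains the outgroup (needed
#' for rooting), the focal taxon, at least one member of the relative set
#' and at least one member of the transfer set.
#'
#' @param clusters List of \code{GeneCluster}.
#' @param cfg A \code{\link{classifierConfig}}.
#' @return The retained sublist (possibly empty).
#' @export
filterClusters <- function(clusters, cfg) {
  keep <- vapply(clusters, function(cl) {
    g <- unique(genomeOf(cl))
    cfg@outgroup %in% g && cfg@focalTaxon %in% g &&
      any(cfg@relativeSet %in% g) && any(cfg@transferSet %in% g)
  }, logical(1))
  clusters[keep]
}

#' Root a gene tree on the outgroup
#'
#' Places the root on the edge subtending the smallest clade containing
#' all outgroup tips, preserving branch lengths and support labels
#' (supports travel with their edges). When the outgroup tips are not
#' monophyletic in the unrooted tree, the root is placed on the edge whose
#' one side maximizes outgroup tips while minimizing non-outgroup tips,
#' and the result is flagged \code{outgroupConflict}.
#'
#' @param st A \code{SupportTree}.
#' @param cfg A \code{\link{classifierConfig}} (supplies the outgroup
#'   genome).
#' @return A rooted \code{SupportTree}; check
#'   \code{st@meta$outgroupConflict}.
#' @export
rootOnOutgroup <- function(st, cfg) {
  phy <- treePhylo(st)
  tg <- tipGenome(st)
  ogTips <- names(tg)[tg == cfg@outgroup]
  if (!length(ogTips))
    stop("no outgroup (", cfg@outgroup, ") tip in tree")
  rooted <- tryCatch(
    ape::root(phy, outgroup = ogTips, resolve.root = TRUE,
              edgelabel = TRUE),
    error = function(e) NULL)
  conflict <- is.null(rooted)
  if (conflict)
    rooted <- .rootMaxOutgroupSide(phy, ogTips)
  meta <- st@meta
  meta$outgroupConflict <- conflict
  SupportTree(rooted, tg, meta = meta)
}

# Fallback rooting for non-monophyletic outgroups: score every candidate
# clade S by (#outgroup in S) - (#non-outgroup in S), over both sides of
# each edge, and root at the best-scoring node.
.rootMaxOutgroupSide <- function(phy, ogTips) {
  ntip <- length(phy$tip.label)
  ogIdx <- match(ogTips, phy$tip.label)
  nodes <- setdiff(phy$edge[, 2], ntip + 1L)
  best <- NULL; bestScore <- -Inf
  for (nd in nodes) {
    tips <- if (nd <= ntip) nd
            else phangorn::Descendants(phy, nd, "tips")[[1]]
    inS <- length(intersect(tips, ogIdx))
    s1 <- inS - (length(tips) - inS)                       # clade side
    s2 <- (length(ogIdx) - inS) -
      ((ntip - length(tips)) - (length(ogIdx) - inS))      # complement
    sc <- max(s1, s2)
    if (sc > bestScore) { bestScore <- sc; best <- nd }
  }
  if (best <= ntip)
    ape::root(phy, outgroup = phy$tip.label[best], resolve.root = TRUE,
              edgelabel = TRUE)
  else
    ape::root(phy, node = best, resolve.root = TRUE, edgelabel = TRUE)
}

#' Classify one focal tip from its sister group and support
#'
#' Ascends from the tip to the first ancestor whose other descendants
#' include at least one non-focal-taxon tip (other focal tips, e.g.
#' in-paralogs, are treated as part of the focal lineage and skipped).
#' The sister set is the genome set of those non-focal tips; the support
#' is the bootstrap of the edge subtending that ancestor (absent when the
#' ancestor is the root). The call is VGT when the sister set lies within
#' the relative set with support >= threshold, HGT when it lies within
#' the transfer set with support >= threshold, otherwise unassigned.
#' Polytomies are allowed: a polytomous sister set is evaluated as a
#' whole.
#'
#' @param st A rooted \code{SupportTree}.
#' @param tip Tip label of the focal transcript.
#' @param cfg A \code{\link{classifierConfig}}.
#' @return A one-row data.frame: \code{transcript}, \code{category}
#'   ("VGT"/"HGT"/"unassigned"), \code{rule} (the rule matched ignoring
#'   support: "VGT", "HGT" or "none"), \code{sisterGenomes}
#'   (comma-separated), \code{support} (NA when absent).
#' @export
classifyTip <- function(st, tip, cfg) {
  phy <- treePhylo(st)
  if (!ape::is.rooted(phy)) stop("tree must be rooted; see rootOnOutgroup()")
  tg <- tipGenome(st)
  ti <- match(tip, phy$tip.label)
  if (is.na(ti)) stop("tip not in tree: ", tip)
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  sup <- nodeSupports(st)
  node <- phy$edge[match(ti, phy$edge[, 2]), 1]
  prevTips <- ti
  nonfocal <- integer()
  repeat {
    cl <- phangorn::Descendants(phy, node, type = "tips")[[1]]
    sisterTips <- setdiff(cl, prevTips)
    nonfocal <- sisterTips[tg[phy$tip.label[sisterTips]] != cfg@focalTaxon]
    if (length(nonfocal) || node == root) break
    prevTips <- cl
    node <- phy$edge[match(node, phy$edge[, 2]), 1]
  }
  sisterGenomes <- sort(unique(unname(tg[phy$tip.label[nonfocal]])))
  support <- if (node == root) NA_real_ else sup[node - ntip]
  rule <- if (!length(sisterGenomes)) "none"
          else if (all(sisterGenomes %in% cfg@relativeSet)) "VGT"
          else if (all(sisterGenomes %in% cfg@transferSet)) "HGT"
          else "none"
  category <- if (rule != "none" && !is.na(support) &&
                  support >= cfg@bsThreshold) rule else "unassigned"
  data.frame(transcript = tip, category = category, rule = rule,
             sisterGenomes = paste(sisterGenomes, collapse = ","),
             support = support, stringsAsFactors = FALSE)
}

#' Classify every focal transcript in a set of clusters
#'
#' Applies the retention filter, roots each gene tree on the outgroup and
#' classifies each focal-taxon tip as VGT, HGT or unassigned.
#'
#' @param clusters List of \code{GeneCluster} (with trees).
#' @param cfg A \code{\link{classifierConfig}}.
#' @param prefiltered Set TRUE if \code{\link{filterClusters}} was already
#'   applied.
#' @return A list: \code{classifications} (one row per focal transcript,
#'   with \code{cluster} and \code{outgroupConflict} columns added) and
#'   \code{summary} (counts and percentages per category; denominator =
#'   all observed focal transcripts).
#' @export
classifyAll <- function(clusters, cfg, prefiltered = FALSE) {
  if (!prefiltered) clusters <- filterClusters(clusters, cfg)
  rows <- list()
  for (cl in clusters) {
    st <- clusterTree(cl)
    if (is.null(st)) next
    rooted <- rootOnOutgroup(st, cfg)
    tg <- tipGenome(rooted)
    focalTips <- names(tg)[tg == cfg@focalTaxon]
    for (tip in focalTips) {
      r <- classifyTip(rooted, tip, cfg)
      r$cluster <- clusterId(cl)
      r$outgroupConflict <- isTRUE(rooted@meta$outgroupConflict)
      rows[[length(rows) + 1L]] <- r
    }
  }
  classifications <- if (length(rows)) do.call(rbind, rows)
    else data.frame(transcript = character(), category = character(),
                    rule = character(), sisterGenomes = character(),
                    support = numeric(), cluster = character(),
                    outgroupConflict = logical())
  n <- nrow(classifications)
  counts <- table(factor(classifications$category,
                         levels = c("VGT", "HGT", "unassigned")))
  summary <- data.frame(category = names(counts),
                        count = as.integer(counts),
                        percent = if (n) 100 * as.integer(counts) / n
                                  else NA_real_,
                        denominator = n, stringsAsFactors = FALSE)
  list(classifications = classifications, summary = summary)
}

#' Sweep the bootstrap threshold
#'
#' Re-evaluates the classification at several bootstrap thresholds and
#' reports, for each, the HGT percentage among resolved transcripts
#' (HGT / (HGT + VGT)); clusters are classified once and thresholded
#' post hoc, which is equivalent to re-running the classifier.
#'
#' @param clusters List of \code{GeneCluster}, or the
#'   \code{classifications} data.frame from \code{\link{classifyAll}}.
#' @param cfg A \code{\link{classifierConfig}}.
#' @param thresholds Integer vector of thresholds (default 50..70 by 5).
#' @return A data.frame: \code{threshold}, \code{nResolved}, \code{nHGT},
#'   \code{hgtPercent} (NA when nothing is resolved at that threshold).
#' @export
sweepThresholds <- function(clusters, cfg,
                            thresholds = c(50, 55, 60, 65, 70)) {
  stopifnot(all(thresholds >= 0 & thresholds <= 100))
  cls <- if (is.data.frame(clusters)) clusters
         else classifyAll(clusters, cfg)$classifications
  out <- lapply(thresholds, function(tau) {
    resolved <- cls$rule != "none" & !is.na(cls$support) &
      cls$support >= tau
    nRes <- sum(resolved)
    nHGT <- sum(resolved & cls$rule == "HGT")
    data.frame(threshold = tau, nResolved = nRes, nHGT = nHGT,
               hgtPercent = if (nRes) 100 * nHGT / nRes else NA_real_)
  })
  do.call(rbind, out)
}
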