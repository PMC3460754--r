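#' Coding-property profile of a transcript
#'
#' Converts a coding sequence into 4 nucleotide frequencies, 16
#' dinucleotide frequencies (overlapping) and 61 codon frequencies (frame
#' 0, stop codons TAA/TAG/TGA excluded from numerator and denominator; a
#' trailing partial codon is dropped). Each block is normalized to sum to
#' 1; windows containing N are excluded from all counts.
#'
#' @param seq Character string or \code{DNAString}.
#' @param jointNormalize Normalize the concatenated 81-vector jointly
#'   instead of per block (default FALSE; the per-block form makes the
#'   blocks contribute comparably to profile distances).
#' @return Named numeric vector of length 81 (names prefixed
#'   \code{nt_}, \code{di_}, \code{cod_}).
#' @export
#' @examples
#' profileTranscript("ACGACG")
profileTranscript <- function(seq, jointNormalize = FALSE) {
  s <- toupper(as.character(seq))
  if (!nchar(s)) stop("empty sequence")
  x <- Biostrings::DNAString(s)
  nt <- Biostrings::oligonucleotideFrequency(x, 1)[c("A", "C", "G", "T")]
  if (sum(nt) == 0) stop("sequence contains no A/C/G/T bases")
  di <- Biostrings::oligonucleotideFrequency(x, 2)
  cod <- Biostrings::oligonucleotideFrequency(x, 3, step = 3)
  cod <- cod[.senseCodons()]
  if (sum(cod) == 0)
    stop("no complete sense codon in frame 0 (coding length < 3?)")
  norm <- function(v) if (sum(v) > 0) v / sum(v) else v
  out <- if (jointNormalize) {
    v <- c(nt, di, cod); v / sum(v)
  } else c(norm(nt), norm(di), norm(cod))
  names(out) <- c(paste0("nt_", c("A", "C", "G", "T")),
                  paste0("di_", names(di)),
                  paste0("cod_", .senseCodons()))
  out
}

#' Chi-squared distance between two frequency profiles
#'
#' d(p, q) = sum_i (p_i - q_i)^2 / (p_i + q_i), skipping features where
#' p_i + q_i = 0. A symmetric non-negative premetric with d(p, p) = 0.
#'
#' @param p,q Numeric vectors of equal length.
#' @return Non-negative numeric.
#' @export
chi2Distance <- function(p, q) {
  if (length(p) != length(q)) stop("profiles must have equal length")
  s <- p + q
  keep <- s > 0
  sum((p[keep] - q[keep])^2 / s[keep])
}

#' Assign a focal transcript a host-like or relative-like affinity
#'
#' Computes the smallest chi-squared distance from the focal profile to
#' each comparison side within the cluster (for a parasite transcript:
#' Malpighiales side = Manihot/Ricinus homologues, host side = Vitis) and
#' labels the transcript by the closer side. Ties classify as
#' relative-side (conservative against the convergence claim).
#'
#' @param focalProfile 81-vector from \code{\link{profileTranscript}}.
#' @param profilesByGenome Named list genome -> list of profiles of that
#'   genome's homologues in the cluster.
#' @param relativeSide Genomes of the relative (Malpighiales) side
#'   (default Manihot/Ricinus; Populus is excluded by default, matching
#'   the comparison's focus on the two closest relatives — include it by
#'   passing it here).
#' @param hostSide Genomes of the host side (default Vitis).
#' @return One-row data.frame: \code{nearestGenome},
#'   \code{nearestDistance}, \code{margin} (smallest relative-side minus
#'   smallest host-side distance; positive = host-like), \code{label}
#'   ("host-like"/"relative-like"); or NULL (with a log message) when a
#'   side has no homologue in the cluster.
#' @export
classifyAffinity <- function(focalProfile, profilesByGenome,
                             relativeSide = c("Manihot", "Ricinus"),
                             hostSide = "Vitis") {
  dRelAll <- unlist(lapply(relativeSide, function(g)
    vapply(profilesByGenome[[g]] %||% list(), chi2Distance, numeric(1),
           p = focalProfile)))
  dHostAll <- unlist(lapply(hostSide, function(g)
    vapply(profilesByGenome[[g]] %||% list(), chi2Distance, numeric(1),
           p = focalProfile)))
  if (!length(dRelAll) || !length(dHostAll)) {
    .log("coding", "cluster lacks a homologue on one comparison side; ",
         "transcript excluded")
    return(NULL)
  }
  dRel <- min(dRelAll); dHost <- min(dHostAll)
  margin <- dRel - dHost
  all <- c(dRelAll, dHostAll)
  sides <- c(rep(relativeSide, times = vapply(relativeSide, function(g)
               length(profilesByGenome[[g]] %||% list()), integer(1))),
             rep(hostSide, times = vapply(hostSide, function(g)
               length(profilesByGenome[[g]] %||% list()), integer(1))))
  data.frame(nearestGenome = sides[which.min(all)],
             nearestDistance = min(all), margin = margin,
             label = if (margin > 0) "host-like" else "relative-like",
             stringsAsFactors = FALSE)
}

#' Affinity calls for every focal VGT transcript in a cluster set
#'
#' Builds coding profiles for all cluster members and calls
#' \code{\link{classifyAffinity}} for each focal transcript of interest.
#'
#' @param clusters List of \code{GeneCluster} with member sequences.
#' @param transcriptIds Focal transcript ids to call (e.g. the VGT set
#'   from the classifier).
#' @param relativeSide,hostSide See \code{\link{classifyAffinity}}.
#' @return Data.frame with one row per callable transcript:
#'   \code{transcript}, \code{cluster}, \code{nearestGenome},
#'   \code{nearestDistance}, \code{margin}, \code{label}.
#' @export
affinityCalls <- function(clusters, transcriptIds,
                          relativeSide = c("Manihot", "Ricinus"),
                          hostSide = "Vitis") {
  rows <- list()
  for (cl in clusters) {
    g <- genomeOf(cl)
    members <- clusterMembers(cl)
    ids <- intersect(transcriptIds, names(members))
    if (!length(ids)) next
    sideGenomes <- c(relativeSide, hostSide)
    profs <- list()
    for (m in names(members)) {
      if (!(g[[m]] %in% sideGenomes)) next
      profs[[g[[m]]]] <- c(profs[[g[[m]]]],
                           list(profileTranscript(members[[m]])))
    }
    for (id in ids) {
      fp <- profileTranscript(members[[id]])
      call <- classifyAffinity(fp, profs, relativeSide, hostSide)
      if (is.null(call)) next
      call$transcript <- id
      call$cluster <- clusterId(cl)
      rows[[length(rows) + 1L]] <- call
    }
  }
  if (!length(rows))
    return(data.frame(transcript = character(), cluster = character(),
                      nearestGenome = character(),
                      nearestDistance = numeric(), margin = numeric(),
                      label = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[c("transcript", "cluster", "nearestGenome", "nearestDistance",
        "margin", "label")]
}

#' Host-like percentage per focal genome
#'
#' @param callsByGenome Named list genome -> affinity-call data.frame
#'   (from \code{\link{affinityCalls}}).
#' @return Data.frame: \code{genome}, \code{nHostLike}, \code{n},
#'   \code{hostLikePercent} (NA, not zero, for an empty call set).
#' @export
affinityRates <- function(callsByGenome) {
  do.call(rbind, lapply(names(callsByGenome), function(g) {
    calls <- callsByGenome[[g]]
    n <- nrow(calls)
    kk <- sum(calls$label == "host-like")
    data.frame(genome = g, nHostLike = kk, n = n,
               hostLikePercent = if (n) 100 * kk / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Exact binomial upper-tail test
#'
#' p = sum_{j=k}^{n} C(n, j) p0^j (1 - p0)^(n-j), computed from the exact
#' binomial distribution function.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials.
#' @param p0 Null success proportion in (0, 1).
#' @return The upper-tail p-value.
#' @export
#' @examples
#' exactBinomialTest(2, 2, 0.5)   # 0.25
exactBinomialTest <- function(k, n, p0) {
  if (n < 0 || k < 0 || k > n) stop("need 0 <= k <= n")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0,1)")
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Rank correlation between expression and host-affinity
#'
#' Spearman correlation between RPKM and the affinity margin (larger
#' margin = more host-like coding properties).
#'
#' @param calls Affinity-call data.frame (with \code{margin}).
#' @param records Expression records (with \code{RPKM}).
#' @return List with \code{rho}, \code{p}, \code{n}; \code{rho} is NA
#'   (flagged in \code{note}) when all margins or all RPKM are tied.
#' @export
expressionAffinityCorrelation <- function(calls, records) {
  m <- merge(calls[c("transcript", "margin")],
             records[c("transcript", "RPKM")], by = "transcript")
  if (nrow(m) < 3) stop("need at least 3 transcripts with both values")
  if (length(unique(m$margin)) == 1 || length(unique(m$RPKM)) == 1)
    return(list(rho = NA_real_, p = NA_real_, n = nrow(m),
                note = "all values tied; correlation undefined"))
  ct <- suppressWarnings(stats::cor.test(m$margin, m$RPKM,
                                         method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(m))
}
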