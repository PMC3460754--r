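#' Count cDNA reads mapping onto each transcript
#'
#' A read counts toward a transcript iff at least one of its k bp
#' fragments matches that transcript exactly (forward or reverse
#' complement). A read matching several transcripts counts once toward
#' each (no fractional assignment).
#'
#' @param cdnaReads Named \code{DNAStringSet} of cDNA reads.
#' @param transcripts Named \code{DNAStringSet}.
#' @param k Fragment size / minimum overlap (default 25).
#' @return Named integer vector N, one entry per transcript.
#' @export
countMappedReads <- function(cdnaReads, transcripts, k = 25) {
  frags <- .fragmentReads(cdnaReads, k)
  hits <- mapFragments(frags, transcripts)
  N <- stats::setNames(integer(length(transcripts)), names(transcripts))
  if (!nrow(hits)) return(N)
  readOf <- sub("\\|[0-9]+$", "", hits$fragment)
  pairs <- unique(data.frame(read = readOf, transcript = hits$transcript,
                             stringsAsFactors = FALSE))
  counts <- table(factor(pairs$transcript, levels = names(transcripts)))
  N[] <- as.integer(counts)
  N
}

#' Overlap-window read-count normalization
#'
#' R = N / (L - k + 1 + l - k): the mapped-read count divided by the
#' number of distinct positions at which a read of length l can overlap a
#' transcript of length L by at least k bases.
#'
#' @param N Mapped-read count (non-negative integer, vectorized).
#' @param L Transcript length in bp.
#' @param k Minimum overlap in bp (default 25).
#' @param l Read length used in mapping (default 25).
#' @return R (non-negative numeric).
#' @export
#' @examples
#' eq1Normalize(100, 500)   # 100/476
eq1Normalize <- function(N, L, k = 25, l = 25) {
  denom <- L - k + 1 + l - k
  if (any(denom <= 0))
    stop(sprintf("non-positive denominator: L=%s, k=%s, l=%s",
                 paste(L[denom <= 0], collapse = ","), k, l))
  N / denom
}

#' Build per-transcript expression records (R and RPKM)
#'
#' Computes the overlap-window value R for every transcript and the
#' standard RPKM, RPKM_t = 1e9 * N_t / (L_t * sum(N)), from the raw
#' counts. Both columns are emitted so either normalization convention is
#' inspectable.
#'
#' @param N Named integer vector of mapped-read counts (from
#'   \code{\link{countMappedReads}}).
#' @param lengths Named integer vector of transcript lengths (bp).
#' @param k Minimum overlap (default 25).
#' @param l Read length used in mapping (default 25).
#' @return Data.frame: \code{transcript}, \code{N}, \code{L}, \code{R},
#'   \code{RPKM}.
#' @export
expressionRecords <- function(N, lengths, k = 25, l = 25) {
  stopifnot(all(names(N) %in% names(lengths)))
  L <- as.numeric(unname(lengths[names(N)]))
  total <- sum(as.numeric(N))
  if (total == 0) stop("no mapped reads: RPKM undefined")
  data.frame(transcript = names(N), N = as.integer(unname(N)), L = L,
             R = eq1Normalize(as.numeric(unname(N)), L, k, l),
             RPKM = 1e9 * as.numeric(unname(N)) / (L * total),
             stringsAsFactors = FALSE)
}

#' Compare expression levels between HGT and VGT transcripts
#'
#' Boxplot-style summaries (n, median, quartiles) of RPKM per category,
#' plus a Welch t test on log2(RPKM + 1).
#'
#' @param records Data.frame from \code{\link{expressionRecords}}.
#' @param classifications Data.frame from \code{\link{classifyAll}}.
#' @return List with \code{records} (category column added),
#'   \code{summaries} and \code{test} (NULL, with a log message, when a
#'   category has < 2 members).
#' @export
compareExpression <- function(records, classifications) {
  m <- merge(records,
             classifications[c("transcript", "category")],
             by = "transcript")
  m <- m[m$category %in% c("VGT", "HGT"), , drop = FALSE]
  summaries <- do.call(rbind, lapply(split(m$RPKM, m$category),
    function(x) data.frame(n = length(x), median = stats::median(x),
                           q1 = unname(stats::quantile(x, 0.25)),
                           q3 = unname(stats::quantile(x, 0.75)))))
  hgt <- m$RPKM[m$category == "HGT"]
  vgt <- m$RPKM[m$category == "VGT"]
  test <- NULL
  if (length(hgt) >= 2 && length(vgt) >= 2)
    test <- welchTTest(log2(hgt + 1), log2(vgt + 1))
  else .log("expression",
            "HGT-vs-VGT expression comparison skipped: group with < 2 members")
  list(records = m, summaries = summaries, test = test,
       scale = "log2(RPKM + 1)")
}
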