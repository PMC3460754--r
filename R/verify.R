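#' Cut a read into non-overlapping k bp fragments
#'
#' Consecutive k-mers from position 1; a trailing remainder shorter than
#' k is discarded. A 150 bp read with k = 25 yields 6 fragments.
#'
#' @param read A character string or \code{DNAString}.
#' @param k Fragment size (default 25).
#' @return Character vector of fragments (empty when the read is shorter
#'   than k).
#' @export
fragmentRead <- function(read, k = 25) {
  stopifnot(k >= 1)
  read <- as.character(read)
  n <- nchar(read)
  m <- n %/% k
  if (m == 0) {
    .log("verify", "read shorter than k = ", k, "; no fragments")
    return(character())
  }
  starts <- (seq_len(m) - 1L) * k + 1L
  substring(read, starts, starts + k - 1L)
}

# Fragment a whole read set; names become "<read>|<fragmentIndex>" with a
# 0-based fragment index.
.fragmentReads <- function(reads, k) {
  seqs <- as.character(reads)
  out <- character(); nm <- character()
  m <- nchar(seqs) %/% k
  keep <- m > 0
  if (!all(keep))
    .log("verify", sum(!keep), " read(s) shorter than k = ", k, " skipped")
  for (i in which(keep)) {
    starts <- (seq_len(m[i]) - 1L) * k + 1L
    out <- c(out, substring(seqs[i], starts, starts + k - 1L))
    nm <- c(nm, paste0(names(seqs)[i], "|", seq_len(m[i]) - 1L))
  }
  stats::setNames(out, nm)
}

#' Map fragments onto transcripts with zero mismatches
#'
#' Reports every exact occurrence of each fragment (forward and
#' reverse-complement) in each transcript — the zero-mismatch alignment
#' of k-mers is exactly substring search. Fragments containing non-ACGT
#' characters cannot match exactly and are skipped.
#'
#' @param fragments Named character vector or \code{DNAStringSet} of
#'   equal-length fragments (as produced by \code{\link{fragmentRead}}).
#' @param transcripts Named \code{DNAStringSet}.
#' @return Data.frame: \code{fragment} (name), \code{transcript},
#'   \code{offset} (0-based start in the transcript), \code{strand}
#'   ("+"/"-").
#' @export
mapFragments <- function(fragments, transcripts) {
  frags <- if (is.character(fragments)) fragments
           else stats::setNames(as.character(fragments), names(fragments))
  empty <- data.frame(fragment = character(), transcript = character(),
                      offset = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  if (!length(frags)) return(empty)
  ok <- !grepl("[^ACGT]", frags)
  frags <- frags[ok]
  if (!length(frags)) return(empty)
  # search one concatenated subject with an N spacer longer than any
  # fragment: ACGT-only fragments cannot match across transcript
  # boundaries, so global hit coordinates map back uniquely
  txSeqs <- as.character(transcripts)
  maxW <- max(nchar(frags))
  spacer <- strrep("N", maxW + 1L)
  subject <- Biostrings::DNAString(paste(txSeqs, collapse = spacer))
  txStart <- cumsum(c(1L, utils::head(nchar(txSeqs) + maxW + 1L, -1L)))
  txIdxOf <- function(gstart) findInterval(gstart, txStart)
  rows <- list()
  addHits <- function(nm, gstarts, strand) {
    if (!length(gstarts)) return()
    idx <- txIdxOf(gstarts)
    rows[[length(rows) + 1L]] <<- data.frame(
      fragment = nm, transcript = names(transcripts)[idx],
      offset = gstarts - txStart[idx], strand = strand,
      stringsAsFactors = FALSE)
  }
  widths <- unique(nchar(frags))
  for (w in widths) {
    sub <- Biostrings::DNAStringSet(frags[nchar(frags) == w])
    for (strand in c("+", "-")) {
      pats <- if (strand == "+") sub
              else Biostrings::reverseComplement(sub)
      if (length(pats) <= 8) {
        # PDict construction overhead dwarfs the search at this size
        for (j in seq_along(pats)) {
          m <- Biostrings::matchPattern(pats[[j]], subject)
          addHits(names(sub)[j], Biostrings::start(m), strand)
        }
      } else {
        pd <- Biostrings::PDict(pats)
        st <- Biostrings::startIndex(Biostrings::matchPDict(pd, subject))
        nHit <- lengths(st)
        if (sum(nHit))
          addHits(rep(names(sub), nHit), unlist(st[nHit > 0]), strand)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$fragment, out$transcript, out$offset), , drop = FALSE]
}

#' Verify genomic integration of transcripts from gDNA fragment hits
#'
#' A transcript is verified iff at least \code{minHits} gDNA read
#' fragments map exactly onto it.
#'
#' @param transcripts Named \code{DNAStringSet} of (cDNA) transcripts.
#' @param gdnaReads Named \code{DNAStringSet} of genomic reads.
#' @param k Fragment size (default 25).
#' @param minHits Minimum fragment hits for verification (default 1, the
#'   most permissive reading).
#' @return Data.frame: \code{transcript}, \code{nHits}, \code{verified}.
#' @export
verifyTranscripts <- function(transcripts, gdnaReads, k = 25, minHits = 1) {
  frags <- .fragmentReads(gdnaReads, k)
  hits <- mapFragments(frags, transcripts)
  counts <- table(factor(hits$transcript, levels = names(transcripts)))
  data.frame(transcript = names(transcripts),
             nHits = as.integer(counts),
             verified = as.integer(counts) >= minHits,
             stringsAsFactors = FALSE)
}

#' Detect introns from split gDNA reads
#'
#' A genomic read spanning an intron maps in two exact blocks: prefix
#' fragments ending at some cDNA position j and later fragments resuming
#' at cDNA position j + 1, separated by unmapped (intronic) read
#' sequence. Fragment anchors are extended base by base to the exact
#' junction; when the junction is ambiguous (identical bases on either
#' side), the placement whose gap starts with GT and ends with AG is
#' preferred. Reads mapping with only a left (or only a right) anchor and
#' unmapped overhang yield partial calls whose unobserved motif flag is
#' NA.
#'
#' @param reads Named \code{DNAStringSet} of gDNA reads.
#' @param transcripts Named \code{DNAStringSet} of cDNA transcripts.
#' @param k Fragment size (default 25).
#' @param minOverhang Minimum unmapped overhang (bp) for a partial call
#'   (default 8; shorter overhangs are indistinguishable from chance).
#' @return Data.frame: \code{read}, \code{transcript}, \code{junction}
#'   (number of cDNA bases before the intron), \code{gap} (observed
#'   intron sequence, possibly partial), \code{donorOK},
#'   \code{acceptorOK} (NA when that end is unobserved), \code{complete}.
#' @export
detectIntrons <- function(reads, transcripts, k = 25, minOverhang = 8) {
  txSeq <- stats::setNames(as.character(transcripts), names(transcripts))
  frags <- .fragmentReads(reads, k)
  hits <- mapFragments(frags, transcripts)
  hits <- hits[hits$strand == "+", , drop = FALSE]
  if (!nrow(hits)) return(.emptyIntronCalls())
  parts <- strsplit(hits$fragment, "|", fixed = TRUE)
  hits$read <- vapply(parts, function(p)
    paste(p[-length(p)], collapse = "|"), character(1))
  hits$fragIdx <- as.integer(vapply(parts, function(p) p[length(p)],
                                    character(1)))
  readSeqs <- stats::setNames(as.character(reads), names(reads))
  calls <- list()
  for (key in unique(paste(hits$read, hits$transcript, sep = "\r"))) {
    rt <- strsplit(key, "\r", fixed = TRUE)[[1]]
    h <- hits[hits$read == rt[1] & hits$transcript == rt[2], , drop = FALSE]
    call <- .splitReadCall(readSeqs[[rt[1]]], txSeq[[rt[2]]], h, k,
                           minOverhang)
    if (!is.null(call)) {
      call$read <- rt[1]; call$transcript <- rt[2]
      calls[[length(calls) + 1L]] <- call
    }
  }
  if (!length(calls)) return(.emptyIntronCalls())
  out <- do.call(rbind, calls)
  out[c("read", "transcript", "junction", "gap", "donorOK", "acceptorOK",
        "complete")]
}

.emptyIntronCalls <- function() {
  data.frame(read = character(), transcript = character(),
             junction = integer(), gap = character(), donorOK = logical(),
             acceptorOK = logical(), complete = logical(),
             stringsAsFactors = FALSE)
}

# Analyse the colinear fragment blocks of one read against one
# transcript; returns a one-row intron call or NULL.
.splitReadCall <- function(readSeq, txSeq, h, k, minOverhang) {
  # keep, per fragment index, the hit colinear with most other hits:
  # diag = cDNA offset - read offset is constant within a block
  h$readOff <- h$fragIdx * k                 # 0-based read offset
  h$diag <- h$offset - h$readOff
  # a split read shows exactly two diagonals (one per exon block);
  # repeats (a fragment matching at several offsets) are vanishingly
  # rare for 25-mers and resolved by keeping the first hit
  h <- h[!duplicated(h$fragIdx), , drop = FALSE]
  h <- h[order(h$fragIdx), , drop = FALSE]
  blocks <- split(h, h$diag)
  if (length(blocks) == 1) {
    b <- blocks[[1]]
    return(.partialCall(readSeq, txSeq, b, k, minOverhang))
  }
  if (length(blocks) != 2) return(NULL)
  # order blocks by read position
  blocks <- blocks[order(vapply(blocks, function(b) min(b$readOff),
                                numeric(1)))]
  left <- blocks[[1]]; right <- blocks[[2]]
  if (max(left$readOff) >= min(right$readOff)) return(NULL)
  # maximal rightward extension of the left anchor
  rL <- max(left$readOff) + k          # 1-based read pos after last match
  oL <- left$offset[which.max(left$readOff)] + k  # 1-based cDNA pos after
  n <- nchar(readSeq); L <- nchar(txSeq)
  while (rL <= n && oL <= L &&
         substr(readSeq, rL, rL) == substr(txSeq, oL, oL)) {
    rL <- rL + 1L; oL <- oL + 1L
  }
  j <- oL - 1L                         # last matching cDNA base (1-based)
  readExonEnd <- rL - 1L
  # maximal leftward extension of the right anchor
  rR <- min(right$readOff) + 1L        # 1-based read start of block
  oR <- right$offset[which.min(right$readOff)] + 1L
  while (rR > 1 && oR > 1 &&
         substr(readSeq, rR - 1L, rR - 1L) == substr(txSeq, oR - 1L, oR - 1L)) {
    rR <- rR - 1L; oR <- oR - 1L
  }
  # adjacency in cDNA up to junction ambiguity: slack w >= 0
  w <- j - (oR - 1L)
  if (w < 0) return(NULL)
  pick <- NULL
  for (s in 0:w) {                     # retract left extension by s
    e1 <- j - s
    gapStart <- readExonEnd - s + 1L
    gapEnd <- (rR + (e1 + 1L - oR)) - 1L
    if (gapEnd < gapStart) next
    gap <- substr(readSeq, gapStart, gapEnd)
    cand <- list(junction = e1, gap = gap,
                 donorOK = startsWith(gap, "GT"),
                 acceptorOK = endsWith(gap, "AG"))
    if (is.null(pick)) pick <- cand
    if (cand$donorOK && cand$acceptorOK) { pick <- cand; break }
  }
  if (is.null(pick)) return(NULL)
  data.frame(junction = pick$junction, gap = pick$gap,
             donorOK = pick$donorOK, acceptorOK = pick$acceptorOK,
             complete = TRUE, stringsAsFactors = FALSE)
}

# Single-block read with a long unmapped overhang: partial intron call.
.partialCall <- function(readSeq, txSeq, b, k, minOverhang) {
  n <- nchar(readSeq); L <- nchar(txSeq)
  # rightward extension
  rL <- max(b$readOff) + k; oL <- b$offset[which.max(b$readOff)] + k
  while (rL <= n && oL <= L &&
         substr(readSeq, rL, rL) == substr(txSeq, oL, oL)) {
    rL <- rL + 1L; oL <- oL + 1L
  }
  rightOverhang <- n - (rL - 1L)
  # leftward extension
  rR <- min(b$readOff) + 1L; oR <- b$offset[which.min(b$readOff)] + 1L
  while (rR > 1 && oR > 1 &&
         substr(readSeq, rR - 1L, rR - 1L) == substr(txSeq, oR - 1L, oR - 1L)) {
    rR <- rR - 1L; oR <- oR - 1L
  }
  leftOverhang <- rR - 1L
  # an overhang at a transcript end is not evidence of an intron
  if (rightOverhang >= minOverhang && oL <= L) {
    gap <- substr(readSeq, rL, n)
    return(data.frame(junction = oL - 1L, gap = gap,
                      donorOK = startsWith(gap, "GT"),
                      acceptorOK = NA, complete = FALSE,
                      stringsAsFactors = FALSE))
  }
  if (leftOverhang >= minOverhang && oR > 1) {
    gap <- substr(readSeq, 1L, rR - 1L)
    return(data.frame(junction = oR - 1L, gap = gap,
                      donorOK = NA, acceptorOK = endsWith(gap, "AG"),
                      complete = FALSE, stringsAsFactors = FALSE))
  }
  NULL
}

#' Percent sequence divergence between two aligned sequences
#'
#' Globally aligns the two sequences (match +1, mismatch -1, gap -2 per
#' position by default) and reports mismatched columns / aligned non-gap
#' columns x 100.
#'
#' @param a,b Character strings or \code{DNAString}s (non-empty).
#' @param match,mismatch,gap Alignment scores (defaults +1/-1/-2);
#'   reported in output metadata by the pipeline.
#' @return Percent divergence in [0, 100].
#' @export
pairwiseDivergence <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- as.character(a); b <- as.character(b)
  if (!nchar(a) || !nchar(b)) stop("sequences must be non-empty")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = -gap)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  nongap <- pa != "-" & sa != "-"
  if (!sum(nongap)) return(NA_real_)
  100 * sum(pa[nongap] != sa[nongap]) / sum(nongap)
}

#' Alignment score of the divergence aligner (for cross-checks)
#'
#' @inheritParams pairwiseDivergence
#' @return The optimal global alignment score.
#' @export
alignmentScore <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(as.character(a)),
    Biostrings::DNAString(as.character(b)), type = "global",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = -gap)
  Biostrings::score(aln)
}
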