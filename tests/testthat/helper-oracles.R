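# Independent oracles used to cross-check the implementation. These are
# deliberately naive (enumeration, brute force, direct formulas) and share
# no code with the package internals they check.

# Brute-force sister search: enumerate every clade of a rooted tree, take
# the smallest one containing `tip` together with at least one tip of a
# non-focal genome; its non-focal genomes are the sister set and its node
# label the support.
bruteSister <- function(phy, tip, tg, focal) {
  ntip <- length(phy$tip.label)
  ti <- match(tip, phy$tip.label)
  nodes <- (ntip + 1L):(ntip + phy$Nnode)
  best <- NULL; bestSize <- Inf
  for (nd in nodes) {
    tips <- phangorn::Descendants(phy, nd, "tips")[[1]]
    if (!(ti %in% tips)) next
    labs <- phy$tip.label[setdiff(tips, ti)]
    nonfocal <- labs[tg[labs] != focal]
    if (!length(nonfocal)) next
    if (length(tips) < bestSize) { bestSize <- length(tips); best <- nd }
  }
  if (is.null(best)) return(NULL)
  tips <- phangorn::Descendants(phy, best, "tips")[[1]]
  labs <- phy$tip.label[setdiff(tips, ti)]
  nonfocal <- labs[tg[labs] != focal]
  sup <- if (best == ntip + 1L) NA_real_
         else suppressWarnings(as.numeric(phy$node.label[best - ntip]))
  list(sisterGenomes = sort(unique(unname(tg[nonfocal]))), support = sup)
}

# Naive exact substring scan (both strands), 0-based offsets.
naiveScan <- function(frag, txt) {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  hit1 <- integer(); hit2 <- integer()
  k <- nchar(frag); n <- nchar(txt)
  if (k <= n) for (i in 1:(n - k + 1)) {
    w <- substr(txt, i, i + k - 1)
    if (w == frag) hit1 <- c(hit1, i - 1L)
    if (w == rc(frag)) hit2 <- c(hit2, i - 1L)
  }
  list(fwd = hit1, rev = hit2)
}

# Needleman-Wunsch global alignment score by dynamic programming.
nwScore <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- gap * 0:n
  D[1, ] <- gap * 0:m
  for (i in 1:n) for (j in 1:m) {
    s <- if (A[i] == B[j]) match else mismatch
    D[i + 1, j + 1] <- max(D[i, j] + s, D[i, j + 1] + gap,
                           D[i + 1, j] + gap)
  }
  D[n + 1, m + 1]
}

# Exhaustive upper-tail binomial probability by outcome enumeration.
enumBinomUpper <- function(k, n, p0) {
  total <- 0
  for (j in k:n)
    total <- total + choose(n, j) * p0^j * (1 - p0)^(n - j)
  total
}

# Welch's t statistic, degrees of freedom and two-sided p-value from the
# textbook formulas.
welchFormula <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  t <- (mean(a) - mean(b)) / sqrt(va / na + vb / nb)
  df <- (va / na + vb / nb)^2 /
    ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Random rooted SupportTree over n tips with random genome assignment and
# random integer supports (used by oracle-equivalence tests).
randomSupportTree <- function(ntips, genomes = c("Rafflesia", "Vitis",
                                                 "Manihot", "Ricinus",
                                                 "Oryza")) {
  phy <- ape::rtree(ntips, rooted = TRUE)
  phy$node.label <- as.character(sample(0:100, phy$Nnode, replace = TRUE))
  phy$node.label[1] <- ""  # root edge: support absent
  tg <- stats::setNames(sample(genomes, ntips, replace = TRUE),
                        phy$tip.label)
  # ensure the focal genome appears at least once
  tg[sample(ntips, 1)] <- "Rafflesia"
  SupportTree(phy, tg)
}

# Random DNA string helper.
randomDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# Position of an error-free read within its source sequence (1-based), by
# exact search; NA when absent.
readStart <- function(read, src) {
  r <- regexpr(read, src, fixed = TRUE)
  if (r[1] == -1) NA_integer_ else as.integer(r[1])
}
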