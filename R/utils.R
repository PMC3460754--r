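# Internal helpers shared across modules.

# One draw from a Dirichlet distribution with parameter vector alpha.
.rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  # guard against all-zero draws at tiny alpha
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

# The 61 sense codons (stop codons TAA, TAG, TGA excluded), in the
# lexicographic order Biostrings uses for trinucleotide counts.
.senseCodons <- function() {
  b <- c("A", "C", "G", "T")
  all64 <- sort(apply(expand.grid(b, b, b), 1, paste0, collapse = ""))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

.stopCodons <- c("TAA", "TAG", "TGA")

# Canonical bipartition keys of an unrooted phylo, one per internal edge.
# Each split is represented by the sorted tip labels on the side NOT
# containing `ref` (a tip guaranteed present), so keys are comparable
# across trees on the same leaf set.
.splitKeys <- function(phy, ref = phy$tip.label[1]) {
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  nodes <- setdiff(unique(phy$edge[, 1]), root)
  if (!length(nodes)) return(character())
  desc <- phangorn::Descendants(phy, nodes, type = "tips")
  keys <- vapply(desc, function(idx) {
    labs <- phy$tip.label[idx]
    if (ref %in% labs) labs <- setdiff(phy$tip.label, labs)
    paste(sort(labs), collapse = "|")
  }, character(1))
  stats::setNames(keys, nodes)
}

# Simple condition-free logging: messages are emitted with a stage tag so
# pipeline runs are auditable; suppressible via suppressMessages().
.log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Uniform integer draw on [lo, hi], safe against R's sample(x, 1) scalar
# surprise when lo == hi.
.sampleRange <- function(lo, hi) {
  if (lo == hi) return(as.integer(lo))
  as.integer(sample(lo:hi, 1))
}
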