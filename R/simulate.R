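#' Simulate per-cluster gene trees with planted HGT and recorded truth
#'
#' For each cluster the generator starts from the accepted species
#' topology restricted to a random taxon subset that always satisfies the
#' cluster-retention filter (outgroup + focal taxon + at least one close
#' relative + the host-side genome). With probability \code{hgtFraction}
#' the focal (parasite) tip is detached and re-attached as sister to the
#' Vitis tip — the operational signature of host-to-parasite HGT. With
#' probability \code{noiseFraction} the resulting tree additionally
#' receives one random NNI rearrangement (gene-tree estimation noise).
#' Branch lengths are exponential draws; bootstrap supports are drawn from
#' \code{supportModel}: edges present in the noise-free tree from the
#' \code{concordant} range, edges created by the NNI from the
#' \code{discordant} range.
#'
#' @param cfg A \code{\link{simulationConfig}}.
#' @return A list with \code{trees} (list of \code{SupportTree}, tips
#'   labelled \code{<cluster>_<genome>}) and \code{truth} (data.frame with
#'   columns \code{cluster}, \code{label} ("VGT"/"HGT"), \code{noised},
#'   \code{focalTip}, \code{taxa}).
#' @export
simulateClusterTrees <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  set.seed(cfg@seed)
  panel <- speciesPanel()
  relatives <- panel$genome[panel$role == "relative"]
  optional <- setdiff(panel$genome,
                      c("Oryza", "Rafflesia", "Vitis", relatives))
  n <- cfg@nClusters
  trees <- vector("list", n)
  truth <- data.frame(cluster = sprintf("c%04d", seq_len(n)),
                      label = NA_character_, noised = NA,
                      focalTip = NA_character_, taxa = NA_character_,
                      stringsAsFactors = FALSE)
  backbone <- speciesTopology()
  for (i in seq_len(n)) {
    keepRel <- relatives[stats::runif(length(relatives)) < cfg@taxonKeepProb]
    if (!length(keepRel)) keepRel <- sample(relatives, 1)
    keepOpt <- optional[stats::runif(length(optional)) < cfg@taxonKeepProb]
    taxa <- c("Oryza", "Rafflesia", "Vitis", keepRel, keepOpt)
    topo <- ape::keep.tip(backbone, taxa)
    isHGT <- stats::runif(1) < cfg@hgtFraction
    if (isHGT) topo <- .graftSisterToVitis(topo)
    truthUn <- ape::unroot(topo)
    noised <- stats::runif(1) < cfg@noiseFraction
    obs <- if (noised) phangorn::rNNI(truthUn, moves = 1) else truthUn
    obs$edge.length <- stats::rexp(nrow(obs$edge), rate = cfg@branchRate)
    obs <- .assignSupports(obs, truthUn, cfg@supportModel)
    cid <- truth$cluster[i]
    genomes <- obs$tip.label
    obs$tip.label <- paste(cid, genomes, sep = "_")
    tg <- stats::setNames(genomes, obs$tip.label)
    trees[[i]] <- SupportTree(obs, tg)
    truth$label[i] <- if (isHGT) "HGT" else "VGT"
    truth$noised[i] <- noised
    truth$focalTip[i] <- paste(cid, "Rafflesia", sep = "_")
    truth$taxa[i] <- paste(sort(taxa), collapse = ",")
  }
  list(trees = trees, truth = truth)
}

# Detach the Rafflesia tip and re-attach it as sister to Vitis, on a
# topology-only rooted tree. Implemented by newick surgery: genome names
# are unique tip labels with no substring collisions among the panel.
.graftSisterToVitis <- function(topo) {
  t2 <- ape::drop.tip(topo, "Rafflesia")
  nwk <- ape::write.tree(t2)
  nwk <- sub("Vitis", "(Vitis,Rafflesia)", nwk, fixed = TRUE)
  ape::read.tree(text = nwk)
}

# Draw integer bootstrap supports per internal node: concordant range for
# splits present in the noise-free tree, discordant range otherwise.
.assignSupports <- function(obs, truthUn, supportModel) {
  keys <- .splitKeys(obs, ref = "Oryza")
  truthKeys <- .splitKeys(truthUn, ref = "Oryza")
  ntip <- length(obs$tip.label)
  lab <- rep("", obs$Nnode)
  for (j in seq_along(keys)) {
    nd <- as.integer(names(keys)[j])
    rng <- if (keys[j] %in% truthKeys) supportModel$concordant
           else supportModel$discordant
    lab[nd - ntip] <- as.character(.sampleRange(rng[1], rng[2]))
  }
  obs$node.label <- lab
  obs
}

#' Simulate genome-specific codon-usage profiles
#'
#' Coding properties are phylogenetically conserved within clades, so the
#' generator draws one codon-frequency profile per clade from a symmetric
#' Dirichlet with parameter \code{cladeConcentration} (smaller = clades
#' more distinct), then one profile per genome from a Dirichlet centred on
#' its clade profile with concentration \code{codonProfileDivergence}
#' (larger = genomes within a clade more alike; in the limit they coincide
#' with the clade mean).
#'
#' @param cfg A \code{\link{simulationConfig}}.
#' @return A 12 x 61 matrix of codon frequencies (rows = genomes, columns
#'   = sense codons), each row summing to 1.
#' @export
simulateCodonProfiles <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  set.seed(cfg@seed + 1L)
  panel <- speciesPanel()
  codons <- .senseCodons()
  clades <- unique(panel$clade)
  cladeProfile <- matrix(NA_real_, length(clades), length(codons),
                         dimnames = list(clades, codons))
  for (cl in clades)
    cladeProfile[cl, ] <- .rdirichlet(rep(cfg@cladeConcentration,
                                          length(codons)))
  out <- matrix(NA_real_, nrow(panel), length(codons),
                dimnames = list(panel$genome, codons))
  for (i in seq_len(nrow(panel))) {
    alpha <- cfg@codonProfileDivergence * cladeProfile[panel$clade[i], ]
    out[panel$genome[i], ] <- .rdirichlet(alpha)
  }
  out
}

#' Simulate transcripts, genomic copies and error-free reads
#'
#' Every cluster member receives a coding sequence whose codons are drawn
#' i.i.d. from its genome's codon profile (so lengths are multiples of 3
#' and contain no internal stop codons). Focal-taxon (parasite)
#' transcripts additionally get a genomic copy which, with probability
#' \code{intronRate}, carries one planted intron: a GT..AG segment
#' inserted at a position leaving at least \code{fragmentSize} bp of exon
#' on each side. cDNA reads are exact substrings of transcripts with
#' per-transcript counts from \code{expressionModel}; gDNA reads are exact
#' substrings of the genomic copies at roughly \code{gdnaCoverage}-fold
#' coverage. All ground truth is recorded.
#'
#' @param cfg A \code{\link{simulationConfig}}.
#' @param sim Output of \code{\link{simulateClusterTrees}}.
#' @param profiles Output of \code{\link{simulateCodonProfiles}}.
#' @return A list with \code{transcripts}, \code{genomic},
#'   \code{cdnaReads}, \code{gdnaReads} (named \code{DNAStringSet}s) and
#'   \code{truth}: \code{expression} (member, genome, cluster, length,
#'   trueCount) and \code{introns} (member, junction = number of cDNA
#'   bases before the intron, intronLength, intronSeq).
#' @export
simulateTranscriptsAndReads <- function(cfg, sim, profiles) {
  stopifnot(is(cfg, "SimulationConfig"))
  set.seed(cfg@seed + 2L)
  k <- cfg@fragmentSize
  l <- cfg@readLength
  codons <- colnames(profiles)
  txs <- character(); gen <- character()
  cdna <- character(); gdna <- character()
  exprRows <- list(); intronRows <- list()
  for (st in sim$trees) {
    tg <- tipGenome(st)
    for (member in names(tg)) {
      genome <- tg[[member]]
      nCod <- .sampleRange(cfg@codonRange[1], cfg@codonRange[2])
      seq <- paste(sample(codons, nCod, replace = TRUE,
                          prob = profiles[genome, ]), collapse = "")
      txs[member] <- seq
      if (genome != "Rafflesia") next
      L <- nchar(seq)
      # genomic copy, possibly with one intron
      g <- seq
      if (stats::runif(1) < cfg@intronRate && L >= 2 * k) {
        ilen <- .sampleRange(cfg@intronLengthRange[1],
                             cfg@intronLengthRange[2])
        j <- .sampleRange(k, L - k)  # cDNA bases before the intron
        intron <- paste0("GT", paste(sample(c("A", "C", "G", "T"),
                                            ilen - 4, replace = TRUE),
                                     collapse = ""), "AG")
        g <- paste0(substr(seq, 1, j), intron, substr(seq, j + 1, L))
        intronRows[[length(intronRows) + 1L]] <-
          data.frame(member = member, junction = j, intronLength = ilen,
                     intronSeq = intron, stringsAsFactors = FALSE)
      }
      gen[member] <- g
      # gDNA reads: uniform starts over the genomic copy
      glen <- nchar(g)
      if (glen >= l) {
        nG <- stats::rpois(1, cfg@gdnaCoverage * glen / l)
        if (nG > 0) {
          starts <- sample.int(glen - l + 1L, nG, replace = TRUE)
          rs <- substring(g, starts, starts + l - 1L)
          names(rs) <- paste0(member, "|g", seq_len(nG))
          gdna <- c(gdna, rs)
        }
      }
      # cDNA reads: per-transcript expression model
      nC <- .drawReadCount(cfg@expressionModel)
      if (L < l) {
        .log("simulate", member, " shorter than read length; no cDNA reads")
        nC <- 0L
      }
      exprRows[[length(exprRows) + 1L]] <-
        data.frame(member = member, genome = genome,
                   cluster = sub("_[^_]+$", "", member),
                   length = L, trueCount = nC, stringsAsFactors = FALSE)
      if (nC > 0) {
        starts <- sample.int(L - l + 1L, nC, replace = TRUE)
        rs <- substring(seq, starts, starts + l - 1L)
        names(rs) <- paste0(member, "|c", seq_len(nC))
        cdna <- c(cdna, rs)
      }
    }
  }
  list(
    transcripts = Biostrings::DNAStringSet(txs),
    genomic = Biostrings::DNAStringSet(gen),
    cdnaReads = Biostrings::DNAStringSet(cdna),
    gdnaReads = Biostrings::DNAStringSet(gdna),
    truth = list(
      expression = do.call(rbind, exprRows),
      introns = if (length(intronRows)) do.call(rbind, intronRows)
                else data.frame(member = character(), junction = integer(),
                                intronLength = integer(),
                                intronSeq = character())
    )
  )
}

.drawReadCount <- function(model) {
  switch(model$type,
    constant = as.integer(model$value),
    lognormal = stats::rpois(1, stats::rlnorm(1, model$meanlog, model$sdlog)),
    stop("unknown expression model type: ", model$type))
}

#' Run the full synthetic-study generator
#'
#' Convenience wrapper: trees + truth, codon profiles, sequences and
#' reads, assembled into a list of \code{\link{GeneCluster}} objects ready
#' for the classifier and the downstream stages.
#'
#' @param cfg A \code{\link{simulationConfig}}.
#' @param sequences Generate sequences and reads too (default TRUE; set
#'   FALSE for tree-only studies, which is much faster).
#' @return A list with \code{config}, \code{clusters}, \code{truth},
#'   \code{profiles} and (when \code{sequences}) \code{transcripts},
#'   \code{genomic}, \code{cdnaReads}, \code{gdnaReads},
#'   \code{expressionTruth}, \code{intronTruth}.
#' @export
#' @examples
#' sim <- simulateStudy(simulationConfig(nClusters = 5, seed = 42),
#'                      sequences = FALSE)
#' length(sim$clusters)
simulateStudy <- function(cfg = simulationConfig(), sequences = TRUE) {
  treeSim <- simulateClusterTrees(cfg)
  profiles <- simulateCodonProfiles(cfg)
  seqSim <- if (sequences)
    simulateTranscriptsAndReads(cfg, treeSim, profiles) else NULL
  clusters <- lapply(seq_along(treeSim$trees), function(i) {
    st <- treeSim$trees[[i]]
    members <- if (sequences) {
      ids <- intersect(names(seqSim$transcripts), names(tipGenome(st)))
      seqSim$transcripts[ids]
    } else Biostrings::DNAStringSet()
    GeneCluster(treeSim$truth$cluster[i], tipGenome(st),
                members = members, tree = st)
  })
  out <- list(config = cfg, clusters = clusters, truth = treeSim$truth,
              profiles = profiles)
  if (sequences)
    out <- c(out, list(transcripts = seqSim$transcripts,
                       genomic = seqSim$genomic,
                       cdnaReads = seqSim$cdnaReads,
                       gdnaReads = seqSim$gdnaReads,
                       expressionTruth = seqSim$truth$expression,
                       intronTruth = seqSim$truth$introns))
  out
}

#' Write a simulated study to disk
#'
#' Emits the standard interchange files: transcripts/reads as FASTA, gene
#' trees as newick (one per line), tip-genome and truth tables as TSV,
#' and the configuration as JSON (seed included).
#'
#' @param sim Output of \code{\link{simulateStudy}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeStudy <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trees <- vapply(sim$clusters,
                  function(cl) writeNewickSupport(clusterTree(cl)),
                  character(1))
  writeLines(trees, file.path(dir, "gene_trees.nwk"))
  tg <- do.call(rbind, lapply(sim$clusters, function(cl) {
    g <- genomeOf(cl)
    data.frame(tip = names(g), genome = unname(g),
               stringsAsFactors = FALSE)
  }))
  writeTSV(tg, file.path(dir, "tip_genome.tsv"))
  cm <- do.call(rbind, lapply(sim$clusters, function(cl) {
    g <- genomeOf(cl)
    data.frame(cluster_id = clusterId(cl), member_id = names(g),
               genome = unname(g), stringsAsFactors = FALSE)
  }))
  writeTSV(cm, file.path(dir, "clusters.tsv"))
  writeTSV(sim$truth, file.path(dir, "truth_labels.tsv"))
  if (!is.null(sim$transcripts)) {
    writeFasta(sim$transcripts, file.path(dir, "transcripts.fasta"))
    writeFasta(sim$genomic, file.path(dir, "genomic_copies.fasta"))
    writeFasta(sim$cdnaReads, file.path(dir, "cdna_reads.fasta"))
    writeFasta(sim$gdnaReads, file.path(dir, "gdna_reads.fasta"))
    writeTSV(sim$expressionTruth, file.path(dir, "truth_expression.tsv"))
    writeTSV(sim$intronTruth, file.path(dir, "truth_introns.tsv"))
  }
  cfg <- sim$config
  cfgList <- lapply(slotNames(cfg), function(s) slot(cfg, s))
  names(cfgList) <- slotNames(cfg)
  jsonlite::write_json(cfgList, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
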