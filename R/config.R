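#' ClassifierConfig: rule sets for sister-group classification
#'
#' Holds the taxon rule sets and bootstrap threshold used to classify a
#' focal transcript as vertically inherited (VGT), horizontally transferred
#' (HGT) or unassigned. The defaults encode the parasite-side analysis:
#' focal taxon Rafflesia, closest organismal relatives Manihot, Populus and
#' Ricinus (Malpighiales), transfer donor side Vitis (host clade), outgroup
#' Oryza, bootstrap threshold 50.
#'
#' @slot focalTaxon Genome name of the taxon under investigation.
#' @slot relativeSet Genomes whose sister placement means VGT.
#' @slot transferSet Genomes whose sister placement means HGT.
#' @slot outgroup Genome used for rooting.
#' @slot bsThreshold Minimum bootstrap support for a resolved call.
#' @export
setClass("ClassifierConfig",
  representation(focalTaxon = "character", relativeSet = "character",
                 transferSet = "character", outgroup = "character",
                 bsThreshold = "numeric"))

setValidity("ClassifierConfig", function(object) {
  msg <- character()
  if (length(intersect(object@relativeSet, object@transferSet)))
    msg <- c(msg, "relativeSet and transferSet must be disjoint")
  if (object@focalTaxon %in% c(object@relativeSet, object@transferSet))
    msg <- c(msg, "focalTaxon must not be in either rule set")
  if (object@bsThreshold < 0 || object@bsThreshold > 100)
    msg <- c(msg, "bsThreshold must lie in [0,100]")
  if (length(msg)) msg else TRUE
})

#' Construct a ClassifierConfig
#'
#' @param focalTaxon Focal genome (default "Rafflesia").
#' @param relativeSet Genomes of the focal taxon's closest organismal
#'   relatives (default Manihot/Populus/Ricinus).
#' @param transferSet Candidate donor genomes (default Vitis).
#' @param outgroup Rooting genome (default "Oryza").
#' @param bsThreshold Bootstrap support threshold in [0,100] (default 50).
#' @return A \code{ClassifierConfig}.
#' @export
#' @examples
#' classifierConfig()                       # parasite-side defaults
#' hostSideConfig()                         # host-side mirror
classifierConfig <- function(focalTaxon = "Rafflesia",
                             relativeSet = c("Manihot", "Populus", "Ricinus"),
                             transferSet = "Vitis",
                             outgroup = "Oryza",
                             bsThreshold = 50) {
  new("ClassifierConfig", focalTaxon = focalTaxon, relativeSet = relativeSet,
      transferSet = transferSet, outgroup = outgroup,
      bsThreshold = bsThreshold)
}

#' @rdname classifierConfig
#' @export
hostSideConfig <- function(bsThreshold = 50) {
  classifierConfig(focalTaxon = "Tetrastigma", relativeSet = "Vitis",
                   transferSet = c("Manihot", "Populus", "Ricinus"),
                   bsThreshold = bsThreshold)
}

#' Control-taxon configuration for background HGT rates
#'
#' Treats a non-parasitic Malpighiales genome (Manihot or Ricinus) as the
#' focal taxon, keeping Vitis as the "transfer" side, to measure how often
#' non-HGT discordance (noise, lineage sorting) produces a Vitis-sister
#' placement. Its remaining Malpighiales relatives form the VGT side.
#'
#' @param focalTaxon "Manihot" or "Ricinus".
#' @param bsThreshold Bootstrap support threshold (default 50).
#' @return A \code{ClassifierConfig}.
#' @export
controlConfig <- function(focalTaxon = c("Manihot", "Ricinus"),
                          bsThreshold = 50) {
  focalTaxon <- match.arg(focalTaxon)
  rel <- setdiff(c("Manihot", "Populus", "Ricinus", "Rafflesia"), focalTaxon)
  classifierConfig(focalTaxon = focalTaxon, relativeSet = rel,
                   transferSet = "Vitis", bsThreshold = bsThreshold)
}

setMethod("show", "ClassifierConfig", function(object) {
  cat("ClassifierConfig: focal", object@focalTaxon,
      "| VGT side:", paste(object@relativeSet, collapse = ","),
      "| HGT side:", paste(object@transferSet, collapse = ","),
      "| outgroup", object@outgroup,
      "| BS threshold", object@bsThreshold, "\n")
})

#' SimulationConfig: parameters of the synthetic study generator
#'
#' Collects every knob of the synthetic-data generator in one validated
#' object. See \code{\link{simulationConfig}} for the meaning and default
#' of each parameter.
#' @export
setClass("SimulationConfig",
  representation(seed = "numeric", nClusters = "numeric",
                 hgtFraction = "numeric", noiseFraction = "numeric",
                 supportModel = "list", codonProfileDivergence = "numeric",
                 cladeConcentration = "numeric",
                 readLength = "numeric", fragmentSize = "numeric",
                 intronRate = "numeric", intronLengthRange = "numeric",
                 expressionModel = "list", codonRange = "numeric",
                 gdnaCoverage = "numeric", taxonKeepProb = "numeric",
                 branchRate = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  probs <- c(hgtFraction = object@hgtFraction,
             noiseFraction = object@noiseFraction,
             intronRate = object@intronRate,
             taxonKeepProb = object@taxonKeepProb)
  bad <- probs < 0 | probs > 1
  if (any(bad))
    msg <- c(msg, sprintf("probabilities outside [0,1]: %s",
                          paste(names(probs)[bad], collapse = ", ")))
  if (object@nClusters < 1)
    msg <- c(msg, "nClusters must be >= 1")
  if (object@readLength < object@fragmentSize)
    msg <- c(msg, "readLength must be >= fragmentSize")
  if (object@codonProfileDivergence <= 0)
    msg <- c(msg, "codonProfileDivergence must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' The defaults define the study conditions the generator emulates: a
#' 12-taxon panel, 200 gene clusters, a 5\% planted HGT fraction (the same
#' order as the ~2\% empirical parasite rate, but high enough that desk-scale
#' runs contain tens of events), 10\% topological noise, 150 bp reads cut
#' into 25 bp fragments, and a 50\% intron rate in genomic copies.
#'
#' @param seed Integer seed; recorded in every output.
#' @param nClusters Number of gene clusters to simulate.
#' @param hgtFraction Probability that a cluster's focal tip is grafted
#'   into the host clade (planted HGT).
#' @param noiseFraction Probability that a tree receives one random NNI
#'   rearrangement (gene-tree estimation noise).
#' @param supportModel List with integer ranges \code{concordant} and
#'   \code{discordant}: bootstrap supports are drawn uniformly from
#'   \code{concordant} for edges present in the noise-free tree and from
#'   \code{discordant} for edges created by NNI noise.
#' @param codonProfileDivergence Dirichlet concentration of per-genome
#'   codon profiles around their clade profile; larger = genomes within a
#'   clade more alike.
#' @param cladeConcentration Symmetric Dirichlet parameter for clade-level
#'   codon profiles; smaller = clades more distinct.
#' @param readLength Simulated read length l in bp (default 150).
#' @param fragmentSize Fragment size k in bp for mapping (default 25).
#' @param intronRate Probability a focal genomic copy carries one intron.
#' @param intronLengthRange Min/max intron length in bp.
#' @param expressionModel List; either \code{list(type = "lognormal",
#'   meanlog, sdlog)} (per-transcript Poisson counts with log-normal means)
#'   or \code{list(type = "constant", value)}.
#' @param codonRange Min/max transcript length in codons.
#' @param gdnaCoverage Expected fold-coverage of genomic copies by gDNA
#'   reads.
#' @param taxonKeepProb Inclusion probability of each optional taxon in a
#'   cluster (required taxa are always kept).
#' @param branchRate Rate of the exponential branch-length distribution
#'   (mean length = 1/rate substitutions/site).
#' @return A \code{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1L,
                             nClusters = 200L,
                             hgtFraction = 0.05,
                             noiseFraction = 0.1,
                             supportModel = list(concordant = c(85L, 100L),
                                                 discordant = c(30L, 70L)),
                             codonProfileDivergence = 200,
                             cladeConcentration = 3,
                             readLength = 150L,
                             fragmentSize = 25L,
                             intronRate = 0.5,
                             intronLengthRange = c(60L, 200L),
                             expressionModel = list(type = "lognormal",
                                                    meanlog = log(50),
                                                    sdlog = 1),
                             codonRange = c(100L, 300L),
                             gdnaCoverage = 2,
                             taxonKeepProb = 0.5,
                             branchRate = 10) {
  new("SimulationConfig", seed = seed, nClusters = nClusters,
      hgtFraction = hgtFraction, noiseFraction = noiseFraction,
      supportModel = supportModel,
      codonProfileDivergence = codonProfileDivergence,
      cladeConcentration = cladeConcentration,
      readLength = readLength, fragmentSize = fragmentSize,
      intronRate = intronRate, intronLengthRange = intronLengthRange,
      expressionModel = expressionModel, codonRange = codonRange,
      gdnaCoverage = gdnaCoverage, taxonKeepProb = taxonKeepProb,
      branchRate = branchRate)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nClusters, "clusters, seed", object@seed,
      "\n  hgtFraction", object@hgtFraction,
      "| noiseFraction", object@noiseFraction,
      "| intronRate", object@intronRate, "\n  reads", object@readLength,
      "bp, fragments", object@fragmentSize, "bp\n")
})
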