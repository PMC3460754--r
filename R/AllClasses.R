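#' @import methods
#' @importFrom Biostrings DNAStringSet
NULL

setOldClass("phylo")

#' SupportTree: a gene tree with per-edge bootstrap supports
#'
#' Wraps an \code{ape} \code{phylo} object whose internal node labels carry
#' bootstrap support values (the RAxML convention: the label of an internal
#' node is the support of the edge subtending it), together with a map from
#' tip labels to genome names.
#'
#' @slot phy A \code{phylo} object. Internal node labels, where present,
#'   must be integers in [0, 100] (empty labels mean "support absent").
#' @slot tipGenome Named character vector mapping every tip label to a
#'   genome name.
#' @slot meta List of free-form flags (e.g. \code{outgroupConflict}).
#'
#' @export
setClass("SupportTree",
  representation(phy = "phylo", tipGenome = "character", meta = "list"),
  prototype(meta = list())
)

validSupportTree <- function(object) {
  phy <- object@phy
  msg <- character()
  if (anyDuplicated(phy$tip.label))
    msg <- c(msg, "tip labels must be unique")
  if (!is.null(phy$edge.length) && any(phy$edge.length < 0))
    msg <- c(msg, "branch lengths must be non-negative")
  sup <- .nodeSupports(phy)
  bad <- !is.na(sup) & (sup < 0 | sup > 100)
  if (any(bad))
    msg <- c(msg, sprintf("support out of [0,100]: %s",
                          paste(sup[bad], collapse = ", ")))
  missing <- setdiff(phy$tip.label, names(object@tipGenome))
  if (length(missing))
    msg <- c(msg, sprintf("tips missing from tipGenome map: %s",
                          paste(missing, collapse = ", ")))
  if (length(msg)) msg else TRUE
}
setValidity("SupportTree", validSupportTree)

# Numeric supports per internal node (index 1 = root node Ntip+1).
# Non-numeric labels (e.g. "", "Root") count as absent.
.nodeSupports <- function(phy) {
  nn <- phy$Nnode
  if (is.null(phy$node.label)) return(rep(NA_real_, nn))
  suppressWarnings(as.numeric(phy$node.label))
}

#' Construct a SupportTree
#'
#' @param phy A \code{phylo} object (node labels = bootstrap supports).
#' @param tipGenome Named character vector, tip label -> genome name.
#' @param meta Optional list of flags.
#' @return A \code{SupportTree}.
#' @export
SupportTree <- function(phy, tipGenome, meta = list()) {
  new("SupportTree", phy = phy,
      tipGenome = tipGenome[phy$tip.label], meta = meta)
}

#' @describeIn SupportTree-class Underlying \code{phylo} object
#' @param x A \code{SupportTree}.
#' @export
treePhylo <- function(x) x@phy

#' @describeIn SupportTree-class Tip label -> genome map
#' @export
tipGenome <- function(x) x@tipGenome

#' @describeIn SupportTree-class Numeric supports per internal node
#'   (NA where absent); first entry is the root node.
#' @export
nodeSupports <- function(x) .nodeSupports(x@phy)

setMethod("show", "SupportTree", function(object) {
  phy <- object@phy
  sup <- .nodeSupports(phy)
  cat("SupportTree with", length(phy$tip.label), "tips (",
      if (ape::is.rooted(phy)) "rooted" else "unrooted", ")\n")
  cat("  genomes:", paste(sort(unique(object@tipGenome)), collapse = ", "), "\n")
  cat("  supports:", sum(!is.na(sup)), "of", phy$Nnode, "internal nodes\n")
  if (length(object@meta))
    cat("  flags:", paste(names(object@meta), collapse = ", "), "\n")
})

#' GeneCluster: one homolog cluster
#'
#' A putative orthology cluster: its member coding sequences, the map from
#' member id to genome, and (optionally) its gene tree.
#'
#' @slot clusterId Cluster identifier.
#' @slot members \code{DNAStringSet} of member sequences (may be empty when
#'   only the tree is analysed).
#' @slot genomeOf Named character vector, member id -> genome name.
#' @slot tree A \code{SupportTree}, or NULL.
#'
#' @export
setClass("GeneCluster",
  representation(clusterId = "character", members = "DNAStringSet",
                 genomeOf = "character", tree = "ANY"),
  prototype(members = Biostrings::DNAStringSet(), tree = NULL)
)

setValidity("GeneCluster", function(object) {
  msg <- character()
  if (length(object@clusterId) != 1L || !nzchar(object@clusterId))
    msg <- c(msg, "clusterId must be a single non-empty string")
  if (length(object@members)) {
    ids <- names(object@members)
    if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
      msg <- c(msg, "member ids must be unique and non-empty")
    if (!all(ids %in% names(object@genomeOf)))
      msg <- c(msg, "every member id needs an entry in genomeOf")
  }
  if (!is.null(object@tree)) {
    if (!is(object@tree, "SupportTree"))
      msg <- c(msg, "tree must be a SupportTree or NULL")
    else {
      tips <- treePhylo(object@tree)$tip.label
      if (!all(tips %in% names(object@genomeOf)))
        msg <- c(msg, "every tree tip must be a cluster member id")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneCluster
#'
#' @param clusterId Cluster identifier.
#' @param genomeOf Named character vector, member id -> genome name.
#' @param members Optional \code{DNAStringSet} (named by member id).
#' @param tree Optional \code{SupportTree}.
#' @return A \code{GeneCluster}.
#' @export
GeneCluster <- function(clusterId, genomeOf,
                        members = Biostrings::DNAStringSet(), tree = NULL) {
  new("GeneCluster", clusterId = clusterId, members = members,
      genomeOf = genomeOf, tree = tree)
}

#' @describeIn GeneCluster-class Cluster identifier
#' @param x A \code{GeneCluster}.
#' @export
clusterId <- function(x) x@clusterId

#' @describeIn GeneCluster-class Member sequences
#' @export
clusterMembers <- function(x) x@members

#' @describeIn GeneCluster-class Member id -> genome map
#' @export
genomeOf <- function(x) x@genomeOf

#' @describeIn GeneCluster-class The gene tree (or NULL)
#' @export
clusterTree <- function(x) x@tree

setMethod("show", "GeneCluster", function(object) {
  cat("GeneCluster", object@clusterId, "with",
      length(object@genomeOf), "members from",
      length(unique(object@genomeOf)), "genomes;",
      if (is.null(object@tree)) "no tree" else "tree attached", "\n")
})
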