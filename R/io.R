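#' Read a FASTA file of DNA sequences
#'
#' Reads a (multi-)FASTA file, uppercases the sequences and validates them
#' against the {A,C,G,T,N} alphabet. Record ids (the first whitespace-
#' delimited token of each header) must be unique; the remainder of the
#' header is kept as the description.
#'
#' @param path Path to a FASTA file.
#' @return A named \code{DNAStringSet}; the \code{description} metadata
#'   column holds the free text after the id.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  # Biostrings silently drops invalid letters with a warning; reject
  # instead of repairing
  x <- withCallingHandlers(
    Biostrings::readDNAStringSet(path),
    warning = function(w) stop("non-ACGTN characters (or malformed ",
                               "records) in ", path, ": ",
                               conditionMessage(w)))
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids)))
    stop("FASTA record with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  if (any(Biostrings::width(x) == 0))
    stop("empty sequence for record(s): ",
         paste(ids[Biostrings::width(x) == 0], collapse = ", "))
  seqs <- toupper(as.character(x))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTN characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::metadata(out)$description <- stats::setNames(desc, ids)
  out
}

#' Write DNA sequences to FASTA
#'
#' @param x A named \code{DNAStringSet} (or named character vector).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("all records need non-empty ids")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Parse a newick string carrying bootstrap supports as node labels
#'
#' Reads a newick tree in the RAxML bootstrap convention: integer internal
#' node labels in [0, 100] are the support of the edge subtending that
#' node; unlabelled internal edges have no support. Tips are checked
#' against the supplied tip-to-genome map.
#'
#' @param text A newick string (use \code{readLines} for a file of one
#'   tree per line).
#' @param tipGenome Named character vector, tip label -> genome name.
#' @return A \code{SupportTree}.
#' @export
#' @examples
#' parseNewickSupport("((A:0.1,B:0.2)80:0.05,C:0.3);",
#'                    c(A = "g1", B = "g2", C = "g3"))
parseNewickSupport <- function(text, tipGenome) {
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("newick parse error: ",
                                           conditionMessage(e)),
                  warning = function(w) stop("newick parse error: ",
                                             conditionMessage(w)))
  if (is.null(phy)) stop("newick parse error: unreadable tree")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip label(s) in newick")
  if (!is.null(phy$node.label)) {
    lab <- phy$node.label
    nonempty <- nzchar(lab)
    num <- suppressWarnings(as.numeric(lab))
    if (any(nonempty & is.na(num)))
      stop("non-numeric internal node label(s): ",
           paste(lab[nonempty & is.na(num)], collapse = ", "))
    if (any(nonempty & (num < 0 | num > 100)))
      stop("support value(s) outside [0,100]: ",
           paste(num[nonempty & (num < 0 | num > 100)], collapse = ", "))
  }
  missing <- setdiff(phy$tip.label, names(tipGenome))
  if (length(missing))
    stop("tip(s) missing from tip-genome map: ",
         paste(missing, collapse = ", "))
  SupportTree(phy, tipGenome)
}

#' Serialize a SupportTree to newick
#'
#' Inverse of \code{\link{parseNewickSupport}}: supports are written back
#' as internal node labels.
#'
#' @param st A \code{SupportTree}.
#' @return A newick string.
#' @export
writeNewickSupport <- function(st) {
  ape::write.tree(treePhylo(st))
}

#' Read a cluster membership table
#'
#' Tab-delimited file with a mandatory header row and columns
#' \code{cluster_id}, \code{member_id}, \code{genome}. Genomes are
#' validated against the panel; member ids must be unique within a
#' cluster.
#'
#' @param path Path to the TSV file.
#' @param panel Character vector of allowed genome names (default: the
#'   12-taxon panel).
#' @return A named list (one entry per cluster) of data.frames with
#'   columns \code{member_id}, \code{genome}.
#' @export
readClusterTable <- function(path, panel = speciesPanel()$genome) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cluster_id", "member_id", "genome")
  if (!all(need %in% names(tab)))
    stop("cluster table needs columns: ", paste(need, collapse = ", "))
  if (nrow(tab) == 0) return(stats::setNames(list(), character()))
  unknown <- setdiff(unique(tab$genome), panel)
  if (length(unknown))
    stop("unknown genome name(s): ", paste(unknown, collapse = ", "))
  dup <- duplicated(tab[c("cluster_id", "member_id")])
  if (any(dup))
    stop("duplicate member id(s) within a cluster: ",
         paste(unique(tab$member_id[dup]), collapse = ", "))
  split(tab[c("member_id", "genome")], tab$cluster_id)
}

#' Read a tip-to-genome map
#'
#' Tab-delimited file with header and columns \code{tip}, \code{genome}.
#'
#' @param path Path to the TSV file.
#' @param panel Allowed genome names (default: the 12-taxon panel).
#' @return Named character vector, tip label -> genome.
#' @export
readTipGenomeTable <- function(path, panel = speciesPanel()$genome) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("tip", "genome") %in% names(tab)))
    stop("tip-genome table needs columns: tip, genome")
  if (anyDuplicated(tab$tip))
    stop("duplicate tip label(s) in tip-genome table")
  unknown <- setdiff(unique(tab$genome), panel)
  if (length(unknown))
    stop("unknown genome name(s): ", paste(unknown, collapse = ", "))
  stats::setNames(tab$genome, tab$tip)
}

#' Write a data.frame as a tab-delimited table with header
#'
#' @param x A data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeTSV <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
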