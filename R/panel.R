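#' The 12-taxon species panel
#'
#' The parasite (Rafflesia, a holoparasitic Malpighiales), its obligate
#' host (Tetrastigma, Vitaceae), nine reference genomes and the monocot
#' outgroup, each tagged with the clade role it plays in the analysis:
#' \code{outgroup}, \code{focal} (parasite), \code{host} (Vitaceae),
#' \code{relative} (non-parasitic Malpighiales) or \code{other}.
#'
#' @return A data.frame with columns \code{genome}, \code{clade},
#'   \code{role}.
#' @export
#' @examples
#' speciesPanel()
speciesPanel <- function() {
  data.frame(
    genome = c("Oryza", "Aquilegia", "Vitis", "Tetrastigma",
               "Manihot", "Ricinus", "Populus", "Rafflesia",
               "Arabidopsis", "Carica", "Medicago", "Mimulus"),
    clade = c("Poaceae", "Ranunculales", "Vitaceae", "Vitaceae",
              "Malpighiales", "Malpighiales", "Malpighiales", "Malpighiales",
              "Brassicales", "Brassicales", "Fabales", "Lamiales"),
    role = c("outgroup", "other", "host", "host",
             "relative", "relative", "relative", "focal",
             "other", "other", "other", "other"),
    stringsAsFactors = FALSE
  )
}

# Accepted species-tree relationships among the panel, used as the
# simulation backbone: Oryza (monocot) roots the tree, Aquilegia is the
# earliest-diverging eudicot, the Vitaceae (Vitis + Tetrastigma) are sister
# to the remaining rosids/asterids, Malpighiales (incl. the parasite) group
# with Medicago among the fabids, Arabidopsis is the malvid and Mimulus the
# asterid representative.
.speciesNewick <- paste0(
  "(Oryza,(Aquilegia,((Vitis,Tetrastigma),",
  "((((Rafflesia,(Populus,(Manihot,Ricinus))),Medicago),",
  "(Arabidopsis,Carica)),Mimulus))));")

#' Accepted species-tree topology for the panel
#'
#' @return A rooted \code{phylo} object over the panel genomes (no branch
#'   lengths; the generator draws them).
#' @export
speciesTopology <- function() {
  ape::read.tree(text = .speciesNewick)
}

#' Map genomes to panel clades
#'
#' @param genomes Character vector of genome names.
#' @return Character vector of clade names.
#' @export
genomeClade <- function(genomes) {
  panel <- speciesPanel()
  idx <- match(genomes, panel$genome)
  if (anyNA(idx))
    stop("unknown genome(s): ", paste(genomes[is.na(idx)], collapse = ", "))
  panel$clade[idx]
}
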