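test_that("the species panel matches the accepted 12-taxon system", {
  panel <- speciesPanel()
  expect_equal(nrow(panel), 12)
  expect_false(anyDuplicated(panel$genome) > 0)
  expect_equal(panel$clade[panel$genome == "Rafflesia"], "Malpighiales")
  expect_equal(panel$clade[panel$genome == "Tetrastigma"], "Vitaceae")
  expect_equal(panel$genome[panel$role == "outgroup"], "Oryza")
  expect_setequal(panel$genome[panel$role == "relative"],
                  c("Manihot", "Populus", "Ricinus"))
  topo <- speciesTopology()
  expect_setequal(topo$tip.label, panel$genome)
})

test_that("noise-free limits plant pure VGT or pure HGT signal", {
  cfg0 <- simulationConfig(nClusters = 50, hgtFraction = 0,
                           noiseFraction = 0, seed = 1)
  sim0 <- simulateClusterTrees(cfg0)
  expect_true(all(sim0$truth$label == "VGT"))
  cfg1 <- simulationConfig(nClusters = 50, hgtFraction = 1,
                           noiseFraction = 0, seed = 1)
  sim1 <- simulateClusterTrees(cfg1)
  expect_true(all(sim1$truth$label == "HGT"))
  # sister checks via the classifier's own rule-free machinery
  cfg <- classifierConfig(bsThreshold = 0)
  for (st in sim1$trees[1:10]) {
    rooted <- rootOnOutgroup(st, cfg)
    tip <- names(tipGenome(st))[tipGenome(st) == "Rafflesia"]
    r <- classifyTip(rooted, tip, cfg)
    expect_equal(r$sisterGenomes, "Vitis")
  }
  for (st in sim0$trees[1:10]) {
    rooted <- rootOnOutgroup(st, cfg)
    tip <- names(tipGenome(st))[tipGenome(st) == "Rafflesia"]
    r <- classifyTip(rooted, tip, cfg)
    expect_true(all(strsplit(r$sisterGenomes, ",")[[1]] %in%
                      c("Manihot", "Populus", "Ricinus")))
  }
})

test_that("planted HGT counts follow the configured binomial", {
  cfg <- simulationConfig(nClusters = 300, hgtFraction = 0.1, seed = 7)
  sim <- simulateClusterTrees(cfg)
  nHGT <- sum(sim$truth$label == "HGT")
  lo <- qbinom(0.005, 300, 0.1); hi <- qbinom(0.995, 300, 0.1)
  expect_gte(nHGT, lo)
  expect_lte(nHGT, hi)
})

test_that("every cluster satisfies the retention filter by construction", {
  cfg <- simulationConfig(nClusters = 40, seed = 2)
  sim <- simulateClusterTrees(cfg)
  for (st in sim$trees) {
    g <- unique(tipGenome(st))
    expect_true(all(c("Oryza", "Rafflesia", "Vitis") %in% g))
    expect_true(any(c("Manihot", "Populus", "Ricinus") %in% g))
  }
})

test_that("codon profiles normalize, are clade-structured and deterministic", {
  cfg <- simulationConfig(seed = 5)
  p <- simulateCodonProfiles(cfg)
  expect_equal(dim(p), c(12, 61))
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  expect_identical(p, simulateCodonProfiles(cfg))
  # within-clade profiles are closer than between-clade (Malpighiales
  # pair vs Malpighiales-Vitaceae pair), by construction of the
  # hierarchical draw
  dWithin <- chi2Distance(p["Manihot", ], p["Ricinus", ])
  dBetween <- chi2Distance(p["Manihot", ], p["Vitis", ])
  expect_lt(dWithin, dBetween)
  # concentration limit: genomes collapse onto the clade profile
  pTight <- simulateCodonProfiles(simulationConfig(
    seed = 5, codonProfileDivergence = 1e7))
  expect_lt(max(abs(pTight["Manihot", ] - pTight["Ricinus", ])), 1e-2)
})

test_that("simulated transcripts are in-frame codon strings without stops", {
  cfg <- simulationConfig(nClusters = 6, seed = 9)
  sim <- simulateStudy(cfg)
  for (s in as.character(sim$transcripts)) {
    expect_equal(nchar(s) %% 3, 0)
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("planted introns carry GT/AG splice motifs and lie in the copy", {
  cfg <- simulationConfig(nClusters = 30, seed = 13, intronRate = 1)
  sim <- simulateStudy(cfg)
  tr <- sim$intronTruth
  expect_gt(nrow(tr), 0)
  for (i in seq_len(nrow(tr))) {
    expect_true(startsWith(tr$intronSeq[i], "GT"))
    expect_true(endsWith(tr$intronSeq[i], "AG"))
    g <- as.character(sim$genomic[[tr$member[i]]])
    cdna <- as.character(sim$transcripts[[tr$member[i]]])
    j <- tr$junction[i]
    expect_identical(g, paste0(substr(cdna, 1, j), tr$intronSeq[i],
                               substr(cdna, j + 1, nchar(cdna))))
  }
})

test_that("with no introns, every gDNA read is a transcript substring", {
  cfg <- simulationConfig(nClusters = 8, seed = 21, intronRate = 0)
  sim <- simulateStudy(cfg)
  for (nm in names(sim$gdnaReads)) {
    src <- sub("\\|g[0-9]+$", "", nm)
    expect_false(is.na(readStart(as.character(sim$gdnaReads[[nm]]),
                                 as.character(sim$transcripts[[src]]))))
  }
})

test_that("a constant expression model yields exact read counts", {
  cfg <- simulationConfig(nClusters = 6, seed = 4,
                          expressionModel = list(type = "constant",
                                                 value = 100))
  sim <- simulateStudy(cfg)
  longEnough <- sim$expressionTruth$length >= cfg@readLength
  expect_true(all(sim$expressionTruth$trueCount[longEnough] == 100))
  counts <- table(sub("\\|c[0-9]+$", "", names(sim$cdnaReads)))
  expect_true(all(counts == 100))
})

test_that("identical configurations reproduce identical studies", {
  cfg <- simulationConfig(nClusters = 5, seed = 17)
  a <- simulateStudy(cfg)
  b <- simulateStudy(cfg)
  expect_identical(as.character(a$transcripts), as.character(b$transcripts))
  expect_identical(as.character(a$cdnaReads), as.character(b$cdnaReads))
  expect_identical(as.character(a$gdnaReads), as.character(b$gdnaReads))
  expect_identical(a$truth, b$truth)
  expect_identical(vapply(a$clusters,
                          function(cl) writeNewickSupport(clusterTree(cl)),
                          character(1)),
                   vapply(b$clusters,
                          function(cl) writeNewickSupport(clusterTree(cl)),
                          character(1)))
})

test_that("writeStudy emits parseable interchange files", {
  cfg <- simulationConfig(nClusters = 4, seed = 19)
  sim <- simulateStudy(cfg)
  dir <- withr::local_tempdir()
  writeStudy(sim, dir)
  expect_true(all(c("gene_trees.nwk", "tip_genome.tsv", "clusters.tsv",
                    "transcripts.fasta", "config.json") %in%
                    list.files(dir)))
  tg <- readTipGenomeTable(file.path(dir, "tip_genome.tsv"))
  trees <- readLines(file.path(dir, "gene_trees.nwk"))
  st <- parseNewickSupport(trees[1], tg)
  expect_s4_class(st, "SupportTree")
  tab <- readClusterTable(file.path(dir, "clusters.tsv"))
  expect_length(tab, 4)
  tx <- readFasta(file.path(dir, "transcripts.fasta"))
  expect_gt(length(tx), 0)
})
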