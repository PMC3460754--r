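# small helper: build a GeneCluster-free SupportTree from newick
stFrom <- function(nwk, tg) parseNewickSupport(nwk, tg)

gmap <- c(Raf = "Rafflesia", Raf2 = "Rafflesia", Vit = "Vitis",
          Man = "Manihot", Ric = "Ricinus", Pop = "Populus",
          Ory = "Oryza", Tet = "Tetrastigma", Ara = "Arabidopsis")

cfgR <- classifierConfig()

test_that("filterClusters implements the taxon-retention rule", {
  mk <- function(genomes) {
    ids <- paste0("m", seq_along(genomes))
    GeneCluster("c1", stats::setNames(genomes, ids))
  }
  keepers <- filterClusters(list(
    mk(c("Oryza", "Rafflesia", "Ricinus", "Vitis")),   # minimal pass
    mk(c("Oryza", "Rafflesia", "Ricinus")),            # no Vitis
    mk(c("Rafflesia", "Ricinus", "Vitis")),            # no outgroup
    mk(c("Oryza", "Rafflesia", "Vitis"))               # no relative
  ), cfgR)
  expect_length(keepers, 1)
  expect_length(filterClusters(list(), cfgR), 0)
})

test_that("rootOnOutgroup places the root next to the outgroup", {
  st <- stFrom("((Raf:0.2,Vit:0.1)80:0.05,(Man:0.1,Ric:0.1)90:0.04,Ory:0.5);",
               gmap)
  rooted <- rootOnOutgroup(st, cfgR)
  phy <- treePhylo(rooted)
  expect_true(ape::is.rooted(phy))
  # Oryza is a child of the root
  root <- length(phy$tip.label) + 1L
  rootKids <- phy$edge[phy$edge[, 1] == root, 2]
  expect_true(match("Ory", phy$tip.label) %in% rootKids)
  expect_false(isTRUE(rooted@meta$outgroupConflict))
  # idempotence: rooting the rooted tree changes nothing topologically
  again <- rootOnOutgroup(rooted, cfgR)
  expect_equal(phangorn::RF.dist(treePhylo(again), phy), 0)
  # supports still attached to the same clades
  cls <- classifyTip(rooted, "Raf", classifierConfig(bsThreshold = 0))
  expect_equal(cls$support, 80)
})

test_that("rooting fails without an outgroup and flags conflicts", {
  st <- stFrom("((Raf:0.2,Vit:0.1)80:0.05,Man:0.1,Ric:0.1);", gmap)
  expect_error(rootOnOutgroup(st, cfgR), "outgroup")
  # two outgroup tips that are not monophyletic
  g2 <- c(O1 = "Oryza", O2 = "Oryza", A = "Vitis", B = "Manihot",
          Raf = "Rafflesia")
  st2 <- stFrom("((O1:0.1,A:0.1)50:0.1,(O2:0.1,B:0.1)60:0.1,Raf:0.2);", g2)
  rooted <- rootOnOutgroup(st2, cfgR)
  expect_true(rooted@meta$outgroupConflict)
  expect_true(ape::is.rooted(treePhylo(rooted)))
})

test_that("classifyTip applies the sister-group and support rules", {
  # HGT: focal sister to Vitis at 75 >= 50
  st <- stFrom("(((Raf,Vit)75,(Man,Ric)90)88,Ory);", gmap)
  r <- classifyTip(st, "Raf", cfgR)
  expect_equal(r$category, "HGT")
  expect_equal(r$support, 75)
  expect_equal(r$sisterGenomes, "Vitis")
  # unassigned: support of the focal+sister clade below threshold
  st2 <- stFrom("(((Man,Ric)90,Raf)45,(Vit,Ory)70);", gmap)
  r2 <- classifyTip(st2, "Raf", cfgR)
  expect_equal(r2$rule, "VGT")
  expect_equal(r2$category, "unassigned")
  # unassigned: mixed sister clade despite high support
  st3 <- stFrom("(((Vit,Man)99,Raf)88,(Ric,Ory)70);", gmap)
  r3 <- classifyTip(st3, "Raf", cfgR)
  expect_equal(r3$category, "unassigned")
  expect_equal(r3$rule, "none")
  # error on missing tip
  expect_error(classifyTip(st, "nope", cfgR), "not in tree")
})

test_that("support is read from the edge subtending focal+sister", {
  # Raf+Vit clade subtended by the 75-labelled edge; sister set support
  # must NOT be the support of the Vitis terminal or the deeper edge
  st <- stFrom("(((Raf,Vit)75,Man)60,Ory);", gmap)
  r <- classifyTip(st, "Raf", classifierConfig(bsThreshold = 0))
  expect_equal(r$support, 75)
  # when the first informative ancestor is the root, support is absent
  # and the call is unassigned even though the sister set is clean
  st2 <- stFrom("(Raf,(Vit,Ory)90);", gmap)
  r2 <- classifyTip(st2, "Raf", cfgR)
  expect_true(is.na(r2$support))
  expect_equal(r2$category, "unassigned")
})

test_that("other focal tips (in-paralogs) are skipped when ascending", {
  st <- stFrom("(((Raf,Raf2)99,Vit)80,Ory);", gmap)
  r <- classifyTip(st, "Raf", cfgR)
  expect_equal(r$sisterGenomes, "Vitis")
  expect_equal(r$support, 80)
  expect_equal(r$category, "HGT")
})

test_that("sister sets containing other reference taxa are unassigned", {
  st <- stFrom("(((Raf,Ara)95,Vit)80,Ory);", gmap)
  r <- classifyTip(st, "Raf", cfgR)
  expect_equal(r$category, "unassigned")
  expect_equal(r$rule, "none")
})

test_that("classification partitions transcripts and swaps symmetrically", {
  sim <- simulateStudy(simulationConfig(nClusters = 60, seed = 23,
                                        noiseFraction = 0.3),
                       sequences = FALSE)
  cls <- classifyAll(sim$clusters, cfgR)
  expect_equal(sum(cls$summary$count), cls$summary$denominator[1])
  expect_equal(nrow(cls$classifications), cls$summary$denominator[1])
  # swapping the rule sets swaps VGT and HGT labels exactly
  swapped <- classifierConfig(relativeSet = "Vitis",
                              transferSet = c("Manihot", "Populus",
                                              "Ricinus"))
  cls2 <- classifyAll(sim$clusters, swapped)
  map <- c(VGT = "HGT", HGT = "VGT", unassigned = "unassigned")
  expect_identical(unname(map[cls$classifications$category]),
                   cls2$classifications$category)
})

test_that("classifyTip agrees with the brute-force bipartition oracle", {
  set.seed(42)
  cfg0 <- classifierConfig(bsThreshold = 0)
  for (i in 1:150) {
    st <- randomSupportTree(sample(4:8, 1))
    tg <- tipGenome(st)
    focalTips <- names(tg)[tg == "Rafflesia"]
    for (tip in focalTips) {
      got <- classifyTip(st, tip, cfg0)
      want <- bruteSister(treePhylo(st), tip, tg, "Rafflesia")
      expect_identical(strsplit(got$sisterGenomes, ",")[[1]],
                       want$sisterGenomes)
      expect_identical(got$support, want$support)
    }
  }
})

test_that("threshold sweep is monotone and handles the empty case", {
  sim <- simulateStudy(simulationConfig(nClusters = 50, seed = 29,
                                        noiseFraction = 0.4),
                       sequences = FALSE)
  cls <- classifyAll(sim$clusters, cfgR)
  sw <- sweepThresholds(cls$classifications, cfgR,
                        thresholds = c(0, 50, 55, 60, 65, 70, 100))
  expect_equal(nrow(sw), 7)
  expect_true(all(diff(sw$nResolved) <= 0))
  # nothing resolved above support 100 is impossible; force the empty
  # case with an impossible threshold on a support-free tree
  st <- stFrom("((Raf,Vit),Ory);", gmap)
  cl <- GeneCluster("c1", stats::setNames(tipGenome(st), names(tipGenome(st))),
                    tree = st)
  # cluster lacks a relative so the filter drops it; classify directly
  one <- classifyTip(st, "Raf", cfgR)
  one$cluster <- "c1"
  sw2 <- sweepThresholds(one, cfgR, thresholds = 50)
  expect_true(is.na(sw2$hgtPercent))
})

test_that("all supports at 100 make the sweep threshold-free", {
  cfg <- simulationConfig(nClusters = 30, seed = 31, noiseFraction = 0,
                          supportModel = list(concordant = c(100L, 100L),
                                              discordant = c(100L, 100L)))
  sim <- simulateStudy(cfg, sequences = FALSE)
  cls <- classifyAll(sim$clusters, cfgR)
  sw <- sweepThresholds(cls$classifications, cfgR)
  expect_equal(length(unique(sw$hgtPercent)), 1)
  expect_equal(length(unique(sw$nResolved)), 1)
})
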