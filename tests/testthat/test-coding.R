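test_that("profileTranscript counts blocks by hand-checkable rules", {
  p <- profileTranscript("ACG")
  expect_equal(unname(p[c("nt_A", "nt_C", "nt_G", "nt_T")]),
               c(1, 1, 1, 0) / 3)
  expect_equal(unname(p["di_AC"]), 0.5)
  expect_equal(unname(p["di_CG"]), 0.5)
  expect_equal(unname(p["cod_ACG"]), 1)
  # stop codon TAA excluded from numerator and denominator
  p2 <- profileTranscript("ACGTAA")
  expect_equal(unname(p2["cod_ACG"]), 1)
  expect_false("cod_TAA" %in% names(p2))
  # trailing partial codon dropped from the codon block only
  p3 <- profileTranscript("ACGT")
  expect_equal(unname(p3["cod_ACG"]), 1)
  expect_equal(unname(p3["nt_T"]), 0.25)
  expect_length(p3, 81)
  expect_error(profileTranscript(""), "empty")
  expect_error(profileTranscript("NNN"), "no A/C/G/T|no complete")
})

test_that("profile blocks each sum to one on random coding sequences", {
  set.seed(61)
  for (i in 1:20) {
    p <- profileTranscript(randomDNA(3 * sample(2:200, 1)))
    expect_equal(sum(p[startsWith(names(p), "nt_")]), 1, tolerance = 1e-9)
    expect_equal(sum(p[startsWith(names(p), "di_")]), 1, tolerance = 1e-9)
    expect_equal(sum(p[startsWith(names(p), "cod_")]), 1,
                 tolerance = 1e-9)
    expect_true(all(p >= 0))
  }
})

test_that("N bases are excluded from frequency counts", {
  p <- profileTranscript("ACGNACG")
  expect_equal(unname(p["nt_T"]), 0)
  expect_equal(sum(p[startsWith(names(p), "nt_")]), 1)
  # dinucleotides spanning the N are not counted
  expect_equal(sum(p[startsWith(names(p), "di_")]), 1)
})

test_that("chi2Distance matches hand evaluation and is a premetric", {
  expect_equal(chi2Distance(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(chi2Distance(c(0.5, 0.5), c(0.25, 0.75)),
               0.0625 / 0.75 + 0.0625 / 1.25)
  set.seed(67)
  for (i in 1:20) {
    p <- runif(81); q <- runif(81)
    expect_equal(chi2Distance(p, q), chi2Distance(q, p))
    expect_gte(chi2Distance(p, q), 0)
    expect_equal(chi2Distance(p, p), 0)
  }
  # zero-sum features skipped rather than dividing by zero
  expect_equal(chi2Distance(c(1, 0), c(1, 0)), 0)
  expect_error(chi2Distance(1:3, 1:2), "equal length")
})

test_that("classifyAffinity labels by smallest side distance with tie rule", {
  focal <- c(1, 0, 0)
  near <- c(0.9, 0.1, 0)     # close
  far <- c(0, 0.5, 0.5)      # far
  profs <- list(Vitis = list(near), Manihot = list(far))
  call <- classifyAffinity(focal, profs)
  expect_equal(call$label, "host-like")
  expect_gt(call$margin, 0)
  expect_equal(call$nearestGenome, "Vitis")
  profs2 <- list(Vitis = list(far), Manihot = list(near),
                 Ricinus = list(far))
  call2 <- classifyAffinity(focal, profs2)
  expect_equal(call2$label, "relative-like")
  # exact tie goes to the relative side (conservative)
  profs3 <- list(Vitis = list(near), Manihot = list(near))
  expect_equal(classifyAffinity(focal, profs3)$label, "relative-like")
  # a missing side excludes the transcript rather than defaulting
  expect_message(res <- classifyAffinity(focal, list(Vitis = list(near))),
                 "excluded")
  expect_null(res)
})

test_that("affinityRates reports percentages and swaps with labels", {
  calls <- data.frame(label = c("host-like", "relative-like",
                                "host-like", "host-like"))
  r <- affinityRates(list(g = calls))
  expect_equal(r$hostLikePercent, 75)
  swapped <- calls
  swapped$label <- ifelse(calls$label == "host-like", "relative-like",
                          "host-like")
  r2 <- affinityRates(list(g = swapped))
  expect_equal(r2$hostLikePercent, 25)
  empty <- affinityRates(list(g = calls[0, , drop = FALSE]))
  expect_true(is.na(empty$hostLikePercent))
})

test_that("exactBinomialTest matches exhaustive enumeration for n <= 12", {
  for (n in 1:12) for (p0 in c(0.096, 0.25, 0.5, 0.9)) {
    for (k in 0:n) {
      expect_equal(exactBinomialTest(k, n, p0), enumBinomUpper(k, n, p0),
                   tolerance = 1e-12)
    }
  }
  expect_equal(exactBinomialTest(0, 1, 0.5), 1)
  expect_equal(exactBinomialTest(2, 2, 0.5), 0.25)
  expect_error(exactBinomialTest(3, 2, 0.5), "k <= n")
  expect_error(exactBinomialTest(1, 2, 0), "p0")
})

test_that("affinity recovery works on well-separated simulated profiles", {
  cfg <- simulationConfig(nClusters = 1, seed = 71,
                          cladeConcentration = 0.5,
                          codonProfileDivergence = 5000)
  profiles <- simulateCodonProfiles(cfg)
  codons <- colnames(profiles)
  set.seed(72)
  drawTx <- function(genome, nCod = 300)
    paste(sample(codons, nCod, TRUE, prob = profiles[genome, ]),
          collapse = "")
  correct <- 0L; n <- 40L
  for (i in seq_len(n)) {
    profs <- list(Manihot = list(profileTranscript(drawTx("Manihot"))),
                  Ricinus = list(profileTranscript(drawTx("Ricinus"))),
                  Vitis = list(profileTranscript(drawTx("Vitis"))))
    # focal drawn from the Malpighiales (Rafflesia) profile
    call <- classifyAffinity(profileTranscript(drawTx("Rafflesia")), profs)
    if (call$label == "relative-like") correct <- correct + 1L
    # and one drawn from the host profile must look host-like
    call2 <- classifyAffinity(profileTranscript(drawTx("Vitis")), profs)
    if (call2$label == "host-like") correct <- correct + 1L
  }
  expect_gte(correct / (2 * n), 0.95)
})

test_that("expression-affinity correlation behaves at the extremes", {
  calls <- data.frame(transcript = paste0("t", 1:10), margin = 1:10)
  rec <- data.frame(transcript = paste0("t", 1:10), RPKM = (1:10)^2)
  r <- expressionAffinityCorrelation(calls, rec)
  expect_equal(r$rho, 1)
  tied <- data.frame(transcript = paste0("t", 1:10), margin = rep(1, 10))
  r2 <- expressionAffinityCorrelation(tied, rec)
  expect_true(is.na(r2$rho))
  expect_match(r2$note, "tied")
  expect_error(expressionAffinityCorrelation(calls[1:2, ], rec),
               "at least 3")
})
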