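test_that("two-sided Fisher p matches exhaustive enumeration on small tables", {
  # equal proportions, observed table is the hypergeometric mode
  r <- fisherTestLog10(10, 20, 25, 50)
  expect_equal(r$p_value, 1)
  expect_equal(r$log10_p, 0)
  # 4-vs-4 alleles: 34/70 by direct enumeration over C(8,4) outcomes
  r <- fisherTestLog10(3, 4, 1, 4)
  expect_equal(r$p_value, 34 / 70, tolerance = 1e-12)
  expect_equal(r$log10_p, log10(34 / 70), tolerance = 1e-12)
  # random spot checks against fisher.test and the dhyper oracle
  set.seed(21)
  for (i in 1:25) {
    n1 <- sample(1:40, 1); n2 <- sample(1:40, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    p <- fisherTestLog10(k1, n1, k2, n2)$p_value
    expect_equal(p, oracleFisherP(k1, n1, k2, n2), tolerance = 1e-12)
    m <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2)
    expect_equal(p, stats::fisher.test(m)$p.value, tolerance = 1e-9)
  }
})

test_that("degenerate margins give p = 1", {
  expect_equal(fisherTestLog10(0, 5, 0, 7)$p_value, 1)
  expect_equal(fisherTestLog10(5, 5, 7, 7)$log10_p, 0)
})

test_that("log-space path stays finite for extreme counts", {
  r <- fisherTestLog10(9000, 10000, 1000, 10000)
  expect_true(is.finite(r$log10_p))
  expect_lt(r$log10_p, -1000)
  expect_equal(r$p_value, 0)   # underflows in linear space, by design
})

test_that("p is monotone as the observed count moves away from expectation", {
  n1 <- 18; n2 <- 27; K <- 20
  ks <- max(0, K - n2):min(K, n1)
  p <- vapply(ks, function(k)
    fisherTestLog10(k, n1, K - k, n2)$p_value, numeric(1))
  mode <- ks[which.max(p)]
  expect_true(all(diff(p[ks >= mode]) <= 1e-12))
  expect_true(all(diff(p[ks <= mode]) >= -1e-12))
})

test_that("swapping effect and other allele flips the sign only", {
  ft <- toyFrequencyTable(rep("rs1", 2), c("P1", "GLOBAL"), c(0.75, 0.25),
                          c(20, 40))
  a <- signedEnrichment("rs1", "P1", ft)
  swapped <- freqRecords(ft)
  swapped$k_effect <- swapped$n_alleles - swapped$k_effect
  swapped$eaf <- 1 - swapped$eaf
  b <- signedEnrichment("rs1", "P1", FrequencyTable(swapped))
  expect_equal(a$signed_stat, -b$signed_stat, tolerance = 1e-12)
  expect_equal(abs(a$log10_p), abs(b$log10_p), tolerance = 1e-12)
})

test_that("signed statistic follows the enrichment/depletion/tie convention", {
  ft <- toyFrequencyTable(rep("rs1", 4), c("GLOBAL", "UP", "DOWN", "TIE"),
                          c(0.5, 0.75, 0.25, 0.5), c(40, 20, 20, 20))
  up <- signedEnrichment("rs1", "UP", ft)
  expect_gt(up$signed_stat, 0)
  expect_equal(up$signed_stat, -up$log10_p)
  expect_lt(signedEnrichment("rs1", "DOWN", ft)$signed_stat, 0)
  expect_equal(signedEnrichment("rs1", "TIE", ft)$signed_stat, 0)
  # the 4-vs-4 worked example: eaf 0.75 vs 0.25 -> +|log10(34/70)|
  ft2 <- toyFrequencyTable(rep("rs1", 2), c("P1", "GLOBAL"), c(0.75, 0.25),
                           c(2, 2))
  expect_equal(signedEnrichment("rs1", "P1", ft2)$signed_stat,
               -log10(34 / 70), tolerance = 1e-12)
})

test_that("matrix assembly is deterministic with catalog row order", {
  cat <- table1Catalog()
  freq <- table1FrequencyTable()
  pops <- c("AMR", "AFR", "EAS", "SAS", "EUR", "KOR")
  em <- buildEnrichmentMatrix(cat, freq, pops)
  expect_equal(dim(em), c(29L, 6L))
  expect_identical(rownames(em), rsids(cat))
  expect_identical(colnames(em), pops)
  # recomputed signs of the published example SNP
  expect_gt(em["rs10818769", "EUR"], 0)
  expect_lt(em["rs10818769", "KOR"], 0)
})

test_that("populations identical to background give a zero matrix", {
  ft <- toyFrequencyTable(rep(c("rsA", "rsB"), each = 2),
                          rep(c("P1", "GLOBAL"), 2),
                          c(0.3, 0.3, 0.7, 0.7), c(50, 50, 50, 50))
  em <- buildEnrichmentMatrix(toyCatalog(rsid = c("rsA", "rsB")),
                              ft, "P1")
  expect_true(all(em == 0))
})

test_that("complement background subtracts the population from the pool", {
  # pool = P1 (30 of 40) + rest (10 of 60); complement bg = rest
  ft <- FrequencyTable(data.frame(
    rsid = "rs1", population = c("P1", "GLOBAL"), eaf = c(0.75, 0.4),
    k_effect = c(30, 40), n_alleles = c(40, 100),
    source = "frequency_file"))
  em <- buildEnrichmentMatrix(toyCatalog(rsid = "rs1"), ft, "P1",
                              backgroundMode = "complement")
  direct <- fisherTestLog10(30, 40, 10, 60)
  expect_equal(abs(em["rs1", "P1"]), -direct$log10_p, tolerance = 1e-12)
})

test_that("classification partitions SNPs and flags the extreme subset", {
  em <- table1SignedMatrix()
  cls <- classifySnps(em, "KOR", extremeThreshold = 100)
  expect_equal(length(cls$extreme), 29L)
  expect_equal(sum(cls$counts[c("enriched", "depleted", "comparable")]),
               nrow(em))
  zero <- matrix(0, 4, 2, dimnames = list(paste0("rs", 1:4), c("A", "B")))
  cls0 <- classifySnps(zero, "A")
  expect_equal(unname(cls0$counts[c("enriched", "depleted", "comparable")]),
               c(0L, 0L, 4L))
})

test_that("population clustering recovers structure and handles edge cases", {
  em <- table1SignedMatrix()
  expect_error(clusterPopulations(em[, "KOR", drop = FALSE]),
               "at least two")
  # identical columns merge first at height 0
  m <- cbind(A = em[, "EUR"], B = em[, "EUR"], C = em[, "KOR"])
  hc <- clusterPopulations(m, metric = "euclidean")
  expect_equal(hc$height[1], 0)
  expect_setequal(rootBipartition(hc)[[1]], c("A", "B"))
  # published bipartition on the packaged matrix
  bp <- rootBipartition(clusterPopulations(em))
  expect_setequal(bp[[1]], c("AFR", "EAS", "KOR"))
  expect_setequal(bp[[2]], c("AMR", "EUR", "SAS"))
  # Newick export carries all leaves
  nwk <- exportNewick(clusterPopulations(em))
  expect_true(all(vapply(colnames(em), grepl, logical(1), x = nwk,
                         fixed = TRUE)))
})
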