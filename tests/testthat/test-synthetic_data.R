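twoCladeConfig <- function(seed, I = 60L, n = 500L) {
  simulationConfig(populations = data.frame(
    label = paste0("P", 1:6), n = n, fst = 0.02,
    latitude = seq(0, 50, 10),
    clade = rep(c("X", "Y"), each = 3)),
    I = I, cladeFst = 0.2, seed = seed)
}

test_that("the generator is deterministic under a fixed seed", {
  cfg <- simulationConfig(I = 25L, seed = 99L)
  a <- simulateAlleleFrequencies(cfg)
  b <- simulateAlleleFrequencies(cfg)
  expect_identical(a$frequencies, b$frequencies)
  ga <- simulateGenotypes(a$frequencies, cfg)
  gb <- simulateGenotypes(b$frequencies, cfg)
  expect_identical(dosages(ga$genotypes), dosages(gb$genotypes))
  ph <- simulatePhenotypes(c(A = 0.5, B = 0.6), c(A = 0, B = 40), cfg)
  ph2 <- simulatePhenotypes(c(A = 0.5, B = 0.6), c(A = 0, B = 40), cfg)
  expect_identical(ph, ph2)
})

test_that("population frequencies stay near the ancestor for tiny drift", {
  cfg <- simulationConfig(populations = data.frame(
    label = "P1", n = 10L, fst = 1e-6, latitude = 0),
    I = 2000L, seed = 7L)
  out <- simulateAlleleFrequencies(cfg)
  close <- abs(out$frequencies[, "P1"] - out$truth$p0) < 1e-2
  expect_gt(mean(close), 0.99)
})

test_that("drift variance follows the Balding-Nichols identity", {
  # p0 pinned near 0.5; variance of the drifted frequency ~ F p0 (1 - p0)
  cfg <- simulationConfig(populations = data.frame(
    label = "P1", n = 10L, fst = 0.1, latitude = 0),
    I = 10000L, ancestralFreqRange = c(0.499, 0.501), seed = 8L)
  out <- simulateAlleleFrequencies(cfg)
  v <- var(out$frequencies[, "P1"])
  expect_lt(abs(v - 0.1 * 0.25), 0.002)
})

test_that("genotypes are Hardy-Weinberg draws from the population frequency", {
  cfg <- simulationConfig(populations = data.frame(
    label = "P1", n = 10000L, fst = 0.1, latitude = 0),
    I = 1L, seed = 9L)
  freq <- matrix(0.3, 1, 1, dimnames = list("rs0000001", "P1"))
  g <- simulateGenotypes(freq, cfg)
  m <- mean(dosages(g$genotypes))
  expect_lt(abs(m - 0.6), 0.015)   # 3 sigma of the binomial mean
  freq1 <- matrix(1, 1, 1, dimnames = list("rs0000001", "P1"))
  g1 <- simulateGenotypes(freq1, cfg)
  expect_true(all(dosages(g1$genotypes) == 2))
})

test_that("phenotypes follow the configured linear model exactly at sigma 0", {
  cfg <- simulationConfig(sigma = 0, seed = 10L)
  grs <- c(A = 0.45, B = 0.55, C = 0.6)
  lat <- c(A = 0, B = 30, C = 50)
  ph <- simulatePhenotypes(grs, lat, cfg)
  expect_equal(ph$concentration,
               cfg$beta0 + cfg$betaGrs * grs + cfg$betaLat * lat,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("two-phase simulation plants exactly the injected discordances", {
  cfg <- simulationConfig(seed = 12L)
  p <- stats::setNames(runif(40, 0.2, 0.8), sprintf("rs%02d", 1:40))
  tp <- simulateTwoPhase(p, nTotal = 1722, nPhase2 = 1099,
                         nDiscordant = 3, config = cfg)
  cat <- toyCatalog(rsid = names(p), effect = rep("G", 40),
                    other = rep("A", 40))
  res <- phaseConcordanceFilter(cat, tp$freq_total, tp$freq_phase2)
  expect_equal(res$report$rsid[res$report$excluded], tp$discordant)
  expect_equal(sum(res$report$excluded), 3L)
  # full overlap: phases identical, nothing excluded
  tp2 <- simulateTwoPhase(p, nTotal = 500, nPhase2 = 500, nDiscordant = 0,
                          config = cfg)
  expect_equal(tp2$freq_total, tp2$freq_phase2)
  # no injection: subsampling noise stays inside the threshold w.h.p.
  expect_lt(max(abs(tp$freq_total[-(1:3)] - tp$freq_phase2[-(1:3)])), 0.10)
})

test_that("emitted fixtures round-trip through the real readers", {
  cfg <- simulationConfig(populations = data.frame(
    label = c("P1", "P2", "KOR"), n = c(15L, 15L, 25L),
    fst = c(0.05, 0.05, 0.1), latitude = c(0, 30, 37)),
    I = 20L, seed = 13L)
  fr <- simulateAlleleFrequencies(cfg)
  sim <- simulateGenotypes(fr$frequencies, cfg)
  dir <- withr::local_tempdir()
  paths <- emitFixtures(sim, dir, freqPopulation = "KOR")
  # VCF: dosages reproduced exactly for the panel populations
  panel <- readPopulationPanel(paths[["sample_map"]])
  gm <- readVcfGenotypes(paths[["vcf"]], panel, sim$catalog)
  orig <- dosages(sim$genotypes)[, colnames(dosages(gm))]
  expect_equal(unname(dosages(gm)), unname(orig), ignore_attr = TRUE)
  # frequency TSV: eafs identical to counting from the held-out cohort
  ft <- readFrequencyTable(paths[["freq"]], sim$catalog, "KOR")
  kor <- dosages(sim$genotypes)[, grepl("^KOR", colnames(
    dosages(sim$genotypes)))]
  expect_equal(freqRecords(ft)$eaf, unname(rowMeans(kor) / 2),
               tolerance = 1e-12)
  # catalog TSV: curation recovers every SNP despite injected duplicates
  raw <- readGwasCatalog(paths[["catalog"]])
  expect_gt(nrow(raw), cfg$I)   # the duplicate row is present
  dd <- dedupAssociations(raw)
  expect_equal(nrow(dd), cfg$I)
  expect_true(any(is.na(dd$risk_allele)))   # the "?" token survived parsing
})

test_that("enrichment signs recover the simulated frequency differences", {
  cfg <- twoCladeConfig(seed = 14L, I = 40L)
  fr <- simulateAlleleFrequencies(cfg)
  freqs <- fr$frequencies
  n <- cfg$populations$n
  glob <- as.numeric(freqs %*% n) / sum(n)
  rows <- lapply(seq_len(ncol(freqs)), function(j) {
    cnt <- countsFromFrequency(freqs[, j], n[j])
    data.frame(rsid = rownames(freqs),
               population = colnames(freqs)[j], eaf = freqs[, j],
               k_effect = cnt$k_effect, n_alleles = cnt$n_alleles,
               source = "frequency_file")
  })
  cntg <- countsFromFrequency(glob, sum(n))
  rows$global <- data.frame(rsid = rownames(freqs), population = "GLOBAL",
                            eaf = glob, k_effect = cntg$k_effect,
                            n_alleles = cntg$n_alleles,
                            source = "frequency_file")
  ft <- FrequencyTable(do.call(rbind, rows))
  cat <- toyCatalog(rsid = rownames(freqs), effect = rep("G", nrow(freqs)),
                    other = rep("A", nrow(freqs)))
  em <- buildEnrichmentMatrix(cat, ft, colnames(freqs))
  for (j in seq_len(ncol(freqs))) {
    d <- freqs[, j] - glob
    big <- abs(d) > 0.05
    expect_true(all(sign(em[big, j]) == sign(d[big])))
  }
})
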