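writeToyVcf <- function(path, samples, records) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), path)
  path
}

test_that("VCF dosages count copies of the effect allele", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeToyVcf(path, c("S1", "S2", "S3"), c(
    "1\t100\trs1001\tC\tT\t.\tPASS\t.\tGT\t0/1\t1/1\t./.",
    "1\t200\trs1002\tC\tG\t.\tPASS\t.\tGT\t0/1\t1/1\t0/0"))
  panel <- PopulationPanel(data.frame(sample_id = c("S1", "S2", "S3"),
                                      population = "P1"))
  # rs1001 effect = ALT (T); rs1002 effect = REF (C)
  cat <- toyCatalog(rsid = c("rs1001", "rs1002"), effect = c("T", "C"),
                    other = c("C", "G"))
  gm <- readVcfGenotypes(path, panel, cat)
  d <- dosages(gm)
  expect_equal(unname(d["rs1001", ]), c(1, 2, NA))
  expect_equal(unname(d["rs1002", ]), c(1, 0, 2))
})

test_that("VCF samples absent from the panel are an error, multi-allelic sites skipped", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeToyVcf(path, c("S1", "S2"), c(
    "1\t100\trs1001\tC\tT\t.\tPASS\t.\tGT\t0/1\t1/1",
    "1\t200\trs1002\tC\tG,A\t.\tPASS\t.\tGT\t0/1\t1/2"))
  panel1 <- PopulationPanel(data.frame(sample_id = "S1", population = "P1"))
  cat <- toyCatalog()
  expect_error(readVcfGenotypes(path, panel1, cat), "S2")
  panel <- PopulationPanel(data.frame(sample_id = c("S1", "S2"),
                                      population = "P1"))
  expect_warning(gm <- readVcfGenotypes(path, panel, cat), "multi-allelic")
  expect_equal(rownames(dosages(gm)), "rs1001")
})

test_that("published frequencies are re-oriented to the effect allele", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tref\talt\talt_freq\tn_individuals",
               "rs1001\tC\tT\t0.919\t1722",
               "rs1002\tC\tG\t0.000\t1722",
               "rs1003\tT\tA\t0.2\t1722"), path)
  cat <- toyCatalog(rsid = c("rs1001", "rs1002", "rs1003"),
                    effect = c("T", "G", "T"), other = c("C", "C", "A"))
  ft <- readFrequencyTable(path, cat, "KOR")
  tb <- freqRecords(ft)
  expect_equal(tb$eaf, c(0.919, 0.0, 0.8))
  expect_equal(tb$n_alleles, rep(3444L, 3))
  expect_equal(tb$k_effect[1], floor(0.919 * 3444 + 0.5))
  expect_equal(tb$source, rep("frequency_file", 3))
})

test_that("invalid published frequencies fail with the line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tref\talt\talt_freq\tn_individuals",
               "rs1001\tC\tT\t1.2\t10"), path)
  expect_error(readFrequencyTable(path, toyCatalog(), "KOR"), "line")
})

test_that("computeEaf counts alleles per group, excluding missing calls", {
  gm <- toyGenotypes(rbind(c(0, 1, 2), c(2, NA, NA)),
                     pops = c("P1", "P1", "P2"))
  tb <- freqRecords(suppressWarnings(computeEaf(gm, "population")))
  get <- function(r, p) tb[tb$rsid == r & tb$population == p, ]
  expect_equal(get("rs2001", "P1")$eaf, 0.25)
  expect_equal(get("rs2001", "P2")$eaf, 1.0)
  # missing calls shrink the denominator, no imputation
  expect_equal(get("rs2002", "P1")$eaf, 1.0)
  expect_equal(get("rs2002", "P1")$n_alleles, 2)
  expect_true(is.na(get("rs2002", "P2")$eaf))
})

test_that("GLOBAL eaf is the allele-count-weighted mean of population eafs", {
  set.seed(11)
  dos <- matrix(sample(0:2, 8 * 30, replace = TRUE), nrow = 8)
  gm <- toyGenotypes(dos, pops = rep(c("P1", "P2", "P3"), c(5, 10, 15)))
  pop <- freqRecords(computeEaf(gm, "population"))
  glob <- freqRecords(computeEaf(gm, "GLOBAL"))
  for (r in unique(pop$rsid)) {
    sub <- pop[pop$rsid == r, ]
    expect_equal(glob$eaf[glob$rsid == r],
                 sum(sub$eaf * sub$n_alleles) / sum(sub$n_alleles))
  }
})

test_that("counts reconstructed from frequencies invert exact counting", {
  expect_equal(countsFromFrequency(0.56, 2504),
               data.frame(k_effect = 2804, n_alleles = 5008))
  expect_equal(countsFromFrequency(0.785, 1722),
               data.frame(k_effect = 2704, n_alleles = 3444))
  expect_equal(countsFromFrequency(1.0, 10)$k_effect, 20)
  # half-up at the .5 boundary
  expect_equal(countsFromFrequency(0.105, 10)$k_effect, 2)
  # round trip: eaf from complete genotypes -> counts -> identical (k, n)
  set.seed(12)
  gm <- toyGenotypes(matrix(sample(0:2, 60, replace = TRUE), nrow = 6),
                     pops = rep("P1", 10))
  tb <- freqRecords(computeEaf(gm, "population"))
  cnt <- countsFromFrequency(tb$eaf, tb$n_alleles / 2)
  expect_equal(cnt$k_effect, tb$k_effect)
  expect_equal(cnt$n_alleles, tb$n_alleles)
})
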