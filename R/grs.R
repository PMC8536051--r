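#' @include methods.R
NULL

#' Composite genetic risk score of one individual
#'
#' Unweighted composite score: the individual's effect-allele dosages are
#' summed over the I catalog SNPs and divided by 2I, giving a score in
#' [0, 1] — 1 for a homozygous carrier of the effect allele at every SNP,
#' 0 for a carrier of none. Missing dosages are, by default, replaced by
#' their Hardy-Weinberg expectation 2p using the individual's population
#' EAF, which keeps the denominator at 2I; \code{missingPolicy = "strict"}
#' refuses missing data instead.
#'
#' @param dosages numeric vector of effect-allele dosages (0/1/2/NA) aligned
#'   to the catalog
#' @param eaf population effect-allele frequencies aligned to the catalog;
#'   only needed to impute missing dosages
#' @param missingPolicy \code{"impute"} or \code{"strict"}
#' @return list: \code{score} in [0, 1] and \code{I}, the number of SNPs
#' @examples
#' individualGrs(c(2, 1, 0, 1))$score   # 0.5
#' @export
individualGrs <- function(dosages, eaf = NULL,
                          missingPolicy = c("impute", "strict")) {
  missingPolicy <- match.arg(missingPolicy)
  I <- length(dosages)
  if (I < 1) stop("need at least one SNP")
  if (all(is.na(dosages))) stop("all dosages missing")
  if (anyNA(dosages)) {
    if (missingPolicy == "strict")
      stop(sum(is.na(dosages)), " missing dosage(s) under strict policy")
    if (is.null(eaf))
      stop("population EAFs required to impute missing dosages")
    stopifnot(length(eaf) == I)
    dosages[is.na(dosages)] <- 2 * eaf[is.na(dosages)]
  }
  list(score = sum(dosages) / (2 * I), I = I)
}

#' Per-population mean composite risk scores
#'
#' Scores every sample with \code{\link{individualGrs}} and summarizes by
#' population (mean, sd, n). With complete genotypes the population mean
#' equals the mean of the population's per-SNP EAFs exactly. Missing dosages
#' are imputed from the sample's own population EAF under the default
#' policy. Empty populations are skipped with a warning.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}
#' @param missingPolicy passed to \code{\link{individualGrs}}
#' @return list with \code{samples} (data.frame sample_id, population,
#'   score) and \code{cohorts} (data.frame population, mean_score, sd_score,
#'   n_samples)
#' @export
cohortGrs <- function(genotypes, missingPolicy = c("impute", "strict")) {
  missingPolicy <- match.arg(missingPolicy)
  d <- dosages(genotypes)
  cd <- SummarizedExperiment::colData(genotypes)
  pops <- unique(cd$population)
  eaf_by_pop <- NULL
  if (anyNA(d) && missingPolicy == "impute") {
    ft <- freqRecords(computeEaf(genotypes, "population"))
    eaf_by_pop <- lapply(stats::setNames(pops, pops), function(p) {
      sub <- ft[ft$population == p, ]
      sub$eaf[match(rownames(d), sub$rsid)]
    })
  }
  scores <- vapply(seq_len(ncol(d)), function(j) {
    individualGrs(d[, j],
                  eaf = eaf_by_pop[[cd$population[j]]],
                  missingPolicy = missingPolicy)$score
  }, numeric(1))
  samples <- data.frame(sample_id = cd$sample_id,
                        population = cd$population, score = scores)
  cohorts <- do.call(rbind, lapply(pops, function(p) {
    s <- scores[cd$population == p]
    data.frame(population = p, mean_score = mean(s),
               sd_score = stats::sd(s), n_samples = length(s))
  }))
  rownames(cohorts) <- NULL
  list(samples = samples, cohorts = cohorts)
}

#' Expected composite risk score from allele frequencies
#'
#' Closed form of the cohort mean score: under binomial dosages, the
#' expectation of the composite score is the mean of the per-SNP
#' effect-allele frequencies. Useful when only published frequencies, not
#' genotypes, are available for a cohort.
#'
#' @param freq a \linkS4class{FrequencyTable}
#' @param population population whose EAFs to average
#' @param catalog optional \linkS4class{SnpCatalog}; when given, all catalog
#'   SNPs must have an EAF, otherwise an error lists the missing ones
#' @return numeric scalar in [0, 1]
#' @export
expectedGrsFromEaf <- function(freq, population, catalog = NULL) {
  tb <- freqRecords(freq)
  tb <- tb[tb$population == population, , drop = FALSE]
  if (!is.null(catalog)) {
    miss <- setdiff(rsids(catalog), tb$rsid[!is.na(tb$eaf)])
    if (length(miss))
      stop("missing EAF for SNP(s): ", paste(miss, collapse = ", "))
    tb <- tb[match(rsids(catalog), tb$rsid), , drop = FALSE]
  }
  if (!nrow(tb)) stop("no rows for population ", population)
  mean(tb$eaf)
}

#' Two-phase frequency-concordance filter
#'
#' Excludes SNPs whose effect-allele frequency differs by more than the
#' threshold (default 0.10, strict inequality, absolute difference) between
#' a cohort's full frequency data and its individually genotyped second
#' phase — discordance that indicates genotyping or sampling artefacts.
#' Order-preserving and idempotent.
#'
#' @param catalog \linkS4class{SnpCatalog}
#' @param freqTotal numeric vector of full-cohort EAFs aligned to the
#'   catalog
#' @param freqPhase2 numeric vector of second-phase EAFs aligned to the
#'   catalog
#' @param threshold exclusion threshold on |difference|
#' @return list with \code{report} (data.frame rsid, freq_total,
#'   freq_phase2, abs_difference, excluded) and \code{catalog}, the filtered
#'   \linkS4class{SnpCatalog}
#' @export
phaseConcordanceFilter <- function(catalog, freqTotal, freqPhase2,
                                   threshold = 0.10) {
  ids <- rsids(catalog)
  if (length(freqTotal) != length(ids) || length(freqPhase2) != length(ids))
    stop("frequency vectors must align with the catalog (",
         length(ids), " SNPs)")
  if (!is.null(names(freqTotal)) && !identical(names(freqTotal), ids))
    stop("freqTotal names do not match catalog rsids")
  if (!is.null(names(freqPhase2)) && !identical(names(freqPhase2), ids))
    stop("freqPhase2 names do not match catalog rsids")
  diff <- abs(freqTotal - freqPhase2)
  excluded <- diff > threshold
  report <- data.frame(rsid = ids, freq_total = as.numeric(freqTotal),
                       freq_phase2 = as.numeric(freqPhase2),
                       abs_difference = as.numeric(diff), excluded = excluded)
  kept <- SnpCatalog(records(catalog)[!excluded, , drop = FALSE],
                     provenance = paste0(catalog@provenance,
                                         " | phase-concordance filtered"))
  list(report = report, catalog = kept)
}
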