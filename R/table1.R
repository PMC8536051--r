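#' @include methods.R
NULL

#' Packaged reference table of extreme Korean-enrichment SNPs
#'
#' The package ships, as a plain-text fixture, the published table of the 29
#' vitamin D concentration-associated SNPs whose signed log10 Fisher
#' statistic in the Korean cohort exceeds 100 in magnitude: per SNP the
#' GRCh37 position, mapped gene, ref/alt alleles, the global effect-allele
#' frequency, and per-population (AMR, AFR, EAS, SAS, EUR, KOR) the EAF and
#' the printed signed log10 p-value. \code{table1Snps} returns it as a
#' data.frame; \code{table1Catalog} as a \linkS4class{SnpCatalog} with the
#' alt allele as effect allele (the table's EAF convention);
#' \code{table1FrequencyTable} reconstructs integer allele counts from the
#' printed EAFs with the given panel sizes; \code{table1SignedMatrix}
#' returns the printed signed statistics as a SNP-by-population matrix.
#'
#' @return see individual descriptions
#' @name table1
NULL

.T1_POPS <- c("AMR", "AFR", "EAS", "SAS", "EUR", "KOR")

#' @rdname table1
#' @export
table1Snps <- function() {
  utils::read.delim(system.file("extdata", "table1_snps.tsv",
                                package = "vdfreq"), check.names = FALSE)
}

#' @rdname table1
#' @export
table1Catalog <- function() {
  t1 <- table1Snps()
  SnpCatalog(data.frame(
    rsid = t1$rsid, chrom = t1$chrom, position = t1$position,
    mapped_gene = t1$mapped_gene, functional_class = t1$functional_class,
    effect_allele = t1$alt_allele, other_allele = t1$ref_allele,
    effect_allele_resolved_by = "catalog"),
    provenance = "packaged reference table (29 extreme SNPs)")
}

#' Published 1000 Genomes phase 3 superpopulation sizes plus cohort sizes
#' used for count reconstruction (diploid individuals).
#'
#' @rdname table1
#' @export
table1PanelSizes <- function() {
  c(GLOBAL = 2504, AMR = 347, AFR = 661, EAS = 504, SAS = 489, EUR = 503,
    KOR = 1722)
}

#' @rdname table1
#' @param panelSizes named vector of diploid sample sizes per population
#'   (must include \code{GLOBAL} and each population column)
#' @export
table1FrequencyTable <- function(panelSizes = table1PanelSizes()) {
  t1 <- table1Snps()
  pops <- c("GLOBAL", .T1_POPS)
  stopifnot(all(pops %in% names(panelSizes)))
  rows <- lapply(pops, function(p) {
    eaf <- t1[[if (p == "GLOBAL") "eaf_GLOBAL" else paste0("eaf_", p)]]
    cnt <- countsFromFrequency(eaf, panelSizes[[p]])
    data.frame(rsid = t1$rsid, population = p, eaf = eaf,
               k_effect = cnt$k_effect, n_alleles = cnt$n_alleles,
               source = "frequency_file")
  })
  FrequencyTable(do.call(rbind, rows))
}

#' @rdname table1
#' @export
table1SignedMatrix <- function() {
  t1 <- table1Snps()
  m <- as.matrix(t1[, paste0("log10p_", .T1_POPS)])
  dimnames(m) <- list(t1$rsid, .T1_POPS)
  m
}
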