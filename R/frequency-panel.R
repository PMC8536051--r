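#' @include methods.R
NULL

# round half away from zero; Fisher p-values at extreme counts are sensitive
# to the rounding rule, so banker's rounding is deliberately avoided
.roundHalfUp <- function(x) floor(x + 0.5)

#' Read a sample-to-population map
#'
#' @param path TSV with columns \code{sample_id}, \code{population},
#'   \code{superpopulation}.
#' @return a \linkS4class{PopulationPanel}
#' @export
readPopulationPanel <- function(path) {
  PopulationPanel(utils::read.delim(path, colClasses = "character"))
}

#' Read effect-allele dosages from a VCF
#'
#' Extracts GT calls at the catalog's sites from a VCF of biallelic SNVs and
#' orients them to the catalog's effect allele: when the effect allele is the
#' VCF ALT the dosage is the number of ALT alleles in the call, when it is
#' the REF the dosage is 2 minus that count. Missing calls become NA.
#' Multi-allelic records at catalog rsids are skipped with a warning, as are
#' catalog SNPs whose ref/alt pair does not contain the effect allele.
#'
#' @param vcfPath VCF (v4.x) file with GT genotypes; variant IDs must be
#'   rsids.
#' @param panel \linkS4class{PopulationPanel}; every VCF sample must appear.
#' @param catalog \linkS4class{SnpCatalog}
#' @return a \linkS4class{GenotypeMatrix} over the catalog SNPs found in the
#'   VCF, rows in catalog order.
#' @export
readVcfGenotypes <- function(vcfPath, panel, catalog) {
  vcf <- VariantAnnotation::readVcf(vcfPath, genome = "GRCh37")
  smp <- panelSamples(panel)
  vcf_samples <- colnames(vcf)
  missing_samples <- setdiff(vcf_samples, smp$sample_id)
  if (length(missing_samples))
    stop("VCF sample(s) absent from panel: ",
         paste(missing_samples, collapse = ", "))

  rec <- records(catalog)
  ids <- rownames(vcf)
  multi <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf)) > 1L
  if (any(multi & ids %in% rec$rsid))
    warning(sum(multi & ids %in% rec$rsid),
            " multi-allelic site(s) at catalog rsids skipped")
  keep_rows <- rec$rsid %in% ids[!multi]
  rec <- rec[keep_rows, , drop = FALSE]
  vidx <- match(rec$rsid, ids)

  gt <- VariantAnnotation::geno(vcf)$GT[vidx, , drop = FALSE]
  ref <- as.character(VariantAnnotation::ref(vcf))[vidx]
  alt <- as.character(unlist(VariantAnnotation::alt(vcf)[vidx]))

  alt_count <- matrix(NA_real_, nrow(gt), ncol(gt),
                      dimnames = dimnames(gt))
  known <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "0|1" = 1, "1/0" = 1,
             "1|0" = 1, "1/1" = 2, "1|1" = 2)
  vals <- known[gt]
  dim(vals) <- dim(gt)
  alt_count[] <- vals

  is_alt <- rec$effect_allele == alt & rec$other_allele == ref
  is_ref <- rec$effect_allele == ref & rec$other_allele == alt
  bad <- !(is_alt | is_ref)
  if (any(bad)) {
    warning(sum(bad), " catalog SNP(s) whose alleles do not match the VCF ",
            "ref/alt pair skipped: ", paste(rec$rsid[bad], collapse = ", "))
    rec <- rec[!bad, , drop = FALSE]
    alt_count <- alt_count[!bad, , drop = FALSE]
    is_alt <- is_alt[!bad]
  }
  dos <- ifelse(rep(is_alt, ncol(alt_count)), alt_count, 2 - alt_count)
  dim(dos) <- dim(alt_count)
  dimnames(dos) <- list(rec$rsid, colnames(alt_count))
  GenotypeMatrix(dos, SnpCatalog(rec, provenance = vcfPath), panel)
}

#' Read a published per-variant frequency table
#'
#' Reads a frequency-database dialect TSV (one population, e.g. a national
#' reference cohort): columns \code{rsid}, \code{ref}, \code{alt},
#' \code{alt_freq} (alternate-allele frequency) and \code{n_individuals}
#' (diploid sample count). Frequencies are re-oriented to the catalog's
#' effect allele (1 − alt_freq when the effect allele is the file's ref) and
#' allele counts reconstructed as \code{n_alleles = 2 * n_individuals},
#' \code{k_effect = round(eaf * n_alleles)} (half-up).
#'
#' @param path frequency TSV
#' @param catalog \linkS4class{SnpCatalog}
#' @param population label for the resulting rows
#' @return a \linkS4class{FrequencyTable} with source
#'   \code{"frequency_file"}, restricted to catalog SNPs present in the file.
#' @export
readFrequencyTable <- function(path, catalog, population) {
  tb <- utils::read.delim(path)
  need <- c("rsid", "ref", "alt", "alt_freq", "n_individuals")
  miss <- setdiff(need, names(tb))
  if (length(miss))
    stop("frequency file lacks column(s): ", paste(miss, collapse = ", "))
  fr <- suppressWarnings(as.numeric(tb$alt_freq))
  bad <- is.na(fr) | fr < 0 | fr > 1
  if (any(bad))
    stop("invalid frequency at line(s) ",
         paste(which(bad) + 1L, collapse = ", "), " of ", path)

  rec <- records(catalog)
  idx <- match(rec$rsid, tb$rsid)
  keep <- which(!is.na(idx))
  rows <- lapply(keep, function(i) {
    j <- idx[i]
    eaf <- if (rec$effect_allele[i] == tb$alt[j] &&
               rec$other_allele[i] == tb$ref[j]) fr[j]
      else if (rec$effect_allele[i] == tb$ref[j] &&
               rec$other_allele[i] == tb$alt[j]) 1 - fr[j]
      else return(NULL)
    n_alleles <- 2L * as.integer(tb$n_individuals[j])
    data.frame(rsid = rec$rsid[i], population = population, eaf = eaf,
               k_effect = .roundHalfUp(eaf * n_alleles),
               n_alleles = n_alleles, source = "frequency_file")
  })
  dropped <- keep[vapply(rows, is.null, logical(1))]
  if (length(dropped))
    warning(length(dropped), " SNP(s) with mismatching alleles skipped: ",
            paste(rec$rsid[dropped], collapse = ", "))
  FrequencyTable(do.call(rbind, rows[!vapply(rows, is.null, logical(1))]))
}

#' Effect-allele frequencies by population group
#'
#' Counts effect alleles per SNP within each group of samples. Missing
#' genotypes reduce the denominator (no imputation): per group,
#' \code{k_effect} is the dosage sum over non-missing samples and
#' \code{n_alleles} twice their number. \code{grouping = "GLOBAL"} pools all
#' samples of the panel into one background group labelled \code{"GLOBAL"}.
#' A group with no non-missing call at a SNP yields an NA row, flagged with
#' a warning.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}
#' @param grouping \code{"population"}, \code{"superpopulation"} or
#'   \code{"GLOBAL"}
#' @return a \linkS4class{FrequencyTable} with source \code{"genotypes"}
#' @export
computeEaf <- function(genotypes,
                       grouping = c("population", "superpopulation",
                                    "GLOBAL")) {
  grouping <- match.arg(grouping)
  d <- dosages(genotypes)
  cd <- SummarizedExperiment::colData(genotypes)
  grp <- switch(grouping,
                population = cd$population,
                superpopulation = cd$superpopulation,
                GLOBAL = rep("GLOBAL", ncol(d)))
  out <- lapply(unique(grp), function(g) {
    dg <- d[, grp == g, drop = FALSE]
    k <- rowSums(dg, na.rm = TRUE)
    n <- 2 * rowSums(!is.na(dg))
    data.frame(rsid = rownames(d), population = g,
               eaf = ifelse(n > 0, k / n, NA_real_),
               k_effect = ifelse(n > 0, k, NA_real_), n_alleles = n,
               source = "genotypes")
  })
  out <- do.call(rbind, out)
  if (any(out$n_alleles == 0))
    warning(sum(out$n_alleles == 0),
            " group/SNP cell(s) with no non-missing calls set to NA")
  rownames(out) <- NULL
  FrequencyTable(out)
}

#' Reconstruct allele counts from a published frequency
#'
#' Inverts a reported effect-allele frequency into integer allele counts for
#' exact testing: \code{n_alleles = 2 * n_individuals} and
#' \code{k_effect = round(eaf * n_alleles)}, rounding half away from zero.
#'
#' @param eaf effect-allele frequency (vectorized), in [0, 1]
#' @param nIndividuals diploid sample count (scalar or vector)
#' @return data.frame with columns \code{k_effect}, \code{n_alleles}
#' @examples
#' countsFromFrequency(0.56, 2504)   # k_effect 2804 of 5008
#' @export
countsFromFrequency <- function(eaf, nIndividuals) {
  stopifnot(all(eaf >= 0 & eaf <= 1), all(nIndividuals > 0))
  n_alleles <- 2 * nIndividuals
  data.frame(k_effect = .roundHalfUp(eaf * n_alleles), n_alleles = n_alleles)
}

#' Write a FrequencyTable to TSV
#'
#' @param freq a \linkS4class{FrequencyTable}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeFrequencyTable <- function(freq, path) {
  utils::write.table(freqRecords(freq), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
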