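#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame metadata elementNROWS
NULL

.BASES <- c("A", "C", "G", "T")

#' Curated SNP catalog
#'
#' Ordered, deduplicated list of trait-associated SNPs with resolved effect
#' alleles. Each record carries the rsid, GRCh37 position, mapped gene,
#' functional class, the effect (risk) allele, the other allele, and how the
#' effect allele was resolved (\code{"catalog"} when the association file
#' stated it, \code{"minor_allele_fallback"} when it had to be taken as the
#' panel minor allele).
#'
#' @slot records data.frame with columns \code{rsid}, \code{chrom},
#'   \code{position}, \code{mapped_gene}, \code{functional_class},
#'   \code{effect_allele}, \code{other_allele}, \code{effect_allele_resolved_by}.
#' @slot provenance character scalar describing where the catalog came from.
#' @exportClass SnpCatalog
setClass("SnpCatalog",
  slots = c(records = "data.frame", provenance = "character"))

setValidity("SnpCatalog", function(object) {
  rec <- object@records
  need <- c("rsid", "chrom", "position", "mapped_gene", "functional_class",
            "effect_allele", "other_allele", "effect_allele_resolved_by")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    return(paste("missing record columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(rec$rsid))
    return("rsids must be unique")
  if (nrow(rec)) {
    if (!all(rec$effect_allele %in% .BASES) || !all(rec$other_allele %in% .BASES))
      return("alleles must be single bases A/C/G/T")
    if (any(rec$effect_allele == rec$other_allele))
      return("effect_allele must differ from other_allele")
  }
  TRUE
})

#' Sample-to-population panel
#'
#' Maps each sample to exactly one population and each population to a
#' superpopulation (continental) group.
#'
#' @slot samples data.frame with columns \code{sample_id}, \code{population},
#'   \code{superpopulation}.
#' @exportClass PopulationPanel
setClass("PopulationPanel", slots = c(samples = "data.frame"))

setValidity("PopulationPanel", function(object) {
  s <- object@samples
  need <- c("sample_id", "population", "superpopulation")
  miss <- setdiff(need, names(s))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(s$sample_id))
    return("sample_ids must be unique")
  if (nrow(s) && (any(!nzchar(s$population)) || any(!nzchar(s$superpopulation))))
    return("population labels must be non-empty")
  TRUE
})

#' Per-SNP, per-population effect-allele frequencies
#'
#' Long-format table keyed by (rsid, population) holding the effect-allele
#' frequency together with the underlying allele counts, so that exact Fisher
#' tests can be run downstream. \code{source} records whether a row was
#' counted from genotypes or reconstructed from a published frequency.
#'
#' @slot table data.frame with columns \code{rsid}, \code{population},
#'   \code{eaf}, \code{k_effect}, \code{n_alleles}, \code{source}.
#' @exportClass FrequencyTable
setClass("FrequencyTable", slots = c(table = "data.frame"))

setValidity("FrequencyTable", function(object) {
  tb <- object@table
  need <- c("rsid", "population", "eaf", "k_effect", "n_alleles", "source")
  miss <- setdiff(need, names(tb))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  ok <- stats::complete.cases(tb[, c("eaf", "k_effect", "n_alleles")])
  if (any(tb$eaf[ok] < 0 | tb$eaf[ok] > 1))
    return("eaf must lie in [0, 1]")
  if (any(tb$k_effect[ok] < 0 | tb$k_effect[ok] > tb$n_alleles[ok]))
    return("k_effect must lie in [0, n_alleles]")
  g <- ok & tb$source == "genotypes"
  if (any(abs(tb$eaf[g] - tb$k_effect[g] / tb$n_alleles[g]) > 1e-12))
    return("genotype-derived eaf must equal k_effect / n_alleles")
  if (anyDuplicated(tb[, c("rsid", "population")]))
    return("(rsid, population) keys must be unique")
  TRUE
})

#' Effect-allele dosage matrix
#'
#' SNP-by-sample matrix of effect-allele dosages (0/1/2, NA for missing
#' calls), stored as a \linkS4class{SummarizedExperiment} with assay
#' \code{"dosage"}; \code{rowData} carries the catalog fields and
#' \code{colData} the sample-to-population map.
#'
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is required")
  d <- SummarizedExperiment::assay(object, "dosage")
  v <- d[!is.na(d)]
  if (length(v) && !all(v %in% c(0, 1, 2)))
    return("dosages must be 0, 1, 2 or NA")
  if (!all(c("sample_id", "population") %in%
           names(SummarizedExperiment::colData(object))))
    return("colData must carry sample_id and population")
  TRUE
})
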