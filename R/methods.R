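#' @include AllGenerics.R
NULL

#' Construct a SnpCatalog
#'
#' @param records data.frame of catalog records (see
#'   \linkS4class{SnpCatalog}); missing optional columns are filled with NA.
#' @param provenance free-text description of the source.
#' @return a \linkS4class{SnpCatalog}
#' @export
SnpCatalog <- function(records, provenance = "unspecified") {
  records <- as.data.frame(records)
  for (col in c("mapped_gene", "functional_class"))
    if (is.null(records[[col]])) records[[col]] <- NA_character_
  if (is.null(records$chrom)) records$chrom <- NA_character_
  if (is.null(records$position)) records$position <- NA_integer_
  if (is.null(records$effect_allele_resolved_by))
    records$effect_allele_resolved_by <- "catalog"
  rownames(records) <- NULL
  new("SnpCatalog", records = records, provenance = provenance)
}

#' Construct a PopulationPanel
#'
#' @param samples data.frame with columns sample_id, population,
#'   superpopulation (superpopulation defaults to the population label).
#' @return a \linkS4class{PopulationPanel}
#' @export
PopulationPanel <- function(samples) {
  samples <- as.data.frame(samples)
  if (is.null(samples$superpopulation))
    samples$superpopulation <- samples$population
  samples$sample_id <- as.character(samples$sample_id)
  rownames(samples) <- NULL
  new("PopulationPanel", samples = samples)
}

#' Construct a FrequencyTable
#'
#' @param table long-format data.frame with columns rsid, population, eaf,
#'   k_effect, n_alleles, source.
#' @return a \linkS4class{FrequencyTable}
#' @export
FrequencyTable <- function(table) {
  table <- as.data.frame(table)
  if (is.null(table$source)) table$source <- "genotypes"
  rownames(table) <- NULL
  new("FrequencyTable", table = table)
}

#' Construct a GenotypeMatrix
#'
#' @param dosage SNP-by-sample numeric matrix of effect-allele dosages
#'   (0/1/2/NA); rownames are rsids, colnames sample ids.
#' @param catalog \linkS4class{SnpCatalog} aligned to the rows.
#' @param panel \linkS4class{PopulationPanel} covering the columns.
#' @return a \linkS4class{GenotypeMatrix}
#' @export
GenotypeMatrix <- function(dosage, catalog, panel) {
  dosage <- as.matrix(dosage)
  rec <- records(catalog)
  stopifnot(nrow(dosage) == nrow(rec))
  if (is.null(rownames(dosage))) rownames(dosage) <- rec$rsid
  smp <- panelSamples(panel)
  idx <- match(colnames(dosage), smp$sample_id)
  if (anyNA(idx))
    stop("samples absent from panel: ",
         paste(colnames(dosage)[is.na(idx)], collapse = ", "))
  cd <- S4Vectors::DataFrame(sample_id = smp$sample_id[idx],
                             population = smp$population[idx],
                             superpopulation = smp$superpopulation[idx],
                             row.names = colnames(dosage))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage),
    rowData = S4Vectors::DataFrame(rec, row.names = rec$rsid),
    colData = cd)
  new("GenotypeMatrix", se)
}

#' @rdname accessors
#' @export
setMethod("records", "SnpCatalog", function(x) x@records)

#' @rdname accessors
#' @export
setMethod("rsids", "SnpCatalog", function(x) x@records$rsid)

#' @rdname accessors
#' @export
setMethod("effectAlleles", "SnpCatalog", function(x)
  stats::setNames(x@records$effect_allele, x@records$rsid))

#' @rdname accessors
#' @export
setMethod("panelSamples", "PopulationPanel", function(x) x@samples)

#' @rdname accessors
#' @param unique logical; return unique population labels instead of the
#'   per-sample vector
#' @export
setMethod("populations", "PopulationPanel", function(x, unique = FALSE) {
  p <- x@samples$population
  if (unique) base::unique(p) else stats::setNames(p, x@samples$sample_id)
})

#' @rdname accessors
#' @export
setMethod("superpopulations", "PopulationPanel", function(x) {
  s <- x@samples[!duplicated(x@samples$population), ]
  stats::setNames(s$superpopulation, s$population)
})

#' @rdname accessors
#' @export
setMethod("freqRecords", "FrequencyTable", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("getEaf", "FrequencyTable", function(x, rsid, population) {
  tb <- x@table
  hit <- tb$rsid == rsid & tb$population == population
  if (!any(hit)) return(NA_real_)
  tb$eaf[hit][1L]
})

#' @rdname accessors
#' @export
setMethod("dosages", "GenotypeMatrix", function(x)
  SummarizedExperiment::assay(x, "dosage"))

#' @rdname accessors
#' @export
setMethod("samplePanel", "GenotypeMatrix", function(x) {
  cd <- SummarizedExperiment::colData(x)
  PopulationPanel(data.frame(sample_id = cd$sample_id,
                             population = cd$population,
                             superpopulation = cd$superpopulation))
})

setMethod("show", "SnpCatalog", function(object) {
  cat("SnpCatalog with", nrow(object@records), "SNPs\n")
  cat("  provenance:", object@provenance, "\n")
  by <- table(object@records$effect_allele_resolved_by)
  if (length(by))
    cat("  effect allele resolved by:",
        paste(sprintf("%s (%d)", names(by), by), collapse = ", "), "\n")
})

setMethod("show", "PopulationPanel", function(object) {
  s <- object@samples
  cat("PopulationPanel:", nrow(s), "samples,",
      length(unique(s$population)), "populations,",
      length(unique(s$superpopulation)), "superpopulations\n")
})

setMethod("show", "FrequencyTable", function(object) {
  tb <- object@table
  cat("FrequencyTable:", nrow(tb), "rows (",
      length(unique(tb$rsid)), "SNPs x",
      length(unique(tb$population)), "populations )\n")
})
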