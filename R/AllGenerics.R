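#' @include AllClasses.R
NULL

#' Accessors for vdfreq classes
#'
#' \code{records} returns the record data.frame of a \linkS4class{SnpCatalog};
#' \code{rsids} its SNP identifiers; \code{effectAlleles} a named vector of
#' effect alleles. \code{panelSamples} returns the sample map of a
#' \linkS4class{PopulationPanel}; \code{populations} the population label per
#' sample (or the unique labels with \code{unique = TRUE});
#' \code{superpopulations} the population-to-superpopulation map.
#' \code{freqRecords} returns the long-format table of a
#' \linkS4class{FrequencyTable} and \code{getEaf} one frequency.
#' \code{dosages} returns the dosage assay of a \linkS4class{GenotypeMatrix}.
#'
#' @param x object
#' @param ... further arguments passed to methods
#' @return see individual descriptions
#' @name accessors
#' @aliases records rsids effectAlleles panelSamples populations
#'   superpopulations freqRecords getEaf dosages samplePanel
NULL

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname accessors
#' @export
setGeneric("rsids", function(x) standardGeneric("rsids"))

#' @rdname accessors
#' @export
setGeneric("effectAlleles", function(x) standardGeneric("effectAlleles"))

#' @rdname accessors
#' @export
setGeneric("panelSamples", function(x) standardGeneric("panelSamples"))

#' @rdname accessors
#' @export
setGeneric("populations", function(x, ...) standardGeneric("populations"))

#' @rdname accessors
#' @export
setGeneric("superpopulations", function(x) standardGeneric("superpopulations"))

#' @rdname accessors
#' @export
setGeneric("freqRecords", function(x) standardGeneric("freqRecords"))

#' @rdname accessors
#' @param rsid SNP identifier
#' @param population population label
#' @export
setGeneric("getEaf", function(x, rsid, population) standardGeneric("getEaf"))

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname accessors
#' @export
setGeneric("samplePanel", function(x) standardGeneric("samplePanel"))
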