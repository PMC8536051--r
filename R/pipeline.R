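#' @include methods.R
NULL

#' Panel ref/alt alleles and alt frequency from a VCF
#'
#' Reads a biallelic-SNV VCF and tabulates, per variant, the ref and alt
#' alleles and the empirical alt-allele frequency over all samples —
#' the panel-side input to \code{\link{harmonizeWithPanel}}. Multi-allelic
#' records are dropped.
#'
#' @param vcfPath VCF file with GT genotypes
#' @return data.frame with columns \code{rsid}, \code{ref}, \code{alt},
#'   \code{alt_freq}
#' @export
panelAllelesFromVcf <- function(vcfPath) {
  vcf <- VariantAnnotation::readVcf(vcfPath, genome = "GRCh37")
  multi <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf)) > 1L
  vcf <- vcf[!multi, ]
  gt <- VariantAnnotation::geno(vcf)$GT
  known <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "0|1" = 1, "1/0" = 1,
             "1|0" = 1, "1/1" = 2, "1|1" = 2)
  cnt <- known[gt]
  dim(cnt) <- dim(gt)
  data.frame(rsid = rownames(vcf),
             ref = as.character(VariantAnnotation::ref(vcf)),
             alt = as.character(unlist(VariantAnnotation::alt(vcf))),
             alt_freq = rowSums(cnt, na.rm = TRUE) /
               (2 * rowSums(!is.na(cnt))))
}

#' Pipeline configuration
#'
#' Declarative configuration of a full run. Every analysis choice that is a
#' genuine judgement call is a named option with its default documented:
#' \code{background_mode} (\code{"inclusive"}: each group is tested against
#' the pooled global panel as-is; \code{"complement"} subtracts the group
#' first), \code{alpha} (0.05, no multiple-testing correction by default),
#' \code{extreme_threshold} (100 on the |signed log10 p| scale),
#' \code{phase_threshold} (0.10 absolute frequency difference, strict),
#' \code{missing_policy} (\code{"impute"}), \code{cluster_metric}
#' (\code{"correlation"}), \code{cluster_linkage} (\code{"complete"}),
#' \code{reference_population} (\code{"EUR"}).
#'
#' @param catalog_path GWAS-catalog association TSV
#' @param vcf_path genotype VCF
#' @param sample_map_path sample-to-population TSV
#' @param freq_path optional frequency-cohort TSV
#' @param freq_population label for the frequency cohort (default
#'   \code{"KOR"})
#' @param phenotype_path optional phenotype TSV
#' @param out_dir output directory
#' @param grouping \code{"superpopulation"} or \code{"population"}
#' @param background_mode,alpha,extreme_threshold,phase_threshold see above
#' @param missing_policy,cluster_metric,cluster_linkage see above
#' @param reference_population reference for difference regressions
#' @param seed integer seed recorded in the manifest
#' @return list of class \code{vdfreqPipelineConfig}
#' @export
pipelineConfig <- function(catalog_path, vcf_path, sample_map_path,
                           freq_path = NULL, freq_population = "KOR",
                           phenotype_path = NULL, out_dir = "vdfreq_out",
                           grouping = "superpopulation",
                           background_mode = "inclusive", alpha = 0.05,
                           extreme_threshold = 100, phase_threshold = 0.10,
                           missing_policy = "impute",
                           cluster_metric = "correlation",
                           cluster_linkage = "complete",
                           reference_population = "EUR", seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(alpha > 0, alpha < 1, extreme_threshold > 0,
            phase_threshold >= 0)
  structure(cfg, class = "vdfreqPipelineConfig")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are \code{\link{pipelineConfig}}
#'   arguments
#' @return list of class \code{vdfreqPipelineConfig}
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

.checkInputs <- function(config) {
  for (p in c(config$catalog_path, config$vcf_path,
              config$sample_map_path, config$freq_path,
              config$phenotype_path))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
}

.out <- function(config, f) file.path(config$out_dir, f)

.stageFile <- function(config, f) {
  p <- .out(config, f)
  if (!file.exists(p))
    stop("stage input ", f, " not found under ", config$out_dir,
         "; run the producing stage first")
  p
}

.readGenotypeStage <- function(config) {
  catalog <- readSnpCatalog(.stageFile(config, "catalog.tsv"))
  panel <- readPopulationPanel(config$sample_map_path)
  gm <- readVcfGenotypes(config$vcf_path, panel, catalog)
  list(catalog = catalog, panel = panel, genotypes = gm)
}

#' Run one pipeline stage
#'
#' Executes a single stage of \code{\link{runPipeline}} against the
#' configuration's output directory, reading any upstream stage outputs from
#' disk, so that running the stages one by one composes to exactly the same
#' outputs as one full run. Stages and their products: \code{curate}
#' (catalog.tsv), \code{freqs} (frequencies.tsv), \code{enrich}
#' (enrichment_matrix.tsv, classification.tsv, population_tree.nwk),
#' \code{grs} (grs_samples.tsv, grs_groups.tsv, grs_cohorts.tsv),
#' \code{associate} (association.json).
#'
#' @param config a \code{\link{pipelineConfig}} or YAML path
#' @param stage stage name
#' @return the stage's manifest fragment, invisibly
#' @export
runStage <- function(config, stage = c("curate", "freqs", "enrich", "grs",
                                       "associate")) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stage <- match.arg(stage)
  .checkInputs(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  frag <- switch(stage,
    curate = {
      assoc <- readGwasCatalog(config$catalog_path)
      dedup <- dedupAssociations(assoc)
      catalog <- harmonizeWithPanel(dedup,
                                    panelAllelesFromVcf(config$vcf_path))
      writeSnpCatalog(catalog, .out(config, "catalog.tsv"))
      list(associations = nrow(assoc), after_dedup = nrow(dedup),
           after_harmonization = nrow(records(catalog)))
    },
    freqs = {
      st <- .readGenotypeStage(config)
      tb <- rbind(freqRecords(computeEaf(st$genotypes, config$grouping)),
                  freqRecords(computeEaf(st$genotypes, "GLOBAL")))
      if (!is.null(config$freq_path)) {
        fcoh <- readFrequencyTable(config$freq_path, st$catalog,
                                   config$freq_population)
        tb <- rbind(tb, freqRecords(fcoh))
      }
      writeFrequencyTable(FrequencyTable(tb),
                          .out(config, "frequencies.tsv"))
      list(rows = nrow(tb),
           groups = setdiff(unique(tb$population),
                            c("GLOBAL", config$freq_population)))
    },
    enrich = {
      catalog <- readSnpCatalog(.stageFile(config, "catalog.tsv"))
      freq <- FrequencyTable(utils::read.delim(
        .stageFile(config, "frequencies.tsv")))
      pops <- setdiff(unique(freqRecords(freq)$population), "GLOBAL")
      em <- buildEnrichmentMatrix(catalog, freq, pops,
                                  backgroundMode = config$background_mode)
      writeEnrichmentMatrix(em, .out(config, "enrichment_matrix.tsv"))
      cls <- lapply(stats::setNames(pops, pops), function(p)
        classifySnps(em, p, alpha = config$alpha,
                     extremeThreshold = config$extreme_threshold))
      cls_df <- do.call(rbind, lapply(pops, function(p)
        data.frame(population = p, t(cls[[p]]$counts))))
      utils::write.table(cls_df, .out(config, "classification.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      hc <- clusterPopulations(em, metric = config$cluster_metric,
                               linkage = config$cluster_linkage)
      exportNewick(hc, .out(config, "population_tree.nwk"))
      list(matrix_shape = dim(em), populations = pops,
           classification = lapply(cls, function(x) as.list(x$counts)),
           root_bipartition = rootBipartition(hc))
    },
    grs = {
      st <- .readGenotypeStage(config)
      grs <- cohortGrs(st$genotypes,
                       missingPolicy = config$missing_policy)
      utils::write.table(grs$samples, .out(config, "grs_samples.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      cohorts <- grs$cohorts
      if (!is.null(config$freq_path)) {
        # a frequency-only cohort has no per-sample scores; report the
        # frequency-based expectation of the composite score instead
        freq <- FrequencyTable(utils::read.delim(
          .stageFile(config, "frequencies.tsv")))
        cohorts <- rbind(cohorts, data.frame(
          population = config$freq_population,
          mean_score = expectedGrsFromEaf(freq, config$freq_population),
          sd_score = NA_real_, n_samples = NA_integer_))
      }
      sp <- superpopulations(st$panel)
      grp_of <- if (config$grouping == "superpopulation")
        sp[grs$samples$population] else grs$samples$population
      grp_scores <- split(grs$samples$score, grp_of)
      grp_df <- data.frame(
        population = names(grp_scores),
        mean_score = vapply(grp_scores, mean, numeric(1)),
        sd_score = vapply(grp_scores, stats::sd, numeric(1)),
        n_samples = lengths(grp_scores))
      utils::write.table(grp_df, .out(config, "grs_groups.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(cohorts, .out(config, "grs_cohorts.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(samples = nrow(grs$samples), cohorts = cohorts$population)
    },
    associate = {
      if (is.null(config$phenotype_path))
        return(invisible(NULL))
      ph <- readPhenotypeTable(config$phenotype_path)
      grp_df <- utils::read.delim(.stageFile(config, "grs_groups.tsv"))
      cohorts <- utils::read.delim(.stageFile(config, "grs_cohorts.tsv"))
      ph$grs <- grp_df$mean_score[match(ph$population, grp_df$population)]
      if (anyNA(ph$grs)) {
        fq <- cohorts$mean_score[match(ph$population, cohorts$population)]
        ph$grs[is.na(ph$grs)] <- fq[is.na(ph$grs)]
      }
      ph <- ph[!is.na(ph$grs), , drop = FALSE]
      da <- differenceAnalysis(ph, reference = config$reference_population)
      fits <- list(
        grs_fit = list(coefficients = as.list(da$grs_fit$coefficients),
                       r_squared = da$grs_fit$r_squared,
                       n = da$grs_fit$n_points),
        latitude_fit = list(
          coefficients = as.list(da$latitude_fit$coefficients),
          r_squared = da$latitude_fit$r_squared,
          n = da$latitude_fit$n_points),
        reference = config$reference_population)
      jsonlite::write_json(fits, .out(config, "association.json"),
                           auto_unbox = TRUE, digits = NA)
      list(r_squared_grs = da$grs_fit$r_squared,
           r_squared_latitude = da$latitude_fit$r_squared)
    })
  invisible(frag)
}

#' Run the full analysis pipeline
#'
#' Executes curate (catalog parsing, deduplication, panel harmonization) ->
#' frequencies (VCF dosages, per-group and global EAFs, optional
#' frequency-cohort table) -> enrichment (signed log10 Fisher matrix,
#' per-group classification, population clustering) -> risk scores
#' (per-sample and per-cohort composite scores, frequency-based expected
#' score for the frequency cohort) -> association (difference regressions,
#' when phenotypes are supplied). All stage outputs are written under
#' \code{out_dir} as TSV/JSON/Newick, plus a JSON manifest recording the
#' package version, seed, input checksums and row counts at every filter.
#' Identical to running the stages individually with \code{\link{runStage}}.
#'
#' @param config a \code{\link{pipelineConfig}} or path to a YAML file
#' @return the manifest, invisibly
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  .checkInputs(config)
  manifest <- list(
    package = as.character(utils::packageVersion("vdfreq")),
    seed = config$seed,
    inputs = lapply(
      Filter(Negate(is.null),
             config[c("catalog_path", "vcf_path", "sample_map_path",
                      "freq_path", "phenotype_path")]),
      function(p) unname(tools::md5sum(p))))
  manifest$curate <- runStage(config, "curate")
  manifest$frequencies <- runStage(config, "freqs")
  manifest$enrichment <- runStage(config, "enrich")
  manifest$grs <- runStage(config, "grs")
  if (!is.null(config$phenotype_path))
    manifest$association <- runStage(config, "associate")
  jsonlite::write_json(manifest, .out(config, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
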