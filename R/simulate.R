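#' @include methods.R
NULL

# substream offsets: each stage reseeds from the root so stages can be
# regenerated independently; kept well below 2^31
.SUBSTREAM <- c(frequencies = 101L, genotypes = 211L, phenotypes = 307L,
                subsampling = 401L)

.substreamSeed <- function(seed, stream) {
  (as.integer(seed) + .SUBSTREAM[[stream]]) %% .Machine$integer.max
}

#' Simulation configuration
#'
#' Bundles the parameters of the multi-population generator. The default
#' population layout mirrors the study design this package analyses: five
#' continental groups with the published 1000 Genomes phase 3 sample sizes
#' (AFR 661, AMR 347, EAS 504, EUR 503, SAS 489) plus an external Korean
#' cohort of 1722, over I = 320 SNPs. Differentiation is Balding-Nichols:
#' each population's allele frequency is Beta-distributed around the
#' ancestral frequency with variance F * p0 * (1 - p0), F acting as an
#' F_ST-like drift parameter (defaults 0.07-0.15, the range typical of
#' human continental groups). Phenotypes follow
#' concentration = b0 + b_grs * GRS + b_lat * latitude + Normal(0, sigma).
#'
#' @param populations data.frame with columns \code{label}, \code{n},
#'   \code{fst}, \code{latitude} and optionally \code{clade} (NA = no clade
#'   level)
#' @param I number of SNPs
#' @param ancestralFreqRange interval the ancestral frequencies are drawn
#'   uniformly from
#' @param cladeFst drift of clade-level intermediate frequencies around the
#'   ancestral frequency (used only for populations with a clade label)
#' @param beta0 baseline concentration (ng/mL)
#' @param betaGrs concentration change per unit of mean composite score
#'   (ng/mL)
#' @param betaLat concentration change per degree of latitude (ng/mL)
#' @param sigma phenotype noise sd (ng/mL)
#' @param seed root seed; all stages derive fixed substreams from it
#' @return a list of class \code{vdfreqSimConfig}
#' @export
simulationConfig <- function(
    populations = data.frame(
      label = c("AFR", "AMR", "EAS", "EUR", "SAS", "KOR"),
      n = c(661L, 347L, 504L, 503L, 489L, 1722L),
      fst = c(0.15, 0.07, 0.12, 0.08, 0.08, 0.12),
      latitude = c(0, 15, 35, 50, 25, 37),
      clade = NA_character_),
    I = 320L,
    ancestralFreqRange = c(0.05, 0.95),
    cladeFst = 0.1,
    beta0 = 25, betaGrs = 30, betaLat = -0.15, sigma = 1,
    seed = 1L) {
  populations <- as.data.frame(populations)
  if (is.null(populations$clade)) populations$clade <- NA_character_
  stopifnot(all(populations$fst > 0 & populations$fst < 1),
            I >= 1, sigma >= 0,
            ancestralFreqRange[1] > 0, ancestralFreqRange[2] < 1)
  structure(list(populations = populations, I = as.integer(I),
                 ancestralFreqRange = ancestralFreqRange,
                 cladeFst = cladeFst, beta0 = beta0, betaGrs = betaGrs,
                 betaLat = betaLat, sigma = sigma,
                 seed = as.integer(seed)),
            class = "vdfreqSimConfig")
}

.rBaldingNichols <- function(p0, fst) {
  a <- p0 * (1 - fst) / fst
  b <- (1 - p0) * (1 - fst) / fst
  stats::rbeta(length(p0), a, b)
}

#' Simulate population allele frequencies (Balding-Nichols)
#'
#' Draws ancestral effect-allele frequencies uniformly from the configured
#' range, then one frequency per population from the Balding-Nichols Beta
#' around them. Populations sharing a clade label first receive a common
#' clade-level intermediate frequency (drift \code{cladeFst} from the
#' ancestor), around which their own frequencies drift — giving a two-level
#' population tree whose clades clustering should recover.
#'
#' @param config a \code{\link{simulationConfig}}
#' @return list: \code{frequencies} (I x populations matrix) and
#'   \code{truth} (ancestral frequencies, clade frequencies, clade
#'   assignments, config)
#' @export
simulateAlleleFrequencies <- function(config) {
  set.seed(.substreamSeed(config$seed, "frequencies"))
  pops <- config$populations
  I <- config$I
  p0 <- stats::runif(I, config$ancestralFreqRange[1],
                     config$ancestralFreqRange[2])
  clades <- unique(pops$clade[!is.na(pops$clade)])
  clade_freq <- NULL
  if (length(clades)) {
    clade_freq <- vapply(clades,
                         function(cl) .rBaldingNichols(p0, config$cladeFst),
                         numeric(I))
    colnames(clade_freq) <- clades
  }
  freq <- vapply(seq_len(nrow(pops)), function(j) {
    base <- if (!is.na(pops$clade[j])) clade_freq[, pops$clade[j]] else p0
    .rBaldingNichols(base, pops$fst[j])
  }, numeric(I))
  dimnames(freq) <- list(sprintf("rs%07d", seq_len(I) + 1e6), pops$label)
  list(frequencies = freq,
       truth = list(p0 = p0, clade_frequencies = clade_freq,
                    clades = stats::setNames(pops$clade, pops$label),
                    config = config))
}

# synthetic biallelic ref/alt pairs, effect allele = alt
.syntheticCatalog <- function(freq, config) {
  I <- nrow(freq)
  ref <- rep(c("A", "C", "G", "T"), length.out = I)
  alt <- rep(c("G", "T", "A", "C"), length.out = I)
  SnpCatalog(data.frame(
    rsid = rownames(freq), chrom = as.character(1 + (seq_len(I) - 1) %% 22),
    position = 10000L + 100L * seq_len(I),
    mapped_gene = NA_character_, functional_class = NA_character_,
    effect_allele = alt, other_allele = ref,
    effect_allele_resolved_by = "catalog"),
    provenance = sprintf("synthetic (seed %d)", config$seed))
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Dosages are Binomial(2, p_pop) independently per sample and SNP.
#'
#' @param frequencies I x populations matrix from
#'   \code{\link{simulateAlleleFrequencies}}
#' @param config the same \code{\link{simulationConfig}}
#' @return list: \code{genotypes} (a \linkS4class{GenotypeMatrix}),
#'   \code{panel}, \code{catalog} (the synthetic \linkS4class{SnpCatalog}
#'   backing the rows)
#' @export
simulateGenotypes <- function(frequencies, config) {
  set.seed(.substreamSeed(config$seed, "genotypes"))
  pops <- config$populations
  I <- nrow(frequencies)
  mats <- lapply(seq_len(nrow(pops)), function(j) {
    m <- matrix(stats::rbinom(I * pops$n[j], 2, rep(frequencies[, j],
                                                    pops$n[j])),
                nrow = I)
    colnames(m) <- sprintf("%s_%04d", pops$label[j], seq_len(pops$n[j]))
    m
  })
  dos <- do.call(cbind, mats)
  rownames(dos) <- rownames(frequencies)
  panel <- PopulationPanel(data.frame(
    sample_id = colnames(dos),
    population = rep(pops$label, pops$n),
    superpopulation = rep(pops$label, pops$n)))
  catalog <- .syntheticCatalog(frequencies, config)
  list(genotypes = GenotypeMatrix(dos, catalog, panel), panel = panel,
       catalog = catalog)
}

#' Simulate population phenotypes
#'
#' Mean 25(OH)D3 concentration per population, linear in the population's
#' mean composite risk score and latitude with independent Gaussian noise:
#' concentration = b0 + b_grs * GRS + b_lat * latitude + Normal(0, sigma).
#'
#' @param grs named vector of population mean composite scores
#' @param latitudes named vector of latitudes (degrees), same populations
#' @param config the \code{\link{simulationConfig}}
#' @return data.frame: population, concentration, latitude, grs
#' @export
simulatePhenotypes <- function(grs, latitudes, config) {
  stopifnot(length(grs) == length(latitudes))
  set.seed(.substreamSeed(config$seed, "phenotypes"))
  eps <- stats::rnorm(length(grs), 0, config$sigma)
  data.frame(population = names(grs),
             concentration = config$beta0 + config$betaGrs * as.numeric(grs) +
               config$betaLat * as.numeric(latitudes) + eps,
             latitude = as.numeric(latitudes), grs = as.numeric(grs))
}

#' Simulate a two-phase cohort frequency comparison
#'
#' Emulates a reference cohort whose full data (n_total individuals) and
#' individually genotyped second phase (a random subsample of n_phase2) are
#' compared SNP by SNP. Genotypes are drawn once for the full cohort; the
#' phase-2 frequency is the empirical frequency of the subsample. A chosen
#' number of SNPs then receive an injected phase-2 shift of magnitude
#' \code{shift} (> 0.10) so the concordance filter has known positives.
#'
#' @param frequencies vector of population allele frequencies (one cohort)
#' @param nTotal full cohort size (individuals)
#' @param nPhase2 second-phase size
#' @param nDiscordant number of SNPs to inject discordance into (the first
#'   \code{nDiscordant} SNPs, for auditability)
#' @param config the \code{\link{simulationConfig}}
#' @param shift injected absolute frequency shift
#' @return list: \code{freq_total}, \code{freq_phase2} (named vectors) and
#'   \code{discordant}, the injected SNP names
#' @export
simulateTwoPhase <- function(frequencies, nTotal, nPhase2, nDiscordant = 0,
                             config, shift = 0.15) {
  stopifnot(nPhase2 <= nTotal, nDiscordant <= length(frequencies),
            shift > 0.10)
  set.seed(.substreamSeed(config$seed, "subsampling"))
  I <- length(frequencies)
  dos <- matrix(stats::rbinom(I * nTotal, 2, rep(frequencies, nTotal)),
                nrow = I)
  freq_total <- rowSums(dos) / (2 * nTotal)
  sub <- sample.int(nTotal, nPhase2)
  freq_phase2 <- rowSums(dos[, sub, drop = FALSE]) / (2 * nPhase2)
  disc <- character(0)
  if (nDiscordant > 0) {
    idx <- seq_len(nDiscordant)
    dir <- ifelse(freq_phase2[idx] <= 0.5, 1, -1)
    freq_phase2[idx] <- pmin(1, pmax(0, freq_phase2[idx] + dir * shift))
    disc <- names(frequencies)[idx]
    if (is.null(disc)) disc <- as.character(idx)
  }
  nm <- names(frequencies)
  if (!is.null(nm)) names(freq_total) <- names(freq_phase2) <- nm
  list(freq_total = freq_total, freq_phase2 = freq_phase2,
       discordant = disc)
}

#' Write simulated data as on-disk fixtures
#'
#' Emits the same plain-text formats the real pipeline consumes, so
#' simulated and downloaded data are interchangeable: a VCF (v4.2, GT only)
#' with the synthetic genotypes, a sample-to-population map TSV, a
#' frequency-database dialect TSV for the designated frequency-only cohort,
#' a GWAS-catalog dialect association TSV (with injected duplicate rows and
#' a "?" risk-allele token so curation code paths are exercised), and a
#' phenotype TSV.
#'
#' @param sim list from \code{\link{simulateGenotypes}}
#' @param dir output directory (created if needed)
#' @param freqPopulation population written as the frequency-file cohort
#'   (default the last one); it is excluded from the VCF, mirroring a
#'   cohort external to the genotype panel
#' @param phenotypes optional data.frame from
#'   \code{\link{simulatePhenotypes}}
#' @return named character vector of file paths
#' @export
emitFixtures <- function(sim, dir, freqPopulation = NULL,
                         phenotypes = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gm <- sim$genotypes
  rec <- records(sim$catalog)
  smp <- panelSamples(sim$panel)
  if (is.null(freqPopulation))
    freqPopulation <- utils::tail(unique(smp$population), 1)
  vcf_samples <- smp$sample_id[smp$population != freqPopulation]
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             sample_map = file.path(dir, "samples.tsv"),
             freq = file.path(dir, "cohort_freq.tsv"),
             catalog = file.path(dir, "associations.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"))

  d <- dosages(gm)[, vcf_samples, drop = FALSE]
  gt <- matrix("./.", nrow(d), ncol(d))
  gt[!is.na(d) & d == 0] <- "0/0"
  gt[!is.na(d) & d == 1] <- "0/1"
  gt[!is.na(d) & d == 2] <- "1/1"
  # catalog effect allele is the synthetic alt
  header <- c("##fileformat=VCFv4.2",
              "##source=vdfreq-simulator",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", vcf_samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(d)), function(i) {
    paste(c(rec$chrom[i], rec$position[i], rec$rsid[i], rec$other_allele[i],
            rec$effect_allele[i], ".", "PASS", ".", "GT", gt[i, ]),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), paths["vcf"])

  utils::write.table(smp[smp$population != freqPopulation, ],
                     paths["sample_map"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  dk <- dosages(gm)[, smp$sample_id[smp$population == freqPopulation],
                    drop = FALSE]
  n_ind <- ncol(dk)
  utils::write.table(
    data.frame(rsid = rec$rsid, ref = rec$other_allele,
               alt = rec$effect_allele,
               alt_freq = rowSums(dk, na.rm = TRUE) /
                 (2 * rowSums(!is.na(dk))),
               n_individuals = n_ind),
    paths["freq"], sep = "\t", quote = FALSE, row.names = FALSE)

  assoc <- data.frame(
    SNPS = rec$rsid,
    `STRONGEST SNP-RISK ALLELE` = paste0(rec$rsid, "-", rec$effect_allele),
    CHR_ID = rec$chrom, CHR_POS = rec$position,
    MAPPED_GENE = "SYNTHETIC", CONTEXT = "intron_variant",
    `STUDY ACCESSION` = "GCST000000", check.names = FALSE)
  if (nrow(assoc) >= 2) {
    assoc$`STRONGEST SNP-RISK ALLELE`[2] <- paste0(rec$rsid[2], "-?")
    assoc <- rbind(assoc, assoc[1, ])   # injected duplicate
  }
  utils::write.table(assoc, paths["catalog"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  if (!is.null(phenotypes)) {
    utils::write.table(
      data.frame(population = phenotypes$population,
                 concentration_ng_per_ml = phenotypes$concentration,
                 latitude_deg = phenotypes$latitude),
      paths["phenotypes"], sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    paths <- paths[names(paths) != "phenotypes"]
  }
  paths
}
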