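#' @include methods.R
NULL

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Two-sided Fisher exact test in log space
#'
#' Exact two-sided test of a 2x2 allele-count table (population vs
#' background), computed entirely in log space so that the log10 p-value
#' stays finite for counts whose p underflows double precision (population
#' panels of thousands of alleles routinely give |log10 p| > 300). The
#' two-sided p sums hypergeometric point probabilities no larger than the
#' observed one, with the customary relative fudge of 1e-7 so that
#' floating-point noise cannot exclude exactly tied tables. Degenerate
#' margins (every allele the effect allele, or none) return p = 1.
#'
#' @param kPop effect-allele count in the tested population
#' @param nPop total allele count in the tested population
#' @param kBg effect-allele count in the background
#' @param nBg total allele count in the background
#' @return list with \code{p_value} (underflows to 0 for extreme tables) and
#'   \code{log10_p} (always finite, <= 0)
#' @examples
#' fisherTestLog10(3, 4, 1, 4)   # p = 34/70
#' @export
fisherTestLog10 <- function(kPop, nPop, kBg, nBg) {
  stopifnot(kPop >= 0, kBg >= 0, kPop <= nPop, kBg <= nBg, nPop > 0, nBg > 0)
  K <- kPop + kBg
  N <- nPop + nBg
  if (K == 0 || K == N)
    return(list(p_value = 1, log10_p = 0))
  ks <- max(0, K - nBg):min(K, nPop)
  lp <- lgamma(nPop + 1) - lgamma(ks + 1) - lgamma(nPop - ks + 1) +
        lgamma(nBg + 1) - lgamma(K - ks + 1) - lgamma(nBg - K + ks + 1) -
        (lgamma(N + 1) - lgamma(K + 1) - lgamma(N - K + 1))
  lobs <- lp[ks == kPop]
  ltot <- .logsumexp(lp[lp <= lobs + log1p(1e-7)])
  ltot <- min(ltot, 0)
  list(p_value = exp(ltot), log10_p = ltot / log(10))
}

#' Signed log10 enrichment of one SNP in one population
#'
#' Runs the two-sided Fisher test of the population's effect-allele counts
#' against the background's and signs the log10 p-value by the direction of
#' the frequency difference: positive (+|log10 p|) when the population EAF
#' exceeds the background EAF (enrichment), negative when it is below
#' (depletion), and exactly 0 on a tie. This is the statistic underlying the
#' population heatmap.
#'
#' @param rsid SNP identifier
#' @param population tested population label
#' @param freq \linkS4class{FrequencyTable} holding both the population and
#'   background rows for \code{rsid}
#' @param background background population label
#' @return one-row data.frame: \code{rsid}, \code{population},
#'   \code{eaf_pop}, \code{eaf_bg}, \code{p_value}, \code{log10_p},
#'   \code{signed_stat}; all statistics NA when either cell is missing.
#' @export
signedEnrichment <- function(rsid, population, freq, background = "GLOBAL") {
  tb <- freqRecords(freq)
  pop <- tb[tb$rsid == rsid & tb$population == population, , drop = FALSE]
  bg <- tb[tb$rsid == rsid & tb$population == background, , drop = FALSE]
  out <- data.frame(rsid = rsid, population = population,
                    eaf_pop = NA_real_, eaf_bg = NA_real_,
                    p_value = NA_real_, log10_p = NA_real_,
                    signed_stat = NA_real_)
  if (!nrow(pop) || !nrow(bg) || is.na(pop$eaf[1]) || is.na(bg$eaf[1]))
    return(out)
  ft <- fisherTestLog10(pop$k_effect[1], pop$n_alleles[1],
                        bg$k_effect[1], bg$n_alleles[1])
  s <- sign(pop$eaf[1] - bg$eaf[1])
  out$eaf_pop <- pop$eaf[1]
  out$eaf_bg <- bg$eaf[1]
  out$p_value <- ft$p_value
  out$log10_p <- ft$log10_p
  out$signed_stat <- if (s == 0) 0 else -s * ft$log10_p
  out
}

#' SNP-by-population matrix of signed enrichment statistics
#'
#' @param catalog \linkS4class{SnpCatalog} fixing the row order
#' @param freq \linkS4class{FrequencyTable} with rows for every requested
#'   population and the background
#' @param populations column labels, in output order
#' @param background background population label
#' @param backgroundMode \code{"inclusive"} tests each population against
#'   the background as given (the default; external cohorts such as a
#'   national reference database are naturally disjoint from a global
#'   panel). \code{"complement"} subtracts the population's allele counts
#'   from the background's before testing, for populations that are
#'   themselves part of the pooled background.
#' @return numeric matrix (SNPs x populations) of signed statistics; cells
#'   with missing frequencies are NA.
#' @export
buildEnrichmentMatrix <- function(catalog, freq, populations,
                                  background = "GLOBAL",
                                  backgroundMode = c("inclusive",
                                                     "complement")) {
  backgroundMode <- match.arg(backgroundMode)
  ids <- rsids(catalog)
  m <- matrix(NA_real_, length(ids), length(populations),
              dimnames = list(ids, populations))
  tb <- freqRecords(freq)
  for (pop in populations) {
    sub <- tb[tb$population %in% c(pop, background), , drop = FALSE]
    if (backgroundMode == "complement") {
      ib <- sub$population == background
      key <- match(sub$rsid[ib], sub$rsid[!ib])
      kp <- sub$k_effect[!ib][key]
      np <- sub$n_alleles[!ib][key]
      if (any(sub$k_effect[ib] < kp | sub$n_alleles[ib] < np, na.rm = TRUE))
        stop("population counts exceed background counts; ", pop,
             " is not contained in ", background)
      sub$k_effect[ib] <- sub$k_effect[ib] - kp
      sub$n_alleles[ib] <- sub$n_alleles[ib] - np
      sub$eaf[ib] <- ifelse(sub$n_alleles[ib] > 0,
                            sub$k_effect[ib] / sub$n_alleles[ib], NA_real_)
    }
    fsub <- FrequencyTable(sub)
    for (id in ids)
      m[id, pop] <- signedEnrichment(id, pop, fsub, background)$signed_stat
  }
  m
}

#' Classify SNPs as enriched / depleted / comparable
#'
#' Partitions the SNPs of one population column by test significance and
#' sign: enriched (p < alpha, positive), depleted (p < alpha, negative),
#' comparable (p >= alpha). The significance threshold is applied on the
#' |signed statistic| scale as |s| > -log10(alpha), which is exact for the
#' untransformed p. A subset of extreme SNPs with |s| above
#' \code{extremeThreshold} is reported separately. Optional multiple-testing
#' adjustment (\code{"bonferroni"}, \code{"BH"}) rescales the p-values before
#' classification; the default applies none.
#'
#' @param matrix enrichment matrix from \code{\link{buildEnrichmentMatrix}}
#' @param population column to classify
#' @param alpha significance level on the p scale
#' @param extremeThreshold threshold on |signed statistic| for the extreme
#'   subset
#' @param adjust multiple-testing correction, one of \code{"none"},
#'   \code{"bonferroni"}, \code{"BH"}
#' @return list with character vectors \code{enriched}, \code{depleted},
#'   \code{comparable}, \code{extreme} and an integer vector \code{counts}
#' @export
classifySnps <- function(matrix, population, alpha = 0.05,
                         extremeThreshold = 100,
                         adjust = c("none", "bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  s <- matrix[, population]
  s <- s[!is.na(s)]
  p <- 10^(-abs(s))
  if (adjust != "none") p <- stats::p.adjust(p, method = adjust)
  sig <- p < alpha
  out <- list(enriched = names(s)[sig & s > 0],
              depleted = names(s)[sig & s < 0],
              comparable = names(s)[!sig],
              extreme = names(s)[abs(s) > extremeThreshold])
  out$counts <- c(enriched = length(out$enriched),
                  depleted = length(out$depleted),
                  comparable = length(out$comparable),
                  extreme = length(out$extreme))
  out
}

#' Hierarchical clustering of population columns
#'
#' Agglomerative clustering of the populations by the similarity of their
#' signed enrichment profiles. The default distance is 1 minus the Pearson
#' correlation between columns, which clusters populations by the pattern of
#' enrichment and depletion rather than by its magnitude — cohorts with very
#' different sample sizes carry very different |log10 p| scales, and a
#' magnitude-based metric would separate them on sample size alone.
#' Euclidean distance is available for magnitude-based clustering. Missing
#' cells are imputed as 0 with a warning.
#'
#' @param matrix enrichment matrix (SNPs x populations)
#' @param metric \code{"correlation"} (default) or \code{"euclidean"}
#' @param linkage agglomeration method passed to \code{\link[stats]{hclust}}
#' @return an \code{\link[stats]{hclust}} tree over the populations
#' @export
clusterPopulations <- function(matrix, metric = c("correlation", "euclidean"),
                               linkage = "complete") {
  metric <- match.arg(metric)
  if (ncol(matrix) < 2)
    stop("need at least two population columns to cluster")
  if (anyNA(matrix)) {
    warning(sum(is.na(matrix)), " missing cell(s) imputed as 0")
    matrix[is.na(matrix)] <- 0
  }
  d <- switch(metric,
              correlation = stats::as.dist(1 - stats::cor(matrix)),
              euclidean = stats::dist(t(matrix)))
  stats::hclust(d, method = linkage)
}

#' Two-group split at the root of a population dendrogram
#'
#' @param hc \code{\link[stats]{hclust}} tree from
#'   \code{\link{clusterPopulations}}
#' @return list of two character vectors of population labels (sorted), the
#'   two clades below the root merge; the list itself is ordered by first
#'   label so the bipartition is set-comparable.
#' @export
rootBipartition <- function(hc) {
  grp <- stats::cutree(hc, k = 2)
  parts <- lapply(split(names(grp), grp), sort)
  names(parts) <- NULL
  parts[order(vapply(parts, `[`, character(1), 1L))]
}

#' Export a dendrogram as a Newick string
#'
#' @param hc \code{\link[stats]{hclust}} tree
#' @param path optional file to write to
#' @return the Newick string, invisibly when written to file
#' @export
exportNewick <- function(hc, path = NULL) {
  tr <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(tr))
  ape::write.tree(tr, file = path)
  invisible(ape::write.tree(tr))
}

#' Write an enrichment matrix to TSV
#'
#' @param matrix enrichment matrix
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeEnrichmentMatrix <- function(matrix, path) {
  df <- data.frame(rsid = rownames(matrix), matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
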