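# shared in-code fixtures: a tiny association TSV, a matching VCF, and
# convenience builders for frequency tables and dosage matrices

writeToyAssociations <- function(path, rows) {
  header <- paste(c("SNPS", "STRONGEST SNP-RISK ALLELE", "CHR_ID",
                    "CHR_POS", "MAPPED_GENE", "CONTEXT",
                    "STUDY ACCESSION"), collapse = "\t")
  writeLines(c(header, rows), path)
  path
}

# five associations, two sharing an rsid, one with an unstated ("?") allele
toyAssociationRows <- function() {
  c("rs1001\trs1001-T\t1\t100\tGENE1\tintron_variant\tGCST001",
    "rs1002\trs1002-G\t1\t200\tGENE2\tintron_variant\tGCST001",
    "rs1001\trs1001-T\t1\t100\tGENE1\tintron_variant\tGCST002",
    "rs1003\trs1003-?\t2\t300\tGENE3\tmissense_variant\tGCST002",
    "rs1002\trs1002-G\t1\t200\tGENE2\tintron_variant\tGCST003")
}

toyPanelAlleles <- function() {
  data.frame(rsid = c("rs1001", "rs1002", "rs1003"),
             ref = c("C", "C", "A"), alt = c("T", "G", "G"),
             alt_freq = c(0.4, 0.6, 0.3))
}

toyCatalog <- function(rsid = c("rs1001", "rs1002"),
                       effect = c("T", "G"), other = c("C", "C")) {
  effect <- rep_len(effect, length(rsid))
  other <- rep_len(other, length(rsid))
  SnpCatalog(data.frame(rsid = rsid, chrom = "1",
                        position = seq_along(rsid) * 100L,
                        mapped_gene = NA, functional_class = NA,
                        effect_allele = effect, other_allele = other,
                        effect_allele_resolved_by = "catalog"),
             provenance = "toy")
}

toyFrequencyTable <- function(rsid, pops, eaf, n_individuals) {
  cnt <- countsFromFrequency(eaf, rep(n_individuals,
                                      length.out = length(eaf)))
  FrequencyTable(data.frame(rsid = rsid, population = pops, eaf = eaf,
                            k_effect = cnt$k_effect,
                            n_alleles = cnt$n_alleles,
                            source = "frequency_file"))
}

# dosage GenotypeMatrix from an explicit matrix, one population per sample
# unless pops given
toyGenotypes <- function(dos, pops = NULL) {
  dos <- as.matrix(dos)
  if (is.null(rownames(dos)))
    rownames(dos) <- sprintf("rs%04d", seq_len(nrow(dos)) + 2000)
  if (is.null(colnames(dos)))
    colnames(dos) <- sprintf("S%03d", seq_len(ncol(dos)))
  if (is.null(pops)) pops <- rep("P1", ncol(dos))
  bases <- rep(c("A", "G"), length.out = 2)
  cat <- SnpCatalog(data.frame(
    rsid = rownames(dos), chrom = "1",
    position = 10L * seq_len(nrow(dos)),
    mapped_gene = NA, functional_class = NA,
    effect_allele = "G", other_allele = "A",
    effect_allele_resolved_by = "catalog"), provenance = "toy")
  panel <- PopulationPanel(data.frame(sample_id = colnames(dos),
                                      population = pops,
                                      superpopulation = pops))
  GenotypeMatrix(dos, cat, panel)
}

# brute-force two-sided Fisher p on the hypergeometric, linear space,
# independent of the package's log-space path
oracleFisherP <- function(k1, n1, k2, n2) {
  K <- k1 + k2; N <- n1 + n2
  if (K == 0 || K == N) return(1)
  ks <- max(0, K - n2):min(K, n1)
  pr <- stats::dhyper(ks, n1, n2, K)
  pobs <- pr[ks == k1]
  sum(pr[pr <= pobs * (1 + 1e-7)])
}
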