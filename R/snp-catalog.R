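#' @include methods.R
NULL

.RC <- c(A = "T", C = "G", G = "C", T = "A")

.reverseComplement <- function(a) unname(.RC[a])

#' Read a GWAS-catalog association export
#'
#' Parses the tab-separated "all associations" dialect of the NHGRI-EBI GWAS
#' catalog. Rows listing several rsids (haplotype or interaction entries) are
#' split on the catalog's \code{";"} / \code{" x "} delimiters, each resulting
#' rsid becoming its own association; such rows are counted in a message.
#' Rows whose SNP field is not an rsid are skipped with a warning.
#'
#' @param path TSV file with at least columns \code{SNPS},
#'   \code{STRONGEST SNP-RISK ALLELE}, \code{CHR_ID}, \code{CHR_POS}.
#' @param trait optional value to filter the \code{DISEASE/TRAIT} or
#'   \code{MAPPED_TRAIT} column on (exact match), for exports that bundle
#'   several traits.
#' @return data.frame of raw associations: \code{rsid},
#'   \code{risk_allele_token}, \code{risk_allele} (single base or NA when the
#'   token ends in \code{"?"}), \code{chrom}, \code{position},
#'   \code{mapped_gene}, \code{functional_class}, \code{study_id}.
#' @export
readGwasCatalog <- function(path, trait = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, check.names = FALSE, quote = "",
                           colClasses = "character")
  need <- c("SNPS", "STRONGEST SNP-RISK ALLELE", "CHR_ID", "CHR_POS")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("association file lacks required column(s): ",
         paste(miss, collapse = ", "))
  if (!is.null(trait)) {
    tcol <- intersect(c("DISEASE/TRAIT", "MAPPED_TRAIT"), names(raw))
    if (!length(tcol)) stop("no trait column to filter on")
    raw <- raw[raw[[tcol[1L]]] == trait, , drop = FALSE]
  }
  col <- function(nm) if (nm %in% names(raw)) raw[[nm]] else
    rep(NA_character_, nrow(raw))

  split_ids <- strsplit(raw$SNPS, "\\s*;\\s*|\\s+x\\s+")
  split_tok <- strsplit(col("STRONGEST SNP-RISK ALLELE"),
                        "\\s*;\\s*|\\s+x\\s+")
  n_multi <- sum(lengths(split_ids) > 1L)
  if (n_multi)
    message(n_multi, " multi-SNP row(s) split into per-rsid associations")

  rows <- lapply(seq_len(nrow(raw)), function(i) {
    ids <- trimws(split_ids[[i]])
    toks <- trimws(split_tok[[i]])
    if (length(toks) != length(ids)) toks <- rep(NA_character_, length(ids))
    data.frame(rsid = ids, risk_allele_token = toks,
               chrom = col("CHR_ID")[i], position = col("CHR_POS")[i],
               mapped_gene = col("MAPPED_GENE")[i],
               functional_class = col("CONTEXT")[i],
               study_id = col("STUDY ACCESSION")[i])
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- data.frame(rsid = character())

  bad <- !grepl("^rs[0-9]+$", out$rsid)
  if (any(bad)) {
    warning(sum(bad), " row(s) with unparseable SNP identifier skipped")
    out <- out[!bad, , drop = FALSE]
  }
  out$position <- suppressWarnings(as.integer(out$position))
  out$position[!is.na(out$position) & out$position <= 0L] <- NA_integer_
  out$risk_allele <- toupper(sub("^.*-", "", out$risk_allele_token))
  out$risk_allele[!out$risk_allele %in% .BASES] <- NA_character_
  rownames(out) <- NULL
  out
}

#' Drop repeated rsids, keeping the first occurrence
#'
#' The catalog reports one association per (study, SNP); for frequency
#' analysis each SNP is used once. The first occurrence in file order is
#' kept, which makes the result deterministic and auditable. Idempotent.
#'
#' @param associations data.frame from \code{\link{readGwasCatalog}}.
#' @return the same data.frame with duplicate rsids removed.
#' @export
dedupAssociations <- function(associations) {
  out <- associations[!duplicated(associations$rsid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Harmonize catalog associations with a genotype panel
#'
#' Restricts associations to SNPs present in the reference panel and resolves
#' the effect allele against the panel's ref/alt pair. Resolution order: the
#' catalog's stated risk allele if it matches a panel allele exactly; its
#' reverse complement for a strand flip (never for strand-ambiguous A/T or
#' C/G SNPs, which are accepted on exact match only and flagged); otherwise
#' the panel minor allele, recorded as \code{minor_allele_fallback} — GWAS
#' entries without a stated risk allele are treated this way because the
#' minor allele is the usual reporting convention. Records whose stated
#' allele matches neither panel allele nor its complement are dropped with a
#' warning.
#'
#' @param associations deduplicated data.frame from
#'   \code{\link{readGwasCatalog}}.
#' @param panelAlleles data.frame with columns \code{rsid}, \code{ref},
#'   \code{alt}, \code{alt_freq} (alt-allele frequency used for the
#'   minor-allele fallback).
#' @param provenance free text stored on the resulting catalog.
#' @return a \linkS4class{SnpCatalog}
#' @export
harmonizeWithPanel <- function(associations, panelAlleles,
                               provenance = "harmonized GWAS catalog") {
  pa <- as.data.frame(panelAlleles)
  stopifnot(all(c("rsid", "ref", "alt", "alt_freq") %in% names(pa)))
  idx <- match(associations$rsid, pa$rsid)
  n_drop <- sum(is.na(idx))
  if (n_drop)
    message(n_drop, " association(s) absent from the panel dropped")
  keep <- associations[!is.na(idx), , drop = FALSE]
  pidx <- idx[!is.na(idx)]

  eff <- other <- character(nrow(keep))
  by <- character(nrow(keep))
  ok <- logical(nrow(keep))
  n_ambig_flagged <- 0L
  for (i in seq_len(nrow(keep))) {
    ref <- pa$ref[pidx[i]]; alt <- pa$alt[pidx[i]]
    minor <- if (pa$alt_freq[pidx[i]] <= 0.5) alt else ref
    a <- keep$risk_allele[i]
    ambiguous <- identical(.reverseComplement(ref), alt)
    if (is.na(a)) {
      eff[i] <- minor; by[i] <- "minor_allele_fallback"; ok[i] <- TRUE
    } else if (a %in% c(ref, alt)) {
      eff[i] <- a; by[i] <- "catalog"; ok[i] <- TRUE
      if (ambiguous) n_ambig_flagged <- n_ambig_flagged + 1L
    } else if (!ambiguous && .reverseComplement(a) %in% c(ref, alt)) {
      eff[i] <- .reverseComplement(a); by[i] <- "catalog"; ok[i] <- TRUE
    } else {
      ok[i] <- FALSE
    }
    if (ok[i]) other[i] <- setdiff(c(ref, alt), eff[i])[1L]
  }
  if (n_ambig_flagged)
    message(n_ambig_flagged,
            " strand-ambiguous SNP(s) accepted on exact allele match")
  if (any(!ok))
    warning(sum(!ok), " record(s) dropped: stated risk allele matches ",
            "neither panel allele nor its complement (",
            paste(keep$rsid[!ok], collapse = ", "), ")")
  keep <- keep[ok, , drop = FALSE]
  SnpCatalog(data.frame(rsid = keep$rsid, chrom = keep$chrom,
                        position = keep$position,
                        mapped_gene = keep$mapped_gene,
                        functional_class = keep$functional_class,
                        effect_allele = eff[ok], other_allele = other[ok],
                        effect_allele_resolved_by = by[ok]),
             provenance = provenance)
}

#' Write / read a curated catalog TSV
#'
#' Round-trip plain-text serialization of a \linkS4class{SnpCatalog}.
#'
#' @param catalog a \linkS4class{SnpCatalog}
#' @param path output (input) TSV path
#' @return \code{writeSnpCatalog} returns \code{path} invisibly;
#'   \code{readSnpCatalog} returns a \linkS4class{SnpCatalog}.
#' @export
writeSnpCatalog <- function(catalog, path) {
  utils::write.table(records(catalog), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeSnpCatalog
#' @param provenance provenance string for the re-read catalog
#' @export
readSnpCatalog <- function(path, provenance = path) {
  rec <- utils::read.delim(path, colClasses = c(chrom = "character",
                                                position = "integer"))
  SnpCatalog(rec, provenance = provenance)
}
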