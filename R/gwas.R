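#' @name gwas-summary
#' @title Post-GWAS summarisation
#' @description
#' Summary rules applied to a per-SNP association table (one row per SNP
#' with chromosome, position, p-value, minor allele frequency and minor
#' allele accession count): quality filtering, Bonferroni-style
#' thresholds from the effective number of independent markers, clumping
#' of associated SNPs into loci wherever adjacent SNPs on a chromosome
#' are less than a gap (default 300 kb) apart, and lead-SNP selection
#' (smallest p-value; ties to the smaller position). The association scan
#' itself is out of scope; this module only consumes its summary table.
NULL

#' Filter SNPs on allele-frequency criteria
#'
#' Keeps SNPs with `maf >= mafMin` and `mac >= macMin` (both inclusive).
#'
#' @param snps data.frame with columns `maf` (minor allele frequency) and
#'   `mac` (number of accessions carrying the minor allele).
#' @param mafMin minimum minor allele frequency (default 0.05).
#' @param macMin minimum minor-allele accession count (default 6).
#' @return the filtered data.frame.
#' @export
filterSNPs <- function(snps, mafMin = 0.05, macMin = 6) {
  stopIfNot(is.data.frame(snps), "snps must be a data.frame")
  stopIfNot(all(c("maf", "mac") %in% names(snps)),
            "snps needs 'maf' and 'mac' columns")
  snps[snps$maf >= mafMin & snps$mac >= macMin, , drop = FALSE]
}

#' Genome-wide p-value thresholds
#'
#' Suggestive `1/N` and significant `0.05/N` thresholds from the
#' effective number of independent markers `N`; their ratio is exactly
#' 0.05.
#'
#' @param nEff effective number of independent markers (>= 1).
#' @return named numeric: `suggestive`, `significant`.
#' @examples
#' gwasThresholds(1e6)
#' @export
gwasThresholds <- function(nEff) {
  stopIfNot(all(is.finite(nEff)) && all(nEff >= 1), "nEff must be >= 1")
  c(suggestive = 1 / nEff, significant = 0.05 / nEff)
}

#' Clump associated SNPs into loci
#'
#' Within each chromosome (SNPs sorted by position), a new locus starts
#' whenever the gap to the previous SNP is at least `gapBp`; loci never
#' span chromosomes. Each locus spans its member extremes and carries the
#' member with the smallest p-value as lead SNP (ties break to the
#' smaller position).
#'
#' @param snps data.frame with columns `chrom`, `pos`, `pvalue` (and any
#'   others, e.g. `snp`, `trait`, `stage`, carried along).
#' @param gapBp gap threshold in base pairs (default 300000): adjacent
#'   SNPs closer than this stay in one locus.
#' @return data.frame with one row per locus: `locus`, `chrom`, `start`,
#'   `end`, `n_snps`, `lead_pos`, `lead_p` (plus `lead_snp` if an `snp`
#'   column is present), and a `members` list-column of row indices into
#'   the sorted input.
#' @examples
#' snps <- data.frame(chrom = "1", pos = c(1e6, 1.2e6, 1.6e6),
#'                    pvalue = c(1e-7, 1e-9, 1e-8))
#' clumpLoci(snps)   # two loci: gaps 200 kb (< 300) and 400 kb (>= 300)
#' @export
clumpLoci <- function(snps, gapBp = 300000) {
  stopIfNot(is.data.frame(snps), "snps must be a data.frame")
  stopIfNot(all(c("chrom", "pos", "pvalue") %in% names(snps)),
            "snps needs 'chrom', 'pos', 'pvalue' columns")
  if (nrow(snps) == 0L)
    return(data.frame(locus = integer(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      n_snps = integer(0), lead_pos = numeric(0),
                      lead_p = numeric(0)))
  ord <- order(snps$chrom, snps$pos)
  s <- snps[ord, , drop = FALSE]
  newChrom <- c(TRUE, s$chrom[-1] != s$chrom[-nrow(s)])
  gap <- c(Inf, diff(s$pos))
  gap[newChrom] <- Inf
  locus <- cumsum(newChrom | gap >= gapBp)
  rows <- lapply(split(seq_len(nrow(s)), locus), function(ix) {
    m <- s[ix, , drop = FALSE]
    best <- ix[order(m$pvalue, m$pos)[1]]
    out <- data.frame(chrom = s$chrom[best][1], start = min(m$pos),
                      end = max(m$pos), n_snps = length(ix),
                      lead_pos = s$pos[best], lead_p = s$pvalue[best],
                      stringsAsFactors = FALSE)
    if (!is.null(s$snp)) out$lead_snp <- s$snp[best]
    out$members <- I(list(ix))
    out
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- cbind(locus = seq_len(nrow(out)), out)
  attr(out, "sorted") <- s
  out
}

#' Cross-trait/stage locus overlaps
#'
#' Given loci computed per (trait, stage) combination, reports for every
#' locus the combinations whose loci overlap it as genomic intervals
#' (same chromosome, intersecting `[start, end]`).
#'
#' @param loci data.frame of loci with columns `chrom`, `start`, `end`,
#'   `trait`, `stage` (as from [clumpLoci()] run per trait/stage, then
#'   row-bound with trait/stage columns added).
#' @return data.frame with one row per locus: its coordinates, its own
#'   `trait`/`stage`, the number of overlapping combinations
#'   (`n_combinations`, including itself) and a comma-separated
#'   `combinations` string.
#' @export
crossTraitOverlap <- function(loci) {
  stopIfNot(is.data.frame(loci), "loci must be a data.frame")
  need <- c("chrom", "start", "end", "trait", "stage")
  stopIfNot(all(need %in% names(loci)),
            "loci needs chrom, start, end, trait, stage columns")
  n <- nrow(loci)
  combo <- paste(loci$trait, loci$stage, sep = "/")
  rows <- lapply(seq_len(n), function(i) {
    hit <- loci$chrom == loci$chrom[i] &
      loci$start <= loci$end[i] & loci$end >= loci$start[i]
    who <- sort(unique(combo[hit]))
    data.frame(chrom = loci$chrom[i], start = loci$start[i],
               end = loci$end[i], trait = loci$trait[i],
               stage = loci$stage[i], n_combinations = length(who),
               combinations = paste(who, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Read a delimited SNP summary table
#'
#' Tab-delimited with a header; expected columns `chrom`, `pos`,
#' `pvalue`, `maf`, `mac` and optionally `snp`, `trait`, `stage`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readSNPTable <- function(path) {
  stopIfNot(file.exists(path), sprintf("no such file: %s", path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "pvalue")
  stopIfNot(all(need %in% names(df)),
            "SNP table needs chrom, pos, pvalue columns")
  df$chrom <- as.character(df$chrom)
  df
}
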