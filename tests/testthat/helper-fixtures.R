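# Shared fixtures: a small calibration profile and task generator so unit
# tests stay fast, plus independent oracles used across files.

smallProfile <- function(frameHeight = 300L, frameWidth = 400L)
  CalibrationProfile(frameHeight = frameHeight, frameWidth = frameWidth)

smallTask <- function(nLeaves = 4, seed = 1, dustDensity = 0, ...)
  samplePlant(nLeaves, seed = seed, profile = smallProfile(),
              lengthRange = c(25, 60), widthRange = c(6, 10),
              dustDensity = dustDensity, ...)

# match measured leaf records to truth rows by nearest area; asserts the
# match is a bijection
matchTruth <- function(records, truth) {
  idx <- vapply(seq_len(nrow(records)), function(i)
    which.min(abs(truth$area_mm2 - records$area_mm2[i])), integer(1))
  expect_equal(sort(idx), seq_len(nrow(truth)))
  idx
}

# brute-force locus clumping oracle: build the "closer than gap" relation
# between same-chromosome SNPs pairwise (O(n^2)) and take its transitive
# closure with union-find; independent of the scan-line implementation
bruteClump <- function(snps, gapBp = 300000) {
  n <- nrow(snps)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && snps$chrom[i] == snps$chrom[j] &&
        abs(snps$pos[i] - snps$pos[j]) < gapBp) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  grp <- split(seq_len(n), roots)
  out <- lapply(grp, function(ix) {
    m <- snps[ix, , drop = FALSE]
    lead <- ix[order(m$pvalue, m$pos)[1]]
    data.frame(chrom = snps$chrom[lead], start = min(m$pos),
               end = max(m$pos), n_snps = length(ix),
               lead_pos = snps$pos[lead], lead_p = snps$pvalue[lead],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out[order(out$chrom, out$start), , drop = FALSE]
}

randomSnps <- function(n, seed, nChrom = 3, span = 5e6) {
  set.seed(seed)
  data.frame(chrom = as.character(sample(seq_len(nChrom), n, TRUE)),
             pos = sample(seq_len(span), n),
             pvalue = 10^(-runif(n, 4, 12)))
}
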