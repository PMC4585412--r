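test_that("SNP filtering applies inclusive MAF and MAC bounds", {
  snps <- data.frame(
    maf = c(0.04, 0.05, 0.5, 0.049, 0.2, 0.05, 0.3, 0.1, 0.06, 0.07),
    mac = c(10, 6, 5, 8, 6, 5, 100, 6, 7, 3))
  kept <- filterSNPs(snps)
  expect_equal(nrow(kept), 5)   # 10 records, 5 fail one bound or the other
  expect_true(all(kept$maf >= 0.05 & kept$mac >= 6))
  expect_equal(nrow(filterSNPs(data.frame(maf = 0.04, mac = 10))), 0)
  expect_equal(nrow(filterSNPs(data.frame(maf = 0.05, mac = 6))), 1)
})

test_that("genome-wide thresholds derive from the effective marker count", {
  expect_equal(gwasThresholds(1e6),
               c(suggestive = 1e-6, significant = 5e-8))
  expect_equal(gwasThresholds(1), c(suggestive = 1, significant = 0.05))
  expect_error(gwasThresholds(0.5), ">= 1")
  for (n in c(2, 17, 829187, 4.4e6)) {
    th <- gwasThresholds(n)
    expect_equal(unname(th["significant"] / th["suggestive"]), 0.05)
  }
  # the published significant threshold implies the suggestive one
  nEff <- 0.05 / 6.03e-8
  expect_equal(signif(unname(gwasThresholds(nEff)["suggestive"]), 3),
               1.21e-6)
})

test_that("clumping follows the adjacent-gap rule", {
  snps <- data.frame(chrom = "1", pos = c(1e6, 1.2e6, 1.6e6),
                     pvalue = c(1e-7, 1e-9, 1e-8))
  loci <- clumpLoci(snps)
  expect_equal(nrow(loci), 2)   # 200 kb merges, 400 kb splits
  expect_equal(loci$start, c(1e6, 1.6e6))
  expect_equal(loci$end, c(1.2e6, 1.6e6))
  expect_equal(loci$lead_pos[1], 1.2e6)
  # single SNP forms its own locus
  expect_equal(nrow(clumpLoci(snps[1, ])), 1)
  # a gap of exactly the threshold starts a new locus
  edge <- data.frame(chrom = "1", pos = c(0, 3e5), pvalue = c(1e-8, 1e-8))
  expect_equal(nrow(clumpLoci(edge)), 2)
  expect_equal(nrow(clumpLoci(data.frame(chrom = "1",
                                         pos = c(0, 3e5 - 1),
                                         pvalue = c(1e-8, 1e-8)))), 1)
  # identical positions on different chromosomes never merge
  two <- data.frame(chrom = c("1", "2"), pos = c(5e5, 5e5),
                    pvalue = c(1e-8, 1e-9))
  expect_equal(nrow(clumpLoci(two)), 2)
})

test_that("lead SNPs take the smallest p, then the smaller position", {
  snps <- data.frame(chrom = "3", pos = c(10, 1000, 2000),
                     pvalue = c(1e-9, 1e-9, 1e-12),
                     snp = c("a", "b", "c"))
  loci <- clumpLoci(snps)
  expect_equal(loci$lead_snp, "c")
  tie <- data.frame(chrom = "3", pos = c(1000, 10), pvalue = c(1e-9, 1e-9),
                    snp = c("b", "a"))
  expect_equal(clumpLoci(tie)$lead_snp, "a")
})

test_that("clumping partitions the input SNPs", {
  snps <- randomSnps(200, seed = 4)
  loci <- clumpLoci(snps)
  members <- unlist(loci$members)
  expect_equal(sort(members), seq_len(nrow(snps)))
  expect_equal(sum(loci$n_snps), nrow(snps))
  s <- attr(loci, "sorted")
  expect_identical(s[order(s$chrom, s$pos), ], s)
})

test_that("clumping agrees with the brute-force transitive-closure oracle", {
  for (seed in 1:40) {
    snps <- randomSnps(sample(5:60, 1), seed = seed)
    got <- clumpLoci(snps)
    got <- got[order(got$chrom, got$start),
               c("chrom", "start", "end", "n_snps", "lead_pos", "lead_p")]
    want <- bruteClump(snps)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("cross-trait overlap is interval intersection per chromosome", {
  loci <- data.frame(
    chrom = c("1", "1", "1", "2"),
    start = c(1e6, 1.1e6, 5e6, 1e6),
    end = c(1.3e6, 1.2e6, 5.2e6, 1.3e6),
    trait = c("GLA", "ALWR", "GLA", "GLA"),
    stage = c("tillering", "tillering", "booting", "milk"))
  ov <- crossTraitOverlap(loci)
  expect_equal(ov$n_combinations, c(2, 2, 1, 1))
  expect_match(ov$combinations[1], "ALWR/tillering")
  expect_match(ov$combinations[1], "GLA/tillering")
  # brute force over all pairs
  for (i in seq_len(nrow(loci))) for (j in seq_len(nrow(loci))) {
    overlaps <- loci$chrom[i] == loci$chrom[j] &&
      loci$start[i] <= loci$end[j] && loci$end[i] >= loci$start[j]
    combo <- paste(loci$trait[j], loci$stage[j], sep = "/")
    expect_equal(grepl(combo, ov$combinations[i], fixed = TRUE) ||
                   combo == paste(loci$trait[i], loci$stage[i], sep = "/"),
                 overlaps || i == j)
  }
})

test_that("SNP tables round-trip through the delimited reader", {
  snps <- randomSnps(20, seed = 2)
  snps$maf <- runif(20, 0, 0.5)
  snps$mac <- sample(1:50, 20, TRUE)
  f <- tempfile(fileext = ".tsv")
  write.table(snps, f, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- readSNPTable(f)
  expect_equal(back$pos, snps$pos)
  expect_equal(back$pvalue, snps$pvalue)
  expect_error(readSNPTable(tempfile()), "no such file")
})
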