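test_that("genotype_matrix validates entries and ids", {
  expect_error(genotype_matrix(matrix(c(0, 3), 1, 2)), "0, 1 or 2")
  expect_error(genotype_matrix(matrix(0:1, 2, 2),
                               sample_ids = c("a", "a")), "duplicated")
  G <- genotype_matrix(matrix(c(0, 1, 2, NA), 2, 2))
  expect_identical(dim(G), c(2L, 2L))
  expect_identical(missing_mask(G), is.na(G$dosages))
})

test_that(".ped alleles are counted against the reference allele", {
  tmp <- withr::local_tempdir()
  pre <- file.path(tmp, "toy")
  writeLines(c("F1 S1 0 0 0 -9 A A A G",
               "F2 S2 0 0 0 -9 G G G G"), paste0(pre, ".ped"))
  writeLines(c("1\tsnp1\t0\t1", "1\tsnp2\t0\t2"), paste0(pre, ".map"))
  G <- load_genotypes(pre, "ped_map")
  # first allele code seen per SNP (A for both) is the counted reference
  expect_equal(unname(G$dosages), matrix(c(2L, 0L, 1L, 0L), 2, 2))
  expect_identical(G$ref, c("A", "A"))
  expect_identical(G$sample_ids, c("S1", "S2"))
})

test_that(".ped missing code 0 0 flags exactly that genotype", {
  tmp <- withr::local_tempdir()
  pre <- file.path(tmp, "miss")
  writeLines(c("F1 S1 0 0 0 -9 A A 0 0",
               "F2 S2 0 0 0 -9 A G G G"), paste0(pre, ".ped"))
  writeLines(c("1\tsnp1\t0\t1", "1\tsnp2\t0\t2"), paste0(pre, ".map"))
  G <- load_genotypes(pre, "ped_map")
  expect_identical(which(missing_mask(G)), 3L)   # sample 1, SNP 2
  # snp2's first non-missing allele code is G, so G is counted there
  expect_identical(G$ref, c("A", "G"))
  expect_equal(G$dosages[2, ], c(snp1 = 1L, snp2 = 2L))
})

test_that("file formats round-trip dosages, mask and ids exactly", {
  set.seed(71)
  X <- matrix(rbinom(50, 2, 0.4), 5, 10)
  X[sample(50, 6)] <- NA
  G <- genotype_matrix(X, sample_ids = paste0("ind", 1:5))
  tmp <- withr::local_tempdir()
  for (fmt in c("bed_bim_fam", "ped_map", "dosage_table")) {
    path <- file.path(tmp, fmt)
    switch(fmt,
           bed_bim_fam = write_plink_bed(G, path),
           ped_map = write_plink_ped(G, path),
           dosage_table = write_dosage_table(G, path))
    G2 <- load_genotypes(path, fmt,
                         ref_alleles = if (fmt == "ped_map") G$ref)
    expect_identical(unname(G2$dosages), unname(G$dosages), info = fmt)
    expect_identical(G2$sample_ids, G$sample_ids, info = fmt)
    expect_identical(G2$snp_ids, G$snp_ids, info = fmt)
  }
})

test_that("malformed PLINK binary input is rejected", {
  tmp <- withr::local_tempdir()
  pre <- file.path(tmp, "bad")
  G <- genotype_matrix(matrix(rbinom(20, 2, .5), 4, 5))
  write_plink_bed(G, pre)
  raw <- readBin(paste0(pre, ".bed"), "raw", 100)
  raw[1] <- as.raw(0xff)
  writeBin(raw, paste0(pre, ".bed"))
  expect_error(read_plink_bed(pre), "magic")
  write_plink_bed(G, pre)
  # truncate the payload -> dimension mismatch
  raw <- readBin(paste0(pre, ".bed"), "raw", 100)
  writeBin(raw[1:(length(raw) - 1)], paste0(pre, ".bed"))
  expect_error(read_plink_bed(pre), "dimension mismatch")
})

test_that("snp_stats matches hand computations and flags degeneracies", {
  G <- genotype_matrix(cbind(a = c(0, 1, 2, 1), b = c(2, 2, 2, 2),
                             c = c(0, NA, NA, NA)))
  st <- snp_stats(G)
  expect_equal(st$mean[1], 1)
  expect_equal(st$freq[1], 0.5)
  expect_equal(st$var_sample[1], 2 / 3)
  expect_equal(st$freq[2], 1)
  expect_true(st$monomorphic[2])
  expect_true(is.na(st$var_sample[3]))    # < 2 observations
  expect_false(isTRUE(st$monomorphic[3]))
})

test_that("sample variance is consistent with the HWE value at large n", {
  set.seed(5)
  x <- rbinom(1e5, 2, 0.3)
  st <- snp_stats(genotype_matrix(matrix(x, ncol = 1)))
  expect_lt(abs(st$var_sample - 0.42) / 0.42, 0.02)
})

test_that("centered dosages sum to zero per SNP over the centering set", {
  set.seed(8)
  X <- matrix(rbinom(120, 2, 0.4), 12, 10)
  cs <- c(2, 4, 5, 9, 11)
  st <- snp_stats(genotype_matrix(X), centering_set = cs)
  cen <- sweep(X[cs, ], 2, st$mean)
  expect_equal(max(abs(colSums(cen))), 0, tolerance = 1e-12)
})

test_that("qc_filter removes individuals first, then SNPs, and is idempotent", {
  # sample 1 misses 2/3 entries; after its removal SNP c is monomorphic (MAF 0)
  X <- rbind(c(NA, NA, 0), c(0, 1, 0), c(1, 2, 0), c(1, 1, 0))
  G <- genotype_matrix(X, sample_ids = paste0("s", 1:4),
                       snp_ids = c("a", "b", "c"))
  res <- qc_filter(G)
  expect_identical(res$report$individuals_removed, 1L)
  expect_identical(res$genotypes$sample_ids, c("s2", "s3", "s4"))
  expect_false("c" %in% res$genotypes$snp_ids)
  twice <- qc_filter(res$genotypes)
  expect_identical(twice$genotypes$dosages, res$genotypes$dosages)
  expect_identical(twice$report$individuals_removed, 0L)
  expect_identical(twice$report$snps_removed, 0L)
})

test_that("qc_filter leaves a clean matrix untouched and errors when empty", {
  set.seed(2)
  G <- genotype_matrix(matrix(rbinom(300, 2, 0.4), 30, 10))
  res <- qc_filter(G)
  expect_identical(res$genotypes$dosages, G$dosages)
  expect_identical(res$report$snps_removed, 0L)
  mono <- genotype_matrix(matrix(2L, 4, 3))
  expect_error(qc_filter(mono), "all SNPs")
})
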