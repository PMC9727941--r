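test_that("founder simulation is deterministic and respects HWE", {
  f1 <- simulate_founders(20, 50, seed = 42)
  f2 <- simulate_founders(20, 50, seed = 42)
  expect_identical(f1$genotypes$dosages, f2$genotypes$dosages)
  expect_identical(f1$maf, f2$maf)
  expect_error(simulate_founders(5, 10, maf_low = 0, maf_high = 0.5))

  # symmetric case: p = 0.5 gives mean dosage 1 (3 SE tolerance)
  f <- simulate_founders(4000, 1, maf_low = 0.5, maf_high = 0.5, seed = 1)
  se <- sqrt(0.5 / 4000)
  expect_lt(abs(mean(f$genotypes$dosages) - 1), 3 * se)

  # HWE genotype frequencies at p = 0.2, n = 1e4: (0.64, 0.32, 0.04)
  f <- simulate_founders(1e4, 1, maf_low = 0.2, maf_high = 0.2, seed = 2)
  frq <- tabulate(f$genotypes$dosages + 1L, 3L) / 1e4
  expect_lt(max(abs(frq - c(0.64, 0.32, 0.04))), 0.02)
})

test_that("gene dropping realizes pedigree kinship and IBD coefficients", {
  # trio + first cousins: founders 1-4, sibs 5,6 of (1,2), cousins 7 of (5,3)
  # and 8 of (6,4)
  spec <- pedigree_spec(4, matings = data.frame(
    parent_a = c(1, 5, 6), parent_b = c(2, 3, 4), n_offspring = c(2, 1, 1)))
  phi <- pedigree_kinship(spec)
  expect_equal(phi[5, 6], 0.25)           # full sibs
  expect_equal(phi[1, 5], 0.25)           # parent-offspring
  expect_equal(phi[5, 8], 0.125)          # uncle-niece
  expect_equal(phi[7, 8], 0.0625)         # first cousins
  dp <- drop_pedigree(spec, m = 500, seed = 3)
  pr <- dp$truth$pairs
  cousin <- pr[(pr$id_a == "P7" & pr$id_b == "P8") |
                 (pr$id_a == "P8" & pr$id_b == "P7"), ]
  expect_equal(unlist(cousin[, c("k0", "k1", "k2")], use.names = FALSE),
               c(0.75, 0.25, 0))
  po <- pr[pr$id_a == "P1" & pr$id_b == "P5", ]
  expect_equal(unlist(po[, c("k0", "k1", "k2")], use.names = FALSE),
               c(0, 1, 0))
  expect_error(pedigree_spec(2, matings = data.frame(
    parent_a = 1, parent_b = 5, n_offspring = 1)), "cyclic|not yet defined")
})

test_that("MZ clones copy genotypes exactly with kinship one half", {
  spec <- pedigree_spec(2,
                        matings = data.frame(parent_a = 1, parent_b = 2,
                                             n_offspring = 1),
                        mz_clones = data.frame(template = 3, n_copies = 1))
  dp <- drop_pedigree(spec, m = 400, seed = 11)
  expect_identical(dp$genotypes$dosages[3, ], dp$genotypes$dosages[4, ])
  expect_equal(dp$phi[3, 4], 0.5)
  mz <- dp$truth$pairs
  mz <- mz[mz$id_a == "P3" & mz$id_b == "P4", ]
  expect_equal(unlist(mz[, c("k0", "k1", "k2")], use.names = FALSE),
               c(0, 0, 1))
})

test_that("sib-pair genotype correlation converges to 2 phi", {
  spec <- pedigree_spec(2, matings = data.frame(parent_a = 1, parent_b = 2,
                                                n_offspring = 2))
  dp <- drop_pedigree(spec, m = 1e5, seed = 13)
  X <- dp$genotypes$dosages
  # per-SNP standardized scores: pooled product estimates the common rho
  Z <- sweep(sweep(X, 2, 2 * dp$maf), 2,
             sqrt(2 * dp$maf * (1 - dp$maf)), "/")
  expect_lt(abs(mean(Z[3, ] * Z[4, ]) - 0.5), 0.01)
})

test_that("true kinship matrices are symmetric with entries in [0, 0.5]", {
  spec <- pedigree_spec(6, matings = data.frame(
    parent_a = c(1, 3, 5, 7), parent_b = c(2, 4, 6, 9),
    n_offspring = c(2, 2, 1, 2)))
  dp <- drop_pedigree(spec, m = 50, seed = 4)
  P <- as_phi_matrix(dp$truth)
  expect_equal(P, t(P))
  expect_true(all(P >= 0 & P <= 0.5))
  expect_equal(diag(P), setNames(rep(0.5, nrow(P)), rownames(P)))
})

test_that("mixed cohort realizes the declared pair kinships exactly", {
  cfg <- sim_cohort_config(n_pairs = c("0.125" = 3, "0.25" = 4, "0.5" = 2),
                           n_singletons = 5, m = 200, seed = 10)
  sim <- simulate_mixed_cohort(cfg)
  expect_identical(nrow(sim$genotypes$dosages), 2L * 9L + 5L)
  pr <- sim$truth$pairs
  expect_identical(nrow(pr), 9L)
  expect_equal(sort(unique(pr$phi)), c(0.125, 0.25, 0.5))
  expect_identical(sum(pr$phi == 0.125), 3L)
  # MZ rows are identical genotypes
  mz <- pr[pr$phi == 0.5, ][1, ]
  expect_identical(sim$genotypes$dosages[mz$id_a, ],
                   sim$genotypes$dosages[mz$id_b, ])
  # singleton-only cohort has no related pairs
  lone <- simulate_mixed_cohort(sim_cohort_config(
    n_pairs = c("0.125" = 0), n_singletons = 3, m = 50, seed = 1))
  expect_identical(nrow(lone$truth$pairs), 0L)
  expect_true(all(as_phi_matrix(lone$truth)[upper.tri(diag(3))] == 0))
})

test_that("sib families are internally 0.25-related and mutually unrelated", {
  sim <- simulate_sib_families(2, 2, 100, seed = 21)
  expect_length(sim$families, 2)
  pr <- sim$families[[1]]$truth$pairs
  expect_identical(nrow(pr), 1L)
  expect_equal(pr$phi, 0.25)
  # cross-family pairs never appear in any truth table
  ids1 <- sim$families[[1]]$truth$sample_ids
  ids2 <- sim$families[[2]]$truth$sample_ids
  expect_length(intersect(ids1, ids2), 0)
})

test_that("within-family genotype correlations average near 0.5", {
  sim <- simulate_sib_families(1, 100, 1e4, seed = 22)
  X <- sim$families[[1]]$genotypes$dosages
  Z <- sweep(sweep(X, 2, 2 * sim$maf), 2,
             sqrt(2 * sim$maf * (1 - sim$maf)), "/")
  cc <- tcrossprod(Z) / ncol(Z)
  expect_lt(abs(mean(cc[upper.tri(cc)]) - 0.5), 0.02)
})

test_that("case-control frequency shifts follow the clamped Gaussian rule", {
  cc0 <- simulate_case_control(10, 10, 500, risk_prop = 0, seed = 31)
  expect_identical(cc0$maf_case, cc0$maf_control)
  expect_length(cc0$risk_snps, 0)
  cc <- simulate_case_control(10, 10, 1e4, risk_prop = 0.05, seed = 32)
  expect_length(cc$risk_snps, 500)
  expect_identical(cc$maf_case[-cc$risk_snps], cc$maf_control[-cc$risk_snps])
  # huge shifts land exactly on the clamps
  big <- simulate_case_control(5, 5, 2000, risk_prop = 1, shift_sd = 10,
                               seed = 33)
  expect_true(all(big$maf_case >= 0.05 & big$maf_case <= 0.95))
  expect_true(any(big$maf_case == 0.05) && any(big$maf_case == 0.95))
})

test_that("phenotype simulation controls the genetic variance fraction", {
  sim <- simulate_sib_families(100, 5, 2000, seed = 41)
  G <- stack_families(sim)
  ph <- simulate_phenotype(G, 0.5, 0.01, seed = 42)
  expect_length(ph$causal, 20)
  expect_equal(var(ph$genetic), 0.5, tolerance = 1e-10)
  expect_lt(abs(var(ph$genetic) / var(ph$y) - 0.5), 0.05)
  # determinism
  ph2 <- simulate_phenotype(G, 0.5, 0.01, seed = 42)
  expect_identical(ph$y, ph2$y)
  # h2 = 0: no genetic signal at all
  ph0 <- simulate_phenotype(G, 0, 0.01, seed = 43)
  expect_identical(unique(ph0$genetic), 0)
  expect_error(simulate_phenotype(G, 1, 0.01), "h2")
})
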