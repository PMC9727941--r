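test_that("scGRM matches the centering arithmetic on a two-sample pair", {
  G <- genotype_matrix(matrix(c(0L, 2L), 2, 1))
  cfg <- estimator_config("known", known_variances = 0.5)
  K <- scgrm(G, cfg)
  # centered scores (-1, +1) scaled by 1/sqrt(0.5): rho = -2, phi = -1
  expect_equal(K$phi[1, 2], -1)
  expect_identical(K$estimator, "scgrm")
})

test_that("scGRM and rGRM match brute-force evaluation on random matrices", {
  set.seed(101)
  for (rep in 1:3) {
    X <- matrix(rbinom(6 * 50, 2, runif(1, 0.2, 0.5)), 6, 50)
    if (rep == 3) X[sample(length(X), 10)] <- NA   # exercise mean imputation
    G <- genotype_matrix(X)
    for (vm in c("sample", "hwe")) {
      K <- scgrm(G, estimator_config(vm))
      expect_equal(unname(K$phi), brute_scgrm(X, vm), tolerance = 1e-12,
                   info = paste("scgrm", vm, rep))
    }
    kv <- runif(50, 0.2, 0.6)
    K <- scgrm(G, estimator_config("known", known_variances = kv))
    expect_equal(unname(K$phi), brute_scgrm(X, "known", known = kv),
                 tolerance = 1e-12)
    # rGRM brute force: summed cross-products over summed variances
    st <- snp_stats(G)
    keep <- which(st$var_sample > 0)
    mu <- st$mean
    C <- matrix(0, 6, 6)
    for (i in 1:6) for (l in 1:6) for (k in keep) {
      xi <- if (is.na(X[i, k])) mu[k] else X[i, k]
      xl <- if (is.na(X[l, k])) mu[k] else X[l, k]
      C[i, l] <- C[i, l] + (xi - mu[k]) * (xl - mu[k])
    }
    Kr <- rgrm(G, estimator_config("sample"))
    expect_equal(unname(Kr$phi), C / sum(st$var_sample[keep]) / 2,
                 tolerance = 1e-12)
  }
})

test_that("rGRM collapses to scGRM under equal per-SNP variances", {
  set.seed(7)
  G <- genotype_matrix(matrix(rbinom(8 * 40, 2, 0.3), 8, 40))
  cfg <- estimator_config("known", known_variances = rep(0.42, 40))
  expect_equal(rgrm(G, cfg)$phi, scgrm(G, cfg)$phi, tolerance = 1e-12)
})

test_that("sample-variance centering forces the negative pair sums exactly", {
  set.seed(19)
  for (n in c(4, 7, 12)) {
    X <- matrix(rbinom(n * 30, 2, 0.4), n, 30)
    K <- scgrm(genotype_matrix(X), estimator_config("sample"))
    R <- kinship_rho(K)
    expect_equal(sum(R[upper.tri(R)]), -(n - 1) / 2, tolerance = 1e-9)
    expect_equal(mean(K$phi[upper.tri(K$phi)]), -1 / (2 * n),
                 tolerance = 1e-9)
    # consequently the all-pairs mean UKin correlation is exactly 0
    Ru <- kinship_rho(ukin(K))
    expect_equal(mean(Ru[upper.tri(Ru)]), 0, tolerance = 1e-9)
  }
})

test_that("UKin equals the per-SNP statistic construction and its n=2 form", {
  set.seed(23)
  X <- matrix(rbinom(6 * 50, 2, 0.35), 6, 50)
  G <- genotype_matrix(X)
  K <- scgrm(G, estimator_config("sample"))
  expect_equal(unname(ukin(K)$phi), brute_ukin_persnp(X, "sample"),
               tolerance = 1e-10)
  kv <- runif(50, 0.3, 0.5)
  Kk <- scgrm(G, estimator_config("known", known_variances = kv))
  expect_equal(unname(ukin(Kk)$phi), brute_ukin_persnp(X, "known", known = kv),
               tolerance = 1e-10)
  # n = 2: both correction sums reduce to the single cross term
  X2 <- matrix(rbinom(2 * 30, 2, 0.4), 2, 30)
  K2 <- scgrm(genotype_matrix(X2), estimator_config("sample"))
  U2 <- ukin(K2)
  expect_equal(2 * U2$phi[1, 2], 2 * (2 * K2$phi[1, 2]) + 1, tolerance = 1e-12)
  expect_error(ukin(U2), "scGRM")
})

test_that("the pair-average identity mean(rho_ukin) = n mean(rho) + 1 holds", {
  set.seed(29)
  for (n in c(3, 6, 11)) {
    X <- matrix(rbinom(n * 40, 2, 0.3), n, 40)
    K <- scgrm(genotype_matrix(X), estimator_config("hwe"))
    R <- kinship_rho(K); Ru <- kinship_rho(ukin(K))
    ut <- upper.tri(R)
    expect_equal(mean(Ru[ut]), n * mean(R[ut]) + 1, tolerance = 1e-10)
  }
})

test_that("KING-robust reproduces hand counts and collapses for identical rows", {
  G <- genotype_matrix(rbind(c(0L, 1L, 1L, 2L), c(2L, 1L, 0L, 1L)))
  expect_equal(king_robust(G)$phi[1, 2], -0.25)
  expect_equal(king_robust_pairs(G, 1, 2)$phi, -0.25)
  # identical genotype vectors with heterozygotes: phi = 0.5 exactly
  g <- c(0L, 1L, 2L, 1L, 1L)
  Gid <- genotype_matrix(rbind(g, g), sample_ids = c("a", "b"))
  expect_equal(king_robust(Gid)$phi[1, 2], 0.5)
  # no heterozygotes anywhere: undefined, flagged
  Gh <- genotype_matrix(rbind(c(0L, 2L), c(2L, 0L)))
  expect_warning(Kh <- king_robust(Gh), "undefined")
  expect_true(is.na(Kh$phi[1, 2]))
})

test_that("KING respects missingness through the shared SNP set", {
  G <- genotype_matrix(rbind(c(0L, 1L, 1L, NA, 2L),
                             c(2L, 1L, NA, 1L, 0L)))
  # shared SNPs: 1, 2, 5 -> Nhh = 1, Nopp = 2, het counts 1 and 1
  expect_equal(king_robust(G)$phi[1, 2], (1 - 4) / 2)
  expect_equal(king_robust_pairs(G, 1, 2)$phi, king_robust(G)$phi[1, 2])
})

test_that("KING mean over simulated parent-offspring pairs is near 0.25", {
  set.seed(37)
  n_po <- 300
  spec <- pedigree_spec(2 * n_po, matings = data.frame(
    parent_a = seq(1, 2 * n_po, by = 2), parent_b = seq(2, 2 * n_po, by = 2),
    n_offspring = 1))
  dp <- drop_pedigree(spec, m = 1e4, seed = 38)
  kp <- king_robust_pairs(dp$genotypes,
                          paste0("P", seq(1, 2 * n_po, by = 2)),
                          paste0("P", 2 * n_po + seq_len(n_po)))
  expect_lt(abs(mean(kp$phi) - 0.25), 0.01)
})

test_that("relationship degrees follow the powers-of-two intervals", {
  expect_identical(as.character(classify_relationship(0.25)), "first_degree")
  expect_identical(as.character(classify_relationship(0.0625)), "third_degree")
  expect_identical(as.character(classify_relationship(0.03)), "unrelated")
  expect_identical(as.character(classify_relationship(0.45)), "MZ")
  expect_identical(as.character(classify_relationship(0.125)),
                   "second_degree")
  # ties at a threshold fall in the more distant class
  expect_identical(as.character(classify_relationship(2^(-3 / 2))),
                   "first_degree")
  expect_identical(as.character(classify_relationship(2^(-9 / 2))),
                   "unrelated")
  expect_error(classify_relationship(NA_real_), "finite")
  # full Table-1 roster classifies to the expected degrees
  phis <- c(MZ = 0.5, parent_offspring = 0.25, full_sib = 0.25,
            half_sib = 0.125, uncle_niece = 0.125, first_cousin = 0.0625,
            unrelated = 0)
  got <- as.character(classify_relationship(unname(phis)))
  expect_identical(got, c("MZ", "first_degree", "first_degree",
                          "second_degree", "second_degree", "third_degree",
                          "unrelated"))
})

test_that("relabeling samples permutes every kinship matrix identically", {
  set.seed(41)
  X <- matrix(rbinom(8 * 60, 2, 0.3), 8, 60)
  perm <- sample(8)
  for (f in list(function(g) scgrm(g, estimator_config("sample")),
                 function(g) ukin(scgrm(g, estimator_config("sample"))),
                 king_robust)) {
    K1 <- f(genotype_matrix(X, sample_ids = paste0("s", 1:8)))
    K2 <- f(genotype_matrix(X[perm, ], sample_ids = paste0("s", 1:8)[perm]))
    expect_equal(K2$phi[paste0("s", 1:8), paste0("s", 1:8)], K1$phi,
                 tolerance = 1e-12)
  }
})

test_that("kinship matrices survive the square and GCTA text round trips", {
  set.seed(43)
  K <- scgrm(genotype_matrix(matrix(rbinom(5 * 30, 2, .4), 5, 30)),
             estimator_config("sample"))
  tmp <- withr::local_tempdir()
  write_kinship_matrix(K, file.path(tmp, "k.tsv"))
  K2 <- read_kinship_matrix(file.path(tmp, "k.tsv"), estimator = "scgrm")
  expect_equal(K2$phi, K$phi, tolerance = 1e-12)
  write_grm_gcta(K, file.path(tmp, "k"))
  K3 <- read_grm_gcta(file.path(tmp, "k"), estimator = "scgrm")
  expect_equal(unname(K3$phi), unname(K$phi), tolerance = 1e-9)
  expect_identical(K3$m, K$m)
})

test_that("estimators refuse degenerate configurations", {
  G <- genotype_matrix(matrix(2L, 4, 3))
  expect_error(scgrm(G, estimator_config("sample")), "monomorphic")
  expect_error(estimator_config("known"), "known_variances")
  Gna <- genotype_matrix(matrix(c(0L, 1L, NA, 2L), 2, 2))
  expect_error(scgrm(Gna, estimator_config("sample",
                                           missing_policy = "error")),
               "missing")
})
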