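# Independent brute-force oracles and small cohort builders used across the
# test files. These deliberately re-derive the estimators with scalar loops
# (no shared code with the package internals).

# brute-force scGRM: double loop over pairs and SNPs
brute_scgrm <- function(X, variance_mode = "sample", known = NULL) {
  n <- nrow(X); m <- ncol(X)
  mu <- colMeans(X, na.rm = TRUE)
  v <- apply(X, 2, function(x) stats::var(x[!is.na(x)]))
  sigma2 <- switch(variance_mode,
                   sample = v,
                   hwe = 2 * (mu / 2) * (1 - mu / 2),
                   known = known)
  keep <- if (variance_mode == "known") which(sigma2 > 0) else
    which(is.finite(sigma2) & sigma2 > 0 & is.finite(v) & v > 0)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (k in keep) {
      xi <- X[i, k]; xj <- X[j, k]
      if (is.na(xi)) xi <- mu[k]
      if (is.na(xj)) xj <- mu[k]
      s <- s + (xi - mu[k]) * (xj - mu[k]) / sigma2[k]
    }
    out[i, j] <- s / length(keep) / 2
  }
  out
}

# per-SNP UKin construction: average over SNPs of the per-SNP statistic
# u(i,i') = 1 + cross(i,i') + half the two leave-one-out cross sums
brute_ukin_persnp <- function(X, variance_mode = "sample", known = NULL) {
  n <- nrow(X); m <- ncol(X)
  mu <- colMeans(X)
  v <- apply(X, 2, stats::var)
  sigma2 <- switch(variance_mode, sample = v,
                   hwe = 2 * (mu / 2) * (1 - mu / 2), known = known)
  keep <- if (variance_mode == "known") which(sigma2 > 0) else
    which(is.finite(sigma2) & sigma2 > 0 & is.finite(v) & v > 0)
  out <- matrix(0, n, n)
  for (k in keep) {
    z <- (X[, k] - mu[k]) / sqrt(sigma2[k])
    cp <- outer(z, z)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      u <- 1 + cp[i, j] + 0.5 * sum(cp[i, -i]) + 0.5 * sum(cp[-j, j])
      out[i, j] <- out[i, j] + u / length(keep)
    }
  }
  out / 2                                 # phi scale
}

# block-diagonal true kinship matrix of a sib-family cohort
sib_phi_true <- function(n_families, family_size) {
  n <- n_families * family_size
  phi <- matrix(0, n, n)
  blk <- matrix(0.25, family_size, family_size)
  diag(blk) <- 0.5
  for (f in seq_len(n_families)) {
    idx <- (f - 1L) * family_size + seq_len(family_size)
    phi[idx, idx] <- blk
  }
  phi
}

# stack a simulate_sib_families() result into one genotype_matrix
stack_families <- function(sim) {
  X <- do.call(rbind, lapply(sim$families, function(f) f$genotypes$dosages))
  genotype_matrix(X, sample_ids = unlist(lapply(sim$families,
                                                function(f) f$genotypes$sample_ids)))
}

# a small mixed cohort configuration reused by the Monte-Carlo oracle tests
small_mixed_cfg <- function(m, seed = NULL)
  sim_cohort_config(n_pairs = c("0.125" = 5, "0.25" = 5, "0.5" = 5),
                    n_singletons = 10, m = m, seed = seed)

# true correlation (rho) matrix of a simulated cohort: 2 phi, diagonal 1
truth_rho <- function(truth) 2 * as_phi_matrix(truth)
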