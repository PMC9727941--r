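# Fast gene-drop primitives shared by the cohort simulators. All operate on a
# fixed per-SNP reference-allele frequency vector p (length m) and realize the
# same Mendelian transmission rules as drop_pedigree, without materializing a
# pedigree table.

.hap <- function(p) stats::rbinom(length(p), 1L, p)

# one gamete from a parent with haplotypes (a, b): per-SNP uniform choice
.gamete <- function(a, b) {
  s <- stats::runif(length(a)) < 0.5
  ifelse(s, a, b)
}

# s full siblings from one founder couple; returns s x m integer matrix
.sib_block <- function(s, p) {
  m <- length(p)
  fa <- .hap(p); fb <- .hap(p); ma <- .hap(p); mb <- .hap(p)
  sel_f <- matrix(stats::runif(s * m) < 0.5, s, m)
  sel_m <- matrix(stats::runif(s * m) < 0.5, s, m)
  FA <- matrix(fa, s, m, byrow = TRUE); FB <- matrix(fb, s, m, byrow = TRUE)
  MA <- matrix(ma, s, m, byrow = TRUE); MB <- matrix(mb, s, m, byrow = TRUE)
  pat <- ifelse(sel_f, FA, FB)
  mat <- ifelse(sel_m, MA, MB)
  g <- pat + mat
  storage.mode(g) <- "integer"
  g
}

# half-sib pair: one shared parent, two unshared parents
.half_sib_pair <- function(p) {
  sa <- .hap(p); sb <- .hap(p)                 # shared parent
  g1 <- .gamete(sa, sb) + .gamete(.hap(p), .hap(p))
  g2 <- .gamete(sa, sb) + .gamete(.hap(p), .hap(p))
  rbind(as.integer(g1), as.integer(g2))
}

.full_sib_pair <- function(p) .sib_block(2L, p)

.mz_pair <- function(p) {
  g <- as.integer(stats::rbinom(length(p), 2L, p))
  rbind(g, g)
}

#' Simulate unrelated founders under HWE and linkage equilibrium
#'
#' Per-SNP minor allele frequencies are drawn uniformly from
#' \code{[maf_low, maf_high]}; genotypes are independent Binomial(2, p) across
#' SNPs and individuals.
#'
#' @param n number of individuals.
#' @param m number of SNPs.
#' @param maf_low,maf_high frequency bounds (0 < low <= high <= 0.5).
#' @param seed optional integer seed.
#' @return list with \code{genotypes} (a \code{genotype_matrix}) and
#'   \code{maf} (the true per-SNP frequencies).
#' @export
simulate_founders <- function(n, m, maf_low = 0.05, maf_high = 0.5,
                              seed = NULL) {
  if (n < 1L || m < 1L) stop("need n >= 1 and m >= 1")
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5))
    stop("need 0 < maf_low <= maf_high <= 0.5")
  if (!is.null(seed)) set.seed(seed)
  p <- stats::runif(m, maf_low, maf_high)
  X <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
  list(genotypes = genotype_matrix(X), maf = p)
}

#' Mixed-relatedness cohort configuration
#'
#' Defaults reproduce the cohort of the general simulation study: 500 pairs
#' each at true kinship 0.125 (half sibs), 0.25 (full sibs) and 0.5 (MZ
#' twins), plus 1000 singletons — 4000 individuals genotyped at 50,000
#' independent SNPs with MAF ~ Uniform[0.05, 0.5]. Different pairs share no
#' founders, so cross-pair kinship is 0.
#'
#' @param n_pairs named numeric vector: number of pairs at each true kinship
#'   value, names among \code{"0.125"}, \code{"0.25"}, \code{"0.5"}.
#' @param n_singletons number of unrelated singletons.
#' @param m number of SNPs.
#' @param maf_low,maf_high frequency bounds.
#' @param seed optional integer seed.
#' @return object of class \code{sim_cohort_config}.
#' @export
sim_cohort_config <- function(n_pairs = c("0.125" = 500, "0.25" = 500,
                                          "0.5" = 500),
                              n_singletons = 1000, m = 50000,
                              maf_low = 0.05, maf_high = 0.5, seed = NULL) {
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5))
    stop("need 0 < maf_low <= maf_high <= 0.5")
  full <- c("0.125" = 0, "0.25" = 0, "0.5" = 0)
  if (length(n_pairs)) {
    if (is.null(names(n_pairs)) || !all(names(n_pairs) %in% names(full)))
      stop("n_pairs must be named with kinship values 0.125, 0.25, 0.5")
    full[names(n_pairs)] <- n_pairs
  }
  if (any(full < 0) || n_singletons < 0) stop("counts must be >= 0")
  structure(list(n_pairs = full, n_singletons = n_singletons, m = m,
                 maf_low = maf_low, maf_high = maf_high, seed = seed),
            class = "sim_cohort_config")
}

#' Simulate a mixed-relatedness cohort
#'
#' Kinship-0.125 pairs are realized as half-sib pairs (IBD 0.5/0.5/0),
#' kinship-0.25 pairs as full-sib pairs (0.25/0.5/0.25), and kinship-0.5
#' pairs as MZ twins (0/0/1); founders are never shared between pairs, and
#' singletons are independent draws.
#'
#' @param cfg a \code{sim_cohort_config}.
#' @return list with \code{genotypes}, \code{truth} (a \code{true_kinship}),
#'   \code{maf} (true per-SNP frequencies), \code{config}.
#' @export
simulate_mixed_cohort <- function(cfg = sim_cohort_config()) {
  stopifnot(inherits(cfg, "sim_cohort_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  m <- cfg$m
  p <- stats::runif(m, cfg$maf_low, cfg$maf_high)
  counts <- cfg$n_pairs
  n <- 2L * sum(counts) + cfg$n_singletons
  if (n < 1L) stop("empty cohort")
  X <- matrix(NA_integer_, n, m)
  ids <- character(n)
  pair_rows <- list()
  row <- 0L
  spec_tbl <- data.frame(
    phi = c(0.125, 0.25, 0.5),
    tag = c("HS", "FS", "MZ"),
    k0 = c(0.5, 0.25, 0), k1 = c(0.5, 0.5, 0), k2 = c(0, 0.25, 1))
  for (r in seq_len(nrow(spec_tbl))) {
    cnt <- counts[[as.character(spec_tbl$phi[r])]]
    if (cnt == 0) next
    gen <- switch(spec_tbl$tag[r], HS = .half_sib_pair,
                  FS = .full_sib_pair, MZ = .mz_pair)
    for (k in seq_len(cnt)) {
      g <- gen(p)
      X[row + 1L, ] <- g[1L, ]; X[row + 2L, ] <- g[2L, ]
      ida <- sprintf("%s%d_a", spec_tbl$tag[r], k)
      idb <- sprintf("%s%d_b", spec_tbl$tag[r], k)
      ids[row + 1L] <- ida; ids[row + 2L] <- idb
      pair_rows[[length(pair_rows) + 1L]] <-
        data.frame(id_a = ida, id_b = idb, phi = spec_tbl$phi[r],
                   k0 = spec_tbl$k0[r], k1 = spec_tbl$k1[r],
                   k2 = spec_tbl$k2[r], stringsAsFactors = FALSE)
      row <- row + 2L
    }
  }
  if (cfg$n_singletons > 0) {
    idx <- row + seq_len(cfg$n_singletons)
    X[idx, ] <- matrix(stats::rbinom(cfg$n_singletons * m, 2L,
                                     rep(p, each = cfg$n_singletons)),
                       cfg$n_singletons, m)
    ids[idx] <- paste0("U", seq_len(cfg$n_singletons))
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(id_a = character(), id_b = character(), phi = numeric(),
               k0 = numeric(), k1 = numeric(), k2 = numeric())
  list(genotypes = genotype_matrix(X, sample_ids = ids),
       truth = true_kinship(ids, pairs), maf = p, config = cfg)
}

# one family of full siblings (two unobserved founder parents), given p
.sib_family <- function(family_size, p, prefix = "F1") {
  g <- .sib_block(family_size, p)
  ids <- sprintf("%s_s%d", prefix, seq_len(family_size))
  idx <- utils::combn(family_size, 2L)
  pairs <- data.frame(id_a = ids[idx[1L, ]], id_b = ids[idx[2L, ]],
                      phi = 0.25, k0 = 0.25, k1 = 0.5, k2 = 0.25,
                      stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(g, sample_ids = ids),
       truth = true_kinship(ids, pairs))
}

#' Simulate unrelated full-sib families
#'
#' Each family consists of \code{family_size} full siblings bred from two
#' unobserved founder parents (only the offspring are emitted); families are
#' mutually unrelated but share the same SNP panel (one pooled frequency
#' draw). Every within-family pair has true kinship 0.25.
#'
#' @param n_families number of families.
#' @param family_size siblings per family (>= 2).
#' @param m number of SNPs.
#' @param maf_low,maf_high frequency bounds.
#' @param seed optional integer seed.
#' @return list with \code{families} (list of \code{list(genotypes, truth)})
#'   and \code{maf} (pooled true frequencies).
#' @export
simulate_sib_families <- function(n_families, family_size, m,
                                  maf_low = 0.05, maf_high = 0.5,
                                  seed = NULL) {
  if (family_size < 2L) stop("family_size must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  p <- stats::runif(m, maf_low, maf_high)
  fams <- lapply(seq_len(n_families), function(f)
    .sib_family(family_size, p, prefix = paste0("F", f)))
  list(families = fams, maf = p)
}

#' Simulate a case-control cohort with allele-frequency shifts at risk SNPs
#'
#' Controls are drawn at MAFs uniform in \code{[maf_low, maf_high]}. A
#' fraction \code{risk_prop} of SNPs are risk SNPs: their case MAF is the
#' control MAF plus Gaussian noise N(0, shift_sd^2), clamped to
#' [0.05, 0.95]. Non-risk SNPs share the same MAF in cases and controls.
#'
#' @param n_cases,n_controls sample sizes.
#' @param m number of SNPs.
#' @param risk_prop proportion of risk SNPs in [0, 1].
#' @param shift_sd standard deviation of the case-MAF shift.
#' @param maf_low,maf_high control frequency bounds.
#' @param seed optional integer seed.
#' @return list with \code{genotypes}, \code{status} (factor case/control),
#'   \code{risk_snps} (indices), \code{maf_control}, \code{maf_case}.
#' @export
simulate_case_control <- function(n_cases, n_controls, m, risk_prop = 0.05,
                                  shift_sd = 0.05, maf_low = 0.05,
                                  maf_high = 0.5, seed = NULL) {
  if (risk_prop < 0 || risk_prop > 1) stop("risk_prop must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  p_ctl <- stats::runif(m, maf_low, maf_high)
  n_risk <- round(risk_prop * m)
  risk <- if (n_risk > 0) sort(sample.int(m, n_risk)) else integer(0)
  p_cas <- p_ctl
  if (n_risk > 0)
    p_cas[risk] <- pmin(pmax(p_ctl[risk] +
                               stats::rnorm(n_risk, 0, shift_sd), 0.05), 0.95)
  Xcas <- matrix(stats::rbinom(n_cases * m, 2L, rep(p_cas, each = n_cases)),
                 n_cases, m)
  Xctl <- matrix(stats::rbinom(n_controls * m, 2L,
                               rep(p_ctl, each = n_controls)),
                 n_controls, m)
  ids <- c(paste0("case", seq_len(n_cases)), paste0("ctrl", seq_len(n_controls)))
  list(genotypes = genotype_matrix(rbind(Xcas, Xctl), sample_ids = ids),
       status = factor(rep(c("case", "control"), c(n_cases, n_controls))),
       risk_snps = risk, maf_control = p_ctl, maf_case = p_cas)
}

#' Simulate an additive polygenic phenotype from genotypes
#'
#' A fraction \code{causal_prop} of polymorphic SNPs is chosen uniformly as
#' causal; their standardized dosages (centered at 2\eqn{\hat p}, scaled by
#' \eqn{\sqrt{2\hat p(1-\hat p)}}) receive i.i.d. Gaussian effects. The
#' genetic score is rescaled so its sample variance is exactly \code{h2}, and
#' an independent Gaussian residual with variance 1 - \code{h2} is added, so
#' the total phenotypic variance is approximately 1.
#'
#' @param G a \code{genotype_matrix} (no missing entries).
#' @param h2 narrow-sense heritability in [0, 1).
#' @param causal_prop proportion of SNPs that are causal.
#' @param seed optional integer seed.
#' @return list with \code{y} (named phenotype vector), \code{causal}
#'   (SNP indices), \code{effects} (per-causal-SNP standardized effects),
#'   \code{genetic} (the genetic component of y).
#' @export
simulate_phenotype <- function(G, h2, causal_prop = 0.01, seed = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (h2 < 0 || h2 >= 1) stop("h2 must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  X <- G$dosages
  if (anyNA(X)) stop("phenotype simulation requires complete genotypes")
  n <- nrow(X); m <- ncol(X)
  p <- colMeans(X) / 2
  poly <- which(p > 0 & p < 1)
  n_causal <- max(1L, round(causal_prop * m))
  if (h2 > 0 && length(poly) == 0L)
    stop("no polymorphic SNPs available for causal effects with h2 > 0")
  causal <- sort(sample(poly, min(n_causal, length(poly))))
  beta <- stats::rnorm(length(causal))
  if (h2 > 0) {
    W <- sweep(X[, causal, drop = FALSE], 2L, 2 * p[causal])
    W <- sweep(W, 2L, sqrt(2 * p[causal] * (1 - p[causal])), "/")
    g <- drop(W %*% beta)
    sg <- stats::sd(g)
    scl <- if (sg > 0) sqrt(h2) / sg else 0
    g <- g * scl
    beta <- beta * scl
  } else {
    g <- rep(0, n)
    beta <- beta * 0
  }
  y <- g + stats::rnorm(n, 0, sqrt(1 - h2))
  names(y) <- G$sample_ids
  list(y = y, causal = causal, effects = beta, genetic = g)
}

#' Simulate a phenotype directly from a kinship model
#'
#' Draws y ~ N(0, h2 * G + (1 - h2) * I) with G = 2 * phi, the
#' variance-component model that REML fits. Used for CI-calibration
#' experiments where the relationship matrix must be exactly correctly
#' specified.
#'
#' @param K a \code{kinship_matrix} or plain kinship (phi-scale) matrix.
#' @param h2 heritability in [0, 1].
#' @param seed optional integer seed.
#' @return named phenotype vector.
#' @export
simulate_phenotype_mvn <- function(K, h2, seed = NULL) {
  phi <- if (inherits(K, "kinship_matrix")) K$phi else as.matrix(K)
  if (h2 < 0 || h2 > 1) stop("h2 must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  G <- 2 * phi
  eg <- eigen(G, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  n <- nrow(G)
  z <- stats::rnorm(n)
  y <- drop(eg$vectors %*% (sqrt(h2 * d + (1 - h2)) * z))
  names(y) <- rownames(phi)
  y
}
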