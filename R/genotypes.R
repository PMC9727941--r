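#' Construct a genotype matrix
#'
#' The central data container: an n x m matrix of biallelic SNP dosages, where
#' entry (i, j) counts copies of the reference allele of SNP j carried by
#' sample i (0, 1 or 2). Missing genotypes are stored as \code{NA}; they are
#' never silently converted to a dosage.
#'
#' @param dosages numeric or integer n x m matrix; every non-missing entry
#'   must be exactly 0, 1 or 2. Missing entries are \code{NA}.
#' @param sample_ids character vector of n unique sample identifiers.
#'   Defaults to existing rownames or \code{"S1"..."Sn"}.
#' @param snp_ids character vector of m unique SNP identifiers. Defaults to
#'   existing colnames or \code{"snp1"..."snpm"}.
#' @param ref,alt per-SNP allele labels; the dosage counts \code{ref}.
#' @return An object of class \code{genotype_matrix}: a list with elements
#'   \code{dosages} (integer matrix with dimnames), \code{sample_ids},
#'   \code{snp_ids}, \code{ref}, \code{alt}.
#' @export
genotype_matrix <- function(dosages, sample_ids = NULL, snp_ids = NULL,
                            ref = NULL, alt = NULL) {
  if (!is.matrix(dosages)) stop("`dosages` must be a matrix")
  n <- nrow(dosages); m <- ncol(dosages)
  if (n < 1L || m < 1L) stop("genotype matrix needs at least 1 sample and 1 SNP")
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("non-missing dosages must be exactly 0, 1 or 2")
  if (is.null(sample_ids)) sample_ids <- rownames(dosages)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  if (is.null(snp_ids)) snp_ids <- colnames(dosages)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(m))
  sample_ids <- as.character(sample_ids); snp_ids <- as.character(snp_ids)
  if (length(sample_ids) != n) stop("length(sample_ids) != nrow(dosages)")
  if (length(snp_ids) != m) stop("length(snp_ids) != ncol(dosages)")
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  if (anyDuplicated(snp_ids)) stop("duplicated SNP ids")
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("B", m)
  if (length(ref) != m || length(alt) != m) stop("ref/alt must have one label per SNP")
  storage.mode(dosages) <- "integer"
  dimnames(dosages) <- list(sample_ids, snp_ids)
  structure(list(dosages = dosages, sample_ids = sample_ids, snp_ids = snp_ids,
                 ref = as.character(ref), alt = as.character(alt)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  nmiss <- sum(is.na(x$dosages))
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%d missing calls, %.2f%%)\n",
              nrow(x$dosages), ncol(x$dosages), nmiss,
              100 * nmiss / length(x$dosages)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Missingness mask
#'
#' @param G a \code{genotype_matrix}.
#' @return logical n x m matrix, \code{TRUE} where the genotype is missing.
#' @export
missing_mask <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  is.na(G$dosages)
}

#' Subset a genotype matrix
#'
#' @param x a \code{genotype_matrix}.
#' @param i sample index (integer, logical or id character vector).
#' @param j SNP index.
#' @param ... unused.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$sample_ids)
  if (missing(j)) j <- seq_along(x$snp_ids)
  if (is.character(i)) i <- match(i, x$sample_ids)
  if (is.character(j)) j <- match(j, x$snp_ids)
  genotype_matrix(x$dosages[i, j, drop = FALSE],
                  sample_ids = x$sample_ids[i], snp_ids = x$snp_ids[j],
                  ref = x$ref[j], alt = x$alt[j])
}

#' Per-SNP summary statistics
#'
#' Observed mean dosage, reference-allele frequency, unbiased sample variance
#' (divisor count - 1), Hardy-Weinberg variance 2p(1-p), and a monomorphic
#' flag, computed over a chosen set of samples with missing entries excluded.
#'
#' @param G a \code{genotype_matrix}.
#' @param centering_set samples over which statistics are computed (indices or
#'   ids); default all samples.
#' @return data.frame with one row per SNP: \code{snp}, \code{n_obs},
#'   \code{mean}, \code{freq}, \code{var_sample}, \code{var_hwe},
#'   \code{monomorphic}. SNPs with fewer than 2 non-missing values in the
#'   centering set get \code{var_sample = NA} (variance undefined).
#' @export
snp_stats <- function(G, centering_set = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  X <- G$dosages
  if (!is.null(centering_set)) {
    if (is.character(centering_set)) centering_set <- match(centering_set, G$sample_ids)
    if (length(centering_set) == 0L) stop("centering_set is empty")
    X <- X[centering_set, , drop = FALSE]
  }
  # integer-native reductions: colSums handles integer input without a
  # double copy of the matrix, and for dosages x^2 = x + 2*(x == 2)
  n_obs <- nrow(X) - colSums(is.na(X))
  s1 <- colSums(X, na.rm = TRUE)
  n2 <- colSums(X == 2L, na.rm = TRUE)
  mu <- s1 / n_obs
  mu[n_obs == 0L] <- NA_real_
  # unbiased sample variance: (sum x^2 - n mu^2) / (n - 1)
  sumsq <- s1 + 2 * n2
  vs <- (sumsq - n_obs * mu^2) / (n_obs - 1)
  vs[n_obs < 2L] <- NA_real_
  vs <- pmax(vs, 0)  # guard tiny negative round-off
  p <- mu / 2
  data.frame(snp = G$snp_ids, n_obs = n_obs, mean = mu, freq = p,
             var_sample = vs, var_hwe = 2 * p * (1 - p),
             monomorphic = !is.na(vs) & vs == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Quality-control filter
#'
#' Removes, in order, individuals with a missing-genotype fraction above
#' \code{ind_miss_max}, then SNPs whose post-removal missing rate exceeds
#' \code{snp_miss_max} or whose minor allele frequency falls below
#' \code{maf_min}. MAF is \code{min(p, 1 - p)} of the observed
#' reference-allele frequency.
#'
#' @param G a \code{genotype_matrix}.
#' @param ind_miss_max maximum tolerated per-individual missing fraction.
#' @param snp_miss_max maximum tolerated per-SNP missing rate.
#' @param maf_min minimum tolerated minor allele frequency.
#' @return list with \code{genotypes} (filtered \code{genotype_matrix}) and
#'   \code{report} (class \code{qc_report}: counts removed at each step).
#' @export
qc_filter <- function(G, ind_miss_max = 0.10, snp_miss_max = 0.05,
                      maf_min = 0.05) {
  stopifnot(inherits(G, "genotype_matrix"))
  thr <- c(ind_miss_max, snp_miss_max, maf_min)
  if (any(thr < 0 | thr > 1)) stop("QC thresholds must lie in [0, 1]")
  miss <- is.na(G$dosages)
  ind_frac <- rowMeans(miss)
  keep_ind <- ind_frac <= ind_miss_max
  if (!any(keep_ind)) stop("qc_filter removed all individuals")
  G2 <- G[which(keep_ind), ]
  st <- snp_stats(G2)
  snp_miss <- 1 - st$n_obs / nrow(G2$dosages)
  maf <- pmin(st$freq, 1 - st$freq)
  keep_snp <- snp_miss <= snp_miss_max & !is.na(maf) & maf >= maf_min
  if (!any(keep_snp)) stop("qc_filter removed all SNPs")
  n_snp_miss <- sum(snp_miss > snp_miss_max)
  n_snp_maf <- sum(keep_snp == FALSE) - n_snp_miss
  G3 <- G2[, which(keep_snp)]
  report <- structure(list(
    n_samples_in = nrow(G$dosages), n_snps_in = ncol(G$dosages),
    individuals_removed = sum(!keep_ind),
    snps_removed_missing = n_snp_miss,
    snps_removed_maf = max(n_snp_maf, 0L),
    snps_removed = sum(!keep_snp),
    n_samples_out = nrow(G3$dosages), n_snps_out = ncol(G3$dosages),
    thresholds = c(ind_miss_max = ind_miss_max, snp_miss_max = snp_miss_max,
                   maf_min = maf_min)), class = "qc_report")
  list(genotypes = G3, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report\n")
  cat(sprintf("  samples_in: %d\n", x$n_samples_in))
  cat(sprintf("  snps_in: %d\n", x$n_snps_in))
  cat(sprintf("  individuals_removed: %d\n", x$individuals_removed))
  cat(sprintf("  snps_removed_missing: %d\n", x$snps_removed_missing))
  cat(sprintf("  snps_removed_maf: %d\n", x$snps_removed_maf))
  cat(sprintf("  samples_out: %d\n", x$n_samples_out))
  cat(sprintf("  snps_out: %d\n", x$n_snps_out))
  invisible(x)
}

#' As a machine-readable one-row table
#' @param x a \code{qc_report}.
#' @return one-row data.frame of the QC counts.
#' @export
as.data.frame.qc_report <- function(x, ...) {
  data.frame(n_samples_in = x$n_samples_in, n_snps_in = x$n_snps_in,
             individuals_removed = x$individuals_removed,
             snps_removed_missing = x$snps_removed_missing,
             snps_removed_maf = x$snps_removed_maf,
             n_samples_out = x$n_samples_out, n_snps_out = x$n_snps_out)
}

#' Estimator configuration
#'
#' Controls how the GRM-type estimators obtain the per-SNP variance sigma_j^2,
#' how missing genotypes are handled, and which samples define the centering
#' means.
#'
#' @param variance_mode source of sigma_j^2: \code{"sample"} (unbiased sample
#'   variance over the centering set), \code{"known"} (user-supplied true
#'   variances, e.g. 2p(1-p) from a simulator or reference panel), or
#'   \code{"hwe"} (2\eqn{\hat p}(1-\eqn{\hat p}) from observed frequencies).
#' @param known_variances per-SNP variances, required (length m, all > 0) when
#'   \code{variance_mode = "known"}.
#' @param missing_policy \code{"mean_impute"} replaces missing dosages by the
#'   per-SNP centering-set mean (the centered score is then 0, contributing
#'   nothing to cross-products); \code{"error"} refuses missing data.
#' @param centering_set samples used to compute the per-SNP means (indices or
#'   ids); default all samples in the analysis.
#' @return object of class \code{estimator_config}.
#' @export
estimator_config <- function(variance_mode = c("sample", "known", "hwe"),
                             known_variances = NULL,
                             missing_policy = c("mean_impute", "error"),
                             centering_set = NULL) {
  variance_mode <- match.arg(variance_mode)
  missing_policy <- match.arg(missing_policy)
  if (variance_mode == "known") {
    if (is.null(known_variances))
      stop("variance_mode = \"known\" requires `known_variances`")
    if (any(!is.finite(known_variances)) || any(known_variances <= 0))
      stop("known_variances must all be finite and > 0")
  }
  structure(list(variance_mode = variance_mode,
                 known_variances = known_variances,
                 missing_policy = missing_policy,
                 centering_set = centering_set),
            class = "estimator_config")
}
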