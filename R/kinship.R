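#' Kinship matrix container
#'
#' An n x n symmetric matrix of pairwise kinship estimates on the phi scale
#' (correlation scale rho = 2 phi available via \code{\link{kinship_rho}}),
#' tagged with the estimator that produced it. Diagonal entries are the pair
#' formulas applied with i = i' (needed for a complete GRM); the estimators
#' are defined for pairs, so the diagonal is a construction choice recorded
#' here rather than an estimate of inbreeding.
#'
#' @param phi n x n numeric matrix (phi scale).
#' @param estimator tag: one of \code{"scgrm"}, \code{"ukin"}, \code{"rgrm"},
#'   \code{"king"}.
#' @param sample_ids character vector of n ids.
#' @param m number of SNPs used.
#' @param config snapshot of the \code{estimator_config} used (list), if any.
#' @return object of class \code{kinship_matrix}.
#' @export
kinship_matrix <- function(phi, estimator, sample_ids = NULL, m = NA_integer_,
                           config = NULL) {
  if (!is.matrix(phi) || nrow(phi) != ncol(phi))
    stop("phi must be a square matrix")
  asym <- abs(phi - t(phi))
  if (any(!is.na(asym)) && max(asym, na.rm = TRUE) > 1e-8)
    stop("phi must be symmetric")
  if (is.null(sample_ids)) sample_ids <- rownames(phi)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(phi)))
  dimnames(phi) <- list(sample_ids, sample_ids)
  structure(list(phi = phi, estimator = as.character(estimator),
                 sample_ids = as.character(sample_ids),
                 m = as.integer(m), config = config),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  off <- x$phi[upper.tri(x$phi)]
  cat(sprintf("kinship_matrix [%s]: %d samples, %s SNPs\n", x$estimator,
              nrow(x$phi), ifelse(is.na(x$m), "?", x$m)))
  cat(sprintf("  off-diagonal phi: mean %.4g, range [%.4g, %.4g], %.1f%% negative\n",
              mean(off, na.rm = TRUE), min(off, na.rm = TRUE),
              max(off, na.rm = TRUE), 100 * mean(off < 0, na.rm = TRUE)))
  invisible(x)
}

#' Correlation-scale estimates
#'
#' @param K a \code{kinship_matrix}.
#' @return the estimate matrix on the genotype-correlation scale rho = 2 phi.
#' @export
kinship_rho <- function(K) {
  stopifnot(inherits(K, "kinship_matrix"))
  2 * K$phi
}

# Resolve centering means and variances for the GRM-type estimators.
# Returns mu (centering-set means), sigma2, and the indices of usable SNPs
# (variance finite and > 0; monomorphic SNPs are dropped so that every
# estimator shares the same SNP set under the same config).
.estimator_prep <- function(G, config) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(config, "estimator_config"))
  if (config$missing_policy == "error" && anyNA(G$dosages))
    stop("missing genotypes present and missing_policy = \"error\"")
  st <- snp_stats(G, centering_set = config$centering_set)
  sigma2 <- switch(config$variance_mode,
                   sample = st$var_sample,
                   hwe = st$var_hwe,
                   known = {
                     kv <- config$known_variances
                     if (length(kv) != ncol(G$dosages))
                       stop("known_variances must have one entry per SNP")
                     kv
                   })
  keep <- is.finite(st$mean) & is.finite(sigma2) & sigma2 > 0
  if (config$variance_mode != "known")
    keep <- keep & !is.na(st$var_sample) & st$var_sample > 0
  if (!any(keep)) stop("no usable SNPs: all monomorphic or variance undefined")
  list(mu = st$mean, sigma2 = sigma2, keep = which(keep))
}

# Blocked accumulation of cross-product matrices. scale_fn maps a centered
# double block (missing imputed to the column mean, i.e. centered score 0) to
# the scaled block whose tcrossprod is accumulated.
.accumulate_crossprod <- function(X, mu, cols, scale_by, block_cols = NULL) {
  n <- nrow(X)
  if (is.null(block_cols)) block_cols <- max(1L, floor(2^24 / n))
  acc <- matrix(0, n, n)
  for (start in seq(1L, length(cols), by = block_cols)) {
    idx <- cols[start:min(start + block_cols - 1L, length(cols))]
    B <- X[, idx, drop = FALSE]
    storage.mode(B) <- "double"
    B <- sweep(B, 2L, mu[idx])
    B[is.na(B)] <- 0                      # mean imputation => centered 0
    if (!is.null(scale_by))
      B <- sweep(B, 2L, scale_by[idx], "/")
    acc <- acc + tcrossprod(B)
  }
  acc
}

#' scGRM kinship estimator
#'
#' The sample-correlation GRM estimate of the genotype correlation for a pair
#' (i, i') is the average over SNPs of the centered cross-product
#' (X_ij - Xbar_j)(X_i'j - Xbar_j) / sigma_j^2; the kinship estimate is half
#' that. Centering means Xbar_j are taken over the configured centering set,
#' and sigma_j^2 comes from the configured variance mode. Because the same
#' observed frequencies center every sample, the all-pairs average of these
#' estimates is forced negative: with sample variances over all n samples the
#' pair estimates sum to exactly -(n-1)/2 on the correlation scale.
#'
#' @param G a \code{genotype_matrix}.
#' @param config an \code{estimator_config}.
#' @return a \code{kinship_matrix} tagged \code{"scgrm"}. Diagonal entries use
#'   the same formula with i = i'.
#' @export
scgrm <- function(G, config = estimator_config()) {
  prep <- .estimator_prep(G, config)
  m_used <- length(prep$keep)
  R <- .accumulate_crossprod(G$dosages, prep$mu, prep$keep,
                             scale_by = sqrt(prep$sigma2)) / m_used
  kinship_matrix(R / 2, "scgrm", sample_ids = G$sample_ids, m = m_used,
                 config = config[c("variance_mode", "missing_policy")])
}

#' rGRM kinship estimator
#'
#' Weights SNPs proportionally to their variance: the correlation estimate is
#' the sum over SNPs of centered cross-products divided by the summed
#' variances, rather than the equal-weight average of per-SNP standardized
#' cross-products used by scGRM. When all SNPs share one variance the two
#' estimators coincide.
#'
#' @inheritParams scgrm
#' @return a \code{kinship_matrix} tagged \code{"rgrm"}.
#' @export
rgrm <- function(G, config = estimator_config()) {
  prep <- .estimator_prep(G, config)
  m_used <- length(prep$keep)
  C <- .accumulate_crossprod(G$dosages, prep$mu, prep$keep, scale_by = NULL)
  R <- C / sum(prep$sigma2[prep$keep])
  kinship_matrix(R / 2, "rgrm", sample_ids = G$sample_ids, m = m_used,
                 config = config[c("variance_mode", "missing_policy")])
}

#' UKin unbiased kinship estimator
#'
#' Corrects the scGRM estimate of each pair by half the off-diagonal row sums
#' of both members plus one, on the correlation scale:
#' rho_tilde(i,i') = rho_hat(i,i') + (S_i + S_i')/2 + 1 with
#' S_i = sum over k != i of rho_hat(i,k). The corrected estimator has
#' expectation equal to the true genotype correlation 2 phi, removing the
#' systematic negative bias of scGRM. The correction is an affine map of the
#' scGRM matrix, so no further genotype pass is needed; the diagonal uses the
#' same formula with i = i' (the row sum entering once from each side).
#'
#' @param scgrm_matrix a \code{kinship_matrix} tagged \code{"scgrm"} whose
#'   diagonal was computed by the pair formula with i = i' (as
#'   \code{\link{scgrm}} does).
#' @return a \code{kinship_matrix} tagged \code{"ukin"}.
#' @export
ukin <- function(scgrm_matrix) {
  stopifnot(inherits(scgrm_matrix, "kinship_matrix"))
  if (!identical(scgrm_matrix$estimator, "scgrm"))
    stop("ukin() corrects an scGRM matrix; got estimator tag \"",
         scgrm_matrix$estimator, "\"")
  R <- 2 * scgrm_matrix$phi
  if (max(abs(R - t(R))) > 1e-8) stop("input matrix must be symmetric")
  S <- rowSums(R) - diag(R)
  n <- nrow(R)
  Rt <- R + (matrix(S, n, n) + matrix(S, n, n, byrow = TRUE)) / 2 + 1
  kinship_matrix(Rt / 2, "ukin", sample_ids = scgrm_matrix$sample_ids,
                 m = scgrm_matrix$m, config = scgrm_matrix$config)
}

#' KING-robust kinship estimator
#'
#' Moment estimator from heterozygote and opposite-homozygote counts:
#' phi_hat(i,j) = (N_het,het - 2 N_opp) / (N_het(i) + N_het(j)), where
#' N_het,het counts SNPs at which both individuals are heterozygous, N_opp
#' counts opposite homozygotes, and N_het(.) counts heterozygous SNPs of each
#' individual over the SNP set non-missing in both. It uses no allele
#' frequencies, making it robust to frequency misspecification.
#'
#' @param G a \code{genotype_matrix} (>= 2 samples).
#' @return a \code{kinship_matrix} tagged \code{"king"}. Pairs in which
#'   neither individual is heterozygous anywhere get \code{NA} (undefined)
#'   with a warning; diagonal entries equal 0.5 by the formula.
#' @export
king_robust <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  X <- G$dosages
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 samples")
  has_missing <- anyNA(X)
  block_cols <- max(1L, floor(2^24 / n))
  m <- ncol(X)
  NAa <- matrix(0, n, n); OP <- matrix(0, n, n)
  HM <- if (has_missing) matrix(0, n, n) else NULL
  for (start in seq(1L, m, by = block_cols)) {
    idx <- start:min(start + block_cols - 1L, m)
    B <- X[, idx, drop = FALSE]
    H <- matrix(0, n, length(idx)); H[!is.na(B) & B == 1L] <- 1
    A0 <- matrix(0, n, length(idx)); A0[!is.na(B) & B == 0L] <- 1
    A2 <- matrix(0, n, length(idx)); A2[!is.na(B) & B == 2L] <- 1
    NAa <- NAa + tcrossprod(H)
    OP <- OP + tcrossprod(A0, A2)
    if (has_missing) {
      M <- matrix(0, n, length(idx)); M[!is.na(B)] <- 1
      HM <- HM + tcrossprod(H, M)
    }
  }
  Nopp <- OP + t(OP)
  if (has_missing) {
    denom <- HM + t(HM)
  } else {
    nhet <- diag(NAa)
    denom <- matrix(nhet, n, n) + matrix(nhet, n, n, byrow = TRUE)
  }
  phi <- (NAa - 2 * Nopp) / denom
  phi[denom == 0] <- NA_real_
  if (anyNA(phi))
    warning("KING kinship undefined (no heterozygous SNPs) for some pairs")
  kinship_matrix(phi, "king", sample_ids = G$sample_ids, m = ncol(X))
}

#' KING-robust estimates for selected pairs
#'
#' Same statistic as \code{\link{king_robust}} computed only for the listed
#' pairs, avoiding the full n x n matrix for large cohorts.
#'
#' @param G a \code{genotype_matrix}.
#' @param id_a,id_b equal-length vectors of sample ids (or indices).
#' @return data.frame with columns \code{id_a}, \code{id_b}, \code{phi}.
#' @export
king_robust_pairs <- function(G, id_a, id_b) {
  stopifnot(inherits(G, "genotype_matrix"))
  X <- G$dosages
  ia <- if (is.character(id_a)) match(id_a, G$sample_ids) else as.integer(id_a)
  ib <- if (is.character(id_b)) match(id_b, G$sample_ids) else as.integer(id_b)
  if (anyNA(ia) || anyNA(ib)) stop("unknown sample ids")
  phi <- vapply(seq_along(ia), function(k) {
    x <- X[ia[k], ]; y <- X[ib[k], ]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    nhh <- sum(x == 1L & y == 1L)
    nopp <- sum((x == 0L & y == 2L) | (x == 2L & y == 0L))
    den <- sum(x == 1L) + sum(y == 1L)
    if (den == 0L) NA_real_ else (nhh - 2 * nopp) / den
  }, numeric(1))
  data.frame(id_a = G$sample_ids[ia], id_b = G$sample_ids[ib], phi = phi,
             stringsAsFactors = FALSE)
}

# degree thresholds: powers of 2 (2^-3/2, 2^-5/2, 2^-7/2, 2^-9/2)
.degree_breaks <- 2^(-c(9, 7, 5, 3) / 2)
.degree_labels <- c("unrelated", "third_degree", "second_degree",
                    "first_degree", "MZ")

#' Classify relationship degree from a kinship estimate
#'
#' Interval rules on powers of two: MZ if phi > 2^(-3/2); first degree in
#' (2^(-5/2), 2^(-3/2)]; second degree in (2^(-7/2), 2^(-5/2)]; third degree
#' in (2^(-9/2), 2^(-7/2)]; unrelated if phi <= 2^(-9/2). Boundaries are
#' half-open with the upper endpoint included in the lower-degree class, so a
#' value exactly at a threshold classifies deterministically to the more
#' distant class.
#'
#' @param phi numeric vector of kinship estimates (finite).
#' @return factor with levels unrelated, third_degree, second_degree,
#'   first_degree, MZ.
#' @export
classify_relationship <- function(phi) {
  if (any(!is.finite(phi))) stop("phi must be finite")
  cut(phi, breaks = c(-Inf, .degree_breaks, Inf), labels = .degree_labels,
      right = TRUE)
}

#' Relationship calls for all pairs of a kinship matrix
#'
#' @param K a \code{kinship_matrix}.
#' @return data.frame with one row per unordered pair: \code{id_a},
#'   \code{id_b}, \code{phi}, \code{degree}.
#' @export
classify_pairs <- function(K) {
  stopifnot(inherits(K, "kinship_matrix"))
  n <- nrow(K$phi)
  ut <- which(upper.tri(K$phi), arr.ind = TRUE)
  phi <- K$phi[ut]
  data.frame(id_a = K$sample_ids[ut[, 1]], id_b = K$sample_ids[ut[, 2]],
             phi = phi, degree = classify_relationship(phi),
             stringsAsFactors = FALSE)
}
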