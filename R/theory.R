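#' True pairwise correlation structure
#'
#' Container for the true genotype correlations rho(i,i') = 2 phi(i,i') of a
#' cohort, used by the closed-form bias calculators. The off-diagonal average
#' rho_bar must lie in [0, 1].
#'
#' @param rho n x n symmetric numeric matrix of true correlations.
#' @return object of class \code{correlation_structure} with fields
#'   \code{rho} and \code{rho_bar}.
#' @export
correlation_structure <- function(rho) {
  rho <- as.matrix(rho)
  if (nrow(rho) != ncol(rho)) stop("rho must be square")
  if (max(abs(rho - t(rho))) > 1e-10) stop("rho must be symmetric")
  n <- nrow(rho)
  if (n < 2L) stop("need at least 2 individuals")
  rho_bar <- sum(rho[upper.tri(rho)]) / (n * (n - 1) / 2)
  if (rho_bar < -1e-12 || rho_bar > 1 + 1e-12)
    stop("average off-diagonal correlation must lie in [0, 1]")
  structure(list(rho = rho, rho_bar = rho_bar), class = "correlation_structure")
}

#' Expected scGRM estimate for one pair
#'
#' Closed-form expectation, under known per-SNP variances, of the centered
#' cross-product (X_ij - Xbar_j)(X_i'j - Xbar_j)/sigma_j^2 — and hence of the
#' scGRM correlation estimate, which averages it over SNPs:
#' rho(i,i') - (1/n) sum_{a != i} rho(i,a) - (1/n) sum_{a != i'} rho(a,i')
#' - 1/n + ((n-1)/n) rho_bar. The deviation of this from rho(i,i') is the
#' systematic scGRM bias induced by centering with observed means.
#'
#' @param structure a \code{correlation_structure}.
#' @param i,ip distinct individual indices.
#' @param scale \code{"rho"} (correlation, default) or \code{"phi"} (kinship,
#'   i.e. half the correlation value).
#' @return the expected estimate (a single number).
#' @export
expected_scgrm_pair <- function(structure, i, ip, scale = c("rho", "phi")) {
  stopifnot(inherits(structure, "correlation_structure"))
  scale <- match.arg(scale)
  R <- structure$rho
  n <- nrow(R)
  if (i == ip) stop("the expectation formula is defined for pairs (i != i')")
  si <- sum(R[i, -i]); sip <- sum(R[-ip, ip])
  out <- R[i, ip] - si / n - sip / n - 1 / n +
    (n - 1) / n * structure$rho_bar
  if (scale == "phi") out / 2 else out
}

#' Expected all-pairs sum of scGRM correlation estimates
#'
#' For every SNP, the centered standardized cross-products summed over all
#' unordered pairs have expectation (n-1)(rho_bar - 1)/2 — non-positive
#' whenever rho_bar <= 1, which is the negative-sum identity explaining the
#' prevalence of negative kinship estimates.
#'
#' @param n number of individuals (>= 2).
#' @param rho_bar average true off-diagonal correlation, in [0, 1].
#' @return the expected sum (correlation scale).
#' @export
expected_pair_sum <- function(n, rho_bar) {
  if (n < 2) stop("need n >= 2")
  if (rho_bar < 0 || rho_bar > 1) stop("rho_bar must be in [0, 1]")
  (n - 1) * (rho_bar - 1) / 2
}

#' Expected average scGRM kinship in a uniformly related group
#'
#' Dividing the expected all-pairs sum by the number of pairs and halving to
#' the kinship scale gives (rho_bar - 1)/(2n): the expected average scGRM
#' kinship estimate in a group of n individuals with average true correlation
#' rho_bar. For a single family of 500 full siblings (rho_bar = 0.5) this is
#' -5e-4 even though every true kinship is 0.25.
#'
#' @param n group size (>= 2).
#' @param rho_bar average true off-diagonal correlation, in [0, 1].
#' @return expected mean kinship estimate (phi scale).
#' @export
expected_family_average_kinship <- function(n, rho_bar) {
  if (n < 2) stop("need n >= 2")
  if (rho_bar < 0 || rho_bar > 1) stop("rho_bar must be in [0, 1]")
  (rho_bar - 1) / (2 * n)
}
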