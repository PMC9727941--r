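#' Family-average kinship experiment (many large full-sib families)
#'
#' Simulates unrelated families of full siblings, and for each family
#' computes the scGRM and UKin kinship matrices with within-family centering
#' and known per-SNP variances 2p(1-p) (the simulator's true frequencies),
#' then averages each over all within-family pairs. The scGRM family
#' averages concentrate around the closed-form value
#' \code{\link{expected_family_average_kinship}(family_size, 0.5)} (negative,
#' although every true kinship is 0.25), while the UKin averages concentrate
#' around 0.25; the two family averages are linked exactly by the affine
#' identity rho_ukin_avg = family_size * rho_scgrm_avg + 1.
#'
#' @param n_families number of families.
#' @param family_size siblings per family (>= 2).
#' @param m SNPs per individual.
#' @param maf_low,maf_high frequency bounds.
#' @param seed optional integer seed.
#' @return object of class \code{sib_family_experiment}: a list with
#'   \code{per_family} (data.frame of family-average phi for both methods),
#'   \code{mean_scgrm}, \code{mean_ukin}, \code{expected_scgrm} (closed
#'   form), \code{max_affine_residual} (largest absolute violation of the
#'   affine identity across families), and the design parameters.
#' @export
run_sib_family_experiment <- function(n_families = 200, family_size = 500,
                                      m = 10000, maf_low = 0.05,
                                      maf_high = 0.5, seed = NULL) {
  if (family_size < 2L) stop("family_size must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  p <- stats::runif(m, maf_low, maf_high)
  cfg <- estimator_config(variance_mode = "known",
                          known_variances = 2 * p * (1 - p))
  avg_s <- avg_u <- numeric(n_families)
  max_resid <- 0
  for (f in seq_len(n_families)) {
    fam <- .sib_family(family_size, p, prefix = paste0("F", f))
    Ks <- scgrm(fam$genotypes, cfg)
    Ku <- ukin(Ks)
    ut <- upper.tri(Ks$phi)
    avg_s[f] <- mean(Ks$phi[ut])
    avg_u[f] <- mean(Ku$phi[ut])
    resid <- abs((2 * avg_u[f]) - (family_size * (2 * avg_s[f]) + 1))
    max_resid <- max(max_resid, resid)
  }
  structure(list(per_family = data.frame(family = seq_len(n_families),
                                         phi_scgrm = avg_s, phi_ukin = avg_u),
                 mean_scgrm = mean(avg_s), mean_ukin = mean(avg_u),
                 expected_scgrm = expected_family_average_kinship(family_size,
                                                                 0.5),
                 max_affine_residual = max_resid,
                 n_families = n_families, family_size = family_size, m = m),
            class = "sib_family_experiment")
}

#' @export
print.sib_family_experiment <- function(x, ...) {
  cat(sprintf("sib_family_experiment: %d families x %d sibs, %d SNPs\n",
              x$n_families, x$family_size, x$m))
  cat(sprintf("  mean family-average scGRM kinship: %.6f (closed form %.6f)\n",
              x$mean_scgrm, x$expected_scgrm))
  cat(sprintf("  mean family-average UKin  kinship: %.6f (true value 0.25)\n",
              x$mean_ukin))
  cat(sprintf("  max |affine identity residual|: %.3g\n",
              x$max_affine_residual))
  invisible(x)
}

#' Per-group bias and SD of kinship estimates
#'
#' Groups every unordered pair of the cohort by its exact true kinship value
#' (pairs absent from the truth table have true kinship 0) and reports the
#' per-group mean deviation from truth and the within-group standard
#' deviation of the estimates, on the phi scale and in units of 1e-3.
#'
#' @param estimates a \code{kinship_matrix}.
#' @param truth a \code{true_kinship} over the same samples.
#' @return data.frame with columns \code{group} (true kinship), \code{n_pairs},
#'   \code{bias}, \code{sd}, \code{bias_1e3}, \code{sd_1e3},
#'   \code{estimator}.
#' @export
group_summary <- function(estimates, truth) {
  stopifnot(inherits(estimates, "kinship_matrix"),
            inherits(truth, "true_kinship"))
  if (!setequal(estimates$sample_ids, truth$sample_ids))
    stop("sample ids of estimates and truth do not match")
  P <- estimates$phi
  ids <- estimates$sample_ids
  n <- nrow(P)
  n_pairs_total <- n * (n - 1) / 2
  s1_tot <- (sum(P) - sum(diag(P))) / 2
  s2_tot <- (sum(P^2) - sum(diag(P)^2)) / 2
  pr <- truth$pairs
  out <- list()
  rel_vals <- numeric(0)
  if (nrow(pr)) {
    ia <- match(pr$id_a, ids); ib <- match(pr$id_b, ids)
    rel_vals <- P[cbind(ia, ib)]
    for (g in sort(unique(pr$phi))) {
      v <- rel_vals[pr$phi == g]
      out[[length(out) + 1L]] <-
        data.frame(group = g, n_pairs = length(v), bias = mean(v) - g,
                   sd = stats::sd(v))
    }
  }
  n0 <- n_pairs_total - length(rel_vals)
  if (n0 > 0) {
    s1 <- s1_tot - sum(rel_vals)
    s2 <- s2_tot - sum(rel_vals^2)
    mean0 <- s1 / n0
    sd0 <- if (n0 > 1) sqrt(max(0, (s2 - n0 * mean0^2) / (n0 - 1))) else NA_real_
    out <- c(list(data.frame(group = 0, n_pairs = n0, bias = mean0,
                             sd = sd0)), out)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$group), , drop = FALSE]
  res$bias_1e3 <- res$bias * 1e3
  res$sd_1e3 <- res$sd * 1e3
  res$estimator <- estimates$estimator
  rownames(res) <- NULL
  res
}

# closed-form scGRM bias prediction for a representative pair of each group
# in a mixed cohort made of disjoint relative pairs plus singletons:
# each member of a kinship-phi pair has off-diagonal true-correlation row sum
# 2*phi, singletons 0.
.predicted_scgrm_bias <- function(groups, counts, n) {
  rho_bar <- 2 * sum(2 * counts * c(0.125, 0.25, 0.5)) / (n * (n - 1))
  vapply(groups, function(g) {
    rs <- 2 * g                            # row sum of each member
    (-2 * rs / n - 1 / n + (n - 1) / n * rho_bar) / 2   # phi scale
  }, numeric(1))
}

#' Mixed-cohort kinship estimation experiment
#'
#' Simulates a cohort of disjoint relative pairs plus singletons
#' (\code{\link{simulate_mixed_cohort}}), estimates kinship with the
#' requested estimators, and summarizes bias and SD per true-kinship group
#' over all pairs. The UKin matrix is derived from the scGRM matrix, so
#' requesting both costs one genotype pass. The summary also carries the
#' closed-form scGRM bias prediction for a representative pair of each group
#' so realized and predicted bias can be compared.
#'
#' @param cfg a \code{sim_cohort_config}.
#' @param estimators subset of \code{c("ukin", "scgrm", "rgrm", "king")}.
#' @param variance_mode \code{"known"} (default: true 2p(1-p) from the
#'   simulator), \code{"sample"} or \code{"hwe"} for the GRM-type
#'   estimators.
#' @param seed optional integer seed (overrides \code{cfg$seed}).
#' @param keep_estimates return the kinship matrices as well (memory-heavy
#'   at full scale).
#' @return object of class \code{mixed_cohort_experiment}: \code{summary}
#'   (stacked \code{\link{group_summary}} rows for all estimators, plus a
#'   \code{predicted_scgrm_bias_1e3} column), \code{n}, \code{m}, and
#'   optionally \code{estimates}.
#' @export
run_mixed_cohort_experiment <- function(cfg = sim_cohort_config(),
                                        estimators = c("ukin", "scgrm",
                                                       "rgrm", "king"),
                                        variance_mode = "known",
                                        seed = NULL,
                                        keep_estimates = FALSE) {
  stopifnot(inherits(cfg, "sim_cohort_config"))
  bad <- setdiff(estimators, c("ukin", "scgrm", "rgrm", "king"))
  if (length(bad)) stop("unknown estimators: ", paste(bad, collapse = ", "))
  if (!is.null(seed)) cfg$seed <- seed
  sim <- simulate_mixed_cohort(cfg)
  n <- length(sim$genotypes$sample_ids)
  config <- if (variance_mode == "known")
    estimator_config(variance_mode = "known",
                     known_variances = 2 * sim$maf * (1 - sim$maf))
  else estimator_config(variance_mode = variance_mode)
  mats <- list()
  if (any(c("scgrm", "ukin") %in% estimators)) {
    Ks <- scgrm(sim$genotypes, config)
    if ("scgrm" %in% estimators) mats$scgrm <- Ks
    if ("ukin" %in% estimators) mats$ukin <- ukin(Ks)
    if (!("scgrm" %in% estimators)) rm(Ks)
  }
  if ("rgrm" %in% estimators) mats$rgrm <- rgrm(sim$genotypes, config)
  if ("king" %in% estimators) mats$king <- king_robust(sim$genotypes)
  summaries <- lapply(mats, group_summary, truth = sim$truth)
  summary <- if (length(summaries)) do.call(rbind, summaries) else
    data.frame(group = numeric(), n_pairs = integer(), bias = numeric(),
               sd = numeric(), bias_1e3 = numeric(), sd_1e3 = numeric(),
               estimator = character())
  rownames(summary) <- NULL
  if (nrow(summary))
    summary$predicted_scgrm_bias_1e3 <-
      1e3 * .predicted_scgrm_bias(summary$group, cfg$n_pairs, n)
  out <- list(summary = summary, n = n, m = cfg$m, config = cfg,
              variance_mode = variance_mode)
  if (keep_estimates) {
    out$estimates <- mats
    out$truth <- sim$truth
  }
  structure(out, class = "mixed_cohort_experiment")
}

#' @export
print.mixed_cohort_experiment <- function(x, ...) {
  cat(sprintf("mixed_cohort_experiment: n = %d, m = %d (variance: %s)\n",
              x$n, x$m, x$variance_mode))
  cat("bias and SD per true-kinship group (units of 1e-3, phi scale):\n")
  print(x$summary[, c("estimator", "group", "n_pairs", "bias_1e3", "sd_1e3",
                      "predicted_scgrm_bias_1e3")], digits = 4)
  invisible(x)
}
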