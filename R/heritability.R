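# Restricted likelihood machinery for the single-GRM model
#   y ~ N(mu 1, sigma2 * (h2 G + (1 - h2) I)).
# The intercept is absorbed first: with L an orthonormal basis of the
# orthogonal complement of 1, the REML criterion is the ordinary likelihood
# of the contrasts L'y ~ N(0, sigma2 * (h2 M + (1 - h2) I)), M = L'GL.
# Working on M rather than G makes REML's exact invariance to components of
# the form u1' + 1u' + c11' (which includes the whole UKin correction)
# hold numerically, not just algebraically.
.reml_contrast_prep <- function(G, tol = 1e-8) {
  n <- nrow(G)
  L <- qr.Q(qr(cbind(rep(1, n), diag(n))))[, 2:n, drop = FALSE]
  M <- crossprod(L, G %*% L)
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  d <- eg$values
  scale_ref <- max(abs(d), 1)
  n_clipped <- sum(d < -tol * scale_ref)
  d <- pmax(d, 0)
  # rotation taking y to the contrast eigenbasis
  list(rot = crossprod(eg$vectors, t(L)), d = d, n = n,
       n_clipped = n_clipped)
}

# profile restricted log-likelihood over h2 given contrast-eigenbasis data
.reml_loglik <- function(h2, ytil, d, n) {
  lam <- h2 * d + (1 - h2)
  if (any(lam < 1e-12)) return(-Inf)
  s2 <- sum(ytil^2 / lam) / (n - 1)
  -0.5 * ((n - 1) * (log(2 * pi * s2) + 1) + sum(log(lam)))
}

# grid scan + local refinement of the profile REML over h2 in [0, 1];
# returns the fit pieces shared by reml_h2 and the coverage fast path
.reml_fit_eigen <- function(ytil, d, n, grid_points = 101L) {
  ll <- function(h) .reml_loglik(h, ytil, d, n)
  grid <- seq(0, 1, length.out = grid_points)
  vals <- vapply(grid, ll, numeric(1))
  best <- which.max(vals)
  lo <- grid[max(1L, best - 1L)]; hi <- grid[min(grid_points, best + 1L)]
  opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-8)
  h2 <- opt$maximum; llmax <- opt$objective
  # the optimizer never lands exactly on the boundary; snap if the boundary
  # value is at least as good
  for (b in c(0, 1)) {
    vb <- ll(b)
    if (is.finite(vb) && vb >= llmax) { h2 <- b; llmax <- vb }
  }
  boundary <- h2 < 1e-6 || h2 > 1 - 1e-6
  # observed information of the profile restricted likelihood (numeric);
  # evaluated at an interior point next to a boundary optimum
  h <- 1e-3
  hc <- min(max(h2, h), 1 - h)
  ll2 <- (ll(hc + h) - 2 * ll(hc) + ll(hc - h)) / h^2
  se <- if (is.finite(ll2) && ll2 < 0) sqrt(-1 / ll2) else NA_real_
  lam <- h2 * d + (1 - h2)
  s2 <- sum(ytil^2 / lam) / (n - 1)
  list(h2 = h2, se = se, loglik = llmax, sigma2 = s2,
       boundary = boundary, n_eval = grid_points + 2L,
       grid = grid, grid_loglik = vals)
}

#' Heritability fit result
#'
#' @param x a \code{heritability_fit} object (from \code{\link{reml_h2}}).
#' @param ... unused.
#' @export
print.heritability_fit <- function(x, ...) {
  cat(sprintf("heritability_fit: h2 = %.4f (SE %.4f), 95%% CI [%.4f, %.4f]\n",
              x$h2, x$se, x$ci95[1], x$ci95[2]))
  cat(sprintf("  sigma_g2 = %.4f, sigma_e2 = %.4f, logLik = %.3f\n",
              x$sigma_g2, x$sigma_e2, x$loglik))
  cat(sprintf("  converged: %s%s (n = %d, %d clipped eigenvalues)\n",
              x$converged, if (x$boundary) " [boundary]" else "", x$n,
              x$n_clipped))
  invisible(x)
}

#' REML heritability from a kinship matrix
#'
#' Fits the single-variance-component model
#' y ~ N(mu 1, sigma_g^2 G + sigma_e^2 I) with G = 2 K (so the diagonal of a
#' self-kinship-0.5 matrix becomes 1), maximizing the restricted likelihood
#' by eigendecomposition of G and one-dimensional profile optimization of
#' h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2) over [0, 1]. The standard error
#' comes from the observed information of the profile restricted likelihood;
#' the 95% CI is the normal interval h2 +/- 1.96 SE. Boundary optima are
#' flagged and their SE carries the same information-based caveat.
#'
#' @param y numeric phenotype vector (named or in the order of \code{K}).
#' @param K a \code{kinship_matrix} or plain phi-scale matrix.
#' @param tol eigenvalue tolerance: eigenvalues of G below \code{-tol} trigger
#'   a warning and are clipped to zero.
#' @param grid_points number of h2 grid points bracketing the optimum before
#'   local refinement.
#' @return object of class \code{heritability_fit}: fields \code{h2},
#'   \code{se}, \code{ci95}, \code{sigma_g2}, \code{sigma_e2}, \code{loglik},
#'   \code{converged}, \code{boundary}, \code{n_iter}, \code{n},
#'   \code{n_clipped}, \code{grid} (the profile grid, for diagnostics).
#' @export
reml_h2 <- function(y, K, tol = 1e-8, grid_points = 101L) {
  phi <- if (inherits(K, "kinship_matrix")) K$phi else as.matrix(K)
  n <- length(y)
  if (any(!is.finite(y))) stop("phenotype must be finite")
  if (n != nrow(phi)) stop("length(y) does not match the kinship matrix")
  if (n < 10L) stop("refusing to fit with n < 10: SE would be meaningless")
  if (!is.null(names(y)) && !is.null(rownames(phi))) {
    if (!all(names(y) %in% rownames(phi))) stop("phenotype ids not in K")
    phi <- phi[names(y), names(y)]
  }
  G <- 2 * phi
  prep <- .reml_contrast_prep(G, tol)
  if (prep$n_clipped > 0)
    warning(prep$n_clipped,
            " negative eigenvalue(s) of the projected GRM clipped to zero")
  if (stats::sd(prep$d) < 1e-8 * max(max(abs(prep$d)), 1))
    stop("GRM is proportional to the identity: sigma_g2 and sigma_e2 are ",
         "not separately identifiable")
  ytil <- drop(prep$rot %*% y)
  fit <- .reml_fit_eigen(ytil, prep$d, n, grid_points)
  structure(list(h2 = fit$h2, se = fit$se,
                 ci95 = c(fit$h2 - 1.96 * fit$se, fit$h2 + 1.96 * fit$se),
                 sigma_g2 = fit$h2 * fit$sigma2,
                 sigma_e2 = (1 - fit$h2) * fit$sigma2,
                 loglik = fit$loglik, converged = is.finite(fit$loglik),
                 boundary = fit$boundary, n_iter = fit$n_eval, n = n,
                 n_clipped = prep$n_clipped,
                 grid = data.frame(h2 = fit$grid, loglik = fit$grid_loglik)),
            class = "heritability_fit")
}

# estimate a kinship matrix for the coverage experiment
.estimate_kinship <- function(G, method, config) {
  switch(method,
         scgrm = scgrm(G, config),
         ukin = ukin(scgrm(G, config)),
         rgrm = rgrm(G, config),
         king = king_robust(G),
         stop("unknown estimator: ", method))
}

#' Heritability CI-coverage experiment
#'
#' Repeatedly simulates a cohort of unrelated full-sib families with a
#' heritable phenotype, estimates kinship by the chosen method (or uses the
#' true kinship), fits \code{\link{reml_h2}}, and records the estimate, SE
#' and whether the 95% normal CI covers the true value.
#'
#' Two phenotype models are available. \code{"causal"} draws SNP effects on
#' standardized dosages (\code{\link{simulate_phenotype}}), so the realized
#' genetic covariance fluctuates around the pedigree expectation.
#' \code{"mvn"} draws y ~ N(0, h2 G + (1-h2) I) from the true-kinship GRM,
#' the exactly correctly specified model, which is the appropriate benchmark
#' for CI calibration.
#'
#' @param reps number of replicates (>= 1).
#' @param true_h2 true heritability.
#' @param n_families,family_size,m cohort design (full-sib families).
#' @param causal_prop proportion of causal SNPs for the causal model.
#' @param estimator \code{"true"}, \code{"ukin"}, \code{"scgrm"},
#'   \code{"rgrm"} or \code{"king"}.
#' @param pheno_model \code{"causal"} or \code{"mvn"}.
#' @param variance_mode variance mode for the GRM-type estimators.
#' @param seed optional integer seed.
#' @return list with \code{results} (one row per replicate: \code{h2},
#'   \code{se}, \code{lo}, \code{hi}, \code{covered}, \code{boundary},
#'   \code{failed}) and \code{summary} (\code{bias}, \code{sd},
#'   \code{coverage}, \code{n_fail}).
#' @export
coverage_experiment <- function(reps, true_h2, n_families = 100,
                                family_size = 5, m = 5000,
                                causal_prop = 0.01,
                                estimator = c("true", "ukin", "scgrm",
                                              "rgrm", "king"),
                                pheno_model = c("causal", "mvn"),
                                variance_mode = "sample", seed = NULL) {
  estimator <- match.arg(estimator)
  pheno_model <- match.arg(pheno_model)
  if (reps < 1) stop("reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- n_families * family_size
  # block-diagonal true kinship of the sib-family cohort (same every rep)
  phi_true <- matrix(0, n, n)
  blk <- matrix(0.25, family_size, family_size)
  diag(blk) <- 0.5
  for (f in seq_len(n_families)) {
    idx <- (f - 1L) * family_size + seq_len(family_size)
    phi_true[idx, idx] <- blk
  }
  fast_mvn_true <- estimator == "true" && pheno_model == "mvn"
  if (fast_mvn_true) {
    prep <- .reml_contrast_prep(2 * phi_true)
    egf <- eigen(2 * phi_true, symmetric = TRUE)   # for simulating y
    dful <- pmax(egf$values, 0)
  }
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    res <- tryCatch({
      if (fast_mvn_true) {
        z <- stats::rnorm(n)
        y <- drop(egf$vectors %*% (sqrt(true_h2 * dful + (1 - true_h2)) * z))
        fit <- .reml_fit_eigen(drop(prep$rot %*% y), prep$d, n)
        list(h2 = fit$h2, se = fit$se, boundary = fit$boundary)
      } else {
        sim <- simulate_sib_families(n_families, family_size, m)
        X <- do.call(rbind, lapply(sim$families,
                                   function(f) f$genotypes$dosages))
        G <- genotype_matrix(X, sample_ids = unlist(lapply(
          sim$families, function(f) f$genotypes$sample_ids)))
        y <- if (pheno_model == "mvn")
          simulate_phenotype_mvn(phi_true, true_h2)
        else simulate_phenotype(G, true_h2, causal_prop)$y
        K <- if (estimator == "true")
          kinship_matrix(phi_true, "true", sample_ids = G$sample_ids)
        else .estimate_kinship(G, estimator,
                               estimator_config(variance_mode = variance_mode))
        fit <- reml_h2(unname(y), K)
        list(h2 = fit$h2, se = fit$se, boundary = fit$boundary)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[r]] <- data.frame(rep = r, h2 = NA_real_, se = NA_real_,
                              lo = NA_real_, hi = NA_real_, covered = NA,
                              boundary = NA, failed = TRUE)
    } else {
      lo <- res$h2 - 1.96 * res$se; hi <- res$h2 + 1.96 * res$se
      rows[[r]] <- data.frame(rep = r, h2 = res$h2, se = res$se, lo = lo,
                              hi = hi,
                              covered = !is.na(lo) && lo <= true_h2 &&
                                true_h2 <= hi,
                              boundary = res$boundary, failed = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  ok <- !results$failed
  list(results = results,
       summary = list(bias = mean(results$h2[ok]) - true_h2,
                      sd = stats::sd(results$h2[ok]),
                      coverage = mean(results$covered[ok]),
                      n_fail = sum(!ok)))
}
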