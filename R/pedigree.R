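#' Pedigree specification for gene dropping
#'
#' Individuals are numbered 1..N in birth order: founders first (ids
#' \code{1..founders}), then the offspring of each mating in order, then MZ
#' clones. A mating may name any previously defined individual as a parent,
#' so multi-generation pedigrees (e.g. first cousins) are built by chaining
#' matings. The birth-order construction makes the graph acyclic: a parent id
#' must be smaller than its offspring's id.
#'
#' @param founders number of founder individuals (drawn from the population
#'   allele frequencies, mutually unrelated, non-inbred).
#' @param matings data.frame with columns \code{parent_a}, \code{parent_b},
#'   \code{n_offspring}; parents are ids of already-defined individuals.
#' @param mz_clones optional data.frame with columns \code{template},
#'   \code{n_copies}: genetically identical copies (MZ twins) of an existing
#'   individual.
#' @return object of class \code{pedigree_spec} with the individual table
#'   (\code{id}, \code{father}, \code{mother}, \code{mz_of}).
#' @export
pedigree_spec <- function(founders, matings = NULL, mz_clones = NULL) {
  founders <- as.integer(founders)
  if (founders < 1L) stop("need at least one founder")
  id <- seq_len(founders)
  father <- mother <- mz_of <- rep(NA_integer_, founders)
  if (!is.null(matings)) {
    matings <- as.data.frame(matings)
    for (r in seq_len(nrow(matings))) {
      pa <- as.integer(matings$parent_a[r]); pb <- as.integer(matings$parent_b[r])
      k <- as.integer(matings$n_offspring[r])
      if (k < 1L) stop("n_offspring must be >= 1")
      if (pa == pb) stop("selfing is not supported")
      nmax <- length(id)
      if (pa > nmax || pb > nmax || pa < 1L || pb < 1L)
        stop("mating ", r, " references an individual not yet defined ",
             "(parents must precede offspring; cyclic pedigrees are invalid)")
      new <- nmax + seq_len(k)
      id <- c(id, new)
      father <- c(father, rep(pa, k)); mother <- c(mother, rep(pb, k))
      mz_of <- c(mz_of, rep(NA_integer_, k))
    }
  }
  if (!is.null(mz_clones)) {
    mz_clones <- as.data.frame(mz_clones)
    for (r in seq_len(nrow(mz_clones))) {
      tpl <- as.integer(mz_clones$template[r])
      k <- as.integer(mz_clones$n_copies[r])
      if (tpl > length(id) || tpl < 1L)
        stop("MZ clone template ", tpl, " not defined")
      new <- length(id) + seq_len(k)
      id <- c(id, new)
      father <- c(father, rep(NA_integer_, k)); mother <- c(mother, rep(NA_integer_, k))
      mz_of <- c(mz_of, rep(tpl, k))
    }
  }
  structure(list(table = data.frame(id = id, father = father, mother = mother,
                                    mz_of = mz_of)),
            class = "pedigree_spec")
}

# resolve an individual to its genetic template (MZ clones share a template)
.ped_template <- function(tab, i) {
  while (!is.na(tab$mz_of[i])) i <- tab$mz_of[i]
  i
}

#' True kinship coefficients of a pedigree
#'
#' Standard recursive kinship computation: phi(a,a) = 1/2 + phi(f_a, m_a)/2,
#' phi(a,b) = (phi(f_a, b) + phi(m_a, b)) / 2 for a not an ancestor of b,
#' founders mutually unrelated and non-inbred. MZ clones inherit their
#' template's coefficients; an MZ pair has phi = 1/2.
#'
#' @param spec a \code{pedigree_spec}.
#' @return n x n numeric kinship matrix.
#' @export
pedigree_kinship <- function(spec) {
  stopifnot(inherits(spec, "pedigree_spec"))
  tab <- spec$table
  n <- nrow(tab)
  phi <- matrix(0, n, n)
  for (a in seq_len(n)) {
    if (!is.na(tab$mz_of[a])) {
      t <- tab$mz_of[a]
      phi[a, seq_len(a - 1L)] <- phi[t, seq_len(a - 1L)]
      phi[seq_len(a - 1L), a] <- phi[a, seq_len(a - 1L)]
      phi[a, a] <- phi[t, t]
    } else if (is.na(tab$father[a])) {
      phi[a, a] <- 0.5
    } else {
      f <- tab$father[a]; m <- tab$mother[a]
      if (a > 1L) {
        b <- seq_len(a - 1L)
        phi[a, b] <- (phi[f, b] + phi[m, b]) / 2
        phi[b, a] <- phi[a, b]
      }
      phi[a, a] <- 0.5 + phi[f, m] / 2
    }
  }
  phi
}

# IBD-sharing probabilities (k0, k1, k2) for a non-inbred pedigree pair.
# For two individuals whose genetic templates both have recorded parents,
# k2 = phi(fa,fb) phi(ma,mb) + phi(fa,mb) phi(ma,fb); if either template is a
# founder, k2 = 0; an MZ pair is (0, 0, 1). Then k1 = 4 phi - 2 k2.
.pair_ibd <- function(tab, phi, a, b) {
  ta <- .ped_template(tab, a); tb <- .ped_template(tab, b)
  if (ta == tb) return(c(k0 = 0, k1 = 0, k2 = 1))
  if (is.na(tab$father[ta]) || is.na(tab$father[tb])) {
    k2 <- 0
  } else {
    fa <- tab$father[ta]; ma <- tab$mother[ta]
    fb <- tab$father[tb]; mb <- tab$mother[tb]
    k2 <- phi[fa, fb] * phi[ma, mb] + phi[fa, mb] * phi[ma, fb]
  }
  k1 <- 4 * phi[a, b] - 2 * k2
  c(k0 = 1 - k1 - k2, k1 = k1, k2 = k2)
}

#' Ground-truth kinship container
#'
#' Stores the related pairs of a simulated cohort (pairs with phi > 0,
#' every unlisted pair having true kinship 0) together with their IBD-sharing
#' probabilities, satisfying phi = k1/4 + k2/2 and k0 + k1 + k2 = 1.
#'
#' @param sample_ids character vector of cohort sample ids.
#' @param pairs data.frame with columns \code{id_a}, \code{id_b}, \code{phi},
#'   \code{k0}, \code{k1}, \code{k2} (related pairs only).
#' @return object of class \code{true_kinship}.
#' @export
true_kinship <- function(sample_ids, pairs) {
  pairs <- as.data.frame(pairs)
  need <- c("id_a", "id_b", "phi", "k0", "k1", "k2")
  if (!all(need %in% names(pairs))) stop("pairs needs columns: ",
                                         paste(need, collapse = ", "))
  if (nrow(pairs)) {
    if (max(abs(pairs$phi - (pairs$k1 / 4 + pairs$k2 / 2))) > 1e-10)
      stop("phi must equal k1/4 + k2/2")
    if (max(abs(pairs$k0 + pairs$k1 + pairs$k2 - 1)) > 1e-10)
      stop("k0 + k1 + k2 must equal 1")
    if (!all(c(pairs$id_a, pairs$id_b) %in% sample_ids))
      stop("pair ids not all present in sample_ids")
  }
  structure(list(sample_ids = as.character(sample_ids), pairs = pairs),
            class = "true_kinship")
}

#' @export
print.true_kinship <- function(x, ...) {
  cat(sprintf("true_kinship: %d samples, %d related pairs\n",
              length(x$sample_ids), nrow(x$pairs)))
  if (nrow(x$pairs))
    print(table(phi = x$pairs$phi))
  invisible(x)
}

#' Dense true kinship matrix
#'
#' @param truth a \code{true_kinship}.
#' @return n x n symmetric matrix with diagonal 0.5 (no inbreeding) and the
#'   listed pair values off-diagonal.
#' @export
as_phi_matrix <- function(truth) {
  stopifnot(inherits(truth, "true_kinship"))
  ids <- truth$sample_ids
  n <- length(ids)
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(phi) <- 0.5
  if (nrow(truth$pairs)) {
    ia <- match(truth$pairs$id_a, ids); ib <- match(truth$pairs$id_b, ids)
    phi[cbind(ia, ib)] <- truth$pairs$phi
    phi[cbind(ib, ia)] <- truth$pairs$phi
  }
  phi
}

#' Write ground-truth kinship to disk
#'
#' Writes the related-pair table (\code{id_a}, \code{id_b}, \code{phi}) to
#' \code{paste0(prefix, ".pairs.tsv")} and the dense square kinship matrix to
#' \code{paste0(prefix, ".matrix.tsv")}.
#'
#' @param truth a \code{true_kinship}.
#' @param prefix output path prefix.
#' @return invisibly, the prefix.
#' @export
write_true_kinship <- function(truth, prefix) {
  stopifnot(inherits(truth, "true_kinship"))
  utils::write.table(truth$pairs[, c("id_a", "id_b", "phi")],
                     paste0(prefix, ".pairs.tsv"), quote = FALSE,
                     row.names = FALSE, sep = "\t")
  phi <- as_phi_matrix(truth)
  df <- data.frame(id = rownames(phi), phi, check.names = FALSE)
  utils::write.table(df, paste0(prefix, ".matrix.tsv"), quote = FALSE,
                     row.names = FALSE, sep = "\t")
  invisible(prefix)
}

#' Gene-drop genotypes through a pedigree
#'
#' Founders receive two haplotypes with per-SNP reference-allele probability
#' equal to the SNP frequency (Hardy-Weinberg, linkage equilibrium). Each
#' offspring inherits, independently per SNP, one uniformly chosen haplotype
#' from each parent (Mendelian transmission without linkage). MZ clones copy
#' their template's genotypes exactly.
#'
#' @param spec a \code{pedigree_spec}.
#' @param m number of SNPs.
#' @param maf_low,maf_high bounds of the uniform distribution the per-SNP
#'   minor allele frequencies are drawn from.
#' @param seed optional integer seed.
#' @param maf optional length-m vector of allele frequencies, overriding the
#'   uniform draw (used to share frequencies across pedigrees).
#' @return list with \code{genotypes} (a \code{genotype_matrix}, all pedigree
#'   members), \code{truth} (a \code{true_kinship} over all pairs with
#'   phi > 0), \code{phi} (full true kinship matrix), \code{maf}.
#' @export
drop_pedigree <- function(spec, m, maf_low = 0.05, maf_high = 0.5,
                          seed = NULL, maf = NULL) {
  stopifnot(inherits(spec, "pedigree_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(maf)) {
    if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5))
      stop("need 0 < maf_low <= maf_high <= 0.5")
    maf <- stats::runif(m, maf_low, maf_high)
  }
  tab <- spec$table
  n <- nrow(tab)
  h1 <- matrix(0L, n, m); h2 <- matrix(0L, n, m)
  for (a in seq_len(n)) {
    if (!is.na(tab$mz_of[a])) {
      t <- tab$mz_of[a]
      h1[a, ] <- h1[t, ]; h2[a, ] <- h2[t, ]
    } else if (is.na(tab$father[a])) {
      h1[a, ] <- stats::rbinom(m, 1L, maf)
      h2[a, ] <- stats::rbinom(m, 1L, maf)
    } else {
      f <- tab$father[a]; mo <- tab$mother[a]
      sf <- stats::runif(m) < 0.5
      sm <- stats::runif(m) < 0.5
      h1[a, ] <- ifelse(sf, h1[f, ], h2[f, ])
      h2[a, ] <- ifelse(sm, h1[mo, ], h2[mo, ])
    }
  }
  ids <- paste0("P", tab$id)
  G <- genotype_matrix(h1 + h2, sample_ids = ids)
  phi <- pedigree_kinship(spec)
  dimnames(phi) <- list(ids, ids)
  pr <- which(upper.tri(phi) & phi > 0, arr.ind = TRUE)
  pairs <- if (nrow(pr)) {
    ks <- t(apply(pr, 1L, function(z) .pair_ibd(tab, phi, z[1], z[2])))
    data.frame(id_a = ids[pr[, 1]], id_b = ids[pr[, 2]],
               phi = phi[pr], k0 = ks[, 1], k1 = ks[, 2], k2 = ks[, 3],
               stringsAsFactors = FALSE)
  } else {
    data.frame(id_a = character(), id_b = character(), phi = numeric(),
               k0 = numeric(), k1 = numeric(), k2 = numeric())
  }
  list(genotypes = G, truth = true_kinship(ids, pairs), phi = phi, maf = maf)
}
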