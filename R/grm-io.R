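#' Write a kinship matrix as a square text file
#'
#' Tab-separated square matrix with sample ids as header row and first
#' column, phi scale.
#'
#' @param K a \code{kinship_matrix}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_kinship_matrix <- function(K, path) {
  stopifnot(inherits(K, "kinship_matrix"))
  df <- data.frame(id = K$sample_ids, K$phi, check.names = FALSE)
  colnames(df) <- c("id", K$sample_ids)
  utils::write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read a square kinship matrix text file
#'
#' @param path file written by \code{\link{write_kinship_matrix}}.
#' @param estimator tag to attach (the file does not store it).
#' @return a \code{kinship_matrix}.
#' @export
read_kinship_matrix <- function(path, estimator = "unknown") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, row.names = 1L)
  kinship_matrix(as.matrix(tab), estimator, sample_ids = rownames(tab))
}

#' Write a GCTA-style lower-triangle GRM text file
#'
#' Writes \code{prefix.grm} (columns: index i, index j <= i, SNP count,
#' relationship value on the GRM scale 2 phi) and \code{prefix.grm.id}
#' (family and individual id). This mirrors the plain-text GRM layout used
#' by GCTA's \code{--make-grm-gz} output.
#'
#' @param K a \code{kinship_matrix}.
#' @param prefix output path prefix.
#' @return invisibly, the prefix.
#' @export
write_grm_gcta <- function(K, prefix) {
  stopifnot(inherits(K, "kinship_matrix"))
  n <- nrow(K$phi)
  idx <- which(lower.tri(K$phi, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  grm <- data.frame(i = idx[, 1], j = idx[, 2],
                    m = ifelse(is.na(K$m), 0L, K$m),
                    value = 2 * K$phi[idx])
  utils::write.table(grm, paste0(prefix, ".grm"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  utils::write.table(data.frame(K$sample_ids, K$sample_ids),
                     paste0(prefix, ".grm.id"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(prefix)
}

#' Read a GCTA-style lower-triangle GRM text file
#'
#' @param prefix path prefix (expects \code{prefix.grm},
#'   \code{prefix.grm.id}).
#' @param estimator tag to attach.
#' @return a \code{kinship_matrix} (phi scale, i.e. GRM values halved).
#' @export
read_grm_gcta <- function(prefix, estimator = "unknown") {
  grm <- utils::read.table(paste0(prefix, ".grm"), header = FALSE)
  ids <- utils::read.table(paste0(prefix, ".grm.id"), header = FALSE,
                           colClasses = "character")[[2]]
  n <- length(ids)
  phi <- matrix(0, n, n)
  phi[cbind(grm[[1]], grm[[2]])] <- grm[[4]] / 2
  phi[cbind(grm[[2]], grm[[1]])] <- grm[[4]] / 2
  kinship_matrix(phi, estimator, sample_ids = ids,
                 m = if (nrow(grm)) grm[[3]][1] else NA_integer_)
}
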