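#' Load genotypes from disk
#'
#' Reads biallelic SNP dosages from PLINK text (.ped/.map), PLINK binary
#' (.bed/.bim/.fam, SNP-major) or a plain tab-separated dosage table (header
#' row of SNP ids, first column of sample ids, entries 0/1/2 or NA). Missing
#' genotypes are flagged as \code{NA} in the dosage matrix.
#'
#' @param path file prefix (PLINK formats) or file path (dosage table).
#' @param format one of \code{"ped_map"}, \code{"bed_bim_fam"},
#'   \code{"dosage_table"}.
#' @param ref_alleles optional character vector naming the counted (reference)
#'   allele per SNP for \code{"ped_map"}; by default the first non-missing
#'   allele code encountered per SNP in file order is counted.
#' @return a \code{genotype_matrix}.
#' @export
load_genotypes <- function(path, format = c("ped_map", "bed_bim_fam",
                                            "dosage_table"),
                           ref_alleles = NULL) {
  format <- match.arg(format)
  switch(format,
         ped_map = read_plink_ped(path, ref_alleles = ref_alleles),
         bed_bim_fam = read_plink_bed(path),
         dosage_table = read_dosage_table(path))
}

#' Read PLINK .ped/.map text files
#'
#' @param prefix path prefix; \code{prefix.ped} and \code{prefix.map} must
#'   exist.
#' @param ref_alleles optional counted allele per SNP (in .map order).
#' @return a \code{genotype_matrix}. The missing code is \code{"0"}.
#' @export
read_plink_ped <- function(prefix, ref_alleles = NULL) {
  ped_file <- paste0(prefix, ".ped"); map_file <- paste0(prefix, ".map")
  if (!file.exists(ped_file)) stop("missing file: ", ped_file)
  if (!file.exists(map_file)) stop("missing file: ", map_file)
  map <- utils::read.table(map_file, header = FALSE,
                           colClasses = "character")
  if (ncol(map) < 4L) stop("malformed .map: expected 4 columns")
  snp_ids <- map[[2]]
  m <- nrow(map)
  lines <- readLines(ped_file)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  n <- length(toks)
  if (n == 0L) stop("empty .ped file")
  width <- 6L + 2L * m
  bad <- which(lengths(toks) != width)
  if (length(bad))
    stop("dimension mismatch: .ped line ", bad[1], " has ", lengths(toks)[bad[1]],
         " fields, expected ", width, " for ", m, " SNPs")
  tok <- matrix(unlist(toks), nrow = n, byrow = TRUE)
  sample_ids <- tok[, 2]
  a1 <- tok[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- tok[, 6L + 2L * seq_len(m), drop = FALSE]
  half <- xor(a1 == "0", a2 == "0")
  if (any(half)) stop("half-missing genotype (single \"0\" allele) in .ped")
  dos <- matrix(NA_integer_, n, m)
  ref <- character(m); alt <- character(m)
  for (j in seq_len(m)) {
    c1 <- a1[, j]; c2 <- a2[, j]
    obs <- c1 != "0"
    codes <- unique(c(rbind(c1[obs], c2[obs])))  # file-order interleave
    if (length(codes) > 2L)
      stop("SNP ", snp_ids[j], " has more than two allele codes: ",
           paste(codes, collapse = ", "))
    rj <- if (!is.null(ref_alleles)) ref_alleles[j]
          else if (length(codes)) codes[1] else "A"
    aj <- setdiff(codes, rj)
    if (length(aj) > 1L)
      stop("SNP ", snp_ids[j], ": allele codes ", paste(codes, collapse = ","),
           " do not match the declared reference allele ", rj)
    if (length(aj) == 0L) aj <- "0"
    dos[obs, j] <- (c1[obs] == rj) + (c2[obs] == rj)
    ref[j] <- rj; alt[j] <- aj[1]
  }
  genotype_matrix(dos, sample_ids = sample_ids, snp_ids = snp_ids,
                  ref = ref, alt = alt)
}

#' Write PLINK .ped/.map text files
#'
#' @param G a \code{genotype_matrix}.
#' @param prefix output path prefix.
#' @return invisibly, the prefix.
#' @export
write_plink_ped <- function(G, prefix) {
  stopifnot(inherits(G, "genotype_matrix"))
  X <- G$dosages; n <- nrow(X); m <- ncol(X)
  map <- data.frame(chr = 1L, snp = G$snp_ids, cm = 0L, bp = seq_len(m))
  utils::write.table(map, paste0(prefix, ".map"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  out <- file(paste0(prefix, ".ped"), "w")
  on.exit(close(out))
  for (i in seq_len(n)) {
    g <- X[i, ]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, G$ref, G$alt))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2L, G$ref, G$alt))
    writeLines(paste(c(G$sample_ids[i], G$sample_ids[i], "0", "0", "0", "-9",
                       as.vector(rbind(a1, a2))), collapse = " "), out)
  }
  invisible(prefix)
}

# PLINK 1 .bed 2-bit codes, SNP-major: 00 = 2 copies of A1, 10 = het,
# 11 = 0 copies of A1, 01 = missing. A1 is taken as the reference allele.
.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

#' Read PLINK binary .bed/.bim/.fam files
#'
#' @param prefix path prefix; \code{prefix.bed}, \code{prefix.bim} and
#'   \code{prefix.fam} must exist. The .bed must be SNP-major (magic bytes
#'   0x6C 0x1B 0x01).
#' @return a \code{genotype_matrix} whose dosage counts the A1 allele of the
#'   .bim file.
#' @export
read_plink_bed <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f)
  bimt <- utils::read.table(bim, header = FALSE, colClasses = "character")
  famt <- utils::read.table(fam, header = FALSE, colClasses = "character")
  m <- nrow(bimt); n <- nrow(famt)
  snp_ids <- bimt[[2]]; sample_ids <- famt[[2]]
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || !identical(raw[1:3], .bed_magic))
    stop("malformed .bed: bad magic bytes (expected 6c 1b 01)")
  bps <- ceiling(n / 4)                   # bytes per SNP
  body <- raw[-(1:3)]
  if (length(body) != bps * m)
    stop("dimension mismatch: .bed has ", length(body), " data bytes, ",
         "expected ", bps * m, " for ", n, " samples x ", m, " SNPs")
  # unpack all 2-bit codes at once
  byte_mat <- matrix(as.integer(body), nrow = bps, ncol = m)
  codes <- matrix(0L, nrow = 4L * bps, ncol = m)
  for (k in 0:3)
    codes[seq.int(k + 1L, by = 4L, length.out = bps), ] <-
      byte_mat %/% (4L^k) %% 4L
  codes <- codes[seq_len(n), , drop = FALSE]
  dos <- matrix(NA_integer_, n, m)
  dos[codes == 0L] <- 2L
  dos[codes == 2L] <- 1L
  dos[codes == 3L] <- 0L                  # code 1 stays NA (missing)
  genotype_matrix(dos, sample_ids = sample_ids, snp_ids = snp_ids,
                  ref = bimt[[5]], alt = bimt[[6]])
}

#' Write PLINK binary .bed/.bim/.fam files
#'
#' @param G a \code{genotype_matrix}.
#' @param prefix output path prefix.
#' @return invisibly, the prefix.
#' @export
write_plink_bed <- function(G, prefix) {
  stopifnot(inherits(G, "genotype_matrix"))
  X <- G$dosages; n <- nrow(X); m <- ncol(X)
  bim <- data.frame(chr = 1L, snp = G$snp_ids, cm = 0L, bp = seq_len(m),
                    a1 = G$ref, a2 = G$alt)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  fam <- data.frame(fid = G$sample_ids, iid = G$sample_ids, pat = 0L,
                    mat = 0L, sex = 0L, pheno = -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  codes <- matrix(1L, n, m)               # default missing (01)
  codes[!is.na(X) & X == 2L] <- 0L
  codes[!is.na(X) & X == 1L] <- 2L
  codes[!is.na(X) & X == 0L] <- 3L
  bps <- ceiling(n / 4)
  padded <- matrix(0L, 4L * bps, m)
  padded[seq_len(n), ] <- codes
  bytes <- matrix(0L, bps, m)
  for (k in 0:3)
    bytes <- bytes + padded[seq.int(k + 1L, by = 4L, length.out = bps), ,
                            drop = FALSE] * 4L^k
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}

#' Read a tab-separated dosage table
#'
#' Header row of SNP ids, first column of sample ids, entries 0/1/2 or NA.
#'
#' @param path file path.
#' @return a \code{genotype_matrix}.
#' @export
read_dosage_table <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, row.names = 1L)
  genotype_matrix(as.matrix(tab), sample_ids = rownames(tab),
                  snp_ids = colnames(tab))
}

#' Write a tab-separated dosage table
#'
#' @param G a \code{genotype_matrix}.
#' @param path file path.
#' @return invisibly, the path.
#' @export
write_dosage_table <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  df <- data.frame(id = G$sample_ids, G$dosages, check.names = FALSE)
  colnames(df) <- c("id", G$snp_ids)
  utils::write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
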