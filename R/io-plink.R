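## Minimal PLINK 1 bed/bim/fam reader (and a writer used to build test
## fixtures in code). The bed format is SNP-major: a 3-byte magic header
## (0x6c 0x1b 0x01) then, per variant, ceil(N/4) bytes of 2-bit codes,
## sample-major within the byte from the lowest bits:
## 00 = hom A1, 01 = missing, 10 = het, 11 = hom A2.
## No R package in this stack reads PLINK bed, hence the in-package reader.

#' Read PLINK bed/bim/fam genotypes
#'
#' Dosages count the A1 (minor, by PLINK convention) allele, mapped here to
#' the ALT column so downstream code sees counted-allele frequencies.
#' Missing genotypes are not supported (hard-call pipelines only).
#'
#' @param prefix path prefix; `prefix.bed`, `prefix.bim`, `prefix.fam` must
#'   exist
#' @return a [genotype_matrix()]
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  fam <- utils::read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3L + m * ceiling(n / 4))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stopf("%s.bed: not a PLINK bed file", prefix)
  if (raw[3] != as.raw(0x01))
    stopf("%s.bed: only SNP-major bed files are supported", prefix)
  body <- raw[-(1:3)]
  bpv <- ceiling(n / 4)
  ## decode 2-bit fields: codes 0,1,2,3 -> dosage of A1: 2, NA, 1, 0.
  ## samples fill each byte from the lowest bits, so interleave the four
  ## shifts before trimming the padding rows
  lut <- c(2L, NA_integer_, 1L, 0L)
  ints <- as.integer(body)
  dim(ints) <- c(bpv, m)
  codes <- array(0L, c(4L, bpv, m))
  codes[1, , ] <- ints %% 4L
  codes[2, , ] <- (ints %/% 4L) %% 4L
  codes[3, , ] <- (ints %/% 16L) %% 4L
  codes[4, , ] <- (ints %/% 64L) %% 4L
  dim(codes) <- c(4L * bpv, m)
  X <- matrix(lut[codes[seq_len(n), , drop = FALSE] + 1L], n, m)
  if (anyNA(X)) stopf("%s.bed contains missing genotypes", prefix)
  map <- data.frame(chrom = bim$chrom, pos = bim$pos, ref = bim$a2,
                    alt = bim$a1, id = bim$id, stringsAsFactors = FALSE)
  genotype_matrix(X, map, as.character(fam[[2]]))
}

#' Write PLINK bed/bim/fam (fixture helper)
#'
#' @param G a [genotype_matrix()]; dosages are written as A1 counts
#' @param prefix output path prefix
#' @return `prefix`, invisibly
#' @export
write_plink <- function(G, prefix) {
  n <- nrow(G$X); m <- ncol(G$X)
  bim <- data.frame(G$map$chrom, G$map$id, 0L, G$map$pos, G$map$alt, G$map$ref)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(G$sample_ids, G$sample_ids, 0L, 0L, 0L, -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  code <- c(`0` = 3L, `1` = 2L, `2` = 0L)   # dosage of A1 -> 2-bit code
  bpv <- ceiling(n / 4)
  out <- raw(3 + m * bpv)
  out[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
  pos <- 4L
  for (j in seq_len(m)) {
    cj <- code[as.character(G$X[, j])]
    cj <- c(cj, rep(0L, 4 * bpv - n))
    dim(cj) <- c(4, bpv)
    byte <- cj[1, ] + 4L * cj[2, ] + 16L * cj[3, ] + 64L * cj[4, ]
    out[pos:(pos + bpv - 1L)] <- as.raw(byte)
    pos <- pos + bpv
  }
  writeBin(out, paste0(prefix, ".bed"))
  invisible(prefix)
}
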