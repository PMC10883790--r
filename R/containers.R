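## Core data containers. Lightweight S3: a dosage matrix with a variant map,
## and a phased haplotype panel. Both keep 1-based bp positions (VCF
## convention) in their maps; interval work elsewhere converts to 0-based
## half-open internally.

#' Construct a genotype matrix
#'
#' Bundles a samples x variants dosage matrix (counts of the alternate
#' allele, 0/1/2) with its variant map. Allele frequencies are always
#' recomputed from the matrix so the stored `p` can never drift out of sync.
#'
#' @param X integer matrix, samples in rows, variants in columns, entries
#'   in \{0,1,2\}
#' @param map data.frame with columns `chrom`, `pos` (1-based bp), `ref`,
#'   `alt`; one row per column of `X`
#' @param sample_ids character vector of row ids (defaults to rownames)
#' @return object of class `genotype_matrix`: list with `X`, `map`
#'   (augmented with `p`, the alt-allele frequency, and `maf`), `sample_ids`
#' @export
genotype_matrix <- function(X, map, sample_ids = rownames(X)) {
  X <- as.matrix(X)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(X)))
  stopifnot(ncol(X) == nrow(map), length(sample_ids) == nrow(X))
  if (!all(X %in% c(0L, 1L, 2L)))
    stopf("dosages must be hard calls in {0,1,2}; fractional dosages are not supported")
  storage.mode(X) <- "integer"
  map <- as.data.frame(map)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(map)))
  key <- paste(map$chrom, map$pos, map$alt, sep = ":")
  if (anyDuplicated(key)) stopf("duplicated (chrom,pos,alt) variant keys")
  if (is.null(map$id)) map$id <- paste(map$chrom, map$pos, sep = ":")
  map$p <- colMeans(X) / 2
  map$maf <- pmin(map$p, 1 - map$p)
  rownames(X) <- sample_ids
  structure(list(X = X, map = map, sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants, %d chromosome(s)\n",
              nrow(x$X), ncol(x$X), length(unique(x$map$chrom))))
  invisible(x)
}

#' Filter a genotype matrix on minor allele frequency
#'
#' @param G a [genotype_matrix()]
#' @param maf_min sites with MAF <= `maf_min` are dropped (the retained set
#'   satisfies MAF > `maf_min`, matching the usual "MAF > 0.01" phrasing)
#' @return filtered `genotype_matrix`
#' @export
filter_maf <- function(G, maf_min) {
  keep <- G$map$maf > maf_min
  if (!any(keep)) stopf("no variants left after MAF > %g filter", maf_min)
  genotype_matrix(G$X[, keep, drop = FALSE], G$map[keep, , drop = FALSE],
                  G$sample_ids)
}

#' Construct a phased haplotype panel
#'
#' Rows are haplotypes (two consecutive rows per sample), columns are sites.
#' Alleles are 0/1; when `polarized` is TRUE, 0 is ancestral and 1 derived,
#' otherwise 0 is REF and 1 ALT.
#'
#' @param H integer matrix of 0/1 alleles, 2N rows (haplotypes) x M columns
#' @param map variant map as in [genotype_matrix()]
#' @param sample_ids N sample ids; haplotype rows 2i-1, 2i belong to sample i
#' @param polarized logical; TRUE when 0/1 are ancestral/derived
#' @return object of class `haplotype_set`
#' @export
haplotype_set <- function(H, map, sample_ids = NULL, polarized = FALSE) {
  H <- as.matrix(H)
  stopifnot(nrow(H) %% 2L == 0L, all(H %in% c(0L, 1L)))
  storage.mode(H) <- "integer"
  n <- nrow(H) / 2L
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  stopifnot(length(sample_ids) == n, ncol(H) == nrow(map))
  map <- as.data.frame(map)
  if (is.null(map$id)) map$id <- paste(map$chrom, map$pos, sep = ":")
  map$p <- colMeans(H)  # derived (or ALT) allele frequency among haplotypes
  map$maf <- pmin(map$p, 1 - map$p)
  structure(list(H = H, map = map, sample_ids = sample_ids,
                 polarized = isTRUE(polarized)),
            class = "haplotype_set")
}

#' @exportS3Method base::print
print.haplotype_set <- function(x, ...) {
  cat(sprintf("<haplotype_set> %d haplotypes (%d samples) x %d sites, %s\n",
              nrow(x$H), length(x$sample_ids), ncol(x$H),
              if (x$polarized) "polarized (0=ancestral)" else "unpolarized (0=REF)"))
  invisible(x)
}

#' Collapse a haplotype panel to dosages
#'
#' @param H a [haplotype_set()]
#' @return a [genotype_matrix()] of alt/derived allele counts per sample
#' @export
haplotypes_to_dosage <- function(H) {
  odd <- seq(1L, nrow(H$H), by = 2L)
  X <- H$H[odd, , drop = FALSE] + H$H[odd + 1L, , drop = FALSE]
  genotype_matrix(X, H$map[c("chrom", "pos", "ref", "alt", "id")],
                  H$sample_ids)
}

#' Subset a haplotype panel to one chromosome
#' @param H a [haplotype_set()]
#' @param chrom chromosome label
#' @return `haplotype_set` restricted to `chrom`
#' @export
subset_chrom <- function(H, chrom) {
  keep <- H$map$chrom == chrom
  haplotype_set(H$H[, keep, drop = FALSE], H$map[keep, , drop = FALSE],
                H$sample_ids, H$polarized)
}
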