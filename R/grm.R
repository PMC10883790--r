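## Genomic relationship matrix (VanRaden/Yang form) and its spectral
## representation. GREML and the mixed-model scan never invert V = A*sg2 +
## I*se2 directly: they work in the eigenbasis of A, where V is diagonal.
## When the GRM is built from fewer markers than samples its rank is at most
## the marker count, and a thin SVD of the standardized genotype matrix
## gives the same spectrum far cheaper than an N x N eigendecomposition;
## the zero-eigenvalue complement is handled analytically.

#' Compute a genomic relationship matrix
#'
#' Yang et al. form: `A_jk = (1/m) sum_i (x_ij - 2p_i)(x_ik - 2p_i) /
#' (2 p_i (1-p_i))`, with `p_i` the alt-allele frequency from the supplied
#' matrix. Sites failing the MAF filter (which removes monomorphic sites)
#' are excluded and counted.
#'
#' @param G a [genotype_matrix()]
#' @param maf_min MAF filter; only SNPs with MAF > `maf_min` enter the GRM
#' @return object of class `grm`: list with `A` (N x N), `m` (markers used),
#'   `ids`, `n_excluded`
#' @export
compute_grm <- function(G, maf_min = 0.01) {
  keep <- G$map$maf > maf_min
  n_excl <- sum(!keep)
  if (!any(keep)) stopf("all SNPs excluded by MAF > %g filter", maf_min)
  Z <- grm_standardize(G$X[, keep, drop = FALSE])
  m <- ncol(Z)
  A <- tcrossprod(Z) / m
  structure(list(A = A, m = m, ids = G$sample_ids, n_excluded = n_excl),
            class = "grm")
}

## Center by 2p and scale by sqrt(2pq); assumes polymorphic columns.
grm_standardize <- function(X) {
  p <- colMeans(X) / 2
  sweep(sweep(X, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), `/`)
}

#' @exportS3Method base::print
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d samples, %d markers (%d excluded by MAF filter)\n",
              length(x$ids), x$m, x$n_excluded))
  invisible(x)
}

#' Spectral representation of a GRM
#'
#' Returns the eigenpairs of `A` in the form used by [greml()] and
#' [mlma_scan()]. From a `grm` this is a dense symmetric eigendecomposition
#' (negative eigenvalues from numerical noise are floored at zero, with the
#' repair magnitude recorded); from a `genotype_matrix` it is a thin SVD of
#' the standardized markers, which is much cheaper when markers < samples.
#'
#' @param x a `grm` or a [genotype_matrix()]
#' @param maf_min MAF filter (genotype-matrix method only)
#' @return object of class `grm_spectrum`: `U` (N x r eigenvectors for the
#'   nonzero part of the spectrum), `d` (eigenvalues), `N`, `r`, `ids`,
#'   `floor_applied`
#' @export
grm_spectrum <- function(x, maf_min = 0.01) UseMethod("grm_spectrum")

#' @export
grm_spectrum.grm <- function(x, maf_min = 0.01) {
  e <- eigen(x$A, symmetric = TRUE)
  floor_applied <- max(0, -min(e$values))
  d <- pmax(e$values, 0)
  structure(list(U = e$vectors, d = d, N = nrow(x$A), r = length(d),
                 ids = x$ids, floor_applied = floor_applied),
            class = "grm_spectrum")
}

#' @export
grm_spectrum.genotype_matrix <- function(x, maf_min = 0.01) {
  keep <- x$map$maf > maf_min
  if (!any(keep)) stopf("all SNPs excluded by MAF > %g filter", maf_min)
  Z <- grm_standardize(x$X[, keep, drop = FALSE])
  m <- ncol(Z)
  if (m >= nrow(Z)) {
    ## full-rank case: the N x N eigenproblem is the cheaper route
    e <- eigen(tcrossprod(Z) / m, symmetric = TRUE)
    floor_applied <- max(0, -min(e$values))
    return(structure(list(U = e$vectors, d = pmax(e$values, 0), N = nrow(Z),
                          r = nrow(Z), ids = x$sample_ids,
                          floor_applied = floor_applied),
                     class = "grm_spectrum"))
  }
  s <- svd(Z, nu = min(dim(Z)), nv = 0)
  structure(list(U = s$u, d = s$d^2 / m, N = nrow(Z), r = length(s$d),
                 ids = x$sample_ids, floor_applied = 0),
            class = "grm_spectrum")
}

#' @export
grm_spectrum.grm_spectrum <- function(x, maf_min = 0.01) x

#' Persist / load a GRM (lower triangle + ids)
#'
#' Plain-text layout: `prefix.grm.ids` holds one sample id per line;
#' `prefix.grm.txt` holds the row-wise lower triangle (including the
#' diagonal), one value per line, full precision.
#'
#' @param grm a `grm`
#' @param prefix output path prefix
#' @return `prefix` invisibly (`write_grm`); a `grm` (`read_grm`)
#' @export
write_grm <- function(grm, prefix) {
  writeLines(grm$ids, paste0(prefix, ".grm.ids"))
  lt <- grm$A[lower.tri(grm$A, diag = TRUE)]
  writeLines(c(sprintf("# m=%d", grm$m), format(lt, digits = 17)),
             paste0(prefix, ".grm.txt"))
  invisible(prefix)
}

#' @rdname write_grm
#' @export
read_grm <- function(prefix) {
  ids <- readLines(paste0(prefix, ".grm.ids"))
  lines <- readLines(paste0(prefix, ".grm.txt"))
  m <- as.integer(sub("# m=", "", lines[1]))
  lt <- as.numeric(lines[-1])
  n <- length(ids)
  A <- matrix(0, n, n)
  A[lower.tri(A, diag = TRUE)] <- lt
  A <- A + t(A) - diag(diag(A))
  structure(list(A = A, m = m, ids = ids, n_excluded = NA_integer_),
            class = "grm")
}
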