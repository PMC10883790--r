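## Per-SNP mixed linear model association (the GPSM scan). Variance
## components are estimated once under the null and held fixed; each SNP is
## then a one-parameter generalized least squares fit under
## V = A sg2 + I se2, solved for all SNPs at once in the eigenbasis of A.

#' Mixed-model association scan of genotype on the generation proxy
#'
#' For each SNP fits `y = mu + b x + a + e` by GLS with `V = A sigma_g^2 +
#' I sigma_e^2` fixed at the [greml()] estimates:
#' `b_hat = x'Py / x'Px` with `P` the REML projection, `SE = (x'Px)^{-1/2}`,
#' and a two-sided Wald chi-square (1 df) p-value. The factorization of `V`
#' is computed once and reused across SNPs. Because the proxy counts years
#' *before* the reference date, an allele rising over calendar time gets a
#' negative `b`.
#'
#' Test SNPs may be a superset of the SNPs used to build the GRM.
#' Monomorphic test SNPs get `b = 0`, `p = 1` and a flag. With
#' `sigma_g2 = 0` the scan reduces exactly to ordinary least squares.
#'
#' @param G [genotype_matrix()] of test SNPs
#' @param y [make_generation_proxy()] object (raw or Box-Cox) or numeric
#' @param K `grm`, `grm_spectrum`, or genotype matrix for the GRM
#' @param vc converged [greml()] estimates for the same `y` and `K`
#' @param covariates optional fixed-effect covariates
#' @return data.frame of association records: `chrom`, `pos`, `id`, `ref`,
#'   `alt`, `p_freq` (alt-allele frequency), `b`, `se`, `p`, `monomorphic`
#' @export
mlma_scan <- function(G, y, K, vc, covariates = NULL) {
  if (inherits(y, "generation_proxy")) y <- y$y
  y <- as.numeric(y)
  if (!isTRUE(vc$converged)) stopf("variance components did not converge; refusing scan")
  spec <- grm_spectrum(K)
  N <- spec$N
  stopifnot(length(y) == N, nrow(G$X) == N)
  X <- cbind(`(Intercept)` = rep(1, N))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  ws <- vc_workspace(y, spec, X)
  tm <- vc_terms(ws, vc$sigma_g2, vc$sigma_e2)
  Py <- p_apply(ws, tm, vc$sigma_e2, y)

  S <- G$X
  storage.mode(S) <- "double"
  mono <- G$map$maf == 0
  se2 <- vc$sigma_e2
  Sstar <- crossprod(spec$U, S)                      # r x m
  ViS <- S / se2 + spec$U %*% (Sstar * (1 / tm$v - 1 / se2))
  xVix <- colSums(S * ViS)
  C <- crossprod(X, ViS)                             # q x m
  xPx <- xVix - colSums(C * (tm$M %*% C))
  xPy <- as.numeric(crossprod(S, Py))
  b <- ifelse(xPx > 0, xPy / xPx, 0)
  se <- ifelse(xPx > 0, sqrt(1 / xPx), NA_real_)
  chi <- ifelse(xPx > 0, xPy^2 / xPx, 0)
  p <- pchisq(chi, df = 1, lower.tail = FALSE)
  b[mono] <- 0; se[mono] <- NA_real_; p[mono] <- 1
  data.frame(chrom = G$map$chrom, pos = G$map$pos, id = G$map$id,
             ref = G$map$ref, alt = G$map$alt, p_freq = G$map$p,
             b = b, se = se, p = p, monomorphic = mono,
             stringsAsFactors = FALSE)
}

#' Significance-threshold ladder
#'
#' Applies the standard ladder of genome-wide thresholds to a scan:
#' nominal `p < 1e-5`, Bonferroni `p < alpha/m`, genome-wide `p < 5e-8`,
#' and Benjamini-Hochberg FDR `q < 0.1` and `q < 0.05`. All inequalities
#' are strict. BH is applied across the whole analysis run.
#'
#' @param records association records from [mlma_scan()]
#' @param m_tests effective number of tests for Bonferroni and BH
#'   (defaults to `nrow(records)`)
#' @param alpha family-wise error rate for Bonferroni
#' @param nominal,genomewide fixed p-value thresholds
#' @return `records` with added `q` and logical flag columns `nominal`,
#'   `bonferroni`, `genomewide`, `fdr10`, `fdr05`; attribute
#'   `threshold_summary` holds the per-flag counts
#' @export
threshold_ladder <- function(records, m_tests = nrow(records), alpha = 0.05,
                             nominal = 1e-5, genomewide = 5e-8) {
  stopifnot(all(records$p > 0 & records$p <= 1))
  records$q <- p.adjust(records$p, method = "BH", n = max(m_tests, nrow(records)))
  records$nominal <- records$p < nominal
  records$bonferroni <- records$p < alpha / m_tests
  records$genomewide <- records$p < genomewide
  records$fdr10 <- records$q < 0.1
  records$fdr05 <- records$q < 0.05
  attr(records, "threshold_summary") <- c(
    nominal = sum(records$nominal), bonferroni = sum(records$bonferroni),
    genomewide = sum(records$genomewide), fdr10 = sum(records$fdr10),
    fdr05 = sum(records$fdr05))
  records
}
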