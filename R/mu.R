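## Composite sweep statistic mu in fixed-SNP-count sliding windows.
## Each window multiplies three sweep signatures:
##   mu_VAR -- local diversity reduction: a swept region has few segregating
##             sites, so the bp span of a 50-SNP window is long;
##   mu_SFS -- site-frequency-spectrum shift: excess singletons and
##             high-frequency derived sites flanking a completed sweep;
##   mu_LD  -- LD pattern: high LD within each flank of the swept site but
##             low LD across it.
## Exact factor constants only rescale the statistic monotonically and the
## outlier call is a rank quantile, so the outlier set is invariant to
## them; the factor forms below are this package's definition.

#' Composite sweep scan (mu statistic) in sliding windows
#'
#' Windows slide one SNP at a time; each window of `window_snps` SNPs gets
#' \deqn{\mu = \mu_{VAR} \cdot \mu_{SFS} \cdot \mu_{LD}} assigned to its
#' central SNP position. Sites are used unfiltered (biallelic restriction
#' only) to preserve the full site frequency spectrum. On polarized panels
#' the SFS factor counts singletons and sites at derived count `n-1`; on
#' unpolarized (folded) panels it counts minor-count-1 sites at half
#' weight.
#'
#' @param H a [haplotype_set()]
#' @param window_snps SNPs per window
#' @param chrom_length chromosome length in bp used to normalize the span
#'   factor (defaults to the maximum SNP position per chromosome)
#' @param ld_eps stabilizer added to the cross-flank mean r^2
#' @param ld_cap cap on `mu_LD` when cross-flank LD vanishes
#' @return list with `windows` (data.frame: `chrom`, `start`, `end`,
#'   `center`, `n_snps`, `stat` = mu, `source = "mu"`) and `factors`
#'   (data.frame: `span`, `mu_var`, `mu_sfs`, `mu_ld`, `mu`)
#' @export
mu_scan <- function(H, window_snps = 50L, chrom_length = NULL,
                    ld_eps = 1e-6, ld_cap = 1e6) {
  stopifnot(inherits(H, "haplotype_set"), window_snps >= 4L)
  n <- nrow(H$H)
  half <- window_snps %/% 2L
  wins <- list(); facs <- list()
  for (ch in unique(H$map$chrom)) {
    Hc <- subset_chrom(H, ch)
    ord <- order(Hc$map$pos)
    Hm <- Hc$H[, ord, drop = FALSE]
    pos <- Hc$map$pos[ord]
    ## only sites segregating in the sample: a monomorphic column is not a
    ## variant, and the span of SNP-count windows over a swept (fixed)
    ## region is exactly the diversity-reduction signal mu_VAR measures
    seg_keep <- colSums(Hm) > 0L & colSums(Hm) < nrow(Hm)
    Hm <- Hm[, seg_keep, drop = FALSE]
    pos <- pos[seg_keep]
    M <- ncol(Hm)
    if (M < window_snps)
      stopf("chromosome %s has %d SNPs, fewer than window_snps=%d",
            ch, M, window_snps)
    clen <- chrom_length %||% max(pos)
    cnt <- colSums(Hm)
    nw <- M - window_snps + 1L
    span <- pos[window_snps:M] - pos[seq_len(nw)]
    mu_var <- (span / clen) / window_snps
    ## SFS factor via running counts
    if (H$polarized) {
      extreme <- as.numeric(cnt == 1L | cnt == n - 1L)
      wt <- 1
    } else {
      extreme <- as.numeric(pmin(cnt, n - cnt) == 1L & cnt > 0L & cnt < n)
      wt <- 0.5
    }
    cs <- c(0, cumsum(extreme))
    mu_sfs <- wt * (cs[window_snps + seq_len(nw)] - cs[seq_len(nw)]) / window_snps
    ## LD factor per window
    i1 <- seq_len(half)
    i2 <- (half + 1L):window_snps
    mu_ld <- numeric(nw)
    Hd <- Hm
    storage.mode(Hd) <- "double"
    for (w in seq_len(nw)) {
      cols <- w:(w + window_snps - 1L)
      suppressWarnings(r2 <- cor(Hd[, cols, drop = FALSE])^2)
      w11 <- r2[i1, i1][upper.tri(r2[i1, i1])]
      w22 <- r2[i2, i2][upper.tri(r2[i2, i2])]
      within <- mean(c(mean(w11, na.rm = TRUE), mean(w22, na.rm = TRUE)),
                     na.rm = TRUE)
      cross <- mean(r2[i1, i2], na.rm = TRUE)
      if (!is.finite(within)) within <- 0
      if (!is.finite(cross)) cross <- 0
      mu_ld[w] <- min(within / (cross + ld_eps), ld_cap)
    }
    mu <- mu_var * mu_sfs * mu_ld
    center <- pos[seq_len(nw) + half]
    wins[[ch]] <- data.frame(chrom = ch, start = pos[seq_len(nw)],
                             end = pos[window_snps:M], center = center,
                             n_snps = window_snps, stat = mu, source = "mu",
                             stringsAsFactors = FALSE)
    facs[[ch]] <- data.frame(chrom = ch, center = center, span = span,
                             mu_var = mu_var, mu_sfs = mu_sfs, mu_ld = mu_ld,
                             mu = mu, stringsAsFactors = FALSE)
  }
  windows <- do.call(rbind, wins)
  factors <- do.call(rbind, facs)
  rownames(windows) <- rownames(factors) <- NULL
  list(windows = windows, factors = factors)
}
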