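## nSL: number-of-segregating-sites-by-length haplotype statistic.
## For a focal SNP, haplotypes are split by the allele they carry; within
## each class, every haplotype pair contributes the length (in segregating
## sites, the focal site included) of the longest interval containing the
## focal site over which the pair is identical. SL is the mean over pairs;
## raw nSL = ln(SL_ancestral / SL_derived). Long shared haplotypes around a
## recently selected derived allele shrink the ratio's denominator, so
## sweeps give large |nSL|. Distances are in site counts -- the statistic
## is genetic-map-free by design.
##
## Tract sums use group refinement rather than explicit pair enumeration:
## walking outward from the focal site, haplotypes are partitioned into
## groups identical so far; the number of still-identical pairs at step t is
## sum over groups of choose(size, 2), and the sum over t of that count
## equals the total pairwise tract length beyond the focal site.

## Sum over pairs of one-sided identity tract lengths for haplotype rows
## `rows`, walking from column j in direction dir (+1/-1), capped at
## `max_extent` steps and at the chromosome edge.
side_tract_sum <- function(H, rows, j, dir, max_extent) {
  nc <- length(rows)
  gid <- rep(1L, nc)
  total <- 0
  capped <- FALSE
  t <- 0L
  M <- ncol(H)
  while (t < max_extent) {
    t <- t + 1L
    col <- j + dir * t
    if (col < 1L || col > M) break
    id2 <- gid * 2L + H[rows, col]
    gid <- match(id2, unique(id2))
    sizes <- tabulate(gid)
    ident <- sum(sizes * (sizes - 1)) / 2
    if (ident == 0) break
    total <- total + ident
    if (t == max_extent) capped <- TRUE
  }
  list(sum = total, capped = capped)
}

#' nSL scan over a phased haplotype panel
#'
#' Computes raw nSL per focal SNP and standardizes scores in equal-width
#' derived-allele-frequency bins (bins holding fewer than `min_bin` SNPs
#' are merged with the nearest populated bin before standardization).
#' On unpolarized panels the allele classes are REF/ALT and downstream
#' window statistics should use `abs(z)`.
#'
#' @param H a [haplotype_set()]
#' @param maf_min focal SNPs must have MAF > `maf_min`
#' @param max_extent cap (in segregating sites per side) on tract length;
#'   records that hit the cap are flagged `capped`
#' @param n_bins number of frequency bins for standardization
#' @param min_bin minimum SNPs per bin before merging
#' @return data.frame: `chrom`, `pos`, `id`, `freq` (derived/ALT), `sl_a`,
#'   `sl_d`, `nsl_raw`, `bin`, `z`, `capped`; attribute `n_skipped` counts
#'   focal SNPs skipped because an allele class had < 2 haplotypes
#' @export
nsl_scan <- function(H, maf_min = 0.01, max_extent = 100L, n_bins = 100L,
                     min_bin = 2L) {
  stopifnot(inherits(H, "haplotype_set"))
  out <- list()
  n_skipped <- 0L
  for (ch in unique(H$map$chrom)) {
    Hc <- subset_chrom(H, ch)
    ord <- order(Hc$map$pos)
    Hm <- Hc$H[, ord, drop = FALSE]
    map <- Hc$map[ord, , drop = FALSE]
    M <- ncol(Hm)
    res <- vector("list", M)
    for (j in seq_len(M)) {
      if (map$maf[j] <= maf_min) next
      rows_d <- which(Hm[, j] == 1L)
      rows_a <- which(Hm[, j] == 0L)
      if (length(rows_d) < 2L || length(rows_a) < 2L) {
        n_skipped <- n_skipped + 1L
        next
      }
      sl <- function(rows) {
        np <- length(rows) * (length(rows) - 1) / 2
        L <- side_tract_sum(Hm, rows, j, -1L, max_extent)
        R <- side_tract_sum(Hm, rows, j, +1L, max_extent)
        list(sl = 1 + (L$sum + R$sum) / np, capped = L$capped || R$capped)
      }
      a <- sl(rows_a); d <- sl(rows_d)
      res[[j]] <- data.frame(chrom = ch, pos = map$pos[j], id = map$id[j],
                             freq = map$p[j], sl_a = a$sl, sl_d = d$sl,
                             nsl_raw = log(a$sl / d$sl),
                             capped = a$capped || d$capped,
                             stringsAsFactors = FALSE)
    }
    out <- c(out, res[!vapply(res, is.null, TRUE)])
  }
  if (!length(out)) stopf("no focal SNPs passed the nSL filters")
  rec <- do.call(rbind, out)

  ## frequency-bin standardization
  bin <- pmin(pmax(floor(rec$freq * n_bins), 0L), n_bins - 1L)
  pop <- table(factor(bin, levels = 0:(n_bins - 1L)))
  populated <- as.integer(names(pop)[pop >= min_bin])
  if (length(populated) == 0) populated <- as.integer(names(pop)[pop > 0])
  ## merge thin bins with the nearest populated bin
  merged <- vapply(bin, function(b)
    populated[which.min(abs(populated - b))], 0L)
  z <- rec$nsl_raw
  for (b in unique(merged)) {
    sel <- merged == b
    mu <- mean(rec$nsl_raw[sel])
    s <- sd(rec$nsl_raw[sel])
    z[sel] <- if (is.na(s) || s == 0) 0 else (rec$nsl_raw[sel] - mu) / s
  }
  rec$bin <- merged
  rec$z <- z
  attr(rec, "n_skipped") <- n_skipped
  rec
}
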