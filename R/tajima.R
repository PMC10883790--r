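#' Tajima's D in fixed-width bins
#'
#' Per bin, computes the number of segregating sites `S`, the mean number
#' of pairwise differences `pi`, and
#' \deqn{D = \frac{\pi - S/a_1}{\sqrt{e_1 S + e_2 S (S-1)}}}
#' with the standard constants derived from the number of sequences `n`
#' (`a1 = sum 1/i`, etc.). Strongly positive D indicates an excess of
#' intermediate-frequency variation (balancing selection); negative D an
#' excess of rare variants (sweep or expansion). D is reported only for
#' bins with `S >= 3`.
#'
#' Bins are `[0, bin_bp)`, `[bin_bp, 2*bin_bp)`, ... in 0-based
#' coordinates, so a SNP at 1-based position `bin_bp` falls in the first
#' bin.
#'
#' @param x a [haplotype_set()] (n = haplotype count) or
#'   [genotype_matrix()] (n = 2 x samples; allele counts from dosages)
#' @param bin_bp bin width in bp
#' @return data.frame: `chrom`, `start`, `end` (1-based closed bin span),
#'   `n_snps` (sites in bin), `S`, `pi`, `stat` (D, `NA` when `S < 3`),
#'   `source = "tajd"`
#' @export
tajima_bins <- function(x, bin_bp = 100000) {
  if (inherits(x, "haplotype_set")) {
    n <- nrow(x$H); cnt <- colSums(x$H); map <- x$map
  } else if (inherits(x, "genotype_matrix")) {
    n <- 2L * nrow(x$X); cnt <- colSums(x$X); map <- x$map
  } else stopf("need a haplotype_set or genotype_matrix")
  if (n < 4) stopf("Tajima's D needs at least 4 sequences")
  const <- tajima_constants(n)
  bin <- (map$pos - 1L) %/% bin_bp
  out <- list()
  for (ch in unique(map$chrom)) {
    sel <- map$chrom == ch
    for (b in sort(unique(bin[sel]))) {
      s <- which(sel & bin == b)
      cj <- cnt[s]
      seg <- cj > 0L & cj < n
      S <- sum(seg)
      pi <- sum(cj[seg] * (n - cj[seg])) / (n * (n - 1) / 2)
      D <- if (S >= 3)
        (pi - S / const$a1) / sqrt(const$e1 * S + const$e2 * S * (S - 1))
      else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = b * bin_bp + 1, end = (b + 1) * bin_bp,
        n_snps = length(s), S = S, pi = pi, stat = D, source = "tajd",
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Standard Tajima constants for n sequences.
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}
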