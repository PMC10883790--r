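## Variable-width windows from a smoothing spline over per-SNP scores
## (inflection-point breakpoints), plus quantile-based outlier calling
## shared by the nSL and mu scans.

#' Spline-defined windows over per-SNP scores
#'
#' Per chromosome, fits a cubic smoothing spline (smoothing parameter by
#' generalized cross-validation) to `abs(z)` versus position and places
#' window breakpoints at the spline's inflection points (sign changes of
#' the second derivative). Windows partition all scored SNPs; the window
#' statistic is the mean `abs(z)` of its SNPs. A chromosome whose fitted
#' curve has no appreciable curvature (or too few distinct positions to
#' fit) becomes a single whole-chromosome window.
#'
#' @param scores [nsl_scan()] output (needs `chrom`, `pos`, `z`)
#' @param min_snps_fit minimum scored SNPs per chromosome to attempt a fit
#' @return data.frame of windows: `chrom`, `start`, `end` (1-based bp span
#'   of member SNPs), `n_snps`, `stat` (mean `abs(z)`), `source = "nsl"`;
#'   attribute `assignment` maps each scored SNP to its window row
#' @export
spline_windows <- function(scores, min_snps_fit = 10L) {
  wins <- list()
  assign_all <- integer(nrow(scores))
  row0 <- 0L
  for (ch in unique(scores$chrom)) {
    sel <- which(scores$chrom == ch)
    x <- scores$pos[sel]
    yv <- abs(scores$z[sel])
    ord <- order(x)
    x <- x[ord]; yv <- yv[ord]
    breaks <- numeric(0)
    if (length(sel) >= min_snps_fit && length(unique(x)) >= 4L) {
      fit <- tryCatch(smooth.spline(x, yv, cv = FALSE), error = function(e) NULL)
      if (!is.null(fit)) {
        grid <- seq(min(x), max(x), length.out = max(512L, 4L * length(x)))
        d2 <- predict(fit, grid, deriv = 2)$y
        ## curvature floor: a fit this close to linear defines no windows
        scale0 <- diff(range(yv)) / max(diff(range(x)), 1)^2
        if (max(abs(d2)) > 1e-3 * scale0 && diff(range(yv)) > 0) {
          idx_nz <- which(abs(d2) >= 1e-6 * max(abs(d2)))
          if (length(idx_nz) > 1) {
            sg <- sign(d2[idx_nz])
            cross <- which(sg[-1] != sg[-length(sg)])
            breaks <- (grid[idx_nz[cross]] + grid[idx_nz[cross + 1]]) / 2
          }
        }
      }
    }
    wid <- findInterval(x, sort(breaks)) + 1L
    ## drop empty window labels, keep ordering
    wid <- match(wid, sort(unique(wid)))
    for (w in sort(unique(wid))) {
      ws <- which(wid == w)
      row0 <- row0 + 1L
      wins[[row0]] <- data.frame(chrom = ch, start = min(x[ws]),
                                 end = max(x[ws]), n_snps = length(ws),
                                 stat = mean(yv[ws]), source = "nsl",
                                 stringsAsFactors = FALSE)
      assign_all[sel[ord[ws]]] <- row0
    }
  }
  out <- do.call(rbind, wins)
  rownames(out) <- NULL
  attr(out, "assignment") <- assign_all
  out
}

#' Quantile outlier calling on window statistics
#'
#' Windows with at least `min_snps` SNPs are eligible; of those, the top
#' `top_frac` by statistic (a count of `ceiling(top_frac * n_eligible)`)
#' are flagged. Ties at the boundary are all included, so a degenerate
#' all-equal input flags every eligible window.
#'
#' @param windows window table ([spline_windows()], [mu_scan()], or
#'   [tajima_bins()] converted to windows)
#' @param top_frac outlier fraction (e.g. 0.005 for nSL windows, 0.0005
#'   for mu windows)
#' @param min_snps minimum SNP count for eligibility
#' @return `windows` with logical `outlier` and `eligible` columns
#' @export
call_outliers <- function(windows, top_frac, min_snps = 3L) {
  stopifnot(top_frac > 0, top_frac < 1)
  eligible <- windows$n_snps >= min_snps & is.finite(windows$stat)
  windows$eligible <- eligible
  windows$outlier <- FALSE
  ne <- sum(eligible)
  if (ne > 0) {
    k <- ceiling(top_frac * ne)
    cut <- sort(windows$stat[eligible], decreasing = TRUE)[k]
    windows$outlier <- eligible & windows$stat >= cut
  }
  windows
}

#' Merge outlier windows into loci
#'
#' Sliding-window scans flag runs of overlapping windows around one sweep;
#' for locus counting and annotation these are merged when they overlap or
#' lie less than `gap` bp apart. The merged locus keeps the span and the
#' lead position (center of its best window).
#'
#' @param windows output of [call_outliers()]; only rows with
#'   `outlier == TRUE` are used
#' @param gap merge distance in bp (strict: gaps `< gap` merge)
#' @return data.frame of loci: `chrom`, `start`, `end`, `lead_pos`, `stat`
#' @export
merge_outlier_windows <- function(windows, gap = 50000) {
  w <- windows[windows$outlier, , drop = FALSE]
  if (nrow(w) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), lead_pos = integer(0),
                      stat = numeric(0)))
  out <- list()
  for (ch in unique(w$chrom)) {
    wc <- w[w$chrom == ch, , drop = FALSE]
    wc <- wc[order(wc$start), , drop = FALSE]
    grp <- cumsum(c(1, wc$start[-1] - cummax_shift(wc$end) >= gap))
    for (g in unique(grp)) {
      sel <- wc[grp == g, , drop = FALSE]
      best <- which.max(sel$stat)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = min(sel$start), end = max(sel$end),
        lead_pos = round((sel$start[best] + sel$end[best]) / 2),
        stat = max(sel$stat), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## running max of `end` shifted by one (for interval chaining)
cummax_shift <- function(end) {
  if (length(end) == 1) return(numeric(0))
  cummax(end)[-length(end)]
}
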