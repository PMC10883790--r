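## Cross-method synthesis: LD profiles around lead loci, locus-set overlap,
## gene/QTL proximity classes, and QTL-class enrichment. Locus sets carry a
## method label ("gpsm_cojo", "nsl", "mu") and one lead position per locus.

#' Build a locus set
#'
#' @param method label: `"gpsm_cojo"`, `"nsl"`, `"mu"`, or any tag
#' @param chrom,pos lead positions (1-based bp); duplicates within the set
#'   are collapsed
#' @param stat optional per-locus statistic
#' @return data.frame of class `locus_set`
#' @export
locus_set <- function(method, chrom, pos, stat = NA_real_) {
  tab <- data.frame(method = method, chrom = as.character(chrom),
                    pos = as.integer(pos), stat = stat,
                    stringsAsFactors = FALSE)
  tab <- tab[!duplicated(tab[c("chrom", "pos")]), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("locus_set", "data.frame")
  tab
}

#' LD profile around lead loci
#'
#' For each locus, `r^2` (squared Pearson correlation of dosage vectors)
#' between the lead SNP and every other SNP within `radius` bp. Zero-
#' variance SNPs are skipped.
#'
#' @param G [genotype_matrix()] containing the lead SNPs
#' @param loci a [locus_set()]
#' @param radius neighborhood radius in bp
#' @return object of class `ld_profile`: list with `method`, `r2` (list of
#'   per-locus r^2 vectors), `mean`, `sd`, `n_pairs`
#' @export
ld_profile <- function(G, loci, radius = 100000) {
  key <- paste(G$map$chrom, G$map$pos)
  idx <- match(paste(loci$chrom, loci$pos), key)
  if (anyNA(idx)) stopf("locus absent from genotype matrix: %s",
                        paste(loci$chrom[is.na(idx)], loci$pos[is.na(idx)],
                              sep = ":", collapse = ", "))
  r2list <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    j <- idx[i]
    nb <- which(G$map$chrom == loci$chrom[i] &
                  abs(G$map$pos - loci$pos[i]) <= radius &
                  seq_along(key) != j)
    if (!length(nb)) { r2list[[i]] <- numeric(0); next }
    x <- G$X[, j]
    if (sd(x) == 0) { r2list[[i]] <- numeric(0); next }
    Y <- G$X[, nb, drop = FALSE]
    keep <- apply(Y, 2, sd) > 0
    r2list[[i]] <- if (any(keep))
      as.numeric(cor(x, Y[, keep, drop = FALSE]))^2 else numeric(0)
  }
  vals <- unlist(r2list)
  structure(list(method = loci$method[1], r2 = r2list,
                 mean = mean(vals), sd = sd(vals), n_pairs = length(vals)),
            class = "ld_profile")
}

#' Compare LD profiles between locus sets
#'
#' Rank-based one-way location test (Kruskal-Wallis) on the pooled r^2
#' values of two or more [ld_profile()]s, with all-pairs Wilcoxon
#' comparisons under Holm adjustment.
#'
#' @param ... named `ld_profile` objects (names default to their method
#'   labels)
#' @return list: `summary` (per-set mean/sd/n), `kruskal`, `pairwise`
#' @export
compare_ld_profiles <- function(...) {
  profs <- list(...)
  nm <- names(profs)
  if (is.null(nm) || any(!nzchar(nm)))
    nm <- vapply(profs, `[[`, "", "method")
  vals <- lapply(profs, function(p) unlist(p$r2))
  g <- factor(rep(nm, lengths(vals)), levels = nm)
  v <- unlist(vals)
  kw <- kruskal.test(v, g)
  pw <- if (nlevels(g) > 1 && all(table(g) > 1))
    stats::pairwise.wilcox.test(v, g, p.adjust.method = "holm", exact = FALSE)
  else NULL
  summary <- data.frame(set = nm,
                        mean_r2 = vapply(vals, mean, 0),
                        sd_r2 = vapply(vals, sd, 0),
                        n = lengths(vals))
  list(summary = summary, kruskal = kw, pairwise = pw)
}

#' Overlap between two locus sets
#'
#' Locus `a` overlaps locus `b` iff they share a chromosome and
#' `|pos_a - pos_b| < tol` (strict, matching the "< 50 kb apart" rule).
#'
#' @param A,B [locus_set()]s
#' @param tol distance threshold in bp (strict)
#' @return list: `pairs` (data.frame of overlapping pairs), `n_pairs`,
#'   `n_a_hit`, `n_b_hit` (loci of each set with at least one partner)
#' @export
overlap_sets <- function(A, B, tol = 50000) {
  pairs <- list()
  for (ch in intersect(unique(A$chrom), unique(B$chrom))) {
    ai <- which(A$chrom == ch); bi <- which(B$chrom == ch)
    dd <- abs(outer(A$pos[ai], B$pos[bi], `-`))
    hit <- which(dd < tol, arr.ind = TRUE)
    if (nrow(hit))
      pairs[[ch]] <- data.frame(a = ai[hit[, 1]], b = bi[hit[, 2]],
                                chrom = ch,
                                pos_a = A$pos[ai[hit[, 1]]],
                                pos_b = B$pos[bi[hit[, 2]]],
                                dist = dd[hit])
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(a = integer(0), b = integer(0), chrom = character(0),
               pos_a = integer(0), pos_b = integer(0), dist = numeric(0))
  rownames(pairs) <- NULL
  list(pairs = pairs, n_pairs = nrow(pairs),
       n_a_hit = length(unique(pairs$a)), n_b_hit = length(unique(pairs$b)))
}

#' Classify loci as within, proximal to, or outside genes
#'
#' A locus is `within` when its position lies inside a gene interval,
#' `proximal` when the nearest gene boundary is `< window` bp away, else
#' `intergenic`. The nearest gene's name is attached.
#'
#' @param loci [locus_set()]
#' @param genes [feature_table()] of gene intervals
#' @param window proximity window in bp (strict)
#' @return list: `classes` (per-locus data.frame with `class` and
#'   `nearest_gene`), `counts`, `fractions` (the within/proximal/intergenic
#'   table layout)
#' @export
proximity_classes <- function(loci, genes, window = 50000) {
  lv <- c("within", "proximal", "intergenic")
  n <- nrow(loci)
  cls <- rep("intergenic", n)
  nearest <- rep(NA_character_, n)
  if (nrow(genes) == 0) {
    warnf("empty gene table: all loci classified intergenic")
  } else {
    ## feature_table is 0-based half-open; compare against 1-based positions
    g1 <- genes$start + 1L
    g2 <- genes$end
    for (i in seq_len(n)) {
      gi <- which(genes$chrom == loci$chrom[i])
      if (!length(gi)) next
      p <- loci$pos[i]
      d <- ifelse(p < g1[gi], g1[gi] - p, ifelse(p > g2[gi], p - g2[gi], 0L))
      j <- which.min(d)
      nearest[i] <- genes$name[gi[j]]
      cls[i] <- if (d[j] == 0) "within" else if (d[j] < window) "proximal"
                else "intergenic"
    }
  }
  classes <- data.frame(chrom = loci$chrom, pos = loci$pos,
                        class = factor(cls, levels = lv),
                        nearest_gene = nearest, stringsAsFactors = FALSE)
  counts <- table(classes$class)
  list(classes = classes, counts = counts, fractions = counts / max(1, n))
}

#' QTL-class enrichment around loci
#'
#' QTL entries within `window` bp of any locus are "hit"; each QTL class is
#' tested for over-representation among hits versus its genome-wide
#' frequency with a hypergeometric tail test, BH-adjusted across classes
#' (significant at `q < fdr`). For each significant class the maximum
#' single-chromosome hit count and that chromosome are reported, since
#' database redundancy often concentrates an enrichment on one chromosome.
#'
#' @param loci [locus_set()]
#' @param qtl [feature_table()] with QTL `class` labels; this table is also
#'   the enrichment background
#' @param window annotation window in bp (strict boundary distance)
#' @param fdr FDR threshold on BH-adjusted p-values
#' @return data.frame per class: `class`, `n_total`, `n_hit`, `p`, `q`,
#'   `significant`, `max_chrom_hits`, `max_chrom`
#' @export
qtl_enrichment <- function(loci, qtl, window = 50000, fdr = 0.1) {
  stopifnot(nrow(qtl) > 0, !all(is.na(qtl$class)))
  q1 <- qtl$start + 1L   # to 1-based closed
  q2 <- qtl$end
  hit <- rep(FALSE, nrow(qtl))
  for (i in seq_len(nrow(loci))) {
    gi <- which(qtl$chrom == loci$chrom[i])
    if (!length(gi)) next
    p <- loci$pos[i]
    d <- ifelse(p < q1[gi], q1[gi] - p, ifelse(p > q2[gi], p - q2[gi], 0L))
    hit[gi[d < window]] <- TRUE
  }
  N <- nrow(qtl)
  n_hits <- sum(hit)
  classes <- sort(unique(qtl$class[!is.na(qtl$class)]))
  res <- lapply(classes, function(cl) {
    inc <- qtl$class == cl & !is.na(qtl$class)
    K <- sum(inc)
    k <- sum(inc & hit)
    p <- phyper(k - 1, K, N - K, n_hits, lower.tail = FALSE)
    mx <- 0L; mxc <- NA_character_
    if (k > 0) {
      tab <- table(qtl$chrom[inc & hit])
      mx <- as.integer(max(tab)); mxc <- names(tab)[which.max(tab)]
    }
    data.frame(class = cl, n_total = K, n_hit = k, p = p,
               max_chrom_hits = mx, max_chrom = mxc, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- p.adjust(res$p, method = "BH")
  res$significant <- res$q < fdr
  res <- res[c("class", "n_total", "n_hit", "p", "q", "significant",
               "max_chrom_hits", "max_chrom")]
  rownames(res) <- NULL
  res
}
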