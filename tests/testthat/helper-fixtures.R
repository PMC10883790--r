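## Shared fixture builders. Everything is generated in code at test time.

## Small random genotype matrix with a valid map.
rand_geno <- function(n, m, seed = 1, p = NULL, chrom = 1L, spacing = 1000L) {
  set.seed(seed)
  if (is.null(p)) p <- runif(m, 0.1, 0.9)
  X <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  ## keep sites polymorphic so GRM standardization is defined
  mono <- colSums(X) %in% c(0L, 2L * n)
  for (j in which(mono)) X[sample(n, 2), j] <- c(0L, 1L)
  map <- data.frame(chrom = chrom, pos = seq_len(m) * spacing,
                    ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_matrix(X, map)
}

## Small random phased haplotype panel.
rand_haps <- function(n_hap, m, seed = 1, polarized = TRUE, spacing = 1000L) {
  set.seed(seed)
  p <- runif(m, 0.2, 0.8)
  H <- matrix(rbinom(n_hap * m, 1, rep(p, each = n_hap)), n_hap, m)
  map <- data.frame(chrom = 1L, pos = seq_len(m) * spacing,
                    ref = "A", alt = "G", stringsAsFactors = FALSE)
  haplotype_set(H, map, polarized = polarized)
}

## Brute-force GRM oracle (naive double loop over the published formula).
grm_oracle <- function(X) {
  n <- nrow(X); m <- ncol(X)
  p <- colMeans(X) / 2
  A <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    s <- 0
    for (i in seq_len(m))
      s <- s + (X[j, i] - 2 * p[i]) * (X[k, i] - 2 * p[i]) /
        (2 * p[i] * (1 - p[i]))
    A[j, k] <- s / m
  }
  A
}

## Exhaustive nSL oracle: enumerate all haplotype pairs within each allele
## class and count, site by site, the identity tract around the focal site
## (in segregating-site units, capped per side).
nsl_oracle <- function(H, j, max_extent = 100L) {
  M <- ncol(H)
  sl_class <- function(rows) {
    if (length(rows) < 2) return(NA_real_)
    tot <- 0; np <- 0
    for (a in seq_along(rows)[-length(rows)]) for (b in (a + 1):length(rows)) {
      ha <- H[rows[a], ]; hb <- H[rows[b], ]
      len <- 1
      t <- 0
      for (col in seq(j - 1, by = -1, length.out = min(max_extent, j - 1))) {
        if (ha[col] != hb[col]) break
        len <- len + 1
      }
      for (col in seq(j + 1, by = 1, length.out = min(max_extent, M - j))) {
        if (ha[col] != hb[col]) break
        len <- len + 1
      }
      tot <- tot + len; np <- np + 1
    }
    tot / np
  }
  list(sl_a = sl_class(which(H[, j] == 0L)),
       sl_d = sl_class(which(H[, j] == 1L)))
}

## Independent Tajima's D oracle: pi by explicit pairwise Hamming distances,
## constants written out from their textbook definitions.
tajima_oracle <- function(H) {
  n <- nrow(H)
  seg <- colSums(H) > 0 & colSums(H) < n
  S <- sum(seg)
  dsum <- 0; np <- 0
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    dsum <- dsum + sum(H[a, seg] != H[b, seg]); np <- np + 1
  }
  pi <- dsum / np
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

## Dense GLS oracle for the mixed-model scan: form V explicitly and solve
## the two-parameter GLS (intercept + SNP) per SNP.
mlma_oracle <- function(X, y, A, sg2, se2) {
  n <- length(y)
  V <- sg2 * A + se2 * diag(n)
  Vi <- solve(V)
  t(apply(X, 2, function(x) {
    D <- cbind(1, x)
    M <- solve(t(D) %*% Vi %*% D)
    beta <- M %*% t(D) %*% Vi %*% y
    se <- sqrt(M[2, 2])
    chi <- (beta[2] / se)^2
    c(b = beta[2], se = se, p = pchisq(chi, 1, lower.tail = FALSE))
  }))
}

## Henderson mixed-model-equation oracle for BLUP (u = sg2 A z).
blup_oracle <- function(y, A, sg2, se2) {
  n <- length(y)
  X <- matrix(1, n, 1)
  lambda <- se2 / sg2
  Ai <- solve(A + 1e-8 * diag(n))
  ## MME: [X'X  X'Z; Z'X  Z'Z + Ai*lambda] [b; u] = [X'y; Z'y], Z = I
  lhs <- rbind(cbind(crossprod(X), t(X)),
               cbind(X, diag(n) + Ai * lambda))
  rhs <- c(crossprod(X, y), y)
  sol <- solve(lhs, rhs)
  list(beta = sol[1], u = sol[-1])
}

## A small simulated dataset reused across tests (cached per session).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_founders = 80, years = 10, offspring_per_year = 80,
                        m_snps = 300, n_trait_loci = 10, n_sampled_total = 200,
                        sampling_skew = 0.2, seed = 99)
      cache <<- simulate_population(cfg)
    }
    cache
  }
})
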