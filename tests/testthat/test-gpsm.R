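test_that("Box-Cox exponent recovers known transformations", {
  set.seed(51)
  ## log-normal: lambda ~ 0
  y <- exp(rnorm(3000))
  expect_lt(abs(boxcox_transform(y)$lambda), 0.1)
  ## already normal (positive-shifted): lambda ~ 1
  y <- rnorm(3000, mean = 20, sd = 2)
  bc <- boxcox_transform(y)
  expect_gt(bc$lambda, 0.8); expect_lt(bc$lambda, 1.2)
  ## construct-and-recover: y = u^(1/0.5) for positive normal u
  u <- rnorm(5000, 30, 3)
  y <- u^(1 / 0.5)
  expect_lt(abs(boxcox_transform(y)$lambda - 0.5), 0.1)
  expect_error(boxcox_transform(rep(2, 10)), "constant")
  ## agrees with the MASS profile-likelihood oracle
  set.seed(52)
  y <- rgamma(800, shape = 2, rate = 0.3)
  bx <- MASS::boxcox(y ~ 1, lambda = seq(-2, 2, 0.01), plotit = FALSE)
  expect_lt(abs(boxcox_transform(y)$lambda - bx$x[which.max(bx$y)]), 0.02)
})

test_that("with sigma_g2 = 0 the mixed-model scan equals ordinary least squares", {
  set.seed(61)
  N <- 60
  G <- rand_geno(N, 20, seed = 62)
  y <- rnorm(N)
  grm <- compute_grm(G, 0.01)
  vc <- structure(list(sigma_g2 = 1e-14, sigma_e2 = 1, converged = TRUE),
                  class = "varcomp")
  rec <- mlma_scan(G, y, grm, vc)
  for (j in seq_len(20)) {
    f <- summary(lm(y ~ G$X[, j]))
    ## coefficients agree for any error variance
    expect_equal(rec$b[j], unname(coef(f)[2, 1]), tolerance = 1e-10)
    ## with sigma_e2 set to the OLS residual variance, SE and the Wald
    ## chi-square p also reproduce the OLS quadratic form exactly
    vcj <- structure(list(sigma_g2 = 1e-14, sigma_e2 = f$sigma^2,
                          converged = TRUE), class = "varcomp")
    rj <- mlma_scan(genotype_matrix(G$X[, j, drop = FALSE],
                                    G$map[j, c("chrom", "pos", "ref", "alt")]),
                    y, grm, vcj)
    expect_equal(rj$se, unname(coef(f)[2, 2]), tolerance = 1e-10)
    tval <- unname(coef(f)[2, 1] / coef(f)[2, 2])
    expect_equal(rj$p, pchisq(tval^2, 1, lower.tail = FALSE), tolerance = 1e-10)
  }
})

test_that("the scan matches a dense per-SNP GLS oracle at N=50, m=5", {
  set.seed(71)
  N <- 50
  G <- rand_geno(N, 5, seed = 72)
  Ggrm <- rand_geno(N, 150, seed = 73)
  grm <- compute_grm(Ggrm, 0.01)
  y <- rnorm(N)
  sg2 <- 0.6; se2 <- 1.1
  vc <- structure(list(sigma_g2 = sg2, sigma_e2 = se2, converged = TRUE),
                  class = "varcomp")
  rec <- mlma_scan(G, y, grm, vc)
  or <- mlma_oracle(G$X, y, grm$A, sg2, se2)
  expect_equal(rec$b, unname(or[, "b"]), tolerance = 1e-8)
  expect_equal(rec$se, unname(or[, "se"]), tolerance = 1e-8)
  expect_equal(rec$p, unname(or[, "p"]), tolerance = 1e-8)
})

test_that("monomorphic SNPs are flagged and unconverged components refused", {
  set.seed(81)
  N <- 40
  G <- rand_geno(N, 4, seed = 82)
  G$X[, 2] <- 0L
  G <- genotype_matrix(G$X, G$map[c("chrom", "pos", "ref", "alt")])
  grm <- compute_grm(rand_geno(N, 100, seed = 83), 0.01)
  vc <- structure(list(sigma_g2 = 0.5, sigma_e2 = 1, converged = TRUE),
                  class = "varcomp")
  rec <- mlma_scan(G, rnorm(N), grm, vc)
  expect_true(rec$monomorphic[2])
  expect_equal(rec$b[2], 0); expect_equal(rec$p[2], 1)
  vc$converged <- FALSE
  expect_error(mlma_scan(G, rnorm(N), grm, vc), "refusing")
})

test_that("threshold ladder applies strict cuts and BH step-up", {
  rec <- data.frame(p = c(0.001, 0.02, 0.9))
  out <- threshold_ladder(rec, m_tests = 3)
  ## hand BH step-up: q = (0.003, 0.03, 0.9)
  expect_equal(out$q, c(0.003, 0.03, 0.9))
  ## all-equal p: q = p, fdr05 for all
  rec <- data.frame(p = rep(0.004, 10))
  out <- threshold_ladder(rec, m_tests = 10)
  expect_equal(out$q, rep(0.004, 10))
  expect_true(all(out$fdr05))
  ## strict inequality at the Bonferroni boundary
  rec <- data.frame(p = c(0.05 / 7, 0.05 / 7 - 1e-12))
  out <- threshold_ladder(rec, m_tests = 7)
  expect_false(out$bonferroni[1])
  expect_true(out$bonferroni[2])
  ## genome-wide flag at p = 4e-8
  rec <- data.frame(p = c(4e-8, 6e-8))
  out <- threshold_ladder(rec, m_tests = 2)
  expect_true(out$genomewide[1])
  expect_false(out$genomewide[2])
  ## q is monotone nondecreasing in p
  set.seed(91)
  rec <- data.frame(p = runif(200))
  out <- threshold_ladder(rec)
  expect_true(all(diff(out$q[order(out$p)]) >= -1e-15))
})

test_that("COJO selects one of a perfect-LD pair and both independent causals", {
  set.seed(101)
  N <- 800
  x1 <- rbinom(N, 2, 0.4)
  x2 <- x1                       # perfect LD
  x3 <- rbinom(N, 2, 0.5)        # independent
  y <- -0.3 * x1 - 0.25 * x3 + rnorm(N, sd = 0.5)
  X <- cbind(x1, x2, x3)
  G <- genotype_matrix(X, data.frame(chrom = 1, pos = c(100, 200, 10000),
                                     ref = "A", alt = "G"))
  rec <- do.call(rbind, lapply(1:3, function(j) {
    f <- summary(lm(y ~ X[, j]))
    data.frame(chrom = "1", pos = G$map$pos[j], id = G$map$id[j],
               ref = "A", alt = "G", p_freq = G$map$p[j],
               b = coef(f)[2, 1], se = coef(f)[2, 2],
               p = pchisq((coef(f)[2, 1] / coef(f)[2, 2])^2, 1, lower.tail = FALSE),
               monomorphic = FALSE)
  }))
  out <- cojo_select(rec, G)
  ## r^2 = 1 pair collapses to one SNP; independent SNP also selected
  expect_equal(nrow(out), 2L)
  expect_true(sum(out$pos %in% c(100, 200)) == 1)
  expect_true(10000 %in% out$pos)
  expect_true(any(grepl("200|100", attr(out, "collinear_dropped"))))
  ## joint effects match the two-SNP regression oracle within 2 SE
  sel <- sort(out$pos)
  f2 <- lm(y ~ X[, match(sel, G$map$pos)])
  for (k in 1:2) {
    i <- which(out$pos == sel[k])
    expect_lt(abs(out$b_joint[i] - coef(f2)[k + 1]), 2 * out$se_joint[i])
  }
})

test_that("COJO handles empty/single candidate sets and is order-invariant", {
  set.seed(111)
  N <- 500
  G <- rand_geno(N, 6, seed = 112)
  ## no candidates
  rec <- data.frame(chrom = "1", pos = G$map$pos, id = G$map$id,
                    ref = "A", alt = "G", p_freq = G$map$p,
                    b = 0.01, se = 0.05, p = 0.5, monomorphic = FALSE)
  expect_equal(nrow(cojo_select(rec, G)), 0L)
  ## single significant SNP: conditional p equals marginal p
  x <- G$X[, 3]
  y <- -0.4 * x + rnorm(N, sd = 0.6)
  f <- summary(lm(y ~ x))
  rec$b[3] <- coef(f)[2, 1]; rec$se[3] <- coef(f)[2, 2]
  rec$p[3] <- pchisq((rec$b[3] / rec$se[3])^2, 1, lower.tail = FALSE)
  out <- cojo_select(rec, G)
  expect_equal(nrow(out), 1L)
  expect_equal(out$cond_p, out$p_marginal, tolerance = 1e-12)
  expect_equal(out$p_joint, out$p_marginal, tolerance = 0.3)
  ## order invariance
  out2 <- cojo_select(rec[sample(nrow(rec)), ], G)
  expect_equal(out$id, out2$id)
})

test_that("an allele rising over calendar time gets a negative coefficient", {
  ## constructed monotone trajectory: allele frequency increases with birth
  ## year; y = years before reference, so the regression slope must be < 0
  set.seed(121)
  N <- 400
  byear <- sort(rep(1:10, length.out = N))
  p_t <- 0.2 + 0.05 * byear          # rising allele
  x <- rbinom(N, 2, p_t)
  y <- max(byear) - byear + runif(N) # years before reference
  G <- genotype_matrix(matrix(x, ncol = 1),
                       data.frame(chrom = 1, pos = 1000, ref = "A", alt = "G"))
  vc <- structure(list(sigma_g2 = 1e-14, sigma_e2 = 1, converged = TRUE),
                  class = "varcomp")
  grm <- compute_grm(rand_geno(N, 50, seed = 122), 0.01)
  rec <- mlma_scan(G, y, grm, vc)
  expect_lt(rec$b[1], 0)
})
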