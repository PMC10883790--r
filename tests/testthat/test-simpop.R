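test_that("skewed birth-year sampling gives exact exponential counts", {
  ## uniform limit
  cfg <- sim_config(sampling_skew = 0, years = 10, n_sampled_total = 100)
  expect_equal(attr(sample_birth_dates(cfg), "counts"), rep(10L, 10))
  ## exact geometric ratio 1:2:4
  cfg <- sim_config(sampling_skew = log(2), years = 3, n_sampled_total = 70)
  expect_equal(attr(sample_birth_dates(cfg), "counts"), c(10L, 20L, 40L))
  ## cannot cover all years
  cfg <- sim_config(years = 10, n_sampled_total = 10)
  cfg$n_sampled_total <- 5
  expect_error(sample_birth_dates(cfg), "cannot cover all years")
})

test_that("strong skew makes birth years left-skewed with monotone counts", {
  cfg <- sim_config(sampling_skew = 0.3, years = 25, n_sampled_total = 5000)
  by <- sample_birth_dates(cfg)
  counts <- attr(by, "counts")
  expect_true(all(diff(counts) >= 0))
  ## oracle: skewness of the target distribution computed directly
  w <- exp(0.3 * 1:25); pr <- w / sum(w)
  mu <- sum(pr * 1:25)
  sk_target <- sum(pr * (1:25 - mu)^3) / sum(pr * (1:25 - mu)^2)^1.5
  expect_lt(sk_target, 0)
  sk <- mean((by - mean(by))^3) / sd(by)^3
  expect_lt(sk, 0)
  expect_equal(sk, sk_target, tolerance = 0.05)
})

test_that("generation proxy is decimal years before the reference date", {
  meta <- data.frame(id = c("a", "b"),
                     birth_date = c("2020-10-19", "2019-04-19"))
  gp <- make_generation_proxy(meta, reference_date = "2020-10-19")
  expect_equal(gp$y[1], 0)
  expect_equal(gp$y[2], 1.5, tolerance = 0.01)  # 18 months
  ## calendar oracle across leap years: day-count / 365.25
  set.seed(4)
  days <- sort(sample(0:5000, 40))
  meta <- data.frame(id = seq_along(days),
                     birth_date = as.Date("2006-01-10") + days)
  gp <- make_generation_proxy(meta, reference_date = as.Date("2020-10-19"))
  oracle <- as.numeric(as.Date("2020-10-19") - (as.Date("2006-01-10") + days)) / 365.25
  expect_equal(gp$y, oracle, tolerance = 0.01)
  ## default reference: latest birth + 1 day; future birth errors
  gp <- make_generation_proxy(meta)
  expect_true(all(gp$y > 0))
  expect_error(make_generation_proxy(meta, reference_date = "2001-01-01"),
               "birth date after reference")
})

test_that("identical seeds reproduce byte-identical simulations", {
  cfg <- sim_config(n_founders = 60, years = 6, offspring_per_year = 60,
                    m_snps = 150, n_trait_loci = 5, n_sampled_total = 100,
                    seed = 31L)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$haplotypes$H, s2$haplotypes$H)
  expect_identical(s1$meta, s2$meta)
  expect_identical(s1$truth$loci, s2$truth$loci)
})

test_that("neutral simulation drifts around zero expected frequency change", {
  deltas <- sapply(1:20, function(s) {
    cfg <- sim_config(n_founders = 100, years = 8, offspring_per_year = 100,
                      m_snps = 60, n_trait_loci = 0, n_sampled_total = 60,
                      mutation_rate = 0, seed = 500 + s)
    sim <- simulate_population(cfg)
    mean(sim$truth$loci$final_freq - sim$truth$loci$founder_freq)
  })
  ## mean change over replicates ~ 0 within 3 SE of the replicate spread
  expect_lt(abs(mean(deltas)), 3 * sd(deltas) / sqrt(length(deltas)))
})

test_that("sweep frequency gain tracks the deterministic recursion", {
  ## non-overlapping-style fast turnover to make 'per year' ~ a generation:
  ## parents eligible for one year only
  gains <- sapply(1:25, function(s) {
    cfg <- sim_config(n_founders = 400, years = 3, offspring_per_year = 400,
                      m_snps = 40, n_trait_loci = 0, mutation_rate = 0,
                      truncation_fraction_m = 1, truncation_fraction_f = 1,
                      parent_age_min = 1, parent_age_max = 1,
                      founder_pool_size = 0,
                      sweep_loci = data.frame(chrom = 1, pos = 5e5, s = 0.1,
                                              start_freq = 0.2),
                      n_sampled_total = 3, seed = 900 + s)
    sim <- simulate_population(cfg)
    traj <- sim$truth$trajectories[, colnames(sim$truth$trajectories) ==
                                       "1:500000", drop = FALSE]
    mean(diff(c(0.2, traj[, 1])))
  })
  ## oracle: iterate Delta p = s p q / (1 + s p) from p = 0.2 for 3 steps
  p <- 0.2; steps <- numeric(3)
  for (g in 1:3) {
    dp <- 0.1 * p * (1 - p) / (1 + 0.1 * p)
    p <- p + dp; steps[g] <- dp
  }
  expect_lt(abs(mean(gains) - mean(steps)),
            3 * sd(gains) / sqrt(length(gains)) + 1e-3)
})

test_that("genotypes are Hardy-Weinberg consistent in a large unselected cohort", {
  ## one unselected generation: each offspring unites two independent random
  ## gametes, so genotype frequencies must match p^2, 2pq, q^2
  cfg <- sim_config(n_founders = 500, years = 1, offspring_per_year = 3000,
                    m_snps = 40, n_trait_loci = 0, mutation_rate = 0,
                    truncation_fraction_m = 1, truncation_fraction_f = 1,
                    n_sampled_total = 3000, sampling_skew = 0, seed = 77)
  sim <- simulate_population(cfg)
  G <- haplotypes_to_dosage(sim$haplotypes)
  n <- nrow(G$X)
  for (j in seq_len(ncol(G$X))) {
    p <- G$map$p[j]
    if (p < 0.05 || p > 0.95) next
    obs_het <- mean(G$X[, j] == 1L)
    exp_het <- 2 * p * (1 - p)
    ## 4 SE binomial envelope per site
    expect_lt(abs(obs_het - exp_het), 4 * sqrt(exp_het * (1 - exp_het) / n))
  }
})

test_that("extinction and fixation edge cases are reported", {
  ## no eligible parents in year 1: parent window starts beyond founder ages
  cfg <- sim_config(n_founders = 20, years = 3, offspring_per_year = 10,
                    m_snps = 20, n_sampled_total = 3,
                    parent_age_min = 11, parent_age_max = 12)
  expect_error(simulate_population(cfg), "extinct.*year 1")
  ## sweep fixed before sampling begins -> warning recorded in truth
  cfg <- sim_config(n_founders = 40, years = 12, offspring_per_year = 60,
                    m_snps = 40, n_trait_loci = 0,
                    sweep_loci = data.frame(chrom = 1, pos = 5e5, s = 9,
                                            start_freq = 0.9),
                    sampling_skew = 3, n_sampled_total = 12, seed = 13)
  expect_warning(sim <- simulate_population(cfg), "fixed")
  expect_true(length(sim$truth$warnings) > 0)
})

test_that("balancing trajectories revert toward the equilibrium frequency", {
  devs <- sapply(1:10, function(s) {
    cfg <- sim_config(n_founders = 150, years = 20, offspring_per_year = 150,
                      m_snps = 50, n_trait_loci = 0,
                      balancing_loci = data.frame(chrom = 1, pos = 5e5,
                                                  h_s = 1, eq_freq = 0.5),
                      n_sampled_total = 20, seed = 700 + s)
    sim <- simulate_population(cfg)
    traj <- sim$truth$trajectories[, "1:500000"]
    mean(abs(traj - 0.5))
  })
  ## drift-only control at the same position
  devs0 <- sapply(1:10, function(s) {
    cfg <- sim_config(n_founders = 150, years = 20, offspring_per_year = 150,
                      m_snps = 50, n_trait_loci = 0,
                      sweep_loci = data.frame(chrom = 1, pos = 5e5, s = 0,
                                              start_freq = 0.5),
                      n_sampled_total = 20, seed = 700 + s)
    sim <- simulate_population(cfg)
    traj <- sim$truth$trajectories[, "1:500000"]
    mean(abs(traj - 0.5))
  })
  expect_lt(mean(devs), mean(devs0))
})

test_that("simulated VCF + metadata round-trip reproduces dosages and proxy", {
  sim <- small_sim()
  tmp <- withr::local_tempdir()
  vcf <- file.path(tmp, "sim.vcf")
  tsv <- file.path(tmp, "meta.tsv")
  write_vcf(sim$haplotypes, vcf)
  write.table(sim$meta, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_vcf(vcf)
  G0 <- haplotypes_to_dosage(sim$haplotypes)
  expect_equal(unname(back$genotypes$X), unname(G0$X))
  expect_identical(back$haplotypes$H, sim$haplotypes$H)
  expect_true(back$haplotypes$polarized)
  meta <- read_metadata(tsv, back$genotypes$sample_ids)
  gp1 <- make_generation_proxy(meta)
  gp0 <- make_generation_proxy(sim$meta)
  expect_equal(gp1$y, gp0$y)
})
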