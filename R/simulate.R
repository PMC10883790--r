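## Forward-in-time simulator of an overlapping-generation diploid population.
##
## Design: cohorts (one per birth year) hold phased haplotypes; parents are
## drawn each year from all individuals whose age falls in the configured
## window, after within-sex truncation on a polygenic trait. Sweep loci
## multiply a parent's sampling weight by (1+s) per derived copy; balancing
## loci apply heterozygote-advantage weights. Recombination is Poisson
## crossovers with uniform breakpoints (no interference). Cohorts older than
## the parent window are dropped to bound memory.

## One recombinant gamete from a parent's two haplotypes.
## chrom_cols: list of column index vectors per chromosome;
## chrom_pos: list of position vectors; morgans: genetic length per chrom.
make_gamete <- function(h1, h2, chrom_cols, chrom_pos, morgans) {
  out <- h1
  for (ci in seq_along(chrom_cols)) {
    cols <- chrom_cols[[ci]]
    k <- rpois(1L, morgans[ci])
    start <- sample.int(2L, 1L)          # which haplotype leads
    if (k == 0L) {
      if (start == 2L) out[cols] <- h2[cols]
      next
    }
    br <- sort(runif(k, 0, 1)) * chrom_pos[[ci]][length(chrom_pos[[ci]])]
    seg <- (findInterval(chrom_pos[[ci]], br) + start) %% 2L
    take2 <- seg == 0L
    out[cols][take2] <- h2[cols][take2]
  }
  out
}

#' Simulate an overlapping-generation population under selection
#'
#' Runs the forward simulator described in [sim_config()]: truncation
#' selection on a polygenic trait, multiplicative sweep advantages,
#' heterozygote-advantage balancing selection, Poisson-crossover
#' recombination, and exponentially skewed genotype sampling. All randomness
#' flows from `config$seed`.
#'
#' @param config a [sim_config()]
#' @return list with
#'   \describe{
#'     \item{haplotypes}{[haplotype_set()] of the genotyped samples
#'       (polarized: founder alleles are coded so 0 is ancestral)}
#'     \item{meta}{data.frame: `id`, `sex`, `birth_date` (Date), `birth_year`
#'       (simulated year index)}
#'     \item{truth}{list: `loci` (per-locus regime, effect/selection
#'       parameter, realized founder and final frequencies), `trajectories`
#'       (years x non-neutral loci frequency matrix), `warnings`}
#'   }
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  nC <- cfg$n_chromosomes
  m <- cfg$m_snps

  ## --- genome layout -------------------------------------------------------
  m_per_chr <- largest_remainder(rep(1, nC), m)
  chrom <- rep(seq_len(nC), m_per_chr)
  pos <- unlist(lapply(m_per_chr, function(mi)
    sort(sample.int(cfg$chrom_length_bp, mi))))
  ## force configured selected-locus positions into the SNP set (replace the
  ## nearest simulated position on that chromosome)
  place_locus <- function(ch, bp) {
    idx <- which(chrom == ch)
    if (!bp %in% pos[idx]) {
      j <- idx[which.min(abs(pos[idx] - bp))]
      pos[j] <<- as.integer(bp)
      pos[idx] <<- sort(pos[idx])
    }
    which(chrom == ch & pos == bp)[1]
  }
  sweep_idx <- integer(0); bal_idx <- integer(0)
  if (!is.null(cfg$sweep_loci))
    sweep_idx <- mapply(place_locus, cfg$sweep_loci$chrom, cfg$sweep_loci$pos)
  if (!is.null(cfg$balancing_loci))
    bal_idx <- mapply(place_locus, cfg$balancing_loci$chrom, cfg$balancing_loci$pos)
  if (anyDuplicated(c(sweep_idx, bal_idx)))
    stopf("sweep/balancing loci collapsed onto the same SNP position")

  chrom_cols <- split(seq_len(m), chrom)
  chrom_pos <- split(pos, chrom)
  morgans <- rep(cfg$chrom_length_morgans, nC)

  ## --- founder population --------------------------------------------------
  law <- cfg$founder_freq_law
  freq <- switch(law$law %||% "uniform",
                 uniform = runif(m, law$lo, law$hi),
                 beta    = rbeta_clamped(m, law$a, law$b),
                 ## neutral-equilibrium SFS: density ~ 1/p on [lo, hi],
                 ## sampled by inverse CDF -- gives Tajima's D near zero
                 neutral = {
                   ## truncation must sit well below 1/(sample haplotypes)
                   ## or the rare tail of the SFS is cut and D drifts upward
                   lo <- law$lo %||% 0.001; hi <- law$hi %||% 0.999
                   lo * (hi / lo)^runif(m)
                 })
  if (length(sweep_idx)) freq[sweep_idx] <- cfg$sweep_loci$start_freq
  if (length(bal_idx)) freq[bal_idx] <- cfg$balancing_loci$eq_freq

  nF <- cfg$n_founders
  if (cfg$founder_pool_size >= 2) {
    ## founders are mosaics of a small ancestral haplotype pool: this gives
    ## the panel LD and haplotype structure, and puts selected alleles on
    ## few ancestral backgrounds (hard-sweep-like single origins)
    np <- cfg$founder_pool_size
    pool <- matrix(rbinom(np * m, 1L, rep(freq, each = np)), np, m)
    assign_pool <- function(idx, fr) {
      ## place the selected allele on round(fr*np) pool haplotypes exactly
      for (j in seq_along(idx)) {
        k <- min(np - 1L, max(1L, round(fr[j] * np)))
        pool[, idx[j]] <<- 0L
        pool[sample.int(np, k), idx[j]] <<- 1L
      }
    }
    if (length(sweep_idx)) assign_pool(sweep_idx, cfg$sweep_loci$start_freq)
    if (length(bal_idx)) assign_pool(bal_idx, cfg$balancing_loci$eq_freq)
    lam <- cfg$founder_mosaic_rate * morgans
    Hf <- matrix(0L, 2L * nF, m)
    for (h in seq_len(2L * nF)) {
      for (ci in seq_len(nC)) {
        cols <- chrom_cols[[ci]]
        cp <- chrom_pos[[ci]]
        k <- rpois(1L, lam[ci])
        br <- sort(runif(k, 0, 1)) * cp[length(cp)]
        seg <- findInterval(cp, br) + 1L
        src <- sample.int(np, k + 1L, replace = TRUE)
        Hf[h, cols] <- pool[cbind(src[seg], cols)]
      }
    }
  } else {
    Hf <- matrix(rbinom(2L * nF * m, 1L, rep(freq, each = 2L * nF)), 2L * nF, m)
  }
  storage.mode(Hf) <- "integer"

  ## polygenic trait
  trait_idx <- integer(0); effects <- numeric(0)
  if (cfg$n_trait_loci > 0) {
    avail <- setdiff(seq_len(m), c(sweep_idx, bal_idx))
    trait_idx <- sort(sample(avail, min(cfg$n_trait_loci, length(avail))))
    effects <- rnorm(length(trait_idx), 0, cfg$trait_effect_sd)
  }
  genetic_value <- function(H2n) {
    if (!length(trait_idx)) return(numeric(nrow(H2n) / 2L))
    odd <- seq(1L, nrow(H2n), by = 2L)
    dos <- H2n[odd, trait_idx, drop = FALSE] + H2n[odd + 1L, trait_idx, drop = FALSE]
    as.numeric(dos %*% effects)
  }
  gF <- genetic_value(Hf)
  var_g <- if (length(trait_idx)) var(gF) else 0
  var_e <- if (cfg$trait_h2 > 0 && var_g > 0)
    var_g * (1 - cfg$trait_h2) / cfg$trait_h2 else 1
  sd_e <- sqrt(var_e)

  ## cohorts: founders spread over the pre-simulation age window so the
  ## parent pool exists from year 1 (overlapping generations from the start)
  span <- seq(1L - cfg$parent_age_max, 0L)
  fyears <- rep(span, largest_remainder(rep(1, length(span)), nF))
  cohorts <- list()
  next_id <- 1L
  for (by in unique(fyears)) {
    sel <- which(fyears == by)
    rows <- as.vector(rbind(2L * sel - 1L, 2L * sel))
    cohorts[[as.character(by)]] <- list(
      year = by,
      H = Hf[rows, , drop = FALSE],
      sex = sample(c("M", "F"), length(sel), replace = TRUE,
                   prob = c(cfg$male_fraction, 1 - cfg$male_fraction)),
      trait = gF[sel] + rnorm(length(sel), 0, sd_e),
      id = sprintf("F%05d", seq(next_id, length.out = length(sel))))
    next_id <- next_id + length(sel)
  }

  ## parental sampling weights from sweep + balancing loci
  fitness_weight <- function(H2n) {
    n <- nrow(H2n) / 2L
    w <- rep(1, n)
    odd <- seq(1L, nrow(H2n), by = 2L)
    if (length(sweep_idx)) {
      dos <- H2n[odd, sweep_idx, drop = FALSE] + H2n[odd + 1L, sweep_idx, drop = FALSE]
      for (j in seq_along(sweep_idx))
        w <- w * (1 + cfg$sweep_loci$s[j])^dos[, j]
    }
    if (length(bal_idx)) {
      dos <- H2n[odd, bal_idx, drop = FALSE] + H2n[odd + 1L, bal_idx, drop = FALSE]
      for (j in seq_along(bal_idx)) {
        hs <- cfg$balancing_loci$h_s[j]; fe <- cfg$balancing_loci$eq_freq[j]
        wg <- c(max(0, 1 - hs * fe), 1, max(0, 1 - hs * (1 - fe)))
        w <- w * wg[dos[, j] + 1L]
      }
    }
    w
  }

  ## --- sampling plan -------------------------------------------------------
  byears <- sample_birth_dates(cfg)
  counts <- attr(byears, "counts")
  if (max(counts) > cfg$offspring_per_year)
    stopf("per-year sample count (%d) exceeds offspring_per_year (%d)",
          max(counts), cfg$offspring_per_year)

  tracked <- sort(unique(as.integer(c(sweep_idx, bal_idx, trait_idx))))
  traj <- matrix(NA_real_, cfg$years, length(tracked))
  if (length(tracked))
    colnames(traj) <- paste0(chrom[tracked], ":", pos[tracked])
  warnings <- character(0)
  samp_rows <- vector("list", cfg$years)
  samp_meta <- vector("list", cfg$years)

  ## --- yearly cycle --------------------------------------------------------
  for (t in seq_len(cfg$years)) {
    eligible <- Filter(function(co) {
      age <- t - co$year; age >= cfg$parent_age_min && age <= cfg$parent_age_max
    }, cohorts)
    if (!length(eligible)) stopf("population extinct in year %d: no eligible parents", t)
    sexes <- unlist(lapply(eligible, `[[`, "sex"))
    traits <- unlist(lapply(eligible, `[[`, "trait"))
    ## flat indexing back into (cohort, individual)
    co_of <- rep(seq_along(eligible), vapply(eligible, function(c) length(c$sex), 1L))
    ind_of <- unlist(lapply(eligible, function(c) seq_along(c$sex)))

    pick_pool <- function(sex, frac) {
      cand <- which(sexes == sex)
      if (!length(cand)) stopf("population extinct in year %d: no eligible %s parents",
                               t, if (sex == "M") "male" else "female")
      keep <- cand[order(traits[cand], decreasing = TRUE)]
      keep[seq_len(max(1L, ceiling(frac * length(keep))))]
    }
    poolM <- pick_pool("M", cfg$truncation_fraction_m)
    poolF <- pick_pool("F", cfg$truncation_fraction_f)

    pool_weights <- function(pool) {
      w <- numeric(length(pool))
      for (ci in unique(co_of[pool])) {
        sel <- pool[co_of[pool] == ci]
        co <- eligible[[ci]]
        wc <- fitness_weight(co$H)
        w[match(sel, pool)] <- wc[ind_of[sel]]
      }
      w
    }
    wM <- pool_weights(poolM); wF <- pool_weights(poolF)

    nO <- cfg$offspring_per_year
    dads <- sample(length(poolM), nO, replace = TRUE, prob = wM)
    moms <- sample(length(poolF), nO, replace = TRUE, prob = wF)

    Hnew <- matrix(0L, 2L * nO, m)
    for (o in seq_len(nO)) {
      pd <- poolM[dads[o]]; pm <- poolF[moms[o]]
      cod <- eligible[[co_of[pd]]]; com <- eligible[[co_of[pm]]]
      rd <- 2L * ind_of[pd] - 1L; rm <- 2L * ind_of[pm] - 1L
      Hnew[2L * o - 1L, ] <- make_gamete(cod$H[rd, ], cod$H[rd + 1L, ],
                                         chrom_cols, chrom_pos, morgans)
      Hnew[2L * o, ] <- make_gamete(com$H[rm, ], com$H[rm + 1L, ],
                                    chrom_cols, chrom_pos, morgans)
    }
    ## recurrent mutation at neutral sites only
    if (cfg$mutation_rate > 0) {
      neutral_cols <- setdiff(seq_len(m), c(sweep_idx, bal_idx, trait_idx))
      n_mut <- rpois(1L, cfg$mutation_rate * 2 * nO * length(neutral_cols))
      if (n_mut > 0L) {
        mr <- sample.int(2L * nO, n_mut, replace = TRUE)
        mc <- sample(neutral_cols, n_mut, replace = TRUE)
        Hnew[cbind(mr, mc)] <- 1L - Hnew[cbind(mr, mc)]
      }
    }
    gO <- genetic_value(Hnew)
    cohorts[[as.character(t)]] <- list(
      year = t, H = Hnew,
      sex = sample(c("M", "F"), nO, replace = TRUE,
                   prob = c(cfg$male_fraction, 1 - cfg$male_fraction)),
      trait = gO + rnorm(nO, 0, sd_e),
      id = sprintf("Y%02dI%04d", t, seq_len(nO)))

    if (length(tracked)) traj[t, ] <- colMeans(Hnew[, tracked, drop = FALSE])

    ## genotype sampling from this birth cohort
    if (counts[t] > 0L) {
      sel <- sort(sample.int(nO, counts[t]))
      rows <- as.vector(rbind(2L * sel - 1L, 2L * sel))
      samp_rows[[t]] <- Hnew[rows, , drop = FALSE]
      day <- sort(sample.int(365L, counts[t], replace = TRUE))
      samp_meta[[t]] <- data.frame(
        id = cohorts[[as.character(t)]]$id[sel],
        sex = cohorts[[as.character(t)]]$sex[sel],
        birth_date = as.Date(sprintf("%d-01-01", cfg$base_year + t - 1L)) + (day - 1L),
        birth_year = t,
        stringsAsFactors = FALSE)
    }
    ## drop cohorts that can no longer parent
    cohorts <- Filter(function(co) t - co$year < cfg$parent_age_max, cohorts)
  }

  ## --- truth table ---------------------------------------------------------
  founder_freq <- colMeans(Hf)
  final_freq <- rep(NA_real_, m)
  last <- cohorts[[as.character(cfg$years)]]
  final_freq <- colMeans(last$H)
  regime <- rep("neutral", m)
  eff <- rep(NA_real_, m)
  regime[trait_idx] <- "polygenic"; eff[trait_idx] <- effects
  regime[sweep_idx] <- "sweep"; eff[sweep_idx] <- cfg$sweep_loci$s
  regime[bal_idx] <- "balancing"; eff[bal_idx] <- cfg$balancing_loci$h_s
  if (length(sweep_idx)) {
    first_sampled <- min(which(counts > 0L))
    for (j in seq_along(sweep_idx)) {
      fx <- which(traj[, match(sweep_idx[j], tracked)] %in% c(0, 1))
      if (length(fx) && min(fx) < first_sampled)
        warnings <- c(warnings, sprintf(
          "sweep locus %d:%d fixed in year %d, before sampling began",
          cfg$sweep_loci$chrom[j], cfg$sweep_loci$pos[j], min(fx)))
    }
  }
  loci <- data.frame(chrom = chrom, pos = pos, regime = regime, effect = eff,
                     founder_freq = founder_freq, final_freq = final_freq,
                     stringsAsFactors = FALSE)

  meta <- do.call(rbind, samp_meta[!vapply(samp_meta, is.null, TRUE)])
  rownames(meta) <- NULL
  H <- do.call(rbind, samp_rows[!vapply(samp_rows, is.null, TRUE)])
  map <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
                    stringsAsFactors = FALSE)
  haps <- haplotype_set(H, map, sample_ids = meta$id, polarized = TRUE)
  if (length(warnings)) for (w in warnings) warnf("%s", w)

  list(haplotypes = haps, meta = meta,
       truth = list(loci = loci, trajectories = traj, tracked_cols = tracked,
                    warnings = warnings))
}

## beta draws clamped away from 0/1 so founder sites stay polymorphic-capable
rbeta_clamped <- function(n, a, b) pmin(pmax(stats::rbeta(n, a, b), 0.01), 0.99)
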