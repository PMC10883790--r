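#' Simulation configuration
#'
#' Builds and validates the configuration for the forward-in-time simulator.
#' The defaults describe a managed livestock-like population: overlapping
#' generations (parents drawn from an age window, default 2-10 years, so no
#' integer generation number exists), stronger truncation on males than
#' females as in cattle breeding, and genotype sampling that grows
#' exponentially toward recent birth years (the left-skewed sampling typical
#' of commercial genotyping).
#'
#' @param n_founders number of founder diploids
#' @param years simulated birth-year span; offspring are born in years
#'   `1..years`
#' @param offspring_per_year diploid offspring born each year
#' @param male_fraction probability an offspring is male
#' @param truncation_fraction_m,truncation_fraction_f fraction of eligible
#'   males/females (ranked on the polygenic trait) kept as parents
#' @param n_chromosomes,chrom_length_bp,chrom_length_morgans genome layout;
#'   each chromosome has the same physical and genetic length
#' @param m_snps total SNP count across chromosomes
#' @param founder_freq_law list: `list(law="uniform", lo=, hi=)`,
#'   `list(law="beta", a=, b=)`, or `list(law="neutral", lo=, hi=)` (density
#'   proportional to 1/p, the neutral-equilibrium site frequency spectrum)
#'   for founder derived-allele frequencies
#' @param founder_pool_size number of distinct ancestral haplotypes the
#'   founder haplotypes are mosaics of (gives founders realistic LD and
#'   haplotype structure; selected alleles start on few backgrounds, so
#'   sweeps are hard-sweep-like). Set to `0` for site-independent founders
#'   (linkage equilibrium)
#' @param founder_mosaic_rate expected mosaic breakpoints per Morgan when
#'   building each founder haplotype from the pool; higher values mean
#'   shorter ancestral segments and faster LD decay
#' @param mutation_rate per-site per-gamete flip probability at neutral
#'   sites (recurrent mutation within the fixed site panel). Keeps the
#'   sample's site frequency spectrum supplied with rare variants, as in
#'   sequence data; selected loci are never mutated
#' @param n_trait_loci,trait_effect_sd,trait_h2 polygenic trait: number of
#'   causal loci, SD of their normal effect sizes, and founder heritability
#' @param sweep_loci data.frame(chrom, pos, s, start_freq): per-copy
#'   multiplicative parental sampling advantage `1+s` per generation
#' @param balancing_loci data.frame(chrom, pos, h_s, eq_freq): heterozygote
#'   advantage; homozygote fitness penalties are split as
#'   `1 - h_s*eq_freq` (ref/ref) and `1 - h_s*(1-eq_freq)` (alt/alt) so the
#'   deterministic equilibrium derived-allele frequency is `eq_freq`
#' @param sampling_skew rate `k`: per-year genotyped counts proportional to
#'   `exp(k * year)`; `k = 0` gives uniform sampling
#' @param n_sampled_total genotyped samples drawn across all years
#' @param parent_age_min,parent_age_max age window (years) within which an
#'   individual can be drawn as a parent
#' @param base_year calendar year mapped to simulated year 1 (birth dates
#'   are emitted as ISO dates)
#' @param seed integer seed; all randomness flows from one generator
#' @return validated list of class `sim_config`
#' @export
sim_config <- function(n_founders = 200,
                       years = 20,
                       offspring_per_year = 200,
                       male_fraction = 0.5,
                       truncation_fraction_m = 0.05,
                       truncation_fraction_f = 0.5,
                       n_chromosomes = 1,
                       chrom_length_bp = 1e6,
                       chrom_length_morgans = 1,
                       m_snps = 1000,
                       founder_freq_law = list(law = "uniform", lo = 0.05, hi = 0.5),
                       founder_pool_size = 24,
                       founder_mosaic_rate = 10,
                       mutation_rate = 1e-4,
                       n_trait_loci = 0,
                       trait_effect_sd = 0.1,
                       trait_h2 = 0.5,
                       sweep_loci = NULL,
                       balancing_loci = NULL,
                       sampling_skew = 0.3,
                       n_sampled_total = 1000,
                       parent_age_min = 2,
                       parent_age_max = 10,
                       base_year = 2001,
                       seed = 1L) {
  cfg <- as.list(environment())
  for (f in c("n_founders", "years", "offspring_per_year", "n_chromosomes",
              "m_snps", "n_sampled_total"))
    if (!is_count(cfg[[f]])) stopf("`%s` must be a positive integer", f)
  if (!is_prop(male_fraction, open_lo = TRUE, open_hi = TRUE))
    stopf("`male_fraction` must be in (0,1)")
  for (f in c("truncation_fraction_m", "truncation_fraction_f"))
    if (!is_prop(cfg[[f]], open_lo = TRUE)) stopf("`%s` must be in (0,1]", f)
  if (!is_prop(trait_h2)) stopf("`trait_h2` must be in [0,1]")
  if (sampling_skew < 0) stopf("`sampling_skew` must be >= 0")
  if (founder_pool_size < 0 || founder_mosaic_rate < 0)
    stopf("founder pool parameters must be >= 0")
  if (!is_prop(mutation_rate)) stopf("`mutation_rate` must be in [0,1]")
  if (parent_age_min < 1 || parent_age_max < parent_age_min)
    stopf("parent age window must satisfy 1 <= min <= max")
  stopifnot(chrom_length_bp >= m_snps / n_chromosomes,
            chrom_length_morgans > 0, trait_effect_sd >= 0,
            n_trait_loci >= 0)
  law <- founder_freq_law$law %||% "uniform"
  if (!law %in% c("uniform", "beta", "neutral"))
    stopf("unknown founder_freq_law '%s'", law)
  check_loci <- function(tab, cols, nm) {
    if (is.null(tab)) return(NULL)
    tab <- as.data.frame(tab)
    if (!all(cols %in% names(tab))) stopf("`%s` needs columns %s", nm,
                                          paste(cols, collapse = ", "))
    if (!all(tab$chrom %in% seq_len(n_chromosomes)))
      stopf("`%s` chromosome out of range", nm)
    if (!all(tab$pos >= 1 & tab$pos <= chrom_length_bp))
      stopf("`%s` position out of range", nm)
    tab
  }
  cfg$sweep_loci <- check_loci(sweep_loci, c("chrom", "pos", "s", "start_freq"),
                               "sweep_loci")
  cfg$balancing_loci <- check_loci(balancing_loci,
                                   c("chrom", "pos", "h_s", "eq_freq"),
                                   "balancing_loci")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' Per-sample birth years under exponentially skewed sampling
#'
#' Genotyped counts per year are proportional to `exp(k * year)` for years
#' `1..T`, rounded with the largest-remainder rule so they sum exactly to the
#' requested total. With `k > 0` recent years dominate, reproducing the
#' extreme left skew of birth dates in commercially genotyped populations.
#'
#' @param config a [sim_config()] (fields `sampling_skew`, `years`,
#'   `n_sampled_total` are used)
#' @return integer vector of birth years, one entry per sample, sorted;
#'   attribute `counts` holds the per-year counts and attribute
#'   `empty_years` any years whose skewed count rounded to zero
#' @export
sample_birth_dates <- function(config) {
  k <- config$sampling_skew
  T <- config$years
  n <- config$n_sampled_total
  if (n < T)
    stopf("n_sampled_total (%d) < years (%d): cannot cover all years", n, T)
  w <- exp(k * seq_len(T))
  counts <- largest_remainder(w, n)
  years <- rep(seq_len(T), counts)
  attr(years, "counts") <- counts
  empty <- which(counts == 0L)
  if (length(empty)) attr(years, "empty_years") <- empty
  years
}

#' Generation proxy from birth dates
#'
#' The generation proxy is the continuous number of years (months and days
#' as a decimal) between an individual's birth date and a reference date.
#' Older individuals therefore have larger proxy values; an allele whose
#' frequency rises over calendar time has a negative regression coefficient
#' on the proxy.
#'
#' @param meta data.frame with columns `id` and `birth_date` (Date, ISO
#'   string, or numeric decimal year)
#' @param reference_date reference (same type as `birth_date`); defaults to
#'   the latest birth date in the data plus one day
#' @return object of class `generation_proxy`: list with `y` (decimal years
#'   before the reference), `reference_date`, `transform = "raw"`,
#'   `lambda = NA`, `sample_ids`
#' @export
make_generation_proxy <- function(meta, reference_date = NULL) {
  stopifnot(all(c("id", "birth_date") %in% names(meta)))
  bd <- meta$birth_date
  if (is.numeric(bd)) {
    ref <- reference_date %||% (max(bd) + 1 / 365.25)
    if (any(bd > ref)) stopf("birth date after reference date")
    y <- ref - bd
  } else {
    bd <- as.Date(bd)
    ref <- if (is.null(reference_date)) max(bd) + 1L else as.Date(reference_date)
    if (any(bd > ref)) stopf("birth date after reference date")
    y <- decimal_years(bd, ref)
  }
  structure(list(y = as.numeric(y), reference_date = ref, transform = "raw",
                 lambda = NA_real_, sample_ids = as.character(meta$id)),
            class = "generation_proxy")
}

#' @exportS3Method base::print
print.generation_proxy <- function(x, ...) {
  cat(sprintf("<generation_proxy> n=%d, %s%s, range [%.2f, %.2f] years\n",
              length(x$y), x$transform,
              if (x$transform == "boxcox") sprintf(" (lambda=%.3f)", x$lambda) else "",
              min(x$y), max(x$y)))
  invisible(x)
}
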