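## End-to-end orchestration: simulate (or load) -> GRM -> REML -> GPSM ->
## COJO -> sweep scans -> synthesis, with a JSON manifest of parameters,
## seeds and output checksums. A rerun with the same config and seed is
## byte-identical (the manifest deliberately records no wall-clock times).

#' Pipeline run configuration
#'
#' Defaults are the analysis protocol settings: genome-wide significance
#' `p_sig = 5e-8`, COJO entry `p_entry = 1e-5`, collinearity cap
#' `r2_cap = 0.9`, nSL window outliers `nsl_top = 0.005` with
#' `min_snps = 3`, mu outliers `mu_top = 5e-4`, 50-kb annotation window,
#' `maf_min = 0.01`, and 100-kb Tajima bins.
#'
#' @param out_dir output directory (created if needed)
#' @param vcf,meta input paths; leave `NULL` and supply `sim` to simulate
#' @param sim a [sim_config()] for simulated input (ignored when `vcf`
#'   given)
#' @param genes,qtl optional feature files for annotation/enrichment
#' @param transform `"raw"` or `"boxcox"` generation proxy
#' @param stages character vector of stages to run (subset of
#'   `c("input","grm","reml","gpsm","cojo","nsl","mu","tajd","synthesis")`);
#'   later stages require earlier ones
#' @param p_sig,p_entry,r2_cap,nsl_top,mu_top,min_snps,annot_window,maf_min,tajd_bin
#'   analysis thresholds (see Details)
#' @param mu_window_snps SNPs per mu window
#' @param ld_radius LD profile radius in bp
#' @param overlap_tol locus-overlap distance in bp
#' @param seed integer seed for the run
#' @return validated list of class `run_config`
#' @export
run_config <- function(out_dir,
                       vcf = NULL, meta = NULL, sim = NULL,
                       genes = NULL, qtl = NULL,
                       transform = c("raw", "boxcox"),
                       stages = c("input", "grm", "reml", "gpsm", "cojo",
                                  "nsl", "mu", "tajd", "synthesis"),
                       p_sig = 5e-8, p_entry = 1e-5, r2_cap = 0.9,
                       nsl_top = 0.005, mu_top = 5e-4, min_snps = 3L,
                       annot_window = 50000, maf_min = 0.01,
                       tajd_bin = 100000, mu_window_snps = 50L,
                       ld_radius = 100000, overlap_tol = 50000,
                       seed = 1L) {
  transform <- match.arg(transform)
  for (f in c("p_sig", "p_entry", "r2_cap", "nsl_top", "mu_top"))
    if (!is_prop(get(f), open_lo = TRUE, open_hi = TRUE))
      stopf("`%s` must be in (0,1), got %g", f, get(f))
  stopifnot(min_snps >= 1, annot_window > 0, maf_min >= 0, maf_min < 0.5,
            tajd_bin > 0, mu_window_snps >= 4, ld_radius > 0, overlap_tol > 0)
  known <- c("input", "grm", "reml", "gpsm", "cojo", "nsl", "mu", "tajd",
             "synthesis")
  if (!all(stages %in% known)) stopf("unknown stage(s): %s",
                                     paste(setdiff(stages, known), collapse = ", "))
  if (is.null(vcf) && is.null(sim))
    stopf("either `vcf`+`meta` inputs or a `sim` config is required")
  cfg <- as.list(environment())
  cfg$known <- NULL
  cfg$f <- NULL
  structure(cfg, class = "run_config")
}

#' Run the end-to-end selection-architecture pipeline
#'
#' Executes the configured stages in dependency order, writes every stage's
#' outputs under `out_dir`, and records parameters, seed, and output file
#' checksums in `manifest.json`. Reruns with an identical configuration and
#' seed produce byte-identical outputs.
#'
#' @param config a [run_config()]
#' @param quiet suppress stage progress messages
#' @return the manifest, invisibly
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- function(...) file.path(config$out_dir, ...)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stages_run <- character(0)
  files <- character(0)
  st <- config$stages
  set.seed(config$seed)

  ## --- input ---------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$vcf)) {
    vcf_path <- config$vcf
    meta_path <- config$meta
  } else {
    say("stage input: simulating population (seed %d)", config$sim$seed)
    sim <- simulate_population(config$sim)
    vcf_path <- od("simulated.vcf")
    meta_path <- od("simulated_meta.tsv")
    write_vcf(sim$haplotypes, vcf_path)
    meta_out <- sim$meta
    meta_out$y <- make_generation_proxy(sim$meta)$y
    utils::write.table(meta_out, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(sim$truth$loci, od("simulated_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    truth <- sim$truth
    files <- c(files, vcf_path, meta_path, od("simulated_truth.tsv"))
  }
  vv <- read_vcf(vcf_path)
  G <- vv$genotypes
  H <- vv$haplotypes
  meta <- read_metadata(meta_path, G$sample_ids)
  stages_run <- c(stages_run, "input")
  if (identical(st, "input") || !any(st != "input")) {
    return(invisible(write_manifest(config, stages_run, files)))
  }

  gp <- make_generation_proxy(meta)
  if (config$transform == "boxcox") gp <- boxcox_transform(gp)

  out <- list()
  ## --- grm / reml / gpsm / cojo -------------------------------------------
  if ("grm" %in% st) {
    say("stage grm: %d samples", nrow(G$X))
    Gf <- filter_maf(G, config$maf_min)
    spec <- grm_spectrum(Gf, maf_min = config$maf_min)
    stages_run <- c(stages_run, "grm")
  }
  if ("reml" %in% st) {
    say("stage reml")
    vc <- greml(gp, spec)
    blup <- blup_predict(gp, spec, vc)
    vcj <- list(sigma_g2 = vc$sigma_g2, sigma_e2 = vc$sigma_e2,
                pve = vc$pve, pve_se = vc$pve_se, se_g2 = vc$se_g2,
                se_e2 = vc$se_e2, loglik = vc$loglik,
                iterations = vc$iterations, converged = vc$converged,
                transform = gp$transform, lambda = gp$lambda)
    jsonlite::write_json(vcj, od("varcomp.json"), auto_unbox = TRUE,
                         digits = NA)
    files <- c(files, od("varcomp.json"))
    out$varcomp <- vc
    out$blup <- blup
    stages_run <- c(stages_run, "reml")
  }
  if ("gpsm" %in% st) {
    say("stage gpsm: %d SNPs", ncol(G$X))
    rec <- mlma_scan(G, gp, spec, vc)
    rec <- threshold_ladder(rec)
    write_results(rec, od("gpsm_assoc.tsv"), "assoc")
    files <- c(files, od("gpsm_assoc.tsv"))
    out$assoc <- rec
    stages_run <- c(stages_run, "gpsm")
  }
  if ("cojo" %in% st) {
    say("stage cojo")
    cj <- cojo_select(rec, G, p_entry = config$p_entry,
                      p_sig = config$p_sig, r2_cap = config$r2_cap)
    utils::write.table(cj, od("cojo.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, od("cojo.tsv"))
    out$cojo <- cj
    stages_run <- c(stages_run, "cojo")
  }

  ## --- sweep scans ---------------------------------------------------------
  if (any(c("nsl", "mu", "tajd") %in% st) && is.null(H))
    stopf("sweep scans need phased haplotypes in the input VCF")
  if ("nsl" %in% st) {
    say("stage nsl")
    nslr <- nsl_scan(H, maf_min = config$maf_min)
    nw <- spline_windows(nslr)
    nw <- call_outliers(nw, config$nsl_top, config$min_snps)
    write_results(nw, od("nsl_windows.tsv"), "windows")
    files <- c(files, od("nsl_windows.tsv"), od("nsl_windows.bed"))
    out$nsl <- list(records = nslr, windows = nw)
    stages_run <- c(stages_run, "nsl")
  }
  if ("mu" %in% st) {
    say("stage mu")
    mu <- mu_scan(H, window_snps = config$mu_window_snps)
    mw <- call_outliers(mu$windows, config$mu_top, min_snps = 1L)
    write_results(mw, od("mu_windows.tsv"), "windows")
    files <- c(files, od("mu_windows.tsv"), od("mu_windows.bed"))
    out$mu <- list(windows = mw, factors = mu$factors)
    stages_run <- c(stages_run, "mu")
  }
  if ("tajd" %in% st) {
    say("stage tajd")
    td <- tajima_bins(H, bin_bp = config$tajd_bin)
    write_results(td, od("tajima_bins.tsv"), "windows")
    files <- c(files, od("tajima_bins.tsv"), od("tajima_bins.bed"))
    out$tajd <- td
    stages_run <- c(stages_run, "tajd")
  }

  ## --- synthesis -----------------------------------------------------------
  if ("synthesis" %in% st) {
    say("stage synthesis")
    sets <- list()
    if (!is.null(out$cojo) && nrow(out$cojo))
      sets$gpsm_cojo <- locus_set("gpsm_cojo", out$cojo$chrom, out$cojo$pos,
                                  -log10(out$cojo$p_joint))
    if (!is.null(out$nsl)) {
      ow <- out$nsl$windows[out$nsl$windows$outlier, , drop = FALSE]
      if (nrow(ow))
        sets$nsl <- locus_set("nsl", ow$chrom,
                              round((ow$start + ow$end) / 2), ow$stat)
    }
    if (!is.null(out$mu)) {
      ml <- merge_outlier_windows(out$mu$windows, gap = config$overlap_tol)
      if (nrow(ml)) sets$mu <- locus_set("mu", ml$chrom, ml$lead_pos, ml$stat)
    }
    syn <- list()
    if (length(sets) >= 2) {
      cmb <- utils::combn(names(sets), 2, simplify = FALSE)
      syn$overlap <- lapply(cmb, function(pr) {
        ov <- overlap_sets(sets[[pr[1]]], sets[[pr[2]]], config$overlap_tol)
        list(sets = pr, n_pairs = ov$n_pairs,
             n_a_hit = ov$n_a_hit, n_b_hit = ov$n_b_hit)
      })
    }
    if (!is.null(config$genes)) {
      genes <- read_features(config$genes, "gene")
      syn$proximity <- lapply(sets, function(s) {
        pc <- proximity_classes(s, genes, config$annot_window)
        as.list(pc$counts)
      })
    }
    if (!is.null(config$qtl)) {
      qtl <- read_features(config$qtl, "qtl")
      syn$enrichment <- lapply(sets, function(s)
        qtl_enrichment(s, qtl, config$annot_window))
    }
    syn$set_sizes <- lapply(sets, nrow)
    jsonlite::write_json(syn, od("synthesis.json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
    files <- c(files, od("synthesis.json"))
    out$synthesis <- syn
    out$locus_sets <- sets
    stages_run <- c(stages_run, "synthesis")
  }

  manifest <- write_manifest(config, stages_run, files)
  out$manifest <- manifest
  out$truth <- truth
  out$genotypes <- G
  out$haplotypes <- H
  out$proxy <- gp
  invisible(out)
}

## Manifest: config (paths relativized), stages, seed, md5 of every output.
write_manifest <- function(config, stages_run, files) {
  cfg <- unclass(config)
  cfg$sim <- if (!is.null(cfg$sim)) unclass(cfg$sim) else NULL
  sums <- tools::md5sum(files)
  names(sums) <- basename(names(sums))
  manifest <- list(package = "selarch",
                   version = as.character(utils::packageVersion("selarch")),
                   seed = config$seed,
                   stages = stages_run,
                   config = cfg,
                   checksums = as.list(sums))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  manifest
}
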