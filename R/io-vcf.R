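## VCF input/output. Reading goes through vcfR; writing emits VCF 4.2 text
## directly (phased biallelic SNPs with an INFO/AA ancestral-allele tag).
## Coordinates in files are 1-based per the VCF convention; the variant maps
## keep them 1-based, and interval code converts at its own boundary.

#' Read a VCF into a genotype matrix (and haplotypes when phased)
#'
#' Restricted to biallelic SNPs; other records are skipped and counted.
#' The INFO `AA` tag, when present at every kept site, polarizes the
#' haplotypes (0 = ancestral).
#'
#' @param path VCF file (may be bgzipped)
#' @param region optional `"chrom"` or `"chrom:start-end"` (1-based,
#'   inclusive) restriction applied after parsing
#' @param maf_min if not `NULL`, drop sites with MAF <= `maf_min`
#' @param haplotypes `"auto"` (return haplotypes when all GT are phased),
#'   `TRUE` (error on the first unphased record), or `FALSE`
#' @return list with `genotypes` ([genotype_matrix()]), `haplotypes`
#'   ([haplotype_set()] or `NULL`), and `skipped` (count of non-biallelic/
#'   non-SNP records)
#' @export
read_vcf <- function(path, region = NULL, maf_min = NULL, haplotypes = "auto") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) fixm <- t(fixm)   # single-record VCF
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  biall <- !is.na(fix$ALT) & !grepl(",", fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  skipped <- sum(!biall)
  if (!any(biall)) stopf("no biallelic SNPs in %s", path)
  gt <- vcfR::extract.gt(v, element = "GT")[biall, , drop = FALSE]
  fix <- fix[biall, , drop = FALSE]
  if (any(is.na(gt))) stopf("missing genotypes are not supported")
  sep <- unique(substr(gt, 2, 2))
  if (any(!sep %in% c("|", "/"))) stopf("mixed ploidy or malformed GT field")
  phased_all <- all(sep == "|")
  if (isTRUE(haplotypes) && !phased_all) {
    bad <- which(substr(gt, 2, 2) == "/", arr.ind = TRUE)[1, ]
    stopf("haplotypes requested but record %s:%s sample %s is unphased",
          fix$CHROM[bad[1]], fix$POS[bad[1]], colnames(gt)[bad[2]])
  }
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  if (!all(c(a1, a2) %in% c("0", "1"))) stopf("mixed ploidy or non-biallelic GT codes")
  A1 <- matrix(as.integer(a1), nrow(gt), ncol(gt))
  A2 <- matrix(as.integer(a2), nrow(gt), ncol(gt))
  X <- t(A1 + A2)  # samples x variants
  map <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT,
                    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                paste(fix$CHROM, fix$POS, sep = ":"), fix$ID),
                    stringsAsFactors = FALSE)
  ## ancestral-allele tag
  aa <- vcfR::extract.info(v, element = "AA")[biall]
  polarized <- !is.null(aa) && !any(is.na(aa)) && all(aa == fix$REF | aa == fix$ALT)

  keep <- rep(TRUE, ncol(X))
  if (!is.null(region)) {
    mt <- regmatches(region, regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1]]
    if (!length(mt)) stopf("malformed region '%s'", region)
    keep <- keep & map$chrom == mt[2]
    if (nzchar(mt[3]))
      keep <- keep & map$pos >= as.integer(mt[4]) & map$pos <= as.integer(mt[5])
    if (!any(keep)) stopf("no variants in region %s", region)
  }
  if (!is.null(maf_min)) {
    p <- colMeans(X) / 2
    keep <- keep & pmin(p, 1 - p) > maf_min
    if (!any(keep)) stopf("no variants left after MAF > %g filter", maf_min)
  }
  G <- genotype_matrix(X[, keep, drop = FALSE], map[keep, , drop = FALSE],
                       colnames(gt))
  H <- NULL
  if (phased_all && !isFALSE(haplotypes)) {
    HM <- matrix(0L, 2L * ncol(gt), nrow(gt))
    HM[seq(1, nrow(HM), 2), ] <- t(A1)
    HM[seq(2, nrow(HM), 2), ] <- t(A2)
    HM <- HM[, keep, drop = FALSE]
    mk <- map[keep, , drop = FALSE]
    if (polarized) {
      flip <- aa[keep] == mk$alt   # ancestral is ALT -> recode so 0=ancestral
      if (any(flip)) HM[, flip] <- 1L - HM[, flip]
    }
    H <- haplotype_set(HM, mk, colnames(gt), polarized = polarized)
  }
  list(genotypes = G, haplotypes = H, skipped = skipped)
}

#' Write a phased haplotype panel as VCF 4.2
#'
#' Emits phased GT (`|` separator) and the INFO `AA` ancestral-allele tag
#' when the panel is polarized (ancestral = REF by construction here).
#'
#' @param H a [haplotype_set()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_vcf <- function(H, path) {
  stopifnot(inherits(H, "haplotype_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##source=selarch %s", as.character(packageVersion("selarch"))),
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", H$sample_ids), collapse = "\t"), con)
  odd <- seq(1L, nrow(H$H), 2L)
  gt <- matrix(paste(H$H[odd, , drop = FALSE], H$H[odd + 1L, , drop = FALSE],
                     sep = "|"),
               nrow = length(odd))   # samples x variants
  info <- if (H$polarized) paste0("AA=", H$map$ref) else "."
  lines <- paste(H$map$chrom, H$map$pos, H$map$id, H$map$ref, H$map$alt,
                 ".", "PASS", info, "GT",
                 apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read per-sample metadata (id, birth date) and align to genotypes
#'
#' @param path TSV with header; must contain `id` and `birth_date` columns
#' @param sample_ids optional genotype sample order to align to; metadata
#'   rows absent from it are dropped with a warning, and genotyped samples
#'   without metadata raise an error
#' @return data.frame aligned to `sample_ids` (or file order)
#' @export
read_metadata <- function(path, sample_ids = NULL) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "birth_date") %in% names(meta)))
    stopf("metadata must have `id` and `birth_date` columns")
  meta$id <- as.character(meta$id)
  if (anyDuplicated(meta$id)) stopf("duplicated sample ids in metadata")
  miss <- meta$id[is.na(meta$birth_date) | meta$birth_date == ""]
  if (length(miss))
    stopf("missing birth date for: %s", paste(miss, collapse = ", "))
  if (!is.null(sample_ids)) {
    extra <- setdiff(meta$id, sample_ids)
    if (length(extra))
      warnf("%d metadata id(s) absent from genotypes, excluded: %s",
            length(extra), paste(head(extra, 5), collapse = ", "))
    absent <- setdiff(sample_ids, meta$id)
    if (length(absent))
      stopf("no metadata for genotyped sample(s): %s",
            paste(head(absent, 5), collapse = ", "))
    meta <- meta[match(sample_ids, meta$id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  meta
}
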