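## Result writers. Association records go out as a fixed-column TSV
## (CHR SNP BP A1 A2 FREQ BETA SE P Q); window scans as a TSV plus a BED
## whose start is pos-1 (BED is 0-based half-open).

#' Write association or window results
#'
#' @param records for `format = "assoc"`, a data.frame with (at least)
#'   columns `chrom`, `id`, `pos`, `alt`, `ref`, `p_freq`, `b`, `se`, `p`,
#'   `q`; for `format = "windows"`, a window table from [spline_windows()] /
#'   [mu_scan()] / [tajima_bins()] with `chrom`, `start`, `end` (1-based
#'   closed bp spans)
#' @param path output TSV path; for windows a sibling `.bed` is written too
#' @param format `"assoc"` or `"windows"`
#' @return `path`, invisibly
#' @export
write_results <- function(records, path, format = c("assoc", "windows")) {
  format <- match.arg(format)
  if (format == "assoc") {
    out <- data.frame(CHR = records$chrom, SNP = records$id, BP = records$pos,
                      A1 = records$alt, A2 = records$ref,
                      FREQ = records$p_freq, BETA = records$b, SE = records$se,
                      P = records$p, Q = records$q)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    cols <- intersect(c("chrom", "start", "end", "n_snps", "stat", "source",
                        "outlier"), names(records))
    utils::write.table(records[cols], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    bed <- data.frame(chrom = records$chrom, start = records$start - 1L,
                      end = records$end)
    bedpath <- sub("\\.[^.]*$", ".bed", path)
    if (identical(bedpath, path)) bedpath <- paste0(path, ".bed")
    utils::write.table(bed, bedpath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
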