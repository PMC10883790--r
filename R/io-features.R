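## Gene/QTL interval tables. Internal representation is 0-based half-open
## [start, end); BED is already in that convention, GFF3 (1-based closed)
## and QTL TSVs (assumed 1-based closed, AnimalQTLdb-style) are converted at
## read time. Conversions happen only here, at the I/O boundary.

#' Read gene or QTL intervals into a feature table
#'
#' Accepts BED (0-based half-open), GFF3 (1-based closed; `gene` records are
#' kept), or a QTL TSV with columns `chrom`, `start`, `end`, `class`
#' (1-based closed). Format is chosen by file extension
#' (`.bed`, `.gff`/`.gff3`, else TSV).
#'
#' @param path input file
#' @param kind `"gene"` or `"qtl"`
#' @return data.frame of class `feature_table`: `chrom`, `start`, `end`
#'   (0-based half-open), `name`, `kind`, `class` (QTL class label or `NA`)
#' @export
read_features <- function(path, kind = c("gene", "qtl")) {
  kind <- match.arg(kind)
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    df <- as.data.frame(rtracklayer::import(path, format = "BED"))
    tab <- data.frame(chrom = as.character(df$seqnames),
                      start = df$start - 1L,  # GRanges is 1-based closed
                      end = df$end,
                      name = if (!is.null(df$name)) as.character(df$name)
                             else paste0("feat", seq_len(nrow(df))),
                      stringsAsFactors = FALSE)
  } else if (ext %in% c("gff", "gff3")) {
    df <- as.data.frame(rtracklayer::import(path, format = "GFF3"))
    if (any(df$type == "gene")) df <- df[df$type == "gene", , drop = FALSE]
    nm <- df$Name %||% df$ID %||% rep(NA_character_, nrow(df))
    tab <- data.frame(chrom = as.character(df$seqnames),
                      start = df$start - 1L,
                      end = df$end,
                      name = ifelse(is.na(nm) | !nzchar(nm),
                                    paste0("feat", seq_len(nrow(df))),
                                    as.character(nm)),
                      stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end")
    if (!all(need %in% names(tab)))
      stopf("TSV feature file needs columns %s", paste(need, collapse = ", "))
    bad <- which(tab$start > tab$end)
    if (length(bad)) stopf("start > end at line %d of %s", bad[1] + 1L, path)
    tab$start <- as.integer(tab$start) - 1L   # 1-based closed -> half-open
    tab$end <- as.integer(tab$end)
    if (is.null(tab$name)) tab$name <- paste0("feat", seq_len(nrow(tab)))
  }
  bad <- which(tab$start > tab$end)
  if (length(bad)) stopf("start > end at record %d of %s", bad[1], path)
  tab$kind <- kind
  if (is.null(tab$class)) tab$class <- NA_character_
  tab <- tab[c("chrom", "start", "end", "name", "kind", "class")]
  class(tab) <- c("feature_table", "data.frame")
  tab
}

#' Build a feature table in code
#'
#' @param chrom,start,end 1-based closed coordinates (converted internally
#'   to 0-based half-open, mirroring [read_features()]'s TSV path)
#' @param name,kind,class as in [read_features()]
#' @return `feature_table`
#' @export
feature_table <- function(chrom, start, end, name = NULL,
                          kind = "gene", class = NA_character_) {
  stopifnot(all(start <= end))
  tab <- data.frame(chrom = chrom, start = as.integer(start) - 1L,
                    end = as.integer(end),
                    name = name %||% paste0("feat", seq_along(chrom)),
                    kind = kind, class = class, stringsAsFactors = FALSE)
  class(tab) <- c("feature_table", "data.frame")
  tab
}
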