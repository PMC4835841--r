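#' Read a UCSC chrom.sizes table
#'
#' Two tab-separated columns, `name<TAB>length`, no header.
#'
#' @param path file path.
#' @param sort put categories in karyotypic order (default)?
#' @return a [gt_genome()].
#' @export
read_chrom_sizes <- function(path, sort = TRUE) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("name", "length"),
                          colClasses = c("character", "numeric"))
  gt_genome(df$name, length = df$length, sort = sort)
}

#' Write a chrom.sizes table
#' @param genome a [gt_genome()] with categories starting at 0.
#' @param path output path.
#' @export
write_chrom_sizes <- function(genome, path) {
  writeLines(sprintf("%s\t%s", genome$name,
                     format(genome$end - genome$start, scientific = FALSE,
                            trim = TRUE)),
             path)
  invisible(path)
}

bed_body_lines <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lines[keep]
}

#' Read a BED3+ file
#'
#' Tab-separated, 0-based half-open. `track`/`browser` lines and `#` comments
#' are skipped. Columns beyond the first three are kept as value columns
#' named `value1`, `value2`, ... with types inferred.
#'
#' @param path file path.
#' @return a normalized [gt_intervals()].
#' @export
read_bed <- function(path) {
  lines <- bed_body_lines(path)
  if (!length(lines)) return(empty_intervals())
  df <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED input needs at least 3 columns")
  names(df) <- c("category", "start", "end",
                 if (ncol(df) > 3) paste0("value", seq_len(ncol(df) - 3)))
  normalize_intervals(as_gt_intervals(df))
}

#' Read a bedGraph file
#'
#' Like [read_bed()] but requires exactly one numeric score column, which is
#' named `value`.
#'
#' @param path file path.
#' @return a normalized [gt_intervals()] with a `value` column.
#' @export
read_bedgraph <- function(path) {
  x <- read_bed(path)
  if (!"value1" %in% names(x) || !is.numeric(x$value1))
    stop("bedGraph input needs a numeric 4th column")
  names(x)[names(x) == "value1"] <- "value"
  x
}

#' Write intervals with one value column as bedGraph
#' @param x a `gt_intervals` (or data frame with category/start/end and a
#'   value column).
#' @param path output path.
#' @param value name of the value column (default `"value"`, falling back to
#'   `"fraction"` / `"mean"` if present).
#' @export
write_bedgraph <- function(x, path, value = NULL) {
  x <- as.data.frame(x)
  if (is.null(value))
    value <- intersect(c("value", "fraction", "mean"), names(x))[1]
  if (is.na(value) || is.null(value) || !value %in% names(x))
    stop("no value column to write")
  writeLines(sprintf("%s\t%s\t%s\t%s", x$category,
                     format(x$start, scientific = FALSE, trim = TRUE),
                     format(x$end, scientific = FALSE, trim = TRUE),
                     format(x[[value]], scientific = FALSE, trim = TRUE)),
             path)
  invisible(path)
}

#' Read a UCSC cytoBand.txt table
#'
#' Five tab-separated columns: `chrom start end band gieStain`,
#' 0-based half-open.
#'
#' @param path file path.
#' @return a normalized [gt_intervals()] with `band` and `stain` columns.
#' @export
read_cytoband <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("category", "start", "end",
                                        "band", "stain"),
                          colClasses = c("character", "numeric", "numeric",
                                         "character", "character"))
  normalize_intervals(as_gt_intervals(df))
}

#' Write a cytoband table
#' @param x intervals with `band` and `stain` columns.
#' @param path output path.
#' @export
write_cytoband <- function(x, path) {
  x <- as.data.frame(x)
  writeLines(sprintf("%s\t%s\t%s\t%s\t%s", x$category,
                     format(x$start, scientific = FALSE, trim = TRUE),
                     format(x$end, scientific = FALSE, trim = TRUE),
                     x$band, x$stain),
             path)
  invisible(path)
}

#' Write intervals as BED (optionally with a score column)
#' @param x a `gt_intervals`.
#' @param path output path.
#' @param score optional name of a numeric column written as BED column 5
#'   (column 4 becomes a running id).
#' @export
write_bed <- function(x, path, score = NULL) {
  x <- as.data.frame(x)
  s <- format(x$start, scientific = FALSE, trim = TRUE)
  e <- format(x$end, scientific = FALSE, trim = TRUE)
  if (is.null(score)) {
    writeLines(sprintf("%s\t%s\t%s", x$category, s, e), path)
  } else {
    writeLines(sprintf("%s\t%s\t%s\t%s\t%s", x$category, s, e,
                       paste0("r", seq_len(nrow(x))),
                       format(x[[score]], scientific = FALSE, trim = TRUE)),
               path)
  }
  invisible(path)
}

#' Path to the bundled human-genome chromosome sizes table
#'
#' A 24-row hg19-style `chrom.sizes` constants table used by the demos, so no
#' download is needed.
#'
#' @return file path inside the installed package.
#' @export
example_chrom_sizes <- function() {
  system.file("extdata", "hg19.chrom.sizes", package = "genotrellis",
              mustWork = TRUE)
}
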