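#' Sort category names in karyotypic order
#'
#' Chromosome-style names (with or without a `"chr"` prefix) are ordered by
#' natural numeric value, followed by X, then Y, then M/MT. Names outside this
#' scheme sort lexicographically after them. Ties are stable.
#'
#' @param names character vector of category names; must be non-empty.
#' @return `names`, reordered.
#' @examples
#' karyotypic_sort(c("chr2", "chr10", "chr1"))
#' karyotypic_sort(c("chrY", "chr22", "chrX"))
#' @export
karyotypic_sort <- function(names) {
  if (length(names) == 0) stop("'names' must be non-empty")
  names <- as.character(names)
  body <- sub("^chr", "", names)
  num <- suppressWarnings(as.numeric(body))
  up <- toupper(body)
  grp <- ifelse(!is.na(num), 0L,
         ifelse(up == "X", 1L,
         ifelse(up == "Y", 2L,
         ifelse(up %in% c("M", "MT"), 3L, 4L))))
  key_num <- ifelse(is.na(num), 0, num)
  key_str <- ifelse(grp == 4L, body, "")
  ord <- order(grp, key_num, key_str, seq_along(names), method = "radix")
  names[ord]
}

#' Define the genomic categories of a figure
#'
#' A genome, for plotting, is an ordered set of named categories, each with an
#' x-extent in base pairs. Categories are chromosomes `[0, length)` by
#' default, but any background region (e.g. a gene body) may be used, in
#' which case its x-axis keeps the native coordinates of the region.
#' Coordinates are 0-based, half-open throughout.
#'
#' @param name character vector of unique category names.
#' @param length numeric vector of category lengths in bp (categories start
#'   at 0). Mutually exclusive with `start`/`end`.
#' @param start,end numeric vectors giving explicit region extents
#'   (`end` exclusive) for background-region categories.
#' @param sort if `TRUE` (default), categories are put in karyotypic order;
#'   otherwise the given order is the plotting order.
#' @return a `gt_genome` data frame with columns `name`, `start`, `end`.
#' @examples
#' gt_genome(c("chr2", "chr1"), length = c(100, 200))
#' gt_genome("TP53", start = 7565097, end = 7590856)
#' @export
gt_genome <- function(name, length = NULL, start = NULL, end = NULL,
                      sort = TRUE) {
  name <- as.character(name)
  if (anyDuplicated(name)) stop("category names must be unique")
  if (!is.null(length)) {
    if (!is.null(start) || !is.null(end))
      stop("give either 'length' or 'start'/'end', not both")
    start <- rep(0, length(name))
    end <- as.numeric(length)
  }
  if (is.null(start) || is.null(end))
    stop("either 'length' or both 'start' and 'end' are required")
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(end <= start))
    stop("category extents must satisfy end > start")
  g <- data.frame(name = name, start = start, end = end,
                  stringsAsFactors = FALSE)
  if (sort) g <- g[match(karyotypic_sort(g$name), g$name), , drop = FALSE]
  rownames(g) <- NULL
  class(g) <- c("gt_genome", "data.frame")
  g
}

#' @export
print.gt_genome <- function(x, ...) {
  cat(sprintf("genome with %d categories (%s bp total)\n",
              nrow(x), format(sum(x$end - x$start), big.mark = ",")))
  print.data.frame(x, ...)
  invisible(x)
}

category_lengths <- function(genome) genome$end - genome$start

#' Construct a set of genomic intervals
#'
#' Intervals are 0-based, half-open `[start, end)` records on named
#' categories, with any number of extra value columns carried through
#' untouched (a strand column, if present, is just another value column).
#'
#' @param category character vector of category names.
#' @param start,end numeric vectors, `0 <= start < end` per record.
#' @param ... named value columns (numeric or character), recycled to the
#'   record count.
#' @return a `gt_intervals` data frame.
#' @examples
#' gt_intervals("chr1", c(10, 30), c(20, 40), value = c(1.5, 2.5))
#' @export
gt_intervals <- function(category, start, end, ...) {
  x <- data.frame(category = as.character(category),
                  start = as.numeric(start), end = as.numeric(end),
                  stringsAsFactors = FALSE)
  vals <- list(...)
  for (nm in names(vals)) x[[nm]] <- vals[[nm]]
  class(x) <- c("gt_intervals", "data.frame")
  check_intervals(x)
  x
}

#' Interpret a plain data frame as genomic intervals
#'
#' The first three columns are taken as category, start and end; remaining
#' columns become value columns.
#'
#' @param df a data frame.
#' @return a `gt_intervals` data frame.
#' @export
as_gt_intervals <- function(df) {
  if (inherits(df, "gt_intervals")) return(df)
  stopifnot(is.data.frame(df), ncol(df) >= 3)
  names(df)[1:3] <- c("category", "start", "end")
  df$category <- as.character(df$category)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  class(df) <- c("gt_intervals", "data.frame")
  check_intervals(df)
  df
}

check_intervals <- function(x) {
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad))
    stop(sprintf("invalid interval(s) at record(s) %s: need 0 <= start < end",
                 paste(utils::head(bad, 5), collapse = ", ")))
  invisible(x)
}

#' @export
print.gt_intervals <- function(x, ...) {
  cat(sprintf("%d genomic interval(s) on %d categorie(s)\n",
              nrow(x), length(unique(x$category))))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  invisible(x)
}

empty_intervals <- function(template = NULL) {
  if (is.null(template))
    return(gt_intervals(character(), numeric(), numeric()))
  template[0, , drop = FALSE]
}

#' Sort intervals into canonical order
#'
#' Records are sorted by (category, start, end); duplicates are preserved.
#' Records with `start >= end` are rejected with their index.
#'
#' @param x a `gt_intervals` object (or coercible data frame).
#' @return the sorted `gt_intervals`.
#' @export
normalize_intervals <- function(x) {
  x <- as_gt_intervals(x)
  ord <- order(x$category, x$start, x$end, method = "radix")
  x <- x[ord, , drop = FALSE]
  rownames(x) <- NULL
  attr(x, "normalized") <- TRUE
  x
}

is_normalized <- function(x) isTRUE(attr(x, "normalized"))

ensure_normalized <- function(x) {
  x <- as_gt_intervals(x)
  if (is_normalized(x)) x else normalize_intervals(x)
}

#' Extract the intervals belonging to one category
#'
#' Keeps records whose category name matches and that overlap the category's
#' extent. With `clip = TRUE` (the drawing default) record endpoints are
#' truncated to the extent; value columns pass through unchanged.
#'
#' @param x a `gt_intervals` object.
#' @param category one row of a [gt_genome()] (or a list with `name`,
#'   `start`, `end`).
#' @param clip truncate records to the category extent?
#' @return the subset as `gt_intervals` (possibly empty).
#' @export
subset_by_category <- function(x, category, clip = TRUE) {
  x <- ensure_normalized(x)
  cs <- as.numeric(category$start); ce <- as.numeric(category$end)
  keep <- x$category == category$name & x$start < ce & x$end > cs
  out <- x[keep, , drop = FALSE]
  if (clip && nrow(out)) {
    out$start <- pmax(out$start, cs)
    out$end <- pmin(out$end, ce)
  }
  rownames(out) <- NULL
  attr(out, "normalized") <- TRUE
  out
}

#' Merge overlapping and adjacent intervals
#'
#' Returns, per category, the minimal set of disjoint intervals with the same
#' per-base coverage footprint (coverage >= 1). Adjacent intervals
#' (`end == next start`) merge under the half-open convention. Value columns
#' are dropped.
#'
#' @param x a `gt_intervals` object.
#' @return merged `gt_intervals` sorted by (category, start).
#' @export
merge_overlaps <- function(x) {
  x <- ensure_normalized(x)
  if (nrow(x) == 0) return(empty_intervals())
  pieces <- lapply(split(seq_len(nrow(x)), x$category), function(idx) {
    # 0-based half-open [s, e) -> 1-based closed [s+1, e]; reduce() merges
    # overlapping and bookended ranges, which is exactly adjacency here
    ir <- IRanges::reduce(IRanges::IRanges(start = x$start[idx] + 1,
                                           end = x$end[idx]))
    data.frame(category = x$category[idx][1],
               start = IRanges::start(ir) - 1,
               end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces[order(names(pieces), method = "radix")])
  rownames(out) <- NULL
  class(out) <- c("gt_intervals", "data.frame")
  attr(out, "normalized") <- TRUE
  out
}
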