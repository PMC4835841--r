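#' Rainfall neighbor distances
#'
#' For each interval, the distance to its nearest neighboring interval on
#' the same category: intervals are sorted by start, the gap between
#' consecutive intervals is `max(next start - end, 0)` (overlapping or
#' touching neighbors give 0), and each interior interval takes the smaller
#' of its two flanking gaps while the first and last take their single gap.
#' Plotted at the interval midpoint against `log10` of the distance
#' (clamped at 1 bp to avoid minus infinity), clusters appear as low
#' "rainfalls".
#'
#' @param x a [gt_intervals()] (normalized internally).
#' @return data frame with `category`, `x` (midpoint bp), `dist` (bp) and
#'   `y` (`log10(max(dist, 1))`). Categories with a single interval
#'   contribute no rows.
#' @examples
#' iv <- gt_intervals("chr1", c(10, 30, 100), c(20, 40, 110))
#' rainfall(iv)
#' @export
rainfall <- function(x) {
  x <- ensure_normalized(x)
  pieces <- lapply(split(seq_len(nrow(x)), x$category), function(idx) {
    n <- length(idx)
    if (n < 2) return(NULL)
    s <- x$start[idx]; e <- x$end[idx]
    gap <- pmax(s[-1] - e[-n], 0)
    d <- if (n == 2) c(gap, gap)
         else c(gap[1], pmin(gap[-(n - 1)], gap[-1]), gap[n - 1])
    data.frame(category = x$category[idx][1], x = (s + e) / 2, dist = d,
               y = log10(pmax(d, 1)), stringsAsFactors = FALSE)
  })
  pieces <- Filter(Negate(is.null), pieces)
  if (!length(pieces))
    return(data.frame(category = character(), x = numeric(),
                      dist = numeric(), y = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, pieces[order(names(pieces), method = "radix")])
  rownames(out) <- NULL
  out
}

# non-overlapping tiling windows over a category extent; the last window is
# truncated at the category end
tile_windows <- function(cat_start, cat_end, w) {
  n_win <- ceiling((cat_end - cat_start) / w)
  starts <- cat_start + (seq_len(n_win) - 1) * w
  data.frame(start = starts, end = pmin(starts + w, cat_end))
}

# bp overlap of one merged-interval list with each tiling window, by
# arithmetic on window indices (integer-exact)
window_overlaps <- function(win, s, e) {
  covered <- numeric(nrow(win))
  if (length(s) == 0) return(covered)
  w0 <- win$start[1]
  wsz <- win$end[1] - win$start[1]      # nominal width (last may be shorter)
  for (i in seq_along(s)) {
    k0 <- max(floor((s[i] - w0) / wsz) + 1, 1)
    k1 <- min(ceiling((e[i] - w0) / wsz), nrow(win))
    if (k1 < k0) next
    kk <- k0:k1
    covered[kk] <- covered[kk] +
      pmax(pmin(e[i], win$end[kk]) - pmax(s[i], win$start[kk]), 0)
  }
  covered
}

#' Windowed genomic density
#'
#' Tiles each category with non-overlapping windows of `window_size` bp (the
#' last window truncated at the category end) and reports the fraction of
#' each window covered by the intervals, after merging overlaps. The
#' `covered` column holds the raw covered bases, so
#' `sum(covered)` equals the merged interval length per category exactly.
#'
#' @param x a [gt_intervals()].
#' @param window_size window width in bp (> 0).
#' @param genome a [gt_genome()] defining the categories to tile.
#' @return data frame with `category`, `start`, `end`, `covered` (bp) and
#'   `fraction` in `[0, 1]` (normalized by each window's actual width).
#' @examples
#' g <- gt_genome("chr1", length = 100)
#' iv <- gt_intervals("chr1", c(0, 40), c(10, 60))
#' genomic_density(iv, 50, g)
#' @export
genomic_density <- function(x, window_size, genome) {
  stopifnot(window_size > 0, inherits(genome, "gt_genome"))
  merged <- merge_overlaps(ensure_normalized(x))
  pieces <- lapply(seq_len(nrow(genome)), function(i) {
    cat <- genome[i, ]
    win <- tile_windows(cat$start, cat$end, window_size)
    sub <- subset_by_category(merged, cat, clip = TRUE)
    covered <- window_overlaps(win, sub$start, sub$end)
    data.frame(category = cat$name, start = win$start, end = win$end,
               covered = covered, fraction = covered / (win$end - win$start),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Coverage-weighted window means
#'
#' Tiles each category with `window_size` windows and reports, per window,
#' the mean of a value column over the overlapping records, weighted by each
#' record's overlap width (overlapping records each contribute their own
#' covered bases). Windows overlapped by no record get `NA`.
#'
#' @inheritParams genomic_density
#' @param value name of the numeric value column.
#' @return data frame with `category`, `start`, `end`, `mean`.
#' @export
window_means <- function(x, value = "value", window_size, genome) {
  stopifnot(window_size > 0, inherits(genome, "gt_genome"))
  x <- ensure_normalized(x)
  need_value(x, value)
  pieces <- lapply(seq_len(nrow(genome)), function(i) {
    cat <- genome[i, ]
    win <- tile_windows(cat$start, cat$end, window_size)
    sub <- subset_by_category(x, cat, clip = TRUE)
    num <- numeric(nrow(win)); den <- numeric(nrow(win))
    if (nrow(sub)) {
      w0 <- win$start[1]
      wsz <- window_size
      for (r in seq_len(nrow(sub))) {
        k0 <- max(floor((sub$start[r] - w0) / wsz) + 1, 1)
        k1 <- min(ceiling((sub$end[r] - w0) / wsz), nrow(win))
        if (k1 < k0) next
        kk <- k0:k1
        ov <- pmax(pmin(sub$end[r], win$end[kk]) -
                   pmax(sub$start[r], win$start[kk]), 0)
        num[kk] <- num[kk] + ov * sub[[value]][r]
        den[kk] <- den[kk] + ov
      }
    }
    data.frame(category = cat$name, start = win$start, end = win$end,
               mean = ifelse(den > 0, num / den, NA_real_),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Export rainfall points as BED with a score column
#' @param rf output of [rainfall()].
#' @param path output path.
#' @export
rainfall_to_bed <- function(rf, path) {
  pos <- floor(rf$x)
  df <- data.frame(category = rf$category, start = pos, end = pos + 1,
                   dist = rf$dist)
  write_bed(structure(df, class = c("gt_intervals", "data.frame")),
            path, score = "dist")
}

#' Export windowed density (or means) as bedGraph
#' @param dens output of [genomic_density()] or [window_means()].
#' @param path output path.
#' @export
density_to_bedgraph <- function(dens, path) {
  write_bedgraph(dens, path,
                 value = if ("fraction" %in% names(dens)) "fraction"
                         else "mean")
}
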