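#' Describe one data track
#'
#' A track is a horizontal band repeated across every category. Within each
#' category cell, tracks are stacked top-to-bottom in the order given and
#' their heights are proportional to `height`.
#'
#' @param height positive height weight (share of the category cell).
#' @param ylim data-space y-limits, `ylim[2] > ylim[1]`; defaults to the
#'   unit interval.
#' @param axis y-axis policy: `"none"`, `"left"` or `"right"`.
#' @param background optional background fill color for the track's panels.
#' @return a `gt_track_spec`.
#' @export
track_spec <- function(height = 1, ylim = c(0, 1), axis = c("none", "left",
                       "right"), background = NULL) {
  axis <- match.arg(axis)
  stopifnot(is.numeric(height), length(height) == 1, height > 0,
            is.numeric(ylim), length(ylim) == 2)
  if (!(ylim[2] > ylim[1])) stop("ylim[2] must exceed ylim[1]")
  structure(list(height = height, ylim = as.numeric(ylim), axis = axis,
                 background = background),
            class = "gt_track_spec")
}

LAYOUT_MODES <- c("one_row", "equal_width", "optimized_grid",
                  "proportional_grid", "compact")

#' Build a genome-level Trellis layout
#'
#' Computes the full figure geometry before any data are seen: a
#' category-to-(row, column) assignment, a panel rectangle for every
#' (category, track) pair, and the affine data-to-canvas transforms. Five
#' styles are available:
#'
#' * `one_row`: all categories in a single row, panel widths proportional to
#'   category length (the classic genome-wide style).
#' * `equal_width`: a standard Trellis grid; every cell has the same width
#'   and short categories leave trailing empty space. The only mode whose
#'   bp-to-canvas scale is not shared across all panels' cells.
#' * `optimized_grid`: categories of similar length share a column
#'   (sort by length descending, chunk into columns of `n_rows`), so far
#'   less space is wasted than in `equal_width`.
#' * `proportional_grid`: categories packed into `n_rows` rows at
#'   proportional widths (same packing as `compact`).
#' * `compact`: non-rectangular packing into at most `n_rows` rows with the
#'   smallest feasible row capacity, preserving karyotypic order; panels are
#'   not vertically aligned across rows.
#'
#' Except for `equal_width` cells, a single global scale (canvas units per
#' bp) is used so x-distances are comparable across panels.
#'
#' @param genome a [gt_genome()]; its order is the plotting order.
#' @param mode layout style, one of
#'   `"one_row"`, `"equal_width"`, `"optimized_grid"`,
#'   `"proportional_grid"`, `"compact"`.
#' @param n_rows,n_cols grid shape. Grid modes require
#'   `n_rows * n_cols >= number of categories` (defaults: near-square).
#'   `proportional_grid`/`compact` use `n_rows` only (default 1).
#' @param tracks an integer count (that many default [track_spec()]s) or a
#'   list of [track_spec()]s.
#' @param canvas_width,canvas_height canvas size in abstract units.
#' @param gap_x horizontal gap between panels, as a fraction of canvas width.
#' @param gap_y vertical gap between tracks within a cell, as a fraction of
#'   canvas height.
#' @param row_gap vertical gap between category rows, as a fraction of
#'   canvas height.
#' @param border draw panel borders when rendering?
#' @return a `gt_layout` object; see [layout_panels()],
#'   [as_layout_document()].
#' @examples
#' g <- gt_genome(c("chr1", "chr2"), length = c(200e6, 100e6))
#' ly <- trellis_layout(g, mode = "one_row", tracks = 2)
#' layout_panels(ly)
#' @export
trellis_layout <- function(genome, mode = LAYOUT_MODES, n_rows = NULL,
                           n_cols = NULL, tracks = 1, canvas_width = 800,
                           canvas_height = 400, gap_x = 0.01, gap_y = 0.005,
                           row_gap = 0.02, border = TRUE) {
  stopifnot(inherits(genome, "gt_genome"), nrow(genome) >= 1)
  mode <- match.arg(mode)
  tracks <- as_track_list(tracks)
  n_cat <- nrow(genome)
  lens <- category_lengths(genome)
  W <- canvas_width; H <- canvas_height
  gx <- gap_x * W

  if (mode %in% c("equal_width", "optimized_grid")) {
    if (is.null(n_cols)) n_cols <- ceiling(sqrt(n_cat))
    if (is.null(n_rows)) n_rows <- ceiling(n_cat / n_cols)
    if (n_rows * n_cols < n_cat)
      stop(sprintf("grid of %d x %d = %d cells cannot hold %d categories",
                   n_rows, n_cols, n_rows * n_cols, n_cat))
  }

  place <- switch(mode,
    one_row = place_one_row(genome, W, gx),
    equal_width = place_equal_width(genome, n_rows, n_cols, W, gx),
    optimized_grid = place_optimized(genome, n_rows, n_cols, W, gx),
    proportional_grid = ,
    compact = place_compact(genome, if (is.null(n_rows)) 1L else n_rows,
                            W, gx))

  asg <- place$assignment          # name,row,col,x0,x1,cell_x0,cell_x1
  rows_total <- max(asg$row)

  rg <- row_gap * H
  tg <- gap_y * H
  row_h <- (H - (rows_total - 1) * rg) / rows_total
  if (row_h <= 0) stop("canvas too small for the requested rows")
  n_tr <- length(tracks)
  shares <- vapply(tracks, `[[`, numeric(1), "height")
  inner <- row_h - (n_tr - 1) * tg
  if (inner <= 0) stop("canvas too small for the requested tracks")
  tr_h <- inner * shares / sum(shares)
  # y measured upward from the canvas bottom; row 1 is the top row
  row_top <- H - (asg$row - 1) * (row_h + rg)

  idx <- rep(seq_len(n_cat), each = n_tr)
  tri <- rep(seq_len(n_tr), times = n_cat)
  tr_top_off <- cumsum(c(0, utils::head(tr_h + tg, -1)))  # from cell top
  y1 <- row_top[idx] - tr_top_off[tri]
  y0 <- y1 - tr_h[tri]
  panels <- data.frame(
    category = genome$name[idx],
    track = tri,
    row = asg$row[idx], col = asg$col[idx],
    x0 = asg$x0[idx], x1 = asg$x1[idx],
    y0 = y0, y1 = y1,
    cell_x0 = asg$cell_x0[idx], cell_x1 = asg$cell_x1[idx],
    xlim0 = genome$start[idx], xlim1 = genome$end[idx],
    ylim0 = vapply(tracks, function(t) t$ylim[1], numeric(1))[tri],
    ylim1 = vapply(tracks, function(t) t$ylim[2], numeric(1))[tri],
    stringsAsFactors = FALSE)

  state <- new.env(parent = emptyenv())
  state$cursor <- 0L
  state$logs <- list()

  structure(list(genome = genome, mode = mode,
                 n_rows = rows_total,
                 n_cols = if (mode %in% c("equal_width", "optimized_grid"))
                            n_cols else max(table(asg$row)),
                 tracks = tracks, canvas = c(width = W, height = H),
                 gaps = c(gap_x = gap_x, gap_y = gap_y, row_gap = row_gap),
                 border = border, scale = place$scale,
                 assignment = asg, panels = panels, state = state),
            class = "gt_layout")
}

as_track_list <- function(tracks) {
  if (is.numeric(tracks) && length(tracks) == 1) {
    if (tracks < 1) stop("at least one track is required")
    return(replicate(as.integer(tracks), track_spec(), simplify = FALSE))
  }
  if (inherits(tracks, "gt_track_spec")) return(list(tracks))
  if (is.list(tracks) && length(tracks) >= 1 &&
      all(vapply(tracks, inherits, logical(1), "gt_track_spec")))
    return(tracks)
  stop("'tracks' must be a count or a list of track_spec()")
}

place_one_row <- function(genome, W, gx) {
  n <- nrow(genome)
  lens <- category_lengths(genome)
  scale <- (W - (n - 1) * gx) / sum(lens)
  if (scale <= 0) stop("canvas too narrow for the horizontal gaps")
  w <- lens * scale
  x0 <- cumsum(c(0, utils::head(w + gx, -1)))
  list(scale = scale,
       assignment = data.frame(name = genome$name, row = 1L,
                               col = seq_len(n), x0 = x0, x1 = x0 + w,
                               cell_x0 = x0, cell_x1 = x0 + w,
                               stringsAsFactors = FALSE))
}

place_equal_width <- function(genome, n_rows, n_cols, W, gx) {
  n <- nrow(genome)
  lens <- category_lengths(genome)
  cw <- (W - (n_cols - 1) * gx) / n_cols
  if (cw <= 0) stop("canvas too narrow for the horizontal gaps")
  scale <- cw / max(lens)    # longest category exactly fills its cell
  row <- ((seq_len(n) - 1) %/% n_cols) + 1L
  col <- ((seq_len(n) - 1) %% n_cols) + 1L
  cx0 <- (col - 1) * (cw + gx)
  list(scale = scale,
       assignment = data.frame(name = genome$name, row = row, col = col,
                               x0 = cx0, x1 = cx0 + lens * scale,
                               cell_x0 = cx0, cell_x1 = cx0 + cw,
                               stringsAsFactors = FALSE))
}

# sort by length descending, chunk into columns of n_rows; within a column,
# karyotypic (= genome) order top to bottom; one global scale over column maxima
assign_columns_optimized <- function(lengths, n_rows, n_cols) {
  n <- length(lengths)
  if (n_rows * n_cols < n)
    stop(sprintf("grid of %d x %d = %d cells cannot hold %d categories",
                 n_rows, n_cols, n_rows * n_cols, n))
  ord <- order(-lengths, seq_len(n))           # descending, stable
  col <- integer(n)
  col[ord] <- ((seq_len(n) - 1) %/% n_rows) + 1L
  row <- integer(n)
  for (cc in unique(col)) {
    members <- which(col == cc)                # already in genome order
    row[members] <- seq_along(members)
  }
  list(col = col, row = row,
       col_max = vapply(seq_len(max(col)),
                        function(cc) max(lengths[col == cc]), numeric(1)))
}

place_optimized <- function(genome, n_rows, n_cols, W, gx) {
  lens <- category_lengths(genome)
  a <- assign_columns_optimized(lens, n_rows, n_cols)
  n_used <- length(a$col_max)
  scale <- (W - (n_used - 1) * gx) / sum(a$col_max)
  if (scale <= 0) stop("canvas too narrow for the horizontal gaps")
  cw <- a$col_max * scale
  cx0 <- cumsum(c(0, utils::head(cw + gx, -1)))
  x0 <- cx0[a$col]
  list(scale = scale,
       assignment = data.frame(name = genome$name, row = a$row, col = a$col,
                               x0 = x0, x1 = x0 + lens * scale,
                               cell_x0 = x0, cell_x1 = cx0[a$col] + cw[a$col],
                               stringsAsFactors = FALSE))
}

# smallest capacity C such that greedy first-fit in the given order needs at
# most n_rows rows; C is bounded below by max(length) and the balanced mean
compact_capacity <- function(lengths, n_rows) {
  lo <- max(max(lengths), ceiling(sum(lengths) / n_rows))
  hi <- sum(lengths)
  feasible <- function(C) compact_pack(lengths, C)$n_rows <= n_rows
  while (lo < hi) {
    mid <- floor((lo + hi) / 2)
    if (feasible(mid)) hi <- mid else lo <- mid + 1
  }
  lo
}

compact_pack <- function(lengths, C) {
  row <- integer(length(lengths)); r <- 1L; acc <- 0
  for (i in seq_along(lengths)) {
    if (acc > 0 && acc + lengths[i] > C) { r <- r + 1L; acc <- 0 }
    row[i] <- r; acc <- acc + lengths[i]
  }
  list(row = row, n_rows = r)
}

place_compact <- function(genome, n_rows, W, gx) {
  stopifnot(n_rows >= 1)
  lens <- category_lengths(genome)
  C <- compact_capacity(lens, n_rows)
  pk <- compact_pack(lens, C)
  max_gaps <- max(tabulate(pk$row) - 1L)
  scale <- (W - max_gaps * gx) / C
  if (scale <= 0) stop("canvas too narrow for the horizontal gaps")
  x0 <- numeric(length(lens)); col <- integer(length(lens))
  for (r in unique(pk$row)) {
    members <- which(pk$row == r)
    w <- lens[members] * scale
    x0[members] <- cumsum(c(0, utils::head(w + gx, -1)))
    col[members] <- seq_along(members)
  }
  list(scale = scale, capacity = C,
       assignment = data.frame(name = genome$name, row = pk$row, col = col,
                               x0 = x0, x1 = x0 + lens * scale,
                               cell_x0 = x0, cell_x1 = x0 + lens * scale,
                               stringsAsFactors = FALSE))
}

#' Panel rectangles of a layout
#' @param layout a `gt_layout`.
#' @return data frame with one row per (category, track) panel: canvas
#'   rectangle (`x0`,`x1`,`y0`,`y1`; y upward), grid position, cell extent
#'   and data limits.
#' @export
layout_panels <- function(layout) layout$panels

#' Retrieve one panel
#' @param layout a `gt_layout`.
#' @param category category name or 1-based index (in plotting order).
#' @param track 1-based track index.
#' @return a one-row data frame from [layout_panels()].
#' @export
get_panel <- function(layout, category, track = 1L) {
  if (is.numeric(category)) {
    if (category < 1 || category > nrow(layout$genome))
      stop(sprintf("category index %d out of range 1..%d",
                   as.integer(category), nrow(layout$genome)))
    category <- layout$genome$name[as.integer(category)]
  }
  if (track < 1 || track > length(layout$tracks))
    stop(sprintf("track index %d out of range 1..%d",
                 as.integer(track), length(layout$tracks)))
  p <- layout$panels[layout$panels$category == category &
                     layout$panels$track == track, , drop = FALSE]
  if (nrow(p) != 1) stop(sprintf("unknown category '%s'", category))
  p
}

#' @export
print.gt_layout <- function(x, ...) {
  cat(sprintf(
    "Trellis layout: %d categories x %d tracks, mode '%s' (%d row(s))\n",
    nrow(x$genome), length(x$tracks), x$mode, x$n_rows))
  cat(sprintf("  canvas %g x %g, scale %.6g canvas units/bp\n",
              x$canvas["width"], x$canvas["height"], x$scale))
  cat(sprintf("  %d panels; %d draw-log entries so far\n",
              nrow(x$panels), length(x$state$logs)))
  invisible(x)
}

#' Map data coordinates into a panel's canvas rectangle
#'
#' The affine map sending `(xlim0, ylim0)` to the panel's lower-left corner
#' and `(xlim1, ylim1)` to its upper-right; y increases upward. Points
#' outside the limits map outside the rectangle (clipping is the painter's
#' job).
#'
#' @param panel one row of [layout_panels()].
#' @param x,y data coordinates (bp, data units), vectorized.
#' @return list with canvas `x` and `y`.
#' @export
data_to_canvas <- function(panel, x, y) {
  p <- as.list(panel)
  if (p$xlim1 <= p$xlim0 || p$ylim1 <= p$ylim0)
    stop("degenerate panel data limits")
  list(x = p$x0 + (x - p$xlim0) / (p$xlim1 - p$xlim0) * (p$x1 - p$x0),
       y = p$y0 + (y - p$ylim0) / (p$ylim1 - p$ylim0) * (p$y1 - p$y0))
}

#' Inverse of [data_to_canvas()]
#' @inheritParams data_to_canvas
#' @param u,v canvas coordinates.
#' @return list with data `x` and `y`.
#' @export
canvas_to_data <- function(panel, u, v) {
  p <- as.list(panel)
  if (p$x1 <= p$x0 || p$y1 <= p$y0) stop("degenerate panel rectangle")
  list(x = p$xlim0 + (u - p$x0) / (p$x1 - p$x0) * (p$xlim1 - p$xlim0),
       y = p$ylim0 + (v - p$y0) / (p$y1 - p$y0) * (p$ylim1 - p$ylim0))
}

#' Plan tick positions for a base-pair axis
#'
#' Ticks fall on "nice" multiples (1, 2 or 5 times a power of ten bp) with a
#' count as close as possible to `target_ticks`; labels are in megabases with
#' an `MB` suffix. First and last tick lie within `xlim`.
#'
#' @param xlim numeric length-2, `xlim[2] > xlim[1]` (bp).
#' @param target_ticks desired number of ticks.
#' @return list with `at` (bp positions), `labels`, and `spacing` (bp).
#' @export
plan_x_axis <- function(xlim, target_ticks = 3) {
  stopifnot(length(xlim) == 2, xlim[2] > xlim[1])
  span <- xlim[2] - xlim[1]
  k <- floor(log10(span))
  cand <- sort(unique(as.vector(outer(c(1, 2, 5), 10^((k - 2):(k + 1))))))
  best <- NULL; best_score <- Inf
  for (s in cand) {
    lo <- ceiling(xlim[1] / s) * s; hi <- floor(xlim[2] / s) * s
    if (hi < lo + s) next
    at <- seq(lo, hi, by = s)
    n <- length(at)
    score <- abs(n - target_ticks)
    if (score < best_score ||
        (score == best_score && !is.null(best) && s > best$spacing)) {
      best <- list(at = at, spacing = s); best_score <- score
    }
  }
  if (is.null(best)) {     # span too small for two nice ticks
    best <- list(at = xlim, spacing = span)
  }
  mb <- best$at / 1e6
  best$labels <- paste0(trimws(formatC(mb, format = "fg", digits = 15,
                                       big.mark = "")), "MB")
  best
}

#' Export the layout geometry as a plain document
#'
#' Serializes everything an external renderer needs: categories, grid
#' assignment, per-panel rectangles with data limits, scale and canvas.
#'
#' @param layout a `gt_layout`.
#' @return a nested list, ready for JSON serialization.
#' @seealso [write_layout_json()]
#' @export
as_layout_document <- function(layout) {
  g <- layout$genome
  list(mode = layout$mode,
       canvas = list(width = unname(layout$canvas["width"]),
                     height = unname(layout$canvas["height"])),
       scale = layout$scale,
       n_rows = layout$n_rows,
       n_tracks = length(layout$tracks),
       categories = lapply(seq_len(nrow(g)), function(i)
         list(name = g$name[i], start = g$start[i], end = g$end[i])),
       tracks = lapply(layout$tracks, function(t)
         list(height = t$height, ylim = t$ylim, axis = t$axis)),
       assignment = lapply(seq_len(nrow(layout$assignment)), function(i) {
         a <- layout$assignment[i, ]
         list(name = a$name, row = a$row, col = a$col,
              x0 = a$x0, x1 = a$x1, cell_x0 = a$cell_x0, cell_x1 = a$cell_x1)
       }),
       panels = lapply(seq_len(nrow(layout$panels)), function(i) {
         p <- layout$panels[i, ]
         list(category = p$category, track = p$track,
              row = p$row, col = p$col,
              rect = c(p$x0, p$y0, p$x1, p$y1),
              xlim = c(p$xlim0, p$xlim1), ylim = c(p$ylim0, p$ylim1))
       }))
}

#' Write the layout geometry document as JSON
#' @param layout a `gt_layout`.
#' @param path output path.
#' @export
write_layout_json <- function(layout, path) {
  json <- jsonlite::toJSON(as_layout_document(layout), auto_unbox = TRUE,
                           digits = 8, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}
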