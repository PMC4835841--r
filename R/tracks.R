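#' Add graphics to one track, panel by panel
#'
#' The panel function is invoked exactly once per category, in plotting
#' order. Each invocation receives a panel context and the clipped
#' per-category subset of `data` (empty where the category has no records).
#' Without an explicit `track`, successive calls fill tracks 1, 2, 3, ...
#'
#' The panel context `ctx` is a list with `category` (name, start, end),
#' `track`, `xlim`, `ylim`, `rect` (the panel's canvas rectangle) and
#' `painter`, whose members `points(x, y, style)`,
#' `polyline(x, y, style)`, `rect(x0, y0, x1, y1, style)`,
#' `segments(x0, y0, x1, y1, style)` and `text(x, y, label, style)` take
#' data-space coordinates and clip everything to the panel.
#'
#' @param layout a `gt_layout`.
#' @param data optional [gt_intervals()] (or coercible data frame).
#' @param panel_fun `function(ctx, subset)`.
#' @param track optional explicit 1-based track index; overrides (and
#'   resets) the cursor.
#' @return the layout, invisibly (its cursor and draw log are updated).
#' @examples
#' g <- gt_genome(c("chr1", "chr2"), length = c(100, 50))
#' ly <- trellis_layout(g, tracks = 1)
#' iv <- gt_intervals("chr1", 10, 20, value = 0.5)
#' add_track(ly, iv, function(ctx, d) {
#'   if (nrow(d)) ctx$painter$points((d$start + d$end) / 2, d$value)
#' })
#' primitive_count(ly)
#' @export
add_track <- function(layout, data = NULL, panel_fun, track = NULL) {
  stopifnot(inherits(layout, "gt_layout"), is.function(panel_fun))
  n_tr <- length(layout$tracks)
  st <- layout$state
  if (is.null(track)) {
    if (st$cursor >= n_tr)
      stop(sprintf("all %d tracks filled; pass an explicit 'track' to overplot",
                   n_tr))
    track <- st$cursor + 1L
  } else {
    track <- as.integer(track)
    if (track < 1 || track > n_tr)
      stop(sprintf("track index %d out of range 1..%d", track, n_tr))
  }
  if (!is.null(data)) data <- ensure_normalized(data)
  for (i in seq_len(nrow(layout$genome))) {
    run_panel(layout, i, track, panel_fun, data)
  }
  st$cursor <- track
  invisible(layout)
}

run_panel <- function(layout, category_index, track, panel_fun, data) {
  cat_row <- layout$genome[category_index, ]
  category <- list(name = cat_row$name, start = cat_row$start,
                   end = cat_row$end)
  subset <- if (is.null(data)) empty_intervals()
            else subset_by_category(data, category, clip = TRUE)
  panel <- get_panel(layout, category$name, track)
  ctx <- list(category = category, track = track,
              xlim = c(panel$xlim0, panel$xlim1),
              ylim = c(panel$ylim0, panel$ylim1),
              rect = c(x0 = panel$x0, y0 = panel$y0,
                       x1 = panel$x1, y1 = panel$y1),
              painter = make_painter(layout, panel))
  withCallingHandlers(
    panel_fun(ctx, subset),
    error = function(e)
      stop(sprintf("panel function failed in category '%s', track %d: %s",
                   category$name, track, conditionMessage(e)),
           call. = FALSE))
  invisible(NULL)
}

#' Add graphics to a single panel
#'
#' Applies the panel function to exactly one (category, track) panel,
#' leaving the track cursor untouched. Calling it twice over-plots.
#'
#' @param layout a `gt_layout`.
#' @param category_index 1-based category index (plotting order) or name.
#' @param track_index 1-based track index.
#' @param panel_fun `function(ctx, subset)`, as in [add_track()].
#' @param data optional intervals; the panel receives its clipped subset.
#' @return the layout, invisibly.
#' @export
add_track_single <- function(layout, category_index, track_index, panel_fun,
                             data = NULL) {
  stopifnot(inherits(layout, "gt_layout"), is.function(panel_fun))
  n_cat <- nrow(layout$genome)
  if (is.character(category_index))
    category_index <- match(category_index, layout$genome$name)
  if (is.na(category_index) || category_index < 1 || category_index > n_cat)
    stop(sprintf("category index out of range 1..%d", n_cat))
  track_index <- as.integer(track_index)
  if (track_index < 1 || track_index > length(layout$tracks))
    stop(sprintf("track index %d out of range 1..%d", track_index,
                 length(layout$tracks)))
  if (!is.null(data)) data <- ensure_normalized(data)
  run_panel(layout, as.integer(category_index), track_index, panel_fun, data)
  invisible(layout)
}

resolve_positions <- function(d, position) {
  if (position == "midpoint") (d$start + d$end) / 2 else d$start
}

need_value <- function(d, value) {
  if (!value %in% names(d))
    stop(sprintf("value column '%s' not found in the data", value))
  d[[value]]
}

#' Built-in points track
#'
#' Draws one marker per record at (position, value), where position is the
#' interval midpoint (default) or start.
#'
#' @param layout a `gt_layout`.
#' @param data intervals with a numeric value column.
#' @param value name of the value column.
#' @param position `"midpoint"` or `"start"`.
#' @param track optional explicit track index.
#' @param style list of style keys (e.g. `col`, `size`) attached to the
#'   primitives.
#' @return the layout, invisibly.
#' @export
add_points_track <- function(layout, data, value = "value",
                             position = c("midpoint", "start"),
                             track = NULL, style = list()) {
  position <- match.arg(position)
  data <- ensure_normalized(data)
  need_value(data, value)
  add_track(layout, data, track = track, panel_fun = function(ctx, d) {
    if (nrow(d) == 0) return(invisible(NULL))
    ctx$painter$points(resolve_positions(d, position), d[[value]],
                       style = style)
  })
}

#' Built-in lines track
#'
#' Draws a polyline through (midpoint, value) in x order per category; a
#' single record degenerates to a dot. With `area = TRUE` the area between
#' the curve and the track's lower y-limit is filled.
#'
#' @inheritParams add_points_track
#' @param area fill the area under the curve?
#' @export
add_lines_track <- function(layout, data, value = "value",
                            position = c("midpoint", "start"),
                            area = FALSE, track = NULL, style = list()) {
  position <- match.arg(position)
  data <- ensure_normalized(data)
  need_value(data, value)
  add_track(layout, data, track = track, panel_fun = function(ctx, d) {
    if (nrow(d) == 0) return(invisible(NULL))
    x <- resolve_positions(d, position)
    ord <- order(x)
    x <- x[ord]; v <- d[[value]][ord]
    if (length(x) == 1) {
      ctx$painter$points(x, v, style = style)
    } else {
      st <- style
      if (area) { st$area <- TRUE; st$baseline <- ctx$ylim[1] }
      ctx$painter$polyline(x, v, style = st)
    }
  })
}

#' Built-in rectangles track
#'
#' One axis-aligned rectangle `[start, end] x [y0, y1]` per record, painted
#' in record order (later records on top).
#'
#' @inheritParams add_points_track
#' @param y0,y1 numeric constants or names of value columns giving the
#'   vertical extent of each rectangle.
#' @param fill a single color, a vector/column name of colors, or a
#'   `function(d)` returning one color per record.
#' @export
add_rect_track <- function(layout, data, y0 = 0, y1 = 1, fill = "grey",
                           track = NULL, style = list()) {
  data <- ensure_normalized(data)
  col_or_const <- function(d, v)
    if (is.character(v) && length(v) == 1 && v %in% names(d)) d[[v]]
    else v
  add_track(layout, data, track = track, panel_fun = function(ctx, d) {
    if (nrow(d) == 0) return(invisible(NULL))
    f <- if (is.function(fill)) fill(d) else col_or_const(d, fill)
    st <- style; st$fill <- f
    ctx$painter$rect(d$start, col_or_const(d, y0),
                     d$end, col_or_const(d, y1), style = st)
  })
}

#' Built-in horizontal-segments track
#'
#' One horizontal segment from start to end at height `value` per record;
#' segments of zero length after clipping are dropped.
#'
#' @inheritParams add_points_track
#' @export
add_segments_track <- function(layout, data, value = "value", track = NULL,
                               style = list()) {
  data <- ensure_normalized(data)
  need_value(data, value)
  add_track(layout, data, track = track, panel_fun = function(ctx, d) {
    if (nrow(d) == 0) return(invisible(NULL))
    ctx$painter$segments(d$start, d[[value]], d$end, d[[value]],
                         style = style)
  })
}

#' Built-in heatmap track
#'
#' The track is divided vertically into equal bands, one per value series;
#' each record paints one cell `[start, end] x band` per series, colored by
#' the color map. With a single series this reduces to a colored rectangle
#' track.
#'
#' @inheritParams add_points_track
#' @param values character vector of value-column names (the series), or a
#'   numeric matrix with one row per record.
#' @param colormap `function(values) -> colors`; see [colormap_linear()].
#' @param series_order optional permutation of the series, bottom band
#'   first (default: given order, bottom to top).
#' @export
add_heatmap_track <- function(layout, data, values,
                              colormap = colormap_sequential(),
                              series_order = NULL, track = NULL,
                              style = list()) {
  data <- ensure_normalized(data)
  if (is.matrix(values)) {
    if (nrow(values) != nrow(data))
      stop("value matrix must have one row per record")
    mat <- values
    colnames(mat) <- colnames(mat) %||% paste0("s", seq_len(ncol(mat)))
    for (j in seq_len(ncol(mat))) data[[colnames(mat)[j]]] <- mat[, j]
    series <- colnames(mat)
  } else {
    series <- as.character(values)
    missing <- setdiff(series, names(data))
    if (length(missing))
      stop(sprintf("value column(s) missing: %s",
                   paste(missing, collapse = ", ")))
    for (s in series)
      if (anyNA(data[[s]]) || !is.numeric(data[[s]]))
        stop(sprintf("series '%s' must be complete and numeric (ragged matrix)",
                     s))
  }
  k <- length(series)
  if (!is.null(series_order)) {
    stopifnot(length(series_order) == k)
    series <- series[series_order]
  }
  add_track(layout, data, track = track, panel_fun = function(ctx, d) {
    if (nrow(d) == 0) return(invisible(NULL))
    yl <- ctx$ylim
    band_h <- (yl[2] - yl[1]) / k
    for (j in seq_len(k)) {
      st <- style
      st$fill <- colormap(d[[series[j]]])
      ctx$painter$rect(d$start, yl[1] + (j - 1) * band_h,
                       d$end, yl[1] + j * band_h, style = st)
    }
  })
}

#' Built-in category-name track
#'
#' One centered text label per category.
#'
#' @inheritParams add_points_track
#' @param strip_chr drop a leading `"chr"` from the label?
#' @export
add_name_track <- function(layout, strip_chr = FALSE, track = NULL,
                           style = list()) {
  add_track(layout, NULL, track = track, panel_fun = function(ctx, d) {
    lab <- ctx$category$name
    if (strip_chr) lab <- sub("^chr", "", lab)
    ctx$painter$text((ctx$xlim[1] + ctx$xlim[2]) / 2,
                     (ctx$ylim[1] + ctx$ylim[2]) / 2, lab,
                     style = c(style, list(anchor = "center")))
  })
}

#' Giemsa stain fill colors
#'
#' Standard cytogenetic-band coloring: `gneg` white, `gpos25`..`gpos100`
#' greys of increasing darkness, `acen` red, `gvar` light grey, `stalk`
#' dark grey. Unknown stains fall back to mid grey with a warning.
#'
#' @param stain character vector of gieStain codes.
#' @return vector of hex colors.
#' @export
stain_color <- function(stain) {
  map <- c(gneg = "#FFFFFF", gpos25 = "#BFBFBF", gpos50 = "#808080",
           gpos75 = "#404040", gpos100 = "#000000", acen = "#D92F27",
           gvar = "#DCDCDC", stalk = "#666666")
  out <- unname(map[stain])
  if (anyNA(out)) {
    warning(sprintf("unknown gieStain value(s): %s; using grey",
                    paste(unique(stain[is.na(out)]), collapse = ", ")))
    out[is.na(out)] <- "#969696"
  }
  out
}

#' Built-in ideogram track
#'
#' Draws each cytogenetic band as a filled rectangle colored by its Giemsa
#' stain, clipped to the category extent, with an outline around the whole
#' ideogram.
#'
#' @inheritParams add_points_track
#' @param cytobands intervals with a `stain` value column (see
#'   [read_cytoband()]).
#' @export
add_ideogram_track <- function(layout, cytobands, track = NULL,
                               style = list()) {
  cytobands <- ensure_normalized(cytobands)
  need_value(cytobands, "stain")
  add_track(layout, cytobands, track = track, panel_fun = function(ctx, d) {
    yl <- ctx$ylim
    pad <- 0.15 * (yl[2] - yl[1])
    if (nrow(d)) {
      st <- style; st$fill <- stain_color(d$stain)
      ctx$painter$rect(d$start, yl[1] + pad, d$end, yl[2] - pad, style = st)
    }
    ctx$painter$rect(ctx$category$start, yl[1] + pad,
                     ctx$category$end, yl[2] - pad,
                     style = list(fill = NA, col = "#000000"))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Linear color map between anchor colors
#'
#' Values are mapped linearly onto `breaks` (clamping outside the range) and
#' interpolated between the anchor colors in RGB space.
#'
#' @param breaks increasing numeric anchors.
#' @param colors one color per anchor.
#' @return `function(values) -> hex colors`.
#' @export
colormap_linear <- function(breaks, colors) {
  stopifnot(length(breaks) == length(colors), length(breaks) >= 2,
            !is.unsorted(breaks, strictly = TRUE))
  ramp <- grDevices::colorRamp(colors, space = "rgb")
  lo <- breaks[1]; hi <- breaks[length(breaks)]
  # map breaks onto [0,1] piecewise-linearly so interior anchors land on
  # their colors exactly
  anchor_t <- seq(0, 1, length.out = length(breaks))
  function(values) {
    v <- pmin(pmax(as.numeric(values), lo), hi)
    t <- stats::approx(breaks, anchor_t, xout = v, rule = 2)$y
    m <- ramp(t)
    grDevices::rgb(m[, 1], m[, 2], m[, 3], maxColorValue = 255)
  }
}

#' Default diverging blue-white-red color map
#' @param limits numeric length-2 value range; the midpoint maps to white.
#' @return a color map function.
#' @export
colormap_divergent <- function(limits = c(-1, 1)) {
  colormap_linear(c(limits[1], mean(limits), limits[2]),
                  c("#2166AC", "#FFFFFF", "#B2182B"))
}

#' Default sequential white-to-dark color map
#' @param limits numeric length-2 value range.
#' @return a color map function.
#' @export
colormap_sequential <- function(limits = c(0, 1)) {
  colormap_linear(limits, c("#FFFFFF", "#08306B"))
}
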