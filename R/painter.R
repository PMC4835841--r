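# Panel painters record primitives into the layout's draw log. Clipping is
# done geometrically in DATA space (against the panel's xlim/ylim), so the
# logged data-space geometry of a track is identical across layout modes and
# the canvas-space geometry differs only by the panel's affine transform.

panel_key <- function(category, track) paste0(category, "\r", track)

# Liang-Barsky segment clip against [xlim] x [ylim]; NULL if fully outside
clip_segment <- function(x0, y0, x1, y1, xlim, ylim) {
  dx <- x1 - x0; dy <- y1 - y0
  p <- c(-dx, dx, -dy, dy)
  q <- c(x0 - xlim[1], xlim[2] - x0, y0 - ylim[1], ylim[2] - y0)
  t0 <- 0; t1 <- 1
  for (k in 1:4) {
    if (p[k] == 0) {
      if (q[k] < 0) return(NULL)
    } else {
      r <- q[k] / p[k]
      if (p[k] < 0) {
        if (r > t1) return(NULL)
        if (r > t0) t0 <- r
      } else {
        if (r < t0) return(NULL)
        if (r < t1) t1 <- r
      }
    }
  }
  c(x0 + t0 * dx, y0 + t0 * dy, x0 + t1 * dx, y0 + t1 * dy)
}

# clip an open polyline, returning a list of pieces (each >= 2 vertices)
clip_polyline <- function(x, y, xlim, ylim) {
  pieces <- list(); cur_x <- numeric(0); cur_y <- numeric(0)
  flush <- function() {
    if (length(cur_x) >= 2)
      pieces[[length(pieces) + 1]] <<- list(x = cur_x, y = cur_y)
    cur_x <<- numeric(0); cur_y <<- numeric(0)
  }
  for (i in seq_len(length(x) - 1)) {
    seg <- clip_segment(x[i], y[i], x[i + 1], y[i + 1], xlim, ylim)
    if (is.null(seg)) { flush(); next }
    if (length(cur_x) == 0) {
      cur_x <- seg[c(1, 3)]; cur_y <- seg[c(2, 4)]
    } else if (isTRUE(all.equal(c(cur_x[length(cur_x)],
                                  cur_y[length(cur_y)]),
                                seg[1:2], tolerance = 1e-12))) {
      cur_x <- c(cur_x, seg[3]); cur_y <- c(cur_y, seg[4])
    } else {
      flush(); cur_x <- seg[c(1, 3)]; cur_y <- seg[c(2, 4)]
    }
  }
  flush()
  pieces
}

make_painter <- function(layout, panel) {
  state <- layout$state
  key <- panel_key(panel$category, panel$track)
  xlim <- c(panel$xlim0, panel$xlim1)
  ylim <- c(panel$ylim0, panel$ylim1)
  t2c <- function(x, y) data_to_canvas(panel, x, y)
  log_entry <- function(entry) {
    entry$category <- panel$category
    entry$track <- panel$track
    if (is.null(state$logs[[key]])) state$logs[[key]] <- list()
    state$logs[[key]][[length(state$logs[[key]]) + 1]] <- entry
    invisible(NULL)
  }

  list(
    points = function(x, y, style = list()) {
      n <- max(length(x), length(y))
      x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
      vis <- x >= xlim[1] & x <= xlim[2] & y >= ylim[1] & y <= ylim[2]
      cc <- t2c(x[vis], y[vis])
      log_entry(list(type = "points", n = n,
                     data = list(x = x, y = y), visible = vis,
                     canvas = list(x = cc$x, y = cc$y), style = style))
    },
    polyline = function(x, y, style = list()) {
      n <- max(length(x), length(y))
      x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
      pieces <- if (n >= 2) clip_polyline(x, y, xlim, ylim) else list()
      canvas <- lapply(pieces, function(p) t2c(p$x, p$y))
      entry <- list(type = "polyline", n = 1L,
                    data = list(x = x, y = y),
                    visible = length(canvas) > 0,
                    canvas = canvas, style = style)
      if (isTRUE(style$area)) {
        base <- min(max(style$baseline %||% ylim[1], ylim[1]), ylim[2])
        entry$baseline_canvas <- t2c(xlim[1], base)$y
      }
      log_entry(entry)
    },
    rect = function(x0, y0, x1, y1, style = list()) {
      n <- max(length(x0), length(y0), length(x1), length(y1))
      x0 <- rep_len(as.numeric(x0), n); y0 <- rep_len(as.numeric(y0), n)
      x1 <- rep_len(as.numeric(x1), n); y1 <- rep_len(as.numeric(y1), n)
      styl <- lapply(style, function(s)
        if (length(s) > 1) rep_len(s, n) else s)
      cx0 <- pmax(pmin(x0, x1), xlim[1]); cx1 <- pmin(pmax(x0, x1), xlim[2])
      cy0 <- pmax(pmin(y0, y1), ylim[1]); cy1 <- pmin(pmax(y0, y1), ylim[2])
      vis <- cx0 < cx1 & cy0 < cy1
      a <- t2c(cx0[vis], cy0[vis]); b <- t2c(cx1[vis], cy1[vis])
      log_entry(list(type = "rect", n = n,
                     data = list(x0 = x0, y0 = y0, x1 = x1, y1 = y1),
                     visible = vis,
                     canvas = list(x0 = a$x, y0 = a$y, x1 = b$x, y1 = b$y),
                     style = styl))
    },
    segments = function(x0, y0, x1, y1, style = list()) {
      n <- max(length(x0), length(y0), length(x1), length(y1))
      x0 <- rep_len(as.numeric(x0), n); y0 <- rep_len(as.numeric(y0), n)
      x1 <- rep_len(as.numeric(x1), n); y1 <- rep_len(as.numeric(y1), n)
      clipped <- lapply(seq_len(n), function(i)
        clip_segment(x0[i], y0[i], x1[i], y1[i], xlim, ylim))
      vis <- !vapply(clipped, is.null, logical(1))
      canvas <- lapply(clipped[vis], function(s) {
        a <- t2c(s[1], s[2]); b <- t2c(s[3], s[4])
        c(a$x, a$y, b$x, b$y)
      })
      log_entry(list(type = "segment", n = n,
                     data = list(x0 = x0, y0 = y0, x1 = x1, y1 = y1),
                     visible = vis, canvas = canvas, style = style))
    },
    text = function(x, y, label, style = list()) {
      n <- max(length(x), length(y), length(label))
      x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
      label <- rep_len(as.character(label), n)
      vis <- x >= xlim[1] & x <= xlim[2] & y >= ylim[1] & y <= ylim[2]
      cc <- t2c(x[vis], y[vis])
      log_entry(list(type = "text", n = n,
                     data = list(x = x, y = y, label = label), visible = vis,
                     canvas = list(x = cc$x, y = cc$y), style = style))
    })
}

#' Inspect the draw log of a layout
#'
#' Every painter call is recorded as one log entry (primitive type, data
#' coordinates, clipped canvas geometry, style) before any rendering; the log
#' is the principal test surface of the package.
#'
#' @param layout a `gt_layout`.
#' @param category optional category name to filter on.
#' @param track optional track index to filter on.
#' @return a list of log entries.
#' @export
draw_log <- function(layout, category = NULL, track = NULL) {
  entries <- unlist(unname(layout$state$logs), recursive = FALSE)
  if (is.null(entries)) entries <- list()
  if (!is.null(category))
    entries <- Filter(function(e) e$category == category, entries)
  if (!is.null(track))
    entries <- Filter(function(e) e$track == track, entries)
  entries
}

#' Count logged primitives
#'
#' Markers, rectangles, segments and text labels count individually;
#' a polyline counts once.
#'
#' @inheritParams draw_log
#' @param type optional primitive type
#'   (`"points"`, `"polyline"`, `"rect"`, `"segment"`, `"text"`).
#' @return integer count.
#' @export
primitive_count <- function(layout, category = NULL, track = NULL,
                            type = NULL) {
  entries <- draw_log(layout, category, track)
  if (!is.null(type)) entries <- Filter(function(e) e$type == type, entries)
  sum(vapply(entries, function(e) as.integer(e$n), integer(1)))
}
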