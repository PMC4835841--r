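# SVG renderer: serializes the draw log with deterministic element order
# and fixed 3-decimal coordinate precision, so the same layout + tracks
# always produce byte-identical output. Canvas y (upward) is flipped to SVG
# y (downward) here.

fmt <- function(x) sprintf("%.3f", x)

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

style_attr <- function(style, i, key, default) {
  v <- style[[key]]
  if (is.null(v)) return(default)
  if (length(v) > 1) v[[min(i, length(v))]] else v
}

#' Render a layout's draw log to SVG
#'
#' Panels are emitted in (category, track) order, each inside a group
#' clipped to its panel rectangle; primitives keep their painter order.
#' Panel borders, track backgrounds and megabase x-axis labels under each
#' category's bottom track are drawn when enabled on the layout.
#'
#' @param layout a `gt_layout` with tracks already added.
#' @param path output `.svg` path.
#' @param axis_ticks target tick count for the per-category x-axis.
#' @return `path`, invisibly.
#' @export
render_svg <- function(layout, path, axis_ticks = 2) {
  W <- unname(layout$canvas["width"]); H <- unname(layout$canvas["height"])
  flip <- function(y) H - y
  out <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                          'width="%s" height="%s" viewBox="0 0 %s %s">'),
                   fmt(W), fmt(H), fmt(W), fmt(H)),
           sprintf('<rect x="0" y="0" width="%s" height="%s" fill="#FFFFFF"/>',
                   fmt(W), fmt(H)))

  panels <- layout$panels
  ord <- order(match(panels$category, layout$genome$name), panels$track)
  panels <- panels[ord, , drop = FALSE]

  # clip paths
  out <- c(out, "<defs>")
  for (i in seq_len(nrow(panels))) {
    p <- panels[i, ]
    out <- c(out, sprintf(
      '<clipPath id="clip%d"><rect x="%s" y="%s" width="%s" height="%s"/></clipPath>',
      i, fmt(p$x0), fmt(flip(p$y1)), fmt(p$x1 - p$x0), fmt(p$y1 - p$y0)))
  }
  out <- c(out, "</defs>")

  for (i in seq_len(nrow(panels))) {
    p <- panels[i, ]
    spec <- layout$tracks[[p$track]]
    out <- c(out, sprintf('<g clip-path="url(#clip%d)">', i))
    if (!is.null(spec$background))
      out <- c(out, sprintf(
        '<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
        fmt(p$x0), fmt(flip(p$y1)), fmt(p$x1 - p$x0), fmt(p$y1 - p$y0),
        spec$background))
    entries <- layout$state$logs[[panel_key(p$category, p$track)]]
    for (e in entries %||% list()) out <- c(out, svg_entry(e, flip))
    out <- c(out, "</g>")
    if (isTRUE(layout$border))
      out <- c(out, sprintf(
        '<rect x="%s" y="%s" width="%s" height="%s" fill="none" stroke="#999999" stroke-width="0.5"/>',
        fmt(p$x0), fmt(flip(p$y1)), fmt(p$x1 - p$x0), fmt(p$y1 - p$y0)))
    if (p$track == length(layout$tracks))
      out <- c(out, svg_x_axis(layout, p, flip, axis_ticks))
  }
  out <- c(out, "</svg>")
  writeLines(out, path)
  invisible(path)
}

svg_entry <- function(e, flip) {
  out <- character(0)
  if (e$type == "points") {
    r <- 1.6 * as.numeric(style_attr(e$style, 1, "size", 1))
    col <- style_attr(e$style, 1, "col", "#000000")
    xs <- e$canvas$x; ys <- e$canvas$y
    for (j in seq_along(xs))
      out <- c(out, sprintf('<circle cx="%s" cy="%s" r="%s" fill="%s"/>',
                            fmt(xs[j]), fmt(flip(ys[j])), fmt(r), col))
  } else if (e$type == "polyline") {
    col <- style_attr(e$style, 1, "col", "#000000")
    for (piece in e$canvas) {
      pts <- paste(fmt(piece$x), fmt(flip(piece$y)), sep = ",",
                   collapse = " ")
      if (isTRUE(e$style$area)) {
        base <- flip(e$baseline_canvas %||% min(piece$y))
        path <- sprintf("M %s,%s L %s L %s,%s Z",
                        fmt(piece$x[1]), fmt(base), pts,
                        fmt(piece$x[length(piece$x)]), fmt(base))
        out <- c(out, sprintf('<path d="%s" fill="%s" stroke="none"/>',
                              path, col))
      } else {
        out <- c(out, sprintf(
          '<polyline points="%s" fill="none" stroke="%s" stroke-width="1"/>',
          pts, col))
      }
    }
  } else if (e$type == "rect") {
    vis_idx <- which(e$visible)
    for (j in seq_along(vis_idx)) {
      fill <- style_attr(e$style, vis_idx[j], "fill", "#808080")
      stroke <- style_attr(e$style, vis_idx[j], "col", NA)
      out <- c(out, sprintf(
        '<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="%s"/>',
        fmt(e$canvas$x0[j]), fmt(flip(e$canvas$y1[j])),
        fmt(e$canvas$x1[j] - e$canvas$x0[j]),
        fmt(e$canvas$y1[j] - e$canvas$y0[j]),
        if (is.na(fill)) "none" else fill,
        if (is.na(stroke)) "none" else stroke))
    }
  } else if (e$type == "segment") {
    col <- style_attr(e$style, 1, "col", "#000000")
    for (s in e$canvas)
      out <- c(out, sprintf(
        '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="1"/>',
        fmt(s[1]), fmt(flip(s[2])), fmt(s[3]), fmt(flip(s[4])), col))
  } else if (e$type == "text") {
    size <- style_attr(e$style, 1, "size", 9)
    col <- style_attr(e$style, 1, "col", "#000000")
    xs <- e$canvas$x; ys <- e$canvas$y
    labs <- e$data$label[e$visible]
    for (j in seq_along(xs))
      out <- c(out, sprintf(
        '<text x="%s" y="%s" text-anchor="middle" font-size="%s" fill="%s">%s</text>',
        fmt(xs[j]), fmt(flip(ys[j])), fmt(size), col,
        xml_escape(labs[j])))
  }
  out
}

svg_x_axis <- function(layout, p, flip, target_ticks) {
  ax <- plan_x_axis(c(p$xlim0, p$xlim1), target_ticks)
  u <- p$x0 + (ax$at - p$xlim0) / (p$xlim1 - p$xlim0) * (p$x1 - p$x0)
  y <- flip(p$y0)
  out <- character(0)
  for (j in seq_along(u)) {
    out <- c(out, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#333333" stroke-width="0.5"/>',
      fmt(u[j]), fmt(y), fmt(u[j]), fmt(y + 3)))
    out <- c(out, sprintf(
      '<text x="%s" y="%s" text-anchor="middle" font-size="6" fill="#333333">%s</text>',
      fmt(u[j]), fmt(y + 10), xml_escape(ax$labels[j])))
  }
  out
}
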