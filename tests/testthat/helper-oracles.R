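# Independent oracles and small random-input generators used across the
# suite. All are deliberately naive (per-base masks, exhaustive enumeration,
# quadratic scans) so they share no code path with the implementation.

rand_intervals <- function(n, max_pos = 1000, categories = "chr1",
                           max_len = 50) {
  cat <- sample(categories, n, replace = TRUE)
  s <- sample.int(max_pos - max_len, n, replace = TRUE) - 1
  len <- sample.int(max_len, n, replace = TRUE)
  gt_intervals(cat, s, s + len)
}

# per-base coverage mask of intervals on one category over [0, size)
coverage_mask <- function(x, category, size) {
  mask <- logical(size)
  rows <- which(x$category == category)
  for (i in rows) {
    lo <- max(x$start[i], 0); hi <- min(x$end[i], size)
    if (lo < hi) mask[(lo + 1):hi] <- TRUE
  }
  mask
}

# quadratic rainfall oracle: for each interval, find its neighbours (the
# nearest other interval strictly before it and strictly after it in
# (start, end) order) by scanning all records, then take the smaller
# boundary gap, clamped at zero
rainfall_oracle <- function(x) {
  out <- NULL
  for (cat in unique(x$category)) {
    idx <- which(x$category == cat)
    n <- length(idx)
    if (n < 2) next
    s <- x$start[idx]; e <- x$end[idx]
    before <- function(i, j)           # (s,e,index) lexicographic order
      s[j] < s[i] || (s[j] == s[i] && (e[j] < e[i] ||
                                       (e[j] == e[i] && j < i)))
    for (i in seq_len(n)) {
      prev <- NA; nxt <- NA
      for (j in seq_len(n)) {
        if (j == i) next
        if (before(i, j)) {          # j precedes i: keep the latest such j
          if (is.na(prev) || before(j, prev)) prev <- j
        } else {                     # j follows i: keep the earliest such j
          if (is.na(nxt) || before(nxt, j)) nxt <- j
        }
      }
      gaps <- c(if (!is.na(prev)) max(s[i] - e[prev], 0),
                if (!is.na(nxt)) max(s[nxt] - e[i], 0))
      out <- rbind(out, data.frame(category = cat, x = (s[i] + e[i]) / 2,
                                   dist = min(gaps)))
    }
  }
  if (is.null(out))
    return(data.frame(category = character(), x = numeric(),
                      dist = numeric()))
  out[order(out$category, out$x), , drop = FALSE]
}

# exhaustive minimal max-row-sum over contiguous partitions into <= k parts
min_contiguous_capacity <- function(lens, k) {
  n <- length(lens)
  best <- Inf
  recurse <- function(i, parts_left, cur_max) {
    if (i > n) { best <<- min(best, cur_max); return(invisible()) }
    if (parts_left == 0) return(invisible())
    acc <- 0
    for (j in i:n) {
      acc <- acc + lens[j]
      recurse(j + 1, parts_left - 1, max(cur_max, acc))
    }
  }
  recurse(1, k, 0)
  best
}

# exhaustive minimal sum of column maxima over partitions of lens into
# groups of size <= n_rows (any assignment, not just contiguous)
min_column_maxima_sum <- function(lens, n_rows, n_cols) {
  n <- length(lens)
  best <- Inf
  assign_next <- function(i, groups) {
    if (i > n) {
      best <<- min(best, sum(vapply(groups, max, numeric(1))))
      return(invisible())
    }
    for (g in seq_along(groups)) {
      if (length(groups[[g]]) < n_rows) {
        g2 <- groups; g2[[g]] <- c(g2[[g]], lens[i])
        assign_next(i + 1, g2)
        if (length(groups[[g]]) == 0) break   # first empty group: no symmetry
      }
    }
  }
  assign_next(1, rep(list(numeric(0)), n_cols))
  best
}

# wasted panel area of a layout, from the exported geometry: unused cell
# width times panel height, summed over panels
wasted_area <- function(layout) {
  p <- layout_panels(layout)
  sum((p$cell_x1 - p$cell_x0 - (p$x1 - p$x0)) * (p$y1 - p$y0))
}

# a panel_fun drawing one marker per record at (midpoint, value), used by
# the layout-independence and clipping tests
points_panel_fun <- function(ctx, d) {
  if (nrow(d)) ctx$painter$points((d$start + d$end) / 2, d$value)
}

expect_entry_within_rect <- function(entry, rect, tol = 1e-9) {
  within <- function(x, lo, hi) all(x >= lo - tol & x <= hi + tol)
  ok <- switch(entry$type,
    points = ,
    text = within(entry$canvas$x, rect["x0"], rect["x1"]) &&
            within(entry$canvas$y, rect["y0"], rect["y1"]),
    rect = within(c(entry$canvas$x0, entry$canvas$x1),
                  rect["x0"], rect["x1"]) &&
           within(c(entry$canvas$y0, entry$canvas$y1),
                  rect["y0"], rect["y1"]),
    segment = all(vapply(entry$canvas, function(s)
      within(s[c(1, 3)], rect["x0"], rect["x1"]) &&
      within(s[c(2, 4)], rect["y0"], rect["y1"]), logical(1))),
    polyline = all(vapply(entry$canvas, function(p)
      within(p$x, rect["x0"], rect["x1"]) &&
      within(p$y, rect["y0"], rect["y1"]), logical(1))),
    TRUE)
  expect_true(ok, info = sprintf("primitive '%s' escapes its panel",
                                 entry$type))
}
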