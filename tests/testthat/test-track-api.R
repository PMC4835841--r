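toy4 <- function(tracks = 1, mode = "one_row", ...) {
  g <- gt_genome(paste0("chr", c(1, 2, 3, 21)),
                 length = c(240e6, 200e6, 160e6, 48e6))
  trellis_layout(g, mode = mode, tracks = tracks, ...)
}

test_that("batch add visits every category once, in plotting order", {
  ly <- toy4(tracks = 2)
  seen <- character(0)
  add_track(ly, NULL, function(ctx, d) seen <<- c(seen, ctx$category$name))
  expect_equal(seen, c("chr1", "chr2", "chr3", "chr21"))
  # empty subset still invoked
  iv <- gt_intervals("chr1", 10, 20, value = 1)
  sizes <- integer(0)
  add_track(ly, iv, function(ctx, d) sizes <<- c(sizes, nrow(d)))
  expect_equal(sizes, c(1, 0, 0, 0))
})

test_that("the cursor advances and errors when all tracks are filled", {
  ly <- toy4(tracks = 3)
  got_tracks <- integer(0)
  f <- function(ctx, d) got_tracks <<- c(got_tracks, ctx$track)
  add_track(ly, NULL, f); add_track(ly, NULL, f); add_track(ly, NULL, f)
  expect_equal(unique(got_tracks), c(1L, 2L, 3L))
  expect_error(add_track(ly, NULL, f), "all 3 tracks filled")
  # explicit index overrides and resets the cursor
  add_track(ly, NULL, f, track = 2)
  expect_equal(ly$state$cursor, 2L)
  expect_error(add_track(ly, NULL, f, track = 9), "out of range")
})

test_that("single-panel addressing draws one panel, cursor untouched", {
  ly <- toy4(tracks = 2)
  calls <- character(0)
  f <- function(ctx, d)
    calls <<- c(calls, paste(ctx$category$name, ctx$track))
  add_track_single(ly, 2, 1, f)
  expect_equal(calls, "chr2 1")
  expect_equal(ly$state$cursor, 0L)
  # same call twice over-plots without error
  add_track_single(ly, 2, 1, function(ctx, d) ctx$painter$points(1e6, 0.5))
  add_track_single(ly, 2, 1, function(ctx, d) ctx$painter$points(1e6, 0.5))
  expect_equal(primitive_count(ly, "chr2", 1, "points"), 2)
  expect_error(add_track_single(ly, 0, 1, f), "out of range")
  expect_error(add_track_single(ly, 1, 3, f), "out of range")
})

test_that("panel function failures are wrapped with panel identity", {
  ly <- toy4()
  expect_error(add_track(ly, NULL, function(ctx, d) stop("boom")),
               "category 'chr1', track 1.*boom")
})

test_that("points track draws one marker per record at (midpoint, value)", {
  ly <- toy4(tracks = list(track_spec(ylim = c(0, 4))))
  iv <- gt_intervals("chr1", c(10e6, 50e6), c(20e6, 52e6), value = c(3, 9))
  add_points_track(ly, iv)
  e <- draw_log(ly, "chr1", 1)[[1]]
  expect_equal(e$data$x, c(15e6, 51e6))
  expect_equal(e$data$y, c(3, 9))
  expect_equal(e$n, 2)
  # the out-of-ylim marker is clipped away from the rendered geometry
  expect_equal(e$visible, c(TRUE, FALSE))
  # start positioning
  ly2 <- toy4()
  add_points_track(ly2, iv, position = "start")
  expect_equal(draw_log(ly2, "chr1", 1)[[1]]$data$x, c(10e6, 50e6))
  expect_error(add_points_track(toy4(), gt_intervals("chr1", 1, 2)),
               "value column")
})

test_that("marker count equals record count across categories", {
  set.seed(13)
  ly <- toy4(tracks = list(track_spec(ylim = c(0, 1))))
  iv <- normalize_intervals(rand_intervals(
    80, max_pos = 4e7, categories = c("chr1", "chr2", "chr21")))
  iv$value <- runif(nrow(iv))
  add_points_track(ly, iv)
  expect_equal(primitive_count(ly, type = "points"), 80)
  for (cat in c("chr1", "chr2", "chr21"))
    expect_equal(primitive_count(ly, cat, type = "points"),
                 sum(iv$category == cat))
})

test_that("lines track draws one polyline with a vertex per record", {
  ly <- toy4(tracks = list(track_spec(ylim = c(0, 10))))
  iv <- gt_intervals(rep("chr1", 4), c(40, 10, 20, 30) * 1e6,
                     c(41, 11, 21, 31) * 1e6, value = c(4, 1, 2, 3))
  add_lines_track(ly, iv)
  e <- draw_log(ly, "chr1", 1)[[1]]
  expect_equal(e$type, "polyline")
  expect_equal(length(e$data$x), 4)
  expect_false(is.unsorted(e$data$x))     # drawn in x order
  expect_equal(e$data$y, 1:4)
  # single record degenerates to a dot
  one <- gt_intervals("chr2", 5e6, 6e6, value = 5)
  add_lines_track(toy4(), one)
  ly3 <- toy4(tracks = 1)
  add_lines_track(ly3, one)
  expect_equal(draw_log(ly3, "chr2", 1)[[1]]$type, "points")
})

test_that("rect track paints record order with per-record fills", {
  ly <- toy4()
  iv <- gt_intervals(rep("chr1", 3), c(0, 50e6, 100e6),
                     c(40e6, 90e6, 140e6))
  add_rect_track(ly, iv, fill = c("#FF0000", "#00FF00", "#0000FF"))
  e <- draw_log(ly, "chr1", 1)[[1]]
  expect_equal(e$type, "rect")
  expect_equal(e$n, 3)
  expect_equal(e$style$fill, c("#FF0000", "#00FF00", "#0000FF"))
  expect_equal(e$data$x0, c(0, 50e6, 100e6))
})

test_that("segments track draws one horizontal segment per record", {
  ly <- toy4(tracks = list(track_spec(ylim = c(0, 4))))
  iv <- gt_intervals(rep("chr1", 2), c(10e6, 60e6), c(30e6, 80e6),
                     value = c(1, 3))
  add_segments_track(ly, iv)
  e <- draw_log(ly, "chr1", 1)[[1]]
  expect_equal(e$type, "segment")
  expect_equal(e$n, 2)
  expect_equal(e$data$y0, c(1, 3))
  expect_equal(e$data$y0, e$data$y1)
})

test_that("heatmap track paints records x series cells in equal bands", {
  ly <- toy4(tracks = list(track_spec(ylim = c(0, 1))))
  iv <- gt_intervals(rep("chr1", 3), c(0, 10e6, 20e6),
                     c(10e6, 20e6, 30e6),
                     s1 = c(0, 0.5, 1), s2 = c(1, 0.5, 0),
                     s3 = c(0, 1, 0), s4 = c(1, 0, 1))
  add_heatmap_track(ly, iv, values = paste0("s", 1:4))
  entries <- draw_log(ly, "chr1", 1)
  expect_equal(length(entries), 4)                  # one rect call per band
  expect_equal(sum(vapply(entries, `[[`, 0L, "n")), 12)  # records x series
  band1 <- entries[[1]]; band4 <- entries[[4]]
  expect_equal(unique(band1$data$y1 - band1$data$y0), 0.25)
  expect_lt(max(band1$data$y1), min(band4$data$y1) + 1e-12)
  # ragged input rejected
  iv$s2[2] <- NA
  expect_error(add_heatmap_track(toy4(), iv, values = paste0("s", 1:4)),
               "ragged")
})

test_that("heatmap colors come from the color map anchors", {
  cm <- colormap_sequential(c(0, 1))
  expect_equal(cm(c(0, 1)), c("#FFFFFF", "#08306B"))
  dv <- colormap_divergent(c(-1, 1))
  expect_equal(dv(0), "#FFFFFF")
  expect_equal(dv(c(-5, 5)), dv(c(-1, 1)))       # clamped
  # single series reduces to a colored rect track
  ly <- toy4()
  iv <- gt_intervals("chr1", 0, 10e6, s1 = 1)
  add_heatmap_track(ly, iv, values = "s1", colormap = cm)
  e <- draw_log(ly, "chr1", 1)[[1]]
  expect_equal(e$style$fill, "#08306B")
  expect_equal(e$data$y1 - e$data$y0, 1)
})

test_that("name track writes one centered label per category", {
  ly <- toy4()
  add_name_track(ly, strip_chr = TRUE)
  expect_equal(primitive_count(ly, type = "text"), 4)
  e <- draw_log(ly, "chr21", 1)[[1]]
  expect_equal(e$data$label, "21")
  expect_equal(e$data$x, 24e6)
  ly2 <- toy4()
  add_name_track(ly2)
  expect_equal(draw_log(ly2, "chr21", 1)[[1]]$data$label, "chr21")
})

test_that("ideogram track maps stains to colors and clips to the extent", {
  expect_equal(stain_color(c("gneg", "acen")), c("#FFFFFF", "#D92F27"))
  expect_true(stain_color("gpos100") == "#000000")
  expect_warning(col <- stain_color("nonsense"), "unknown gieStain")
  expect_equal(col, "#969696")

  g <- gt_genome("chr1", length = 100)
  ly <- trellis_layout(g)
  cb <- gt_intervals(rep("chr1", 3), c(0, 40, 90), c(40, 90, 200),
                     band = c("p1", "q1", "q2"),
                     stain = c("gneg", "acen", "gpos50"))
  add_ideogram_track(ly, cb)
  entries <- draw_log(ly, "chr1", 1)
  bands <- entries[[1]]
  expect_equal(bands$style$fill, c("#FFFFFF", "#D92F27", "#808080"))
  # the subset arrives clipped to the category extent, so the band ends
  # exactly at the panel edge
  expect_equal(bands$data$x1[3], 100)
  expect_equal(bands$canvas$x1[3], get_panel(ly, "chr1", 1)$x1)
  # the outline rect spans the whole category
  outline <- entries[[2]]
  expect_equal(c(outline$data$x0, outline$data$x1), c(0, 100))
})

test_that("identical add calls give identical data-space logs on any layout", {
  set.seed(17)
  iv <- normalize_intervals(rand_intervals(
    50, max_pos = 4e7, categories = c("chr1", "chr2", "chr3", "chr21")))
  iv$value <- runif(nrow(iv))
  logs <- list()
  for (mode in c("one_row", "equal_width", "optimized_grid",
                 "proportional_grid", "compact")) {
    ly <- toy4(tracks = list(track_spec(ylim = c(0, 1)),
                             track_spec(ylim = c(0, 1))),
               mode = mode, n_rows = 2, n_cols = 2)
    add_points_track(ly, iv)
    add_lines_track(ly, iv)
    logs[[mode]] <- lapply(draw_log(ly), function(e)
      e[c("type", "category", "track", "data", "visible")])
  }
  for (mode in names(logs)[-1])
    expect_identical(logs[[mode]], logs$one_row)
})

test_that("all rendered geometry stays inside its panel rectangle", {
  set.seed(23)
  for (mode in c("one_row", "compact", "equal_width")) {
    ly <- toy4(tracks = list(track_spec(ylim = c(0, 1)),
                             track_spec(ylim = c(-5, 5))),
               mode = mode, n_rows = 2, n_cols = 2)
    iv <- normalize_intervals(rand_intervals(
      40, max_pos = 3e8, max_len = 1e7,
      categories = c("chr1", "chr2", "chr3", "chr21")))
    iv$value <- rnorm(nrow(iv), 0, 6)      # many values beyond ylim
    add_points_track(ly, iv)
    add_segments_track(ly, iv, track = 2)
    ly$state$cursor <- 1L
    add_lines_track(ly, iv, track = 2)
    for (e in draw_log(ly)) {
      p <- get_panel(ly, e$category, e$track)
      expect_entry_within_rect(e, c(x0 = p$x0, y0 = p$y0,
                                    x1 = p$x1, y1 = p$y1))
    }
  }
})
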