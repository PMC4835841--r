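hg_subset <- function() {
  g <- read_chrom_sizes(example_chrom_sizes())
  g <- g[g$name %in% c("chr1", "chr3", "chr20", "chr21"), ]
  class(g) <- c("gt_genome", "data.frame")
  g
}

test_that("one-row placement makes panel widths proportional to length", {
  g <- gt_genome(c("chr1", "chr2"), length = c(100, 50))
  ly <- trellis_layout(g, "one_row", canvas_width = 150, gap_x = 0)
  p <- layout_panels(ly)
  expect_equal(p$x1 - p$x0, c(100, 50))
  expect_equal(ly$scale, 1)

  g3 <- gt_genome(paste0("chr", 1:3), length = c(200, 100, 100))
  ly3 <- trellis_layout(g3, "one_row", canvas_width = 100, gap_x = 0)
  expect_equal(layout_panels(ly3)$x1 - layout_panels(ly3)$x0,
               c(50, 25, 25))                    # scale = 100/400
})

test_that("equal-width grid gives identical cells, scaled to the longest", {
  g <- hg_subset()
  ly <- trellis_layout(g, "equal_width", n_rows = 2, n_cols = 2)
  p <- layout_panels(ly)
  cw <- p$cell_x1 - p$cell_x0
  expect_equal(length(unique(round(cw, 9))), 1)
  # longest category exactly fills its cell; short ones leave empty space
  waste <- cw - (p$x1 - p$x0)
  expect_equal(waste[p$category == "chr1"], 0)
  expect_gt(min(waste[p$category %in% c("chr20", "chr21")]), 0)
  # row-major karyotypic fill
  expect_equal(p$row[match(c("chr1", "chr3", "chr20", "chr21"),
                           p$category)], c(1, 1, 2, 2))
  # closed-form wasted fraction against summed geometry
  lens <- g$end - g$start
  expect_equal(wasted_area(ly) / sum((p$cell_x1 - p$cell_x0) * (p$y1 - p$y0)),
               1 - sum(lens) / (4 * max(lens)))
  expect_error(trellis_layout(g, "equal_width", n_rows = 1, n_cols = 2),
               "cannot hold")
})

test_that("optimized grid groups similar lengths into the same column", {
  g <- hg_subset()
  ly <- trellis_layout(g, "optimized_grid", n_rows = 2, n_cols = 2)
  a <- ly$assignment
  expect_equal(sort(a$name[a$col == 1]), c("chr1", "chr3"))
  expect_equal(sort(a$name[a$col == 2]), c("chr20", "chr21"))
  # karyotypic order top-to-bottom within a column
  expect_lt(a$row[a$name == "chr1"], a$row[a$name == "chr3"])
  # less wasted area than the equal-width grid on the same canvas
  lye <- trellis_layout(g, "equal_width", n_rows = 2, n_cols = 2)
  expect_lt(wasted_area(ly), wasted_area(lye))
  # equal lengths: deterministic karyotypic chunking
  ge <- gt_genome(paste0("chr", 1:4), length = rep(100, 4))
  lyt <- trellis_layout(ge, "optimized_grid", n_rows = 2, n_cols = 2)
  expect_equal(lyt$assignment$col, c(1, 1, 2, 2))
})

test_that("compact packing uses the minimal contiguous capacity", {
  g <- gt_genome(paste0("chr", 1:5), length = c(5, 4, 3, 2, 1))
  ly <- trellis_layout(g, "compact", n_rows = 2, canvas_width = 90,
                       gap_x = 0)
  a <- ly$assignment
  # capacity 9 (not the balanced mean 7.5, which would need 3 rows)
  expect_equal(a$row, c(1, 1, 2, 2, 2))
  expect_equal(a$x0, c(0, 50, 0, 30, 50))   # scale = 90/9 = 10
  expect_equal(ly$n_rows, 2)

  # n_rows = n: the capacity collapses to the longest category and the
  # greedy pack may merge short neighbours, never exceeding n rows
  ly1 <- trellis_layout(g, "compact", n_rows = 5, canvas_width = 50,
                        gap_x = 0)
  rows1 <- split(c(5, 4, 3, 2, 1), ly1$assignment$row)
  expect_lte(ly1$n_rows, 5)
  expect_equal(max(vapply(rows1, sum, numeric(1))), 5)  # capacity = longest

  # n_rows = 1 reduces to the one-row geometry
  lyc <- trellis_layout(g, "compact", n_rows = 1, canvas_width = 200)
  lyo <- trellis_layout(g, "one_row", canvas_width = 200)
  expect_equal(layout_panels(lyc)[, c("x0", "x1", "y0", "y1")],
               layout_panels(lyo)[, c("x0", "x1", "y0", "y1")])
})

test_that("compact capacity matches exhaustive contiguous partition search", {
  set.seed(21)
  for (rep in 1:40) {
    n <- sample(2:10, 1)
    k <- sample(1:4, 1)
    lens <- sample.int(1000, n, replace = TRUE)
    g <- gt_genome(paste0("c", seq_len(n)), length = lens, sort = FALSE)
    ly <- trellis_layout(g, "compact", n_rows = k)
    rows <- split(lens, ly$assignment$row)
    expect_lte(ly$n_rows, k)
    got_capacity <- max(vapply(rows, sum, numeric(1)))
    expect_equal(got_capacity, min_contiguous_capacity(lens, k))
    # karyotypic/input order preserved across rows
    expect_false(is.unsorted(ly$assignment$row))
  }
})

test_that("tracks split each cell by height share, top to bottom", {
  g <- gt_genome("chr1", length = 100)
  ly <- trellis_layout(g, "one_row",
                       tracks = list(track_spec(height = 3),
                                     track_spec(height = 1)),
                       canvas_height = 400, gap_y = 0, row_gap = 0)
  p <- layout_panels(ly)
  expect_equal((p$y1 - p$y0), c(300, 100))
  expect_gt(p$y0[p$track == 1], p$y0[p$track == 2])  # track 1 on top
  # degenerate single cell spans the canvas
  expect_equal(p$y1[1], 400)
  expect_equal(p$y0[2], 0)
})

test_that("panels never overlap and lie within the canvas", {
  set.seed(5)
  for (mode in c("one_row", "equal_width", "optimized_grid", "compact",
                 "proportional_grid")) {
    n <- sample(3:8, 1)
    g <- gt_genome(paste0("chr", 1:n),
                   length = sample.int(1e6, n) + 1e5)
    ly <- trellis_layout(g, mode, n_rows = 2, n_cols = ceiling(n / 2),
                         tracks = 2)
    p <- layout_panels(ly)
    expect_true(all(p$x0 >= -1e-9 & p$x1 <= ly$canvas["width"] + 1e-9))
    expect_true(all(p$y0 >= -1e-9 & p$y1 <= ly$canvas["height"] + 1e-9))
    for (i in seq_len(nrow(p) - 1)) {
      for (j in (i + 1):nrow(p)) {
        ox <- min(p$x1[i], p$x1[j]) - max(p$x0[i], p$x0[j])
        oy <- min(p$y1[i], p$y1[j]) - max(p$y0[i], p$y0[j])
        expect_false(ox > 1e-9 && oy > 1e-9)
      }
    }
  }
})

test_that("layout geometry is a pure function of the request", {
  g <- toy_genome(6, seed = 8)
  a <- trellis_layout(g, "optimized_grid", n_rows = 2, n_cols = 3,
                      tracks = 3)
  b <- trellis_layout(g, "optimized_grid", n_rows = 2, n_cols = 3,
                      tracks = 3)
  expect_identical(layout_panels(a), layout_panels(b))
  expect_identical(as_layout_document(a), as_layout_document(b))
})

test_that("data/canvas transforms are affine, invertible and edge-exact", {
  g <- gt_genome("chr1", start = 1000, end = 2000)
  ly <- trellis_layout(g, tracks = list(track_spec(ylim = c(-2, 6))))
  p <- get_panel(ly, "chr1", 1)
  corner <- data_to_canvas(p, 1000, -2)
  expect_equal(c(corner$x, corner$y), c(p$x0, p$y0))
  mid <- data_to_canvas(p, 1500, 2)
  expect_equal(c(mid$x, mid$y), c((p$x0 + p$x1) / 2, (p$y0 + p$y1) / 2))
  set.seed(31)
  x <- runif(200, 0, 3000); y <- runif(200, -10, 10)
  cc <- data_to_canvas(p, x, y)
  back <- canvas_to_data(p, cc$x, cc$y)
  expect_equal(back$x, x, tolerance = 1e-9)
  expect_equal(back$y, y, tolerance = 1e-9)
})

test_that("x-axis planning picks nice megabase ticks", {
  ax <- plan_x_axis(c(0, 249250621), target_ticks = 5)
  expect_equal(ax$spacing, 5e7)
  expect_equal(ax$at, seq(0, 2e8, 5e7))
  expect_equal(ax$labels[c(1, 5)], c("0MB", "200MB"))
  tiny <- plan_x_axis(c(0, 10), target_ticks = 2)
  expect_true(identical(tiny$at, c(0, 5, 10)) ||
              identical(tiny$at, c(0, 10)))
  # determinism for equal-width limits
  expect_identical(plan_x_axis(c(5e6, 9e7), 4), plan_x_axis(c(5e6, 9e7), 4))
  expect_true(all(ax$at >= 0 & ax$at <= 249250621))
})

test_that("geometry document serializes every panel with its transforms", {
  g <- hg_subset()
  ly <- trellis_layout(g, "compact", n_rows = 2, tracks = 2)
  doc <- as_layout_document(ly)
  expect_equal(length(doc$panels), 8)
  expect_equal(doc$mode, "compact")
  p <- withr::local_tempfile(fileext = ".json")
  write_layout_json(ly, p)
  round <- jsonlite::fromJSON(p, simplifyVector = FALSE)
  expect_equal(length(round$panels), 8)
  expect_equal(round$panels[[1]]$category, doc$panels[[1]]$category)
  expect_equal(round$scale, doc$scale, tolerance = 1e-6)
})
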