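# genotrellis

Genome-level Trellis layouts and multi-track plotting for R.

Trellis graphics split data by a categorical variable and draw each subset
in its own panel. For genome-wide data the natural category is the
chromosome, but chromosome lengths span a five-fold range, so standard
Trellis engines either waste most of the space given to short chromosomes
(equal panel widths) or shrink every chromosome into an unreadable sliver
(all in one row). `genotrellis` separates figure construction into two
independent steps:

1. **Layout** — `trellis_layout()` computes per-category, per-track panel
   rectangles before any data are seen, under five styles: proportional
   one-row, equal-width grid, length-optimized grid (similar-length
   chromosomes share a column), proportional grid, and compact
   non-rectangular packing (rows filled to a provably minimal capacity,
   without vertical alignment). All styles except the equal-width grid use
   a single global bp-to-canvas scale, so distances are comparable across
   panels.
2. **Graphics** — `add_track()` iterates a user panel function over the
   categories, handing each call the clipped per-category subset of the
   data and a painter restricted to its panel. Built-in tracks cover
   points, lines, rectangles, segments, heatmaps, category names and
   cytoband ideograms. The same track code runs unchanged on any layout.

Two genome statistics used by the showcase figures are built in:

* **Rainfall distances** — for each interval, the distance to its nearest
  neighbour in sorted order, `dist_i = min(gap(i-1,i), gap(i,i+1))` with
  `gap = max(next start − end, 0)`, plotted at the interval midpoint
  against `log10(max(dist, 1))`; clusters of regions appear as low
  "rainfalls".
* **Windowed genomic density** — the fraction of each tiling window
  covered by the (merged) interval set, with covered bases reported as
  exact integers.

Inputs are the field's plain-text formats: UCSC `chrom.sizes`, BED3+ /
bedGraph, and 5-column `cytoBand.txt`, all 0-based half-open internally.
Output is deterministic SVG plus a JSON geometry document that external
renderers can consume.

## Worked example

```r
library(genotrellis)

g <- read_chrom_sizes(example_chrom_sizes())        # bundled hg19 sizes
g <- g[g$name %in% c("chr1", "chr3", "chr20", "chr21"), ]
class(g) <- c("gt_genome", "data.frame")

ly <- trellis_layout(g, "optimized_grid", n_rows = 2, n_cols = 2,
                     tracks = 2)
ly
#> Trellis layout: 4 categories x 2 tracks, mode 'optimized_grid' (2 row(s))
#>   canvas 800 x 400, scale 2.53622e-06 canvas units/bp
#>   8 panels; 0 draw-log entries so far
```

The optimized grid puts chr1 and chr3 in one column and chr20 and chr21 in
the other, so the short chromosomes waste no space. Now some clustered
synthetic regions, their rainfall distances and windowed density:

```r
dmr <- clustered_intervals(g, n_clusters = 4, per_cluster = 30, seed = 11)
rf <- rainfall(dmr)
head(rf, 3)
#>   category     x dist        y
#> 1     chr1 32445 7816 3.892985
#> 2     chr1 41261 7816 3.892985
#> 3     chr1 50401 5235 3.718917

dens <- genomic_density(dmr, 2e6, g)
head(dens[dens$fraction > 0, ], 3)
#>   category start   end covered  fraction
#> 1     chr1 0e+00 2e+06   28611 0.0143055
#> 2     chr1 2e+06 4e+06   29021 0.0145105
#> 4     chr1 6e+06 8e+06    1000 0.0005000
```

Each rainfall row is one region: `x` its midpoint, `dist` the distance in
bp to its nearest neighbouring region, `y` the log10-transformed distance
that gets plotted (here ~10^3.9 bp ≈ 8 kb — these regions sit in a
cluster). Each density row is one 2 Mb window with the covered bases and
the covered fraction. Draw both into the layout and render:

```r
add_points_track(ly, gt_intervals(rf$category, rf$x, rf$x + 1,
                                  value = rf$y / 9), position = "start")
add_lines_track(ly, as_gt_intervals(dens[, c("category", "start", "end",
                                             "fraction")]),
                value = "fraction", area = TRUE)
render_svg(ly, "example.svg")
primitive_count(ly)
#> [1] 487
```

Every painter call lands in an inspectable draw log (`draw_log()`,
`primitive_count()`) before rendering, clipped to its panel.

## Command line

A thin wrapper over the same functions is installed under `exec/`:

```sh
Rscript exec/genotrellis plot --config fig.yaml \
    --chrom-sizes hg19.chrom.sizes --out fig.svg
Rscript exec/genotrellis demo gallery  --out gallery/ --seed 1
Rscript exec/genotrellis demo rainfall --out rainfall.svg --seed 7
```

The config is declarative YAML or JSON (layout block plus a track list;
track types: `points`, `lines`, `rects`, `segments`, `heatmap`,
`ideogram`, `names`, `density`, `rainfall`). `--layout-json` dumps the
geometry document instead of drawing. Exit status 2 flags config errors, 1
runtime failures.

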