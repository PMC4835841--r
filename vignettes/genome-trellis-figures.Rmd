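---
title: "Genome-level Trellis figures: layouts, tracks and the statistics behind them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-level Trellis figures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genotrellis)
```

## The problem

Trellis graphics condition a figure on a categorical variable and draw each
subset in its own panel. For genome-wide data the conditioning variable is
almost always the chromosome — but chromosomes differ in length by a factor
of five or more, so a standard Trellis grid (equal panel widths) pads short
chromosomes with dead space, and the popular all-in-one-row style shrinks
every chromosome as their number grows. This package treats the **layout**
as a first-class object, computed before any data are seen, and lets
arbitrary **track** graphics be added afterwards. Because the two steps are
independent, the identical track-adding code runs on any layout style; the
package's tests assert this literally, by comparing draw logs across modes.

## The layout model

A *genome* is an ordered list of categories, each an interval in base pairs
(0-based, half-open everywhere; 1-based inputs such as some cytoband
variants are converted at the reader boundary). Categories are chromosomes
`[0, length)` by default, but any background region — a gene body, say —
can serve, keeping its native coordinates rather than being re-zeroed.
Strand is ignored throughout; a strand column is carried as an opaque value
column. Ordering defaults to karyotypic (natural numeric, then X, Y, M/MT;
anything else lexicographically after — the natural-sort rule for
non-standard names is this package's own convention, since no universal one
exists).

`trellis_layout()` converts the genome plus a list of `track_spec()`s into
panel rectangles under one of five styles:

* **one_row** — all categories in one row, widths proportional to length.
* **equal_width** — the standard Trellis grid, row-major karyotypic fill.
  The scale is chosen so the longest category exactly fills its cell;
  shorter ones leave trailing empty space. This is deliberately the only
  mode without a globally comparable x-scale, and it exists mainly as the
  baseline the other styles improve on.
* **optimized_grid** — categories are sorted by length (descending) and
  chunked into columns of `n_rows`; each column is as wide as its longest
  member. This chunking is provably optimal for the total of column maxima
  among all assignments with at most `n_rows` per column (the classic
  argument: the $i$-th largest column maximum can never beat the
  $((i-1)r+1)$-th largest length), which under a global scale also
  minimizes wasted area; the test suite verifies it against exhaustive
  enumeration for small genomes.
* **proportional_grid** / **compact** — categories are packed, in
  karyotypic order, into at most `n_rows` rows of proportional widths. The
  row capacity is the *smallest* max-row-sum over contiguous partitions,
  found by binary search over capacities with a greedy first-fit
  feasibility check; the result is verified against brute-force
  enumeration of all contiguous partitions. Rows need not align
  vertically (a non-rectangular figure), trading cross-row positional
  comparability for maximal use of space. The two-row proportional style
  and the compact style share this packing; they are one mode under two
  names.

All modes except `equal_width` share a single global bp-to-canvas scale, so
a megabase has the same width in every panel. Within a category cell,
tracks are stacked top-to-bottom with heights proportional to their
`height` weights. Default gaps are 1 % of the canvas width between panels
horizontally, 0.5 % of the height between tracks, and 2 % between category
rows — all configurable. Canvas y increases upward in the geometry API; the
SVG writer flips it.

One practical note on `compact` with `n_rows` equal to the category count:
the minimal capacity collapses to the longest category, and the greedy pack
may still place several short categories on one row. Fewer rows than
requested is always acceptable; more never happens.

## Adding graphics

`add_track()` iterates a panel function over the categories of the layout,
in plotting order. The function receives a context (category, track index,
data limits, panel rectangle, painter) and the clipped per-category subset
of the data — an empty subset still triggers the call, so panel functions
can draw backgrounds for dataless chromosomes. Without an explicit track
index, consecutive calls fill tracks 1, 2, 3, … and error once all tracks
are filled; `add_track_single()` addresses one panel without moving the
cursor. Indices are 1-based in the user API.

The painter records every primitive (points, polyline, rect, segments,
text) into an inspectable **draw log** before anything is rendered; the log
is the package's principal test surface. Clipping is geometric and happens
in *data* space (Liang–Barsky for segments and polylines, interval
intersection for rectangles, containment for markers and text anchors), so
a track's logged data-space geometry is identical across layout modes and
its canvas geometry differs only by each panel's affine transform. A marker
whose value exceeds the track's y-limits is logged (counts are preserved
for auditing) but marked invisible and contributes no rendered geometry.

Five built-in tracks cover the common cases — points, lines (optionally
area-filled), rectangles, horizontal segments, and heatmaps (the track is
sliced into equal horizontal bands, one per value series, bottom to top by
default) — plus a category-name track and an ideogram track that colors
cytogenetic bands by Giemsa stain (gneg white through gpos100 black, acen
red, gvar light grey, stalk dark grey; unknown stains warn and fall back to
mid grey). Built-in x-positions use interval midpoints, switchable to
starts. Continuous values map to color through piecewise-linear
interpolation between anchor colors; a blue-white-red diverging map and a
white-to-navy sequential map ship as defaults.

## The two statistics

**Rainfall distances.** For intervals sorted by (start, end) within a
category, the gap between consecutive intervals is
`max(next start − end, 0)`; each interior interval takes the smaller of its
two flanking gaps, the first and last their single gap, and a category with
one interval yields nothing. Distances are measured between interval
*boundaries*, not midpoints, which is the natural reading of "distance to
the neighbouring region" for extended regions. The plotted y is
`log10(max(dist, 1))` — the 1 bp clamp avoids minus infinity for touching
or overlapping neighbours and is this package's choice. Note that
"neighbour" means adjacent in sorted order: when one interval fully
contains another, the all-pairs separation minimum can differ, and the
test oracle deliberately re-derives the sorted-neighbour definition by
quadratic scan rather than reusing any code from the implementation.
Mixed classes (e.g. hyper- and hypo-methylated regions) are computed per
class and overlaid with distinct styles.

**Windowed density.** Each category is tiled with non-overlapping windows
(the last truncated at the category end and normalized by its actual
width); the intervals are merged first (union coverage); each window
reports the covered fraction. Tiling, not sliding, windows are used. The
returned `covered` column holds raw covered bases as integers, so the
conservation identity — summed covered bases equal the merged interval
length — holds exactly, with no floating-point caveat. `window_means()`
generalizes this to a coverage-weighted mean of any value column, with
overlapping records each contributing their own covered bases and
uncovered windows reported as `NA`.

## Synthetic data

The generators exist so every figure and statistic is testable without
downloads, and their defaults describe the study conditions rather than
tuning knobs. `toy_genome()` draws uniform lengths in 50–250 Mb — the span
of real mammalian chromosomes. `clustered_intervals()` emulates the
spatial statistics of differentially methylated regions: uniform cluster
centers, 20 intervals of 1 kb within a ±100 kb cluster half-width, plus a
Poisson background of 10⁻⁸ intervals per bp (one per 100 Mb). This
reproduces the feature rainfall plots exist to show — clustered sets have
much lower median neighbour distance than count-matched uniform sets — but
not the biology it stands for: no CpG-island preference, no chromatin
covariates, no inter-sample noise, so passing tests demonstrate geometric
and statistical correctness, not biological realism. `fraction_matrix()`
emulates per-window alignment fractions for many species in three blocks
of distinct means (defaults 0.8/0.5/0.2, sd 0.05, clipped to [0, 1]),
chosen so that average-linkage clustering recovers the blocks — mirroring
how such heatmap tracks are ordered in practice. `toy_cytobands()` splits
each category into 2–8 bands cycling the gieStain vocabulary with an acen
pair at the middle, enough to exercise the ideogram color map, not to
mimic real banding.

All generators take a seed, restore the caller's RNG state, and are
bit-reproducible; derived seeds in the demos stay below 2³¹.

## Numerical and rendering choices

Tick positions use 1/2/5 × 10ᵏ spacings nearest the requested count,
labeled in megabases. Interval validity (`0 ≤ start < end`) is enforced at
construction with the offending record index; zero-width intervals are
rejected rather than silently dropped. Merging delegates the interval
union to `IRanges::reduce()` after converting the half-open convention at
the call boundary, and adjacency (`end == next start`) merges, as the
half-open reading requires. Panel transforms are plain affines; round
trips are accurate to 10⁻⁹ relative tolerance in the tests.

The SVG writer emits panels in (category, track) order, primitives in
painter order, and all coordinates at fixed three-decimal precision, which
makes output byte-identical across runs and platforms — the property the
determinism tests assert. Each panel group also carries an SVG clip path as
a second line of defense, though the geometry is already clipped. Raster
export is out of scope; SVG is the canonical format.

## Problem sizes in the test suite

The suite generates everything it needs at run time: proportionality over
100 random genomes, waste-dominance with exhaustive column-assignment
enumeration over 200 genomes of up to 8 categories, compact-capacity
brute force for up to 10 categories and 4 rows, 1,000 random interval sets
each for the rainfall and density oracles (with full per-base verification
on a subsample), and the full five-mode draw-log comparison. These sizes
were chosen to exhaust the small-case combinatorics the algorithms depend
on while keeping the whole suite comfortably under a minute.

## Known limitations

No sliding windows, no kernel density estimation, no statistical tests of
clustering. No sequence or alignment formats, no liftover. No interactive
zoom, circular layouts, or text-collision avoidance beyond fixed margins.
Gene-model drawing is done with rect/segment primitives rather than
dedicated exon/intron glyphs. The hierarchical clustering used to order
heatmap series is delegated to `stats::hclust()` in examples and is not
part of the package surface.
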