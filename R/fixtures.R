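# Deterministic synthetic-data generators: toy genomes, clustered interval
# sets (rainfall-style data), cytoband tables and multi-series fraction
# matrices. Every generator takes a seed and restores the caller's RNG
# state, so the same seed gives bit-identical output.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a toy genome
#'
#' `n` categories named `chr1` ... `chrN` with integer lengths drawn
#' uniformly from `length_range`.
#'
#' @param n number of categories.
#' @param length_range numeric length-2, bp.
#' @param seed integer seed; the same seed reproduces the genome exactly.
#' @return a [gt_genome()].
#' @export
toy_genome <- function(n = 4, length_range = c(5e7, 2.5e8), seed = 1) {
  stopifnot(n >= 1, length_range[1] > 0, length_range[2] >= length_range[1])
  lens <- with_seed(seed,
    floor(stats::runif(n, length_range[1], length_range[2] + 1)))
  lens <- pmin(lens, length_range[2])
  gt_genome(paste0("chr", seq_len(n)), length = lens)
}

#' Generate clustered intervals
#'
#' Emulates the spatial structure of differentially methylated regions:
#' per category, `n_clusters` cluster centers are placed uniformly; each
#' cluster holds `per_cluster` intervals whose starts are uniform within
#' `center +/- cluster_width / 2`; a Poisson background adds
#' `background_rate` intervals per bp uniformly over the category. All
#' intervals have fixed length `interval_length` and are clipped to the
#' category extent.
#'
#' @param genome a [gt_genome()].
#' @param n_clusters clusters per category.
#' @param cluster_width cluster span in bp.
#' @param per_cluster intervals per cluster.
#' @param background_rate background intervals per bp (Poisson).
#' @param interval_length fixed interval length in bp.
#' @param seed integer seed.
#' @return a normalized [gt_intervals()].
#' @export
clustered_intervals <- function(genome, n_clusters = 5, cluster_width = 2e5,
                                per_cluster = 20, background_rate = 1e-8,
                                interval_length = 1000, seed = 1) {
  stopifnot(inherits(genome, "gt_genome"))
  with_seed(seed, {
    pieces <- lapply(seq_len(nrow(genome)), function(i) {
      len <- genome$end[i] - genome$start[i]
      centers <- stats::runif(n_clusters, genome$start[i], genome$end[i])
      starts <- unlist(lapply(centers, function(cc)
        stats::runif(per_cluster, cc - cluster_width / 2,
                     cc + cluster_width / 2)))
      n_bg <- stats::rpois(1, background_rate * len)
      starts <- c(starts, stats::runif(n_bg, genome$start[i], genome$end[i]))
      starts <- floor(starts)
      ends <- starts + interval_length
      s <- pmax(starts, genome$start[i]); e <- pmin(ends, genome$end[i])
      keep <- s < e
      data.frame(category = genome$name[i], start = s[keep], end = e[keep],
                 stringsAsFactors = FALSE)
    })
    normalize_intervals(as_gt_intervals(do.call(rbind, pieces)))
  })
}

#' Generate a multi-series fraction matrix over genomic windows
#'
#' Emulates per-window alignment-fraction data for many species with group
#' structure: the series fall into blocks (e.g. close, intermediate and
#' distant relatives) with distinct means; per-window values are Gaussian
#' around the block mean, clipped to `[0, 1]`.
#'
#' @param genome a [gt_genome()].
#' @param window_size window width in bp.
#' @param block_sizes integer vector, number of series per block.
#' @param block_means mean fraction per block (same length).
#' @param sd Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return a normalized [gt_intervals()] whose value columns `s1`, `s2`, ...
#'   hold the per-series fractions; attribute `"series_block"` maps series
#'   to block index.
#' @export
fraction_matrix <- function(genome, window_size = 2e6,
                            block_sizes = c(4, 4, 4),
                            block_means = c(0.8, 0.5, 0.2),
                            sd = 0.05, seed = 1) {
  stopifnot(inherits(genome, "gt_genome"),
            length(block_sizes) == length(block_means))
  win <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    w <- tile_windows(genome$start[i], genome$end[i], window_size)
    data.frame(category = genome$name[i], start = w$start, end = w$end,
               stringsAsFactors = FALSE)
  }))
  k <- sum(block_sizes)
  block_of <- rep(seq_along(block_sizes), block_sizes)
  with_seed(seed, {
    for (j in seq_len(k)) {
      v <- stats::rnorm(nrow(win), block_means[block_of[j]], sd)
      win[[paste0("s", j)]] <- pmin(pmax(v, 0), 1)
    }
    out <- normalize_intervals(as_gt_intervals(win))
    attr(out, "series_block") <- block_of
    out
  })
}

#' Generate a toy cytoband table
#'
#' Splits each category into 2-8 bands with stains cycling through the
#' gieStain vocabulary and an `acen` centromere pair near the middle —
#' enough to exercise the ideogram color mapping.
#'
#' @param genome a [gt_genome()].
#' @param seed integer seed.
#' @return a normalized [gt_intervals()] with `band` and `stain` columns.
#' @export
toy_cytobands <- function(genome, seed = 1) {
  stopifnot(inherits(genome, "gt_genome"))
  stains <- c("gneg", "gpos25", "gpos50", "gpos75", "gpos100", "gvar",
              "stalk")
  with_seed(seed, {
    pieces <- lapply(seq_len(nrow(genome)), function(i) {
      s0 <- genome$start[i]; e0 <- genome$end[i]
      k <- sample(2:8, 1)
      cuts <- sort(floor(stats::runif(k - 1, s0 + 1, e0 - 1)))
      edges <- unique(c(s0, cuts, e0))
      st <- stains[(seq_len(length(edges) - 1) - 1) %% length(stains) + 1]
      # centromere: the band straddling the midpoint and its successor
      mid <- (s0 + e0) / 2
      ci <- max(findInterval(mid, edges, left.open = TRUE), 1)
      st[ci] <- "acen"
      if (ci + 1 <= length(st)) st[ci + 1] <- "acen"
      data.frame(category = genome$name[i],
                 start = utils::head(edges, -1), end = edges[-1],
                 band = paste0("b", seq_len(length(edges) - 1)),
                 stain = st, stringsAsFactors = FALSE)
    })
    normalize_intervals(as_gt_intervals(do.call(rbind, pieces)))
  })
}
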