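#' Circular binary segmentation of ordered probe statistics
#'
#' Recursive change-point segmentation: within each current segment, the arc
#' `(i, j]` maximizing the two-sample |t| between the probes inside and
#' outside the arc is found by exhaustive scan (ties broken toward the
#' smallest left boundary, then the shortest arc), and the split is accepted
#' iff a permutation test of that maximal |t| gives `p <= alpha`. Accepted
#' arcs introduce change points at both boundaries; recursion continues until
#' no segment can be split. Segments within a chromosome always partition its
#' probe sequence.
#'
#' For segments longer than `max_exact_n` probes the arc scan runs on a
#' coarse boundary grid and the best grid arc is refined by an exact scan in
#' its neighborhood.
#'
#' @param values Numeric vector of probe statistics in genomic order.
#' @param chrom Optional chromosome label per value; segmentation never
#'   crosses a chromosome boundary.
#' @param alpha Significance level for accepting a split.
#' @param n_perm Number of permutations.
#' @param min_width Minimum probes on each side of a split.
#' @param seed Integer seed for the permutation streams.
#' @param max_exact_n Largest segment scanned exhaustively.
#' @return A tibble of segments: `chrom`, `start_index`, `end_index`
#'   (1-based, inclusive, into `values`), `n_probes`, `seg_mean`.
#' @export
#' @examples
#' x <- c(rep(0, 10), rep(3, 10))
#' cbs_segment(x, n_perm = 100, seed = 1)
cbs_segment <- function(values, chrom = NULL, alpha = 0.01, n_perm = 1000,
                        min_width = 2, seed = NULL, max_exact_n = 5000) {
  if (!all(is.finite(values))) abort("values must be finite")
  if (is.null(chrom)) chrom <- rep("chr1", length(values))
  if (length(chrom) != length(values)) abort("chrom must match values")
  if (is.null(seed)) seed <- floor(runif(1, 0, 2^31 - 1))

  counter <- new.env()
  counter$k <- 0L
  next_seed <- function() {
    counter$k <- counter$k + 1L
    substream_seed(seed, paste0("cbs_perm_", counter$k))
  }

  split_points <- function(x) {
    n <- length(x)
    if (n < 2 * min_width) return(integer())
    if (var(x) == 0) return(integer())
    stride <- max(1L, ceiling(n / max_exact_n))
    # the permutation test replays the scan n_perm times, so its grid is
    # capped more tightly; observed and permuted maxima use the same stride,
    # keeping the test calibrated at any resolution
    stride_perm <- max(stride, ceiling(n / 1000))
    t_test <- if (stride_perm > stride) {
      .cbs_max_t(x, min_width, stride_perm)$t
    } else {
      NULL
    }
    best <- .cbs_max_t(x, min_width, stride)
    if (best$i < 0 || !is.finite(best$t)) return(integer())
    p <- .cbs_perm_p(x, t_test %||% best$t, min_width, n_perm, alpha,
                     next_seed(), stride_perm)
    if (stride > 1L) {
      # refine the boundary location (not the test) by an exact local scan
      refined <- .cbs_max_t(x, min_width, 1L,
                            max(0L, best$i - stride),
                            min(n - 1L, best$i + stride),
                            max(1L, best$j - stride),
                            min(n, best$j + stride))
      if (refined$i >= 0) best <- refined
    }
    if (p > alpha) return(integer())
    cuts <- integer()
    if (best$i > 0) cuts <- c(cuts, best$i)
    if (best$j < n) cuts <- c(cuts, best$j)
    if (length(cuts) == 0) return(integer())  # arc equals the whole segment
    # recurse on the resulting pieces
    bounds <- c(0L, cuts, n)
    out <- cuts
    for (b in seq_len(length(bounds) - 1)) {
      lo <- bounds[b]; hi <- bounds[b + 1]
      sub <- split_points(x[(lo + 1):hi])
      out <- c(out, lo + sub)
    }
    sort(unique(out))
  }

  chrom_rle <- rle(as.character(chrom))
  offsets <- cumsum(c(0, chrom_rle$lengths))
  segs <- purrr::map_dfr(seq_along(chrom_rle$values), function(ci) {
    lo <- offsets[ci]; hi <- offsets[ci + 1]
    x <- values[(lo + 1):hi]
    cuts <- split_points(x)
    bounds <- c(0L, cuts, length(x))
    tibble(
      chrom = chrom_rle$values[ci],
      start_index = lo + utils::head(bounds, -1) + 1L,
      end_index = lo + bounds[-1],
      n_probes = diff(bounds),
      seg_mean = purrr::map2_dbl(utils::head(bounds, -1), bounds[-1],
                                 function(a, b) mean(x[(a + 1):b]))
    )
  })
  segs$seg_id <- sprintf("seg%04d", seq_len(nrow(segs)))
  segs |> select("seg_id", dplyr::everything())
}

#' Attach genomic coordinates to index-based segments
#'
#' Maps each segment's probe index range onto the probe map, yielding BED
#' style 0-based half-open coordinates from the first probe's start to the
#' last probe's end.
#'
#' @param segments Tibble from [cbs_segment()] run on probe-ordered values.
#' @param probe_map Probe tibble (`probe_id`, `chrom`, `start`, `end`) in the
#'   same order as the segmented values.
#' @return The segments tibble with `start`, `end`, `first_probe_id`,
#'   `last_probe_id` columns added.
#' @export
locate_segments <- function(segments, probe_map) {
  check_columns(probe_map, c("probe_id", "chrom", "start", "end"), "probe_map")
  segments |>
    mutate(start = probe_map$start[.data$start_index],
           end = probe_map$end[.data$end_index],
           first_probe_id = probe_map$probe_id[.data$start_index],
           last_probe_id = probe_map$probe_id[.data$end_index])
}
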