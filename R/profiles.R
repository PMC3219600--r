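#' Sliding-window percent methylation along chromosomes
#'
#' Windows are anchored at the chromosome start and step by `step` (defaults:
#' 5 Mb windows sliding 1 Mb); the last partial window is retained. Per
#' window, percent methylation is `100 * methylated / total` over the probes
#' whose start falls in the window; empty windows are flagged missing.
#'
#' @param probe_states Tibble with `probe_id` and `state`
#'   (`"methylated"`/`"unmethylated"`), e.g. one genotype's column of the
#'   truth set or EM-classified probe states.
#' @param probe_map Probe tibble (`probe_id`, `chrom`, `start`).
#' @param window,step Window size and stride in bp.
#' @param chrom_lengths Optional named vector of chromosome lengths; defaults
#'   to the last probe end per chromosome.
#' @return Tibble `chrom`, `window_start`, `window_end`,
#'   `percent_methylated`, `n_probes`, `missing`.
#' @export
window_methylation <- function(probe_states, probe_map,
                               window = 5e6, step = 1e6,
                               chrom_lengths = NULL) {
  check_columns(probe_states, c("probe_id", "state"), "probe_states")
  if (step > window) warn("step larger than window: windows will not overlap")
  dat <- probe_map |>
    inner_join(probe_states |> select("probe_id", "state"), by = "probe_id")
  if (is.null(chrom_lengths)) {
    chrom_lengths <- dat |>
      group_by(.data$chrom) |>
      summarise(len = max(.data$end)) |>
      (\(d) setNames(d$len, d$chrom))()
  }
  purrr::map_dfr(names(chrom_lengths), function(cn) {
    len <- chrom_lengths[[cn]]
    starts <- seq(0, max(0, len - 1), by = step)
    d <- dat[dat$chrom == cn, ]
    purrr::map_dfr(starts, function(s) {
      e <- min(s + window, len)
      in_w <- d$start >= s & d$start < e
      n <- sum(in_w)
      tibble(chrom = cn, window_start = s, window_end = e,
             percent_methylated = if (n > 0)
               100 * sum(d$state[in_w] == "methylated") / n else NA_real_,
             n_probes = n, missing = n == 0)
    })
  })
}

# map probe midpoints to metagene coordinates for one gene orientation
# upstream flank -> [-flank, 0); body -> [0, 1000]; downstream -> (1000, 1000+flank]
metagene_coord <- function(mid, tss, tts, strand, flank) {
  if (strand == "-") {
    d_tss <- tss - mid
    d_tts <- tts - mid
  } else {
    d_tss <- mid - tss
    d_tts <- mid - tts
  }
  glen <- abs(tts - tss)
  ifelse(d_tss < 0, 1000 * d_tss / flank,           # upstream, scaled to [-1000,0)
         ifelse(d_tts > 0, 1000 + 1000 * d_tts / flank,  # downstream
                1000 * d_tss / glen))               # body, [0,1000]
}

#' Metagene methylation profile by gene class
#'
#' Maps every probe within `flank` bp of a gene's transcription start (TSS)
#' or termination (TTS) site — or inside the gene — onto a common metagene
#' axis: the upstream flank, the gene body rescaled to 1000 units, and the
#' downstream flank, each cut into `n_bins` bins. Minus-strand genes are
#' flipped so the axis always runs 5' to 3'. Per gene class (any grouping
#' column of `genes`, e.g. FGS vs rejected, expression category, synteny,
#' subgenome), the per-bin mean of the probe values is reported. Averaging
#' is over probe-gene pairs: a probe near two genes contributes to both.
#'
#' @param values Tibble `probe_id`, `value` (e.g. a methylation contrast).
#' @param probe_map Probe tibble (`probe_id`, `chrom`, `start`, `end`).
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`, `strand`
#'   plus the grouping column).
#' @param class_by Name of the `genes` column to stratify by (NULL = one
#'   pooled class `"all"`).
#' @param flank Flank size in bp.
#' @param n_bins Bins per region (upstream/body/downstream).
#' @return Tibble `gene_class`, `region`, `bin`, `position` (bin midpoint on
#'   the metagene axis), `mean_value`, `n_probes`.
#' @export
metagene_profile <- function(values, probe_map, genes, class_by = NULL,
                             flank = 1000, n_bins = 20) {
  check_columns(values, c("probe_id", "value"), "values")
  dat <- probe_map |>
    inner_join(values |> select("probe_id", "value"), by = "probe_id") |>
    mutate(mid = (.data$start + .data$end) / 2)

  genes <- genes |>
    mutate(gene_class = if (is.null(class_by)) "all" else
      as.character(.data[[class_by]]))
  bad <- genes$end <= genes$start
  if (any(bad)) {
    warn(sprintf("skipping %d gene(s) with non-positive length", sum(bad)))
    genes <- genes[!bad, ]
  }

  pairs <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    tss <- if (g$strand == "+") g$start else g$end
    tts <- if (g$strand == "+") g$end else g$start
    lo <- min(g$start, g$end) - flank
    hi <- max(g$start, g$end) + flank
    d <- dat[dat$chrom == g$chrom & dat$mid >= lo & dat$mid <= hi, ]
    if (nrow(d) == 0) return(NULL)
    coord <- metagene_coord(d$mid, tss, tts, g$strand, flank)
    tibble(gene_class = g$gene_class, coord = coord, value = d$value)
  })
  if (nrow(pairs) == 0) {
    return(tibble(gene_class = character(), region = character(),
                  bin = integer(), position = numeric(),
                  mean_value = numeric(), n_probes = integer()))
  }

  pairs |>
    filter(.data$coord >= -1000, .data$coord <= 2000) |>
    mutate(
      region = ifelse(.data$coord < 0, "upstream",
                      ifelse(.data$coord <= 1000, "body", "downstream")),
      rel = ifelse(.data$region == "upstream", .data$coord + 1000,
                   ifelse(.data$region == "body", .data$coord,
                          .data$coord - 1000)),
      bin = pmin(n_bins, 1L + floor(.data$rel / (1000 / n_bins)))
    ) |>
    group_by(.data$gene_class, .data$region, .data$bin) |>
    summarise(mean_value = mean(.data$value), n_probes = n(),
              .groups = "drop") |>
    mutate(position = (as.numeric(.data$bin) - 0.5) * (1000 / n_bins) +
             ifelse(.data$region == "upstream", -1000,
                    ifelse(.data$region == "body", 0, 1000))) |>
    arrange(.data$gene_class, factor(.data$region,
                                     c("upstream", "body", "downstream")),
            .data$bin)
}

#' CpG dinucleotide density on the metagene axis
#'
#' For every gene, the upstream flank, body, and downstream flank are cut
#' into `n_bins` bins each and the proportion of CpG dinucleotides —
#' `#CG / (bin length - 1)` — is computed on the transcription strand, then
#' averaged over genes.
#'
#' @param genome `DNAStringSet` or `tm_reference`.
#' @param genes Gene tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @param flank Flank size in bp.
#' @param n_bins Bins per region.
#' @return Tibble `region`, `bin`, `position`, `cpg_proportion`, `n_genes`.
#' @export
cpg_profile <- function(genome, genes, flank = 1000, n_bins = 20) {
  if (inherits(genome, "tm_reference")) genome <- genome$genome
  per_gene <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    chrom_seq <- genome[[g$chrom]]
    clen <- length(chrom_seq)
    region_bins <- function(lo, hi, region) {
      # lo/hi 0-based half-open on the plus strand, already 5'->3' ordered
      bounds <- round(seq(lo, hi, length.out = n_bins + 1))
      purrr::map_dfr(seq_len(n_bins), function(b) {
        s <- max(0, bounds[b]); e <- min(clen, bounds[b + 1])
        if (e - s < 2) return(tibble(region = region, bin = b,
                                     cpg_proportion = NA_real_))
        seq_b <- Biostrings::subseq(chrom_seq, s + 1, e)
        n_cg <- Biostrings::countPattern("CG", seq_b)
        tibble(region = region, bin = b,
               cpg_proportion = n_cg / (e - s - 1))
      })
    }
    up <- region_bins(g$start - flank, g$start, "upstream")
    body <- region_bins(g$start, g$end, "body")
    down <- region_bins(g$end, g$end + flank, "downstream")
    res <- bind_rows(up, body, down)
    if (g$strand == "-") {
      # CpG counts are strand-symmetric; flip the axis for minus genes
      res <- res |>
        mutate(region = c(upstream = "downstream", body = "body",
                          downstream = "upstream")[.data$region],
               bin = n_bins + 1L - .data$bin)
    }
    res$gene_id <- g$gene_id
    res
  })
  per_gene |>
    filter(!is.na(.data$cpg_proportion)) |>
    group_by(.data$region, .data$bin) |>
    summarise(cpg_proportion = mean(.data$cpg_proportion),
              n_genes = n(), .groups = "drop") |>
    mutate(position = (as.numeric(.data$bin) - 0.5) * (1000 / n_bins) +
             ifelse(.data$region == "upstream", -1000,
                    ifelse(.data$region == "body", 0, 1000))) |>
    arrange(factor(.data$region, c("upstream", "body", "downstream")),
            .data$bin)
}
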