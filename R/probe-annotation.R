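#' Count perfect and close genomic matches for probe sequences
#'
#' Perfect matches are exact substring occurrences of the probe (either
#' strand). Close matches are alignments of the whole probe with at most
#' `floor((1 - identity_threshold) * length)` edits (substitutions or
#' indels), i.e. at least 90% identity over at least 90% of the probe by
#' default, found with [Biostrings::matchPattern()] allowing indels;
#' overlapping hits are merged into loci, and loci containing a perfect hit
#' are not counted again as close.
#'
#' @param probe_sequences Named character vector (or `DNAStringSet`) of probe
#'   sequences; minimum length 20 nt; ambiguous bases are an error.
#' @param genome A `DNAStringSet` (or `tm_reference`, whose genome is used).
#' @param identity_threshold Minimum identity/coverage for a close match.
#' @return Tibble `probe_id`, `perfect_match_count`, `close_match_count`.
#' @export
count_matches <- function(probe_sequences, genome, identity_threshold = 0.90) {
  if (inherits(genome, "tm_reference")) genome <- genome$genome
  if (is.character(probe_sequences)) {
    probe_sequences <- Biostrings::DNAStringSet(probe_sequences)
  }
  if (is.null(names(probe_sequences))) {
    names(probe_sequences) <- sprintf("p%06d", seq_along(probe_sequences))
  }
  lens <- Biostrings::width(probe_sequences)
  if (any(lens < 20)) abort("probe length must be at least 20")
  freqs <- Biostrings::alphabetFrequency(probe_sequences, baseOnly = TRUE)
  if (any(freqs[, "other"] > 0)) abort("ambiguous bases in probe")

  subjects <- c(as.list(genome), as.list(Biostrings::reverseComplement(genome)))

  purrr::imap_dfr(as.list(probe_sequences), function(p, pid) {
    # epsilon guards the floor against floating-point droop (0.1 * 30 -> 2.99..)
    k <- floor((1 - identity_threshold) * length(p) + 1e-9)
    perfect <- 0L
    loci <- 0L
    for (subj in subjects) {
      exact <- Biostrings::matchPattern(p, subj)
      perfect <- perfect + length(exact)
      if (k > 0) {
        close <- Biostrings::matchPattern(p, subj, max.mismatch = k,
                                          with.indels = TRUE)
        if (length(close) > 0) {
          merged <- IRanges::reduce(as(close, "IRanges"))
          has_perfect <- IRanges::overlapsAny(merged, as(exact, "IRanges"))
          loci <- loci + sum(!has_perfect)
        }
      }
    }
    tibble(probe_id = pid, perfect_match_count = perfect,
           close_match_count = loci)
  })
}

#' Apply the probe filter cascade
#'
#' Filters are applied in the stated, order-dependent sequence (each
#' percentage or count downstream refers to the set surviving the previous
#' filter):
#'
#' 1. `"chr9_thinning"` — keep every `thin_step`-th probe (the 1st, 4th, ...)
#'    of the densely tiled chromosome 9, restoring spacing comparable to the
#'    other chromosomes;
#' 2. `"unique"` — keep single-copy probes; by default
#'    `perfect_match_count == 1` and `close_match_count == 0`
#'    (`unique_definition = "perfect_and_close"`), or only the perfect-match
#'    condition with `"perfect_only"`;
#' 3. `"cgh"` — keep probes whose CGH contrast is strictly greater than
#'    `cgh_threshold` (default -1), removing copy-variable probes.
#'
#' @param probe_map Probe tibble with `probe_id`, `chrom`,
#'   `perfect_match_count`, `close_match_count`.
#' @param estimates Optional `tm_estimates` with a `cgh` column (required for
#'   the `"cgh"` filter).
#' @param filters Character vector of filter names, applied in order.
#' @param cgh_threshold Strict lower bound for the CGH filter.
#' @param unique_definition `"perfect_and_close"` or `"perfect_only"`.
#' @param chr9 Name of the densely tiled chromosome.
#' @param thin_step Thinning period.
#' @return The surviving probe tibble, with attributes `filter_log` (tibble:
#'   filter, n_before, n_removed, n_after) and `removed` (tibble: probe_id,
#'   removed_by) recording provenance.
#' @export
apply_probe_filters <- function(probe_map, estimates = NULL,
                                filters = c("chr9_thinning", "unique", "cgh"),
                                cgh_threshold = -1,
                                unique_definition = c("perfect_and_close",
                                                      "perfect_only"),
                                chr9 = "chr9", thin_step = 3) {
  unique_definition <- match.arg(unique_definition)
  known <- c("chr9_thinning", "unique", "cgh")
  bad <- setdiff(filters, known)
  if (length(bad) > 0) abort(sprintf("unknown filter name(s): %s",
                                     paste(bad, collapse = ", ")))
  cur <- probe_map
  log <- list()
  removed <- list()
  for (f in filters) {
    n_before <- nrow(cur)
    keep <- switch(f,
      chr9_thinning = {
        is9 <- cur$chrom == chr9
        idx9 <- cumsum(is9)
        !is9 | ((idx9 - 1) %% thin_step == 0)
      },
      unique = {
        if (unique_definition == "perfect_and_close") {
          cur$perfect_match_count == 1 & cur$close_match_count == 0
        } else {
          cur$perfect_match_count == 1
        }
      },
      cgh = {
        if (is.null(estimates)) abort("the 'cgh' filter needs estimates")
        cgh <- estimates$cgh[match(cur$probe_id, estimates$probe_id)]
        !is.na(cgh) & cgh > cgh_threshold
      }
    )
    removed[[f]] <- tibble(probe_id = cur$probe_id[!keep], removed_by = f)
    cur <- cur[keep, ]
    log[[f]] <- tibble(filter = f, n_before = n_before,
                       n_removed = n_before - nrow(cur), n_after = nrow(cur))
  }
  attr(cur, "filter_log") <- bind_rows(log)
  attr(cur, "removed") <- bind_rows(removed)
  cur
}

#' Assign each probe to its gene context
#'
#' The probe midpoint decides everything: the feature class (exon, intron,
#' UTR when inside a gene; intergenic otherwise) and the gene assignment —
#' the nearest gene (by distance from midpoint to TSS) among genes that
#' contain the probe or whose TSS or TTS lies within `flank` bp of it; ties
#' prefer FGS over rejected models, then the lexicographically smallest
#' gene id. Distances are transcription-strand oriented: upstream of the TSS
#' is negative, and minus-strand genes are flipped.
#'
#' @param probe_map Probe tibble (`probe_id`, `chrom`, `start`, `end`).
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `class`, `utr5_len`, `utr3_len`).
#' @param exons Optional exon tibble (`gene_id`, `start`, `end`); without it
#'   every in-gene, non-UTR probe is `exon`.
#' @param flank Maximum distance from TSS/TTS for assignment (bp).
#' @return Tibble `probe_id`, `feature`, `gene_id` (NA if intergenic
#'   context), `distance_to_TSS`, `distance_to_TTS`.
#' @export
annotate_probe_context <- function(probe_map, genes, exons = NULL,
                                   flank = 1000) {
  check_columns(probe_map, c("probe_id", "chrom", "start", "end"), "probe_map")
  check_columns(genes, c("gene_id", "chrom", "start", "end", "strand"),
                "genes")
  mid <- (probe_map$start + probe_map$end) / 2

  g_tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  g_tts <- ifelse(genes$strand == "+", genes$end, genes$start)

  # candidate probe-gene pairs: containment or TSS/TTS within flank of midpoint
  pr <- GenomicRanges::GRanges(probe_map$chrom,
                               IRanges::IRanges(start = floor(mid) + 1,
                                                width = 1))
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(start = pmin(genes$start,
                                                             g_tss - flank,
                                                             g_tts - flank) + 1,
                                                end = pmax(genes$end,
                                                           g_tss + flank,
                                                           g_tts + flank)))
  hits <- GenomicRanges::findOverlaps(pr, gr)
  cand <- tibble(p = S4Vectors::queryHits(hits), g = S4Vectors::subjectHits(hits)) |>
    mutate(
      mid = mid[.data$p],
      contained = .data$mid >= genes$start[.data$g] & .data$mid < genes$end[.data$g],
      near_tss = abs(.data$mid - g_tss[.data$g]) <= flank,
      near_tts = abs(.data$mid - g_tts[.data$g]) <= flank
    ) |>
    filter(.data$contained | .data$near_tss | .data$near_tts) |>
    mutate(
      tss_dist = abs(.data$mid - g_tss[.data$g]),
      is_fgs = genes$class[.data$g] == "FGS",
      gene_id = genes$gene_id[.data$g]
    ) |>
    group_by(.data$p) |>
    arrange(.data$tss_dist, dplyr::desc(.data$is_fgs), .data$gene_id,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup()

  out <- tibble(probe_id = probe_map$probe_id,
                feature = "intergenic",
                gene_id = NA_character_,
                distance_to_TSS = NA_real_,
                distance_to_TTS = NA_real_)
  if (nrow(cand) > 0) {
    gi <- cand$g
    sgn <- ifelse(genes$strand[gi] == "+", 1, -1)
    out$gene_id[cand$p] <- cand$gene_id
    out$distance_to_TSS[cand$p] <- sgn * (cand$mid - g_tss[gi])
    out$distance_to_TTS[cand$p] <- sgn * (cand$mid - g_tts[gi])

    inside <- cand$contained
    feat <- rep("intergenic", nrow(cand))
    if (any(inside)) {
      u5 <- genes$utr5_len[gi] %||% rep(0, length(gi))
      u3 <- genes$utr3_len[gi] %||% rep(0, length(gi))
      d_tss <- sgn * (cand$mid - g_tss[gi])
      d_tts <- sgn * (cand$mid - g_tts[gi])
      is_utr <- inside & (d_tss < u5 | d_tts > -u3)
      feat[is_utr] <- "UTR"
      body <- inside & !is_utr
      if (!is.null(exons)) {
        in_exon <- purrr::map_lgl(seq_len(nrow(cand)), function(r) {
          if (!body[r]) return(FALSE)
          ex <- exons[exons$gene_id == cand$gene_id[r], ]
          any(cand$mid[r] >= ex$start & cand$mid[r] < ex$end)
        })
        feat[body & in_exon] <- "exon"
        feat[body & !in_exon] <- "intron"
      } else {
        feat[body] <- "exon"
      }
    }
    out$feature[cand$p] <- feat
  }
  out
}
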