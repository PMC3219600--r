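#' Call differentially methylated probes
#'
#' Probes whose differential-methylation q-value is strictly below
#' `q_threshold` (default 0.001) are called, and partitioned by the sign of
#' the differential contrast: positive = B73 hypermethylated, negative =
#' Mo17 hypermethylated; an exactly-zero contrast with a significant q is
#' kept but flagged with `direction = "unclassified"`.
#'
#' @param estimates Moderated `tm_estimates` (needs `diff_meth` and
#'   `q_diff_meth`).
#' @param q_threshold Strict q-value cutoff.
#' @return Tibble `probe_id`, `diff_meth`, `q`, `direction`.
#' @export
call_variable_probes <- function(estimates, q_threshold = 0.001) {
  check_columns(estimates, c("probe_id", "diff_meth", "q_diff_meth"),
                "estimates")
  estimates |>
    filter(!is.na(.data$q_diff_meth), .data$q_diff_meth < q_threshold) |>
    mutate(direction = dplyr::case_when(
      .data$diff_meth > 0 ~ "B73_hyper",
      .data$diff_meth < 0 ~ "Mo17_hyper",
      TRUE ~ "unclassified"
    )) |>
    select("probe_id", "diff_meth", q = "q_diff_meth", "direction") |>
    as_tibble()
}

#' Call DMR segments from classified segments
#'
#' DMRs are the segments whose mixture label is decisive (`"low"` = Mo17
#' hypermethylated, `"high"` = B73 hypermethylated) and that span at least
#' `min_probes` probes. Each DMR is annotated with the fraction of its
#' member probes that are independently significant at the stricter
#' per-probe cutoff `strict_q` (default 1e-4), its overlapping
#' high-confidence (FGS) and working-set (WGS) genes, a flag for lying
#' within `gene_margin` bp of an FGS gene, and an IBD flag.
#'
#' @param segments Classified segments with genomic coordinates
#'   (see [classify_by_posterior()] and [locate_segments()]).
#' @param estimates Moderated `tm_estimates` (for the strict per-probe
#'   fractions); may be NULL.
#' @param probe_map Probe tibble in segmentation order.
#' @param genes Optional gene tibble (`gene_id`, `chrom`, `start`, `end`,
#'   `class`).
#' @param ibd Optional IBD interval tibble (`chrom`, `start`, `end`).
#' @param min_probes Minimum probes per DMR (default 3).
#' @param strict_q Strict per-probe q cutoff for the annotation column.
#' @param gene_margin Distance defining "near a gene" (default 500 bp).
#' @return Tibble of DMR records (class `tm_dmrs`): segment fields plus
#'   `direction`, `fraction_probes_q_significant`, `n_fgs_genes`,
#'   `n_wgs_genes`, `within_500bp_fgs`, `ibd_flag`.
#' @export
call_dmr_segments <- function(segments, estimates = NULL, probe_map = NULL,
                              genes = NULL, ibd = NULL,
                              min_probes = 3, strict_q = 1e-4,
                              gene_margin = 500) {
  check_columns(segments, c("label", "n_probes", "seg_mean"), "segments")
  dmrs <- segments |>
    filter(.data$label %in% c("low", "high"),
           .data$n_probes >= min_probes) |>
    mutate(direction = ifelse(.data$label == "high", "B73_hyper", "Mo17_hyper"))

  dmrs$fraction_probes_q_significant <- NA_real_
  if (!is.null(estimates) && nrow(dmrs) > 0 &&
      "q_diff_meth" %in% names(estimates)) {
    q <- estimates$q_diff_meth
    dmrs$fraction_probes_q_significant <- purrr::map2_dbl(
      dmrs$start_index, dmrs$end_index,
      function(a, b) mean(q[a:b] < strict_q, na.rm = TRUE)
    )
  }

  dmrs$n_fgs_genes <- 0L
  dmrs$n_wgs_genes <- 0L
  dmrs$within_500bp_fgs <- FALSE
  if (!is.null(genes) && nrow(dmrs) > 0 && nrow(genes) > 0) {
    ov <- function(margin, subset_genes) {
      purrr::map_int(seq_len(nrow(dmrs)), function(i) {
        sum(subset_genes$chrom == dmrs$chrom[i] &
              subset_genes$start < dmrs$end[i] + margin &
              subset_genes$end > dmrs$start[i] - margin)
      })
    }
    fgs <- genes[genes$class == "FGS", ]
    dmrs$n_fgs_genes <- ov(0, fgs)
    dmrs$n_wgs_genes <- ov(0, genes)
    dmrs$within_500bp_fgs <- ov(gene_margin, fgs) > 0
  }

  dmrs$ibd_flag <- FALSE
  if (!is.null(ibd) && nrow(dmrs) > 0 && nrow(ibd) > 0) {
    dmrs$ibd_flag <- purrr::map_lgl(seq_len(nrow(dmrs)), function(i) {
      any(ibd$chrom == dmrs$chrom[i] & ibd$start <= dmrs$start[i] &
            ibd$end >= dmrs$end[i])
    })
  }
  class(dmrs) <- c("tm_dmrs", class(dmrs))
  dmrs
}

#' Summarize DMRs and test gene-class enrichment
#'
#' Reports the length distribution (with the under-5 kb and under-10 kb
#' breakpoints), the percent of DMRs without any overlapping gene
#' (intergenic), counts with at least one FGS/WGS gene, and — when a gene
#' class column and background are available — a Pearson chi-square test
#' (no continuity correction) of the DMR-gene class distribution against the
#' full FGS background.
#'
#' @param dmrs A `tm_dmrs` tibble.
#' @param genes Optional gene tibble with `gene_id`, `chrom`, `start`, `end`,
#'   `class` and the enrichment column.
#' @param enrich_by Optional name of the `genes` column to test enrichment
#'   on (e.g. `"syntenic"`, `"subgenome"`, `"expression"`).
#' @param correct Continuity correction flag passed to the chi-square test.
#' @return A list with `summary` (one-row tibble) and `enrichment` (tibble
#'   with statistic, df, p.value, or NULL).
#' @export
summarize_dmrs <- function(dmrs, genes = NULL, enrich_by = NULL,
                           correct = FALSE) {
  if (nrow(dmrs) == 0) {
    return(list(summary = tibble(n_dmrs = 0L), enrichment = NULL))
  }
  len <- dmrs$end - dmrs$start
  summary <- tibble(
    n_dmrs = nrow(dmrs),
    n_b73_hyper = sum(dmrs$direction == "B73_hyper"),
    n_mo17_hyper = sum(dmrs$direction == "Mo17_hyper"),
    n_under_5kb = sum(len < 5000),
    n_under_10kb = sum(len < 10000),
    total_length = sum(len),
    pct_intergenic = 100 * mean(dmrs$n_wgs_genes == 0),
    n_with_fgs = sum(dmrs$n_fgs_genes > 0),
    n_with_wgs = sum(dmrs$n_wgs_genes > 0)
  )

  enrichment <- NULL
  if (!is.null(genes) && !is.null(enrich_by)) {
    dmr_genes <- purrr::map_dfr(seq_len(nrow(dmrs)), function(i) {
      genes[genes$chrom == dmrs$chrom[i] & genes$start < dmrs$end[i] &
              genes$end > dmrs$start[i], ]
    }) |> distinct(.data$gene_id, .keep_all = TRUE)
    bg <- genes[genes$class == "FGS", ]
    if (nrow(dmr_genes) > 0 && nrow(bg) > 0) {
      lv <- sort(unique(as.character(bg[[enrich_by]])))
      tab <- rbind(
        dmr = table(factor(as.character(dmr_genes[[enrich_by]]), levels = lv)),
        background = table(factor(as.character(bg[[enrich_by]]), levels = lv))
      )
      tab <- tab[, colSums(tab) > 0, drop = FALSE]
      if (ncol(tab) >= 2) {
        ct <- suppressWarnings(chisq.test(tab, correct = correct))
        enrichment <- tibble(variable = enrich_by,
                             statistic = unname(ct$statistic),
                             df = unname(ct$parameter),
                             p.value = ct$p.value)
      }
    }
  }
  list(summary = summary, enrichment = enrichment)
}
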