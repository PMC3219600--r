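#' Run the full differential-methylation pipeline on an intensity table
#'
#' Chains the analysis stages: (optional) normalization, per-probe contrast
#' fitting, (optional) moderated statistics with probe-level calls,
#' segmentation of the differential methylation statistic by circular binary
#' segmentation, a 3-component Gaussian-mixture fit to the segment means,
#' posterior classification, and DMR calling. The same machinery, applied to
#' the `cgh` statistic, yields CNV/PAV segments (`segment_statistic =
#' "cgh"`, where low = fewer copies in Mo17 / PAV and high = more copies in
#' Mo17).
#'
#' @param table Intensity tibble (see [sim_arrays()]).
#' @param probe_map Probe tibble in genomic order matching the table.
#' @param normalize Apply [normalize_arrays()] first.
#' @param moderate Compute moderated statistics and probe-level calls (needs
#'   positive residual variances; turn off for noise-free data).
#' @param segment_statistic `"diff_meth"` or `"cgh"`.
#' @param genes,ibd Optional annotation inputs forwarded to
#'   [call_dmr_segments()].
#' @param alpha,n_perm,min_width CBS parameters.
#' @param em_K,posterior_threshold Mixture parameters.
#' @param q_threshold Probe-level call cutoff.
#' @param min_probes Minimum probes per called segment.
#' @param seed Integer seed (CBS permutations).
#' @return A list (class `tm_pipeline`): `estimates`, `probe_calls`,
#'   `segments` (classified, located), `mixture`, `dmrs`.
#' @export
run_pipeline <- function(table, probe_map,
                         normalize = TRUE,
                         moderate = TRUE,
                         segment_statistic = c("diff_meth", "cgh"),
                         genes = NULL, ibd = NULL,
                         alpha = 0.01, n_perm = 1000, min_width = 2,
                         em_K = 3, posterior_threshold = 0.95,
                         q_threshold = 0.001, min_probes = 3,
                         seed = NULL) {
  segment_statistic <- match.arg(segment_statistic)
  if (normalize) table <- normalize_arrays(table)
  est <- fit_contrasts(table)
  est <- est[match(probe_map$probe_id, est$probe_id), ]

  probe_calls <- NULL
  if (moderate) {
    est <- moderate_stats(est)
    probe_calls <- call_variable_probes(est, q_threshold = q_threshold)
  }

  values <- est[[segment_statistic]]
  segs <- cbs_segment(values, chrom = probe_map$chrom, alpha = alpha,
                      n_perm = n_perm, min_width = min_width, seed = seed)
  segs <- locate_segments(segs, probe_map)
  if (nrow(segs) >= 2 * em_K) {
    mix <- em_fit(segs$seg_mean, K = em_K)
    segs <- classify_by_posterior(segs, mix, threshold = posterior_threshold)
  } else {
    # too few segments to support a mixture (e.g. an unsegmented null
    # genome): nothing can be called decisively
    mix <- NULL
    segs$label <- "unclassified"
    segs$posterior <- NA_real_
  }
  dmrs <- call_dmr_segments(segs, estimates = if (moderate) est else NULL,
                            probe_map = probe_map, genes = genes, ibd = ibd,
                            min_probes = min_probes)

  structure(list(estimates = est, probe_calls = probe_calls,
                 segments = segs, mixture = mix, dmrs = dmrs),
            class = "tm_pipeline")
}

#' Compare called DMRs with an implanted truth set
#'
#' Matches each true interval to calls of the correct direction and reports
#' recall, precision, the fraction of true intervals recovered with exact
#' probe boundaries, and per-call direction accuracy.
#'
#' @param dmrs Called DMR tibble (`chrom`, `start`, `end`, `direction`).
#' @param truth_dmrs Truth tibble (`chrom`, `start`, `end`, `direction`).
#' @return One-row tibble: `n_true`, `n_called`, `recall`, `precision`,
#'   `exact_boundary_fraction`, `direction_accuracy`.
#' @export
evaluate_dmr_recovery <- function(dmrs, truth_dmrs) {
  overlaps <- function(a, b) {
    a$chrom == b$chrom & a$start < b$end & a$end > b$start
  }
  n_true <- nrow(truth_dmrs)
  n_called <- nrow(dmrs)
  if (n_true == 0 || n_called == 0) {
    return(tibble(n_true = n_true, n_called = n_called,
                  recall = if (n_true == 0) NA_real_ else 0,
                  precision = if (n_called == 0) NA_real_ else 0,
                  exact_boundary_fraction = NA_real_,
                  direction_accuracy = NA_real_))
  }
  hit <- logical(n_true); exact <- logical(n_true)
  call_correct <- logical(n_called); call_hit <- logical(n_called)
  for (i in seq_len(n_true)) {
    tr <- truth_dmrs[i, ]
    ov <- which(dmrs$chrom == tr$chrom & dmrs$start < tr$end &
                  dmrs$end > tr$start)
    good <- ov[dmrs$direction[ov] == tr$direction]
    hit[i] <- length(good) > 0
    exact[i] <- any(dmrs$start[good] == tr$start & dmrs$end[good] == tr$end)
    call_hit[ov] <- TRUE
    call_correct[good] <- TRUE
  }
  tibble(
    n_true = n_true, n_called = n_called,
    recall = mean(hit),
    precision = mean(call_correct),
    exact_boundary_fraction = mean(exact),
    direction_accuracy = sum(call_correct) / max(1, sum(call_hit))
  )
}
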