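#' Screen for identical-by-descent (IBD) candidate regions
#'
#' Scans each chromosome with windows of the minimum region length, marking
#' windows with no structural-variant (CNV/PAV) segment overlap and SNP
#' density at most `genome_density / fold_threshold`; overlapping passing
#' windows are merged into maximal candidate regions. Per region the SNP
#' fold reduction is `genome-wide SNP rate / region SNP rate` (regions with
#' zero SNPs report an infinite fold reduction and are flagged).
#'
#' @param snps Tibble `chrom`, `pos` of SNP positions.
#' @param cgh_segments Classified CGH segments; rows whose `label` is
#'   `"low"` or `"high"` (CNV/PAV) exclude windows they overlap. NULL = no
#'   structural exclusion.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param min_length Minimum region length in bp (the 2 Mb criterion, scaled
#'   for synthetic genomes).
#' @param fold_threshold Minimum SNP-density fold reduction.
#' @param step Window step in bp (default `min_length / 10`).
#' @return Tibble `chrom`, `start`, `end`, `length`, `n_snps`,
#'   `snp_fold_reduction`, `zero_snp_flag`.
#' @export
ibd_screen <- function(snps, cgh_segments = NULL, chrom_lengths,
                       min_length = 1e5, fold_threshold = 25,
                       step = NULL) {
  check_columns(snps, c("chrom", "pos"), "snps")
  step <- step %||% max(1, round(min_length / 10))
  genome_len <- sum(chrom_lengths)
  genome_rate <- nrow(snps) / genome_len
  if (genome_rate == 0) abort("no SNPs supplied; genome-wide rate undefined")

  sv <- if (!is.null(cgh_segments)) {
    cgh_segments |> filter(.data$label %in% c("low", "high"))
  } else {
    tibble(chrom = character(), start = numeric(), end = numeric())
  }

  regions <- purrr::map_dfr(names(chrom_lengths), function(cn) {
    len <- chrom_lengths[[cn]]
    if (len < min_length) return(NULL)
    starts <- seq(0, len - min_length, by = step)
    pos <- snps$pos[snps$chrom == cn]
    sv_cn <- sv[sv$chrom == cn, ]
    pass <- vapply(starts, function(s) {
      e <- s + min_length
      dens <- sum(pos >= s & pos < e) / min_length
      no_sv <- !any(sv_cn$start < e & sv_cn$end > s)
      no_sv && dens <= genome_rate / fold_threshold
    }, logical(1))
    if (!any(pass)) return(NULL)
    r <- IRanges::reduce(IRanges::IRanges(start = starts[pass] + 1,
                                          width = min_length))
    tibble(chrom = cn, start = IRanges::start(r) - 1, end = IRanges::end(r))
  })
  if (nrow(regions) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  length = numeric(), n_snps = integer(),
                  snp_fold_reduction = numeric(), zero_snp_flag = logical()))
  }
  regions |>
    mutate(
      length = .data$end - .data$start,
      n_snps = purrr::pmap_int(list(.data$chrom, .data$start, .data$end),
        function(cn, s, e) sum(snps$chrom == cn & snps$pos >= s & snps$pos < e)),
      snp_fold_reduction = genome_rate / (.data$n_snps / .data$length),
      zero_snp_flag = .data$n_snps == 0
    )
}

#' Overlay variable methylation calls onto regions
#'
#' Counts, per region, the variable methylation probes and variable
#' methylation segments falling inside it by interval intersection (a probe
#' counts if its interval lies within the region; a segment if it overlaps).
#'
#' @param regions Tibble `chrom`, `start`, `end` (e.g. from [ibd_screen()]
#'   or the packaged region table).
#' @param probe_calls Variable-probe calls joined with coordinates
#'   (`chrom`, `start`, `end`); NULL = zero counts.
#' @param dmrs DMR tibble (`chrom`, `start`, `end`); NULL = zero counts.
#' @return `regions` with `variable_probe_count` and
#'   `variable_segment_count` columns.
#' @export
overlay_regions <- function(regions, probe_calls = NULL, dmrs = NULL) {
  check_columns(regions, c("chrom", "start", "end"), "regions")
  count_in <- function(iv, contained) {
    if (is.null(iv) || nrow(iv) == 0) return(rep(0L, nrow(regions)))
    purrr::map_int(seq_len(nrow(regions)), function(i) {
      same <- iv$chrom == regions$chrom[i]
      if (contained) {
        sum(same & iv$start >= regions$start[i] & iv$end <= regions$end[i])
      } else {
        sum(same & iv$start < regions$end[i] & iv$end > regions$start[i])
      }
    })
  }
  regions |>
    mutate(variable_probe_count = count_in(probe_calls, TRUE),
           variable_segment_count = count_in(dmrs, FALSE))
}

#' Summarize a table of IBD regions
#'
#' Totals over an IBD region table: region count, summed variable probe and
#' segment counts, total length and the largest region length.
#'
#' @param regions Tibble with `start`, `end` (same units) and
#'   `variable_probe_count` / `variable_segment_count` columns (the packaged
#'   region table uses `variable_probes` / `variable_segments`; both
#'   spellings are accepted).
#' @return One-row tibble of totals.
#' @export
summarize_ibd_regions <- function(regions) {
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(regions)) return(regions[[nm]])
    NULL
  }
  vp <- pick("variable_probe_count", "variable_probes")
  vs <- pick("variable_segment_count", "variable_segments")
  if (is.null(vp) || is.null(vs)) abort("regions lack variable-count columns")
  tibble(
    n_regions = nrow(regions),
    total_variable_probes = sum(vp),
    total_variable_segments = sum(vs),
    total_length = sum(regions$end - regions$start),
    max_length = max(regions$end - regions$start)
  )
}
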