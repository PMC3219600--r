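#' Implant ground-truth methylation states, DMRs, CNVs, and IBD blocks
#'
#' Draws a per-probe, per-genotype methylation state (a stated fraction of
#' probes methylated, identical in both genotypes at baseline), then implants:
#' differentially methylated regions (DMRs) by flipping the state of one
#' genotype over a run of at least `min_dmr_probes` consecutive probes;
#' copy-number / presence-absence (CNV/PAV) intervals; and identical-by-descent
#' (IBD) haplotype blocks in which SNP density is reduced at least
#' `ibd_fold_reduction`-fold relative to the genome background. DMRs are
#' labelled with their generating control model: `cis` (state follows the
#' local haplotype), `trans` (state follows an unlinked controller locus,
#' recorded per DMR), or `pure_epiallele` (placed inside an IBD block with no
#' SNP within 1 kb).
#'
#' @param reference A `tm_reference` from [sim_reference()].
#' @param dmr_count,cnv_count,ibd_count Numbers of intervals to implant.
#' @param fraction_methylated Baseline probability a probe is methylated.
#' @param min_dmr_probes,max_dmr_probes Range of probes per implanted DMR.
#' @param cnv_probes Probes per implanted CNV/PAV interval.
#' @param min_gap_probes Minimum untouched probes between implanted
#'   intervals; intervals closer than this are not statistically resolvable
#'   as distinct regions at segment resolution.
#' @param ibd_min_length Minimum IBD block length in bp (the field's 2 Mb
#'   criterion rescaled to the synthetic genome).
#' @param snp_rate Background SNP density in SNPs per bp (default one per
#'   1.2 kb).
#' @param ibd_fold_reduction Fold reduction of SNP density inside IBD blocks.
#' @param prop_trans Proportion of non-pure DMRs under trans control.
#' @param controls Optional character vector of length `dmr_count` fixing
#'   each DMR's control model (`"cis"`, `"trans"`, `"pure_epiallele"`);
#'   overrides the random mix.
#' @param seed Integer seed.
#' @return An object of class `tm_truth`: list with tibbles `probe_states`
#'   (probe_id, chrom, start, end, b73, mo17 in {"methylated","unmethylated"}),
#'   `dmrs` (chrom, start, end, probe range, direction, control,
#'   controller coordinates for trans DMRs), `cnvs`, `ibd`, and `snps`
#'   (chrom, pos).
#' @export
sim_truth <- function(reference,
                      dmr_count = 10,
                      cnv_count = 4,
                      ibd_count = 1,
                      fraction_methylated = 0.5,
                      min_dmr_probes = 3,
                      max_dmr_probes = 8,
                      cnv_probes = 10,
                      min_gap_probes = 10,
                      ibd_min_length = 1e5,
                      snp_rate = 1 / 1200,
                      ibd_fold_reduction = 36,
                      prop_trans = 0.25,
                      controls = NULL,
                      seed = NULL) {
  stopifnot(inherits(reference, "tm_reference"))
  if (fraction_methylated <= 0 || fraction_methylated >= 1) {
    abort("fraction_methylated must be in (0, 1)")
  }
  probes <- reference$probes
  chroms <- reference$chromosomes

  with_substream(seed, "truth", {
    base <- ifelse(runif(nrow(probes)) < fraction_methylated,
                   "methylated", "unmethylated")
    states <- probes |>
      select("probe_id", "probe_index", "chrom", "start", "end") |>
      mutate(b73 = base, mo17 = base)

    # IBD blocks first so pure-epiallele DMRs can be placed inside them
    ibd <- tibble(chrom = character(), start = numeric(), end = numeric())
    for (i in seq_len(ibd_count)) {
      cn <- chroms$chrom[1 + (i - 1) %% nrow(chroms)]
      clen <- chroms$length[chroms$chrom == cn]
      w <- min(clen * 0.4, ibd_min_length * runif(1, 1, 2))
      if (w < ibd_min_length) abort("requested IBD block wider than chromosome")
      s <- floor(runif(1, 0, clen - w))
      ibd <- bind_rows(ibd, tibble(chrom = cn, start = s, end = s + w))
    }

    # DMRs: runs of consecutive probes, state flipped in one genotype
    if (is.null(controls)) {
      n_pure <- if (ibd_count > 0 && dmr_count > 0)
        min(dmr_count, max(1, round(dmr_count / 4))) else 0
      controls <- c(rep("pure_epiallele", n_pure),
                    sample(c("cis", "trans"), dmr_count - n_pure,
                           replace = TRUE,
                           prob = c(1 - prop_trans, prop_trans)))
    } else {
      if (length(controls) != dmr_count) {
        abort("controls must have one entry per DMR")
      }
      bad <- setdiff(controls, c("cis", "trans", "pure_epiallele"))
      if (length(bad) > 0) abort(sprintf("unknown control model: %s", bad[1]))
      if (any(controls == "pure_epiallele") && ibd_count == 0) {
        abort("pure_epiallele DMRs need at least one IBD block")
      }
      # place pure DMRs first so the IBD pool is still open
      controls <- controls[order(controls != "pure_epiallele")]
    }
    dmrs <- list()
    used <- rep(FALSE, nrow(probes))
    pick_run <- function(idx_pool, n_pr) {
      # choose a start so that the run stays on one chromosome and keeps at
      # least one untouched probe away from every other implanted interval
      # (abutting intervals would not be distinct regions)
      for (attempt in 1:200) {
        i0 <- sample(idx_pool, 1)
        run <- i0:(i0 + n_pr - 1)
        if (max(run) > nrow(probes)) next
        if (length(unique(probes$chrom[run])) != 1) next
        guard <- max(1, run[1] - min_gap_probes):
          min(nrow(probes), run[n_pr] + min_gap_probes)
        if (any(used[guard])) next
        return(run)
      }
      abort("could not place interval; chromosome too small for request")
    }
    for (k in seq_len(dmr_count)) {
      n_pr <- sample(min_dmr_probes:max_dmr_probes, 1)
      if (n_pr > nrow(probes)) abort("requested DMR wider than chromosome")
      ctrl <- controls[k]
      pool <- seq_len(nrow(probes) - n_pr)
      if (ctrl == "pure_epiallele") {
        in_ibd <- purrr::map_lgl(seq_len(nrow(probes)), function(i) {
          any(ibd$chrom == probes$chrom[i] & probes$start[i] >= ibd$start &
                probes$end[i] <= ibd$end)
        })
        pool <- intersect(pool, which(in_ibd))
        if (length(pool) == 0) abort("IBD block too small to host a pure DMR")
      }
      run <- pick_run(pool, n_pr)
      used[run] <- TRUE
      direction <- sample(c("B73_hyper", "Mo17_hyper"), 1)
      # flip the hypermethylated genotype to methylated, the other to un-
      states$b73[run] <- if (direction == "B73_hyper") "methylated" else "unmethylated"
      states$mo17[run] <- if (direction == "Mo17_hyper") "methylated" else "unmethylated"
      cn <- probes$chrom[run[1]]
      dmrs[[k]] <- tibble(
        dmr_id = sprintf("dmr%03d", k), chrom = cn,
        start = probes$start[run[1]], end = probes$end[run[length(run)]],
        first_probe = run[1], last_probe = run[length(run)],
        n_probes = n_pr, direction = direction, control = ctrl
      )
    }
    dmrs <- if (length(dmrs) > 0) bind_rows(dmrs) else
      tibble(dmr_id = character(), chrom = character(), start = numeric(),
             end = numeric(), first_probe = integer(), last_probe = integer(),
             n_probes = integer(), direction = character(), control = character())

    # controllers for trans DMRs: unlinked loci kept clear of every DMR so
    # that introgressions covering one never accidentally cover the other
    dmrs$controller_chrom <- NA_character_
    dmrs$controller_start <- NA_real_
    dmrs$controller_end <- NA_real_
    ctrl_width <- 5000
    for (k in which(dmrs$control == "trans")) {
      cn <- dmrs$chrom[k]
      clen <- chroms$length[chroms$chrom == cn]
      ctrl_margin <- min(25000, round(clen * 0.05))
      for (attempt in 1:200) {
        cs <- floor(runif(1, 0, clen - ctrl_width))
        near <- dmrs$chrom == cn &
          dmrs$start - ctrl_margin < cs + ctrl_width &
          dmrs$end + ctrl_margin > cs
        if (!any(near)) break
        if (attempt == 200) abort("could not place trans controller locus")
      }
      dmrs$controller_chrom[k] <- cn
      dmrs$controller_start[k] <- cs
      dmrs$controller_end[k] <- cs + ctrl_width
    }

    # CNV / PAV intervals over unused probe runs
    cnvs <- list()
    for (k in seq_len(cnv_count)) {
      run <- pick_run(seq_len(nrow(probes) - cnv_probes), cnv_probes)
      used[run] <- TRUE
      cnvs[[k]] <- tibble(
        cnv_id = sprintf("cnv%03d", k), chrom = probes$chrom[run[1]],
        start = probes$start[run[1]], end = probes$end[run[length(run)]],
        first_probe = run[1], last_probe = run[length(run)],
        class = sample(c("M_gt_B", "M_lt_B_or_PAV"), 1)
      )
    }
    cnvs <- if (length(cnvs) > 0) bind_rows(cnvs) else
      tibble(cnv_id = character(), chrom = character(), start = numeric(),
             end = numeric(), first_probe = integer(), last_probe = integer(),
             class = character())

    # SNPs: homogeneous background, thinned inside IBD; none within 1 kb of
    # a pure-epiallele DMR
    snps <- purrr::map_dfr(seq_len(nrow(chroms)), function(i) {
      cn <- chroms$chrom[i]; clen <- chroms$length[i]
      n_bg <- rbinom(1, clen, snp_rate)
      pos <- sort(floor(runif(n_bg, 0, clen)))
      keep <- rep(TRUE, length(pos))
      for (j in which(ibd$chrom == cn)) {
        inside <- pos >= ibd$start[j] & pos < ibd$end[j]
        keep[inside] <- keep[inside] & (runif(sum(inside)) < 1 / ibd_fold_reduction)
      }
      pure <- dmrs[dmrs$control == "pure_epiallele" & dmrs$chrom == cn, ]
      for (j in seq_len(nrow(pure))) {
        keep[pos >= pure$start[j] - 1000 & pos < pure$end[j] + 1000] <- FALSE
      }
      tibble(chrom = cn, pos = pos[keep])
    })

    structure(list(probe_states = states, dmrs = dmrs, cnvs = cnvs,
                   ibd = ibd, snps = snps,
                   params = list(fraction_methylated = fraction_methylated,
                                 ibd_min_length = ibd_min_length,
                                 snp_rate = snp_rate,
                                 ibd_fold_reduction = ibd_fold_reduction)),
              class = "tm_truth")
  })
}
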