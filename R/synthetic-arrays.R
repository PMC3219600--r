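#' Simulate two-color meDIP tiling-array intensities
#'
#' Produces a long-format intensity table with the factor structure the
#' linear-model stage expects: per genotype (B73/Mo17), an immunoprecipitated
#' (IP, Cy5) and an input (Cy3) channel for each biological replicate, with
#' one two-channel array per genotype x replicate. On the log2 scale each
#' intensity is
#' `baseline + copy-number term + methylation term + dye + array + N(0, sigma^2)`:
#' the methylation term adds `mu_meth` to IP channels of probes methylated in
#' that genotype (giving the bimodal log2(IP/input) signal the analysis
#' assumes), and the copy-number term lowers (PAV/deletion) or raises (gain)
#' the Mo17 channels at implanted CNV probes.
#'
#' @param truth A `tm_truth` from [sim_truth()].
#' @param reference The `tm_reference` the truth was built on.
#' @param n_reps Biological replicates per genotype (default 3, the standard
#'   leaf-tissue design).
#' @param mu_meth Methylation effect size on the log2 scale.
#' @param sigma Residual noise SD on the log2 scale.
#' @param dye_effect Additive offset applied to Cy5 channels.
#' @param array_effect SD of per-array random offsets (0 disables).
#' @param baseline Baseline log2 intensity.
#' @param pav_depth Log2 drop of the Mo17 channels at `M_lt_B_or_PAV` probes
#'   (background floor).
#' @param cnv_gain Log2 gain of the Mo17 channels at `M_gt_B` probes.
#' @param seed Integer seed.
#' @return A tibble (class `tm_intensities`) with columns `probe_id`,
#'   `sample_id`, `factor` (`B73_IP`, `Mo17_IP`, `B73_input`, `Mo17_input`),
#'   `replicate`, `dye` (`Cy5`/`Cy3`), `array`, `log2_intensity`.
#' @export
sim_arrays <- function(truth, reference,
                       n_reps = 3,
                       mu_meth = 2,
                       sigma = 0.3,
                       dye_effect = 0,
                       array_effect = 0,
                       baseline = 10,
                       pav_depth = -3,
                       cnv_gain = 1,
                       seed = NULL) {
  stopifnot(inherits(truth, "tm_truth"))
  if (n_reps < 1) abort("n_reps must be at least 1")
  if (sigma < 0) abort("sigma must be non-negative")

  states <- truth$probe_states
  n_probes <- nrow(states)

  # per-probe copy-number term for Mo17 channels
  mo17_cn <- rep(0, n_probes)
  for (i in seq_len(nrow(truth$cnvs))) {
    run <- truth$cnvs$first_probe[i]:truth$cnvs$last_probe[i]
    mo17_cn[run] <- if (truth$cnvs$class[i] == "M_lt_B_or_PAV") pav_depth else cnv_gain
  }

  meth_b73 <- as.numeric(states$b73 == "methylated") * mu_meth
  meth_mo17 <- as.numeric(states$mo17 == "methylated") * mu_meth

  design <- tidyr::expand_grid(
    genotype = c("B73", "Mo17"),
    channel = c("IP", "input"),
    replicate = seq_len(n_reps)
  ) |>
    mutate(factor = paste(.data$genotype, .data$channel, sep = "_"),
           dye = ifelse(.data$channel == "IP", "Cy5", "Cy3"),
           array = paste0(.data$genotype, "_r", .data$replicate),
           sample_id = paste0(.data$factor, "_r", .data$replicate))

  with_substream(seed, "arrays", {
    arrays <- unique(design$array)
    array_off <- setNames(rnorm(length(arrays), 0, array_effect), arrays)
    tbl <- purrr::pmap_dfr(design, function(genotype, channel, replicate,
                                            factor, dye, array, sample_id) {
      mu <- baseline +
        (if (genotype == "Mo17") mo17_cn else 0) +
        (if (channel == "IP") (if (genotype == "B73") meth_b73 else meth_mo17) else 0) +
        (if (dye == "Cy5") dye_effect else 0) +
        array_off[[array]]
      tibble(
        probe_id = states$probe_id,
        sample_id = sample_id,
        factor = factor,
        replicate = replicate,
        dye = dye,
        array = array,
        log2_intensity = mu + rnorm(n_probes, 0, sigma)
      )
    })
    class(tbl) <- c("tm_intensities", class(tbl))
    tbl
  })
}
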