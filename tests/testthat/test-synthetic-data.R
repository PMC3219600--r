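test_that("reference tiling matches spacing and respects chromosome bounds", {
  ref <- sim_reference(chromosomes = c(chrA = 1e5), spacing = 200,
                       repeat_fraction = 0, genes_per_mb = 20, seed = 1)
  p <- ref$probes
  expect_equal(nrow(p), floor((1e5 - 50) / 200) + 1)
  expect_true(all(diff(p$start) > 0))
  expect_true(all(p$end - p$start == 50))
  expect_true(all(p$end <= 1e5))
  # non-overlapping at 200 bp spacing
  expect_true(all(diff(p$start) >= 50))
})

test_that("chr9 is tiled densely and repeats are excluded", {
  ref <- sim_reference(chromosomes = c(chr9 = 1e4), spacing = 200,
                       chr9_spacing = 56, repeat_fraction = 0,
                       genes_per_mb = 20, seed = 2)
  expect_equal(nrow(ref$probes), floor((1e4 - 50) / 56) + 1)

  ref2 <- sim_reference(chromosomes = c(chrA = 2e5), repeat_fraction = 0.3,
                        genes_per_mb = 20, seed = 3)
  p <- ref2$probes
  r <- ref2$repeats
  overlaps_repeat <- purrr::map_lgl(seq_len(nrow(p)), function(i) {
    any(r$start < p$end[i] & r$end > p$start[i])
  })
  expect_false(any(overlaps_repeat))
})

test_that("degenerate tiling errors", {
  expect_error(sim_reference(chromosomes = c(chrA = 100), spacing = 200),
               "degenerate tiling")
})

test_that("duplicated blocks give the annotated copy number, confirmed by search", {
  ref <- sim_reference(chromosomes = c(chrA = 1e5), repeat_fraction = 0,
                       genes_per_mb = 10, duplicate_blocks = 1,
                       duplicate_block_length = 5000, seed = 4)
  dup_probes <- ref$probes[ref$probes$perfect_match_count == 2, ]
  expect_gt(nrow(dup_probes), 10)
  # oracle: exact string search over the generated genome
  counts <- count_matches(
    setNames(dup_probes$sequence[1:5], dup_probes$probe_id[1:5]), ref)
  expect_equal(counts$perfect_match_count, rep(2L, 5))
  uniq <- ref$probes[ref$probes$perfect_match_count == 1, ][1:5, ]
  counts1 <- count_matches(setNames(uniq$sequence, uniq$probe_id), ref)
  expect_equal(counts1$perfect_match_count, rep(1L, 5))
})

test_that("truth respects counts, widths and methylated fraction", {
  ref <- sim_reference(chromosomes = c(chrA = 5e5), repeat_fraction = 0,
                       genes_per_mb = 20, seed = 5)
  tr <- sim_truth(ref, dmr_count = 5, cnv_count = 2, ibd_count = 1,
                  ibd_min_length = 5e4, fraction_methylated = 0.5, seed = 6)
  expect_equal(nrow(tr$dmrs), 5)
  expect_true(all(tr$dmrs$n_probes >= 3))
  # baseline identity outside implanted intervals
  tr0 <- sim_truth(ref, dmr_count = 0, cnv_count = 0, ibd_count = 0,
                   seed = 7)
  expect_equal(tr0$probe_states$b73, tr0$probe_states$mo17)
  # binomial 99% CI on the methylated fraction
  n <- nrow(tr0$probe_states)
  frac <- mean(tr0$probe_states$b73 == "methylated")
  expect_lt(abs(frac - 0.5), 2.58 * sqrt(0.25 / n))
})

test_that("trans DMRs carry exactly one controller locus; pure DMRs have no nearby SNP", {
  ref <- sim_reference(chromosomes = c(chrA = 5e5), repeat_fraction = 0,
                       genes_per_mb = 20, seed = 8)
  tr <- sim_truth(ref, dmr_count = 8, cnv_count = 0, ibd_count = 1,
                  ibd_min_length = 1e5, prop_trans = 0.5, seed = 9)
  trans <- tr$dmrs[tr$dmrs$control == "trans", ]
  expect_true(all(!is.na(trans$controller_start)))
  pure <- tr$dmrs[tr$dmrs$control == "pure_epiallele", ]
  expect_gt(nrow(pure), 0)
  for (i in seq_len(nrow(pure))) {
    near <- tr$snps$chrom == pure$chrom[i] &
      tr$snps$pos >= pure$start[i] - 1000 & tr$snps$pos < pure$end[i] + 1000
    expect_equal(sum(near), 0)
  }
  # IBD SNP density reduced
  ibd <- tr$ibd[1, ]
  in_ibd <- sum(tr$snps$chrom == ibd$chrom & tr$snps$pos >= ibd$start &
                  tr$snps$pos < ibd$end)
  rate_ibd <- in_ibd / (ibd$end - ibd$start)
  rate_bg <- nrow(tr$snps) / sum(ref$chromosomes$length)
  expect_lt(rate_ibd, rate_bg / 5)
})

test_that("array simulation is exact at sigma = 0 and reproducible under a seed", {
  ref <- sim_reference(chromosomes = c(chrA = 5e4), repeat_fraction = 0,
                       genes_per_mb = 10, seed = 10)
  tr <- sim_truth(ref, dmr_count = 2, cnv_count = 1, ibd_count = 0,
                  cnv_probes = 5, seed = 11)
  tab <- sim_arrays(tr, ref, n_reps = 1, mu_meth = 2, sigma = 0,
                    dye_effect = 0, array_effect = 0, seed = 12)
  wide <- tidyr::pivot_wider(tab[, c("probe_id", "factor", "log2_intensity")],
                             names_from = "factor",
                             values_from = "log2_intensity")
  wide <- wide[match(tr$probe_states$probe_id, wide$probe_id), ]
  # IP - input equals mu_meth exactly for methylated probes, 0 otherwise
  b73_meth <- wide$B73_IP - wide$B73_input
  expect_equal(b73_meth, ifelse(tr$probe_states$b73 == "methylated", 2, 0))
  # PAV probes: Mo17 input at the background floor, B73 input at baseline
  pav <- tr$cnvs[tr$cnvs$class == "M_lt_B_or_PAV", ]
  if (nrow(pav) > 0) {
    run <- pav$first_probe[1]:pav$last_probe[1]
    expect_equal(unique(wide$Mo17_input[run]), 10 - 3)
    expect_equal(unique(wide$B73_input[run]), 10)
  }
  # bit-exact reproducibility
  tab2 <- sim_arrays(tr, ref, n_reps = 3, sigma = 0.4, seed = 13)
  tab3 <- sim_arrays(tr, ref, n_reps = 3, sigma = 0.4, seed = 13)
  expect_identical(tab2, tab3)
  expect_error(sim_arrays(tr, ref, sigma = -1), "sigma")
})

test_that("noiseless contrasts propagate the implanted effect size", {
  ref <- sim_reference(chromosomes = c(chrA = 5e4), repeat_fraction = 0,
                       genes_per_mb = 10, seed = 14)
  tr <- sim_truth(ref, dmr_count = 2, cnv_count = 0, ibd_count = 0, seed = 15)
  tab <- sim_arrays(tr, ref, n_reps = 3, mu_meth = 2, sigma = 0, seed = 16)
  est <- fit_contrasts(tab)
  est <- est[match(tr$probe_states$probe_id, est$probe_id), ]
  expected <- ifelse(tr$probe_states$b73 == "methylated", 2, 0) -
    ifelse(tr$probe_states$mo17 == "methylated", 2, 0)
  expect_equal(est$diff_meth, expected, tolerance = 1e-12)
})

test_that("NIL states follow the governing haplotype", {
  ref <- sim_reference(chromosomes = c(chrA = 5e5, chrB = 5e5),
                       repeat_fraction = 0, genes_per_mb = 10, seed = 17)
  tr <- sim_truth(ref, dmr_count = 6, cnv_count = 0, ibd_count = 1,
                  ibd_min_length = 1e5, prop_trans = 0.5, seed = 18)
  panel <- sim_nil_panel(tr, ref, n_nils = 8, seed = 19)
  states <- panel$states
  intro <- panel$introgressions
  covered <- function(nid, cn, pos) {
    iv <- intro[intro$nil_id == nid & intro$chrom == cn, ]
    any(iv$start <= pos & pos < iv$end)
  }
  for (r in seq_len(nrow(states))) {
    s <- states[r, ]
    dmr <- tr$dmrs[tr$dmrs$dmr_id == s$dmr_id, ]
    donor <- ifelse(s$recurrent_parent == "B73", "Mo17", "B73")
    gov_geno <- if (dmr$control == "trans") {
      cmid <- (dmr$controller_start + dmr$controller_end) / 2
      if (covered(s$nil_id, dmr$controller_chrom, cmid)) donor else s$recurrent_parent
    } else {
      mid <- (dmr$start + dmr$end) / 2
      if (covered(s$nil_id, dmr$chrom, mid)) donor else s$recurrent_parent
    }
    hyper <- ifelse(dmr$direction == "B73_hyper", "B73", "Mo17")
    expected <- ifelse(gov_geno == hyper, "methylated", "unmethylated")
    expect_identical(s$state, expected)
  }
  # every DMR is mappable: some NIL carries an introgression over it
  per_dmr <- dplyr::count(states[states$haplotype_at_dmr !=
                                   states$recurrent_parent, ], dmr_id)
  expect_setequal(per_dmr$dmr_id, tr$dmrs$dmr_id)
})

test_that("qPCR simulation obeys enzyme chemistry", {
  # both genotypes unmethylated, dependent enzyme: all Cts equal
  q0 <- sim_qpcr(c(B73 = "unmethylated", Mo17 = "unmethylated"),
                 sigma_ct = 0, enzyme = "MspJI")
  expect_equal(unique(c(q0$mock_ct, q0$digest_ct)), 20)
  # Mo17 methylated only
  q1 <- sim_qpcr(c(B73 = "unmethylated", Mo17 = "methylated"),
                 delta_ct = 5, sigma_ct = 0, enzyme = "MspJI")
  expect_equal(q1$digest_ct[q1$genotype == "Mo17"] -
                 q1$mock_ct[q1$genotype == "Mo17"], 5)
  expect_equal(q1$digest_ct[q1$genotype == "B73"] -
                 q1$mock_ct[q1$genotype == "B73"], 0)
  # methylation-sensitive enzyme inverts the logic
  q2 <- sim_qpcr(c(B73 = "unmethylated", Mo17 = "methylated"),
                 delta_ct = 5, sigma_ct = 0, enzyme = "HpaII")
  expect_equal(q2$digest_ct[q2$genotype == "B73"] -
                 q2$mock_ct[q2$genotype == "B73"], 5)
  expect_equal(q2$digest_ct[q2$genotype == "Mo17"] -
                 q2$mock_ct[q2$genotype == "Mo17"], 0)
  expect_error(sim_qpcr(c(B73 = "methylated"), enzyme = "EcoRI"),
               "unknown enzyme")
  expect_error(sim_qpcr(c(B73 = "methylated"), delta_ct = -1), "delta_ct")
})

test_that("generator outputs are reproducible bit-exactly under a fixed seed", {
  r1 <- sim_reference(chromosomes = c(chrA = 1e5), genes_per_mb = 20, seed = 42)
  r2 <- sim_reference(chromosomes = c(chrA = 1e5), genes_per_mb = 20, seed = 42)
  expect_identical(r1$probes, r2$probes)
  expect_identical(as.character(r1$genome), as.character(r2$genome))
  t1 <- sim_truth(r1, ibd_min_length = 2e4, seed = 42)
  t2 <- sim_truth(r2, ibd_min_length = 2e4, seed = 42)
  expect_identical(t1$probe_states, t2$probe_states)
  expect_identical(t1$snps, t2$snps)
})
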