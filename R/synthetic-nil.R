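#' Simulate a near-isogenic-line (NIL) panel with known methylation states
#'
#' Generates NILs that are mostly one recurrent parent's genome with a small
#' number of donor introgression intervals, then derives each NIL's true
#' methylation state at every implanted DMR from the DMR's control model:
#' for `cis` and `pure_epiallele` DMRs the state follows the local haplotype
#' at the DMR; for `trans` DMRs it follows the haplotype at the controller
#' locus; NILs without an introgression at the relevant locus retain the
#' recurrent parent's state (optionally destabilized at `instability` rate).
#' For every DMR, `ensure_coverage` NILs are guaranteed to carry a donor
#' introgression spanning the DMR (and, for trans DMRs, a further subset
#' spanning the controller), so each DMR is mappable.
#'
#' @param truth A `tm_truth` from [sim_truth()].
#' @param reference The matching `tm_reference`.
#' @param n_nils Number of NILs (split between B73- and Mo17-recurrent).
#' @param segments_per_nil Random background introgressions per NIL.
#' @param ensure_coverage Minimum number of NILs with an introgression over
#'   each DMR (and over each trans controller).
#' @param instability Probability that a control NIL (no introgression at the
#'   DMR) switches away from the recurrent state (default 0: fully stable).
#' @param seed Integer seed.
#' @return A list (class `tm_nil_panel`) with `nils` (tibble: nil_id,
#'   recurrent_parent), `introgressions` (tibble: nil_id, chrom, start, end;
#'   0-based half-open, non-overlapping within a NIL), and `states`
#'   (tibble: nil_id, dmr_id, haplotype_at_dmr, state in
#'   {"methylated","unmethylated"}).
#' @export
sim_nil_panel <- function(truth, reference,
                          n_nils = 10,
                          segments_per_nil = 2,
                          ensure_coverage = 3,
                          instability = 0,
                          seed = NULL) {
  stopifnot(inherits(truth, "tm_truth"))
  if (n_nils < 1) abort("n_nils must be at least 1")
  chroms <- reference$chromosomes
  dmrs <- truth$dmrs

  with_substream(seed, "nil_panel", {
    nils <- tibble(
      nil_id = sprintf("NIL%02d", seq_len(n_nils)),
      recurrent_parent = rep(c("B73", "Mo17"), length.out = n_nils)
    )

    intro <- list()
    add_intro <- function(nil_id, cn, s, e) {
      intro[[length(intro) + 1]] <<- tibble(nil_id = nil_id, chrom = cn,
                                            start = s, end = e)
    }
    for (i in seq_len(n_nils)) {
      for (k in seq_len(segments_per_nil)) {
        ci <- sample(nrow(chroms), 1)
        w <- round(runif(1, 0.005, 0.015) * chroms$length[ci])
        s <- floor(runif(1, 0, chroms$length[ci] - w))
        add_intro(nils$nil_id[i], chroms$chrom[ci], s, s + w)
      }
    }
    # guarantee coverage of each DMR (and of trans controllers)
    cover <- function(cn, s, e, how_many, avoid = character()) {
      pool <- setdiff(nils$nil_id, avoid)
      if (length(pool) < how_many) pool <- nils$nil_id
      chosen <- sample(pool, min(how_many, length(pool)))
      clen <- chroms$length[chroms$chrom == cn]
      for (nid in chosen) {
        pad <- round(runif(2, 1000, 5000))
        add_intro(nid, cn, max(0, s - pad[1]), min(clen, e + pad[2]))
      }
      chosen
    }
    for (j in seq_len(nrow(dmrs))) {
      at_dmr <- cover(dmrs$chrom[j], dmrs$start[j], dmrs$end[j],
                      ensure_coverage)
      if (dmrs$control[j] == "trans") {
        # the informative trans pattern needs NILs introgressed at the DMR
        # but not at the controller, so keep the two sets apart
        cover(dmrs$controller_chrom[j], dmrs$controller_start[j],
              dmrs$controller_end[j], max(1, ensure_coverage - 2),
              avoid = at_dmr)
      }
    }
    introgressions <- bind_rows(intro) |>
      group_by(.data$nil_id, .data$chrom) |>
      dplyr::group_modify(function(d, g) {
        r <- IRanges::reduce(IRanges::IRanges(start = d$start + 1, end = d$end))
        tibble(start = IRanges::start(r) - 1, end = IRanges::end(r))
      }) |>
      ungroup()

    # per-NIL per-DMR haplotype and true state
    has_intro <- function(nid, cn, pos) {
      iv <- introgressions[introgressions$nil_id == nid &
                             introgressions$chrom == cn, ]
      any(iv$start <= pos & pos < iv$end)
    }
    parental_state <- function(dmr, genotype) {
      if (dmr$direction == "B73_hyper") {
        if (genotype == "B73") "methylated" else "unmethylated"
      } else {
        if (genotype == "Mo17") "methylated" else "unmethylated"
      }
    }
    states <- purrr::map_dfr(seq_len(nrow(dmrs)), function(j) {
      dmr <- dmrs[j, ]
      mid <- (dmr$start + dmr$end) / 2
      purrr::map_dfr(seq_len(n_nils), function(i) {
        nid <- nils$nil_id[i]
        recurrent <- nils$recurrent_parent[i]
        donor <- if (recurrent == "B73") "Mo17" else "B73"
        hap_dmr <- if (has_intro(nid, dmr$chrom, mid)) donor else recurrent
        governing <- if (dmr$control == "trans") {
          cmid <- (dmr$controller_start + dmr$controller_end) / 2
          if (has_intro(nid, dmr$controller_chrom, cmid)) donor else recurrent
        } else {
          hap_dmr
        }
        st <- parental_state(dmr, governing)
        # control NILs may destabilize at the configured rate
        if (hap_dmr == recurrent && governing == recurrent &&
            instability > 0 && runif(1) < instability) {
          st <- setdiff(c("methylated", "unmethylated"), st)
        }
        tibble(nil_id = nid, dmr_id = dmr$dmr_id,
               recurrent_parent = recurrent,
               haplotype_at_dmr = hap_dmr, state = st)
      })
    })

    structure(list(nils = nils, introgressions = introgressions,
                   states = states),
              class = "tm_nil_panel")
  })
}

#' Simulate methylation-digest qPCR measurements
#'
#' Emulates the qPCR readout of a methylation digest assay: for
#' methylation-dependent enzymes (MspJI, FspEI) a methylated template is cut,
#' so the digest reaction amplifies later — digest Ct = mock Ct + `delta_ct`
#' when the template is methylated; for methylation-sensitive enzymes (HpaII,
#' PstI) the logic inverts (unmethylated templates are cut). Gaussian noise
#' `sigma_ct` is added to every Ct.
#'
#' @param states A tibble with columns `assay_id`, `genotype`, `state`
#'   (`"methylated"`/`"unmethylated"`), or a named character vector of states
#'   for a single assay (names = genotypes).
#' @param baseline_ct Mock-reaction Ct.
#' @param delta_ct Ct shift caused by digestion (must be positive).
#' @param sigma_ct SD of Ct noise.
#' @param enzyme One of `"MspJI"`, `"FspEI"`, `"HpaII"`, `"PstI"`.
#' @param seed Integer seed.
#' @return Tibble with columns `assay_id`, `genotype`, `enzyme`, `mock_ct`,
#'   `digest_ct`.
#' @export
#' @examples
#' sim_qpcr(c(B73 = "methylated", Mo17 = "unmethylated"), sigma_ct = 0)
sim_qpcr <- function(states,
                     baseline_ct = 20,
                     delta_ct = 5,
                     sigma_ct = 0,
                     enzyme = "MspJI",
                     seed = NULL) {
  if (delta_ct <= 0) abort("delta_ct must be positive")
  dependent <- c("MspJI", "FspEI")
  sensitive <- c("HpaII", "PstI")
  if (!enzyme %in% c(dependent, sensitive)) {
    abort(sprintf("unknown enzyme '%s'", enzyme))
  }
  if (is.character(states) && !is.null(names(states))) {
    states <- tibble(assay_id = "assay1", genotype = names(states),
                     state = unname(states))
  }
  check_columns(states, c("assay_id", "genotype", "state"), "states")

  cut_when_methylated <- enzyme %in% dependent
  with_substream(seed, "qpcr", {
    n <- nrow(states)
    cut <- if (cut_when_methylated) states$state == "methylated"
           else states$state == "unmethylated"
    tibble(
      assay_id = states$assay_id,
      genotype = states$genotype,
      enzyme = enzyme,
      mock_ct = baseline_ct + rnorm(n, 0, sigma_ct),
      digest_ct = baseline_ct + ifelse(cut, delta_ct, 0) + rnorm(n, 0, sigma_ct)
    )
  })
}
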