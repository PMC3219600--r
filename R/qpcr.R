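#' qPCR relative methylation between two genotypes
#'
#' Computes `(b73_mock - b73_digest) - (mo17_mock - mo17_digest)`. With a
#' methylation-dependent digest (MspJI/FspEI), a methylated template is cut
#' and its digest Ct rises, so under this formula values above zero reflect
#' higher methylation in Mo17 and values below zero higher methylation in
#' B73. `sign_flip = TRUE` returns the negated value for workflows that
#' report B73-positive differentials.
#'
#' @param b73_mock,b73_digest,mo17_mock,mo17_digest Ct values (vectorized).
#' @param sign_flip Negate the result.
#' @return Numeric differential methylation value(s).
#' @export
#' @examples
#' qpcr_relative_methylation(20, 25, 20, 20)  # -5: B73 digested more
qpcr_relative_methylation <- function(b73_mock, b73_digest,
                                      mo17_mock, mo17_digest,
                                      sign_flip = FALSE) {
  val <- (b73_mock - b73_digest) - (mo17_mock - mo17_digest)
  if (sign_flip) -val else val
}

#' Call a methylation state from a digest/mock Ct pair
#'
#' For a methylation-dependent enzyme, higher methylation means more
#' digestion and a larger `digest_ct - mock_ct` differential. The
#' differential is thresholded into low / intermediate / high states.
#' A differential below the noise floor of -1 triggers a digestion-anomaly
#' warning (the digest reaction amplified earlier than the mock).
#'
#' @param mock_ct,digest_ct Ct values (vectorized).
#' @param thresholds Length-2 numeric `(t_low, t_high)`: differentials below
#'   `t_low` are `"low"`, above `t_high` `"high"`, otherwise
#'   `"intermediate"`.
#' @return Tibble `differential_ct`, `state`.
#' @export
#' @examples
#' call_state(20, 25)
call_state <- function(mock_ct, digest_ct, thresholds = c(1, 3)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  d <- digest_ct - mock_ct
  if (any(d < -1)) warn("digestion anomaly: differential Ct below -1")
  tibble(
    differential_ct = d,
    state = dplyr::case_when(
      d < thresholds[1] ~ "low",
      d > thresholds[2] ~ "high",
      TRUE ~ "intermediate"
    )
  )
}

#' Classify a DMR as cis- or trans-controlled from a NIL panel
#'
#' Among NILs carrying a donor introgression over the DMR, computes the
#' fraction whose measured state matches the donor parent's state (the cis
#' expectation: the local haplotype predicts methylation) versus the
#' recurrent parent's state (the trans expectation: an unlinked controller,
#' usually un-introgressed, keeps the recurrent pattern — a minority of
#' donor-state NILs is tolerated for the cases where the controller itself
#' is introgressed). The call is `cis` iff the donor-match fraction is at
#' least `majority` and exceeds the recurrent-match fraction; `trans` iff
#' the recurrent-match fraction is at least `majority`; otherwise
#' `ambiguous`. NILs without an introgression at the DMR form the control
#' set and yield a stability report (fractions expected / partial /
#' switched, where `partial` is an intermediate state).
#'
#' @param nil_states Tibble with `nil_id`, `state` (`"methylated"`,
#'   `"unmethylated"`, or `"intermediate"`), `recurrent_parent`
#'   (`"B73"`/`"Mo17"`), and `introgressed_at_dmr` (logical).
#' @param parental_states Named character vector, e.g.
#'   `c(B73 = "methylated", Mo17 = "unmethylated")`; the two states must
#'   differ.
#' @param majority Match fraction required for a decisive call.
#' @return A list (class `tm_cis_trans`): `call` (`"cis"`, `"trans"`,
#'   `"ambiguous"`), `donor_match_fraction`, `recurrent_match_fraction`,
#'   `n_informative`, and `stability` (tibble with fractions
#'   expected/partial/switched over control NILs).
#' @export
classify_cis_trans <- function(nil_states, parental_states,
                               majority = 0.75) {
  check_columns(nil_states, c("nil_id", "state", "recurrent_parent",
                              "introgressed_at_dmr"), "nil_states")
  if (length(unique(parental_states)) < 2) {
    abort("parental states must be distinct")
  }
  donor_of <- c(B73 = "Mo17", Mo17 = "B73")

  info <- nil_states |> filter(.data$introgressed_at_dmr)
  if (nrow(info) == 0) abort("unmappable DMR: no informative NILs")
  donor_state <- parental_states[donor_of[info$recurrent_parent]]
  recurrent_state <- parental_states[info$recurrent_parent]
  donor_frac <- mean(info$state == donor_state)
  rec_frac <- mean(info$state == recurrent_state)

  call <- if (donor_frac >= majority && donor_frac > rec_frac) {
    "cis"
  } else if (rec_frac >= majority) {
    "trans"
  } else {
    "ambiguous"
  }

  ctrl <- nil_states |> filter(!.data$introgressed_at_dmr)
  stability <- if (nrow(ctrl) > 0) {
    exp_state <- parental_states[ctrl$recurrent_parent]
    sw_state <- parental_states[donor_of[ctrl$recurrent_parent]]
    tibble(
      n_controls = nrow(ctrl),
      fraction_expected = mean(ctrl$state == exp_state),
      fraction_partial = mean(ctrl$state == "intermediate"),
      fraction_switched = mean(ctrl$state == sw_state)
    )
  } else {
    tibble(n_controls = 0L, fraction_expected = NA_real_,
           fraction_partial = NA_real_, fraction_switched = NA_real_)
  }

  structure(list(call = call,
                 donor_match_fraction = donor_frac,
                 recurrent_match_fraction = rec_frac,
                 n_informative = nrow(info),
                 stability = stability),
            class = "tm_cis_trans")
}

#' @export
print.tm_cis_trans <- function(x, ...) {
  cat(sprintf("%s (donor match %.2f, recurrent match %.2f, n = %d)\n",
              x$call, x$donor_match_fraction, x$recurrent_match_fraction,
              x$n_informative))
  invisible(x)
}

#' Tally a validation assay table
#'
#' Summarizes a table of validated variable-methylation segments: counts by
#' assay direction prefix (`BDMR_*` = B73-hypermethylated direction,
#' `MDMR_*` = Mo17 direction), by confirmation flag, by IBD flag, and by
#' cis/trans label. If an IBD region table is supplied its largest region
#' length (stop - start) is reported alongside.
#'
#' @param rows Validation tibble with columns `assay_id`, `confirmed`
#'   (logical), `ibd` (logical), `cis_trans` (character or NA) — see
#'   [read_validation_assays()].
#' @param ibd_regions Optional IBD region tibble with `start`/`end` columns
#'   (any consistent unit).
#' @return One-row tibble of counts.
#' @export
tally_validation_table <- function(rows, ibd_regions = NULL) {
  if (nrow(rows) == 0) {
    return(tibble(n_assays = 0L, n_b73_direction = 0L, n_mo17_direction = 0L,
                  n_confirmed = 0L, n_ibd = 0L, n_cis = 0L, n_trans = 0L,
                  max_ibd_length = NA_real_))
  }
  check_columns(rows, c("assay_id", "confirmed", "ibd", "cis_trans"), "rows")
  prefix <- sub("_.*$", "", rows$assay_id)
  bad <- !prefix %in% c("BDMR", "MDMR")
  if (any(bad)) {
    abort(sprintf("malformed assay row(s): %s",
                  paste(rows$assay_id[bad], collapse = ", ")))
  }
  tibble(
    n_assays = nrow(rows),
    n_b73_direction = sum(prefix == "BDMR"),
    n_mo17_direction = sum(prefix == "MDMR"),
    n_confirmed = sum(rows$confirmed, na.rm = TRUE),
    n_ibd = sum(rows$ibd, na.rm = TRUE),
    n_cis = sum(rows$cis_trans == "cis", na.rm = TRUE),
    n_trans = sum(rows$cis_trans == "trans", na.rm = TRUE),
    max_ibd_length = if (!is.null(ibd_regions))
      max(ibd_regions$end - ibd_regions$start) else NA_real_
  )
}

#' Read the packaged IBD region table
#'
#' A plain-text transcription of the published table of ten
#' identical-by-descent candidate regions of the B73-Mo17 genome
#' (coordinates in Mb) with their SNP-diversity fold reductions and variable
#' methylation counts.
#'
#' @param path Override the packaged file (mainly for tests).
#' @return Tibble with columns `chrom`, `start`, `end`, `length`
#'   (Mb), `fold_reduction`, `variable_probes`, `variable_segments`.
#' @export
read_ibd_regions <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ibd_regions_table4.csv",
                                package = "tilemeth", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(chrom = readr::col_character()))
}

#' Read the packaged validation assay table
#'
#' A plain-text transcription of the published characterization of 33
#' variable methylation segments: qPCR relative methylation under two
#' methylation-dependent enzymes, the confirmation flag, the IBD flag, and
#' the cis/trans label where mapped. Flags are consumed verbatim.
#'
#' @param path Override the packaged file.
#' @return Tibble with columns `seg_id`, `chrom`, `start`, `end`,
#'   `assay_id`, `mspji_relmeth`, `fspei_relmeth`, `confirmed`, `ibd`,
#'   `cis_trans`.
#' @export
read_validation_assays <- function(path = NULL) {
  path <- path %||% system.file("extdata", "validation_assays_table5.csv",
                                package = "tilemeth", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    chrom = readr::col_character(),
                    confirmed = readr::col_logical(),
                    ibd = readr::col_logical(),
                    cis_trans = readr::col_character()
                  ))
}
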