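#' Fit per-probe factor models and compute the methylation contrasts
#'
#' Fits, for every probe, a least-squares model with one mean per channel
#' factor (`B73_IP`, `Mo17_IP`, `B73_input`, `Mo17_input`) and computes the
#' four biologically meaningful contrasts:
#'
#' * `b73_meth`  = B73_IP - B73_input (B73 methylation, log2(IP/input));
#' * `cgh`       = Mo17_input - B73_input (copy number / hybridization
#'   efficiency);
#' * `mo17_meth_corr` = Mo17_IP - Mo17_input (Mo17 methylation corrected for
#'   differential hybridization efficiency, i.e. Mo17_IP - (cgh + B73_input));
#' * `diff_meth` = b73_meth - mo17_meth_corr (differential methylation;
#'   positive = B73 hypermethylated).
#'
#' With the single-dye-per-factor design (IP always Cy5, input always Cy3)
#' the dye term is confounded with the IP/input distinction and is absorbed
#' into the factor means; `cgh` (input vs input, same dye) and `diff_meth`
#' (IP vs IP after input correction) are the dye-free quantities.
#'
#' @param table Intensity tibble with columns `probe_id`, `factor`,
#'   `log2_intensity` (see [sim_arrays()]).
#' @return A tibble (class `tm_estimates`), one row per probe, with the four
#'   contrast estimates, their standard errors (`se_*`), the residual
#'   variance `s2` and residual degrees of freedom `df`. Probes with zero
#'   residual df keep their estimates but have `se_* = NA`. Contrast
#'   variance multipliers are stored in the `"contrast_var"` attribute.
#' @export
fit_contrasts <- function(table) {
  check_columns(table, c("probe_id", "factor", "log2_intensity"),
                "intensity table")
  factors <- c("B73_IP", "Mo17_IP", "B73_input", "Mo17_input")
  missing <- setdiff(factors, unique(table$factor))
  if (length(missing) > 0) {
    abort(sprintf("missing factor(s): %s", paste(missing, collapse = ", ")))
  }

  if (!"sample_id" %in% names(table)) {
    table <- table |>
      group_by(.data$probe_id, .data$factor) |>
      mutate(sample_id = paste0(.data$factor, "_r", row_number())) |>
      ungroup()
  }
  wide <- table |>
    select("probe_id", "sample_id", "log2_intensity") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "log2_intensity") |>
    arrange(.data$probe_id)
  samp_factor <- table |>
    distinct(.data$sample_id, .data$factor)
  samp_factor <- samp_factor$factor[match(names(wide)[-1], samp_factor$sample_id)]
  Y <- as.matrix(wide[, -1])

  X <- sapply(factors, function(f) as.numeric(samp_factor == f))
  xtx_inv <- solve(crossprod(X))
  beta <- Y %*% X %*% xtx_inv            # probes x 4 factor means
  colnames(beta) <- factors

  fitted <- beta %*% t(X)
  resid <- Y - fitted
  df <- nrow(X) - ncol(X)
  s2 <- if (df > 0) rowSums(resid^2) / df else rep(NA_real_, nrow(Y))

  # contrast matrix in factor-mean space
  L <- cbind(
    b73_meth       = c(1, 0, -1, 0),
    cgh            = c(0, 0, -1, 1),
    mo17_meth_corr = c(0, 1, 0, -1),
    diff_meth      = c(1, -1, -1, 1)
  )
  rownames(L) <- factors
  est <- beta %*% L
  v_c <- diag(t(L) %*% xtx_inv %*% L)
  se <- sqrt(outer(s2, v_c))
  colnames(se) <- paste0("se_", colnames(L))

  out <- tibble(probe_id = wide$probe_id) |>
    dplyr::bind_cols(as_tibble(est), as_tibble(se)) |>
    mutate(s2 = s2, df = df)
  attr(out, "contrast_var") <- v_c
  class(out) <- c("tm_estimates", class(out))
  out
}
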