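#' Empirical-Bayes moderated statistics with FDR control
#'
#' Shrinks each probe's residual variance toward a prior estimated across all
#' probes and computes moderated t-statistics, two-sided p-values and
#' Benjamini-Hochberg q-values for every contrast. The prior
#' `(d0, s0^2)` is obtained by moment-matching the distribution of
#' log sample variances (digamma/trigamma matching of the scaled-F model for
#' sample variances); the posterior variance is
#' `s2_post = (d0 * s0^2 + df * s2) / (d0 + df)` and the moderated t has
#' `d0 + df` degrees of freedom. Probes with zero residual df (or zero sample
#' variance) take no part in prior estimation; probes with `df = 0` keep `NA`
#' statistics.
#'
#' @param estimates A `tm_estimates` tibble from [fit_contrasts()].
#' @param fdr_q Target FDR level recorded with the fit (used by callers when
#'   thresholding q-values; default 0.05).
#' @return The estimates tibble with added columns `s2_post` and, per
#'   contrast `c`, `t_c`, `p_c`, `q_c`. Prior df `d0`, prior variance `s02`
#'   and `fdr_q` are stored as attributes and surfaced by
#'   [glance.tm_estimates()].
#' @export
moderate_stats <- function(estimates, fdr_q = 0.05) {
  check_columns(estimates, c("s2", "df"), "estimates")
  v_c <- attr(estimates, "contrast_var")
  if (is.null(v_c)) abort("estimates must come from fit_contrasts()")
  contrasts <- names(v_c)

  ok <- is.finite(estimates$s2) & estimates$s2 > 0 & estimates$df > 0
  if (sum(ok) < 10) abort("insufficient probes to estimate prior")

  prior <- fit_variance_prior(estimates$s2[ok], estimates$df[ok])
  d0 <- prior$d0
  s02 <- prior$s02

  df <- estimates$df
  s2 <- estimates$s2
  s2_post <- ifelse(df > 0 & is.finite(s2),
                    if (is.finite(d0)) (d0 * s02 + df * s2) / (d0 + df) else s02,
                    NA_real_)
  df_total <- if (is.finite(d0)) d0 + df else Inf

  out <- estimates
  out$s2_post <- s2_post
  for (cn in contrasts) {
    t_ <- out[[cn]] / sqrt(s2_post * v_c[[cn]])
    p_ <- 2 * pt(-abs(t_), df = df_total)
    out[[paste0("t_", cn)]] <- t_
    out[[paste0("p_", cn)]] <- p_
    out[[paste0("q_", cn)]] <- p.adjust(p_, method = "BH")
  }
  attr(out, "prior") <- list(d0 = d0, s02 = s02, fdr_q = fdr_q)
  attr(out, "contrast_var") <- v_c
  out
}

# moment-matching fit of the variance prior on the log scale
# (scaled-F model for sample variances; see the methods vignette)
fit_variance_prior <- function(s2, df) {
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(df / 2))
  if (is.na(evar) || evar <= 0) {
    # no excess spread beyond sampling noise: infinite prior df, pooled scale
    return(list(d0 = Inf, s02 = mean(s2)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

# Newton solve of trigamma(y) = x
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' @export
glance.tm_estimates <- function(x, ...) {
  prior <- attr(x, "prior")
  tibble(
    n_probes = nrow(x),
    residual_df = x$df[1],
    prior_df = prior$d0 %||% NA_real_,
    prior_variance = prior$s02 %||% NA_real_,
    fdr_q = prior$fdr_q %||% NA_real_
  )
}

#' @export
tidy.tm_estimates <- function(x, ...) {
  contrasts <- names(attr(x, "contrast_var"))
  purrr::map_dfr(contrasts, function(cn) {
    tibble(
      probe_id = x$probe_id,
      contrast = cn,
      estimate = x[[cn]],
      std.error = x[[paste0("se_", cn)]],
      statistic = x[[paste0("t_", cn)]] %||% rep(NA_real_, nrow(x)),
      p.value = x[[paste0("p_", cn)]] %||% rep(NA_real_, nrow(x)),
      q.value = x[[paste0("q_", cn)]] %||% rep(NA_real_, nrow(x))
    )
  })
}
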