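#' Fit a univariate Gaussian mixture by EM
#'
#' Standard expectation-maximization for a K-component univariate normal
#' mixture with unequal variances. Initialization is deterministic
#' (quantile-based: component means at evenly spaced quantiles, e.g. the
#' 10th/50th/90th percentiles for K = 3) so a fit is reproducible without a
#' seed; if a component collapses (variance below `var_floor` with
#' negligible weight) the fit restarts from jittered initial values, up to 5
#' times, before erroring. Component variances are floored at `var_floor` so
#' that exactly-clustered (noise-free) data remain fittable. Components are
#' reported sorted by mean.
#'
#' @param values Numeric data vector.
#' @param K Number of components (default 3: hypomethylated in one genotype,
#'   unchanged, hypermethylated).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param var_floor Lower bound on component variances.
#' @param seed Integer seed (used only for restart jitter).
#' @return An object of class `tm_mixture`: list with `K`, `means`,
#'   `variances`, `proportions`, `log_likelihood` (per-iteration trace in
#'   `loglik_trace`), `n_iterations`, `converged`, `n`.
#' @export
#' @examples
#' m <- em_fit(c(rnorm(100, -2, .2), rnorm(100, 2, .2)), K = 2)
#' tidy(m)
em_fit <- function(values, K = 3, tol = 1e-6, max_iter = 500,
                   var_floor = 1e-8, seed = NULL) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 2 * K) abort("need at least 2 observations per component")

  qs <- seq(0.1, 0.9, length.out = K)
  base_means <- unname(quantile(x, qs, type = 7))
  base_vars <- rep(max(var(x) / K, var_floor), K)

  run_em <- function(mu, sig2, pi_k) {
    ll_trace <- numeric()
    ll_old <- -Inf
    converged <- FALSE
    it <- 0
    while (it < max_iter) {
      it <- it + 1
      dens <- sapply(seq_len(K), function(k) pi_k[k] * dnorm(x, mu[k], sqrt(sig2[k])))
      dens <- matrix(dens, nrow = n)
      rowsum_d <- rowSums(dens)
      if (any(rowsum_d <= 0 | !is.finite(rowsum_d))) return(NULL)
      ll <- sum(log(rowsum_d))
      ll_trace <- c(ll_trace, ll)
      post <- dens / rowsum_d
      nk <- colSums(post)
      if (any(nk < 1e-10)) return(NULL)
      pi_k <- nk / n
      mu <- colSums(post * x) / nk
      sig2 <- pmax(colSums(post * (outer(x, mu, "-")^2)) / nk, var_floor)
      if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-12)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
    }
    if (any(sig2 < 1e-12)) return(NULL)
    list(mu = mu, sig2 = sig2, pi_k = pi_k, ll = ll_trace, it = it,
         converged = converged)
  }

  fit <- run_em(base_means, base_vars, rep(1 / K, K))
  attempt <- 0
  while (is.null(fit) && attempt < 5) {
    attempt <- attempt + 1
    fit <- with_substream(seed %||% 7L, paste0("em_restart_", attempt), {
      jit <- rnorm(K, 0, sd(x) / 4 + 1e-6)
      run_em(base_means + jit, base_vars * runif(K, 0.5, 2), rep(1 / K, K))
    })
  }
  if (is.null(fit)) abort("EM failed: component collapsed after 5 restarts")

  ord <- order(fit$mu)
  structure(list(
    K = K,
    means = fit$mu[ord],
    variances = fit$sig2[ord],
    proportions = fit$pi_k[ord],
    log_likelihood = fit$ll[length(fit$ll)],
    loglik_trace = fit$ll,
    n_iterations = fit$it,
    converged = fit$converged,
    n = n
  ), class = "tm_mixture")
}

#' @export
print.tm_mixture <- function(x, ...) {
  cat(sprintf("Gaussian mixture, K = %d (n = %d, loglik = %.3f, %s)\n",
              x$K, x$n, x$log_likelihood,
              if (x$converged) "converged" else "not converged"))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.tm_mixture <- function(x, ...) {
  tibble(component = seq_len(x$K), mean = x$means,
         variance = x$variances, proportion = x$proportions)
}

#' @export
glance.tm_mixture <- function(x, ...) {
  tibble(K = x$K, log_likelihood = x$log_likelihood,
         n_iterations = x$n_iterations, converged = x$converged, n = x$n)
}

#' Posterior component membership probabilities under a fitted mixture
#'
#' @param model A `tm_mixture`.
#' @param x Numeric values.
#' @return Matrix `length(x)` by `K` of posteriors; rows sum to 1.
#' @export
mixture_posterior <- function(model, x) {
  stopifnot(inherits(model, "tm_mixture"))
  dens <- sapply(seq_len(model$K), function(k) {
    model$proportions[k] * dnorm(x, model$means[k], sqrt(model$variances[k]))
  })
  dens <- matrix(dens, nrow = length(x))
  rs <- rowSums(dens)
  # values far in the tails of every component: fall back to nearest mean
  far <- rs <= 0 | !is.finite(rs)
  if (any(far)) {
    for (i in which(far)) {
      z <- abs(x[i] - model$means) / sqrt(model$variances)
      dens[i, ] <- 0
      dens[i, which.min(z)] <- 1
    }
    rs <- rowSums(dens)
  }
  dens / rs
}

#' Classify segments by mixture posterior probability
#'
#' Computes, for every segment mean, the posterior probability of each
#' mixture component and labels the segment when one decisive component
#' exceeds the threshold: the lowest-mean component maps to `"low"`, the
#' highest-mean component to `"high"` (for a 3-component fit the middle
#' component maps to `"no_change"`); segments with no posterior above the
#' threshold are `"unclassified"`. In the differential-methylation use the
#' low/high labels correspond to Mo17/B73 hypermethylation; in the CGH use,
#' to fewer/more copies in Mo17.
#'
#' @param segments Segment tibble with a `seg_mean` column.
#' @param model A `tm_mixture` fitted on the same statistic.
#' @param threshold Posterior probability required to assign a label (must be
#'   in `(0.5, 1]`; default 0.95).
#' @return The segments tibble with `label` and `posterior` (the winning
#'   component's posterior) plus per-component `posterior_k` columns.
#' @export
classify_by_posterior <- function(segments, model, threshold = 0.95) {
  stopifnot(inherits(model, "tm_mixture"))
  if (threshold <= 0.5 || threshold > 1) abort("threshold must be in (0.5, 1]")
  check_columns(segments, "seg_mean", "segments")
  post <- mixture_posterior(model, segments$seg_mean)
  K <- model$K
  comp_label <- rep("unclassified", K)
  comp_label[1] <- "low"
  comp_label[K] <- "high"
  if (K == 3) comp_label[2] <- "no_change"
  win <- apply(post, 1, which.max)
  win_p <- post[cbind(seq_len(nrow(post)), win)]
  label <- ifelse(win_p > threshold, comp_label[win], "unclassified")
  out <- segments
  out$label <- label
  out$posterior <- win_p
  for (k in seq_len(K)) out[[paste0("posterior_", k)]] <- post[, k]
  out
}
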