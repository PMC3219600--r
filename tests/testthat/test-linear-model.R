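test_that("normalization equalizes channel medians and preserves ranks", {
  ref <- sim_reference(chromosomes = c(chrA = 1e5), repeat_fraction = 0,
                       genes_per_mb = 10, seed = 1)
  tr <- sim_truth(ref, dmr_count = 2, cnv_count = 0, ibd_count = 0, seed = 2)
  tab <- sim_arrays(tr, ref, n_reps = 3, sigma = 0.3, array_effect = 0.5,
                    dye_effect = 0.3, seed = 3)
  norm <- normalize_arrays(tab)
  med <- norm |>
    dplyr::group_by(array) |>
    dplyr::summarise(m = median(log2_intensity))
  expect_lt(diff(range(med$m)), 1e-9)
  # rank order within a channel preserved
  s1 <- tab$sample_id[1]
  before <- tab$log2_intensity[tab$sample_id == s1]
  after <- norm$log2_intensity[norm$sample_id == s1]
  expect_identical(order(before), order(after))
})

test_that("a pure log2 offset between arrays is removed", {
  set.seed(4)
  base <- tibble::tibble(
    probe_id = sprintf("p%03d", 1:200),
    log2_intensity = rnorm(200, 10, 0.5)
  )
  tab <- dplyr::bind_rows(
    base |> dplyr::mutate(sample_id = "s1", array = "a1"),
    base |> dplyr::mutate(sample_id = "s2", array = "a2",
                          log2_intensity = log2_intensity + 1.0)
  )
  norm <- normalize_arrays(tab)
  m <- norm |> dplyr::group_by(array) |>
    dplyr::summarise(m = median(log2_intensity))
  expect_lt(abs(diff(m$m)), 1e-12)
  # the two channels become identical probe-by-probe
  w <- tidyr::pivot_wider(norm[, c("probe_id", "sample_id", "log2_intensity")],
                          names_from = "sample_id",
                          values_from = "log2_intensity")
  expect_equal(w$s1, w$s2, tolerance = 1e-12)
})

test_that("normalization rejects degenerate input", {
  tab <- tibble::tibble(probe_id = c("p1", "p2"), sample_id = "s1",
                        array = "a1", log2_intensity = c(1, 2))
  expect_error(normalize_arrays(tab), "at least 2 arrays")
  tab2 <- dplyr::bind_rows(
    tab |> dplyr::mutate(array = "a1", sample_id = "s1"),
    tibble::tibble(probe_id = c("p1", "p2"), sample_id = "s2",
                   array = "a2", log2_intensity = c(3, 3))
  )
  expect_error(normalize_arrays(tab2), "zero spread")
})

test_that("noiseless contrasts reproduce the contrast algebra", {
  tab <- make_intensities(list(
    pA = c(B73_IP = 2, Mo17_IP = 0, B73_input = 0, Mo17_input = 0)
  ))
  est <- fit_contrasts(tab)
  expect_equal(est$b73_meth, 2)
  expect_equal(est$cgh, 0)
  expect_equal(est$mo17_meth_corr, 0)
  expect_equal(est$diff_meth, 2)

  # PAV correction property: an input shift moves cgh but not diff_meth
  tab2 <- make_intensities(list(
    pav = c(B73_IP = 3, Mo17_IP = 1, B73_input = 1, Mo17_input = -1)
  ))
  est2 <- fit_contrasts(tab2)
  expect_equal(est2$cgh, -2)
  expect_equal(est2$b73_meth, 2)
  expect_equal(est2$mo17_meth_corr, 2)
  expect_equal(est2$diff_meth, 0)
})

test_that("estimates match an independent OLS oracle", {
  set.seed(5)
  mus <- list(
    p1 = c(B73_IP = 2.5, Mo17_IP = 1.2, B73_input = 0.3, Mo17_input = -0.4),
    p2 = c(B73_IP = 0.0, Mo17_IP = 0.0, B73_input = 0.0, Mo17_input = 0.0),
    p3 = c(B73_IP = -1, Mo17_IP = 2, B73_input = 1, Mo17_input = 1)
  )
  tab <- make_intensities(mus, n_reps = 3, noise = 0.5, seed = 6)
  est <- fit_contrasts(tab)
  for (pid in names(mus)) {
    d <- tab[tab$probe_id == pid, ]
    fit <- lm(log2_intensity ~ 0 + factor, data = d)
    cf <- coef(fit)
    names(cf) <- sub("^factor", "", names(cf))
    row <- est[est$probe_id == pid, ]
    expect_equal(row$b73_meth, unname(cf["B73_IP"] - cf["B73_input"]),
                 tolerance = 1e-10)
    expect_equal(row$cgh, unname(cf["Mo17_input"] - cf["B73_input"]),
                 tolerance = 1e-10)
    expect_equal(row$diff_meth,
                 unname((cf["B73_IP"] - cf["B73_input"]) -
                          (cf["Mo17_IP"] - cf["Mo17_input"])),
                 tolerance = 1e-10)
    expect_equal(row$s2, summary(fit)$sigma^2, tolerance = 1e-10)
    # SE of b73_meth from the oracle covariance
    v <- vcov(fit)
    cvec <- c("factorB73_IP" = 1, "factorB73_input" = -1)
    se <- sqrt(v["factorB73_IP", "factorB73_IP"] +
                 v["factorB73_input", "factorB73_input"] -
                 2 * v["factorB73_IP", "factorB73_input"])
    expect_equal(row$se_b73_meth, se, tolerance = 1e-10)
  }
})

test_that("contrast algebra identity holds on noisy fits", {
  ref <- sim_reference(chromosomes = c(chrA = 5e4), repeat_fraction = 0,
                       genes_per_mb = 10, seed = 7)
  tr <- sim_truth(ref, dmr_count = 3, cnv_count = 1, ibd_count = 0, seed = 8)
  tab <- sim_arrays(tr, ref, sigma = 0.5, seed = 9)
  est <- fit_contrasts(tab)
  expect_lt(max(abs(est$diff_meth + est$mo17_meth_corr - est$b73_meth)), 1e-9)
})

test_that("a missing factor is reported by name", {
  tab <- make_intensities(list(p1 = c(B73_IP = 1, Mo17_IP = 1,
                                      B73_input = 0, Mo17_input = 0)))
  expect_error(fit_contrasts(tab[tab$factor != "Mo17_input", ]), "Mo17_input")
})

test_that("moderation shrinks variances toward the prior, between the endpoints", {
  set.seed(10)
  mus <- setNames(
    replicate(50, c(B73_IP = 0, Mo17_IP = 0, B73_input = 0, Mo17_input = 0),
              simplify = FALSE),
    sprintf("p%03d", 1:50))
  tab <- make_intensities(mus, n_reps = 3, noise = 0.4, seed = 11)
  est <- moderate_stats(fit_contrasts(tab))
  prior <- attr(est, "prior")
  lo <- pmin(est$s2, prior$s02)
  hi <- pmax(est$s2, prior$s02)
  expect_true(all(est$s2_post >= lo - 1e-12 & est$s2_post <= hi + 1e-12))
  expect_true(prior$d0 > 0)
})

test_that("the equal-variance limit reduces the moderated t to the pooled t", {
  # all sample variances identical: the moment-matching prior has zero
  # log-variance spread, so d0 -> Inf and t uses exactly that variance
  n_probes <- 30
  set.seed(12)
  base_noise <- c(-1, 0, 1) * 0.3   # same residuals for every probe/factor
  tab <- purrr::map_dfr(sprintf("p%03d", 1:n_probes), function(pid) {
    mu <- rnorm(1)
    tidyr::expand_grid(factor = c("B73_IP", "Mo17_IP", "B73_input",
                                  "Mo17_input"),
                       replicate = 1:3) |>
      dplyr::mutate(probe_id = pid,
                    sample_id = paste0(factor, "_r", replicate),
                    log2_intensity = mu + base_noise[replicate])
  })
  est <- moderate_stats(fit_contrasts(tab))
  prior <- attr(est, "prior")
  expect_true(is.infinite(prior$d0))
  v_c <- attr(est, "contrast_var")
  t_manual <- est$diff_meth / sqrt(prior$s02 * v_c[["diff_meth"]])
  expect_equal(est$t_diff_meth, t_manual, tolerance = 1e-9)
})

test_that("the shrinkage fixed point leaves s2 = s02 unchanged", {
  # algebra of the posterior variance at s2 == s02
  d0 <- 4; s02 <- 0.25; d <- 8
  expect_equal((d0 * s02 + d * s02) / (d0 + d), s02)
})

test_that("moderation agrees with an independent empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  # homogeneous noise: the infinite-prior-df branch
  set.seed(13)
  mus <- setNames(
    replicate(200, c(B73_IP = 0, Mo17_IP = 0, B73_input = 0,
                     Mo17_input = 0), simplify = FALSE),
    sprintf("p%03d", 1:200))
  tab <- make_intensities(mus, n_reps = 3, noise = 0.5, seed = 14)
  raw <- fit_contrasts(tab)
  est <- moderate_stats(raw)
  prior <- attr(est, "prior")
  sq <- limma::squeezeVar(raw$s2, df = raw$df)
  expect_equal(prior$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(prior$s02, sq$var.prior, tolerance = 1e-6)
  expect_equal(est$s2_post, sq$var.post, tolerance = 1e-8)

  # heterogeneous per-probe noise: finite prior df via trigamma inversion
  set.seed(20)
  tab2 <- purrr::map_dfr(sprintf("q%03d", 1:300), function(pid) {
    s <- sqrt(0.1 / rchisq(1, df = 5) * 5)   # scaled inverse-chi-square SDs
    make_intensities(setNames(list(c(B73_IP = 0, Mo17_IP = 0, B73_input = 0,
                                     Mo17_input = 0)), pid),
                     n_reps = 3, noise = s)
  })
  raw2 <- fit_contrasts(tab2)
  est2 <- moderate_stats(raw2)
  prior2 <- attr(est2, "prior")
  sq2 <- limma::squeezeVar(raw2$s2, df = raw2$df)
  expect_true(is.finite(prior2$d0))
  expect_equal(prior2$d0, sq2$df.prior, tolerance = 1e-6)
  expect_equal(prior2$s02, sq2$var.prior, tolerance = 1e-6)
  expect_equal(est2$s2_post, sq2$var.post, tolerance = 1e-8)
})

test_that("null simulation p-values are calibrated and BH matches brute force", {
  ref <- sim_reference(chromosomes = c(chrA = 2.1e6), repeat_fraction = 0,
                       genes_per_mb = 2, seed = 15)
  tr <- sim_truth(ref, dmr_count = 0, cnv_count = 0, ibd_count = 0, seed = 16)
  tab <- sim_arrays(tr, ref, sigma = 0.4, seed = 17)
  est <- moderate_stats(fit_contrasts(tab))
  n <- nrow(est)
  expect_gte(n, 10000)
  frac01 <- mean(est$p_diff_meth < 0.01)
  expect_lt(abs(frac01 - 0.01), 4 * sqrt(0.01 * 0.99 / n))
  expect_lte(mean(est$q_diff_meth < 0.05), 0.055)
  # BH equivalence on these p-values and on random vectors
  expect_equal(est$q_diff_meth, bh_stepup(est$p_diff_meth), tolerance = 1e-12)
  set.seed(18)
  for (i in 1:5) {
    p <- runif(97)^runif(1, 0.5, 2)
    expect_equal(p.adjust(p, "BH"), bh_stepup(p), tolerance = 1e-12)
  }
})

test_that("moderation refuses tiny probe sets", {
  mus <- setNames(replicate(5, c(B73_IP = 0, Mo17_IP = 0, B73_input = 0,
                                 Mo17_input = 0), simplify = FALSE),
                  sprintf("p%d", 1:5))
  tab <- make_intensities(mus, n_reps = 2, noise = 0.3, seed = 19)
  expect_error(moderate_stats(fit_contrasts(tab)), "insufficient probes")
})
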