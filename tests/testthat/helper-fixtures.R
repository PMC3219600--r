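# shared fixture builders and independent oracles

# hand-built intensity table: one row per factor x replicate, per probe
make_intensities <- function(means, n_reps = 1, noise = 0, seed = NULL) {
  # means: named list probe_id -> c(B73_IP=, Mo17_IP=, B73_input=, Mo17_input=)
  if (!is.null(seed)) set.seed(seed)
  factors <- c("B73_IP", "Mo17_IP", "B73_input", "Mo17_input")
  purrr::imap_dfr(means, function(mu, pid) {
    tidyr::expand_grid(factor = factors, replicate = seq_len(n_reps)) |>
      dplyr::mutate(
        probe_id = pid,
        sample_id = paste0(factor, "_r", replicate),
        dye = ifelse(grepl("IP$", factor), "Cy5", "Cy3"),
        array = paste0(sub("_.*", "", factor), "_r", replicate),
        log2_intensity = mu[factor] + rnorm(dplyr::n(), 0, noise)
      )
  })
}

# uniform probe map on one chromosome, 100 bp spacing, 50 bp probes
make_probe_map <- function(n, chrom = "chr1", spacing = 100, width = 50) {
  tibble::tibble(
    probe_id = sprintf("p%06d", seq_len(n)),
    probe_index = seq_len(n),
    chrom = chrom,
    start = (seq_len(n) - 1) * spacing,
    end = (seq_len(n) - 1) * spacing + width,
    perfect_match_count = 1L,
    close_match_count = 0L
  )
}

# brute-force BH step-up oracle
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    q[o[i]] <- min(1, running)
  }
  q
}

# exhaustive single-change-point split maximizing the two-sample |t|
best_single_split <- function(x) {
  n <- length(x)
  best <- list(k = NA, t = -Inf)
  for (k in 1:(n - 1)) {
    a <- x[1:k]; b <- x[(k + 1):n]
    ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    pooled <- ss / (n - 2)
    if (pooled <= 0) pooled <- 1e-12
    t <- abs(mean(a) - mean(b)) / sqrt(pooled * (1 / k + 1 / (n - k)))
    if (t > best$t) best <- list(k = k, t = t)
  }
  best
}

# quadratic all-pairs interval overlap oracle (half-open intervals)
overlap_count_oracle <- function(regions, intervals, contained = FALSE) {
  vapply(seq_len(nrow(regions)), function(i) {
    same <- intervals$chrom == regions$chrom[i]
    if (contained) {
      sum(same & intervals$start >= regions$start[i] &
            intervals$end <= regions$end[i])
    } else {
      sum(same & intervals$start < regions$end[i] &
            intervals$end > regions$start[i])
    }
  }, integer(1))
}

# full-scan sliding-window edit-distance close-match oracle:
# loci on one strand where the best whole-probe alignment has <= k edits,
# merged into runs
close_match_loci_oracle <- function(probe, subject, k) {
  L <- nchar(probe)
  n <- nchar(subject)
  if (n < L - k) return(integer(0))
  widths <- max(1, L - k):(L + k)
  hit_ranges <- list()
  for (s in 1:n) {
    for (w in widths) {
      if (s + w - 1 > n) next
      window <- substr(subject, s, s + w - 1)
      d <- utils::adist(probe, window)
      if (d <= k) {
        hit_ranges[[length(hit_ranges) + 1]] <- c(s, s + w - 1)
      }
    }
  }
  if (length(hit_ranges) == 0) return(IRanges::IRanges())
  m <- do.call(rbind, hit_ranges)
  IRanges::reduce(IRanges::IRanges(start = m[, 1], end = m[, 2]))
}
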