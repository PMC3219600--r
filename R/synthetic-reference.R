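#' Generate a synthetic repeat-masked reference with a tiling probe map
#'
#' Builds a desk-scale stand-in for a tiled low-copy plant genome: random DNA
#' chromosomes, masked repeat intervals excluded from tiling, a probe map
#' spaced every `spacing` bp (a chromosome named `"chr9"`, if present, is
#' tiled more densely, mirroring the higher-resolution tiling of one
#' chromosome on the real platform), and a set of gene models with the
#' annotation fields the downstream profiling operations consume
#' (high-confidence/rejected class, strand, synteny, subgenome, expression
#' category).
#'
#' Probes are annotated with their true genomic copy number: probes that fall
#' wholly inside a duplicated block carry `perfect_match_count` equal to the
#' number of copies of that block; all other probes are unique by
#' construction (random 50-mers collide with negligible probability at these
#' genome sizes).
#'
#' @param chromosomes Named integer vector of chromosome lengths in bp.
#' @param spacing Probe spacing in bp for ordinary chromosomes.
#' @param chr9_spacing Probe spacing for the chromosome named `"chr9"`.
#' @param probe_length Probe length in bp.
#' @param repeat_fraction Fraction of each chromosome masked as repeat and
#'   excluded from tiling.
#' @param genes_per_mb Approximate gene density (genes per Mb of chromosome).
#' @param duplicate_blocks Number of duplicated block families to implant.
#' @param duplicate_block_length Length in bp of each duplicated block.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @return An object of class `tm_reference`: a list with elements
#'   `genome` ([Biostrings::DNAStringSet]), `chromosomes` (tibble of
#'   name/length/centromere), `probes`, `genes`, `exons`, `repeats`,
#'   `duplications` (tibbles). Probe coordinates are 0-based half-open.
#' @export
#' @examples
#' ref <- sim_reference(chromosomes = c(chr1 = 50000), seed = 1)
#' nrow(ref$probes)
sim_reference <- function(chromosomes = c(chr1 = 1e6, chr2 = 1e6),
                          spacing = 200,
                          chr9_spacing = 56,
                          probe_length = 50,
                          repeat_fraction = 0.2,
                          genes_per_mb = 100,
                          duplicate_blocks = 0,
                          duplicate_block_length = 5000,
                          seed = NULL) {
  if (length(chromosomes) < 1) abort("need at least one chromosome")
  if (is.null(names(chromosomes)) || any(!nzchar(names(chromosomes)))) {
    abort("chromosomes must be a named vector of lengths")
  }
  if (any(chromosomes <= 0)) abort("chromosome lengths must be positive")
  if (spacing <= 0 || chr9_spacing <= 0) abort("spacing must be positive")
  if (any(spacing >= chromosomes & names(chromosomes) != "chr9") ||
      any(chr9_spacing >= chromosomes & names(chromosomes) == "chr9")) {
    abort("degenerate tiling: spacing is not smaller than a chromosome length")
  }

  with_substream(seed, "reference", {
    chrom_names <- names(chromosomes)
    seqs <- lapply(chromosomes, function(len) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    })

    # masked repeat intervals (0-based half-open), merged
    repeats <- purrr::map2_dfr(chrom_names, as.numeric(chromosomes), function(cn, len) {
      target <- repeat_fraction * len
      if (target < 500) return(tibble(chrom = character(), start = numeric(), end = numeric()))
      iv <- list(); covered <- 0
      while (covered < target) {
        w <- round(runif(1, 500, 3000))
        s <- floor(runif(1, 0, max(1, len - w)))
        iv[[length(iv) + 1]] <- c(s, s + w)
        covered <- covered + w
      }
      m <- do.call(rbind, iv)
      r <- IRanges::reduce(IRanges::IRanges(start = m[, 1] + 1, end = m[, 2]))
      tibble(chrom = cn, start = IRanges::start(r) - 1, end = IRanges::end(r))
    })

    # duplicated block families: copy a source block to a second location
    duplications <- tibble(family = integer(), chrom = character(),
                           start = numeric(), end = numeric())
    if (duplicate_blocks > 0) {
      cn <- chrom_names[[1]]
      len <- as.numeric(chromosomes[[1]])
      if (len < 4 * duplicate_block_length) {
        abort("chromosome too short for requested duplicated blocks")
      }
      for (f in seq_len(duplicate_blocks)) {
        src <- floor(runif(1, 0, len / 2 - duplicate_block_length))
        dst <- floor(runif(1, len / 2, len - duplicate_block_length))
        block <- substr(seqs[[cn]], src + 1, src + duplicate_block_length)
        substr(seqs[[cn]], dst + 1, dst + duplicate_block_length) <- block
        duplications <- bind_rows(duplications, tibble(
          family = f, chrom = cn,
          start = c(src, dst), end = c(src, dst) + duplicate_block_length
        ))
      }
    }

    # tile probes over non-repeat sequence
    probes <- purrr::map2_dfr(chrom_names, as.numeric(chromosomes), function(cn, len) {
      sp <- if (identical(cn, "chr9")) chr9_spacing else spacing
      starts <- seq(0, len - probe_length, by = sp)
      p <- tibble(chrom = cn, start = starts, end = starts + probe_length)
      rep_cn <- repeats[repeats$chrom == cn, ]
      if (nrow(rep_cn) > 0) {
        pr <- IRanges::IRanges(start = p$start + 1, end = p$end)
        rr <- IRanges::IRanges(start = rep_cn$start + 1, end = rep_cn$end)
        hit <- IRanges::overlapsAny(pr, rr)
        p <- p[!hit, ]
      }
      p
    })
    probes <- probes |>
      arrange(factor(.data$chrom, levels = chrom_names), .data$start) |>
      mutate(probe_id = sprintf("p%06d", row_number()),
             probe_index = row_number()) |>
      select("probe_id", "probe_index", "chrom", "start", "end")

    # true copy-number annotation from the duplication bookkeeping
    probes$perfect_match_count <- 1L
    probes$close_match_count <- 0L
    if (nrow(duplications) > 0) {
      for (f in unique(duplications$family)) {
        fam <- duplications[duplications$family == f, ]
        inside <- probes$chrom %in% fam$chrom &
          purrr::map_lgl(seq_len(nrow(probes)), function(i) {
            any(probes$start[i] >= fam$start & probes$end[i] <= fam$end &
                  probes$chrom[i] == fam$chrom)
          })
        probes$perfect_match_count[inside] <- nrow(fam)
      }
    }

    # probe sequences from the genome (after duplication was written in)
    probes$sequence <- purrr::pmap_chr(
      list(probes$chrom, probes$start, probes$end),
      function(cn, s, e) substr(seqs[[cn]], s + 1, e)
    )

    genes_exons <- sim_gene_models(chrom_names, chromosomes, genes_per_mb)

    structure(list(
      genome = Biostrings::DNAStringSet(unlist(seqs)[chrom_names]),
      chromosomes = tibble(chrom = chrom_names,
                           length = as.numeric(chromosomes),
                           centromere = round(as.numeric(chromosomes) / 2)),
      probes = probes,
      genes = genes_exons$genes,
      exons = genes_exons$exons,
      repeats = repeats,
      duplications = duplications
    ), class = "tm_reference")
  })
}

# random non-overlapping gene models with annotation labels and exon structure
sim_gene_models <- function(chrom_names, chromosomes, genes_per_mb) {
  genes <- list(); exons <- list(); gid <- 0
  rejected_classes <- c("low_confidence", "transposon", "pseudogene")
  for (cn in chrom_names) {
    len <- as.numeric(chromosomes[[cn]])
    n_target <- max(1, round(genes_per_mb * len / 1e6))
    pos <- 2000
    made <- 0
    while (made < n_target && pos < len - 4000) {
      gap <- round(runif(1, 500,
                         max(600, min(5000,
                                      (len - pos) / max(1, n_target - made)))))
      glen <- round(runif(1, 500, 3000))
      start <- pos + gap
      end <- start + glen
      if (end > len - 1000) break
      gid <- gid + 1
      gene_id <- sprintf("g%05d", gid)
      is_fgs <- runif(1) < 0.4
      n_ex <- sample(1:4, 1)
      genes[[length(genes) + 1]] <- tibble(
        gene_id = gene_id, chrom = cn, start = start, end = end,
        strand = sample(c("+", "-"), 1),
        class = if (is_fgs) "FGS" else sample(rejected_classes, 1),
        syntenic = if (is_fgs) runif(1) < 0.65 else runif(1) < 0.2,
        subgenome = sample(1:2, 1),
        expression = if (is_fgs) sample(c("none", "Q1", "Q2", "Q3", "Q4"), 1)
                     else "none",
        utr5_len = min(150, floor(glen / 10)),
        utr3_len = min(150, floor(glen / 10)),
        n_exons = n_ex
      )
      # exon/intron structure: split body into 2*n_ex - 1 alternating blocks
      bounds <- round(seq(start, end, length.out = 2 * n_ex))
      ex <- tibble(
        gene_id = gene_id, chrom = cn,
        start = bounds[seq(1, 2 * n_ex - 1, by = 2)],
        end = bounds[seq(2, 2 * n_ex, by = 2)],
        exon_rank = seq_len(n_ex)
      )
      exons[[length(exons) + 1]] <- ex
      pos <- end
      made <- made + 1
    }
  }
  empty_genes <- tibble(gene_id = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        strand = character(), class = character(),
                        syntenic = logical(), subgenome = integer(),
                        expression = character(), utr5_len = numeric(),
                        utr3_len = numeric(), n_exons = integer())
  empty_exons <- tibble(gene_id = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        exon_rank = integer())
  list(genes = bind_rows(empty_genes, genes),
       exons = bind_rows(empty_exons, exons))
}
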