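#' Write a synthetic reference to standard flat files
#'
#' Writes the genome as FASTA, the probe map as BED (0-based half-open) plus
#' a TSV annotation (copy-number counts and sequences), the gene models as
#' GFF3 (1-based, inclusive) plus an attribute TSV, and the repeat mask as
#' BED.
#'
#' @param reference A `tm_reference`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_reference <- function(reference, dir) {
  stopifnot(inherits(reference, "tm_reference"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    probes_bed = file.path(dir, "probes.bed"),
    probes_tsv = file.path(dir, "probes.tsv"),
    genes_gff = file.path(dir, "genes.gff3"),
    genes_tsv = file.path(dir, "gene_attributes.tsv"),
    repeats_bed = file.path(dir, "repeats.bed")
  )
  Biostrings::writeXStringSet(reference$genome, paths[["genome"]])
  readr::write_tsv(reference$probes |>
                     select("chrom", "start", "end", "probe_id"),
                   paths[["probes_bed"]], col_names = FALSE)
  readr::write_tsv(reference$probes, paths[["probes_tsv"]])
  g <- reference$genes
  gff <- sprintf("%s\ttilemeth\tgene\t%d\t%d\t.\t%s\t.\tID=%s;class=%s",
                 g$chrom, g$start + 1, g$end, g$strand, g$gene_id, g$class)
  readr::write_lines(c("##gff-version 3", gff), paths[["genes_gff"]])
  readr::write_tsv(g, paths[["genes_tsv"]])
  readr::write_tsv(reference$repeats, paths[["repeats_bed"]],
                   col_names = FALSE)
  invisible(paths)
}

#' Write / read a long-format intensity table
#'
#' CSV schema: `probe_id, sample_id, factor, replicate, dye, array,
#' log2_intensity`.
#'
#' @param table Intensity tibble.
#' @param path CSV path.
#' @return `write_intensities` returns the path invisibly;
#'   `read_intensities` returns the tibble.
#' @export
write_intensities <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_intensities
#' @export
read_intensities <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(tbl, c("probe_id", "sample_id", "factor", "log2_intensity"),
                "intensity file")
  dup <- tbl |> count(.data$probe_id, .data$sample_id) |> filter(n > 1)
  if (nrow(dup) > 0) abort("duplicate (probe, sample) pairs in intensity file")
  class(tbl) <- c("tm_intensities", class(tbl))
  tbl
}

#' Write truth tables, NIL maps and segment calls
#'
#' Truth tables go to TSV; NIL introgression maps and segments to BED-like
#' files (0-based half-open).
#'
#' @param truth A `tm_truth`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "tm_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    states = file.path(dir, "probe_states.tsv"),
    dmrs = file.path(dir, "dmrs.tsv"),
    cnvs = file.path(dir, "cnvs.tsv"),
    ibd = file.path(dir, "ibd.bed"),
    snps = file.path(dir, "snps.tsv")
  )
  readr::write_tsv(truth$probe_states, paths[["states"]])
  readr::write_tsv(truth$dmrs, paths[["dmrs"]])
  readr::write_tsv(truth$cnvs, paths[["cnvs"]])
  readr::write_tsv(truth$ibd, paths[["ibd"]], col_names = FALSE)
  readr::write_tsv(truth$snps, paths[["snps"]])
  invisible(paths)
}

#' Write segments as BED6+
#'
#' Columns: chrom, start, end, label, seg_mean, n_probes and any posterior
#' columns present.
#'
#' @param segments Located, classified segment tibble.
#' @param path Output path.
#' @export
write_segments <- function(segments, path) {
  check_columns(segments, c("chrom", "start", "end", "label", "seg_mean",
                            "n_probes"), "segments")
  cols <- intersect(c("chrom", "start", "end", "label", "seg_mean",
                      "n_probes", "posterior"), names(segments))
  readr::write_tsv(segments[, cols], path, col_names = FALSE)
  invisible(path)
}
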