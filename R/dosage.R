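# Genome proportion, genome space, and rDNA copy-number estimation.
#
# GP is the percentage of all QC-passed input reads that map to the rDNA
# gene reference; it converts to genome space (GP x genome size / 100) and
# to copies per 1C (GP x genome size / gene length). Genome sizes are
# mandatory inputs (taken from C-value databases externally; no lookup is
# bundled) and are interpreted per 1C.

#' Genome proportion of mapped reads
#'
#' @param mapped_reads number of reads mapped to the rDNA reference.
#' @param total_reads total number of reads analyzed (all QC-passed input
#'   reads, not just mapped ones).
#' @return percentage `100 * mapped / total`.
#' @export
genome_proportion <- function(mapped_reads, total_reads) {
  stopifnot(length(mapped_reads) == 1L, length(total_reads) == 1L)
  if (total_reads <= 0) stop("total_reads must be positive")
  if (mapped_reads < 0 || mapped_reads > total_reads)
    stop("mapped_reads must be in [0, total_reads]")
  100 * mapped_reads / total_reads
}

#' Genome space occupied by an rDNA element
#'
#' @param gp genome proportion in percent.
#' @param gs genome size in bp per 1C.
#' @return bp of genome space, `gp/100 * gs`.
#' @export
genome_space <- function(gp, gs) {
  stopifnot(gp >= 0, gs > 0)
  gp / 100 * gs
}

#' rDNA copy number per 1C from genome proportion
#'
#' `copies = (GP / 100) x GS / gene_length`, with `gene_length` the length
#' of the reference used in mapping (120 bp for 5S, 3391 bp for 26S).
#'
#' @param gp genome proportion in percent.
#' @param gs genome size in bp per 1C.
#' @param gene_length mapping reference length in bp.
#' @return copies per 1C.
#' @export
copy_number <- function(gp, gs, gene_length) {
  stopifnot(gp >= 0, gs > 0)
  if (gene_length <= 0) stop("gene_length must be positive")
  gp / 100 * gs / gene_length
}

#' Split a total copy number by subgenome
#'
#' @param copies total copies per 1C.
#' @param proportions a [subgenome_proportions()] report computed from
#'   genomic (not transcriptomic) reads, or a bare numeric `p_b`.
#' @return named numeric `c(parent_a, parent_b)`; sums to `copies` exactly.
#' @export
split_by_subgenome <- function(copies, proportions) {
  p_b <- if (inherits(proportions, "subgenome_proportions"))
    proportions$p_b else proportions
  stopifnot(is.numeric(p_b), length(p_b) == 1L, p_b >= 0, p_b <= 1,
            copies >= 0)
  c(parent_a = copies * (1 - p_b), parent_b = copies * p_b)
}

#' Estimate rDNA copy number from reads end-to-end
#'
#' Maps reads to the genic reference of `ref_a` (both parental variants map
#' to it at their mutual identity, well above the similarity threshold),
#' computes GP over all input reads, converts to genome space and copies per
#' 1C, and splits copies by subgenome using diagnostic-site allele counts
#' from the same mapping. The default length fraction is 0.5 so that reads
#' overlapping the genic region by at least half their length are counted:
#' with a reference no longer than the reads, the accepted start window then
#' spans approximately one gene length per repeat copy, which keeps the
#' GP-to-copies conversion unbiased.
#'
#' @param reads named character vector of genomic reads (single-end).
#' @param units list with parental [gene_reference()]s `A` and `B`.
#' @param snps a [derive_diagnostic_snps()] result on the `A` frame.
#' @param genome_size genome size in bp per 1C.
#' @param gene_length mapping reference length; defaults to the genic
#'   length of `units$A`.
#' @param length_fraction,similarity_fraction mapping thresholds.
#' @param prefilter_k k-mer prefilter for the mapper (default 11; exact
#'   mapping decisions are unchanged for reads sharing any seed).
#' @param min_site_coverage minimum depth for a diagnostic site to enter the
#'   subgenome split.
#' @param scheme a [score_scheme()].
#' @return object of class `copy_number_estimate`: list with `mapped`,
#'   `total`, `gp` (percent), `genome_space` (bp), `copies` (per 1C),
#'   `copies_a`, `copies_b`, `p_b`, `gs`, `gene_length`, and the
#'   `proportions` report.
#' @export
estimate_copy_number <- function(reads, units, snps, genome_size,
                                 gene_length = NULL,
                                 length_fraction = 0.5,
                                 similarity_fraction = 0.8,
                                 prefilter_k = 11L, min_site_coverage = 1L,
                                 scheme = score_scheme()) {
  stopifnot(inherits(units$A, "gene_reference"))
  if (is.null(gene_length)) gene_length <- nchar(units$A$genic_seq)
  mapped <- map_reads(reads, units$A, length_fraction, similarity_fraction,
                      scheme, prefilter_k = prefilter_k,
                      keep_unmapped = FALSE)
  n_total <- attr(mapped, "n_total")
  gp <- genome_proportion(nrow(mapped), n_total)
  copies <- copy_number(gp, genome_size, gene_length)
  pu <- build_pileup(mapped, reads, units$A)
  prop <- subgenome_proportions(pu, snps, min_site_coverage)
  split <- split_by_subgenome(copies, prop)
  structure(list(mapped = nrow(mapped), total = n_total, gp = gp,
                 genome_space = genome_space(gp, genome_size),
                 copies = copies, copies_a = unname(split["parent_a"]),
                 copies_b = unname(split["parent_b"]), p_b = prop$p_b,
                 gs = genome_size, gene_length = gene_length,
                 proportions = prop),
            class = "copy_number_estimate")
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf(
    "<copy_number_estimate> GP %.4g%% (%d/%d reads), %.3g bp genome space\n",
    x$gp, x$mapped, x$total, x$genome_space))
  cat(sprintf("  copies/1C: %.0f total = %.0f parent A + %.0f parent B\n",
              x$copies, x$copies_a, x$copies_b))
  invisible(x)
}

#' Serialize a copy-number estimate as a one-row TSV
#'
#' @param est a [estimate_copy_number()] result.
#' @param path output file.
#' @param sample_label label for the row.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(est, path, sample_label = "sample") {
  stopifnot(inherits(est, "copy_number_estimate"))
  df <- data.frame(sample = sample_label, mapped = est$mapped,
                   total = est$total, gp_pct = est$gp,
                   genome_space_bp = est$genome_space,
                   copies_1c = est$copies, copies_parent_a = est$copies_a,
                   copies_parent_b = est$copies_b)
  write_tsv(df, path)
}
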