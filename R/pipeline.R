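# Report assembly tying the stages into the three analyses: expression
# proportions (SNP pooling + clade classification), rDNA dosage, and
# long-read tandem arrays. Every report embeds the resolved configuration
# and seed; with default settings outputs are byte-identical across reruns
# of the same seed and config (timestamps are opt-in for that reason).

default_run_params <- function() {
  list(length_fraction_5s = 0.9, length_fraction_26s = 0.5,
       length_fraction_gp = 0.5, similarity_fraction = 0.8,
       min_coverage = 400L, min_count = 40L, min_freq = 0.05,
       min_read_len = 111L, subsample_target = 600L, rare_frac = 0.05,
       long_min_len = 2000L, long_min_identity = 0.90)
}

provenance_block <- function(cfg, params, timestamp = FALSE) {
  list(package = "rdnaquant",
       version = as.character(utils::packageVersion("rdnaquant")),
       seed = cfg$seed, config = unclass(cfg), params = params,
       timestamp = if (timestamp) format(Sys.time(), tz = "UTC") else NULL)
}

#' Expression analysis: subgenome attribution of a transcript read pool
#'
#' Runs both estimators of the homeolog mixture: (i) SNP pooling - map all
#' reads to the parent-A genic reference, build a pileup, and pool
#' diagnostic-site allele counts; (ii) clade classification - extract and
#' trim gene reads (>110 nt), subsample, collapse to variants, build an NJ
#' tree against both parental references under Jukes-Cantor distances, and
#' count reads per parental clade with the rare/highly-mutated exclusion
#' rule. Also reports the variant diversity summary.
#'
#' @param reads named character vector of transcriptomic reads.
#' @param units list with parental [gene_reference()]s `A` and `B`.
#' @param snps a [derive_diagnostic_snps()] result (A vs B).
#' @param sample_label row label for the summary tables.
#' @param length_fraction,similarity_fraction mapping thresholds (5S
#'   defaults 0.9 / 0.8).
#' @param min_read_len trimmed-read length filter (default 111).
#' @param subsample_target classification subsample size (about 200-600).
#' @param subsample_seed seed for the subsample.
#' @param rare_frac rare-variant exclusion threshold.
#' @param min_site_coverage minimum depth for diagnostic sites in the SNP
#'   estimator.
#' @param scheme a [score_scheme()].
#' @return list with `proportions` ([subgenome_proportions()]),
#'   `classification` ([classify_reads()] output), `variants`
#'   (variant table), `diversity` (one-row summary), `inheritance`
#'   (one-row data frame shaped like the published inheritance table:
#'   total/per-parent reads and percentages from the clade classification),
#'   and `pileup`.
#' @export
run_expression_analysis <- function(reads, units, snps,
                                    sample_label = "sample",
                                    length_fraction = 0.9,
                                    similarity_fraction = 0.8,
                                    min_read_len = 111L,
                                    subsample_target = 600L,
                                    subsample_seed = 1L,
                                    rare_frac = 0.05,
                                    min_site_coverage = 1L,
                                    scheme = score_scheme()) {
  mapped <- map_reads(reads, units$A, length_fraction, similarity_fraction,
                      scheme, keep_unmapped = FALSE)
  pu <- build_pileup(mapped, reads, units$A)
  prop <- subgenome_proportions(pu, snps, min_site_coverage)

  gr <- extract_gene_reads(reads, units$A, min_read_len, length_fraction,
                           similarity_fraction, scheme)
  gr <- subsample_reads(gr, subsample_target, subsample_seed)
  vt <- collapse_variants(gr)
  cls <- classify_reads(vt, units$A, units$B, rare_frac)
  cc <- cls$counts
  classified <- cc$reads_parent_a + cc$reads_parent_b
  inheritance <- data.frame(
    sample = sample_label, total_reads = cc$n,
    reads_parent_a = cc$reads_parent_a,
    pct_parent_a = as.numeric(format_percent(
      cc$reads_parent_a / classified, 1L)),
    reads_parent_b = cc$reads_parent_b,
    pct_parent_b = as.numeric(format_percent(
      cc$reads_parent_b / classified, 1L)),
    reads_excluded = cc$reads_excluded, stringsAsFactors = FALSE)
  list(proportions = prop, classification = cls, variants = vt,
       diversity = diversity_summary(vt, sample_label),
       inheritance = inheritance, pileup = pu)
}

#' Dosage analysis: GP, genome space and copy number with subgenome split
#'
#' Thin wrapper over [estimate_copy_number()] adding a labelled one-row
#' summary table.
#'
#' @inheritParams estimate_copy_number
#' @param sample_label row label.
#' @return list with `estimate` and `summary` (one-row data frame).
#' @export
run_dosage_analysis <- function(reads, units, snps, genome_size,
                                sample_label = "sample", gene_length = NULL,
                                length_fraction = 0.5,
                                similarity_fraction = 0.8,
                                prefilter_k = 11L, scheme = score_scheme()) {
  est <- estimate_copy_number(reads, units, snps, genome_size, gene_length,
                              length_fraction, similarity_fraction,
                              prefilter_k, scheme = scheme)
  summary <- data.frame(sample = sample_label, mapped = est$mapped,
                        total = est$total, gp_pct = est$gp,
                        genome_space_bp = est$genome_space,
                        copies_1c = est$copies,
                        copies_parent_a = est$copies_a,
                        copies_parent_b = est$copies_b,
                        stringsAsFactors = FALSE)
  list(estimate = est, summary = summary)
}

#' Array analysis: long-read tandem structure
#'
#' Thin wrapper over [analyze_arrays()].
#'
#' @inheritParams analyze_arrays
#' @param sample_label row label attached to the family summary.
#' @return a `tandem_array_report` with the label attached.
#' @export
run_array_analysis <- function(reads, units, sample_label = "sample",
                               min_identity = 0.90, min_len = 2000L, ...) {
  rep <- analyze_arrays(reads, units, min_identity, min_len, ...)
  rep$families <- cbind(sample = sample_label, rep$families)
  rep
}

#' Run the full synthetic-data pipeline
#'
#' Generates parental units, transcriptomic, genomic and long reads from a
#' [sim_config()], and runs the expression, dosage and array analyses,
#' returning a merged report bundle with provenance.
#'
#' @param cfg a [sim_config()].
#' @param params optional overrides of `default_run_params()` entries.
#' @param timestamp embed a wall-clock timestamp in provenance? Off by
#'   default so that identical seed and config yield byte-identical
#'   serialized reports.
#' @return object of class `run_report`: list with `units`, `snps`,
#'   `expression`, `dosage`, `arrays`, `truth` and `provenance`.
#' @export
run_pipeline <- function(cfg = sim_config(), params = list(),
                         timestamp = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  p <- utils::modifyList(default_run_params(), params)
  units <- build_parental_units(cfg)
  snps <- derive_diagnostic_snps(units$A, units$B)

  trans <- simulate_short_reads(cfg, units, "transcriptomic")
  genom <- simulate_short_reads(cfg, units, "genomic")
  longr <- simulate_long_reads(cfg, units)

  expr <- run_expression_analysis(
    trans$reads, units, snps, sample_label = "transcriptomic",
    length_fraction = p$length_fraction_5s,
    similarity_fraction = p$similarity_fraction,
    min_read_len = p$min_read_len, subsample_target = p$subsample_target,
    subsample_seed = cfg$seed, rare_frac = p$rare_frac)

  dosage <- if (!is.null(cfg$genome_size_1c)) run_dosage_analysis(
    genom$reads, units, snps, cfg$genome_size_1c,
    sample_label = "genomic", length_fraction = p$length_fraction_gp,
    similarity_fraction = p$similarity_fraction) else NULL

  arrays <- run_array_analysis(longr$reads, units, sample_label = "long",
                               min_identity = p$long_min_identity,
                               min_len = p$long_min_len)

  truth <- list(expr_prop_b = cfg$expr_prop_b, copies_a = cfg$copies_a,
                copies_b = cfg$copies_b,
                monomer_len_a = cfg$monomer_len_a,
                monomer_len_b = cfg$monomer_len_b,
                long_families = table(longr$manifest$origin))
  structure(list(units = units, snps = snps, expression = expr,
                 dosage = dosage, arrays = arrays, truth = truth,
                 provenance = provenance_block(cfg, p, timestamp)),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$provenance$seed, "\n\nInheritance:\n")
  print(x$expression$inheritance, row.names = FALSE)
  cat("\nDiversity:\n")
  print(x$expression$diversity, row.names = FALSE)
  if (!is.null(x$dosage)) {
    cat("\nDosage:\n")
    print(x$dosage$summary, row.names = FALSE)
  }
  cat("\nArray families:\n")
  print(x$arrays$families, row.names = FALSE)
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' Emits deterministic TSV/JSON/Newick artifacts: inheritance and diversity
#' summary tables, the subgenome proportion report, the variant table, the
#' classification tree, the dosage summary, the per-read array report and
#' family summary, and a provenance JSON.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  write_tsv(report$expression$inheritance, fp("inheritance.tsv"))
  write_tsv(report$expression$diversity, fp("diversity.tsv"))
  write_snpquant_tsv(report$expression$proportions, fp("snp_proportions.tsv"))
  vt <- report$expression$variants
  va <- report$expression$classification$counts$assignments
  write_tsv(cbind(vt, va[match(vt$variant_id, va$variant_id),
                         c("assigned_parent", "excluded")]),
            fp("variants.tsv"))
  write_newick(report$expression$classification$tree, fp("tree.nwk"))
  if (!is.null(report$dosage))
    write_tsv(report$dosage$summary, fp("dosage.tsv"))
  write_tsv(report$arrays$report, fp("array_reads.tsv"))
  write_tsv(report$arrays$families, fp("array_families.tsv"))
  write_snps_tsv(report$snps, fp("diagnostic_snps.tsv"))
  jsonlite::write_json(report$provenance, fp("provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}
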