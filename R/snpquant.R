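# Variant filtering and diagnostic-SNP subgenome proportion estimation.
#
# "Countable" reads at a site are aligned reads carrying a non-gap base
# there, so site coverage is A+C+G+T (deletions are tracked separately and
# never called as alleles). The filters are descriptive thresholds, not
# hypothesis tests; no multiple-testing control is applied.

#' Call variants from a pileup under coverage/count/frequency thresholds
#'
#' One call per (site, non-reference base) passing all of: coverage >=
#' `min_coverage`, supporting count >= `min_count`, frequency
#' (count/coverage) >= `min_freq`. Defaults are the high-frequency SNP
#' filters (400 / 40 / 5%); use `low_input_filters()` for the reduced preset
#' (100 / 10 / 5%) intended for libraries with poor 5S representation.
#'
#' @param pileup a [build_pileup()] result.
#' @param min_coverage minimum countable reads covering the site.
#' @param min_count minimum countable reads supporting the allele.
#' @param min_freq minimum allele frequency.
#' @return data frame with `ref_id`, `pos` (0-based), `pos_1based`,
#'   `ref_base`, `alt_base`, `coverage`, `count`, `frequency`, `passed`
#'   (all returned rows pass; the column eases TSV round-trips).
#' @export
call_variants <- function(pileup, min_coverage = 400L, min_count = 40L,
                          min_freq = 0.05) {
  stopifnot(inherits(pileup, "pileup"),
            min_coverage >= 0, min_count >= 0, min_freq >= 0)
  counts <- pileup$counts[, c("A", "C", "G", "T"), drop = FALSE]
  L <- nrow(counts)
  empty <- data.frame(ref_id = character(), pos = integer(),
                      pos_1based = integer(), ref_base = character(),
                      alt_base = character(), coverage = integer(),
                      count = integer(), frequency = numeric(),
                      passed = logical(), stringsAsFactors = FALSE)
  if (L == 0L) return(empty)
  ref_chars <- strsplit(pileup$ref_seq, "")[[1L]]
  coverage <- rowSums(counts)
  out <- vector("list", L)
  bases <- colnames(counts)
  for (i in seq_len(L)) {
    if (coverage[i] < min_coverage) next
    alts <- setdiff(bases, ref_chars[i])
    cnt <- counts[i, alts]
    freq <- cnt / coverage[i]
    keep <- cnt >= min_count & freq >= min_freq & cnt > 0L
    if (!any(keep)) next
    out[[i]] <- data.frame(ref_id = pileup$ref_id, pos = i - 1L,
                           pos_1based = i, ref_base = ref_chars[i],
                           alt_base = alts[keep],
                           coverage = as.integer(coverage[i]),
                           count = as.integer(cnt[keep]),
                           frequency = unname(freq[keep]), passed = TRUE,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(empty)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Low-representation variant filter preset
#'
#' @return list with `min_coverage = 100`, `min_count = 10`,
#'   `min_freq = 0.05`.
#' @export
low_input_filters <- function() {
  list(min_coverage = 100L, min_count = 10L, min_freq = 0.05)
}

#' Subgenome proportions from diagnostic-site allele counts
#'
#' At each diagnostic site with depth >= `min_site_coverage`, reads carrying
#' `allele_a` vs `allele_b` are counted (any other base goes to `n_other`).
#' The primary estimator pools the counts over all qualifying sites; the
#' percentage denominator is classified evidence only (`N_a + N_b`), not
#' total depth. Per-site proportions are also reported for heterogeneity
#' diagnostics.
#'
#' @param pileup pileup on the `ref_a` coordinate frame.
#' @param snps a [derive_diagnostic_snps()] result.
#' @param min_site_coverage minimum countable depth for a site to qualify.
#' @return object of class `subgenome_proportions`: list with per-`sites`
#'   data frame (`pos_1based`, `n_allele_a`, `n_allele_b`, `n_other`,
#'   `depth`, `p_b`, `used`), pooled `n_a`, `n_b`, `p_a`, `p_b`, and
#'   `excluded_sites` (1-based positions below coverage).
#' @export
subgenome_proportions <- function(pileup, snps, min_site_coverage = 1L) {
  stopifnot(inherits(pileup, "pileup"), inherits(snps, "diagnostic_snp_set"))
  sites <- snps$sites
  if (nrow(sites) == 0L) stop("no informative sites: empty diagnostic set")
  if (max(sites$pos) >= nrow(pileup$counts))
    stop("diagnostic site beyond pileup reference length")
  counts <- pileup$counts[, c("A", "C", "G", "T"), drop = FALSE]
  idx <- sites$pos + 1L
  n_a <- counts[cbind(idx, match(sites$allele_a, colnames(counts)))]
  n_b <- counts[cbind(idx, match(sites$allele_b, colnames(counts)))]
  depth <- rowSums(counts)[idx]
  used <- depth >= min_site_coverage
  if (!any(used)) stop("no informative sites: all below minimum coverage")
  df <- data.frame(pos_1based = idx, n_allele_a = n_a, n_allele_b = n_b,
                   n_other = as.integer(depth - n_a - n_b),
                   depth = as.integer(depth),
                   p_b = ifelse(n_a + n_b > 0, n_b / (n_a + n_b), NA_real_),
                   used = used, stringsAsFactors = FALSE)
  N_a <- sum(n_a[used])
  N_b <- sum(n_b[used])
  if (N_a + N_b == 0L)
    stop("no informative sites: no reads carry either parental allele")
  structure(list(ref_a_id = snps$ref_a_id, ref_b_id = snps$ref_b_id,
                 sites = df, n_a = N_a, n_b = N_b,
                 p_a = N_a / (N_a + N_b), p_b = N_b / (N_a + N_b),
                 excluded_sites = idx[!used]),
            class = "subgenome_proportions")
}

#' @export
print.subgenome_proportions <- function(x, ...) {
  cat(sprintf(
    "<subgenome_proportions> %s:%s = %d:%d  (p_b = %s%%, %d site(s)%s)\n",
    x$ref_a_id, x$ref_b_id, x$n_a, x$n_b, format_percent(x$p_b, 1L),
    sum(x$sites$used),
    if (length(x$excluded_sites))
      paste0(", ", length(x$excluded_sites), " below coverage") else ""))
  invisible(x)
}

#' Render a proportion as a percentage string
#'
#' Rounds half away from zero, matching how the published tables render
#' integer and one-decimal percentages.
#'
#' @param x proportion(s) in `[0, 1]`.
#' @param decimals 0 or 1.
#' @return character vector of percentages (no `%` sign).
#' @export
format_percent <- function(x, decimals = 1L) {
  stopifnot(decimals %in% c(0L, 1L))
  f <- 10^decimals
  v <- sign(x) * floor(abs(x) * 100 * f + 0.5 + sqrt(.Machine$double.eps)) / f
  sprintf(paste0("%.", decimals, "f"), v)
}

#' Format a subgenome proportion report's percentages
#'
#' @param report a [subgenome_proportions()] result.
#' @param decimals 0 or 1.
#' @return list with `pct_a` and `pct_b` (pooled, rendered) and `sites`
#'   (per-site rendered `pct_b`).
#' @export
format_percentages <- function(report, decimals = 1L) {
  stopifnot(inherits(report, "subgenome_proportions"))
  list(pct_a = format_percent(report$p_a, decimals),
       pct_b = format_percent(report$p_b, decimals),
       sites = data.frame(pos_1based = report$sites$pos_1based,
                          pct_b = ifelse(is.na(report$sites$p_b), "",
                                         format_percent(
                                           ifelse(is.na(report$sites$p_b), 0,
                                                  report$sites$p_b),
                                           decimals))))
}

#' Serialize variant calls or proportion reports as TSV
#'
#' @param x a [call_variants()] data frame or [subgenome_proportions()]
#'   result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_snpquant_tsv <- function(x, path) {
  if (inherits(x, "subgenome_proportions")) {
    sites <- x$sites
    sites$row <- "site"
    pooled <- data.frame(pos_1based = NA_integer_, n_allele_a = x$n_a,
                         n_allele_b = x$n_b, n_other = NA_integer_,
                         depth = NA_integer_, p_b = x$p_b, used = TRUE,
                         row = "pooled")
    write_tsv(rbind(sites, pooled), path)
  } else {
    write_tsv(x, path)
  }
  invisible(path)
}
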