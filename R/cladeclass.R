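# Reconstruction of 5S variants from reads, neighbor-joining classification
# into parental clades under Jukes-Cantor distances, and the modified Nei
# haplotype diversity.
#
# All reads are coordinate-trimmed onto the reference genic frame, so
# variant-to-variant distances are pairwise mismatch fractions over the
# common trimmed window; no multiple sequence alignment is needed for these
# near-identical 120-mers.

#' Extract and trim gene reads
#'
#' Keeps reads whose best local alignment to the genic reference passes the
#' mapping thresholds, trims each to its aligned genic interval (projected
#' onto reference coordinates, minus-strand reads reverse-complemented into
#' genic orientation), and drops trimmed reads shorter than `min_len`
#' (default 111, i.e. strictly longer than 110 nt).
#'
#' @param reads named character vector of reads.
#' @param gene_ref the [gene_reference()] to extract against.
#' @param min_len minimum trimmed length in nt.
#' @param length_fraction,similarity_fraction mapping acceptance thresholds.
#' @param scheme a [score_scheme()].
#' @return object of class `gene_reads`: data frame with `read_id`, `seq`
#'   (reference-frame projection; deletions as `-`), `ref_start`, `ref_end`
#'   (0-based half-open). Attribute `ref_id` names the reference.
#' @export
extract_gene_reads <- function(reads, gene_ref, min_len = 111L,
                               length_fraction = 0.9,
                               similarity_fraction = 0.8,
                               scheme = score_scheme()) {
  stopifnot(inherits(gene_ref, "gene_reference"))
  if (is.null(names(reads)))
    names(reads) <- sprintf("read_%06d", seq_along(reads))
  mapped <- map_reads(reads, gene_ref, length_fraction, similarity_fraction,
                      scheme, keep_unmapped = FALSE)
  if (nrow(mapped) == 0L) {
    out <- data.frame(read_id = character(), seq = character(),
                      ref_start = integer(), ref_end = integer(),
                      stringsAsFactors = FALSE)
  } else {
    proj <- as.character(project_reads_cpp(mapped$ref_start, mapped$cigar,
                                           mapped$read_start,
                                           oriented_reads(mapped, reads)))
    out <- data.frame(read_id = mapped$read_id, seq = proj,
                      ref_start = mapped$ref_start, ref_end = mapped$ref_end,
                      stringsAsFactors = FALSE)
    out <- out[out$ref_end - out$ref_start >= min_len, , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, ref_id = gene_ref$id, class = c("gene_reads", "data.frame"))
}

#' Randomly subsample a read set without replacement
#'
#' Identity when the set already holds at most `target_n` reads. The seed is
#' recorded on the result for provenance.
#'
#' @param readset a `gene_reads` data frame.
#' @param target_n target number of reads (the analysis subsamples to about
#'   200-600 reads per species).
#' @param seed integer seed.
#' @return `gene_reads` data frame of at most `target_n` rows, original
#'   order preserved.
#' @export
subsample_reads <- function(readset, target_n = 600L, seed = 1L) {
  stopifnot(inherits(readset, "gene_reads"), target_n >= 1)
  if (nrow(readset) > target_n) {
    set.seed(seed)
    keep <- sort(sample.int(nrow(readset), target_n))
    readset <- readset[keep, , drop = FALSE]
    rownames(readset) <- NULL
  }
  attr(readset, "subsample_seed") <- seed
  readset
}

#' Collapse trimmed reads into a variant frequency table
#'
#' Reads are grouped by exact sequence identity over the common genic window
#' (the intersection of all trimmed intervals). Variants are ordered by
#' descending count (ties broken by sequence) and singletons flagged.
#'
#' @param readset a `gene_reads` data frame.
#' @return object of class `variant_table`: data frame with `variant_id`,
#'   `sequence` (common-window sequence), `count`, `singleton`. Attributes:
#'   `n` (total reads), `window` (0-based half-open common window on the
#'   reference), `ref_id`.
#' @export
collapse_variants <- function(readset) {
  stopifnot(inherits(readset, "gene_reads"))
  if (nrow(readset) == 0L) stop("empty read set")
  ws <- max(readset$ref_start)
  we <- min(readset$ref_end)
  if (we - ws < 1L)
    stop("reads share no common genic window; trim or filter first")
  key <- substring(readset$seq, ws - readset$ref_start + 1L,
                   we - readset$ref_start)
  tab <- table(key)
  ord <- order(-as.integer(tab), names(tab))
  counts <- as.integer(tab)[ord]
  seqs <- names(tab)[ord]
  out <- data.frame(variant_id = sprintf("V%03d", seq_along(seqs)),
                    sequence = seqs, count = counts,
                    singleton = counts == 1L, stringsAsFactors = FALSE)
  structure(out, n = sum(counts), window = c(ws, we),
            ref_id = attr(readset, "ref_id"),
            class = c("variant_table", "data.frame"))
}

#' Jukes-Cantor distance from a mismatch fraction
#'
#' `d = -(3/4) log(1 - (4/3) p)`. Fractions at or beyond the model's
#' saturation point (p >= 0.75) are capped at `max_distance` with a warning.
#'
#' @param p mismatch fraction(s) in `[0, 1]`.
#' @param max_distance saturation cap.
#' @return distance(s).
#' @export
jc_distance <- function(p, max_distance = 5) {
  stopifnot(all(p >= 0 & p <= 1))
  sat <- p >= 0.75
  if (any(sat))
    warning(sum(sat), " mismatch fraction(s) at or beyond Jukes-Cantor ",
            "saturation (p >= 0.75); capped at ", max_distance)
  d <- ifelse(sat, max_distance, -0.75 * log(1 - (4 / 3) * pmin(p, 0.749999)))
  pmin(d, max_distance)
}

mismatch_fraction <- function(a, b) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  comparable <- ca != "-" & cb != "-"
  if (!any(comparable)) return(0)
  sum(ca[comparable] != cb[comparable]) / sum(comparable)
}

sanitize_label <- function(x) gsub("[^A-Za-z0-9_.]", "_", x)

#' Jukes-Cantor distance matrix for a variant table plus parental references
#'
#' The parental genic regions are trimmed to the table's common window and
#' appended as leaves; pairwise mismatch fractions (gap columns excluded)
#' are transformed with [jc_distance()].
#'
#' @param table a [collapse_variants()] result.
#' @param ref_a,ref_b [gene_reference()] objects with genic regions on the
#'   same coordinate frame as the table (equal lengths required).
#' @param max_distance saturation cap passed to [jc_distance()].
#' @return symmetric labelled distance matrix; reference leaf labels are the
#'   sanitized reference ids, stored in attributes `ref_a_label` and
#'   `ref_b_label`.
#' @export
variant_distance_matrix <- function(table, ref_a, ref_b, max_distance = 5) {
  stopifnot(inherits(table, "variant_table"),
            inherits(ref_a, "gene_reference"),
            inherits(ref_b, "gene_reference"))
  if (nchar(ref_a$genic_seq) != nchar(ref_b$genic_seq))
    stop("parental genic regions must be the same length for classification")
  w <- attr(table, "window")
  if (w[2L] > nchar(ref_a$genic_seq))
    stop("variant window extends beyond the reference genic region")
  seqs <- c(table$sequence,
            substr(ref_a$genic_seq, w[1L] + 1L, w[2L]),
            substr(ref_b$genic_seq, w[1L] + 1L, w[2L]))
  la <- sanitize_label(ref_a$id)
  lb <- sanitize_label(ref_b$id)
  if (la == lb) lb <- paste0(lb, "_2")
  labels <- c(table$variant_id, la, lb)
  n <- length(seqs)
  P <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L))
    for (j in seq(i + 1L, n))
      P[i, j] <- P[j, i] <- mismatch_fraction(seqs[i], seqs[j])
  D <- matrix(jc_distance(as.vector(P), max_distance), n, n,
              dimnames = dimnames(P))
  attr(D, "ref_a_label") <- la
  attr(D, "ref_b_label") <- lb
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical agglomerative neighbor joining. Ties in the Q criterion are
#' broken by the lexicographically smallest sorted label pair (labels of
#' internal clusters are the smallest member label), so the topology is
#' deterministic. Negative branch lengths are clamped to zero with the
#' deficit moved to the sister branch.
#'
#' @param D symmetric distance matrix with zero diagonal and unique row
#'   names (>= 3 labels).
#' @return an unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  if (is.null(rownames(D))) stop("D must have row names")
  if (max(abs(D - t(D))) > 1e-8) stop("D must be symmetric")
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 labels")
  labs <- rownames(D)
  if (anyDuplicated(labs)) stop("labels must be unique")

  nwk <- labs     # growing subtree strings
  key <- labs     # tie-break key: smallest member label of each cluster
  Dm <- D
  m <- n
  while (m > 3L) {
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pk <- apply(cand, 1L, function(ij)
      paste(sort(c(key[ij[1L]], key[ij[2L]])), collapse = "\r"))
    sel <- cand[order(pk)[1L], ]
    i <- sel[[1L]]; j <- sel[[2L]]
    li <- Dm[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- Dm[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newd <- (Dm[i, ] + Dm[j, ] - Dm[i, j]) / 2
    merged <- sprintf("(%s:%.15g,%s:%.15g)", nwk[i], li, nwk[j], lj)
    mkey <- min(key[i], key[j])
    keep <- setdiff(seq_len(m), c(i, j))
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    nwk <- c(nwk[keep], merged)
    key <- c(key[keep], mkey)
    m <- m - 1L
  }
  d12 <- Dm[1L, 2L]; d13 <- Dm[1L, 3L]; d23 <- Dm[2L, 3L]
  l <- c((d12 + d13 - d23) / 2, (d12 + d23 - d13) / 2, (d13 + d23 - d12) / 2)
  l <- pmax(l, 0)
  text <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                  nwk[1L], l[1L], nwk[2L], l[2L], nwk[3L], l[3L])
  ape::read.tree(text = text)
}

#' Assign variant leaves to parental clades
#'
#' Each variant leaf is assigned to the parental reference with the smaller
#' path distance in the tree (ties go to `ref_a_label` with a warning).
#' Rare, highly mutated variants are excluded: those whose summed reads are
#' below `rare_frac` of the input reads AND whose tree distance to BOTH
#' references exceeds half the reference-to-reference path distance (i.e.
#' sequences falling outside both main clades).
#'
#' @param tree a [nj_tree()] result containing both reference leaves.
#' @param table the [collapse_variants()] table matching the variant leaves.
#' @param ref_a_label,ref_b_label reference leaf labels.
#' @param rare_frac rarity threshold as a fraction of input reads.
#' @return object of class `clade_counts`: list with `reads_parent_a`,
#'   `reads_parent_b`, `reads_excluded`, `n`, and per-variant `assignments`
#'   (data frame: `variant_id`, `count`, `dist_a`, `dist_b`,
#'   `assigned_parent`, `excluded`).
#' @export
assign_clades <- function(tree, table, ref_a_label, ref_b_label,
                          rare_frac = 0.05) {
  stopifnot(inherits(tree, "phylo"), inherits(table, "variant_table"))
  if (!all(c(ref_a_label, ref_b_label) %in% tree$tip.label))
    stop("reference leaf missing from tree")
  cd <- ape::cophenetic.phylo(tree)
  if (!all(table$variant_id %in% rownames(cd)))
    stop("variant leaf missing from tree")
  da <- cd[table$variant_id, ref_a_label]
  db <- cd[table$variant_id, ref_b_label]
  thr <- cd[ref_a_label, ref_b_label] / 2
  n <- attr(table, "n")
  assigned <- ifelse(da < db, "A", ifelse(db < da, "B", "A"))
  if (any(da == db))
    warning(sum(da == db), " variant(s) equidistant from both references; ",
            "assigned to '", ref_a_label, "' by tie-break")
  excluded <- table$count < rare_frac * n & da > thr & db > thr
  structure(list(
    reads_parent_a = sum(table$count[assigned == "A" & !excluded]),
    reads_parent_b = sum(table$count[assigned == "B" & !excluded]),
    reads_excluded = sum(table$count[excluded]),
    n = n,
    ref_a_label = ref_a_label, ref_b_label = ref_b_label,
    assignments = data.frame(variant_id = table$variant_id,
                             count = table$count, dist_a = unname(da),
                             dist_b = unname(db),
                             assigned_parent = assigned, excluded = excluded,
                             stringsAsFactors = FALSE)),
    class = "clade_counts")
}

#' @export
print.clade_counts <- function(x, ...) {
  cat(sprintf(
    "<clade_counts> n=%d: parent A %d (%s%%), parent B %d (%s%%), excluded %d\n",
    x$n, x$reads_parent_a,
    format_percent(x$reads_parent_a / max(1, x$reads_parent_a + x$reads_parent_b), 1L),
    x$reads_parent_b,
    format_percent(x$reads_parent_b / max(1, x$reads_parent_a + x$reads_parent_b), 1L),
    x$reads_excluded))
  invisible(x)
}

#' Modified Nei haplotype diversity
#'
#' `h = (n / (n - 1)) (1 - sum((x_i / n)^2))` over variant read counts
#' `x_i`, with the read count `n` in place of the usual `2n` (haploid rRNA
#' read pools rather than diploid genotypes).
#'
#' @param x a [collapse_variants()] table or an integer vector of variant
#'   counts.
#' @return diversity `h` in `[0, 1]`.
#' @export
nei_diversity <- function(x) {
  counts <- if (inherits(x, "variant_table")) x$count else x
  stopifnot(is.numeric(counts), all(counts >= 1))
  n <- sum(counts)
  if (n < 2) stop("diversity undefined for fewer than 2 reads")
  (n / (n - 1)) * (1 - sum((counts / n)^2))
}

#' Diversity summary row for a variant table
#'
#' Mirrors the published diversity-table columns: reads, variants, modified
#' Nei diversity, major-variant count, major share of all reads, and major
#' share after exclusion of singleton reads (`major / (n - singleton
#' reads)`; this last convention is not uniquely fixed by the published
#' tables and is flagged as convention-dependent in the documentation).
#'
#' @param table a [collapse_variants()] result.
#' @param sample_label label for the row.
#' @return one-row data frame: `sample`, `n_reads`, `n_variants`,
#'   `diversity`, `major_count`, `major_pct`, `major_pct_excl_singletons`.
#' @export
diversity_summary <- function(table, sample_label = "sample") {
  stopifnot(inherits(table, "variant_table"))
  n <- attr(table, "n")
  major <- table$count[1L]
  n_singleton <- sum(table$count[table$singleton])
  data.frame(sample = sample_label, n_reads = n, n_variants = nrow(table),
             diversity = if (n >= 2) nei_diversity(table) else NA_real_,
             major_count = major,
             major_pct = as.numeric(format_percent(major / n, 1L)),
             major_pct_excl_singletons =
               as.numeric(format_percent(major / (n - n_singleton), 1L)),
             stringsAsFactors = FALSE)
}

#' Classify reads into parental clades end-to-end
#'
#' Convenience wrapper: builds the JC distance matrix for a variant table
#' plus the two parental references, runs [nj_tree()] and [assign_clades()].
#'
#' @inheritParams variant_distance_matrix
#' @param rare_frac rarity threshold passed to [assign_clades()].
#' @return list with `tree` (phylo), `counts` ([assign_clades()] result) and
#'   `distance_matrix`.
#' @export
classify_reads <- function(table, ref_a, ref_b, rare_frac = 0.05,
                           max_distance = 5) {
  D <- variant_distance_matrix(table, ref_a, ref_b, max_distance)
  tree <- nj_tree(D)
  counts <- assign_clades(tree, table, attr(D, "ref_a_label"),
                          attr(D, "ref_b_label"), rare_frac)
  list(tree = tree, counts = counts, distance_matrix = D)
}

#' Write a classification tree as Newick
#'
#' @param tree a `phylo` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
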