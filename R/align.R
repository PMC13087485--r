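# Local alignment of short reads against small rDNA reference sets.
#
# Mapping is all-vs-best exact dynamic programming (Smith-Waterman) rather
# than indexed seeding: references are at most a few kb, so the optimum is
# affordable and reproducible. An optional exact k-mer prefilter skips reads
# sharing no seed with any reference (useful when background reads dominate,
# as in genome-proportion estimation); reads that share a seed are scored by
# the identical exhaustive path.

#' Alignment score scheme
#'
#' Match +1; mismatch, insertion and deletion costs applied as negative
#' contributions. Defaults are the fixed read-mapping parameters of the
#' analysis (match 1, mismatch 2, insertion 3, deletion 3).
#'
#' @param match match score (> 0).
#' @param mismatch,insertion,deletion positive cost magnitudes.
#' @return an object of class `score_scheme`.
#' @export
score_scheme <- function(match = 1L, mismatch = 2L, insertion = 3L,
                         deletion = 3L) {
  stopifnot(match > 0, mismatch > 0, insertion > 0, deletion > 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 insertion = as.integer(insertion),
                 deletion = as.integer(deletion)),
            class = "score_scheme")
}

#' Optimal local alignment of a read against a reference
#'
#' Exact Smith-Waterman under the package score scheme, with a deterministic
#' tie-break among co-optimal alignments: smallest reference start, then
#' smallest read start, then shortest alignment.
#'
#' @param read,ref DNA strings.
#' @param scheme a [score_scheme()].
#' @return list with `score`, 0-based half-open `ref_start`/`ref_end` and
#'   `read_start`/`read_end`, `cigar` (runs of `=`, `X`, `I`, `D`),
#'   `identity` (matches / alignment columns), `read_aligned_fraction`
#'   (aligned read bases / read length), or `NULL` when no positive-scoring
#'   alignment exists.
#' @export
local_align <- function(read, ref, scheme = score_scheme()) {
  stopifnot(is.character(read), nzchar(read), is.character(ref), nzchar(ref))
  a <- sw_align_cpp(toupper(read), toupper(ref), scheme$match, scheme$mismatch,
                    scheme$insertion, scheme$deletion)
  if (!a$found) return(NULL)
  list(score = a$score, ref_start = a$ref_start, ref_end = a$ref_end,
       read_start = a$read_start, read_end = a$read_end, cigar = a$cigar,
       identity = a$nmatch / a$ncols,
       read_aligned_fraction = (a$read_end - a$read_start) / nchar(read))
}

ref_sequences <- function(refs, what = c("genic", "monomer")) {
  what <- match.arg(what)
  if (inherits(refs, "gene_reference")) refs <- list(refs)
  if (is.character(refs)) {
    if (is.null(names(refs))) names(refs) <- paste0("ref", seq_along(refs))
    return(refs)
  }
  stopifnot(is.list(refs), length(refs) > 0L,
            all(vapply(refs, inherits, TRUE, "gene_reference")))
  seqs <- vapply(refs, function(r)
    if (what == "genic") r$genic_seq else monomer_seq(r), "")
  names(seqs) <- vapply(refs, `[[`, "", "id")
  seqs
}

#' Map reads against a reference set
#'
#' Each read and its reverse complement are aligned to every reference; the
#' best-scoring alignment is accepted when its aligned read fraction is at
#' least `length_fraction` and its identity at least `similarity_fraction`
#' (the analysis defaults: length fraction 0.9 for 5S, 0.5 for 26S;
#' similarity fraction 0.8). Score ties across references are broken by
#' reference order and flagged with a warning.
#'
#' @param reads character vector of reads (named, or names are generated).
#' @param refs list of [gene_reference()] (genic regions are used) or a
#'   named character vector of reference sequences.
#' @param length_fraction,similarity_fraction acceptance thresholds in
#'   `(0, 1]`.
#' @param scheme a [score_scheme()].
#' @param prefilter_k k-mer length for the exact seed prefilter; 0 (default)
#'   disables it and every read is aligned exhaustively.
#' @param keep_unmapped keep rows for unmapped reads (`NA` fields)?
#' @return data frame of class `mapped_reads` with one row per (kept) read:
#'   `read_id`, `ref_id`, `strand`, `score`, 0-based half-open
#'   `ref_start`/`ref_end`, `read_start`/`read_end` (on the oriented read),
#'   `identity`, `aligned_fraction`, `cigar`, `tie`, `mapped`. Attributes
#'   `n_total` and `n_prefiltered` record totals.
#' @export
map_reads <- function(reads, refs, length_fraction = 0.9,
                      similarity_fraction = 0.8, scheme = score_scheme(),
                      prefilter_k = 0L, keep_unmapped = TRUE) {
  if (length_fraction <= 0 || length_fraction > 1 ||
      similarity_fraction <= 0 || similarity_fraction > 1)
    stop("length_fraction and similarity_fraction must be in (0, 1]")
  seqs <- ref_sequences(refs)
  if (length(seqs) == 0L) stop("empty reference list")
  if (is.null(names(reads)))
    names(reads) <- sprintf("read_%06d", seq_along(reads))
  res <- map_reads_cpp(unname(toupper(reads)), unname(seqs), scheme$match,
                       scheme$mismatch, scheme$insertion, scheme$deletion,
                       length_fraction, similarity_fraction,
                       as.integer(prefilter_k), keep_unmapped)
  df <- data.frame(read_id = names(reads)[res$read_index],
                   ref_id = names(seqs)[res$ref_index],
                   strand = res$strand, score = res$score,
                   ref_start = res$ref_start, ref_end = res$ref_end,
                   read_start = res$read_start, read_end = res$read_end,
                   identity = res$identity,
                   aligned_fraction = res$aligned_fraction,
                   cigar = res$cigar, tie = res$tie == 1L,
                   stringsAsFactors = FALSE)
  df$mapped <- !is.na(df$ref_id)
  if (any(df$tie & df$mapped))
    warning(sum(df$tie & df$mapped),
            " read(s) aligned equally well to more than one reference; ",
            "assigned by reference order")
  attr(df, "n_total") <- res$n_total
  attr(df, "n_prefiltered") <- res$n_prefiltered
  attr(df, "ref_ids") <- names(seqs)
  class(df) <- c("mapped_reads", class(df))
  df
}

#' Map a single read
#'
#' @inheritParams map_reads
#' @param read a single DNA string.
#' @return single-row data frame (see [map_reads()]), or `NULL` if unmapped.
#' @export
map_read <- function(read, refs, length_fraction = 0.9,
                     similarity_fraction = 0.8, scheme = score_scheme()) {
  df <- map_reads(setNames(read, "read"), refs, length_fraction,
                  similarity_fraction, scheme, keep_unmapped = FALSE)
  if (nrow(df) == 0L) NULL else df
}

oriented_reads <- function(mapped, reads) {
  seqs <- toupper(unname(reads[mapped$read_id]))
  rev <- which(mapped$strand == "-")
  if (length(rev)) seqs[rev] <- reverse_complement(seqs[rev])
  seqs
}

#' Build a per-position pileup from mapped reads
#'
#' Counts aligned bases per reference position. Insertions relative to the
#' reference are ignored; deletions are counted in a separate channel.
#'
#' @param mapped a `mapped_reads` data frame (rows for other references are
#'   dropped).
#' @param reads the original reads (named character vector).
#' @param ref the [gene_reference()] (or named sequence) the pileup is on.
#' @return object of class `pileup`: list with `ref_id`, `ref_seq`, `counts`
#'   (L x 5 integer matrix, columns A, C, G, T, del), `depth` (row sums) and
#'   `n_reads`.
#' @export
build_pileup <- function(mapped, reads, ref) {
  if (inherits(ref, "gene_reference")) {
    ref_id <- ref$id
    ref_seq <- ref$genic_seq
  } else {
    stopifnot(is.character(ref), length(ref) == 1L)
    ref_id <- if (is.null(names(ref))) "ref" else names(ref)
    ref_seq <- toupper(unname(ref))
  }
  mapped <- mapped[!is.na(mapped$ref_id) & mapped$ref_id == ref_id, ,
                   drop = FALSE]
  L <- nchar(ref_seq)
  if (nrow(mapped) > 0L &&
      (max(mapped$ref_end) > L || min(mapped$ref_start) < 0L))
    stop("mapped coordinates outside reference '", ref_id, "'")
  counts <- pileup_cpp(L, mapped$ref_start, mapped$read_start, mapped$cigar,
                       oriented_reads(mapped, reads))
  colnames(counts) <- c("A", "C", "G", "T", "del")
  structure(list(ref_id = ref_id, ref_seq = ref_seq, counts = counts,
                 depth = as.integer(rowSums(counts)),
                 n_reads = nrow(mapped)),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %s: %d positions, %d reads, max depth %d\n",
              x$ref_id, nrow(x$counts), x$n_reads,
              if (nrow(x$counts)) max(x$depth) else 0L))
  invisible(x)
}

#' Serialize a pileup as TSV
#'
#' Columns: `ref`, `pos_1based`, `A`, `C`, `G`, `T`, `del`, `depth`.
#'
#' @param pileup a [build_pileup()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pileup_tsv <- function(pileup, path) {
  stopifnot(inherits(pileup, "pileup"))
  df <- data.frame(ref = pileup$ref_id,
                   pos_1based = seq_len(nrow(pileup$counts)),
                   pileup$counts, depth = pileup$depth)
  write_tsv(df, path)
}

#' Export mapped reads as SAM
#'
#' Emits a minimal SAM file (header with reference lengths; CIGAR from the
#' alignment edit operations with soft clips for unaligned read ends).
#'
#' @param mapped a `mapped_reads` data frame.
#' @param reads the original reads (named character vector).
#' @param refs the reference set used for mapping.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(mapped, reads, refs, path) {
  seqs <- ref_sequences(refs)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", names(seqs), nchar(seqs))),
             con, sep = "\n")
  for (i in seq_len(nrow(mapped))) {
    row <- mapped[i, ]
    if (is.na(row$ref_id)) {
      writeLines(paste(row$read_id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                       toupper(unname(reads[row$read_id])), "*", sep = "\t"),
                 con, sep = "\n")
      next
    }
    seq <- oriented_reads(row, reads)
    lead <- row$read_start
    trail <- nchar(seq) - row$read_end
    cigar <- paste0(if (lead > 0) paste0(lead, "S"), row$cigar,
                    if (trail > 0) paste0(trail, "S"))
    flag <- if (row$strand == "-") 16L else 0L
    writeLines(paste(row$read_id, flag, row$ref_id, row$ref_start + 1L, 255L,
                     cigar, "*", 0L, 0L, seq, "*", sep = "\t"),
               con, sep = "\n")
  }
  invisible(path)
}
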