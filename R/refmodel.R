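# Parental rDNA references and diagnostic SNP sets.
#
# Coordinates are 0-based half-open internally; every user-facing report
# renders positions 1-based.

#' Construct a parental rDNA gene reference
#'
#' A reference holds the genic region of one parental rDNA unit (120 bp for
#' 5S; user-supplied length for 26S), an optional intergenic spacer (IGS),
#' and the monomer length (genic + IGS) of the tandem repeat unit.
#'
#' @param id reference identifier.
#' @param subgenome subgenome label (e.g. `"A"`, `"H"`).
#' @param genic_seq DNA string (A/C/G/T; `U` is normalized to `T`).
#' @param igs_seq optional intergenic spacer DNA string.
#' @param monomer_len optional monomer length in bp; defaults to
#'   `nchar(genic_seq) + nchar(igs_seq)` when an IGS is given.
#' @return an object of class `gene_reference`.
#' @export
gene_reference <- function(id, subgenome, genic_seq, igs_seq = NULL,
                           monomer_len = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(subgenome), length(subgenome) == 1L)
  genic_seq <- normalize_dna(genic_seq, id)
  if (!is.null(igs_seq)) {
    igs_seq <- normalize_dna(igs_seq, paste0(id, " (IGS)"))
    if (is.null(monomer_len)) monomer_len <- nchar(genic_seq) + nchar(igs_seq)
  }
  if (!is.null(monomer_len)) {
    monomer_len <- as.integer(monomer_len)
    if (is.na(monomer_len) || monomer_len < nchar(genic_seq))
      stop("monomer_len of '", id, "' must be >= genic length")
  }
  structure(list(id = id, subgenome = subgenome, genic_seq = genic_seq,
                 igs_seq = igs_seq, monomer_len = monomer_len),
            class = "gene_reference")
}

normalize_dna <- function(seq, what) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("sequence of '", what, "' must be a non-empty string")
  seq <- chartr("Uu", "Tt", seq)
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", seq), "")[[1]])
    stop("record '", what, "' contains non-DNA characters: ",
         paste(bad, collapse = ", "),
         " (IUPAC ambiguity codes are rejected, not resolved)")
  }
  seq
}

#' @export
print.gene_reference <- function(x, ...) {
  cat(sprintf("<gene_reference> %s  subgenome %s  genic %d bp%s\n",
              x$id, x$subgenome, nchar(x$genic_seq),
              if (!is.null(x$monomer_len))
                sprintf("  monomer %d bp", x$monomer_len) else ""))
  invisible(x)
}

#' Full monomer sequence (genic + IGS) of a reference
#'
#' @param ref a `gene_reference`.
#' @return character monomer sequence; the genic region alone when no IGS is
#'   attached.
#' @export
monomer_seq <- function(ref) {
  stopifnot(inherits(ref, "gene_reference"))
  paste0(ref$genic_seq, if (is.null(ref$igs_seq)) "" else ref$igs_seq)
}

#' Load parental rDNA references from FASTA
#'
#' Headers carry `id|subgenome[|monomer_len]`. Sequences are uppercased and
#' `U` is normalized to `T`; any other non-ACGT character is an error naming
#' the offending record.
#'
#' @param path FASTA file.
#' @return list of [gene_reference()] objects.
#' @export
load_references <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- tryCatch(read_fasta(path),
                   error = function(e) stop("cannot parse FASTA '", path,
                                            "': ", conditionMessage(e)))
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  fields <- strsplit(names(seqs), "|", fixed = TRUE)
  ids <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate reference ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  refs <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    f <- fields[[i]]
    if (length(f) < 2L)
      stop("record '", ids[i], "': header must be id|subgenome[|monomer_len]")
    ml <- if (length(f) >= 3L) {
      v <- suppressWarnings(as.integer(f[3L]))
      if (is.na(v)) stop("record '", ids[i], "': invalid monomer_len '",
                         f[3L], "'")
      v
    } else NULL
    refs[[i]] <- gene_reference(ids[i], f[2L], unname(seqs[i]),
                                monomer_len = ml)
  }
  names(refs) <- ids
  refs
}

#' Percent identity of two aligned sequences
#'
#' Columns where either string carries a gap (`-`) are excluded from both
#' numerator and denominator.
#'
#' @param a,b equal-length aligned strings.
#' @return fraction of identical comparable columns, in `[0, 1]`.
#' @export
percent_identity <- function(a, b) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  if (nchar(a) != nchar(b))
    stop("aligned strings must have equal length")
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  comparable <- ca != "-" & cb != "-"
  if (!any(comparable)) stop("zero comparable (gap-free) columns")
  sum(ca[comparable] == cb[comparable]) / sum(comparable)
}

#' Derive the diagnostic SNP set distinguishing two parental references
#'
#' For equal-length genic regions (the usual case: both 5S variants are
#' 120 nt) sites are the mismatching positions. Unequal lengths are globally
#' aligned end-to-end with free end gaps under the package score scheme and
#' gap columns are excluded from the site list.
#'
#' @param ref_a,ref_b [gene_reference()] objects.
#' @return an object of class `diagnostic_snp_set` with elements
#'   `ref_a_id`, `ref_b_id`, `sites` (data frame: `pos` 0-based on the genic
#'   alignment, `allele_a`, `allele_b`) and `n_columns` (comparable
#'   alignment columns).
#' @export
derive_diagnostic_snps <- function(ref_a, ref_b) {
  stopifnot(inherits(ref_a, "gene_reference"), inherits(ref_b, "gene_reference"))
  a <- ref_a$genic_seq
  b <- ref_b$genic_seq
  if (nchar(a) != nchar(b)) {
    sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                   baseOnly = TRUE)
    aln <- Biostrings::pairwiseAlignment(a, b, type = "overlap",
                                         substitutionMatrix = sm,
                                         gapOpening = 0, gapExtension = 3)
    a <- as.character(Biostrings::alignedPattern(aln))
    b <- as.character(Biostrings::alignedSubject(aln))
  }
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  comparable <- ca != "-" & cb != "-"
  diff <- which(comparable & ca != cb)
  sites <- data.frame(pos = diff - 1L, allele_a = ca[diff], allele_b = cb[diff],
                      stringsAsFactors = FALSE)
  if (nrow(sites) == 0L)
    warning("references '", ref_a$id, "' and '", ref_b$id,
            "' are identical: no diagnostic sites, ",
            "downstream subgenome attribution is impossible")
  structure(list(ref_a_id = ref_a$id, ref_b_id = ref_b$id, sites = sites,
                 n_columns = sum(comparable)),
            class = "diagnostic_snp_set")
}

#' @export
print.diagnostic_snp_set <- function(x, ...) {
  cat(sprintf("<diagnostic_snp_set> %s vs %s: %d site(s), identity %.1f%%\n",
              x$ref_a_id, x$ref_b_id, nrow(x$sites),
              100 * (1 - nrow(x$sites) / x$n_columns)))
  if (nrow(x$sites)) {
    df <- x$sites
    df$pos_1based <- df$pos + 1L
    print(df[, c("pos_1based", "allele_a", "allele_b")], row.names = FALSE)
  }
  invisible(x)
}

#' Serialize a diagnostic SNP set as TSV
#'
#' Columns: `pos_1based`, `allele_a`, `allele_b`.
#'
#' @param snps a `diagnostic_snp_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_snps_tsv <- function(snps, path) {
  stopifnot(inherits(snps, "diagnostic_snp_set"))
  df <- data.frame(pos_1based = snps$sites$pos + 1L,
                   allele_a = snps$sites$allele_a,
                   allele_b = snps$sites$allele_b)
  write_tsv(df, path)
}
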