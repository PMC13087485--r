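#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output file.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named")
  con <- file(path, "wb")  # binary mode: byte-identical output across platforms
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", names(seqs)[i]),
                 substring(s, starts, pmin(starts + width - 1L, nchar(s)))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Write reads to a FASTQ file
#'
#' Qualities default to a constant Q30 (Sanger encoding).
#'
#' @param seqs named character vector of read sequences.
#' @param path output file.
#' @param quals optional character vector of quality strings.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path, quals = NULL) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("all reads must be named")
  if (is.null(quals)) quals <- strrep("?", nchar(seqs))
  stopifnot(length(quals) == length(seqs))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", names(seqs)), seqs, "+", quals)),
             con, sep = "\n")
  invisible(path)
}

#' Read sequences from FASTA/FASTQ
#'
#' Thin wrappers over Biostrings parsers returning plain named character
#' vectors, the representation used throughout the package.
#'
#' @param path input file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fastq")
  setNames(toupper(as.character(x)), names(x))
}

#' Write a data frame as TSV
#'
#' @param df data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

reverse_complement <- function(x) as.character(revcomp_cpp(x))
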