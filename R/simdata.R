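# Synthetic data generator emulating the two-variant 5S rDNA system of
# Cardamine allopolyploids: a pair of parental references whose genic regions
# differ at a fixed number of deamination-biased sites, strongly skewed
# transcript pools, genomic reads drawn uniformly over a genome containing
# both tandem arrays, and long reads made of tandem monomer copies.

#' Simulation configuration
#'
#' Defaults reflect the study conditions the generator emulates: a 120-nt 5S
#' genic region with 7 diagnostic substitutions, >=70% of them C->T/G->A;
#' monomers of 720 bp (parent A, the *C. amara*-like type 2 variant) and
#' 650 bp (parent B, the partner type 1 variant); per-1C copy numbers inside
#' the observed ranges (114-543 for A, 580-4930 for the partner); transcript
#' pools with <=4% minor-parent contribution (default 97.6% parent B);
#' ~120-nt reads with 0.2% substitution errors; 2-20 kb long reads.
#'
#' @param seed integer seed controlling every random draw.
#' @param l_genic genic region length in bp.
#' @param n_diag number of diagnostic substitutions between the parents.
#' @param deamination_bias minimum fraction of substitutions forced C->T or
#'   G->A (when enough C/G positions exist).
#' @param monomer_len_a,monomer_len_b monomer (genic + IGS) lengths in bp.
#' @param copies_a,copies_b rDNA copies per 1C per parent.
#' @param expr_prop_b fraction of transcript reads from parent B.
#' @param n_genomic_reads,n_transcript_reads read counts.
#' @param read_len read length in nt.
#' @param err_rate per-base substitution error probability (< 0.05).
#' @param indel_rate per-base indel probability; kept as a hook, default 0.
#' @param n_long_reads number of long reads.
#' @param long_len_range length 2 integer vector, min/max long-read bp.
#' @param n_long_a,n_long_b optional exact per-parent long-read counts;
#'   when `NULL` the parent of each long read is drawn proportionally to
#'   array size (copies x monomer length).
#' @param genome_size_1c genome size in bp per 1C; `NULL` simulates a pure
#'   rDNA pool with no background reads.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, l_genic = 120L, n_diag = 7L,
                       deamination_bias = 0.7,
                       monomer_len_a = 720L, monomer_len_b = 650L,
                       copies_a = 500L, copies_b = 2000L,
                       expr_prop_b = 0.976,
                       n_genomic_reads = 20000L, n_transcript_reads = 2000L,
                       read_len = 120L, err_rate = 0.002, indel_rate = 0,
                       n_long_reads = 22L, long_len_range = c(2000L, 20000L),
                       n_long_a = NULL, n_long_b = NULL,
                       genome_size_1c = 2.4e8) {
  cfg <- list(seed = as.integer(seed), l_genic = as.integer(l_genic),
              n_diag = as.integer(n_diag), deamination_bias = deamination_bias,
              monomer_len_a = as.integer(monomer_len_a),
              monomer_len_b = as.integer(monomer_len_b),
              copies_a = as.integer(copies_a), copies_b = as.integer(copies_b),
              expr_prop_b = expr_prop_b,
              n_genomic_reads = as.integer(n_genomic_reads),
              n_transcript_reads = as.integer(n_transcript_reads),
              read_len = as.integer(read_len), err_rate = err_rate,
              indel_rate = indel_rate,
              n_long_reads = as.integer(n_long_reads),
              long_len_range = as.integer(long_len_range),
              n_long_a = if (is.null(n_long_a)) NULL else as.integer(n_long_a),
              n_long_b = if (is.null(n_long_b)) NULL else as.integer(n_long_b),
              genome_size_1c = genome_size_1c)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (expr_prop_b < 0 || expr_prop_b > 1)
      stop("expr_prop_b must be in [0, 1]")
    if (err_rate < 0 || err_rate >= 0.05)
      stop("err_rate must be in [0, 0.05)")
    if (n_diag >= l_genic) stop("n_diag must be < l_genic")
    if (n_diag < 0) stop("n_diag must be >= 0")
    if (monomer_len_a < l_genic || monomer_len_b < l_genic)
      stop("monomer lengths must be >= genic length")
    if (length(long_len_range) != 2L ||
        long_len_range[1L] > long_len_range[2L])
      stop("long_len_range must be c(min, max)")
    if (long_len_range[1L] < max(monomer_len_a, monomer_len_b))
      stop("long_len_range minimum must be >= monomer length")
    if (!is.null(genome_size_1c)) {
      rdna_bp <- copies_a * monomer_len_a + copies_b * monomer_len_b
      if (genome_size_1c < rdna_bp)
        stop("genome_size_1c smaller than total rDNA space")
    }
  })
  invisible(cfg)
}

#' Build a pair of synthetic parental rDNA units
#'
#' Parent A's genic region is random DNA; parent B's is parent A with exactly
#' `n_diag` substitutions at distinct positions, at least a
#' `deamination_bias` fraction of them C->T or G->A (when enough C/G
#' positions exist). Each parent gets a distinct random IGS padding the unit
#' to its monomer length.
#'
#' @param cfg a [sim_config()].
#' @return list of two [gene_reference()] objects named `A` and `B`.
#' @export
build_parental_units <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  genic_a <- as.character(random_dna_cpp(1L, cfg$l_genic))
  chars <- strsplit(genic_a, "")[[1L]]

  n_diag <- cfg$n_diag
  # Diagnostic sites are kept >= 3 bp from the genic ends and mutually
  # spaced: a mismatch needs three flanking matches to outweigh local-
  # alignment clipping, so sites flush with a molecule end or clustered at
  # a terminus would be systematically unreadable. The emulated system's
  # polymorphic sites are internal and evenly spread along the gene.
  eligible <- seq(4L, cfg$l_genic - 3L)
  if (n_diag > length(eligible)) stop("n_diag exceeds available positions")
  min_gap <- min(8L, max(1L, (cfg$l_genic - 6L) %/% max(1L, n_diag)))
  cg <- eligible[chars[eligible] %in% c("C", "G")]
  n_bias <- min(ceiling(cfg$deamination_bias * n_diag), length(cg), n_diag)
  n_rest <- n_diag - n_bias
  pos_bias <- pos_rest <- integer(0)
  for (try in seq_len(1000L)) {
    pos_bias <- if (n_bias > 0) sort(sample(cg, n_bias)) else integer(0)
    remaining <- setdiff(eligible, pos_bias)
    if (n_rest > length(remaining)) stop("n_diag exceeds available positions")
    pos_rest <- if (n_rest > 0) sort(sample(remaining, n_rest)) else integer(0)
    if (n_diag < 2L ||
        min(diff(sort(c(pos_bias, pos_rest)))) >= min_gap) break
    if (try == 1000L) stop("cannot place ", n_diag,
                           " diagnostic sites at spacing ", min_gap)
  }

  chars_b <- chars
  chars_b[pos_bias] <- ifelse(chars[pos_bias] == "C", "T", "A")
  for (p in pos_rest) {
    alt <- setdiff(c("A", "C", "G", "T"), chars[p])
    # keep unconstrained sites out of the deamination class so the realized
    # C->T/G->A fraction tracks the configured bias
    if (chars[p] == "C") alt <- setdiff(alt, "T")
    if (chars[p] == "G") alt <- setdiff(alt, "A")
    chars_b[p] <- sample(alt, 1L)
  }
  genic_b <- paste(chars_b, collapse = "")

  igs_a <- as.character(random_dna_cpp(1L, cfg$monomer_len_a - cfg$l_genic))
  igs_b <- as.character(random_dna_cpp(1L, cfg$monomer_len_b - cfg$l_genic))
  list(A = gene_reference("parent_A", "A", genic_a, igs_seq = igs_a),
       B = gene_reference("parent_B", "B", genic_b, igs_seq = igs_b))
}

#' Simulate short genomic or transcriptomic reads with a truth manifest
#'
#' Genomic mode draws read start positions uniformly over a genome of
#' `genome_size_1c` bp containing both parental tandem arrays
#' (`copies x monomer_len` bp each; reads falling outside the arrays become
#' random background sequence). Transcriptomic mode draws the template
#' parent with probability `(1 - expr_prop_b) : expr_prop_b` from the genic
#' region only. Reads are fixed length, both strands equiprobable, with iid
#' substitution errors at `err_rate` and constant Q30 qualities.
#'
#' @param cfg a [sim_config()].
#' @param units output of [build_parental_units()].
#' @param mode `"genomic"` or `"transcriptomic"`.
#' @return an object of class `sim_reads`: list with `reads` (named character
#'   vector), `quals`, `manifest` (data frame: `read_id`, `origin`, `start`,
#'   `strand`), `mode`, `truth` (configured proportions/copies), `config`.
#' @export
simulate_short_reads <- function(cfg, units,
                                 mode = c("genomic", "transcriptomic")) {
  stopifnot(inherits(cfg, "sim_config"))
  mode <- match.arg(mode)
  L <- cfg$read_len

  if (mode == "genomic") {
    set.seed(cfg$seed + 1L)
    n <- cfg$n_genomic_reads
    if (L > cfg$monomer_len_a || L > cfg$monomer_len_b)
      stop("read_len exceeds template (monomer) length")
    bp_a <- as.numeric(cfg$copies_a) * cfg$monomer_len_a
    bp_b <- as.numeric(cfg$copies_b) * cfg$monomer_len_b
    if (is.null(cfg$genome_size_1c)) {
      prob <- c(bp_a, bp_b, 0)
    } else {
      prob <- c(bp_a, bp_b, cfg$genome_size_1c - bp_a - bp_b)
    }
    origin <- sample(c("A", "B", "background"), n, replace = TRUE,
                     prob = prob / sum(prob))
    starts <- integer(n)
    seqs <- character(n)
    for (p in c("A", "B")) {
      idx <- which(origin == p)
      if (!length(idx)) next
      mlen <- if (p == "A") cfg$monomer_len_a else cfg$monomer_len_b
      tpl <- strrep(monomer_seq(units[[p]]), 2L)  # linearized circular tandem
      s <- sample.int(mlen, length(idx), replace = TRUE) - 1L
      starts[idx] <- s
      seqs[idx] <- substring(tpl, s + 1L, s + L)
    }
    bg <- which(origin == "background")
    if (length(bg)) {
      seqs[bg] <- as.character(random_dna_cpp(length(bg), L))
      starts[bg] <- NA_integer_
    }
  } else {
    set.seed(cfg$seed + 2L)
    n <- cfg$n_transcript_reads
    if (L > cfg$l_genic)
      stop("read_len exceeds template (transcript) length")
    origin <- ifelse(stats::runif(n) < cfg$expr_prop_b, "B", "A")
    starts <- sample.int(cfg$l_genic - L + 1L, n, replace = TRUE) - 1L
    seqs <- character(n)
    for (p in c("A", "B")) {
      idx <- which(origin == p)
      if (!length(idx)) next
      seqs[idx] <- substring(units[[p]]$genic_seq, starts[idx] + 1L,
                             starts[idx] + L)
    }
  }

  strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
  rev <- which(strand == "-")
  if (length(rev)) seqs[rev] <- reverse_complement(seqs[rev])
  seqs <- as.character(mutate_seqs_cpp(seqs, cfg$err_rate))

  ids <- sprintf("%s_%06d", substr(mode, 1L, 1L), seq_len(n))
  names(seqs) <- ids
  manifest <- data.frame(read_id = ids, origin = origin, start = starts,
                         strand = strand, stringsAsFactors = FALSE)
  truth <- list(expr_prop_b = cfg$expr_prop_b,
                copies_a = cfg$copies_a, copies_b = cfg$copies_b,
                monomer_len_a = cfg$monomer_len_a,
                monomer_len_b = cfg$monomer_len_b,
                genome_size_1c = cfg$genome_size_1c)
  structure(list(reads = seqs, quals = setNames(strrep("?", nchar(seqs)), ids),
                 manifest = manifest, mode = mode, truth = truth,
                 config = cfg),
            class = "sim_reads")
}

#' Simulate long reads of tandem rDNA arrays
#'
#' Each long read is at least three tandem copies of one parent's monomer,
#' linearized from the circular tandem with a random phase offset, truncated
#' to a length drawn uniformly from `long_len_range`, with iid substitution
#' errors.
#'
#' @param cfg a [sim_config()].
#' @param units output of [build_parental_units()].
#' @return an object of class `sim_reads` (FASTA-style; no qualities) whose
#'   manifest records the true family of each read.
#' @export
simulate_long_reads <- function(cfg, units) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 3L)
  n <- cfg$n_long_reads
  if (!is.null(cfg$n_long_a) || !is.null(cfg$n_long_b)) {
    na <- if (is.null(cfg$n_long_a)) 0L else cfg$n_long_a
    nb <- if (is.null(cfg$n_long_b)) n - na else cfg$n_long_b
    if (na + nb != n) stop("n_long_a + n_long_b must equal n_long_reads")
    family <- sample(rep(c("A", "B"), c(na, nb)))
  } else {
    bp_a <- as.numeric(cfg$copies_a) * cfg$monomer_len_a
    bp_b <- as.numeric(cfg$copies_b) * cfg$monomer_len_b
    family <- sample(c("A", "B"), n, replace = TRUE,
                     prob = c(bp_a, bp_b) / (bp_a + bp_b))
  }
  lens <- sample(seq(cfg$long_len_range[1L], cfg$long_len_range[2L]), n,
                 replace = TRUE)
  seqs <- character(n)
  for (i in seq_len(n)) {
    mlen <- if (family[i] == "A") cfg$monomer_len_a else cfg$monomer_len_b
    k <- max(3L, ceiling(lens[i] / mlen))
    lens[i] <- max(lens[i], 3L * mlen)  # enforce >= 3 tandem copies
    phase <- sample.int(mlen, 1L) - 1L
    tandem <- strrep(monomer_seq(units[[family[i]]]), k + 1L)
    seqs[i] <- substr(tandem, phase + 1L, phase + lens[i])
  }
  seqs <- as.character(mutate_seqs_cpp(seqs, cfg$err_rate))
  ids <- sprintf("long_%03d", seq_len(n))
  names(seqs) <- ids
  manifest <- data.frame(read_id = ids, origin = family, start = NA_integer_,
                         strand = "+", length = nchar(seqs),
                         stringsAsFactors = FALSE)
  structure(list(reads = seqs, quals = NULL, manifest = manifest,
                 mode = "long", truth = list(
                   monomer_len_a = cfg$monomer_len_a,
                   monomer_len_b = cfg$monomer_len_b,
                   n_family_a = sum(family == "A"),
                   n_family_b = sum(family == "B")),
                 config = cfg),
            class = "sim_reads")
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf("<sim_reads> %s: %d reads (seed %d)\n", x$mode,
              length(x$reads), x$config$seed))
  print(table(x$manifest$origin))
  invisible(x)
}

#' Write a ground-truth manifest as JSON
#'
#' @param sim a `sim_reads` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manifest_json <- function(sim, path) {
  stopifnot(inherits(sim, "sim_reads"))
  obj <- list(mode = sim$mode, seed = sim$config$seed, truth = sim$truth,
              reads = sim$manifest)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
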