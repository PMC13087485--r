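test_that("local alignment scores match hand-derived values", {
  u <- fixture_units()
  ref <- u$A$genic_seq

  # read identical to the 120-nt reference
  a <- local_align(ref, ref)
  expect_equal(a$score, 120L)
  expect_equal(a$identity, 1)
  expect_equal(c(a$ref_start, a$ref_end), c(0L, 120L))
  expect_equal(a$read_aligned_fraction, 1)

  # one internal substitution: 119 matches - 1 mismatch = 117
  chars <- strsplit(ref, "")[[1]]
  chars[60] <- setdiff(c("A", "C", "G", "T"), chars[60])[1]
  a2 <- local_align(paste(chars, collapse = ""), ref)
  expect_equal(a2$score, 119L - 2L)
  expect_equal(a2$identity, 119 / 120)

  # completely unrelated: no positive-scoring alignment only if no shared base
  expect_null(local_align("AAAA", "CCCC"))
})

test_that("aligner agrees with the exhaustive DP oracle on random pairs", {
  set.seed(99)
  for (i in 1:300) {
    a <- rand_dna(sample(5:30, 1))
    b <- rand_dna(sample(5:30, 1))
    res <- local_align(a, b)
    expect_equal(if (is.null(res)) 0L else res$score,
                 sw_oracle_score(a, b),
                 info = sprintf("pair %d: %s vs %s", i, a, b))
  }
})

test_that("alignment handles indels with the configured gap costs", {
  ref <- strrep("ACGTT", 8)  # 40 nt
  # deletion of one base from the read: 39 matches - 3 = 36
  read <- paste0(substr(ref, 1, 19), substr(ref, 21, 40))
  a <- local_align(read, ref)
  expect_equal(a$score, sw_oracle_score(read, ref))
  expect_true(grepl("D", a$cigar))
})

test_that("read mapping applies length and similarity acceptance thresholds", {
  u <- fixture_units()
  refs <- list(u$A, u$B)

  m <- map_read(u$A$genic_seq, refs)
  expect_equal(m$ref_id, "amara")
  expect_equal(m$identity, 1)

  # 30% mismatches: unmapped at similarity 0.8
  chars <- strsplit(u$A$genic_seq, "")[[1]]
  set.seed(3)
  flip <- sample(120, 36)
  for (p in flip) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  expect_null(map_read(paste(chars, collapse = ""), refs))

  # a read shorter than length_fraction * read length of genic overlap fails
  short_overlap <- paste0(rand_dna(40), substr(u$A$genic_seq, 1, 60))
  expect_null(map_read(short_overlap, refs, length_fraction = 0.9))
  expect_false(is.null(map_read(short_overlap, refs, length_fraction = 0.5)))
})

test_that("minus-strand reads map to the same interval with equal identity", {
  u <- fixture_units()
  set.seed(4)
  for (i in 1:20) {
    start <- sample(0:20, 1)
    len <- sample(90:100, 1)
    read <- substr(u$B$genic_seq, start + 1, start + len)
    fwd <- map_read(read, list(u$A, u$B))
    rev <- map_read(as.character(rdnaquant:::reverse_complement(read)),
                    list(u$A, u$B))
    expect_equal(fwd$ref_id, rev$ref_id)
    expect_equal(fwd$ref_start, rev$ref_start)
    expect_equal(fwd$ref_end, rev$ref_end)
    expect_equal(fwd$identity, rev$identity)
    expect_equal(rev$strand, "-")
  }
})

test_that("pileups count bases, deletions and depth correctly", {
  u <- fixture_units()
  reads <- setNames(rep(u$A$genic_seq, 10), sprintf("r%02d", 1:10))
  mapped <- map_reads(reads, u$A, keep_unmapped = FALSE)
  pu <- build_pileup(mapped, reads, u$A)
  expect_equal(pu$depth, rep(10L, 120L))
  expect_equal(sum(pu$counts[, "del"]), 0L)

  # mixed alleles at a diagnostic site
  reads2 <- setNames(c(rep(u$A$genic_seq, 5), rep(u$B$genic_seq, 5)),
                     sprintf("m%02d", 1:10))
  mapped2 <- map_reads(reads2, u$A, keep_unmapped = FALSE)
  pu2 <- build_pileup(mapped2, reads2, u$A)
  site <- u$diag_pos[2]  # 1-based
  aa <- substr(u$A$genic_seq, site, site)
  ab <- substr(u$B$genic_seq, site, site)
  expect_equal(unname(pu2$counts[site, aa]), 5L)
  expect_equal(unname(pu2$counts[site, ab]), 5L)
  expect_equal(pu2$depth[site], 10L)
  # depth never exceeds the number of mapped reads
  expect_true(all(pu2$depth <= nrow(mapped2)))
})

test_that("k-mer prefilter changes no mapping decisions on simulated reads", {
  cfg <- sim_config(seed = 20, n_genomic_reads = 400, genome_size_1c = 3e6,
                    copies_a = 300, copies_b = 1000)
  units <- build_parental_units(cfg)
  sim <- simulate_short_reads(cfg, units, "genomic")
  exact <- map_reads(sim$reads, units$A, length_fraction = 0.5,
                     keep_unmapped = FALSE)
  seeded <- map_reads(sim$reads, units$A, length_fraction = 0.5,
                      prefilter_k = 11, keep_unmapped = FALSE)
  expect_identical(exact$read_id, seeded$read_id)
  expect_identical(exact$score, seeded$score)
  expect_gt(attr(seeded, "n_prefiltered"), 0L)
})

test_that("SAM export round-trips coordinates through samtools-style fields", {
  u <- fixture_units()
  reads <- setNames(c(u$A$genic_seq,
                      as.character(rdnaquant:::reverse_complement(
                        substr(u$B$genic_seq, 1, 115))),
                      rand_dna(50)),
                    c("fwd", "rev", "junk"))
  mapped <- map_reads(reads, list(u$A, u$B))
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(mapped, reads, list(u$A, u$B), sam)
  lines <- readLines(sam)
  expect_equal(sum(startsWith(lines, "@SQ")), 2L)
  body <- strsplit(lines[!startsWith(lines, "@")], "\t")
  expect_equal(length(body), 3L)
  fwd <- body[[which(vapply(body, `[`, "", 1) == "fwd")]]
  expect_equal(fwd[2], "0")
  expect_equal(fwd[3], "amara")
  expect_equal(fwd[4], "1")
  expect_equal(fwd[6], "120=")
  rev <- body[[which(vapply(body, `[`, "", 1) == "rev")]]
  expect_equal(rev[2], "16")
  junk <- body[[which(vapply(body, `[`, "", 1) == "junk")]]
  expect_equal(junk[2], "4")
})

test_that("simulated mixtures reach the expected minor-allele frequencies", {
  cfg <- sim_config(seed = 21, n_transcript_reads = 4000, expr_prop_b = 0.976,
                    err_rate = 0.002)
  units <- build_parental_units(cfg)
  snps <- derive_diagnostic_snps(units$A, units$B)
  sim <- simulate_short_reads(cfg, units, "transcriptomic")
  mapped <- map_reads(sim$reads, units$A, keep_unmapped = FALSE)
  pu <- build_pileup(mapped, sim$reads, units$A)
  counts <- pu$counts[, c("A", "C", "G", "T")]
  for (k in seq_len(nrow(snps$sites))) {
    site <- snps$sites$pos[k] + 1L
    maf <- counts[site, snps$sites$allele_a[k]] / sum(counts[site, ])
    se <- sqrt(0.024 * 0.976 / sum(counts[site, ]))
    expect_lt(abs(maf - 0.024), 3 * se + 0.004)  # 0.004 allows error bases
  }
})
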