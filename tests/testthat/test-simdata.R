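test_that("parental units differ at the configured number of biased sites", {
  cfg <- sim_config(seed = 1)
  units <- build_parental_units(cfg)
  expect_equal(nchar(units$A$genic_seq), 120L)
  expect_equal(hamming(units$A$genic_seq, units$B$genic_seq), 7L)
  expect_equal(units$A$monomer_len, 720L)
  expect_equal(units$B$monomer_len, 650L)

  # degenerate control: no diagnostic sites
  cfg0 <- sim_config(seed = 2, n_diag = 0)
  u0 <- build_parental_units(cfg0)
  expect_equal(u0$A$genic_seq, u0$B$genic_seq)
})

test_that("deamination bias is respected across seeds", {
  for (seed in 1:5) {
    cfg <- sim_config(seed = seed, deamination_bias = 1.0)
    u <- build_parental_units(cfg)
    ca <- strsplit(u$A$genic_seq, "")[[1]]
    cb <- strsplit(u$B$genic_seq, "")[[1]]
    diff <- which(ca != cb)
    expect_length(diff, 7L)
    from_to <- paste0(ca[diff], cb[diff])
    expect_true(all(from_to %in% c("CT", "GA")))
  }
  # default bias 0.7: at least ceiling(0.7 * 7) = 5 deamination-class changes
  cfg <- sim_config(seed = 3)
  u <- build_parental_units(cfg)
  ca <- strsplit(u$A$genic_seq, "")[[1]]
  cb <- strsplit(u$B$genic_seq, "")[[1]]
  diff <- which(ca != cb)
  expect_gte(sum(paste0(ca[diff], cb[diff]) %in% c("CT", "GA")), 5L)
})

test_that("transcript read pools follow the configured expression skew", {
  cfg <- sim_config(seed = 5, n_transcript_reads = 327, expr_prop_b = 0.976)
  units <- build_parental_units(cfg)
  sim <- simulate_short_reads(cfg, units, "transcriptomic")
  n_b <- sum(sim$manifest$origin == "B")
  se <- sqrt(327 * 0.976 * 0.024)
  expect_lt(abs(n_b - 327 * 0.976), 3 * se)

  cfg1 <- sim_config(seed = 5, n_transcript_reads = 200, expr_prop_b = 1.0)
  sim1 <- simulate_short_reads(cfg1, units, "transcriptomic")
  expect_equal(sum(sim1$manifest$origin == "A"), 0L)
})

test_that("error-free reads are exact template substrings in either strand", {
  cfg <- sim_config(seed = 6, err_rate = 0, n_transcript_reads = 50,
                    n_genomic_reads = 50, genome_size_1c = NULL)
  units <- build_parental_units(cfg)
  for (mode in c("transcriptomic", "genomic")) {
    sim <- simulate_short_reads(cfg, units, mode)
    for (i in seq_along(sim$reads)) {
      org <- sim$manifest$origin[i]
      tpl <- if (mode == "transcriptomic") units[[org]]$genic_seq
             else strrep(monomer_seq(units[[org]]), 2)
      seq <- sim$reads[[i]]
      if (sim$manifest$strand[i] == "-")
        seq <- as.character(rdnaquant:::reverse_complement(seq))
      expect_true(grepl(seq, tpl, fixed = TRUE))
    }
  }
})

test_that("identical seed and config give byte-identical outputs", {
  cfg <- sim_config(seed = 9, n_transcript_reads = 100, n_genomic_reads = 100,
                    n_long_reads = 4, long_len_range = c(2160, 4000))
  units1 <- build_parental_units(cfg)
  units2 <- build_parental_units(cfg)
  expect_identical(units1, units2)
  for (mode in c("transcriptomic", "genomic")) {
    s1 <- simulate_short_reads(cfg, units1, mode)
    s2 <- simulate_short_reads(cfg, units2, mode)
    expect_identical(s1$reads, s2$reads)
    expect_identical(s1$manifest, s2$manifest)
  }
  l1 <- simulate_long_reads(cfg, units1)
  l2 <- simulate_long_reads(cfg, units2)
  expect_identical(l1$reads, l2$reads)

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fastq(s1$reads, f1, s1$quals)
  write_fastq(s2$reads, f2, s2$quals)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("genomic read origins converge to array sizes; genic reads to copies", {
  cfg <- sim_config(seed = 10, n_genomic_reads = 1e5, genome_size_1c = NULL,
                    copies_a = 500, copies_b = 2000, err_rate = 0)
  units <- build_parental_units(cfg)
  sim <- simulate_short_reads(cfg, units, "genomic")
  # reads are drawn uniformly per bp, so origin counts follow array bp sizes
  bp <- c(A = 500 * 720, B = 2000 * 650)
  n_a <- sum(sim$manifest$origin == "A")
  n_b <- sum(sim$manifest$origin == "B")
  expect_lt(abs(n_a / (n_a + n_b) - bp["A"] / sum(bp)), 0.01)
  # reads overlapping the genic region (equal windows per copy) follow the
  # copy-number ratio: starts within [g - (L - m), g + Lg - m] map per copy
  gstart <- 0  # genic region leads each monomer
  L <- cfg$read_len
  m <- ceiling(0.5 * L)
  in_window <- function(start, mlen) {
    s <- start %% mlen
    s <= (120 - m) || s >= (mlen - (L - m))
  }
  ga <- sum(vapply(sim$manifest$start[sim$manifest$origin == "A"],
                   in_window, TRUE, mlen = 720))
  gb <- sum(vapply(sim$manifest$start[sim$manifest$origin == "B"],
                   in_window, TRUE, mlen = 650))
  expect_lt(abs(ga / (ga + gb) - 500 / 2500), 3 * sqrt(0.2 * 0.8 / (ga + gb)))
})

test_that("manifest proportions are unbiased across seeds", {
  devs <- vapply(1:20, function(seed) {
    cfg <- sim_config(seed = seed, n_transcript_reads = 1000,
                      expr_prop_b = 0.976)
    units <- build_parental_units(cfg)
    sim <- simulate_short_reads(cfg, units, "transcriptomic")
    mean(sim$manifest$origin == "B") - 0.976
  }, 0)
  se <- sqrt(0.976 * 0.024 / 1000)
  expect_lt(mean(abs(devs)), 2 * se)
})

test_that("long reads are >= 3 tandem copies with recorded families", {
  cfg <- sim_config(seed = 12, n_long_reads = 8, long_len_range = c(2160, 6000),
                    err_rate = 0)
  units <- build_parental_units(cfg)
  sim <- simulate_long_reads(cfg, units)
  expect_length(sim$reads, 8L)
  for (i in seq_along(sim$reads)) {
    fam <- sim$manifest$origin[i]
    mlen <- if (fam == "A") 720 else 650
    expect_gte(nchar(sim$reads[[i]]), 3 * mlen)
    # error-free read is a substring of the infinite tandem
    k <- ceiling(nchar(sim$reads[[i]]) / mlen) + 2
    expect_true(grepl(sim$reads[[i]], strrep(monomer_seq(units[[fam]]), k),
                      fixed = TRUE))
  }
  # exact family counts when requested
  cfg2 <- sim_config(seed = 13, n_long_reads = 22, n_long_a = 2, n_long_b = 20,
                     long_len_range = c(2160, 8000))
  sim2 <- simulate_long_reads(cfg2, units)
  expect_equal(sum(sim2$manifest$origin == "A"), 2L)
  expect_equal(sum(sim2$manifest$origin == "B"), 20L)
})

test_that("sim_config rejects invalid study parameters", {
  expect_error(sim_config(expr_prop_b = 1.2), "expr_prop_b")
  expect_error(sim_config(err_rate = 0.2), "err_rate")
  expect_error(sim_config(n_diag = 200), "n_diag")
  expect_error(sim_config(long_len_range = c(100, 5000)), "long_len_range")
  expect_error(sim_config(read_len = 200, n_transcript_reads = 10) |>
                 (\(cfg) simulate_short_reads(cfg,
                    build_parental_units(cfg), "transcriptomic"))(),
               "read_len")
})
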