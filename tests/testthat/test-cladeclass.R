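test_that("gene-read extraction trims to the genic frame and length-filters", {
  u <- fixture_units()
  # exact full-length read is kept untouched
  gr <- extract_gene_reads(setNames(u$A$genic_seq, "full"), u$A)
  expect_equal(nrow(gr), 1L)
  expect_equal(gr$seq, u$A$genic_seq)
  expect_equal(c(gr$ref_start, gr$ref_end), c(0L, 120L))

  # 109-nt genic overlap: mapped but dropped by the >110 nt rule
  gr109 <- extract_gene_reads(setNames(substr(u$A$genic_seq, 1, 109), "x"),
                              u$A)
  expect_equal(nrow(gr109), 0L)
  # 111 nt passes
  gr111 <- extract_gene_reads(setNames(substr(u$A$genic_seq, 1, 111), "x"),
                              u$A)
  expect_equal(nrow(gr111), 1L)

  # minus-strand reads come back in genic orientation
  rc <- as.character(rdnaquant:::reverse_complement(u$B$genic_seq))
  grm <- extract_gene_reads(setNames(rc, "rev"), u$A)
  expect_equal(grm$seq, u$B$genic_seq)
})

test_that("subsampling is uniform, seeded and an identity below target", {
  u <- fixture_units()
  reads <- setNames(rep(u$A$genic_seq, 50), sprintf("r%03d", 1:50))
  gr <- extract_gene_reads(reads, u$A)
  sub1 <- subsample_reads(gr, 20, seed = 7)
  sub2 <- subsample_reads(gr, 20, seed = 7)
  expect_equal(nrow(sub1), 20L)
  expect_identical(sub1$read_id, sub2$read_id)
  sub3 <- subsample_reads(gr, 20, seed = 8)
  expect_false(identical(sub1$read_id, sub3$read_id))
  expect_identical(subsample_reads(gr, 600, seed = 1)$read_id, gr$read_id)
})

test_that("variant collapse groups identical sequences over the window", {
  u <- fixture_units()
  reads <- setNames(c(rep(u$A$genic_seq, 10), rep(u$B$genic_seq, 3),
                      substr(u$A$genic_seq, 1, 115)),
                    sprintf("r%02d", 1:14))
  gr <- extract_gene_reads(reads, u$A)
  vt <- collapse_variants(gr)
  # common window is [0,115); A and B variants remain distinct there
  expect_equal(attr(vt, "window"), c(0L, 115L))
  expect_equal(attr(vt, "n"), 14L)
  expect_equal(vt$count, c(11L, 3L))  # truncated A read merges with A variant
  expect_equal(vt$singleton, c(FALSE, FALSE))

  # all-identical and all-distinct limits
  one <- collapse_variants(extract_gene_reads(
    setNames(rep(u$A$genic_seq, 10), paste0("s", 1:10)), u$A))
  expect_equal(nrow(one), 1L)
  expect_equal(one$count, 10L)
})

test_that("Jukes-Cantor distances follow the closed form and saturate", {
  expect_equal(jc_distance(0), 0)
  expect_equal(jc_distance(7 / 120), -0.75 * log(1 - (4 / 3) * 7 / 120))
  expect_equal(round(jc_distance(7 / 120), 4), 0.0607)
  expect_lt(jc_distance(0.74), 5)
  expect_warning(d <- jc_distance(0.75), "saturation")
  expect_equal(d, 5)
  expect_warning(jc_distance(c(0.2, 0.9)), "1 mismatch")
})

test_that("neighbor joining reproduces 3-taxon closed-form branch lengths", {
  D <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3, dimnames = list(c("a", "b", "c"),
                                                c("a", "b", "c")))
  tr <- nj_tree(D)
  cd <- tree_distances(tr)
  expect_equal(cd[rownames(D), colnames(D)], D)
  # matrix of zeros -> star with zero lengths
  Z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  trz <- nj_tree(Z)
  expect_true(all(trz$edge.length == 0))
})

test_that("neighbor joining recovers additive matrices exactly", {
  skip_if_not_installed("phangorn")
  set.seed(123)
  for (n in c(4, 5, 6, 8)) {
    for (rep in 1:5) {
      gen <- ape::rtree(n, rooted = FALSE,
                        br = function(k) stats::runif(k, 0.05, 1))
      D <- ape::cophenetic.phylo(gen)
      ord <- sample(rownames(D))
      D <- D[ord, ord]
      tr <- nj_tree(D)
      # distances reproduced exactly
      cd <- tree_distances(tr)[rownames(D), colnames(D)]
      expect_equal(cd, D, tolerance = 1e-8)
      # topology identical to the generating tree
      expect_equal(phangorn::RF.dist(ape::unroot(gen), tr), 0)
    }
  }
})

test_that("neighbor joining matches brute-force topology search at 5 taxa", {
  skip_if_not_installed("phangorn")
  set.seed(321)
  labs <- letters[1:5]
  for (rep in 1:5) {
    gen <- ape::rtree(5, rooted = FALSE, tip.label = labs,
                      br = function(k) stats::runif(k, 0.1, 1))
    D <- ape::cophenetic.phylo(gen)[labs, labs]
    fits <- lapply(phangorn::allTrees(5, rooted = FALSE, tip.label = labs),
                   ls_fit_topology, D = D)
    rss <- vapply(fits, `[[`, 0, "rss")
    expect_equal(sum(rss < 1e-10), 1L)  # additive: unique best topology
    best <- which.min(rss)
    tr <- nj_tree(D)
    expect_equal(phangorn::RF.dist(
      phangorn::allTrees(5, rooted = FALSE, tip.label = labs)[[best]],
      tr), 0)
  }
})

test_that("neighbor joining is deterministic under ties", {
  D <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(D) <- 0
  t1 <- ape::write.tree(nj_tree(D))
  t2 <- ape::write.tree(nj_tree(D))
  expect_identical(t1, t2)
})

test_that("clade assignment follows proximity, ties and the exclusion rule", {
  u <- fixture_units()
  # table: one abundant variant identical to B, one rare far-out variant
  far <- rand_dna(120)
  reads <- setNames(c(rep(u$B$genic_seq, 96)), paste0("b", 1:96))
  gr <- extract_gene_reads(reads, u$A)
  vt <- collapse_variants(gr)
  cls <- classify_reads(vt, u$A, u$B)
  expect_equal(cls$counts$reads_parent_b, 96L)
  expect_equal(cls$counts$reads_parent_a, 0L)
  expect_equal(cls$counts$reads_excluded, 0L)

  # hand-built distance matrix: variant V_far is beyond both references
  # and rare -> excluded; V_near sits inside the B clade
  D <- matrix(0, 4, 4,
              dimnames = list(c("V_near", "V_far", "refA", "refB"),
                              c("V_near", "V_far", "refA", "refB")))
  D["refA", "refB"] <- D["refB", "refA"] <- 0.06
  D["V_near", "refB"] <- D["refB", "V_near"] <- 0.01
  D["V_near", "refA"] <- D["refA", "V_near"] <- 0.05
  D["V_far", "refA"] <- D["refA", "V_far"] <- 0.40
  D["V_far", "refB"] <- D["refB", "V_far"] <- 0.41
  D["V_far", "V_near"] <- D["V_near", "V_far"] <- 0.40
  tree <- nj_tree(D)
  tab <- structure(data.frame(variant_id = c("V_near", "V_far"),
                              sequence = c("x", "y"), count = c(97L, 3L),
                              singleton = c(FALSE, FALSE)),
                   n = 100L, window = c(0L, 120L), ref_id = "refA",
                   class = c("variant_table", "data.frame"))
  cc <- assign_clades(tree, tab, "refA", "refB", rare_frac = 0.05)
  expect_equal(cc$reads_parent_b, 97L)
  expect_equal(cc$reads_excluded, 3L)

  # the same variant with >= 5% of reads is never excluded
  tab2 <- tab
  tab2$count <- c(90L, 10L)
  cc2 <- assign_clades(tree, tab2, "refA", "refB", rare_frac = 0.05)
  expect_equal(cc2$reads_excluded, 0L)
  expect_equal(cc2$reads_parent_a, 10L)  # far variant closer to A

  # equidistant variant goes to ref_a with a warning
  De <- matrix(0, 3, 3, dimnames = list(c("V1", "refA", "refB"),
                                        c("V1", "refA", "refB")))
  De["refA", "refB"] <- De["refB", "refA"] <- 0.06
  De["V1", "refA"] <- De["refA", "V1"] <- 0.03
  De["V1", "refB"] <- De["refB", "V1"] <- 0.03
  tabe <- structure(data.frame(variant_id = "V1", sequence = "z",
                               count = 10L, singleton = FALSE),
                    n = 10L, window = c(0L, 120L), ref_id = "refA",
                    class = c("variant_table", "data.frame"))
  expect_warning(cce <- assign_clades(nj_tree(De), tabe, "refA", "refB"),
                 "equidistant")
  expect_equal(cce$reads_parent_a, 10L)
})

test_that("modified Nei diversity matches hand evaluation and invariants", {
  expect_equal(nei_diversity(c(10)), 0)            # monomorphic
  expect_equal(nei_diversity(rep(1, 7)), 1)        # all singletons
  expect_equal(nei_diversity(c(3, 1)), 0.5)        # (4/3)(1 - 10/16)
  expect_error(nei_diversity(c(1)), "fewer than 2")
  expect_error(nei_diversity(c(0, 2)))
  set.seed(5)
  for (i in 1:20) {
    counts <- sample(1:50, sample(2:10, 1), replace = TRUE)
    h <- nei_diversity(counts)
    expect_gte(h, 0)
    expect_lte(h, 1)
    expect_equal(h, nei_diversity(sample(counts)))  # relabeling invariance
  }
})

test_that("clade and SNP estimators agree on error-free simulations", {
  cfg <- sim_config(seed = 31, n_transcript_reads = 400, expr_prop_b = 0.9,
                    err_rate = 0)
  units <- build_parental_units(cfg)
  snps <- derive_diagnostic_snps(units$A, units$B)
  res <- run_expression_analysis(sim <- simulate_short_reads(
    cfg, units, "transcriptomic")$reads, units, snps)
  p_snp <- res$proportions$p_b
  cc <- res$classification$counts
  p_clade <- cc$reads_parent_b / (cc$reads_parent_a + cc$reads_parent_b)
  expect_lt(abs(p_snp - p_clade), 0.02)
  # exclusion removes (almost) nothing on clean data
  expect_lte(cc$reads_excluded, 0.05 * cc$n)
})

test_that("diversity summaries mirror the published table conventions", {
  u <- fixture_units()
  # 125 major + 24 minor reads over 19 variants (5 doubletons, 14 singletons)
  minor <- character(0)
  chars <- strsplit(u$A$genic_seq, "")[[1]]
  variants <- vapply(30:48, function(k) {
    # interior positions: terminal mismatches would be clipped by the
    # local aligner and merge the variant back into the major sequence
    v <- chars
    v[k] <- setdiff(c("A", "C", "G", "T"), v[k])[1]
    paste(v, collapse = "")
  }, "")
  reads <- c(rep(u$A$genic_seq, 125), rep(variants[1:5], each = 2),
             variants[6:19])
  names(reads) <- sprintf("r%03d", seq_along(reads))
  vt <- collapse_variants(extract_gene_reads(reads, u$A))
  expect_equal(nrow(vt), 20L)
  expect_equal(attr(vt, "n"), 149L)
  ds <- diversity_summary(vt, "amara_transcriptomic")
  expect_equal(ds$major_count, 125L)
  expect_equal(ds$major_pct, 83.9)
  expect_equal(ds$major_pct_excl_singletons,
               as.numeric(format_percent(125 / (149 - 14), 1L)))
})
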