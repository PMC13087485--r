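# Independent oracles and small fixture builders shared across tests.

# Plain-R exhaustive Smith-Waterman DP (score only), written independently
# of the package's aligner as a cross-check oracle.
sw_oracle_score <- function(a, b, match = 1, mismatch = 2, gap_ins = 3,
                            gap_del = 3) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j]) match else -mismatch
      H[i + 1, j + 1] <- max(0, H[i, j] + s,
                             H[i, j + 1] - gap_ins,   # consume read
                             H[i + 1, j] - gap_del)   # consume ref
      if (H[i + 1, j + 1] > best) best <- H[i + 1, j + 1]
    }
  }
  best
}

rand_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                       replace = TRUE), collapse = "")

# Fixed 120-nt parental pair differing at exactly 7 known positions
# (1-based 5, 20, 41, 58, 77, 96, 113), mostly C->T/G->A.
fixture_units <- function() {
  set.seed(42)
  a <- rand_dna(120)
  ca <- strsplit(a, "")[[1]]
  pos <- c(5L, 20L, 41L, 58L, 77L, 96L, 113L)
  cb <- ca
  for (p in pos) {
    cb[p] <- switch(ca[p], C = "T", G = "A", A = "G", T = "C")
  }
  igs_a <- rand_dna(600)
  igs_b <- rand_dna(530)
  list(A = gene_reference("amara", "A", a, igs_seq = igs_a),
       B = gene_reference("partner", "B", paste(cb, collapse = ""),
                          igs_seq = igs_b),
       diag_pos = pos)
}

# Hamming distance of two equal-length strings
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Least-squares branch-length fit of a distance matrix on a fixed topology;
# returns the fitted pairwise distances and the residual sum of squares.
ls_fit_topology <- function(tree, D) {
  labs <- rownames(D)
  tree$edge.length <- rep(1, nrow(tree$edge))
  n <- length(labs)
  pairs <- t(combn(n, 2))
  tipidx <- match(labs, tree$tip.label)
  A <- matrix(0, nrow(pairs), nrow(tree$edge))
  d <- numeric(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    np <- ape::nodepath(tree, tipidx[pairs[p, 1]], tipidx[pairs[p, 2]])
    for (k in seq_len(length(np) - 1)) {
      e <- which((tree$edge[, 1] == np[k] & tree$edge[, 2] == np[k + 1]) |
                 (tree$edge[, 1] == np[k + 1] & tree$edge[, 2] == np[k]))
      A[p, e] <- 1
    }
    d[p] <- D[pairs[p, 1], pairs[p, 2]]
  }
  b <- qr.coef(qr(A), d)
  b[is.na(b)] <- 0
  fitted <- as.vector(A %*% b)
  list(rss = sum((fitted - d)^2), fitted = fitted, observed = d)
}

# Pairwise tree distances of a phylo tree, as a labelled matrix
tree_distances <- function(tree) {
  ape::cophenetic.phylo(tree)
}
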