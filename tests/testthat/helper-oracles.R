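# Brute-force oracles and tiny fixtures shared across the test files.
# The oracles are deliberately naive re-implementations used only to verify
# the package's optimised routines on small instances.

# all monotone one-to-one alignments of nq query vs nt template positions:
# every k-subset of query positions paired in order with every k-subset of
# template positions (k = 0..min(nq, nt))
enumerate_alignments <- function(nq, nt) {
  out <- list(matrix(integer(0), ncol = 2))
  for (k in seq_len(min(nq, nt))) {
    qs <- utils::combn(nq, k)
    ts <- utils::combn(nt, k)
    for (a in seq_len(ncol(qs))) {
      for (b in seq_len(ncol(ts))) {
        out[[length(out) + 1L]] <- cbind(qs[, a], ts[, b])
      }
    }
  }
  out
}

# affine gap cost of a run of `len` unaligned positions
.gap_cost <- function(len, gap_open, gap_extend) {
  if (len <= 0) 0 else gap_open + (len - 1) * gap_extend
}

# score of one explicit alignment under the package's gap model
brute_align_score <- function(S, pairs, gap_open, gap_extend, ends_free) {
  total <- if (nrow(pairs)) sum(S[pairs]) else 0
  k <- nrow(pairs)
  if (k >= 2) {
    for (w in seq_len(k - 1)) {
      total <- total +
        .gap_cost(pairs[w + 1, 1] - pairs[w, 1] - 1, gap_open, gap_extend) +
        .gap_cost(pairs[w + 1, 2] - pairs[w, 2] - 1, gap_open, gap_extend)
    }
  }
  if (!ends_free) {
    nq <- nrow(S); nt <- ncol(S)
    if (k == 0) {
      total <- total + .gap_cost(nq, gap_open, gap_extend) +
        .gap_cost(nt, gap_open, gap_extend)
    } else {
      total <- total +
        .gap_cost(pairs[1, 1] - 1, gap_open, gap_extend) +
        .gap_cost(pairs[1, 2] - 1, gap_open, gap_extend) +
        .gap_cost(nq - pairs[k, 1], gap_open, gap_extend) +
        .gap_cost(nt - pairs[k, 2], gap_open, gap_extend)
    }
  }
  total
}

# exhaustive-enumeration optimum of the alignment objective
brute_best_alignment <- function(S, gap_open, gap_extend, ends_free) {
  best <- -Inf
  for (p in enumerate_alignments(nrow(S), ncol(S))) {
    sc <- brute_align_score(S, p, gap_open, gap_extend, ends_free)
    if (sc > best) best <- sc
  }
  best
}

# contact map overlap by a literal double loop over aligned index pairs
brute_cmo <- function(query_map, template_map, pairs) {
  total <- 0
  k <- nrow(pairs)
  if (k < 2) return(0)
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      i <- pairs[a, 1]; j <- pairs[b, 1]
      fi <- pairs[a, 2]; fj <- pairs[b, 2]
      if (j > i + 1 && fj > fi + 1) {
        total <- total + query_map$values[i, j] * template_map$values[fi, fj]
      }
    }
  }
  total
}

# exhaustive sign enumeration: the best CMO over all 2^t sign vectors
exhaustive_sign_cmo <- function(query_basis, template_basis, query_map,
                                template_map, gap_open = -1,
                                gap_extend = -0.1, ends_free = TRUE) {
  t_eff <- min(query_basis$order_t, template_basis$order_t)
  qb <- truncate_basis(query_basis, t_eff)
  tb <- truncate_basis(template_basis, t_eff)
  best <- -Inf
  grid <- expand.grid(rep(list(c(1, -1)), t_eff))
  for (r in seq_len(nrow(grid))) {
    signs <- as.numeric(grid[r, ])
    S <- score_matrix(qb, tb, signs)
    aln <- global_align(S, gap_open, gap_extend, ends_free)
    cmo <- cmo_score(query_map, template_map, aln)
    if (cmo > best) best <- cmo
  }
  best
}

# random symmetric matrix with zero diagonal
random_symmetric <- function(n, scale = 1) {
  m <- matrix(stats::rnorm(n * n, sd = scale), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# random binary contact map respecting symmetry and the exclusion band
random_binary_map <- function(n, density = 0.3, min_separation = 2L) {
  m <- matrix(0, n, n)
  ut <- which(upper.tri(m) & abs(row(m) - col(m)) >= min_separation)
  on <- ut[stats::runif(length(ut)) < density]
  m[on] <- 1
  m <- m + t(m)
  dm <- matrix(stats::runif(n * n, 1, 20), n)
  dm <- (dm + t(dm)) / 2
  diag(dm) <- 0
  dm[m == 1] <- dm[m == 1] / 4   # contacts are short distances
  contact_map(m, kind = "observed-binary", distances = dm, threshold = 10,
              min_separation = min_separation)
}

# random predicted-probability map
random_prob_map <- function(n, density = 0.3, min_separation = 2L) {
  m <- matrix(0, n, n)
  ut <- which(upper.tri(m) & abs(row(m) - col(m)) >= min_separation)
  on <- ut[stats::runif(length(ut)) < density]
  m[on] <- stats::runif(length(on))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  contact_map(m, kind = "predicted-probability",
              min_separation = min_separation)
}

# a hand-written 3-residue PDB (ALA, GLY, SER on chain A; GLY has no CB)
# plus one chain-B residue, for reader tests
tiny_pdb_text <- c(
  "HEADER    TEST",
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
  "ATOM      3  CB  ALA A   1       1.500   2.500   3.500  1.00  0.00           C",
  "ATOM      4  CA  GLY A   2       4.000   5.000   6.000  1.00  0.00           C",
  "ATOM      5  CA  SER A   3       7.000   8.000   9.000  1.00  0.00           C",
  "ATOM      6  CB  SER A   3       7.200   8.200   9.200  1.00  0.00           C",
  "ATOM      7  CA  LEU B   1      10.000  11.000  12.000  1.00  0.00           C",
  "TER",
  "END")

write_tiny_pdb <- function(path = tempfile(fileext = ".pdb"),
                           lines = tiny_pdb_text) {
  writeLines(lines, path)
  path
}
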