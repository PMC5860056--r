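test_that("score_matrix is the signed sum of scaled outer products", {
  qb <- eigen_basis(2, 1, values = 4, scaled_vectors = cbind(c(1, 2)))
  tb <- eigen_basis(2, 1, values = 4, scaled_vectors = cbind(c(3, 4)))
  expect_equal(score_matrix(qb, tb, signs = 1),
               matrix(c(3, 6, 4, 8), 2))
  expect_equal(score_matrix(qb, tb, signs = -1),
               -matrix(c(3, 6, 4, 8), 2))
})

test_that("a zero-weight secondary-structure bonus is a no-op, a positive one rewards state matches", {
  set.seed(41)
  qb <- decompose(random_symmetric(4), 3)
  tb <- decompose(random_symmetric(5), 3)
  qss <- ss_string("HHEC")
  tss <- ss_string("HECCC")
  base <- score_matrix(qb, tb)
  expect_equal(score_matrix(qb, tb, query_ss = qss, template_ss = tss,
                            ss_weight = 0), base)
  boosted <- score_matrix(qb, tb, query_ss = qss, template_ss = tss,
                          ss_weight = 2)
  expect_equal(boosted[1, 1], base[1, 1] + 2)  # H vs H
  expect_equal(boosted[1, 2], base[1, 2])      # H vs E
  expect_error(score_matrix(qb, tb, query_ss = ss_string("HH"),
                            template_ss = tss, ss_weight = 1), "length")
})

test_that("simple alignments behave as expected at the corners", {
  S <- matrix(-5, 3, 3); diag(S) <- 5
  a <- global_align(S, gap_open = -1, gap_extend = -1, ends_free = FALSE)
  expect_equal(a$pairs, cbind(1:3, 1:3))
  expect_equal(a$dp_score, 15)
  one <- global_align(matrix(7, 1, 1))
  expect_equal(one$pairs, cbind(1L, 1L))
  expect_equal(one$dp_score, 7)
  expect_error(global_align(matrix(numeric(0), 0, 0)), "empty")
  expect_error(global_align(matrix(1, 2, 2), gap_open = 1), "nonpositive")
})

test_that("dynamic programming equals exhaustive enumeration on random matrices", {
  set.seed(42)
  for (trial in 1:200) {
    nq <- sample(2:6, 1); nt <- sample(2:7, 1)
    S <- matrix(stats::rnorm(nq * nt, sd = 2), nq, nt)
    ge <- -stats::runif(1, 0, 1); go <- ge - stats::runif(1, 0, 2)
    free <- trial %% 2 == 0
    a <- global_align(S, go, ge, ends_free = free)
    expect_equal(a$dp_score, brute_best_alignment(S, go, ge, free),
                 tolerance = 1e-9)
    # the returned alignment attains its reported score
    expect_equal(brute_align_score(S, a$pairs, go, ge, free), a$dp_score,
                 tolerance = 1e-9)
  }
})

test_that("alignments returned are monotone and in bounds", {
  set.seed(43)
  for (trial in 1:50) {
    S <- matrix(stats::rnorm(8 * 10), 8, 10)
    a <- global_align(S, -0.5, -0.1, ends_free = trial %% 2 == 0)
    p <- a$pairs
    if (nrow(p) > 1) {
      expect_true(all(diff(p[, 1]) > 0))
      expect_true(all(diff(p[, 2]) > 0))
    }
    expect_true(all(p[, 1] >= 1 & p[, 1] <= 8))
    expect_true(all(p[, 2] >= 1 & p[, 2] <= 10))
  }
})

test_that("cmo_score counts superimposed contacts under the non-consecutive constraints", {
  m <- matrix(0, 5, 5)
  for (p in list(c(1, 4), c(2, 5), c(1, 5))) {
    m[p[1], p[2]] <- m[p[2], p[1]] <- 1
  }
  dm <- matrix(5, 5, 5); diag(dm) <- 0
  cm <- contact_map(m, "observed-binary", distances = dm, threshold = 10)
  identity_aln <- cm_alignment(cbind(1:5, 1:5), 5, 5)
  expect_equal(cmo_score(cm, cm, identity_aln), 3)
  zero <- contact_map(matrix(0, 5, 5), "observed-binary",
                      distances = dm, threshold = 10)
  expect_equal(cmo_score(zero, cm, identity_aln), 0)
  expect_equal(cmo_score(cm, zero, identity_aln), 0)
})

test_that("cmo_score matches the brute-force double loop on random instances", {
  set.seed(44)
  for (trial in 1:200) {
    nq <- sample(4:8, 1); nt <- sample(4:10, 1)
    qm <- if (trial %% 2 == 0) random_binary_map(nq) else random_prob_map(nq)
    tm <- random_binary_map(nt)
    k <- sample(0:min(nq, nt), 1)
    pairs <- if (k > 0) cbind(sort(sample(nq, k)), sort(sample(nt, k)))
    else matrix(integer(0), ncol = 2)
    aln <- cm_alignment(pairs, nq, nt)
    expect_equal(cmo_score(qm, tm, aln), brute_cmo(qm, tm, pairs),
                 tolerance = 1e-12)
  }
})

test_that("cmo never exceeds the smaller of the two total contact weights", {
  set.seed(45)
  for (trial in 1:30) {
    qm <- random_prob_map(10)
    tm <- random_binary_map(12)
    res <- align_maps(qm, tm, t = 5)
    expect_lte(res$cmo,
               min(sum(qm$values[upper.tri(qm$values)]),
                   sum(tm$values[upper.tri(tm$values)])) + 1e-12)
  }
})

test_that("cmo is invariant when the same eigenvector sign flips in both bases", {
  set.seed(46)
  qm <- random_prob_map(12)
  tm <- random_binary_map(12)
  qb <- decompose(qm, 4); tb <- decompose(tm, 4)
  S1 <- score_matrix(qb, tb, signs = c(1, 1, 1, 1))
  # flip vector 2 in both bases: products of the two flips cancel
  qb2 <- qb; qb2$vectors[, 2] <- -qb2$vectors[, 2]
  qb2$scaled_vectors[, 2] <- -qb2$scaled_vectors[, 2]
  tb2 <- tb; tb2$vectors[, 2] <- -tb2$vectors[, 2]
  tb2$scaled_vectors[, 2] <- -tb2$scaled_vectors[, 2]
  S2 <- score_matrix(qb2, tb2, signs = c(1, 1, 1, 1))
  expect_equal(S1, S2)
})

test_that("sign search recovers a deliberately sign-scrambled self-match", {
  set.seed(47)
  p <- make_chain(40, "helix-bundle", jitter = 0.2, seed = 2)
  tm <- p$true_map
  tb <- decompose(tm, 4)
  # query basis = template basis with vectors 2 and 4 flipped
  qb <- tb
  for (k in c(2, 4)) {
    qb$vectors[, k] <- -qb$vectors[, k]
    qb$scaled_vectors[, k] <- -qb$scaled_vectors[, k]
  }
  res <- sign_search(qb, tb, tm, tm)
  self_cmo <- cmo_score(tm, tm, cm_alignment(cbind(1:40, 1:40), 40, 40))
  expect_equal(res$cmo, self_cmo)
})

test_that("sign search accepts only strict improvements and never falls below baseline", {
  set.seed(48)
  for (trial in 1:10) {
    qm <- random_prob_map(12)
    tm <- random_binary_map(14)
    qb <- decompose(qm, 4); tb <- decompose(tm, 4)
    base_S <- score_matrix(truncate_basis(qb, 4), truncate_basis(tb, 4))
    base_aln <- global_align(base_S)
    base_cmo <- cmo_score(qm, tm, base_aln)
    res <- sign_search(qb, tb, qm, tm)
    expect_gte(res$cmo, base_cmo)
    expect_true(all(res$signs %in% c(-1, 1)))
  }
})

test_that("with a single eigenvector at most two alignments are evaluated", {
  set.seed(49)
  qm <- random_prob_map(10)
  tm <- random_binary_map(10)
  res <- sign_search(decompose(qm, 1), decompose(tm, 1), qm, tm)
  expect_lte(res$n_evaluations, 3L)  # baseline + flip (+ one closing sweep)
})
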