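make_scoring_fixture <- function(n = 12, seed = 51) {
  # aligned identity pair of maps where query probability is an exact
  # decreasing linear function of template distance
  set.seed(seed)
  d <- matrix(stats::runif(n * n, 4, 15), n)
  d <- (d + t(d)) / 2; diag(d) <- 0
  band <- abs(row(d) - col(d)) < 2
  vals <- (d <= 8) * 1; vals[band] <- 0
  tm <- contact_map(vals, "observed-binary", distances = d, threshold = 8)
  p <- pmin(pmax(1 - d / 20, 0), 1); p[band] <- 0; diag(p) <- 0
  qm <- contact_map(p, "predicted-probability")
  list(qm = qm, tm = tm,
       aln = cm_alignment(cbind(1:n, 1:n), n, n))
}

test_that("an exact linear probability-distance relation gives r = -1 and the t sentinel", {
  f <- make_scoring_fixture()
  cs <- correlation_score(f$qm, f$tm, f$aln)
  expect_false(cs$unscorable)
  expect_equal(cs$r, -1)
  expect_equal(cs$t_statistic, -1e6)
})

test_that("zero-variance or tiny alignments are reported unscorable", {
  f <- make_scoring_fixture()
  const <- contact_map(matrix(0.5 * (abs(row(diag(12)) - col(diag(12))) >= 2),
                              12, 12), "predicted-probability")
  cs <- correlation_score(const, f$tm, f$aln)
  expect_true(cs$unscorable)
  expect_true(is.na(cs$r))
  short <- cm_alignment(cbind(1:2, 1:2), 12, 12)
  expect_true(correlation_score(f$qm, f$tm, short)$unscorable)
})

test_that("the t-statistic matches its closed form and cor.test", {
  # closed form at r = -0.9, n = 12
  r <- -0.9; n <- 12
  expect_equal(r * sqrt(n - 2) / sqrt(1 - r^2), -6.529, tolerance = 1e-3)
  set.seed(52)
  n <- 14
  d <- matrix(stats::runif(n * n, 4, 15), n); d <- (d + t(d)) / 2; diag(d) <- 0
  band <- abs(row(d) - col(d)) < 2
  vals <- (d <= 8) * 1; vals[band] <- 0
  tm <- contact_map(vals, "observed-binary", distances = d, threshold = 8)
  p <- pmin(pmax(1 - d / 20 + stats::rnorm(n * n, sd = 0.05), 0), 1)
  p <- (p + t(p)) / 2; p[band] <- 0; diag(p) <- 0
  qm <- contact_map(p, "predicted-probability")
  aln <- cm_alignment(cbind(1:n, 1:n), n, n)
  cs <- correlation_score(qm, tm, aln)
  # independent oracle: collect the same pairs and hand them to cor.test
  idx <- which(upper.tri(d) & abs(row(d) - col(d)) >= 2, arr.ind = TRUE)
  ct <- stats::cor.test(p[idx], d[idx])
  expect_equal(cs$r, unname(ct$estimate), tolerance = 1e-9)
  expect_equal(cs$t_statistic, unname(ct$statistic), tolerance = 1e-9)
  expect_equal(cs$t_statistic,
               cs$r * sqrt(cs$n_pairs - 2) / sqrt(1 - cs$r^2),
               tolerance = 1e-9)
})

test_that("correlation depends only on the alignment and matrices, not template identity", {
  f <- make_scoring_fixture()
  a <- correlation_score(f$qm, f$tm, f$aln)
  relabeled <- f$tm  # same object: identity is not an input to the score
  b <- correlation_score(f$qm, relabeled, f$aln)
  expect_identical(a, b)
})

simulate_logistic <- function(n, beta, seed) {
  set.seed(seed)
  t_stat <- stats::rnorm(n, 0, 3)
  fq <- stats::runif(n)
  ft <- stats::runif(n)
  eta <- beta[1] + beta[2] * t_stat + beta[3] * fq + beta[4] * ft
  data.frame(t_statistic = t_stat, frac_query = fq, frac_template = ft,
             label = stats::rbinom(n, 1, stats::plogis(eta)))
}

test_that("fit_logistic recovers known generating coefficients", {
  d <- simulate_logistic(5000, c(-1, 0.5, 2, 1), seed = 53)
  m <- fit_logistic(d)
  expect_false(m$stabilized)
  expect_equal(m$intercept, -1, tolerance = 0.15)
  expect_equal(m$coef_t, 0.5, tolerance = 0.15)
  expect_equal(m$coef_frac_query, 2, tolerance = 0.15)
  expect_equal(m$coef_frac_template, 1, tolerance = 0.15)
})

test_that("a null generator yields a near-null model predicting the base rate", {
  d <- simulate_logistic(5000, c(0, 0, 0, 0), seed = 54)
  m <- fit_logistic(d)
  expect_lt(abs(m$coef_t), 0.1)
  expect_lt(abs(m$coef_frac_query), 0.3)
  expect_lt(abs(m$coef_frac_template), 0.3)
  p <- match_probability(m, d$t_statistic, d$frac_query, d$frac_template)
  expect_equal(mean(p), mean(d$label), tolerance = 0.02)
})

test_that("only the informative feature picks up weight", {
  d <- simulate_logistic(5000, c(0, 1, 0, 0), seed = 55)
  m <- fit_logistic(d)
  expect_equal(m$coef_t, 1, tolerance = 0.15)
  expect_lt(abs(m$coef_frac_query), 0.3)
  expect_lt(abs(m$coef_frac_template), 0.3)
})

test_that("fitted probabilities agree with an independent convex optimizer", {
  d <- simulate_logistic(600, c(-0.5, 0.4, 1.2, 0.8), seed = 56)
  m <- fit_logistic(d)
  # independent route: direct BFGS maximum likelihood
  X <- cbind(1, d$t_statistic, d$frac_query, d$frac_template)
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(d$label * eta - log1p(exp(eta)))
  }
  opt <- stats::optim(rep(0, 4), nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  p_pkg <- match_probability(m, d$t_statistic, d$frac_query, d$frac_template)
  p_opt <- stats::plogis(drop(X %*% opt$par))
  expect_equal(p_pkg, p_opt, tolerance = 1e-6)
})

test_that("perfect separation falls back to a flagged ridge fit", {
  d <- data.frame(t_statistic = c(-(5:14), 5:14) / 2,
                  frac_query = rep(0.5, 20), frac_template = rep(0.5, 20),
                  label = rep(c(1, 0), each = 10))
  m <- fit_logistic(d)
  expect_true(m$stabilized)
  expect_true(all(is.finite(c(m$intercept, m$coef_t, m$coef_frac_query,
                              m$coef_frac_template))))
  # direction still learned: negative t (good match) maps to high probability
  expect_gt(match_probability(m, -5, 0.5, 0.5), 0.9)
  expect_lt(match_probability(m, 5, 0.5, 0.5), 0.1)
})

test_that("match_probability is the plain sigmoid and monotone per coefficient sign", {
  null_model <- logistic_model(0, 0, 0, 0)
  expect_equal(match_probability(null_model, 3, 0.2, 0.9), 0.5)
  expect_lt(match_probability(logistic_model(-50, 0, 0, 0), 0, 0, 0), 1e-20)
  expect_equal(match_probability(logistic_model(0, 1, 0, 0), 0, 1, 1), 0.5)
  m <- logistic_model(-0.5, -0.8, 1.5, 0.7)
  ts <- seq(-5, 5, length.out = 11)
  p_t <- match_probability(m, ts, 0.5, 0.5)
  expect_true(all(diff(p_t) < 0))          # coef_t < 0: decreasing in t
  fq <- seq(0, 1, length.out = 11)
  expect_true(all(diff(match_probability(m, 0, fq, 0.5)) > 0))
  expect_true(is.na(match_probability(m, NA_real_, 0.5, 0.5)))
})
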