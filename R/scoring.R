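## Final match scoring: Pearson correlation between query contact
## probabilities and template inter-residue distances over the alignment,
## its t-statistic, and a 3-feature logistic match-probability model.

# t set to +/- this value when |r| = 1 (the closed form diverges); large
# enough to dominate any realistic finite t, finite so downstream sums stay
# well defined
.t_sentinel <- 1e6

#' Correlation score of an aligned match
#'
#' Over all aligned query pairs `(i, j)` with `i < j`,
#' `|i - j| >= min_separation` and `f(j) > f(i) + 1`, correlates the query
#' contact probability `p_ij` with the template inter-residue distance
#' `d_f(i),f(j)` (Angstrom). A genuine fold match places high-probability
#' contacts at short template distances, so `r` is strongly negative. The
#' associated statistic `t = r * sqrt(n - 2) / sqrt(1 - r^2)` makes matches
#' comparable across alignment lengths.
#'
#' Degenerate cases: with fewer than 3 usable pairs, or zero variance in
#' either variable, the match is unscorable and `r`/`t` are `NA`; with
#' `|r| = 1` the t-statistic is reported as `+/-1e6`.
#'
#' @param query_map a predicted-probability [contact_map()].
#' @param template_map an observed [contact_map()] carrying distances.
#' @param alignment a [cm_alignment()].
#' @param min_separation minimum query sequence separation of included
#'   pairs (default 2, matching the contact-map convention).
#' @return A list: `r`, `n_pairs`, `t_statistic`, `unscorable`.
#' @export
correlation_score <- function(query_map, template_map, alignment,
                              min_separation = 2L) {
  stopifnot(inherits(query_map, "contact_map"),
            inherits(template_map, "contact_map"),
            inherits(alignment, "cm_alignment"))
  if (is.null(template_map$distances))
    stop("template map must carry a distances matrix")
  if (alignment$query_len != query_map$size ||
      alignment$template_len != template_map$size)
    stop("alignment size does not match the maps")
  p <- alignment$pairs
  k <- nrow(p)
  unscorable <- list(r = NA_real_, n_pairs = 0L, t_statistic = NA_real_,
                     unscorable = TRUE)
  if (k < 2L) return(unscorable)
  qi <- p[, 1]; ti <- p[, 2]
  sel_q <- outer(qi, qi, function(a, b) b - a >= min_separation)
  sel_t <- outer(ti, ti, function(a, b) b - a > 1L)
  sel <- which(sel_q & sel_t, arr.ind = TRUE)
  n <- nrow(sel)
  if (n < 3L) { unscorable$n_pairs <- n; return(unscorable) }
  x <- query_map$values[cbind(qi[sel[, 1]], qi[sel[, 2]])]
  y <- template_map$distances[cbind(ti[sel[, 1]], ti[sel[, 2]])]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    unscorable$n_pairs <- n
    return(unscorable)
  }
  r <- stats::cor(x, y)
  t_stat <- if (abs(r) >= 1 - 1e-15) sign(r) * .t_sentinel
  else r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, n_pairs = n, t_statistic = t_stat, unscorable = FALSE)
}

#' Logistic match-probability model
#'
#' Coefficients of a logistic regression of match correctness on three
#' features of a match: the correlation t-statistic, the fraction of the
#' query that is aligned, and the fraction of the template that is aligned.
#'
#' @param intercept,coef_t,coef_frac_query,coef_frac_template finite reals.
#' @param stabilized logical; `TRUE` when the fit needed ridge
#'   stabilisation (perfectly separated training data).
#' @return An object of class `logistic_model`.
#' @export
logistic_model <- function(intercept, coef_t, coef_frac_query,
                           coef_frac_template, stabilized = FALSE) {
  co <- c(intercept, coef_t, coef_frac_query, coef_frac_template)
  if (any(!is.finite(co))) stop("model coefficients must be finite")
  structure(list(intercept = intercept, coef_t = coef_t,
                 coef_frac_query = coef_frac_query,
                 coef_frac_template = coef_frac_template,
                 stabilized = stabilized),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf(
    "<logistic_model> logit(p) = %.4g + %.4g t + %.4g fq + %.4g ft%s\n",
    x$intercept, x$coef_t, x$coef_frac_query, x$coef_frac_template,
    if (x$stabilized) " (ridge-stabilised)" else ""))
  invisible(x)
}

#' Fit the logistic match-probability model
#'
#' Maximum-likelihood logistic regression of a binary match label on the
#' t-statistic and the two aligned fractions (a convex problem, so the fit
#' is deterministic given the data). If the data are perfectly separated
#' the unpenalised MLE diverges; the fit then falls back to a mild ridge
#' penalty (lambda 1e-4 on the slopes) and flags the model as stabilised.
#'
#' @param data data.frame with columns `t_statistic`, `frac_query`,
#'   `frac_template` and `label` (0/1), at least one example of each label.
#' @return A [logistic_model()].
#' @export
fit_logistic <- function(data) {
  need <- c("t_statistic", "frac_query", "frac_template", "label")
  if (!all(need %in% names(data))) stop("data must have columns ",
                                        paste(need, collapse = ", "))
  if (!all(data$label %in% c(0, 1)) || length(unique(data$label)) < 2L)
    stop("label must be 0/1 with both classes present")
  X <- as.matrix(data[c("t_statistic", "frac_query", "frac_template")])
  if (any(!is.finite(X))) stop("features must be finite")
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(label ~ t_statistic + frac_query + frac_template,
               data = data, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!separated) {
    co <- stats::coef(fit)
    return(logistic_model(co[[1]], co[[2]], co[[3]], co[[4]]))
  }
  # ridge-penalised negative log-likelihood, slopes only
  y <- data$label
  Xd <- cbind(1, X)
  lambda <- 1e-4
  nll <- function(beta) {
    eta <- drop(Xd %*% beta)
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      lambda * sum(beta[-1]^2)
  }
  grad <- function(beta) {
    eta <- drop(Xd %*% beta)
    mu <- 1 / (1 + exp(-eta))
    drop(crossprod(Xd, mu - y)) + 2 * lambda * c(0, beta[-1])
  }
  opt <- stats::optim(rep(0, 4), nll, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  logistic_model(opt$par[1], opt$par[2], opt$par[3], opt$par[4],
                 stabilized = TRUE)
}

#' Match probability under a logistic model
#'
#' `sigmoid(b0 + b_t t + b_q fq + b_tm ft)`; `NA` when the match was
#' unscorable (undefined t-statistic).
#'
#' @param model a [logistic_model()].
#' @param t_statistic,frac_query,frac_template match features (vectors of a
#'   common length are accepted).
#' @return Probabilities in \[0, 1\] (`NA` where `t_statistic` is `NA`).
#' @export
match_probability <- function(model, t_statistic, frac_query, frac_template) {
  stopifnot(inherits(model, "logistic_model"))
  eta <- model$intercept + model$coef_t * t_statistic +
    model$coef_frac_query * frac_query +
    model$coef_frac_template * frac_template
  stats::plogis(eta)
}
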