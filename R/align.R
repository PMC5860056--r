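## The alignment engine: eigenvector score matrix, global DP alignment,
## contact map overlap, and the greedy eigenvector sign search.

#' Alignment between two contact maps
#'
#' A monotone one-to-one partial mapping between query and template
#' positions: aligned pairs are strictly increasing in both coordinates, so
#' residue order is preserved and each position aligns to at most one
#' position in the other protein.
#'
#' @param pairs k x 2 integer matrix of (query_pos, template_pos), 1-based.
#' @param query_len,template_len sequence lengths.
#' @param dp_score dynamic-programming objective value of the alignment.
#' @return An object of class `cm_alignment`.
#' @export
cm_alignment <- function(pairs, query_len, template_len, dp_score = NA_real_) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs)) {
    if (any(pairs[, 1] < 1L | pairs[, 1] > query_len) ||
        any(pairs[, 2] < 1L | pairs[, 2] > template_len))
      stop("alignment pair out of bounds")
    if (nrow(pairs) > 1L &&
        (any(diff(pairs[, 1]) <= 0L) || any(diff(pairs[, 2]) <= 0L)))
      stop("alignment pairs must be strictly increasing in both coordinates")
  }
  structure(list(pairs = pairs, query_len = as.integer(query_len),
                 template_len = as.integer(template_len),
                 dp_score = dp_score),
            class = "cm_alignment")
}

#' @export
print.cm_alignment <- function(x, ...) {
  cat(sprintf("<cm_alignment> %d pairs (query %d, template %d), dp_score %.4g\n",
              nrow(x$pairs), x$query_len, x$template_len, x$dp_score))
  invisible(x)
}

#' Eigenvector alignment score matrix
#'
#' `S[i, j] = sum_k s_k (u'_k)_i (v'_k)_j` over the scaled eigenvectors
#' `u'` of the query and `v'` of the template, with per-eigenvector signs
#' `s_k` for the query side. The score is high where eigenvector entries
#' agree in sign, which is what makes dynamic programming over S a proxy for
#' superimposing the two maps. Optionally a constant bonus is added at
#' positions whose query secondary-structure state matches the template's.
#'
#' @param query_basis,template_basis [eigen_basis()] objects; both are
#'   truncated to the smaller of the two orders.
#' @param signs integer vector in \{-1, +1\}, one per retained query
#'   eigenvector (recycled from 1 if shorter after truncation is an error).
#' @param query_ss,template_ss optional [ss_string()] objects for the
#'   secondary-structure bonus.
#' @param ss_weight bonus added where states match (default 0 = off).
#' @return A numeric `n_query` x `n_template` matrix.
#' @export
score_matrix <- function(query_basis, template_basis,
                         signs = rep(1, min(query_basis$order_t,
                                            template_basis$order_t)),
                         query_ss = NULL, template_ss = NULL,
                         ss_weight = 0) {
  t_eff <- min(query_basis$order_t, template_basis$order_t)
  if (length(signs) != t_eff)
    stop("signs must have length ", t_eff, " (the effective order)")
  if (!all(signs %in% c(-1, 1))) stop("signs must be +1 or -1")
  U <- query_basis$scaled_vectors[, seq_len(t_eff), drop = FALSE]
  V <- template_basis$scaled_vectors[, seq_len(t_eff), drop = FALSE]
  S <- tcrossprod(sweep(U, 2L, signs, "*"), V)
  if (ss_weight != 0) {
    if (is.null(query_ss) || is.null(template_ss))
      stop("ss_weight != 0 requires both secondary-structure strings")
    qs <- strsplit(query_ss$states, "")[[1]]
    ts <- strsplit(template_ss$states, "")[[1]]
    if (length(qs) != nrow(S) || length(ts) != ncol(S))
      stop("secondary-structure length does not match basis size")
    S <- S + ss_weight * outer(qs, ts, "==")
  }
  S
}

#' Global alignment of a score matrix
#'
#' Maximum-score alignment under an affine gap model (a gap run of length g
#' costs `gap_open + (g - 1) * gap_extend`). By default terminal gaps are
#' free (semi-global variant), so a short domain matched against a longer
#' chain is not punished at the termini; set `ends_free = FALSE` for a
#' strict global alignment. Traceback ties prefer the diagonal, then up,
#' then left, making the result deterministic.
#'
#' @param S numeric score matrix (rows = query, columns = template).
#' @param gap_open,gap_extend nonpositive gap penalties on the score scale
#'   of `S` (defaults -1 and -0.1); opening must cost at least as much as
#'   extending (`gap_open <= gap_extend`), which keeps the affine run cost
#'   model well defined.
#' @param ends_free logical; free terminal gaps (default `TRUE`).
#' @return A [cm_alignment()].
#' @export
global_align <- function(S, gap_open = -1, gap_extend = -0.1,
                         ends_free = TRUE) {
  S <- as.matrix(S)
  if (nrow(S) == 0L || ncol(S) == 0L) stop("empty score matrix")
  if (gap_open > 0 || gap_extend > 0)
    stop("gap penalties must be nonpositive")
  if (gap_open > gap_extend)
    stop("gap_open must be at least as costly as gap_extend")
  res <- .align_dp_cpp(S, gap_open, gap_extend, ends_free)
  cm_alignment(res$pairs, nrow(S), ncol(S), dp_score = res$score)
}

#' Contact map overlap of an alignment
#'
#' The (probability-weighted) number of query contacts superimposed on
#' template contacts by the alignment `f`: the sum over aligned query pairs
#' `(i, j)` with `j > i + 1` and `f(j) > f(i) + 1` of
#' `query[i, j] * template[f(i), f(j)]`. Contacts between consecutive
#' residues are not counted, and aligning a contact to a non-contact is not
#' penalised. For a binary query map this is the classic CMO count; for a
#' probabilistic query map it is the natural weighted generalisation.
#'
#' @param query_map,template_map [contact_map()] objects.
#' @param alignment a [cm_alignment()] consistent with both map sizes.
#' @return A single nonnegative number.
#' @export
cmo_score <- function(query_map, template_map, alignment) {
  stopifnot(inherits(query_map, "contact_map"),
            inherits(template_map, "contact_map"),
            inherits(alignment, "cm_alignment"))
  if (alignment$query_len != query_map$size ||
      alignment$template_len != template_map$size)
    stop("alignment size does not match the maps")
  p <- alignment$pairs
  k <- nrow(p)
  if (k < 2L) return(0)
  qi <- p[, 1]; ti <- p[, 2]
  Q <- query_map$values[qi, qi, drop = FALSE]
  Tm <- template_map$values[ti, ti, drop = FALSE]
  # pairs are strictly increasing, so a > b in pair index implies order in
  # both sequences; the non-consecutive constraints need the index gaps > 1
  okq <- outer(qi, qi, function(a, b) b - a > 1L)
  okt <- outer(ti, ti, function(a, b) b - a > 1L)
  sum(Q * Tm * (okq & okt))
}

#' Greedy eigenvector sign search
#'
#' Each eigenvector is defined only up to a global sign, and alignment
#' quality depends on the chosen signs. Exhausting all 2^t sign
#' combinations is exponential in t; instead the search starts from all-plus
#' signs and repeatedly sweeps the query eigenvectors in order of descending
#' absolute eigenvalue, flipping one sign at a time, realigning, and
#' accepting the flip only if the contact map overlap strictly increases.
#' After any accepted flip the sweep restarts at the first eigenvector;
#' the search stops when a full sweep accepts nothing. Because the CMO
#' strictly increases on every acceptance and is bounded, the procedure
#' terminates, with a number of alignment evaluations that grows
#' quadratically (not exponentially) in t. Only the query signs are
#' searched: flipping eigenvector k in both maps at once leaves the score
#' matrix unchanged, so template signs would be redundant.
#'
#' @param query_basis,template_basis [eigen_basis()] objects.
#' @param query_map,template_map the corresponding [contact_map()]s.
#' @param gap_open,gap_extend,ends_free passed to [global_align()].
#' @param query_ss,template_ss,ss_weight passed to [score_matrix()].
#' @return A list: `signs` (the accepted sign vector), `alignment` (the
#'   final [cm_alignment()]), `cmo` (its contact map overlap), and
#'   `n_evaluations` (number of alignments computed, for scaling checks).
#' @export
sign_search <- function(query_basis, template_basis, query_map, template_map,
                        gap_open = -1, gap_extend = -0.1, ends_free = TRUE,
                        query_ss = NULL, template_ss = NULL, ss_weight = 0) {
  t_eff <- min(query_basis$order_t, template_basis$order_t)
  qb <- truncate_basis(query_basis, t_eff)
  tb <- truncate_basis(template_basis, t_eff)
  evaluate <- function(signs) {
    S <- score_matrix(qb, tb, signs, query_ss = query_ss,
                      template_ss = template_ss, ss_weight = ss_weight)
    aln <- global_align(S, gap_open, gap_extend, ends_free)
    list(alignment = aln, cmo = cmo_score(query_map, template_map, aln))
  }
  signs <- rep(1, t_eff)
  best <- evaluate(signs)
  n_eval <- 1L
  repeat {
    improved <- FALSE
    for (k in seq_len(t_eff)) {
      cand_signs <- signs
      cand_signs[k] <- -cand_signs[k]
      cand <- evaluate(cand_signs)
      n_eval <- n_eval + 1L
      if (cand$cmo > best$cmo) {  # strict increase guarantees termination
        signs <- cand_signs
        best <- cand
        improved <- TRUE
        break  # restart the sweep at the largest eigenvalue
      }
    }
    if (!improved) break
  }
  list(signs = signs, alignment = best$alignment, cmo = best$cmo,
       n_evaluations = n_eval)
}

#' Align two contact maps end to end
#'
#' Convenience wrapper: decomposes both maps (if bases are not supplied),
#' runs the sign search, and returns its result.
#'
#' @param query_map,template_map [contact_map()] objects.
#' @param t number of eigenpairs (default 20, clamped to the map sizes).
#' @param ... passed on to [sign_search()].
#' @return See [sign_search()].
#' @export
align_maps <- function(query_map, template_map, t = 20L, ...) {
  qb <- decompose(query_map, t)
  tb <- decompose(template_map, t)
  sign_search(qb, tb, query_map, template_map, ...)
}
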