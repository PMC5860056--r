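## Contact-map construction from coordinates or predicted contact lists,
## plus the sparse long-range subsetting protocol.

#' Contact map
#'
#' A symmetric matrix over residue pairs. Observed maps (built from
#' coordinates) are binary with an accompanying full inter-residue distance
#' matrix; predicted maps hold contact probabilities. Pairs closer in
#' sequence than `min_separation` are zeroed: contacts between consecutive
#' residues are trivially true under any distance threshold and carry no
#' fold information.
#'
#' @param values symmetric numeric matrix, zero diagonal.
#' @param kind `"observed-binary"` or `"predicted-probability"`.
#' @param distances full symmetric distance matrix in Angstrom (observed
#'   maps only).
#' @param threshold contact distance threshold in Angstrom (observed maps
#'   only).
#' @param min_separation smallest |i - j| retained; pairs below it are 0.
#' @return An object of class `contact_map`.
#' @export
contact_map <- function(values, kind = c("observed-binary",
                                         "predicted-probability"),
                        distances = NULL, threshold = NULL,
                        min_separation = 2L) {
  kind <- match.arg(kind)
  values <- unname(as.matrix(values))
  n <- nrow(values)
  stopifnot(ncol(values) == n, n >= 1)
  if (max(abs(values - t(values))) > 1e-12) stop("contact map must be symmetric")
  if (kind == "observed-binary") {
    if (!all(values %in% c(0, 1))) stop("observed map values must be 0/1")
    if (is.null(distances)) stop("observed maps require a distances matrix")
    distances <- unname(as.matrix(distances))
    stopifnot(nrow(distances) == n, ncol(distances) == n)
  } else {
    if (any(values < 0 | values > 1)) stop("probabilities must lie in [0, 1]")
    if (!is.null(distances)) stop("predicted maps carry no distances")
  }
  min_separation <- as.integer(min_separation)
  stopifnot(min_separation >= 1L)
  band <- abs(row(values) - col(values)) < min_separation
  if (any(values[band] != 0)) stop("pairs with |i-j| < min_separation must be 0")
  structure(list(size = n, values = values, kind = kind,
                 distances = distances, threshold = threshold,
                 min_separation = min_separation),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %s, n = %d, %d contacts (|i-j| >= %d)\n",
              x$kind, x$size, sum(x$values[upper.tri(x$values)] > 0),
              x$min_separation))
  invisible(x)
}

#' Build an observed contact map from chain coordinates
#'
#' Marks residue pairs whose chosen atoms lie within `threshold` Angstrom.
#' The conventional threading choice is the CB atom (side-chain direction)
#' with a CA fallback for glycine; informative thresholds lie around
#' 7-10 Angstrom.
#'
#' @param coords a [chain_coords()] object with at least 2 residues.
#' @param threshold contact distance threshold in Angstrom (default 10).
#' @param atom `"CB"` for CB-with-CA-fallback (default) or `"CA"`.
#' @param min_separation exclude pairs with |i - j| below this (default 2,
#'   i.e. drop the self and consecutive-residue diagonals).
#' @return A `contact_map` of kind `observed-binary`, with the full distance
#'   matrix attached.
#' @export
map_from_coords <- function(coords, threshold = 10, atom = c("CB", "CA"),
                            min_separation = 2L) {
  stopifnot(inherits(coords, "chain_coords"), threshold > 0)
  atom <- match.arg(atom)
  n <- length(coords)
  if (n < 2L) stop("need at least 2 residues to build a contact map")
  xyz <- if (atom == "CA") coords$ca else {
    m <- coords$cb
    miss <- !is.finite(m[, 1])
    m[miss, ] <- coords$ca[miss, , drop = FALSE]
    m
  }
  dm <- as.matrix(stats::dist(xyz))
  vals <- (dm <= threshold) * 1
  vals[abs(row(vals) - col(vals)) < as.integer(min_separation)] <- 0
  contact_map(vals, kind = "observed-binary", distances = unname(dm),
              threshold = threshold, min_separation = min_separation)
}

#' Build a predicted contact map from a contact list
#'
#' By default the map holds raw contact probabilities; eigendecomposition
#' applies to any real symmetric matrix, so no binarisation is needed.
#' Optional binarisation at a probability cutoff is provided for ablation.
#'
#' @param contacts a [predicted_contacts()] object.
#' @param min_separation zero out pairs with |i - j| below this (default 2).
#' @param binarize_at if non-`NULL`, set entries to 1 where probability is
#'   at least this value and 0 elsewhere.
#' @return A `contact_map` of kind `predicted-probability`.
#' @export
map_from_predictions <- function(contacts, min_separation = 2L,
                                 binarize_at = NULL) {
  stopifnot(inherits(contacts, "predicted_contacts"))
  n <- contacts$length
  vals <- matrix(0, n, n)
  r <- contacts$records
  if (nrow(r)) {
    v <- if (is.null(binarize_at)) r$prob else (r$prob >= binarize_at) * 1
    vals[cbind(r$i, r$j)] <- v
    vals[cbind(r$j, r$i)] <- v
  }
  vals[abs(row(vals) - col(vals)) < as.integer(min_separation)] <- 0
  contact_map(vals, kind = "predicted-probability",
              min_separation = min_separation)
}

#' Select a sparse long-range subset of predicted contacts
#'
#' Emulates running the method on sparse data: keep only long-range records
#' (sequence separation of at least `long_range_min_separation`) and then
#' either the highest-probability `L/k` of them (`mode = "top"`, ties broken
#' by `(i, j)` order) or a uniformly sampled subset of the same size
#' (`mode = "random"`). If fewer eligible records exist than requested, all
#' are kept.
#'
#' @param contacts a [predicted_contacts()] object.
#' @param mode `"top"` or `"random"`.
#' @param count_rule one of `"L"`, `"L/2"`, `"L/5"`, `"L/10"`; the kept
#'   count is `floor(L/k)` with a minimum of 1.
#' @param long_range_min_separation minimum |i - j| for a record to be
#'   eligible; the default 22 keeps separations > 21 residues.
#' @param seed integer seed for `mode = "random"`.
#' @return A [predicted_contacts()] object over the same length L.
#' @export
subset_contacts <- function(contacts, mode = c("top", "random"),
                            count_rule = c("L", "L/2", "L/5", "L/10"),
                            long_range_min_separation = 22L, seed = 1L) {
  stopifnot(inherits(contacts, "predicted_contacts"))
  mode <- match.arg(mode)
  count_rule <- match.arg(count_rule)
  k <- c("L" = 1, "L/2" = 2, "L/5" = 5, "L/10" = 10)[[count_rule]]
  n_keep <- max(1L, contacts$length %/% k)
  r <- contacts$records
  r <- r[abs(r$i - r$j) >= long_range_min_separation, , drop = FALSE]
  if (nrow(r) > n_keep) {
    if (mode == "top") {
      ord <- order(-r$prob, r$i, r$j)
      r <- r[ord[seq_len(n_keep)], , drop = FALSE]
    } else {
      r <- r[local_sample(seed, nrow(r), n_keep), , drop = FALSE]
    }
  }
  predicted_contacts(contacts$length, r$i, r$j, r$prob)
}

# sample() under a private RNG stream so callers' RNG state is untouched
local_sample <- function(seed, n, size) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  sample.int(n, size)
}
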