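## Fold-library construction, query-vs-library search, benchmark filters,
## TPR@k, and aligned-backbone model output.

#' Template entry of a fold library
#'
#' @param id template identifier.
#' @param sequence amino-acid sequence (1-letter codes).
#' @param contact_map observed [contact_map()] with distances.
#' @param basis precomputed [eigen_basis()] of the contact map.
#' @param ss optional [ss_string()].
#' @param labels optional named character vector with any of `class`,
#'   `fold`, `superfamily`, `family`.
#' @param coords optional [chain_coords()], kept when backbone models are
#'   wanted (not serialised into the library container).
#' @return An object of class `template_entry`.
#' @export
template_entry <- function(id, sequence, contact_map, basis, ss = NULL,
                           labels = NULL, coords = NULL) {
  stopifnot(inherits(contact_map, "contact_map"),
            inherits(basis, "eigen_basis"))
  n <- contact_map$size
  if (nchar(sequence) != n) stop("sequence length != contact map size")
  if (basis$size != n) stop("basis size != contact map size")
  if (!is.null(ss) && length(ss) != n) stop("ss length != contact map size")
  structure(list(id = as.character(id), length = n, sequence = sequence,
                 ss = ss, contact_map = contact_map, basis = basis,
                 labels = labels, coords = coords),
            class = "template_entry")
}

#' Fold library
#'
#' @param entries list of [template_entry()] objects (unique ids).
#' @param params named list of construction parameters (threshold, t, ...).
#' @return An object of class `fold_library`.
#' @export
fold_library <- function(entries, params = list()) {
  ids <- vapply(entries, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate template ids")
  structure(list(entries = entries, ids = ids, params = params),
            class = "fold_library")
}

#' @export
length.fold_library <- function(x) length(x$entries)

#' @export
print.fold_library <- function(x, ...) {
  cat(sprintf("<fold_library> %d templates\n", length(x)))
  invisible(x)
}

#' Build a fold library from structure files
#'
#' Reads each PDB file, builds its observed contact map and eigenbasis, and
#' collects the results. Files that cannot be parsed are skipped with a
#' warning (a large structure set routinely contains a few unusable files);
#' entry order follows the input order, so rebuilding from identical inputs
#' is deterministic.
#'
#' @param structure_paths character vector of PDB paths.
#' @param ids template ids; defaults to file base names without extension.
#' @param threshold contact distance threshold in Angstrom (default 10).
#' @param t eigenpairs to precompute per template (default 20).
#' @param atom contact atom convention, see [map_from_coords()].
#' @param min_separation see [map_from_coords()].
#' @param labels optional data.frame with columns `id` and any of `class`,
#'   `fold`, `superfamily`, `family`.
#' @param keep_coords retain coordinates on each entry (needed only for
#'   [write_aligned_model()]).
#' @return A [fold_library()].
#' @export
build_library <- function(structure_paths, ids = NULL, threshold = 10,
                          t = 20L, atom = "CB", min_separation = 2L,
                          labels = NULL, keep_coords = FALSE) {
  if (length(structure_paths) == 0L) stop("no structure paths given")
  if (is.null(ids)) ids <- sub("\\.[^.]*$", "", basename(structure_paths))
  stopifnot(length(ids) == length(structure_paths))
  entries <- list()
  for (k in seq_along(structure_paths)) {
    e <- tryCatch({
      coords <- read_structure(structure_paths[k])
      cm <- map_from_coords(coords, threshold = threshold, atom = atom,
                            min_separation = min_separation)
      basis <- decompose(cm, t)
      lab <- NULL
      if (!is.null(labels)) {
        row <- labels[labels$id == ids[k], , drop = FALSE]
        if (nrow(row) == 1L) {
          keep <- intersect(c("class", "fold", "superfamily", "family"),
                            names(row))
          lab <- unlist(row[1, keep])
        }
      }
      template_entry(ids[k], paste(coords$aa, collapse = ""), cm, basis,
                     labels = lab,
                     coords = if (keep_coords) coords else NULL)
    }, error = function(err) {
      warning("skipping ", structure_paths[k], ": ", conditionMessage(err))
      NULL
    })
    if (!is.null(e)) entries[[length(entries) + 1L]] <- e
  }
  if (length(entries) == 0L) stop("no structure file could be read")
  fold_library(entries, params = list(threshold = threshold, t = t,
                                      atom = atom,
                                      min_separation = min_separation))
}

#' Search configuration
#'
#' Bundles the tunable parameters of a library search.
#'
#' @param t eigenpairs used for the query (default 20; per template the
#'   effective order is the smaller of the two bases).
#' @param gap_open,gap_extend,ends_free alignment gap model, see
#'   [global_align()].
#' @param ss_weight secondary-structure bonus weight (default 0 = off;
#'   1.0 is a reasonable on-switch on the eigenvector score scale).
#' @param min_separation sequence-separation floor for map construction
#'   and the correlation score.
#' @param rank_by `"auto"` (match probability when a model is set, else
#'   t-statistic, else CMO), `"probability"`, `"t"` or `"cmo"`.
#' @param model optional [logistic_model()] for match probabilities.
#' @param min_query_len shortest query length accepted (default 30).
#' @return A list of class `search_config`.
#' @export
search_config <- function(t = 20L, gap_open = -1, gap_extend = -0.1,
                          ends_free = TRUE, ss_weight = 0,
                          min_separation = 2L,
                          rank_by = c("auto", "probability", "t", "cmo"),
                          model = NULL, min_query_len = 30L) {
  rank_by <- match.arg(rank_by)
  structure(list(t = as.integer(t), gap_open = gap_open,
                 gap_extend = gap_extend, ends_free = ends_free,
                 ss_weight = ss_weight,
                 min_separation = as.integer(min_separation),
                 rank_by = rank_by, model = model,
                 min_query_len = as.integer(min_query_len)),
            class = "search_config")
}

.rank_results <- function(df, rank_by, has_model) {
  key <- switch(rank_by,
                auto = if (has_model) "probability" else "t",
                rank_by)
  ord <- switch(
    key,
    # more negative t = stronger anticorrelation = better; NA (unscorable) last
    t = order(df$t_statistic, df$template_id, na.last = TRUE),
    probability = order(-df$match_probability, df$template_id, na.last = TRUE),
    cmo = order(-df$cmo, df$template_id))
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Search a fold library with a predicted contact map
#'
#' For every template: truncate both eigenbases to a common order, run the
#' greedy sign search to the best contact-map-overlap alignment, then score
#' the match by the probability/distance correlation and (optionally) the
#' logistic match probability. Results are ranked by the configured key,
#' ties broken by template id, so the ranking does not depend on library
#' entry order. Runtime is linear in library size at fixed t.
#'
#' @param contacts the query's [predicted_contacts()].
#' @param library a [fold_library()].
#' @param query_id identifier used in outputs.
#' @param query_ss optional [ss_string()] for the query.
#' @param config a [search_config()].
#' @return An object of class `ranked_results`: list with `query_id`,
#'   `results` (data.frame: rank, template_id, cmo, pearson_r, n_pairs,
#'   t_statistic, frac_query_aligned, frac_template_aligned,
#'   match_probability, label columns), `alignments` (named list of
#'   [cm_alignment()]), and `params`.
#' @export
search_library <- function(contacts, library, query_id = "query",
                           query_ss = NULL, config = search_config()) {
  stopifnot(inherits(contacts, "predicted_contacts"),
            inherits(library, "fold_library"),
            inherits(config, "search_config"))
  if (length(library) == 0L) stop("empty fold library")
  if (contacts$length < config$min_query_len)
    stop("query shorter than min_query_len (", config$min_query_len, ")")
  qmap <- map_from_predictions(contacts,
                               min_separation = config$min_separation)
  qbasis <- decompose(qmap, config$t)
  rows <- vector("list", length(library))
  alignments <- vector("list", length(library))
  for (k in seq_along(library$entries)) {
    e <- library$entries[[k]]
    use_ss <- config$ss_weight != 0 && !is.null(query_ss) && !is.null(e$ss)
    sr <- sign_search(qbasis, e$basis, qmap, e$contact_map,
                      gap_open = config$gap_open,
                      gap_extend = config$gap_extend,
                      ends_free = config$ends_free,
                      query_ss = if (use_ss) query_ss else NULL,
                      template_ss = if (use_ss) e$ss else NULL,
                      ss_weight = if (use_ss) config$ss_weight else 0)
    cs <- correlation_score(qmap, e$contact_map, sr$alignment,
                            min_separation = config$min_separation)
    npair <- nrow(sr$alignment$pairs)
    fq <- npair / qmap$size
    ft <- npair / e$length
    prob <- if (!is.null(config$model) && !cs$unscorable)
      match_probability(config$model, cs$t_statistic, fq, ft)
    else NA_real_
    lab <- function(l) if (!is.null(e$labels) && l %in% names(e$labels))
      unname(e$labels[[l]]) else NA_character_
    rows[[k]] <- data.frame(
      template_id = e$id, cmo = sr$cmo, pearson_r = cs$r,
      n_pairs = cs$n_pairs, t_statistic = cs$t_statistic,
      frac_query_aligned = fq, frac_template_aligned = ft,
      match_probability = prob,
      class = lab("class"), fold = lab("fold"),
      superfamily = lab("superfamily"), family = lab("family"),
      stringsAsFactors = FALSE)
    alignments[[k]] <- sr$alignment
  }
  df <- do.call(rbind, rows)
  names(alignments) <- df$template_id
  df <- .rank_results(df, config$rank_by, !is.null(config$model))
  structure(list(query_id = query_id, results = df,
                 alignments = alignments[df$template_id],
                 params = config),
            class = "ranked_results")
}

#' @export
print.ranked_results <- function(x, ...) {
  cat(sprintf("<ranked_results> query %s, %d templates\n",
              x$query_id, nrow(x$results)))
  print(utils::head(x$results[c("rank", "template_id", "cmo", "pearson_r",
                                "t_statistic", "frac_query_aligned",
                                "match_probability")], 5))
  invisible(x)
}

#' Filter ranked hits for benchmark evaluation
#'
#' Drops hits covering less than `min_query_overlap` of the query (hits too
#' partial to build a useful model from) and, when homology exclusion is
#' requested, hits sharing the query's label at the excluded hierarchy
#' levels (simulating a library with no homologous relatives). Order is
#' preserved and ranks are reassigned.
#'
#' @param results a `ranked_results` object.
#' @param min_query_overlap minimum `frac_query_aligned` (default 0.4).
#' @param exclude_levels subset of `c("family", "superfamily")`.
#' @param query_labels named character vector with the query's labels
#'   (required when `exclude_levels` is nonempty).
#' @return A filtered `ranked_results` object.
#' @export
filter_results <- function(results, min_query_overlap = 0.4,
                           exclude_levels = character(0),
                           query_labels = NULL) {
  stopifnot(inherits(results, "ranked_results"))
  bad <- setdiff(exclude_levels, c("family", "superfamily"))
  if (length(bad)) stop("cannot exclude level(s): ", paste(bad, collapse = ", "))
  df <- results$results
  keep <- df$frac_query_aligned >= min_query_overlap
  for (lev in exclude_levels) {
    if (is.null(query_labels) || !lev %in% names(query_labels))
      stop("query_labels must provide '", lev, "' for exclusion")
    if (anyNA(df[[lev]]))
      stop("templates lack '", lev, "' labels needed for exclusion")
    keep <- keep & df[[lev]] != query_labels[[lev]]
  }
  df <- df[keep, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  structure(list(query_id = results$query_id, results = df,
                 alignments = results$alignments[df$template_id],
                 params = results$params),
            class = "ranked_results")
}

#' True positive rate at rank k
#'
#' Fraction of queries whose top-k hits contain at least one template with
#' the query's label at the given hierarchy level. Queries for which no
#' correct-level template exists anywhere in their (filtered) result list
#' are removed from the denominator: after homology exclusion a true
#' positive may be unattainable for some queries, and counting those would
#' conflate library coverage with ranking quality.
#'
#' @param per_query_results list of `ranked_results` objects.
#' @param query_labels data.frame with columns `query_id` and the label
#'   levels.
#' @param level one of `"class"`, `"fold"`, `"superfamily"`.
#' @param k rank depth (1, 2, 5, 10, ...).
#' @return A list: `tpr` (in \[0, 1\]), `n_scored` (denominator),
#'   `n_excluded` (queries with no attainable true positive).
#' @export
tpr_at_k <- function(per_query_results, query_labels,
                     level = c("fold", "class", "superfamily"), k = 1L) {
  level <- match.arg(level)
  if (length(per_query_results) == 0L) stop("no query results")
  hit <- logical(0); attainable <- logical(0)
  for (res in per_query_results) {
    truth <- query_labels[[level]][query_labels$query_id == res$query_id]
    if (length(truth) != 1L)
      stop("no ", level, " label for query ", res$query_id)
    labs <- res$results[[level]]
    attainable <- c(attainable, any(labs == truth, na.rm = TRUE))
    top <- utils::head(labs, k)
    hit <- c(hit, any(top == truth, na.rm = TRUE))
  }
  n_scored <- sum(attainable)
  if (n_scored == 0L)
    return(list(tpr = NA_real_, n_scored = 0L,
                n_excluded = length(per_query_results)))
  list(tpr = sum(hit & attainable) / n_scored, n_scored = n_scored,
       n_excluded = length(per_query_results) - n_scored)
}

#' Write a low-resolution aligned-backbone model
#'
#' For each aligned pair, copies the template CA coordinate and labels it
#' with the query residue identity and query numbering; unaligned query
#' residues are omitted. The result is a CA-only PDB model of the query
#' threaded onto the template backbone.
#'
#' @param query_seq query amino-acid sequence (1-letter codes).
#' @param template a [template_entry()] whose `coords` are present, or a
#'   [chain_coords()] object.
#' @param alignment a [cm_alignment()] (query vs that template).
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_aligned_model <- function(query_seq, template, alignment, path) {
  coords <- if (inherits(template, "template_entry")) template$coords
  else template
  if (is.null(coords) || !inherits(coords, "chain_coords"))
    stop("template coordinates unavailable (build the library with keep_coords = TRUE)")
  stopifnot(inherits(alignment, "cm_alignment"))
  if (alignment$query_len != nchar(query_seq))
    stop("query sequence length does not match the alignment")
  if (alignment$template_len != length(coords))
    stop("template length does not match the alignment")
  p <- alignment$pairs
  if (nrow(p) == 0L) stop("empty alignment, nothing to write")
  qaa <- strsplit(query_seq, "")[[1]][p[, 1]]
  model <- chain_coords("A", resno = p[, 1], aa = qaa,
                        ca = coords$ca[p[, 2], , drop = FALSE])
  write_structure(model, path)
}

#' Write a ranked-results table
#'
#' Plain-text tab-separated table, one row per hit: rank, template id, CMO,
#' Pearson r, pair count, t-statistic, aligned fractions, match
#' probability.
#'
#' @param results a `ranked_results` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  stopifnot(inherits(results, "ranked_results"))
  cols <- c("rank", "template_id", "cmo", "pearson_r", "n_pairs",
            "t_statistic", "frac_query_aligned", "frac_template_aligned",
            "match_probability")
  utils::write.table(results$results[cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
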