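## Deterministic synthetic-data generator: idealised CA traces (helix
## bundles, beta meanders, random coils), their observed contact maps, noisy
## "predicted" contact lists emulating a sequence-based contact predictor,
## and a labelled benchmark library with held-out queries.

# idealised geometry constants (Angstrom)
.geom <- list(
  ca_step = 3.8,        # consecutive CA-CA distance
  helix_rise = 1.5,     # rise per residue along the helix axis
  helix_radius = 2.3,   # CA helix radius
  helix_spacing = 9.5,  # axis-to-axis packing distance in a bundle
  strand_rise = 3.4,    # rise per residue along a strand
  sheet_spacing = 4.8,  # strand-to-strand distance in a sheet
  threshold = 10)       # contact threshold the generator guarantees maps for

# per-residue turn angle making the helix CA-CA step exactly ca_step
.helix_turn <- 2 * asin(sqrt(.geom$ca_step^2 - .geom$helix_rise^2) /
                          (2 * .geom$helix_radius))
# pleat amplitude making the strand CA-CA step exactly ca_step
.strand_pleat <- sqrt(.geom$ca_step^2 - .geom$strand_rise^2) / 2

# fold any number of integers into one valid seed (exact double arithmetic,
# reduced mod 2^31 - 1 so derived seeds never overflow R's 32-bit integers)
mix_seed <- function(...) {
  s <- 104729
  for (x in c(...)) s <- (s * 69069 + as.numeric(x)) %% 2147483647
  as.integer(s)
}

# evaluate `code` under a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

.rotate <- function(v, axis, angle) {
  # Rodrigues rotation of row-vector v about unit axis
  k <- axis / sqrt(sum(axis^2))
  v * cos(angle) + pracma_cross(k, v) * sin(angle) +
    k * sum(k * v) * (1 - cos(angle))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# k intermediate points on a circular arc from A to B such that all k+1
# chords have length ca_step; requires |B - A| < (k+1) * ca_step
.arc_bridge <- function(A, B, k, normal = c(0, 0, 1)) {
  step <- .geom$ca_step
  d <- sqrt(sum((B - A)^2))
  if (d >= (k + 1) * step - 1e-9)
    stop("anchors too far apart for an arc bridge")
  ratio <- d / step
  f <- function(theta) sin(theta / 2) / sin(theta / (2 * (k + 1))) - ratio
  theta <- stats::uniroot(f, c(1e-8, 2 * pi - 1e-8), tol = 1e-12)$root
  R <- step / (2 * sin(theta / (2 * (k + 1))))
  u <- (B - A) / d
  w <- normal - sum(normal * u) * u
  if (sqrt(sum(w^2)) < 1e-8) w <- pracma_cross(u, c(1, 0, 0))
  if (sqrt(sum(w^2)) < 1e-8) w <- pracma_cross(u, c(0, 1, 0))
  w <- w / sqrt(sum(w^2))
  h <- R * cos(theta / 2)
  centre <- (A + B) / 2 - h * w
  axis <- pracma_cross(u, w)
  a0 <- A - centre
  # rotation sign: pick the direction that lands on B after angle theta
  endp <- .rotate(a0, axis, theta)
  sgn <- if (sum((endp - (B - centre))^2) <
             sum((.rotate(a0, axis, -theta) - (B - centre))^2)) 1 else -1
  t(vapply(seq_len(k), function(i)
    centre + .rotate(a0, axis, sgn * i * theta / (k + 1)),
    numeric(3)))
}

.ideal_helix <- function(n, origin, up = TRUE, phase = 0) {
  i <- seq_len(n) - 1
  z <- .geom$helix_rise * i * (if (up) 1 else -1)
  ang <- phase + i * .helix_turn
  cbind(origin[1] + .geom$helix_radius * cos(ang),
        origin[2] + .geom$helix_radius * sin(ang),
        origin[3] + z)
}

.ideal_strand <- function(n, origin, forward = TRUE) {
  i <- seq_len(n) - 1
  x <- .geom$strand_rise * i * (if (forward) 1 else -1)
  cbind(origin[1] + x, origin[2],
        origin[3] + .strand_pleat * ifelse(i %% 2 == 0, 1, -1))
}

.build_segmented <- function(n_residues, seg_len_range, loop_len, make_seg,
                             ss_letter) {
  # chains segments generated by make_seg(len, index, anchor) with arc
  # bridges of loop_len residues in between, until n_residues are placed
  xyz <- NULL; ss <- character(0); seg_idx <- 0L
  while (is.null(xyz) || nrow(xyz) < n_residues) {
    seg_idx <- seg_idx + 1L
    len <- sample(seg_len_range[1]:seg_len_range[2], 1L)
    seg <- make_seg(len, seg_idx)
    if (is.null(xyz)) {
      xyz <- seg
      ss <- rep(ss_letter, nrow(seg))
    } else {
      bridge <- .arc_bridge(xyz[nrow(xyz), ], seg[1, ], loop_len,
                            normal = c(0.3, 0.1, 1))
      xyz <- rbind(xyz, bridge, seg)
      ss <- c(ss, rep("C", loop_len), rep(ss_letter, nrow(seg)))
    }
  }
  list(xyz = xyz[seq_len(n_residues), , drop = FALSE],
       ss = ss[seq_len(n_residues)])
}

# antiparallel meander wrapped around a cylinder: adjacent strands pair at
# sheet spacing, and the sheet's curvature closes the first strand against
# the last, giving the sequence-long-range contacts real beta folds have
.build_meander <- function(n_residues) {
  lens <- integer(0)
  while (sum(lens) + 3L * length(lens) < n_residues + 3L)
    lens <- c(lens, sample(6:10, 1L))
  n_seg <- length(lens)
  n_seg <- max(n_seg, 3L)
  lens <- c(lens, rep(8L, n_seg))[seq_len(n_seg)]
  theta <- 2 * pi / n_seg
  R <- .geom$sheet_spacing / (2 * sin(theta / 2))
  xyz <- NULL; ss <- character(0)
  for (s in seq_len(n_seg)) {
    len <- lens[s]
    up <- s %% 2L == 1L
    phi <- (s - 1) * theta
    i <- seq_len(len) - 1
    z <- 3.4 * i * (if (up) 1 else -1) + (if (up) 0 else 3.4 * (len - 1))
    r <- R + .strand_pleat * ifelse(i %% 2 == 0, 1, -1)
    seg <- cbind(r * cos(phi), r * sin(phi), z)
    if (is.null(xyz)) {
      xyz <- seg; ss <- rep("E", len)
    } else {
      bridge <- .arc_bridge(xyz[nrow(xyz), ], seg[1, ], 3L,
                            normal = c(cos(phi), sin(phi), 0.2))
      xyz <- rbind(xyz, bridge, seg)
      ss <- c(ss, rep("C", 3L), rep("E", len))
    }
    if (nrow(xyz) >= n_residues) break
  }
  list(xyz = xyz[seq_len(n_residues), , drop = FALSE],
       ss = ss[seq_len(n_residues)])
}

#' Generate a synthetic CA trace
#'
#' Builds an idealised single-chain CA trace with exact 3.8 Angstrom
#' consecutive spacing: packed helices (`helix-bundle`), an antiparallel
#' sheet (`beta-meander`) or a soft self-avoiding random walk
#' (`random-coil`), optionally perturbed by isotropic Gaussian coordinate
#' jitter. Deterministic for a given `(seed, arch_seed)` pair; `arch_seed`
#' fixes the architecture (segment lengths) separately from the
#' jitter/sequence noise so that structurally related chains ("family
#' members") can be generated by varying `seed` at fixed `arch_seed`.
#'
#' @param n_residues chain length (at least 10).
#' @param topology `"helix-bundle"`, `"beta-meander"` or `"random-coil"`.
#' @param jitter standard deviation of Gaussian coordinate noise
#'   (Angstrom, default 0).
#' @param seed integer seed for jitter and sequence.
#' @param arch_seed integer seed for the architecture; defaults to `seed`.
#' @param id identifier for the generated protein.
#' @return An object of class `synthetic_protein`: list with `id`,
#'   `coords` ([chain_coords()]), `true_map` (observed [contact_map()] at
#'   the generator's 10 Angstrom threshold), `ss` ([ss_string()]),
#'   `topology` and `fold_family` (filled by [make_benchmark()]).
#' @export
make_chain <- function(n_residues,
                       topology = c("helix-bundle", "beta-meander",
                                    "random-coil"),
                       jitter = 0, seed = 1L, arch_seed = seed,
                       id = "synthetic") {
  topology <- match.arg(topology)
  stopifnot(n_residues >= 10L, jitter >= 0)
  built <- with_seed(mix_seed(arch_seed, 1L), {
    if (topology == "helix-bundle") {
      .build_segmented(
        n_residues, c(10L, 16L), 4L,
        function(len, idx) {
          up <- idx %% 2L == 1L
          origin <- c((idx - 1L) * .geom$helix_spacing, 0,
                      if (up) 0 else (len - 1L) * .geom$helix_rise)
          .ideal_helix(len, origin, up = up, phase = (idx - 1L) * 0.7)
        }, "H")
    } else if (topology == "beta-meander") {
      .build_meander(n_residues)
    } else {
      xyz <- matrix(0, n_residues, 3)
      dir <- c(1, 0, 0)
      for (i in 2:n_residues) {
        for (try in 1:25) {
          cand_dir <- dir + 0.45 * stats::rnorm(3)
          cand_dir <- cand_dir / sqrt(sum(cand_dir^2))
          cand <- xyz[i - 1, ] + .geom$ca_step * cand_dir
          prev <- xyz[seq_len(max(1, i - 3)), , drop = FALSE]
          if (min(sqrt(rowSums(sweep(prev, 2, cand)^2))) > 3.2) break
        }
        dir <- cand_dir
        xyz[i, ] <- cand
      }
      list(xyz = xyz, ss = rep("C", n_residues))
    }
  })
  final <- with_seed(mix_seed(seed, 2L), {
    xyz <- built$xyz
    if (jitter > 0)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = jitter), ncol = 3)
    aa <- sample(names(.aa3to1), n_residues, replace = TRUE)
    list(xyz = xyz, aa = .aa3to1[aa])
  })
  coords <- chain_coords("A", resno = seq_len(n_residues), aa = final$aa,
                         ca = final$xyz)
  true_map <- map_from_coords(coords, threshold = .geom$threshold,
                              atom = "CB", min_separation = 2L)
  structure(list(id = id, coords = coords, true_map = true_map,
                 ss = ss_string(paste(built$ss, collapse = "")),
                 topology = topology, fold_family = NA_integer_),
            class = "synthetic_protein")
}

#' @export
print.synthetic_protein <- function(x, ...) {
  cat(sprintf("<synthetic_protein> %s: %s, %d residues\n",
              x$id, x$topology, length(x$coords)))
  invisible(x)
}

#' Emulate predictor output: a noisy contact list from a true map
#'
#' True contacts receive probabilities drawn from Beta(`prob_sharpness`, 1)
#' (concentrated near 1 for large sharpness); a `flip_rate` fraction of the
#' true contacts is dropped, and spurious non-contact pairs are added at a
#' rate chosen so their expected number equals the expected number dropped,
#' with low Beta(1, `prob_sharpness`) probabilities. `prob_sharpness = Inf`
#' gives the noiseless limit (probability exactly 1 on every kept contact).
#' Deterministic for a given seed.
#'
#' Real sequence-based predictors emit a score for every residue pair, not
#' only for pairs they believe in; the resulting output list is dominated
#' by records with very low confidence. `background_rate` emulates that
#' tail: the given fraction of the remaining non-contact pairs is
#' additionally reported, with Beta(1, `background_sharpness`)
#' probabilities (default concentration 50, i.e. scores mostly below a few
#' percent, the magnitude real predictors assign to pairs they reject).
#' The default rate 0 keeps the list sparse; 1 reports every eligible
#' pair, which is what ranked-versus-randomized contact selection
#' experiments assume.
#'
#' @param true_map an observed [contact_map()].
#' @param flip_rate fraction of contacts dropped (and expected fraction
#'   spuriously added), in \[0, 0.5).
#' @param prob_sharpness Beta concentration of the probability noise.
#' @param seed integer seed.
#' @param background_rate fraction of remaining non-contact pairs reported
#'   with low-confidence scores (default 0).
#' @param background_sharpness Beta concentration of the background
#'   scores (default 50).
#' @return A [predicted_contacts()] object.
#' @export
noisy_predictions <- function(true_map, flip_rate = 0.1, prob_sharpness = 8,
                              seed = 1L, background_rate = 0,
                              background_sharpness = 50) {
  stopifnot(inherits(true_map, "contact_map"),
            flip_rate >= 0, flip_rate < 0.5, prob_sharpness > 0,
            background_rate >= 0, background_rate <= 1,
            background_sharpness > 0)
  ut <- upper.tri(true_map$values) &
    abs(row(true_map$values) - col(true_map$values)) >= true_map$min_separation
  con <- which(ut & true_map$values > 0, arr.ind = TRUE)
  non <- which(ut & true_map$values == 0, arr.ind = TRUE)
  with_seed(mix_seed(seed, 3L), {
    keep <- stats::runif(nrow(con)) >= flip_rate
    kept <- con[keep, , drop = FALSE]
    p_true <- if (is.infinite(prob_sharpness)) rep(1, nrow(kept))
    else stats::rbeta(nrow(kept), prob_sharpness, 1)
    spur_rate <- if (nrow(non)) flip_rate * nrow(con) / nrow(non) else 0
    add <- stats::runif(nrow(non)) < spur_rate
    added <- non[add, , drop = FALSE]
    p_spur <- if (is.infinite(prob_sharpness)) rep(0, nrow(added))
    else stats::rbeta(nrow(added), 1, prob_sharpness)
    rest <- non[!add, , drop = FALSE]
    bg <- rest[stats::runif(nrow(rest)) < background_rate, , drop = FALSE]
    p_bg <- if (is.infinite(background_sharpness)) rep(0, nrow(bg))
    else stats::rbeta(nrow(bg), 1, background_sharpness)
    predicted_contacts(true_map$size,
                       c(kept[, 1], added[, 1], bg[, 1]),
                       c(kept[, 2], added[, 2], bg[, 2]),
                       c(p_true, p_spur, p_bg))
  })
}

#' Long-range contact overlap between two maps
#'
#' Jaccard index of the long-range contact sets (pairs with sequence
#' separation at least `min_separation`) of two observed maps, compared as
#' index-pair sets so the maps may differ in size. Long-range contacts are
#' the fold-defining signal; short-range contacts are near-universal within
#' a secondary-structure class and are excluded from the comparison.
#'
#' @param map_a,map_b observed [contact_map()] objects.
#' @param min_separation sequence-separation floor (default 12).
#' @return Jaccard overlap in \[0, 1\].
#' @export
contact_overlap <- function(map_a, map_b, min_separation = 12L) {
  pairs_of <- function(m) {
    ut <- which(upper.tri(m$values) & m$values > 0 &
                  abs(row(m$values) - col(m$values)) >= min_separation,
                arr.ind = TRUE)
    paste(ut[, 1], ut[, 2])
  }
  a <- pairs_of(map_a); b <- pairs_of(map_b)
  if (length(a) == 0L && length(b) == 0L) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Generate a labelled benchmark: fold library plus held-out queries
#'
#' Creates `n_families` structural families. Each family has a fixed
#' architecture (topology alternating between helix bundle and beta
#' meander, lengths drawn once per family); its members are independently
#' jittered realisations of that architecture. `members_per_family` members
#' enter the fold library; one extra held-out member per family provides
#' the query, as a noisy predicted contact list of its true map. Labels
#' follow a 4-level hierarchy: class = topology, and fold, superfamily,
#' family all distinct per generated family (each family is its own fold),
#' so homology-exclusion filters can be exercised.
#'
#' @param n_families number of families (at least 1).
#' @param members_per_family library members per family (at least 1).
#' @param seed master seed; every random choice derives from it.
#' @param flip_rate,prob_sharpness,background_rate query noise, see
#'   [noisy_predictions()].
#' @param member_jitter coordinate jitter of members around the family
#'   architecture (Angstrom, default 0.4).
#' @param length_range range chain lengths are drawn from per family.
#' @param t eigenpairs precomputed per template (default 10; ample for
#'   chains of this size).
#' @return A list: `library` (a [fold_library()]), `queries` (list of
#'   per-query lists: `query_id`, `contacts`, `true_map`, `protein`,
#'   `labels`), and `query_labels` (data.frame for [tpr_at_k()]).
#' @export
make_benchmark <- function(n_families, members_per_family, seed = 1L,
                           flip_rate = 0.1, prob_sharpness = 8,
                           background_rate = 0, member_jitter = 0.4,
                           length_range = c(60L, 90L), t = 10L) {
  stopifnot(n_families >= 1L, members_per_family >= 1L)
  fam_meta <- with_seed(mix_seed(seed, 4L), {
    lapply(seq_len(n_families), function(f) {
      list(n = sample(length_range[1]:length_range[2], 1L),
           topology = if (f %% 2L == 1L) "helix-bundle" else "beta-meander",
           arch_seed = mix_seed(seed, 5L, f))
    })
  })
  entries <- list()
  queries <- list()
  for (f in seq_len(n_families)) {
    meta <- fam_meta[[f]]
    fam <- sprintf("fam%03d", f)
    labels <- c(class = if (meta$topology == "helix-bundle") "a" else "b",
                fold = sprintf("fold%03d", f),
                superfamily = sprintf("sf%03d", f),
                family = fam)
    for (m in seq_len(members_per_family)) {
      p <- make_chain(meta$n, meta$topology, jitter = member_jitter,
                      seed = mix_seed(seed, 6L, f, m),
                      arch_seed = meta$arch_seed,
                      id = sprintf("%s_m%d", fam, m))
      p$fold_family <- f
      entries[[length(entries) + 1L]] <- template_entry(
        p$id, paste(p$coords$aa, collapse = ""), p$true_map,
        decompose(p$true_map, t), ss = p$ss, labels = labels,
        coords = p$coords)
    }
    qp <- make_chain(meta$n, meta$topology, jitter = member_jitter,
                     seed = mix_seed(seed, 6L, f, 0L),
                     arch_seed = meta$arch_seed,
                     id = sprintf("%s_query", fam))
    qp$fold_family <- f
    queries[[f]] <- list(
      query_id = qp$id,
      contacts = noisy_predictions(qp$true_map, flip_rate, prob_sharpness,
                                   seed = mix_seed(seed, 7L, f),
                                   background_rate = background_rate),
      true_map = qp$true_map, protein = qp, labels = labels)
  }
  query_labels <- do.call(rbind, lapply(queries, function(q)
    data.frame(query_id = q$query_id, class = q$labels[["class"]],
               fold = q$labels[["fold"]],
               superfamily = q$labels[["superfamily"]],
               family = q$labels[["family"]], stringsAsFactors = FALSE)))
  list(library = fold_library(entries,
                              params = list(threshold = .geom$threshold,
                                            t = t, seed = seed)),
       queries = queries, query_labels = query_labels)
}

#' Write benchmark fixtures as standard files
#'
#' Materialises a [make_benchmark()] result as PDB files (library), RR
#' contact files and FASTA sequences (queries) and a tab-separated label
#' table, so the command-line interface can be exercised end to end.
#'
#' @param benchmark result of [make_benchmark()].
#' @param dir output directory (created).
#' @return Invisibly, a list with the written paths: `pdb_dir`,
#'   `pdb_files`, `query_dir`, `labels_file`.
#' @export
write_benchmark_files <- function(benchmark, dir) {
  pdb_dir <- file.path(dir, "pdb")
  query_dir <- file.path(dir, "queries")
  dir.create(pdb_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(query_dir, recursive = TRUE, showWarnings = FALSE)
  pdb_files <- character(0)
  lab_rows <- list()
  for (e in benchmark$library$entries) {
    stopifnot(!is.null(e$coords))
    path <- file.path(pdb_dir, paste0(e$id, ".pdb"))
    write_structure(e$coords, path)
    pdb_files <- c(pdb_files, path)
    lab_rows[[length(lab_rows) + 1L]] <- data.frame(
      id = e$id, class = e$labels[["class"]], fold = e$labels[["fold"]],
      superfamily = e$labels[["superfamily"]],
      family = e$labels[["family"]], stringsAsFactors = FALSE)
  }
  for (q in benchmark$queries) {
    write_predicted_contacts(q$contacts,
                             file.path(query_dir, paste0(q$query_id, ".rr")),
                             target = q$query_id)
    writeLines(c(paste0(">", q$query_id),
                 paste(q$protein$coords$aa, collapse = "")),
               file.path(query_dir, paste0(q$query_id, ".fasta")))
  }
  labels_file <- file.path(dir, "labels.tsv")
  utils::write.table(do.call(rbind, lab_rows), labels_file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(pdb_dir = pdb_dir, pdb_files = pdb_files,
                 query_dir = query_dir, labels_file = labels_file))
}
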