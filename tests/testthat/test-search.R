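# a small shared benchmark; built once per test run
bench_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_benchmark(4, 2, seed = 7)
    cache
  }
})

exact_contacts <- function(map) {
  # a query contact list reproducing an observed map at probability 1
  ut <- which(upper.tri(map$values) & map$values > 0, arr.ind = TRUE)
  predicted_contacts(map$size, ut[, 1], ut[, 2], rep(1, nrow(ut)))
}

test_that("build_library reads structures, skips corrupt files, and is deterministic", {
  b <- bench_small()
  dir <- tempfile("fix")
  files <- write_benchmark_files(b, dir)
  lib <- build_library(files$pdb_files, threshold = 10, t = 6)
  expect_equal(length(lib), length(b$library))
  expect_equal(vapply(lib$entries, `[[`, 1L, "length"),
               vapply(b$library$entries, `[[`, 1L, "length"))
  # maps from written-and-reread coordinates match the originals
  expect_equal(lib$entries[[1]]$contact_map$values,
               b$library$entries[[1]]$contact_map$values)
  # corrupt file among the inputs: skipped with a warning, others kept
  bad <- file.path(dir, "broken.pdb")
  writeLines("not a pdb at all", bad)
  expect_warning(lib2 <- build_library(c(files$pdb_files, bad)), "skipping")
  expect_equal(length(lib2), length(b$library))
  # determinism of the serialised container
  d1 <- tempfile(); d2 <- tempfile()
  write_library(lib, d1); write_library(lib, d2)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  id <- lib$ids[1]
  expect_identical(
    readLines(file.path(d1, "entries", paste0(id, ".json"))),
    readLines(file.path(d2, "entries", paste0(id, ".json"))))
})

test_that("every library entry is recognised first by its own exact contact map", {
  b <- bench_small()
  cfg <- search_config(t = 8)
  for (e in b$library$entries) {
    res <- search_library(exact_contacts(e$contact_map), b$library,
                          query_id = e$id, config = cfg)
    expect_equal(res$results$template_id[1], e$id)
    # self-CMO is the template's own contact count
    n_contacts <- sum(e$contact_map$values[upper.tri(e$contact_map$values)])
    expect_equal(res$results$cmo[1], n_contacts)
  }
})

test_that("an all-zero query map yields a defined, id-tie-broken ranking", {
  b <- bench_small()
  L <- b$library$entries[[1]]$length
  empty <- predicted_contacts(L)
  res <- search_library(empty, b$library, config = search_config(t = 4))
  expect_equal(nrow(res$results), length(b$library))
  expect_true(all(res$results$cmo == 0))
  expect_true(all(is.na(res$results$t_statistic)))
  # unscorable everywhere: ordering falls back to template id
  expect_equal(res$results$template_id, sort(b$library$ids))
})

test_that("ranking is independent of library entry order", {
  b <- bench_small()
  q <- b$queries[[2]]
  cfg <- search_config(t = 6)
  res1 <- search_library(q$contacts, b$library, config = cfg)
  perm <- rev(seq_along(b$library$entries))
  shuffled <- fold_library(b$library$entries[perm], b$library$params)
  res2 <- search_library(q$contacts, shuffled, config = cfg)
  expect_equal(res1$results, res2$results)
})

test_that("search validates query length and library emptiness", {
  b <- bench_small()
  short <- predicted_contacts(10)
  expect_error(search_library(short, b$library), "min_query_len")
  expect_error(search_library(short, fold_library(list())), "empty")
})

test_that("filter_results drops low-coverage hits at the 40% boundary and respects exclusions", {
  b <- bench_small()
  q <- b$queries[[1]]
  res <- search_library(q$contacts, b$library, query_id = q$query_id,
                        config = search_config(t = 6))
  # doctor coverages to probe the boundary: 0.39 dropped, 0.40 kept
  res$results$frac_query_aligned <- 0.40
  res$results$frac_query_aligned[2] <- 0.39
  dropped <- filter_results(res)
  expect_equal(nrow(dropped$results), nrow(res$results) - 1L)
  expect_false(res$results$template_id[2] %in% dropped$results$template_id)
  # family exclusion removes exactly the query's own family
  fam <- filter_results(res, exclude_levels = "family",
                        query_labels = q$labels)
  expect_false(any(fam$results$family == q$labels[["family"]]))
  expect_true(all(sort(unique(fam$results$family)) ==
                    setdiff(sort(unique(res$results$family)),
                            q$labels[["family"]])))
  # family+superfamily exclusion here empties nothing further (1 family per
  # superfamily) but must keep only other superfamilies
  both <- filter_results(res, exclude_levels = c("family", "superfamily"),
                         query_labels = q$labels)
  expect_false(any(both$results$superfamily == q$labels[["superfamily"]]))
  expect_error(filter_results(res, exclude_levels = "fold"), "cannot exclude")
  expect_error(filter_results(res, exclude_levels = "family"), "query_labels")
})

test_that("tpr_at_k counts correct-level hits and prunes unattainable queries", {
  mk <- function(qid, fams) {
    df <- data.frame(template_id = paste0(fams, "_t"), cmo = 0,
                     pearson_r = 0, n_pairs = 10, t_statistic = 0,
                     frac_query_aligned = 1, frac_template_aligned = 1,
                     match_probability = NA_real_,
                     class = "a", fold = fams, superfamily = fams,
                     family = fams, stringsAsFactors = FALSE)
    df$rank <- seq_len(nrow(df))
    structure(list(query_id = qid, results = df, alignments = NULL,
                   params = NULL), class = "ranked_results")
  }
  labels <- data.frame(query_id = c("q1", "q2", "q3", "q4"),
                       class = "a", fold = c("f1", "f2", "f3", "f9"),
                       superfamily = c("f1", "f2", "f3", "f9"),
                       family = c("f1", "f2", "f3", "f9"),
                       stringsAsFactors = FALSE)
  results <- list(mk("q1", c("f1", "f2")),   # hit at rank 1
                  mk("q2", c("f1", "f2")),   # hit at rank 2
                  mk("q3", c("f1", "f2", "f3")),  # hit at rank 3
                  mk("q4", c("f1", "f2")))   # unattainable: f9 absent
  r1 <- tpr_at_k(results, labels, level = "fold", k = 1)
  expect_equal(r1$tpr, 1 / 3)
  expect_equal(r1$n_scored, 3L)
  expect_equal(r1$n_excluded, 1L)
  r2 <- tpr_at_k(results, labels, level = "fold", k = 2)
  expect_equal(r2$tpr, 2 / 3)
  ks <- c(1, 2, 5, 10)
  tprs <- vapply(ks, function(k)
    tpr_at_k(results, labels, level = "fold", k = k)$tpr, numeric(1))
  expect_true(all(diff(tprs) >= 0))   # monotone in k
})

test_that("aligned-backbone models copy template CA coordinates under query numbering", {
  b <- bench_small()
  e <- b$library$entries[[1]]
  n <- e$length
  # identity self-alignment: model equals the template CA trace
  aln <- cm_alignment(cbind(1:n, 1:n), n, n)
  path <- tempfile(fileext = ".pdb")
  write_aligned_model(e$sequence, e, aln, path)
  back <- read_structure(path)
  expect_equal(back$ca, e$coords$ca, tolerance = 1e-3)  # PDB has 3 decimals
  expect_equal(paste(back$aa, collapse = ""), e$sequence)
  # partial alignment: one ATOM record per aligned pair, query numbering kept
  sub <- cm_alignment(cbind(seq(2, 20, by = 2), seq(3, 21, by = 2)), n, n)
  write_aligned_model(e$sequence, e, sub, path)
  lines <- readLines(path)
  expect_equal(sum(grepl("^ATOM", lines)), 10L)
  back2 <- read_structure(path)
  expect_equal(back2$resno, seq(2, 20, by = 2))
  expect_equal(back2$ca, e$coords$ca[seq(3, 21, by = 2), ], tolerance = 1e-3)
  # template without retained coordinates is an error
  no_coords <- e; no_coords$coords <- NULL
  expect_error(write_aligned_model(e$sequence, no_coords, aln, path),
               "coordinates unavailable")
})

test_that("search runtime grows roughly linearly with library size", {
  b <- make_benchmark(6, 2, seed = 9)
  q <- b$queries[[1]]
  cfg <- search_config(t = 6)
  half <- fold_library(b$library$entries[1:6], b$library$params)
  full <- fold_library(b$library$entries, b$library$params)
  t_half <- system.time(search_library(q$contacts, half, config = cfg))[["elapsed"]]
  t_full <- system.time(search_library(q$contacts, full, config = cfg))[["elapsed"]]
  # doubling the library should cost clearly less than ~2.5x (loose bound;
  # avoids flakiness from timer resolution on very fast runs)
  expect_lt(t_full, 2.5 * max(t_half, 0.05))
})
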