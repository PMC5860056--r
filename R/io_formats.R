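## File-format readers/writers: PDB structures, CASP-RR contact lists,
## PSIPRED ss2, FASTA, and the versioned fold-library container.

#' Chain coordinates
#'
#' Ordered CA (and, where present, CB) coordinates of one protein chain.
#'
#' @param chain_id chain identifier.
#' @param resno integer vector of residue numbers (strictly increasing order
#'   is not required of the source; order of appearance is kept).
#' @param aa character vector of 1-letter amino-acid codes (`X` for
#'   nonstandard residues).
#' @param ca numeric n x 3 matrix of CA coordinates in Angstrom.
#' @param cb numeric n x 3 matrix of CB coordinates; rows of `NA` where the
#'   residue (e.g. glycine) has no CB.
#' @return An object of class `chain_coords`.
#' @export
chain_coords <- function(chain_id, resno, aa, ca, cb = NULL) {
  n <- length(resno)
  stopifnot(n >= 1, length(aa) == n, nrow(ca) == n, ncol(ca) == 3)
  if (is.null(cb)) cb <- matrix(NA_real_, n, 3)
  stopifnot(nrow(cb) == n, ncol(cb) == 3)
  if (any(!is.finite(ca))) stop("every residue must have a finite CA coordinate")
  structure(
    list(chain_id = chain_id, resno = as.integer(resno), aa = as.character(aa),
         ca = unname(as.matrix(ca)), cb = unname(as.matrix(cb))),
    class = "chain_coords")
}

#' @export
length.chain_coords <- function(x) length(x$resno)

#' @export
print.chain_coords <- function(x, ...) {
  cat(sprintf("<chain_coords> chain %s, %d residues, %d with CB\n",
              x$chain_id, length(x), sum(is.finite(x$cb[, 1]))))
  invisible(x)
}

# 3-to-1 letter mapping for the 20 standard amino acids only.
.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V")

#' Read one chain of a PDB file as CA/CB coordinates
#'
#' Reads `ATOM` records of a single chain (first model only). Waters and
#' HETATM records are ignored; for alternate locations and insertion-code
#' duplicates the first occurrence wins; residues lacking a CA atom are
#' dropped with a warning and the remaining positions are renumbered
#' contiguously downstream (a contact map needs one coordinate per position).
#' The 20 standard amino acids map to their 1-letter codes, any other
#' polymer residue maps to `X` but keeps its coordinates.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier, or `"first"` (default) for the first chain
#'   encountered.
#' @return A [chain_coords()] object.
#' @export
read_structure <- function(path, chain = "first") {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("unparseable PDB ", path, ": ",
                                           conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")), ,
           drop = FALSE]
  if (nrow(at) == 0L) stop("no standard ATOM records in ", path)
  if (identical(chain, "first")) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("chain '", chain, "' not found in ", path)

  # residue key in order of appearance; insert codes make duplicates distinct,
  # the first occurrence of a duplicated (resno, insert) pair wins
  ins <- ifelse(is.na(at$insert), "", at$insert)
  key <- paste(at$resno, ins, sep = "_")
  keys <- unique(key)
  pick_atom <- function(k, elety) {
    rows <- which(key == k & at$elety == elety)
    if (length(rows) == 0L) return(NULL)
    at[rows[1L], ] # first occurrence wins (covers altloc duplicates)
  }
  resno <- integer(0); aa <- character(0)
  ca <- NULL; cb <- NULL; dropped <- 0L
  for (k in keys) {
    ca_at <- pick_atom(k, "CA")
    if (is.null(ca_at)) { dropped <- dropped + 1L; next }
    cb_at <- pick_atom(k, "CB")
    resno <- c(resno, ca_at$resno)
    aa1 <- .aa3to1[ca_at$resid]
    aa <- c(aa, ifelse(is.na(aa1), "X", aa1))
    ca <- rbind(ca, c(ca_at$x, ca_at$y, ca_at$z))
    cb <- rbind(cb, if (is.null(cb_at)) c(NA_real_, NA_real_, NA_real_)
                else c(cb_at$x, cb_at$y, cb_at$z))
  }
  if (length(resno) == 0L) stop("chain '", chain, "' has no residue with a CA atom")
  if (dropped > 0L)
    warning(sprintf("%d residue(s) without CA dropped from %s chain %s",
                    dropped, basename(path), chain))
  chain_coords(chain, resno, aa, ca, cb)
}

#' Write a CA-only PDB file
#'
#' Emits one `ATOM` record per residue using the CA coordinate; used for the
#' synthetic fixtures and for aligned-backbone models.
#'
#' @param coords a [chain_coords()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(coords, path) {
  stopifnot(inherits(coords, "chain_coords"))
  aa3 <- names(.aa3to1)[match(coords$aa, .aa3to1)]
  aa3[is.na(aa3)] <- "UNK"
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_along(coords$resno), aa3, coords$chain_id, coords$resno,
    coords$ca[, 1], coords$ca[, 2], coords$ca[, 3])
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Predicted contact list
#'
#' A list of residue-index pairs with contact probabilities, as produced by
#' sequence-based contact predictors (CASP-RR style). Records are normalised
#' to `i < j`, duplicates collapsed keeping the maximum probability.
#'
#' @param length query sequence length L.
#' @param i,j 1-based residue indices.
#' @param prob contact probabilities in \[0, 1\].
#' @return An object of class `predicted_contacts`: list with elements
#'   `length` and `records` (data.frame `i`, `j`, `prob` sorted by `(i, j)`).
#' @export
predicted_contacts <- function(length, i = integer(0), j = integer(0),
                               prob = numeric(0)) {
  stopifnot(length >= 1, base::length(i) == base::length(j),
            base::length(i) == base::length(prob))
  i <- as.integer(i); j <- as.integer(j); prob <- as.numeric(prob)
  if (any(i == j)) stop("self-contact records (i == j) are not allowed")
  if (any(i < 1L | j < 1L | i > length | j > length))
    stop("contact index out of range 1..", length)
  if (any(!is.finite(prob) | prob < 0 | prob > 1))
    stop("probabilities must lie in [0, 1]")
  ii <- pmin(i, j); jj <- pmax(i, j)
  if (base::length(ii)) {
    d <- data.frame(i = ii, j = jj, prob = prob)
    d <- d[order(d$i, d$j, -d$prob), , drop = FALSE]
    d <- d[!duplicated(d[c("i", "j")]), , drop = FALSE]  # keep max prob
    rownames(d) <- NULL
  } else {
    d <- data.frame(i = integer(0), j = integer(0), prob = numeric(0))
  }
  structure(list(length = as.integer(length), records = d),
            class = "predicted_contacts")
}

#' @export
print.predicted_contacts <- function(x, ...) {
  cat(sprintf("<predicted_contacts> L = %d, %d records\n",
              x$length, nrow(x$records)))
  invisible(x)
}

#' Read a CASP-RR style predicted contact file
#'
#' Accepts the usual loose RR layout: optional header/footer lines
#' (`PFRMAT`, `TARGET`, `MODEL`, `END`, a plain sequence line, comments) and
#' data lines whose first, second and last whitespace-separated fields are
#' `i`, `j` and the probability (distance-bound columns in between are
#' ignored).
#'
#' @param path path to the contact file.
#' @param length query sequence length; indices beyond it are an error.
#' @return A [predicted_contacts()] object.
#' @export
read_predicted_contacts <- function(path, length) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  keep_i <- integer(0); keep_j <- integer(0); keep_p <- numeric(0)
  for (ln in lines) {
    if (grepl("^(PFRMAT|TARGET|AUTHOR|METHOD|MODEL|REMARK|END|#)", ln)) next
    if (grepl("^[A-Za-z]+$", ln)) next  # bare sequence line
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    if (base::length(f) < 3L) stop("malformed contact line: '", ln, "'")
    i <- suppressWarnings(as.integer(f[1]))
    j <- suppressWarnings(as.integer(f[2]))
    p <- suppressWarnings(as.numeric(f[base::length(f)]))
    if (is.na(i) || is.na(j) || is.na(p))
      stop("malformed contact line: '", ln, "'")
    keep_i <- c(keep_i, i); keep_j <- c(keep_j, j); keep_p <- c(keep_p, p)
  }
  predicted_contacts(length, keep_i, keep_j, keep_p)
}

#' Write a CASP-RR style contact file
#'
#' @param contacts a [predicted_contacts()] object.
#' @param path output path.
#' @param target optional target identifier written in the header.
#' @return `path`, invisibly.
#' @export
write_predicted_contacts <- function(contacts, path, target = "query") {
  stopifnot(inherits(contacts, "predicted_contacts"))
  r <- contacts$records
  writeLines(c("PFRMAT RR", paste("TARGET", target),
               sprintf("%d %d 0 8 %.6f", r$i, r$j, r$prob), "END"), path)
  invisible(path)
}

#' Secondary structure string
#'
#' @param states character scalar over the 3-state alphabet `H` (helix),
#'   `E` (strand), `C` (coil), one letter per residue.
#' @param conf optional numeric vector of per-residue confidences in \[0, 1\].
#' @return An object of class `ss_string`.
#' @export
ss_string <- function(states, conf = NULL) {
  stopifnot(is.character(states), length(states) == 1L)
  chars <- strsplit(states, "")[[1]]
  if (length(chars) == 0L) stop("empty secondary-structure string")
  if (!all(chars %in% c("H", "E", "C")))
    stop("secondary-structure states must be H, E or C")
  if (!is.null(conf)) {
    stopifnot(length(conf) == length(chars), all(conf >= 0 & conf <= 1))
  }
  structure(list(states = states, conf = conf), class = "ss_string")
}

#' @export
length.ss_string <- function(x) nchar(x$states)

#' Read a PSIPRED ss2 file
#'
#' Standard vertical-format PSIPRED output: comment/blank header, then rows
#' `index residue state conf_C conf_H conf_E`. PSIPRED's coil letter `C` is
#' kept; the per-residue confidence is the maximum of the three state
#' probabilities.
#'
#' @param path path to the ss2 file.
#' @return An [ss_string()] object.
#' @export
read_ss2 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty ss2 file: ", path)
  states <- character(length(lines)); conf <- numeric(length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "[[:space:]]+")[[1]]
    if (length(f) < 6L) stop("malformed ss2 row: '", lines[k], "'")
    idx <- suppressWarnings(as.integer(f[1]))
    if (is.na(idx) || idx != k) stop("inconsistent ss2 index at row ", k)
    st <- f[3]
    if (!st %in% c("H", "E", "C")) stop("invalid ss2 state '", st, "'")
    p <- suppressWarnings(as.numeric(f[4:6]))
    if (any(is.na(p))) stop("malformed ss2 confidences at row ", k)
    states[k] <- st
    conf[k] <- max(p)
  }
  ss_string(paste(states, collapse = ""), conf = pmin(conf, 1))
}

#' Read a single sequence from a FASTA file
#'
#' @param path path to a FASTA file; the first sequence is returned.
#' @return A list with `id` and `seq` (uppercase character scalar).
#' @export
read_fasta_seq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA header in ", path)
  from <- hdr[1] + 1L
  to <- if (length(hdr) > 1L) hdr[2] - 1L else length(lines)
  seq <- toupper(gsub("[[:space:]]", "", paste(lines[from:to], collapse = "")))
  if (!nzchar(seq)) stop("empty sequence in ", path)
  list(id = sub("^>\\s*(\\S+).*$", "\\1", lines[hdr[1]]), seq = seq)
}

## ---------------------------------------------------------------------------
## Fold-library container: a directory holding a versioned manifest plus one
## JSON file per template, so entries can be iterated without loading all.

.library_format_version <- "1"

.entry_to_json_list <- function(e) {
  cm <- e$contact_map
  ut <- which(upper.tri(cm$values) & cm$values != 0, arr.ind = TRUE)
  list(
    id = e$id, length = e$length, sequence = e$sequence,
    ss = if (is.null(e$ss)) NULL else e$ss$states,
    labels = if (is.null(e$labels)) NULL else as.list(e$labels),
    threshold = cm$threshold, min_separation = cm$min_separation,
    contact_i = as.integer(ut[, 1]), contact_j = as.integer(ut[, 2]),
    distances = as.numeric(cm$distances),
    eigenvalues = e$basis$values,
    scaled_vectors = as.numeric(e$basis$scaled_vectors),
    order_t = e$basis$order_t)
}

.entry_from_json_list <- function(x) {
  n <- x$length
  vals <- matrix(0, n, n)
  if (length(x$contact_i)) {
    idx <- cbind(x$contact_i, x$contact_j)
    vals[idx] <- 1
    vals[idx[, c(2, 1), drop = FALSE]] <- 1
  }
  dm <- matrix(x$distances, n, n)
  cm <- contact_map(vals, kind = "observed-binary", distances = dm,
                    threshold = x$threshold, min_separation = x$min_separation)
  basis <- eigen_basis(
    size = n, order_t = x$order_t, values = x$eigenvalues,
    scaled_vectors = matrix(x$scaled_vectors, n, x$order_t))
  template_entry(
    id = x$id, sequence = x$sequence,
    ss = if (is.null(x$ss)) NULL else ss_string(x$ss),
    contact_map = cm, basis = basis,
    labels = if (is.null(x$labels)) NULL else unlist(x$labels))
}

#' Write a fold library to disk
#'
#' The container is a directory with a versioned `manifest.json` (format
#' version, construction parameters, entry index) and one JSON file per
#' template under `entries/`, so that a library can be iterated without
#' loading every entry. Contacts are stored as sparse index pairs; the full
#' inter-residue distance matrix and the precomputed scaled eigenvectors are
#' stored so that searching never re-decomposes a template map.
#'
#' @param library a `fold_library` object (see [build_library()]).
#' @param path directory to create (must not already contain a manifest
#'   unless `overwrite = TRUE`).
#' @param overwrite replace an existing library at `path`.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path, overwrite = FALSE) {
  stopifnot(inherits(library, "fold_library"))
  manifest_path <- file.path(path, "manifest.json")
  if (file.exists(manifest_path) && !overwrite)
    stop("library already exists at ", path, " (use overwrite = TRUE)")
  dir.create(file.path(path, "entries"), recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(library$entries, `[[`, "", "id")
  files <- paste0("entries/", ids, ".json")
  for (k in seq_along(library$entries)) {
    jsonlite::write_json(.entry_to_json_list(library$entries[[k]]),
                         file.path(path, files[k]),
                         auto_unbox = TRUE, digits = I(17), null = "null")
  }
  manifest <- list(format = "cmthread-fold-library",
                   version = .library_format_version,
                   params = library$params,
                   n_entries = length(ids), ids = ids, files = files)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a fold library from disk
#'
#' @param path library directory written by [write_library()].
#' @param ids optional subset of entry ids to load.
#' @return A `fold_library` object.
#' @export
read_library <- function(path, ids = NULL) {
  manifest_path <- file.path(path, "manifest.json")
  if (!file.exists(manifest_path)) stop("no library manifest at ", path)
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (!identical(m$format, "cmthread-fold-library"))
    stop("not a fold library: ", path)
  if (!identical(as.character(m$version), .library_format_version))
    stop("unsupported library format version '", m$version, "' (expected ",
         .library_format_version, ")")
  want <- if (is.null(ids)) m$ids else ids
  if (!all(want %in% m$ids)) stop("entry id(s) not in library index")
  files <- m$files[match(want, m$ids)]
  entries <- lapply(files, function(f) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) stop("library entry file missing: ", f)
    .entry_from_json_list(jsonlite::read_json(fp, simplifyVector = TRUE))
  })
  fold_library(entries, params = m$params)
}
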