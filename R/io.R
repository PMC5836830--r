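# Data model and TSV input/output.
#
# All exchange formats are tab-separated UTF-8 text; lines starting
# with "#" are comments.  Protein identifiers are opaque case-sensitive
# strings (no ORF/systematic-name mapping is attempted) and must not
# contain tab characters.

# canonical unordered-pair key; also used as edge identity
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\t")
}

pair_id <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Construct a weighted protein-protein interaction network
#'
#' An undirected graph with strictly positive edge weights.  Edges are
#' stored with endpoints in lexicographic order, so `weight(i, j) ==
#' weight(j, i)` by construction.  Self-edges are rejected.
#'
#' @param edges data.frame with columns `a`, `b` (protein identifiers)
#'   and `weight` (positive numeric).  Duplicate edges are collapsed to
#'   the maximum weight with a warning.
#' @param extra_proteins optional character vector of isolated proteins
#'   to include in the vertex set.
#' @return an object of class `ppi_network` with elements `proteins`
#'   (sorted character vector) and `edges` (data.frame `a`, `b`,
#'   `weight`; `a < b`).
#' @export
ppi_network <- function(edges, extra_proteins = character()) {
  stopifnot(is.data.frame(edges), all(c("a", "b", "weight") %in% names(edges)))
  a <- as.character(edges$a)
  b <- as.character(edges$b)
  w <- as.numeric(edges$weight)
  if (any(!is.finite(w)) || any(w <= 0)) {
    pk_validation_error("edge weights must be finite and strictly positive")
  }
  self <- a == b
  if (any(self)) {
    warning(sprintf("dropping %d self-edge(s)", sum(self)))
    a <- a[!self]; b <- b[!self]; w <- w[!self]
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\t")
  if (anyDuplicated(key)) {
    warning(sprintf("collapsing %d duplicate edge(s) to the maximum weight",
                    sum(duplicated(key))))
    w <- as.numeric(tapply(w, key, max)[unique(key)])
    keep <- !duplicated(key)
    lo <- lo[keep]; hi <- hi[keep]
  }
  edges <- data.frame(a = lo, b = hi, weight = w, stringsAsFactors = FALSE)
  proteins <- sort(unique(c(lo, hi, as.character(extra_proteins))))
  structure(list(proteins = proteins, edges = edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d proteins, %d weighted edges\n",
              length(x$proteins), nrow(x$edges)))
  invisible(x)
}

n_edges <- function(net) nrow(net$edges)

#' Test whether a pair of proteins is an edge of the network
#' @param net a [ppi_network()]
#' @param a,b protein identifiers (vectorized)
#' @return logical vector
#' @export
has_edge <- function(net, a, b) {
  pair_key(a, b) %in% pair_key(net$edges$a, net$edges$b)
}

#' Edge weight lookup
#' @inheritParams has_edge
#' @return numeric vector; `NA` for non-edges
#' @export
edge_weight <- function(net, a, b) {
  m <- match(pair_key(a, b), pair_key(net$edges$a, net$edges$b))
  net$edges$weight[m]
}

# named list protein -> list(nbr = character, w = numeric)
adjacency_list <- function(net) {
  e <- net$edges
  ends <- c(e$a, e$b)
  other <- c(e$b, e$a)
  w <- c(e$weight, e$weight)
  split_idx <- split(seq_along(ends), ends)
  adj <- lapply(split_idx, function(ix) list(nbr = other[ix], w = w[ix]))
  # isolated proteins get empty neighborhoods
  missing <- setdiff(net$proteins, names(adj))
  adj[missing] <- list(list(nbr = character(), w = numeric()))
  adj
}

split_fields <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 2L) f <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  f
}

read_tsv_lines <- function(path) {
  if (!file.exists(path)) pk_validation_error("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a weighted PPI edge list
#'
#' The `generic-3col` dialect expects `protein_a TAB protein_b TAB
#' weight`.  The `wi-phi` dialect tolerates a header line and extra
#' per-source score columns: the first two fields are protein names and
#' the *last* numeric field is the weight.  In both dialects duplicate
#' edges keep the maximum weight and self-edges are dropped, each with
#' a warning.
#'
#' @param path file path
#' @param dialect `"generic-3col"` or `"wi-phi"`
#' @return a [ppi_network()]
#' @export
read_weighted_ppi <- function(path, dialect = c("generic-3col", "wi-phi")) {
  dialect <- match.arg(dialect)
  src <- read_tsv_lines(path)
  lines <- src$lines
  lineno <- src$lineno
  if (length(lines) == 0L) {
    return(ppi_network(data.frame(a = character(), b = character(),
                                  weight = numeric())))
  }
  fields <- lapply(lines, split_fields)
  if (dialect == "wi-phi") {
    # header detection: first line whose last field is non-numeric
    f1 <- fields[[1L]]
    if (length(f1) >= 3L &&
        is.na(suppressWarnings(as.numeric(f1[length(f1)])))) {
      fields <- fields[-1L]
      lineno <- lineno[-1L]
      lines <- lines[-1L]
    }
  }
  n <- length(fields)
  a <- character(n); b <- character(n); w <- numeric(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 3L) {
      pk_parse_error("line %d: expected at least 3 fields, got %d",
                     lineno[i], length(f))
    }
    a[i] <- f[1L]; b[i] <- f[2L]
    wf <- if (dialect == "wi-phi") {
      num <- suppressWarnings(as.numeric(f[-(1:2)]))
      if (all(is.na(num))) NA_real_ else num[max(which(!is.na(num)))]
    } else {
      suppressWarnings(as.numeric(f[3L]))
    }
    if (is.na(wf)) pk_parse_error("line %d: weight does not parse as a number",
                                  lineno[i])
    if (wf <= 0) pk_validation_error("line %d: nonpositive weight %g",
                                     lineno[i], wf)
    w[i] <- wf
  }
  ppi_network(data.frame(a = a, b = b, weight = w, stringsAsFactors = FALSE))
}

#' Write a network in the generic 3-column format
#' @param net a [ppi_network()]
#' @param path output file path
#' @export
write_weighted_ppi <- function(net, path) {
  # %.17g keeps the weight bit-exact through a write/read cycle
  writeLines(sprintf("%s\t%s\t%.17g", net$edges$a, net$edges$b,
                     net$edges$weight), path)
  invisible(path)
}

#' Construct a complex catalog
#'
#' @param complexes named list; each element a character vector of
#'   member proteins (deduplicated; at least two distinct members).
#' @return object of class `complex_catalog`
#' @export
complex_catalog <- function(complexes) {
  stopifnot(is.list(complexes))
  complexes <- lapply(complexes, function(m) unique(as.character(m)))
  small <- names(complexes)[vapply(complexes, length, 1L) < 2L]
  if (length(small)) {
    pk_validation_error("complex(es) with fewer than 2 distinct members: %s",
                        paste(small, collapse = ", "))
  }
  structure(list(complexes = complexes), class = "complex_catalog")
}

#' @export
print.complex_catalog <- function(x, ...) {
  sizes <- vapply(x$complexes, length, 1L)
  cat(sprintf("complex_catalog: %d complexes (%d heterodimers)\n",
              length(sizes), sum(sizes == 2L)))
  invisible(x)
}

#' Read a complex membership catalog
#'
#' Two-column rows `complex_id TAB protein`, one row per membership.
#' Memberships are grouped by complex and deduplicated; complexes with
#' fewer than two distinct members are rejected.
#'
#' @param path file path
#' @return a [complex_catalog()]
#' @export
read_complex_catalog <- function(path) {
  src <- read_tsv_lines(path)
  if (length(src$lines) == 0L) {
    return(structure(list(complexes = list()), class = "complex_catalog"))
  }
  fields <- lapply(src$lines, split_fields)
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad)) {
    pk_parse_error("line %d: expected 2 fields (complex_id, protein)",
                   src$lineno[bad[1L]])
  }
  cid <- vapply(fields, `[`, "", 1L)
  member <- vapply(fields, `[`, "", 2L)
  complex_catalog(split(member, factor(cid, levels = unique(cid))))
}

#' Write a catalog as two-column membership rows
#' @param catalog a [complex_catalog()]
#' @param path output file path
#' @export
write_complex_catalog <- function(catalog, path) {
  cid <- rep(names(catalog$complexes),
             vapply(catalog$complexes, length, 1L))
  member <- unlist(catalog$complexes, use.names = FALSE)
  write.table(data.frame(cid, member), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a per-protein profile table
#'
#' Holds the protein-level feature vectors consumed by the kernels:
#' either domain multiplicity counts (`kind = "domain-count"`) or 0/1
#' presence profiles across genomes or subcellular compartments
#' (`kind = "binary-profile"`).
#'
#' @param mat numeric matrix, proteins in rows (rownames required),
#'   feature columns labelled by colnames.
#' @param kind `"domain-count"` or `"binary-profile"`
#' @return object of class `profile_table`
#' @export
profile_table <- function(mat, kind = c("domain-count", "binary-profile")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  if (any(!is.finite(mat)) || any(mat < 0)) {
    pk_validation_error("profile entries must be finite and nonnegative")
  }
  if (any(mat != round(mat))) {
    pk_validation_error("profile entries must be integers")
  }
  if (kind == "binary-profile" && any(mat > 1)) {
    pk_validation_error("binary profile entries must be 0 or 1")
  }
  structure(list(kind = kind, mat = mat), class = "profile_table")
}

#' @export
print.profile_table <- function(x, ...) {
  cat(sprintf("profile_table (%s): %d proteins x %d columns\n",
              x$kind, nrow(x$mat), ncol(x$mat)))
  invisible(x)
}

#' Read a per-protein profile table
#'
#' For `kind = "domain-count"` the file holds `protein TAB domain`
#' rows; multiplicity is encoded by repetition and the column order is
#' the file's first-seen domain order.  For `kind = "binary-profile"`
#' the file starts with a header `protein TAB label1 ... labelm`
#' followed by `protein TAB 0/1 ...` rows; header order is preserved.
#'
#' @param path file path
#' @param kind `"domain-count"` or `"binary-profile"`
#' @return a [profile_table()]
#' @export
read_profile_table <- function(path, kind = c("domain-count", "binary-profile")) {
  kind <- match.arg(kind)
  src <- read_tsv_lines(path)
  fields <- lapply(src$lines, split_fields)
  if (kind == "domain-count") {
    bad <- which(vapply(fields, length, 1L) < 2L)
    if (length(bad)) {
      pk_parse_error("line %d: expected 2 fields (protein, domain)",
                     src$lineno[bad[1L]])
    }
    protein <- vapply(fields, `[`, "", 1L)
    domain <- vapply(fields, `[`, "", 2L)
    prot_lvls <- unique(protein)
    dom_lvls <- unique(domain)
    mat <- matrix(0, length(prot_lvls), length(dom_lvls),
                  dimnames = list(prot_lvls, dom_lvls))
    if (length(protein)) {
      tab <- table(factor(protein, prot_lvls), factor(domain, dom_lvls))
      mat[] <- as.numeric(tab)
    }
    return(profile_table(mat, "domain-count"))
  }
  if (length(fields) == 0L) pk_parse_error("binary profile file is empty")
  header <- fields[[1L]]
  labels <- header[-1L]
  rows <- fields[-1L]
  lineno <- src$lineno[-1L]
  mat <- matrix(0, length(rows), length(labels),
                dimnames = list(NULL, labels))
  prot <- character(length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) != length(labels) + 1L) {
      pk_parse_error("line %d: expected %d fields, got %d",
                     lineno[i], length(labels) + 1L, length(f))
    }
    prot[i] <- f[1L]
    v <- suppressWarnings(as.numeric(f[-1L]))
    if (any(is.na(v)) || !all(v %in% c(0, 1))) {
      pk_validation_error("line %d: binary profile entries must be 0 or 1",
                          lineno[i])
    }
    mat[i, ] <- v
  }
  rownames(mat) <- prot
  profile_table(mat, "binary-profile")
}

#' Write a profile table
#'
#' Domain-count tables are written as `protein TAB domain` rows with
#' multiplicity encoded by repetition (proteins with all-zero vectors
#' emit no rows); binary profiles are written as a header matrix.
#'
#' @param table a [profile_table()]
#' @param path output file path
#' @export
write_profile_table <- function(table, path) {
  mat <- table$mat
  if (table$kind == "domain-count") {
    prot <- rep(rownames(mat), times = rowSums(mat))
    dom <- unlist(lapply(seq_len(nrow(mat)), function(i) {
      rep(colnames(mat), times = mat[i, ])
    }), use.names = FALSE)
    write.table(data.frame(prot, dom), path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    header <- paste(c("protein", colnames(mat)), collapse = "\t")
    body <- vapply(seq_len(nrow(mat)), function(i) {
      paste(c(rownames(mat)[i], format(mat[i, ], trim = TRUE)),
            collapse = "\t")
    }, "")
    writeLines(c(header, body), path)
  }
  invisible(path)
}

#' Construct a labeled set of protein pairs
#'
#' @param a,b character vectors of protein identifiers (pair endpoints;
#'   stored with `a < b`)
#' @param label integer vector of +1 / -1 labels
#' @return object of class `pair_set`: data.frame columns `a`, `b`,
#'   `label`
#' @export
pair_set <- function(a, b, label) {
  a <- as.character(a); b <- as.character(b)
  label <- as.integer(label)
  stopifnot(length(a) == length(b), length(a) == length(label))
  if (!all(label %in% c(-1L, 1L))) {
    pk_validation_error("labels must be -1 or +1")
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  if (anyDuplicated(paste(lo, hi, sep = "\t"))) {
    pk_validation_error("duplicate pairs in pair set")
  }
  structure(data.frame(a = lo, b = hi, label = label,
                       stringsAsFactors = FALSE),
            class = c("pair_set", "data.frame"))
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("pair_set: %d pairs (%d positive, %d negative)\n",
              nrow(x), sum(x$label == 1L), sum(x$label == -1L)))
  invisible(x)
}

#' Build labeled training examples from a network and a catalog
#'
#' A pair is a *positive* example when it is a network edge and equals
#' the member set of some size-2 complex (a catalogued heterodimer).
#' A pair is a *negative* example when it is a network edge, is not a
#' catalogued heterodimer, and both proteins co-occur in at least one
#' complex of size three or more.  All other edges are unlabeled and
#' excluded.
#'
#' @param network a [ppi_network()]
#' @param catalog a [complex_catalog()]
#' @return a [pair_set()] (possibly empty)
#' @export
build_examples <- function(network, catalog) {
  e <- network$edges
  sizes <- vapply(catalog$complexes, length, 1L)
  hetero <- catalog$complexes[sizes == 2L]
  hetero_keys <- unique(vapply(hetero, function(m) pair_key(m[1L], m[2L]), ""))
  large <- catalog$complexes[sizes >= 3L]
  comember_keys <- unique(unlist(lapply(large, function(m) {
    idx <- utils::combn(sort(m), 2L)
    pair_key(idx[1L, ], idx[2L, ])
  }), use.names = FALSE))
  key <- pair_key(e$a, e$b)
  pos <- key %in% hetero_keys
  neg <- !pos & key %in% comember_keys
  keep <- pos | neg
  pair_set(e$a[keep], e$b[keep], ifelse(pos[keep], 1L, -1L))
}

#' Read a labeled pair set (`a TAB b TAB label`)
#' @param path file path
#' @return a [pair_set()]
#' @export
read_pair_set <- function(path) {
  src <- read_tsv_lines(path)
  if (length(src$lines) == 0L) {
    return(pair_set(character(), character(), integer()))
  }
  fields <- lapply(src$lines, split_fields)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad)) {
    pk_parse_error("line %d: expected 3 fields (a, b, label)",
                   src$lineno[bad[1L]])
  }
  lab <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  if (any(is.na(lab))) pk_parse_error("non-integer label in pair set file")
  pair_set(vapply(fields, `[`, "", 1L), vapply(fields, `[`, "", 2L), lab)
}

#' Write a labeled pair set (`a TAB b TAB label`)
#' @param pairs a [pair_set()]
#' @param path output file path
#' @export
write_pair_set <- function(pairs, path) {
  write.table(as.data.frame(pairs), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
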