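# Feature maps: the 7-dimensional network/domain pair vector psi and
# per-protein profile vectors phi.

# max/min over possibly-empty sets; the empty-set convention is 0 so
# that psi stays total on degree-1 endpoints and common-neighbor-free
# pairs (weights are strictly positive, so 0 is an identifiable
# sentinel rather than an attainable weight).
max0 <- function(x) if (length(x)) max(x) else 0
min0 <- function(x) if (length(x)) min(x) else 0

psi_names <- c("w_ij", "nbr_w_max", "nbr_w_min", "common_nbr_minmax",
               "cross_nbr_absdiff_max", "n_dom_max", "n_dom_min")

psi_one <- function(adj, counts, wij, i, j) {
  ni <- adj[[i]]
  nj <- adj[[j]]
  keep_i <- ni$nbr != j
  keep_j <- nj$nbr != i
  wi <- ni$w[keep_i]
  wj <- nj$w[keep_j]
  f2 <- max(max0(wi), max0(wj))
  f3 <- min(min0(wi), min0(wj))
  common <- intersect(ni$nbr, nj$nbr)
  f4 <- if (length(common)) {
    max(pmin(ni$w[match(common, ni$nbr)], nj$w[match(common, nj$nbr)]))
  } else 0
  # max |w_ik1 - w_jk2| over the cross product is attained at the
  # extremes of either neighborhood
  f5 <- if (length(wi) && length(wj)) {
    max(max(wi) - min(wj), max(wj) - min(wi))
  } else 0
  di <- if (i %in% names(counts)) counts[[i]] else 0
  dj <- if (j %in% names(counts)) counts[[j]] else 0
  c(wij, f2, f3, f4, f5, max(di, dj), min(di, dj))
}

#' Network/domain feature vector for one protein pair
#'
#' Computes the seven pair features used alongside the pairwise
#' kernels: (1) the edge weight w_ij; (2) the maximum and (3) minimum
#' weight among edges incident to either endpoint, excluding the pair
#' edge itself; (4) the strongest common neighbor, i.e. the maximum
#' over shared neighbors k of min(w_ik, w_jk); (5) the largest
#' absolute difference |w_ik1 - w_jk2| over the two neighborhoods;
#' (6) the larger and (7) smaller total domain count of the two
#' proteins.  Every max/min over an empty index set is 0.
#'
#' The rationale is that the edge inside a heterodimer tends to be
#' heavier than the edges around it, so the pair weight together with
#' its neighborhood summary is discriminative.
#'
#' @param network a [ppi_network()]
#' @param domain_table a [profile_table()] of kind `"domain-count"`
#'   (a protein absent from the table has domain count 0)
#' @param a,b the pair; must be an edge of `network`
#' @return named numeric vector of length 7
#' @export
psi <- function(network, domain_table, a, b) {
  w <- edge_weight(network, a, b)
  if (is.na(w)) {
    pk_validation_error("pair (%s, %s) is not an edge of the network", a, b)
  }
  adj <- adjacency_list(network)
  counts <- rowSums(domain_table$mat)
  out <- psi_one(adj, counts, w, a, b)
  names(out) <- psi_names
  out
}

#' Feature matrix for a list of pairs
#'
#' @param network a [ppi_network()]
#' @param domain_table a [profile_table()] of kind `"domain-count"`
#' @param pairs a [pair_set()] or data.frame with columns `a`, `b`
#' @return numeric matrix, one row per pair (rownames `"a|b"`),
#'   columns the seven psi features
#' @export
psi_matrix <- function(network, domain_table, pairs) {
  w <- edge_weight(network, pairs$a, pairs$b)
  if (anyNA(w)) {
    bad <- which(is.na(w))[1L]
    pk_validation_error("pair (%s, %s) is not an edge of the network",
                        pairs$a[bad], pairs$b[bad])
  }
  adj <- adjacency_list(network)
  counts <- rowSums(domain_table$mat)
  out <- matrix(0, nrow(pairs), 7L,
                dimnames = list(pair_id(pairs$a, pairs$b), psi_names))
  for (r in seq_len(nrow(pairs))) {
    out[r, ] <- psi_one(adj, counts, w[r], pairs$a[r], pairs$b[r])
  }
  out
}

#' Per-protein profile vector lookup
#'
#' Exact lookup with no normalization; a protein absent from the table
#' maps to the zero vector.
#'
#' @param table a [profile_table()]
#' @param protein protein identifier
#' @return named numeric vector over the table's columns
#' @export
phi <- function(table, protein) {
  if (protein %in% rownames(table$mat)) {
    table$mat[protein, ]
  } else {
    stats::setNames(numeric(ncol(table$mat)), colnames(table$mat))
  }
}

# matrix of phi vectors for a protein list; absent proteins -> zero rows
phi_matrix <- function(table, proteins) {
  out <- matrix(0, length(proteins), ncol(table$mat),
                dimnames = list(proteins, colnames(table$mat)))
  hit <- proteins %in% rownames(table$mat)
  out[hit, ] <- table$mat[proteins[hit], , drop = FALSE]
  out
}

#' Export a psi feature matrix as TSV for inspection
#' @param features matrix from [psi_matrix()]
#' @param path output file path
#' @export
write_features <- function(features, path) {
  df <- data.frame(pair = rownames(features), features,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# optional per-feature min-max scaling, fit on training rows only
psi_scale_fit <- function(train_features) {
  list(min = apply(train_features, 2L, min),
       max = apply(train_features, 2L, max))
}

psi_scale_apply <- function(features, fit) {
  rng <- fit$max - fit$min
  rng[rng == 0] <- 1     # constant features map to 0
  scaled <- sweep(features, 2L, fit$min, "-")
  sweep(scaled, 2L, rng, "/")
}
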