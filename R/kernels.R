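# Protein-level kernels (Min, MinMax, scale-normalized Min), pairwise
# lifts (MLPK, TPPK, their sum, Domain Composition), the combined pair
# kernel, and Gram matrix assembly.

check_nonneg_pair <- function(x, y) {
  if (length(x) != length(y)) {
    pk_validation_error("kernel arguments must have equal length")
  }
  if (any(x < 0) || any(y < 0)) {
    pk_validation_error("kernel arguments must be elementwise nonnegative")
  }
}

#' Min kernel
#'
#' Sum of elementwise minima of two nonnegative vectors.  On domain
#' count vectors it counts shared domains with multiplicity; on binary
#' profiles it counts shared 1-entries, so it relaxes the all-or-none
#' Domain Composition comparison to a graded similarity.
#'
#' @param x,y nonnegative numeric vectors of equal length
#' @return nonnegative scalar
#' @export
min_kernel <- function(x, y) {
  check_nonneg_pair(x, y)
  sum(pmin(x, y))
}

#' MinMax (Tanimoto) kernel
#'
#' Ratio of the elementwise-min sum to the elementwise-max sum: the
#' intersection-over-union normalization of the Min kernel, in
#' \[0, 1\].  Defined as 0 when the max sum is 0 (two all-zero
#' vectors).
#'
#' @inheritParams min_kernel
#' @return scalar in \[0, 1\]
#' @export
minmax_kernel <- function(x, y) {
  check_nonneg_pair(x, y)
  denom <- sum(pmax(x, y))
  if (denom == 0) 0 else sum(pmin(x, y)) / denom
}

#' Scale-normalize a kernel
#'
#' Returns the kernel `K(x, y) / sqrt(K(x, x) K(y, y))`, defined as 0
#' when either self-kernel is 0 (keeps Gram matrices total on
#' annotation-free proteins).
#'
#' @param kernel a function of two vectors
#' @return a function of two vectors
#' @export
scale_normalize <- function(kernel) {
  force(kernel)
  function(x, y) {
    kxx <- kernel(x, x)
    kyy <- kernel(y, y)
    if (kxx <= 0 || kyy <= 0) 0 else kernel(x, y) / sqrt(kxx * kyy)
  }
}

#' Metric learning pairwise kernel (MLPK) lift
#'
#' Lifts a protein-level kernel K to unordered pairs via
#' `(K(x1,x3) - K(x1,x4) - K(x2,x3) + K(x2,x4))^2`.  MLPK compares the
#' *difference* between a pair's elements in feature space, so it
#' fires when pairs are similar to other pairs even if the two
#' partners are dissimilar to each other -- the structure expected of
#' heterodimers.
#'
#' @param kernel protein-level kernel function of two vectors
#' @return function `(x1, x2, x3, x4) -> scalar`
#' @export
mlpk <- function(kernel) {
  force(kernel)
  function(x1, x2, x3, x4) {
    (kernel(x1, x3) - kernel(x1, x4) - kernel(x2, x3) + kernel(x2, x4))^2
  }
}

#' Tensor product pairwise kernel (TPPK) lift
#'
#' Lifts a protein-level kernel K to unordered pairs via
#' `K(x1,x3) K(x2,x4) + K(x1,x4) K(x2,x3)`: both matched assignments
#' of partners are compared and tensor-multiplied.
#'
#' @inheritParams mlpk
#' @return function `(x1, x2, x3, x4) -> scalar`
#' @export
tppk <- function(kernel) {
  force(kernel)
  function(x1, x2, x3, x4) {
    kernel(x1, x3) * kernel(x2, x4) + kernel(x1, x4) * kernel(x2, x3)
  }
}

#' Domain Composition kernel
#'
#' The 0/1 baseline pair kernel: 1 iff the two pairs have exactly the
#' same domain compositions under the direct or the crossed assignment
#' (count vectors compared for exact equality with multiplicity), else
#' 0.
#'
#' @param dom_table a [profile_table()] of kind `"domain-count"`
#'   (a protein absent from the table has the zero composition)
#' @return function `(p1, p2, p3, p4) -> 0 or 1` taking protein
#'   identifiers
#' @export
domain_composition_kernel <- function(dom_table) {
  force(dom_table)
  function(p1, p2, p3, p4) {
    v1 <- phi(dom_table, p1); v2 <- phi(dom_table, p2)
    v3 <- phi(dom_table, p3); v4 <- phi(dom_table, p4)
    direct <- all(v1 == v3) && all(v2 == v4)
    crossed <- all(v1 == v4) && all(v2 == v3)
    as.numeric(direct || crossed)
  }
}

#' Kernel specification
#'
#' Bundles the choices that define one combined pair kernel: the
#' protein-level base kernel, the pairwise lift, the protein feature
#' source, and the mixing weight `alpha` on the pairwise term.  The
#' combined kernel is the linear inner product of the two pairs' psi
#' vectors plus `alpha` times the lifted kernel;
#' `pairwise = "mlpk+tppk"` adds both lifts with the same `alpha`,
#' `pairwise = "none"` reduces to the psi inner product, and
#' `pairwise = "domain-composition"` ignores `base` and `feature`.
#'
#' @param base `"min"`, `"minmax"` or `"scale-normalized-min"`
#' @param pairwise `"mlpk"`, `"tppk"`, `"mlpk+tppk"`,
#'   `"domain-composition"` or `"none"`
#' @param feature `"dom"`, `"phylo"` or `"local"` -- which profile
#'   table feeds the base kernel
#' @param alpha nonnegative mixing weight
#' @return object of class `kernel_spec`
#' @export
kernel_spec <- function(base = c("scale-normalized-min", "min", "minmax"),
                        pairwise = c("mlpk", "tppk", "mlpk+tppk",
                                     "domain-composition", "none"),
                        feature = c("dom", "phylo", "local"),
                        alpha = 0) {
  base <- match.arg(base)
  pairwise <- match.arg(pairwise)
  feature <- match.arg(feature)
  alpha <- as.numeric(alpha)
  if (!is.finite(alpha) || alpha < 0) {
    pk_validation_error("alpha must be a nonnegative real")
  }
  structure(list(base = base, pairwise = pairwise, feature = feature,
                 alpha = alpha),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("kernel_spec: base=%s pairwise=%s feature=%s alpha=%g\n",
              x$base, x$pairwise, x$feature, x$alpha))
  invisible(x)
}

spec_label <- function(spec) {
  if (spec$pairwise == "none") return("psi-only")
  if (spec$pairwise == "domain-composition") return("domain-composition")
  sprintf("%s-%s-%s", spec$feature, spec$base, spec$pairwise)
}

# protein-level base kernel matrix between the rows of X and Y,
# accumulated column-by-column so entries match a per-pair sum(pmin())
# evaluation bit for bit
base_kernel_matrix <- function(X, Y, base) {
  kmin <- matrix(0, nrow(X), nrow(Y))
  for (d in seq_len(ncol(X))) {
    kmin <- kmin + outer(X[, d], Y[, d], pmin)
  }
  if (base == "min") return(kmin)
  if (base == "minmax") {
    kmax <- matrix(0, nrow(X), nrow(Y))
    for (d in seq_len(ncol(X))) {
      kmax <- kmax + outer(X[, d], Y[, d], pmax)
    }
    out <- kmin
    out[kmax > 0] <- kmin[kmax > 0] / kmax[kmax > 0]
    out[kmax == 0] <- 0
    return(out)
  }
  # scale-normalized Min: K(x,x) = sum(x) for nonnegative x
  sx <- rowSums(X)
  sy <- rowSums(Y)
  denom <- sqrt(outer(sx, sy))
  out <- kmin
  out[denom > 0] <- kmin[denom > 0] / denom[denom > 0]
  out[denom == 0] <- 0
  out
}

feature_table <- function(tables, feature) {
  tbl <- tables[[feature]]
  if (is.null(tbl)) {
    pk_validation_error("no profile table supplied for feature source '%s'",
                        feature)
  }
  tbl
}

# pairwise-kernel block between two pair lists, from a protein-level
# base kernel matrix B over `proteins`
pairwise_block <- function(spec, pairs_a, pairs_b, proteins, B, dom_table) {
  i1 <- match(pairs_a$a, proteins); i2 <- match(pairs_a$b, proteins)
  j1 <- match(pairs_b$a, proteins); j2 <- match(pairs_b$b, proteins)
  if (spec$pairwise == "domain-composition") {
    comp <- apply(phi_matrix(dom_table, proteins), 1L, paste, collapse = ",")
    e13 <- outer(comp[i1], comp[j1], "==")
    e24 <- outer(comp[i2], comp[j2], "==")
    e14 <- outer(comp[i1], comp[j2], "==")
    e23 <- outer(comp[i2], comp[j1], "==")
    return(((e13 & e24) | (e14 & e23)) + 0)
  }
  K13 <- B[i1, j1, drop = FALSE]
  K14 <- B[i1, j2, drop = FALSE]
  K23 <- B[i2, j1, drop = FALSE]
  K24 <- B[i2, j2, drop = FALSE]
  km <- (K13 - K14 - K23 + K24)^2
  kt <- K13 * K24 + K14 * K23
  switch(spec$pairwise,
         "mlpk" = km,
         "tppk" = kt,
         "mlpk+tppk" = km + kt)
}

#' Combined pair kernel between two protein pairs
#'
#' Scalar evaluation of the combined kernel
#' `<psi(pair1), psi(pair2)> + alpha * K_pairwise(pair1, pair2)` for
#' one pair of pairs; [gram()] is the vectorized form.
#'
#' @param spec a [kernel_spec()]
#' @param network a [ppi_network()]; both pairs must be edges
#' @param tables named list of [profile_table()]s with elements `dom`
#'   and (as needed) `phylo`, `local`
#' @param pair1,pair2 character vectors of length 2
#' @return scalar kernel value
#' @export
pair_kernel <- function(spec, network, tables, pair1, pair2) {
  p1 <- data.frame(a = min(pair1), b = max(pair1),
                   stringsAsFactors = FALSE)
  p2 <- data.frame(a = min(pair2), b = max(pair2),
                   stringsAsFactors = FALSE)
  g <- gram(spec, p1, p2, network, tables)
  g$entries[1L, 1L]
}

#' Gram matrix of the combined kernel between two pair lists
#'
#' Evaluates the combined kernel on every (row, column) pair of pairs.
#' Protein-level base-kernel values are computed once per protein pair
#' and shared across all pairwise-kernel entries; the result is
#' contractually identical to a naive double loop over
#' [pair_kernel()].
#'
#' @param spec a [kernel_spec()]
#' @param pairs_a,pairs_b [pair_set()]s or data.frames with columns
#'   `a`, `b`; `pairs_b = NULL` means `pairs_a` vs itself (square,
#'   symmetric Gram)
#' @param network a [ppi_network()]
#' @param tables named list of profile tables (`dom`, `phylo`,
#'   `local`); `dom` is always required for the psi domain counts
#' @return object of class `gram_matrix` with elements `entries`,
#'   `row_pairs`, `col_pairs`, `spec`
#' @export
gram <- function(spec, pairs_a, pairs_b = NULL, network, tables) {
  square <- is.null(pairs_b)
  if (square) pairs_b <- pairs_a
  dom_table <- feature_table(tables, "dom")
  psi_a <- psi_matrix(network, dom_table, pairs_a)
  psi_b <- if (square) psi_a else psi_matrix(network, dom_table, pairs_b)
  entries <- psi_a %*% t(psi_b)
  if (spec$pairwise != "none") {
    proteins <- unique(c(pairs_a$a, pairs_a$b, pairs_b$a, pairs_b$b))
    if (spec$pairwise == "domain-composition") {
      B <- NULL
    } else {
      X <- phi_matrix(feature_table(tables, spec$feature), proteins)
      B <- base_kernel_matrix(X, X, spec$base)
    }
    entries <- entries + spec$alpha *
      pairwise_block(spec, pairs_a, pairs_b, proteins, B, dom_table)
  }
  dimnames(entries) <- list(pair_id(pairs_a$a, pairs_a$b),
                            pair_id(pairs_b$a, pairs_b$b))
  structure(list(entries = entries,
                 row_pairs = pair_id(pairs_a$a, pairs_a$b),
                 col_pairs = pair_id(pairs_b$a, pairs_b$b),
                 spec = spec),
            class = "gram_matrix")
}

#' @export
print.gram_matrix <- function(x, ...) {
  cat(sprintf("gram_matrix: %d x %d (%s, alpha=%g)\n",
              nrow(x$entries), ncol(x$entries), spec_label(x$spec),
              x$spec$alpha))
  invisible(x)
}

#' Write a Gram matrix as TSV plus a sidecar spec JSON
#'
#' @param g a `gram_matrix` from [gram()]
#' @param path output TSV path; the kernel specification is written to
#'   `<path>.json` for provenance
#' @export
write_gram <- function(g, path) {
  df <- data.frame(pair = g$row_pairs, g$entries, check.names = FALSE)
  colnames(df) <- c("pair", g$col_pairs)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(g$spec), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
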