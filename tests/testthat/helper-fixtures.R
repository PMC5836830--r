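# Shared fixtures and independent oracles.

write_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# small hand network used across feature tests:
# edges AB:5, AC:1, BD:2, CD:3; domains A={D1,D1}, B={D2}
toy_network <- function() {
  ppi_network(data.frame(a = c("A", "A", "B", "C"),
                         b = c("B", "C", "D", "D"),
                         weight = c(5, 1, 2, 3)))
}

toy_dom_table <- function() {
  mat <- rbind(A = c(2, 0, 0), B = c(0, 1, 0))
  colnames(mat) <- c("D1", "D2", "D3")
  profile_table(mat, "domain-count")
}

# random small instance: network whose edges include `n_pairs` labeled
# pairs, plus dom/phylo/local tables over all proteins
random_instance <- function(seed, n_proteins = 14, n_pairs = 10,
                            n_domains = 6, n_genomes = 5, n_locs = 4) {
  set.seed(seed)
  proteins <- sprintf("R%02d", seq_len(n_proteins))
  cmb <- combn(proteins, 2)
  n_edges <- min(ncol(cmb), max(n_pairs + 5, round(ncol(cmb) * 0.5)))
  pick <- sample(ncol(cmb), n_edges)
  net <- ppi_network(data.frame(a = cmb[1, pick], b = cmb[2, pick],
                                weight = round(runif(n_edges, 0.2, 5), 3)))
  dom <- matrix(rpois(n_proteins * n_domains, 0.5), n_proteins,
                dimnames = list(proteins, sprintf("D%d", 1:n_domains)))
  phylo <- matrix(rbinom(n_proteins * n_genomes, 1, 0.5), n_proteins,
                  dimnames = list(proteins, sprintf("G%d", 1:n_genomes)))
  loc <- matrix(rbinom(n_proteins * n_locs, 1, 0.3), n_proteins,
                dimnames = list(proteins, sprintf("L%d", 1:n_locs)))
  e <- net$edges
  idx <- sample(nrow(e), min(n_pairs, nrow(e)))
  pairs <- pair_set(e$a[idx], e$b[idx],
                    sample(c(-1L, 1L), length(idx), replace = TRUE))
  list(network = net,
       tables = list(dom = profile_table(dom + 0, "domain-count"),
                     phylo = profile_table(phylo + 0, "binary-profile"),
                     local = profile_table(loc + 0, "binary-profile")),
       pairs = pairs)
}

# every kernel_spec combination exercised by the property suite
all_specs <- function(alpha = 0.7) {
  specs <- list()
  for (base in c("min", "minmax", "scale-normalized-min")) {
    for (pw in c("mlpk", "tppk", "mlpk+tppk")) {
      specs[[length(specs) + 1L]] <- kernel_spec(base, pw, "dom", alpha)
    }
  }
  specs[[length(specs) + 1L]] <- kernel_spec(pairwise = "domain-composition",
                                             alpha = alpha)
  specs[[length(specs) + 1L]] <- kernel_spec(pairwise = "none", alpha = 0)
  specs
}

# --- independent oracle: scalar, double-loop combined kernel ----------
# Built from the exported scalar primitives (psi, phi, min_kernel,
# mlpk, tppk, domain_composition_kernel), never from gram()'s
# vectorized path.
oracle_base_fun <- function(base) {
  switch(base,
         "min" = min_kernel,
         "minmax" = minmax_kernel,
         "scale-normalized-min" = scale_normalize(min_kernel))
}

oracle_pair_kernel <- function(spec, network, tables, p1, p2) {
  v <- sum(psi(network, tables$dom, p1[1], p1[2]) *
           psi(network, tables$dom, p2[1], p2[2]))
  if (spec$pairwise == "none") return(v)
  if (spec$pairwise == "domain-composition") {
    kc <- domain_composition_kernel(tables$dom)
    return(v + spec$alpha * kc(p1[1], p1[2], p2[1], p2[2]))
  }
  bk <- oracle_base_fun(spec$base)
  tbl <- tables[[spec$feature]]
  x1 <- phi(tbl, p1[1]); x2 <- phi(tbl, p1[2])
  x3 <- phi(tbl, p2[1]); x4 <- phi(tbl, p2[2])
  k <- switch(spec$pairwise,
              "mlpk" = mlpk(bk)(x1, x2, x3, x4),
              "tppk" = tppk(bk)(x1, x2, x3, x4),
              "mlpk+tppk" = mlpk(bk)(x1, x2, x3, x4) +
                            tppk(bk)(x1, x2, x3, x4))
  v + spec$alpha * k
}

oracle_gram <- function(spec, pairs_a, pairs_b, network, tables) {
  out <- matrix(0, nrow(pairs_a), nrow(pairs_b))
  for (i in seq_len(nrow(pairs_a))) {
    for (j in seq_len(nrow(pairs_b))) {
      out[i, j] <- oracle_pair_kernel(
        spec, network, tables,
        c(pairs_a$a[i], pairs_a$b[i]), c(pairs_b$a[j], pairs_b$b[j]))
    }
  }
  out
}

# relative PSD check: smallest eigenvalue of a square Gram must not be
# more negative than -tol times the largest
expect_psd <- function(entries, tol = 1e-8) {
  ev <- eigen((entries + t(entries)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  expect_gte(min(ev), -tol * max(abs(ev)))
}

# small planted-signal simulation for fast pipeline tests
small_sim_params <- function(seed, ...) {
  sim_params(n_proteins = 80L, n_positive_pairs = 14L,
             n_large_complexes = 10L, n_templates = 4L,
             n_domains = 30L, n_genomes = 20L, seed = seed, ...)
}
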