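# Seeded synthetic benchmark generator.
#
# The generator plants the two statistical premises the method rests
# on: (i) the edge inside a heterodimer is heavier than the edges
# around it, and (ii) positive pairs share domain-composition
# templates with *other* positive pairs while the two partners of a
# pair have different compositions (the structure MLPK is built to
# exploit and TPPK is not).

# run a block under a fixed, fully specified RNG and restore the
# caller's RNG state afterwards
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Simulation parameters
#'
#' Defaults describe a small yeast-like benchmark: 300 proteins, 40
#' planted heterodimer pairs drawing their domain compositions from 8
#' shared template pairs, 30 larger complexes (sizes 3-6) whose
#' internal edges supply negatives, a sparse random background, and
#' log-normal edge weights whose log-means (2.0 for planted
#' heterodimer edges vs 0.5 for everything else, sd 0.4 each) encode
#' the premise that the weight inside a heterodimer exceeds its
#' neighborhood weights.  Weights are dimensionless interaction
#' confidences; only their order relations matter to the features.
#'
#' @param n_proteins number of proteins
#' @param n_domains size of the domain alphabet
#' @param n_templates number of domain-composition template pairs
#'   shared across positive pairs
#' @param n_positive_pairs number of planted heterodimer pairs
#' @param n_large_complexes number of complexes of size 3-6
#' @param background_edge_prob probability of a random background edge
#' @param mu_heterodimer,mu_background log-means of the log-normal
#'   weight distributions (planted heterodimer edges vs all others)
#' @param sigma_weight common log-sd of the weight distributions
#' @param domain_noise_prob per-domain-slot corruption probability
#'   when copying a template composition
#' @param n_genomes number of genomes in the phylogenetic profiles
#' @param n_localizations number of subcellular compartments
#' @param localization_informative correlate localization within
#'   complexes (default `FALSE`: uninformative columns)
#' @param seed integer seed; all generator randomness derives from it
#' @return object of class `sim_params`
#' @export
sim_params <- function(n_proteins = 300L, n_domains = 60L,
                       n_templates = 8L, n_positive_pairs = 40L,
                       n_large_complexes = 30L,
                       background_edge_prob = 0.02,
                       mu_heterodimer = 2.0, mu_background = 0.5,
                       sigma_weight = 0.4, domain_noise_prob = 0.1,
                       n_genomes = 50L, n_localizations = 10L,
                       localization_informative = FALSE, seed = 1L) {
  p <- list(n_proteins = as.integer(n_proteins),
            n_domains = as.integer(n_domains),
            n_templates = as.integer(n_templates),
            n_positive_pairs = as.integer(n_positive_pairs),
            n_large_complexes = as.integer(n_large_complexes),
            background_edge_prob = background_edge_prob,
            mu_heterodimer = mu_heterodimer,
            mu_background = mu_background,
            sigma_weight = sigma_weight,
            domain_noise_prob = domain_noise_prob,
            n_genomes = as.integer(n_genomes),
            n_localizations = as.integer(n_localizations),
            localization_informative = isTRUE(localization_informative),
            seed = as.integer(seed))
  if (p$background_edge_prob < 0 || p$background_edge_prob > 1 ||
      p$domain_noise_prob < 0 || p$domain_noise_prob > 1) {
    pk_validation_error("probabilities must lie in [0, 1]")
  }
  if (2L * p$n_positive_pairs > p$n_proteins) {
    pk_validation_error(
      "infeasible: %d positive pairs need %d proteins but only %d available",
      p$n_positive_pairs, 2L * p$n_positive_pairs, p$n_proteins)
  }
  if (p$n_proteins - 2L * p$n_positive_pairs < 6L &&
      p$n_large_complexes > 0L) {
    pk_validation_error("not enough proteins left for large complexes")
  }
  structure(p, class = "sim_params")
}

# one random domain composition as a multiset of domain slots
random_slots <- function(n_domains, size) {
  sample.int(n_domains, size, replace = TRUE)
}

# corrupt each slot independently with prob p
corrupt_slots <- function(slots, n_domains, p) {
  hit <- runif(length(slots)) < p
  slots[hit] <- sample.int(n_domains, sum(hit), replace = TRUE)
  slots
}

slots_to_counts <- function(slots, n_domains) {
  tabulate(slots, nbins = n_domains)
}

noisy_profile <- function(pattern, flip_prob) {
  flip <- runif(length(pattern)) < flip_prob
  ifelse(flip, 1L - pattern, pattern)
}

#' Generate a synthetic heterodimer benchmark
#'
#' Produces a weighted network, three profile tables (domain counts,
#' phylogenetic profiles, localization), a complex catalog, and the
#' planted truth, all deterministically from `params$seed`.
#'
#' Construction: each planted positive pair becomes a size-2 complex
#' and a network edge with a heavy (heterodimer-distributed) weight;
#' its two proteins receive *different* noisy copies of one template
#' composition pair, so positives resemble other positives of the
#' same template across pairs but not within a pair.  Large complexes
#' are drawn from the remaining proteins, all their internal pairs
#' become background-weight edges (the candidate negatives), and
#' sparse random background edges are added.  Phylogenetic profiles
#' share a Bernoulli pattern within each complex (flip noise 0.1);
#' localization columns are independent noise unless
#' `localization_informative`.
#'
#' @param params a [sim_params()]
#' @return list of class `hd_simulation` with elements `network`,
#'   `tables` (list `dom`, `phylo`, `local`), `catalog`, `truth`
#'   (planted positive pairs, large complexes, params) and `params`
#' @export
simulate_heterodimers <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  restore <- local_rng(params$seed)
  on.exit(restore())

  p <- params
  proteins <- sprintf("P%04d", seq_len(p$n_proteins))
  domains <- sprintf("D%03d", seq_len(p$n_domains))

  ## template composition pairs: two different compositions each
  templates <- vector("list", p$n_templates)
  for (t in seq_len(p$n_templates)) {
    repeat {
      s1 <- random_slots(p$n_domains, sample(2:4, 1L))
      s2 <- random_slots(p$n_domains, sample(2:4, 1L))
      if (!identical(slots_to_counts(s1, p$n_domains),
                     slots_to_counts(s2, p$n_domains))) break
    }
    templates[[t]] <- list(s1 = s1, s2 = s2)
  }

  ## planted positive pairs on the first 2 * n_positive_pairs proteins
  pos_proteins <- sample(proteins, 2L * p$n_positive_pairs)
  pos_a <- pos_proteins[seq_len(p$n_positive_pairs)]
  pos_b <- pos_proteins[p$n_positive_pairs + seq_len(p$n_positive_pairs)]
  template_of <- rep_len(seq_len(p$n_templates), p$n_positive_pairs)

  dom_counts <- matrix(0L, p$n_proteins, p$n_domains,
                       dimnames = list(proteins, domains))
  for (i in seq_len(p$n_positive_pairs)) {
    tpl <- templates[[template_of[i]]]
    dom_counts[pos_a[i], ] <- slots_to_counts(
      corrupt_slots(tpl$s1, p$n_domains, p$domain_noise_prob), p$n_domains)
    dom_counts[pos_b[i], ] <- slots_to_counts(
      corrupt_slots(tpl$s2, p$n_domains, p$domain_noise_prob), p$n_domains)
  }
  ## background proteins draw the same 2-4 slot sizes as the
  ## templates, so only domain composition -- never raw domain count
  ## -- distinguishes planted proteins from the background
  rest <- setdiff(proteins, pos_proteins)
  for (pr in rest) {
    dom_counts[pr, ] <- slots_to_counts(
      random_slots(p$n_domains, sample(2:4, 1L)), p$n_domains)
  }

  ## catalog: heterodimers + large complexes from the non-positive pool
  complexes <- stats::setNames(
    lapply(seq_len(p$n_positive_pairs),
           function(i) c(pos_a[i], pos_b[i])),
    sprintf("HD%03d", seq_len(p$n_positive_pairs)))
  large <- list()
  if (p$n_large_complexes > 0L) {
    sizes <- sample(3:6, p$n_large_complexes, replace = TRUE)
    large <- stats::setNames(
      lapply(sizes, function(s) sample(rest, s)),
      sprintf("CPX%03d", seq_len(p$n_large_complexes)))
    complexes <- c(complexes, large)
  }

  ## edges: planted heterodimer edges (heavy), intra-complex edges and
  ## random background edges (light); first writer wins on collisions
  edge_env <- new.env(parent = emptyenv())
  add_edges <- function(a, b, w) {
    keys <- pair_key(a, b)
    for (i in seq_along(keys)) {
      if (is.null(edge_env[[keys[i]]])) edge_env[[keys[i]]] <- w[i]
    }
  }
  add_edges(pos_a, pos_b,
            rlnorm(p$n_positive_pairs, p$mu_heterodimer, p$sigma_weight))
  for (cpx in large) {
    cmb <- utils::combn(sort(cpx), 2L)
    add_edges(cmb[1L, ], cmb[2L, ],
              rlnorm(ncol(cmb), p$mu_background, p$sigma_weight))
  }
  if (p$background_edge_prob > 0) {
    cmb <- utils::combn(proteins, 2L)
    pick <- runif(ncol(cmb)) < p$background_edge_prob
    add_edges(cmb[1L, pick], cmb[2L, pick],
              rlnorm(sum(pick), p$mu_background, p$sigma_weight))
  }
  keys <- sort(ls(edge_env))
  parts <- strsplit(keys, "\t", fixed = TRUE)
  edges <- data.frame(
    a = vapply(parts, `[`, "", 1L),
    b = vapply(parts, `[`, "", 2L),
    weight = vapply(keys, function(k) edge_env[[k]], 0),
    stringsAsFactors = FALSE)
  network <- ppi_network(edges, extra_proteins = proteins)

  ## phylogenetic profiles: shared Bernoulli pattern per complex with
  ## flip noise 0.1; first group assignment wins
  genomes <- sprintf("G%03d", seq_len(p$n_genomes))
  phylo <- matrix(0L, p$n_proteins, p$n_genomes,
                  dimnames = list(proteins, genomes))
  assigned <- character(0)
  for (grp in complexes) {
    pattern <- rbinom(p$n_genomes, 1L, 0.4)
    for (pr in setdiff(grp, assigned)) {
      phylo[pr, ] <- noisy_profile(pattern, 0.1)
    }
    assigned <- union(assigned, grp)
  }
  for (pr in setdiff(proteins, assigned)) {
    phylo[pr, ] <- rbinom(p$n_genomes, 1L, 0.4)
  }

  ## localization: independent sparse membership unless informative
  locs <- sprintf("loc%02d", seq_len(p$n_localizations))
  localization <- matrix(0L, p$n_proteins, p$n_localizations,
                         dimnames = list(proteins, locs))
  if (p$localization_informative) {
    assigned <- character(0)
    for (grp in complexes) {
      pattern <- rbinom(p$n_localizations, 1L, 0.3)
      for (pr in setdiff(grp, assigned)) {
        localization[pr, ] <- noisy_profile(pattern, 0.1)
      }
      assigned <- union(assigned, grp)
    }
    for (pr in setdiff(proteins, assigned)) {
      localization[pr, ] <- rbinom(p$n_localizations, 1L, 0.3)
    }
  } else {
    localization[] <- rbinom(length(localization), 1L, 0.25)
  }

  truth <- list(
    positive_pairs = data.frame(a = pmin(pos_a, pos_b),
                                b = pmax(pos_a, pos_b),
                                template = template_of,
                                stringsAsFactors = FALSE),
    large_complexes = large,
    params = unclass(p))

  structure(list(network = network,
                 tables = list(
                   dom = profile_table(dom_counts + 0, "domain-count"),
                   phylo = profile_table(phylo + 0, "binary-profile"),
                   local = profile_table(localization + 0, "binary-profile")),
                 catalog = complex_catalog(complexes),
                 truth = truth,
                 params = p),
            class = "hd_simulation")
}

#' @export
print.hd_simulation <- function(x, ...) {
  cat(sprintf(
    "hd_simulation (seed %d): %d proteins, %d edges, %d planted pairs, %d complexes\n",
    x$params$seed, length(x$network$proteins), n_edges(x$network),
    nrow(x$truth$positive_pairs), length(x$catalog$complexes)))
  invisible(x)
}

#' Write a simulation bundle to a directory
#'
#' Emits `network.tsv`, `domains.tsv`, `phylo.tsv`,
#' `localization.tsv`, `complexes.tsv` in the exchange formats of the
#' readers, plus `truth.json` with the planted structure.
#'
#' @param sim an `hd_simulation`
#' @param dir output directory (created if absent)
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_weighted_ppi(sim$network, file.path(dir, "network.tsv"))
  write_profile_table(sim$tables$dom, file.path(dir, "domains.tsv"))
  write_profile_table(sim$tables$phylo, file.path(dir, "phylo.tsv"))
  write_profile_table(sim$tables$local, file.path(dir, "localization.tsv"))
  write_complex_catalog(sim$catalog, file.path(dir, "complexes.tsv"))
  jsonlite::write_json(
    list(positive_pairs = sim$truth$positive_pairs,
         large_complexes = sim$truth$large_complexes,
         params = sim$truth$params),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
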