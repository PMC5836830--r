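test_that("min kernel matches hand-computed values and validates", {
  x <- c(2, 0, 1, 1, 0)
  expect_equal(min_kernel(x, x), 4)
  expect_equal(min_kernel(x, c(0, 1, 1, 0, 0)), 1)
  expect_equal(min_kernel(x, rep(0, 5)), 0)
  expect_error(min_kernel(c(-1, 0), c(0, 0)), class = "pk_validation_error")
  expect_error(min_kernel(c(1, 0), c(0, 0, 1)), class = "pk_validation_error")
})

test_that("scale normalization has unit diagonal and the zero convention", {
  nmin <- scale_normalize(min_kernel)
  x <- c(2, 0, 1, 1, 0)
  expect_equal(nmin(x, x), 1)
  expect_equal(nmin(x, c(0, 1, 1, 0, 0)), 1 / sqrt(4 * 2))
  expect_equal(nmin(rep(0, 5), x), 0)
})

test_that("minmax kernel is the intersection-over-union in [0,1]", {
  x <- c(2, 0, 1, 1, 0)
  expect_equal(minmax_kernel(x, x), 1)
  expect_equal(minmax_kernel(c(1, 0), c(0, 2)), 0)   # disjoint supports
  expect_equal(minmax_kernel(x, c(1, 1, 1, 0, 0)), 2 / 5)
  expect_equal(minmax_kernel(rep(0, 3), rep(0, 3)), 0)
  for (seed in 1:20) {
    set.seed(seed)
    a <- rpois(6, 1); b <- rpois(6, 1)
    v <- minmax_kernel(a, b)
    expect_gte(v, 0); expect_lte(v, 1)
    # cross-check numerator/denominator against independent pieces
    denom <- sum(pmax(a, b))
    if (denom > 0) expect_equal(v, min_kernel(a, b) / denom)
  }
})

test_that("mlpk and tppk reproduce hand substitutions", {
  x1 <- c(1, 0); x2 <- c(0, 1); x3 <- c(1, 1); x4 <- c(0, 0)
  expect_equal(mlpk(min_kernel)(x1, x2, x3, x4), 0)  # (1-0-1+0)^2
  expect_equal(tppk(min_kernel)(x1, x2, x3, x4), 0)  # 1*0 + 0*1
  # self-comparison identities
  K <- min_kernel
  expect_equal(mlpk(K)(x1, x2, x1, x2),
               (K(x1, x1) + K(x2, x2) - 2 * K(x1, x2))^2)
  expect_equal(tppk(K)(x1, x2, x1, x2),
               K(x1, x1) * K(x2, x2) + K(x1, x2)^2)
  # x1 == x2 collapses MLPK to 0 against anything
  expect_equal(mlpk(K)(x3, x3, x1, x4), 0)
})

test_that("pairwise kernels are swap-invariant on random inputs", {
  set.seed(1)
  for (rep in 1:15) {
    xs <- replicate(4, rpois(5, 1), simplify = FALSE)
    for (lift in list(mlpk(min_kernel), tppk(min_kernel),
                      mlpk(minmax_kernel), tppk(minmax_kernel))) {
      v <- lift(xs[[1]], xs[[2]], xs[[3]], xs[[4]])
      expect_equal(lift(xs[[2]], xs[[1]], xs[[3]], xs[[4]]), v)
      expect_equal(lift(xs[[1]], xs[[2]], xs[[4]], xs[[3]]), v)
      expect_equal(lift(xs[[3]], xs[[4]], xs[[1]], xs[[2]]), v)
    }
  }
})

test_that("domain composition kernel matches direct or crossed equality", {
  mat <- rbind(P1 = c(1, 2), P2 = c(0, 1), P3 = c(1, 2), P4 = c(0, 1),
               P5 = c(3, 0))
  colnames(mat) <- c("D1", "D2")
  kc <- domain_composition_kernel(profile_table(mat, "domain-count"))
  expect_equal(kc("P1", "P2", "P1", "P2"), 1)      # identity
  expect_equal(kc("P1", "P2", "P4", "P3"), 1)      # crossed assignment
  expect_equal(kc("P1", "P2", "P5", "P3"), 0)      # no assignment works
  expect_equal(kc("P1", "P2", "unknownA", "unknownB"), 0)
})

test_that("combined kernel is the psi inner product plus alpha times the lift", {
  inst <- random_instance(21)
  p1 <- c(inst$pairs$a[1], inst$pairs$b[1])
  p2 <- c(inst$pairs$a[2], inst$pairs$b[2])
  # alpha = 0 reduces to the psi inner product
  s0 <- kernel_spec("min", "mlpk+tppk", "dom", alpha = 0)
  psi_ip <- sum(psi(inst$network, inst$tables$dom, p1[1], p1[2]) *
                psi(inst$network, inst$tables$dom, p2[1], p2[2]))
  expect_equal(pair_kernel(s0, inst$network, inst$tables, p1, p2), psi_ip)
  # alpha = 1, mlpk+tppk equals psi + K_M + K_T term by term
  s1 <- kernel_spec("min", "mlpk+tppk", "dom", alpha = 1)
  x <- lapply(c(p1, p2), function(p) phi(inst$tables$dom, p))
  expect_equal(pair_kernel(s1, inst$network, inst$tables, p1, p2),
               psi_ip +
                 mlpk(min_kernel)(x[[1]], x[[2]], x[[3]], x[[4]]) +
                 tppk(min_kernel)(x[[1]], x[[2]], x[[3]], x[[4]]))
})

test_that("combined kernel is affine in alpha", {
  inst <- random_instance(22)
  pairs <- inst$pairs
  for (pw in c("mlpk", "tppk", "mlpk+tppk", "domain-composition")) {
    g0 <- gram(kernel_spec("minmax", pw, "dom", 0), pairs, NULL,
               inst$network, inst$tables)$entries
    g1 <- gram(kernel_spec("minmax", pw, "dom", 1), pairs, NULL,
               inst$network, inst$tables)$entries
    for (a in c(0.3, 2)) {
      ga <- gram(kernel_spec("minmax", pw, "dom", a), pairs, NULL,
                 inst$network, inst$tables)$entries
      expect_equal(ga, g0 + a * (g1 - g0))
    }
  }
})

test_that("gram equals the naive double-loop oracle for every spec", {
  inst <- random_instance(31, n_proteins = 12, n_pairs = 8)
  a_pairs <- inst$pairs[1:5, ]
  b_pairs <- inst$pairs[4:8, ]
  for (spec in all_specs(alpha = 0.6)) {
    g <- gram(spec, a_pairs, b_pairs, inst$network, inst$tables)
    expect_equal(unname(g$entries),
                 oracle_gram(spec, a_pairs, b_pairs, inst$network,
                             inst$tables),
                 tolerance = 1e-10)
    # square case is symmetric
    gs <- gram(spec, inst$pairs, NULL, inst$network, inst$tables)
    expect_equal(gs$entries, t(gs$entries), tolerance = 1e-12)
  }
})

test_that("gram respects row/column order and the 1x1 case", {
  inst <- random_instance(33)
  pairs <- inst$pairs
  spec <- kernel_spec("min", "mlpk", "dom", 0.5)
  g <- gram(spec, pairs, NULL, inst$network, inst$tables)
  perm <- rev(seq_len(nrow(pairs)))
  gp <- gram(spec, pairs[perm, ], pairs, inst$network, inst$tables)
  expect_equal(unname(gp$entries), unname(g$entries[perm, ]))
  # 1x1 Gram of a pair with itself at alpha = 0 is ||psi||^2
  one <- pairs[1, ]
  g1 <- gram(kernel_spec(pairwise = "none"), one, NULL, inst$network,
             inst$tables)
  expect_equal(unname(g1$entries[1, 1]),
               sum(psi(inst$network, inst$tables$dom, one$a, one$b)^2))
})

test_that("square grams of every spec are PSD on random instances", {
  for (seed in 1:8) {
    inst <- random_instance(seed + 100, n_proteins = 16, n_pairs = 12)
    for (spec in all_specs(alpha = 0.8)) {
      g <- gram(spec, inst$pairs, NULL, inst$network, inst$tables)
      expect_psd(g$entries)
    }
  }
})

test_that("write_gram emits the matrix and a spec sidecar", {
  inst <- random_instance(40)
  spec <- kernel_spec("minmax", "tppk", "phylo", 0.2)
  g <- gram(spec, inst$pairs, NULL, inst$network, inst$tables)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gram(g, path)
  back <- read.delim(path, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), g$entries, ignore_attr = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$base, "minmax")
  expect_equal(side$alpha, 0.2)
})
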