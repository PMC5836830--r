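# Class-weighted C-SVC on precomputed Gram matrices, stratified k-fold
# cross-validation, and the alpha / C+ / C- grid protocol.

#' Fit a class-weighted C-SVC on a precomputed Gram matrix
#'
#' Solves the soft-margin SVM dual with separate penalty constants
#' `c_pos` / `c_neg` for slack on positive / negative examples, which
#' compensates for the heavy class imbalance between the few
#' catalogued heterodimers and the many intra-complex edges.  The
#' solver is an in-package SMO with second-order working-set
#' selection; the stored signed dual coefficients satisfy the box
#' constraints `0 <= coef_i <= c_pos` for positives and
#' `-c_neg <= coef_i <= 0` for negatives.
#'
#' @param train_gram square symmetric Gram matrix (a `gram_matrix`
#'   from [gram()] or a plain numeric matrix)
#' @param labels integer vector of +1 / -1 labels, both classes
#'   present
#' @param c_pos,c_neg positive penalty constants
#' @param tol SMO stopping tolerance on the maximal KKT violation
#' @param max_iter iteration cap
#' @return object of class `csvc_model`: `dual_coefficients` (signed),
#'   `bias`, `training_pair_ids`, `c_pos`, `c_neg`, `iterations`,
#'   `converged`, `objective`
#' @export
svc_fit <- function(train_gram, labels, c_pos, c_neg,
                    tol = 1e-3, max_iter = 10000000L) {
  K <- if (inherits(train_gram, "gram_matrix")) train_gram$entries else train_gram
  ids <- rownames(K)
  labels <- as.integer(labels)
  if (!is.matrix(K) || nrow(K) != ncol(K)) {
    pk_validation_error("training Gram must be square")
  }
  if (length(labels) != nrow(K)) {
    pk_validation_error("labels must parallel the Gram rows")
  }
  if (!all(labels %in% c(-1L, 1L))) {
    pk_validation_error("labels must be -1 or +1")
  }
  if (length(unique(labels)) < 2L) {
    pk_validation_error("training labels contain a single class")
  }
  if (c_pos <= 0 || c_neg <= 0) {
    pk_validation_error("c_pos and c_neg must be positive")
  }
  sol <- smo_csvc(K, labels, c_pos, c_neg, eps = tol,
                  max_iter = as.integer(max_iter))
  structure(list(dual_coefficients = as.numeric(sol$coef),
                 bias = sol$bias,
                 training_pair_ids = ids,
                 labels = labels,
                 c_pos = c_pos, c_neg = c_neg,
                 iterations = sol$iterations,
                 converged = sol$converged,
                 objective = sol$objective),
            class = "csvc_model")
}

#' @export
print.csvc_model <- function(x, ...) {
  cat(sprintf(
    "csvc_model: %d training pairs, %d support vectors, C+=%g C-=%g\n",
    length(x$dual_coefficients), sum(x$dual_coefficients != 0),
    x$c_pos, x$c_neg))
  invisible(x)
}

#' Predict labels from a cross Gram matrix
#'
#' The decision value of a test pair x is
#' `sum_i coef_i K(x_i, x) + bias`; the label is +1 when the decision
#' value is >= 0 (ties at exactly 0 are positive).
#'
#' @param model a [svc_fit()] model
#' @param cross_gram matrix of kernel values, rows = test pairs,
#'   columns = training pairs in the model's training order (a
#'   `gram_matrix` or plain matrix)
#' @return list with `decision` (numeric) and `label` (+1/-1 integer)
#' @export
svc_predict <- function(model, cross_gram) {
  K <- if (inherits(cross_gram, "gram_matrix")) cross_gram$entries else cross_gram
  if (ncol(K) != length(model$dual_coefficients)) {
    pk_validation_error("cross Gram has %d columns but model has %d training pairs",
                        ncol(K), length(model$dual_coefficients))
  }
  if (!is.null(colnames(K)) && !is.null(model$training_pair_ids) &&
      !identical(colnames(K), model$training_pair_ids)) {
    pk_validation_error("cross Gram columns do not match the training pairs")
  }
  decision <- as.numeric(K %*% model$dual_coefficients) + model$bias
  list(decision = decision,
       label = ifelse(decision >= 0, 1L, -1L))
}

#' Precision, recall and F-measure from confusion counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F = 2 * precision * recall / (precision + recall)`, with the
#' zero-denominator conventions precision = 0 when no pair is
#' predicted positive, recall = 0 when there are no positives, and
#' F = 0 when precision + recall = 0 (small folds can legitimately
#' produce empty predictions).
#'
#' @param tp,fp,fn nonnegative integer counts of true positives,
#'   false positives and false negatives
#' @return named numeric vector `(precision, recall, f_measure)`
#' @export
prf <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0) || any(c(tp, fp, fn) != round(c(tp, fp, fn)))) {
    pk_validation_error("tp, fp, fn must be nonnegative integers")
  }
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  c(precision = precision, recall = recall, f_measure = f)
}

#' Stratified fold assignment
#'
#' Shuffles each class with the given seed and deals it round-robin
#' over folds, so per-fold positive counts differ by at most one.
#'
#' @param labels +1/-1 labels
#' @param n_folds number of folds
#' @param seed integer seed (fold construction only)
#' @return integer vector of fold indices in `1..n_folds`
#' @export
make_folds <- function(labels, n_folds, seed) {
  if (sum(labels == 1L) < n_folds || sum(labels == -1L) < n_folds) {
    pk_validation_error(
      "need at least %d examples of each class for %d folds",
      n_folds, n_folds)
  }
  fold <- integer(length(labels))
  rng <- local_rng(seed)
  on.exit(rng())
  for (cls in c(1L, -1L)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

report_from_folds <- function(per_fold, config) {
  averaged <- list(precision = mean(per_fold$precision),
                   recall = mean(per_fold$recall),
                   f_measure = mean(per_fold$f_measure))
  structure(list(per_fold = per_fold, averaged = averaged,
                 config = config),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "evaluation_report (%d folds): precision %.3f, recall %.3f, F %.3f\n",
    nrow(x$per_fold), x$averaged$precision, x$averaged$recall,
    x$averaged$f_measure))
  invisible(x)
}

# evaluate one (alpha, c_pos, c_neg) point from precomputed parts;
# psi_gram = Psi %*% t(Psi) (or NULL when scale_psi), pair_block = the
# unscaled pairwise-kernel matrix (NULL for pairwise = "none")
cv_point <- function(parts, labels, alpha, c_pos, c_neg, fold,
                     scale_psi = FALSE, tol = 1e-3) {
  n_folds <- max(fold)
  K_pair <- if (is.null(parts$pair_block)) 0 else alpha * parts$pair_block
  if (!scale_psi) K_full <- parts$psi_gram + K_pair
  rows <- lapply(seq_len(n_folds), function(f) {
    te <- which(fold == f)
    tr <- which(fold != f)
    if (scale_psi) {
      fit <- psi_scale_fit(parts$psi[tr, , drop = FALSE])
      psi_s <- psi_scale_apply(parts$psi, fit)
      Ktr <- tcrossprod(psi_s[tr, , drop = FALSE])
      Kte <- psi_s[te, , drop = FALSE] %*% t(psi_s[tr, , drop = FALSE])
      if (!identical(K_pair, 0)) {
        Ktr <- Ktr + K_pair[tr, tr, drop = FALSE]
        Kte <- Kte + K_pair[te, tr, drop = FALSE]
      }
    } else {
      Ktr <- K_full[tr, tr, drop = FALSE]
      Kte <- K_full[te, tr, drop = FALSE]
    }
    model <- svc_fit(Ktr, labels[tr], c_pos, c_neg, tol = tol)
    pred <- svc_predict(model, Kte)
    tp <- sum(pred$label == 1L & labels[te] == 1L)
    fp <- sum(pred$label == 1L & labels[te] == -1L)
    fn <- sum(pred$label == -1L & labels[te] == 1L)
    m <- prf(tp, fp, fn)
    data.frame(fold = f, tp = tp, fp = fp, fn = fn,
               precision = m[["precision"]], recall = m[["recall"]],
               f_measure = m[["f_measure"]])
  })
  do.call(rbind, rows)
}

# precompute the alpha-independent Gram parts for one spec
gram_parts <- function(pairs, network, tables, spec) {
  dom_table <- feature_table(tables, "dom")
  Psi <- psi_matrix(network, dom_table, pairs)
  pair_block <- NULL
  if (spec$pairwise != "none") {
    proteins <- unique(c(pairs$a, pairs$b))
    B <- NULL
    if (spec$pairwise != "domain-composition") {
      X <- phi_matrix(feature_table(tables, spec$feature), proteins)
      B <- base_kernel_matrix(X, X, spec$base)
    }
    pair_block <- pairwise_block(spec, pairs, pairs, proteins, B, dom_table)
  }
  list(psi = Psi, psi_gram = tcrossprod(Psi), pair_block = pair_block)
}

#' Cross-validate a kernel specification
#'
#' Stratified k-fold cross-validation of the class-weighted C-SVC
#' under the combined kernel.  The full Gram matrix is assembled once
#' and each fold's training / test blocks are sliced from it; with
#' `scale_psi = TRUE` the optional per-feature min-max scaling of psi
#' is re-fit on each training fold.
#'
#' @param pairs a [pair_set()]
#' @param network a [ppi_network()]
#' @param tables named list of profile tables (`dom`, and `phylo` /
#'   `local` as required by `spec`)
#' @param spec a [kernel_spec()]
#' @param c_pos,c_neg penalty constants
#' @param n_folds number of folds (default 10)
#' @param seed integer seed for fold construction
#' @param scale_psi fit per-feature min-max scaling of psi on each
#'   training fold (default `FALSE`, the literal inner product)
#' @param tol SMO stopping tolerance
#' @return an `evaluation_report`: `per_fold` (fold, TP, FP, FN,
#'   precision, recall, F), `averaged` (unweighted fold means),
#'   `config`
#' @export
cross_validate <- function(pairs, network, tables, spec, c_pos, c_neg,
                           n_folds = 10L, seed = 1L, scale_psi = FALSE,
                           tol = 1e-3) {
  labels <- pairs$label
  fold <- make_folds(labels, n_folds, seed)
  parts <- gram_parts(pairs, network, tables, spec)
  per_fold <- cv_point(parts, labels, spec$alpha, c_pos, c_neg, fold,
                       scale_psi = scale_psi, tol = tol)
  report_from_folds(per_fold,
                    config = list(spec = spec, c_pos = c_pos,
                                  c_neg = c_neg, n_folds = n_folds,
                                  seed = seed, scale_psi = scale_psi))
}

#' Grid search over alpha and the penalty constants
#'
#' Evaluates every combination of kernel specification, mixing weight
#' `alpha`, `c_pos` and `c_neg` by cross-validation, reusing the
#' alpha-independent Gram parts of each specification.  Ties on mean
#' F-measure are broken by higher mean precision, then smaller
#' `alpha`, then smaller `c_pos`, then input order.
#'
#' @inheritParams cross_validate
#' @param specs a [kernel_spec()] or list of them (their `alpha` is
#'   overridden by the grid)
#' @param alpha_grid,cpos_grid,cneg_grid nonempty numeric grids
#' @return list with `table` (one row per evaluated point: spec
#'   label, alpha, c_pos, c_neg, mean precision / recall / F) and
#'   `best` (the argmax row plus its `evaluation_report`)
#' @export
grid_search <- function(pairs, network, tables, specs,
                        alpha_grid, cpos_grid, cneg_grid = 1.0,
                        n_folds = 10L, seed = 1L, scale_psi = FALSE,
                        tol = 1e-3) {
  if (inherits(specs, "kernel_spec")) specs <- list(specs)
  if (!length(specs) || !length(alpha_grid) || !length(cpos_grid) ||
      !length(cneg_grid)) {
    pk_validation_error("grids and spec list must be nonempty")
  }
  labels <- pairs$label
  fold <- make_folds(labels, n_folds, seed)
  rows <- list()
  reports <- list()
  k <- 0L
  for (s in seq_along(specs)) {
    spec <- specs[[s]]
    parts <- gram_parts(pairs, network, tables, spec)
    for (a in alpha_grid) for (cp in cpos_grid) for (cn in cneg_grid) {
      per_fold <- cv_point(parts, labels, a, cp, cn, fold,
                           scale_psi = scale_psi, tol = tol)
      spec_a <- spec
      spec_a$alpha <- a
      rep <- report_from_folds(per_fold,
                               config = list(spec = spec_a, c_pos = cp,
                                             c_neg = cn,
                                             n_folds = n_folds,
                                             seed = seed,
                                             scale_psi = scale_psi))
      k <- k + 1L
      rows[[k]] <- data.frame(spec = spec_label(spec), alpha = a,
                              c_pos = cp, c_neg = cn,
                              precision = rep$averaged$precision,
                              recall = rep$averaged$recall,
                              f_measure = rep$averaged$f_measure)
      reports[[k]] <- rep
    }
  }
  table <- do.call(rbind, rows)
  ord <- order(-table$f_measure, -table$precision, table$alpha,
               table$c_pos, seq_len(nrow(table)))
  best_i <- ord[1L]
  list(table = table,
       best = c(as.list(table[best_i, ]),
                list(report = reports[[best_i]])))
}

#' Write an evaluation report as TSV (per fold) and JSON
#'
#' @param report an `evaluation_report`
#' @param path_prefix files `<path_prefix>.tsv` and
#'   `<path_prefix>.json` are written
#' @export
write_report <- function(report, path_prefix) {
  write.table(report$per_fold, paste0(path_prefix, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- report$config
  cfg$spec <- unclass(cfg$spec)
  jsonlite::write_json(list(averaged = report$averaged,
                            per_fold = report$per_fold,
                            config = cfg),
                       paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path_prefix)
}
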