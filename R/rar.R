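# Retain-And-Retrain (RAR): keep only the top-salient cells, recompute
# functional network connectivity, retrain an independent RBF-SVM, and
# compare performance under model-derived vs random importance.

#' Zero out all cells outside a retain mask
#'
#' @param record A [timecourse_record].
#' @param mask Logical `C x T` retain mask (see [select_top_fraction()]).
#' @return The record with `data * mask` (masked cells exactly 0).
#' @export
apply_retain_mask <- function(record, mask) {
  if (!identical(dim(record$data), dim(mask))) {
    stop("mask is ", nrow(mask), "x", ncol(mask), ", record is ",
         nrow(record$data), "x", ncol(record$data))
  }
  record$data <- record$data * mask
  record
}

#' Functional network connectivity matrix
#'
#' Static FNC: Pearson correlation between every pair of component time
#' courses over the full time axis.  Pairs involving a zero-variance
#' component (e.g. a component fully zeroed by a retain mask) are set to
#' 0; the number of such degenerate components is reported.  The diagonal
#' is 1 by convention.
#'
#' @param record A [timecourse_record] (possibly masked).
#' @return A `C x C` symmetric matrix with attribute
#'   `"n_degenerate"` (components with zero variance).
#' @export
compute_fnc <- function(record) {
  x <- record$data
  if (ncol(x) < 3L) stop("need T >= 3 time points for FNC")
  sds <- apply(x, 1L, stats::sd)
  degen <- sds == 0
  r <- suppressWarnings(stats::cor(t(x)))
  r[degen, ] <- 0
  r[, degen] <- 0
  diag(r) <- 1
  attr(r, "n_degenerate") <- sum(degen)
  r
}

#' Vectorize an FNC matrix into SVM features
#'
#' Strict upper triangle in row-major order: `(1,2), (1,3), ..., (1,C),
#' (2,3), ...`; length `C (C - 1) / 2` (1378 for C = 53).
#'
#' @param fnc A `C x C` FNC matrix.
#' @return Numeric feature vector.
#' @export
fnc_features <- function(fnc) {
  C <- nrow(fnc)
  # t() because upper.tri indexes column-major; row-major order wanted
  tf <- t(fnc)
  tf[lower.tri(tf)]
}

# Inverse of fnc_features (used in tests and group summaries).
fnc_from_features <- function(feats, C) {
  m <- matrix(0, C, C)
  tm <- t(m)
  tm[lower.tri(tm)] <- feats
  m <- t(tm)
  m <- m + t(m)
  diag(m) <- 1
  m
}

# RBF-SVM with inner grid search, returning test-fold decision values.
# Grid per the "parameter grid + 3-fold CV" protocol: cost in
# {0.1, 1, 10, 100}, gamma = scale heuristic x {0.1, 1, 10}.
svm_grid_fold <- function(Xtr, ytr, Xte, inner_folds = 3L, seed = 1L) {
  gamma0 <- 1 / (ncol(Xtr) * max(stats::var(as.vector(Xtr)), 1e-12))
  grid <- expand.grid(cost = c(0.1, 1, 10, 100),
                      gamma = gamma0 * c(0.1, 1, 10))
  inner <- stratified_folds(ytr, inner_folds, seed = seed)
  cv_auc <- vapply(seq_len(nrow(grid)), function(g) {
    aucs <- vapply(seq_len(inner_folds), function(f) {
      tr <- inner != f; te <- inner == f
      fit <- e1071::svm(Xtr[tr, , drop = FALSE], factor(ytr[tr]),
                        kernel = "radial", cost = grid$cost[g],
                        gamma = grid$gamma[g], scale = FALSE)
      dv <- attr(stats::predict(fit, Xtr[te, , drop = FALSE],
                                decision.values = TRUE), "decision.values")
      # orient decision values toward class 1
      sgn <- if (colnames(dv)[1L] == "1") 1 else -1
      binary_auc(ytr[te], sgn * dv[, 1L])
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  best <- which.max(cv_auc)
  fit <- e1071::svm(Xtr, factor(ytr), kernel = "radial",
                    cost = grid$cost[best], gamma = grid$gamma[best],
                    scale = FALSE)
  dv <- attr(stats::predict(fit, Xte, decision.values = TRUE),
             "decision.values")
  sgn <- if (colnames(dv)[1L] == "1") 1 else -1
  list(decision = sgn * dv[, 1L], cost = grid$cost[best],
       gamma = grid$gamma[best])
}

#' Cross-validated SVM performance on FNC features
#'
#' For each outer fold, a nonlinear (RBF) SVM is grid-searched with inner
#' 3-fold cross-validation on the training subjects only, refit on the
#' full training fold, and scored on the untouched test fold.  AUC uses
#' the SVM's continuous decision values.
#'
#' @param features Numeric matrix, subjects x FNC features.
#' @param labels Binary labels (0/1), one per subject.
#' @param folds Integer fold assignment per subject (use the same folds
#'   as the deep-model cross-validation).
#' @param seed Seed for the inner grid-search folds.
#' @return data.frame with one row per fold: `fold, auc, accuracy, cost,
#'   gamma`.
#' @export
rar_auc <- function(features, labels, folds, seed = 1L) {
  stopifnot(nrow(features) == length(labels),
            length(folds) == length(labels))
  seeds <- derive_seeds(seed, max(folds))
  rows <- lapply(sort(unique(folds)), function(f) {
    tr <- folds != f; te <- folds == f
    if (length(unique(labels[tr])) < 2L || length(unique(labels[te])) < 2L) {
      stop("fold ", f, " has a single class")
    }
    sg <- svm_grid_fold(features[tr, , drop = FALSE], labels[tr],
                        features[te, , drop = FALSE], seed = seeds[f])
    data.frame(fold = f,
               auc = binary_auc(labels[te], sg$decision),
               accuracy = mean((sg$decision > 0) == (labels[te] == 1L)),
               cost = sg$cost, gamma = sg$gamma)
  })
  do.call(rbind, rows)
}

#' Compare salient-mask and random-mask RAR reports
#'
#' Pairs the per-(fold, repeat) AUC cells of two RAR reports, reports the
#' mean difference and a paired Wilcoxon signed-rank p-value, and flags
#' whether the salient estimator beats the random baseline
#' (`xi(X^M | g_i) > xi(X^M | g^R)`).
#'
#' @param report_salient,report_random data.frames with matching `fold`
#'   (and optionally `rep`) columns and an `auc` column.
#' @return List with `diffs`, `mean_diff`, `p_value`,
#'   `salient_beats_random`, and `n_positive` (cells where salient wins).
#' @export
compare_estimators <- function(report_salient, report_random) {
  keys <- intersect(c("fold", "rep"), names(report_salient))
  a <- report_salient[do.call(order, report_salient[keys]), ]
  b <- report_random[do.call(order, report_random[keys]), ]
  if (nrow(a) != nrow(b) ||
      !identical(a[keys], b[keys])) {
    stop("reports have mismatched fold/repeat grids")
  }
  d <- a$auc - b$auc
  p <- if (all(d == 0)) 1 else
    suppressWarnings(stats::wilcox.test(a$auc, b$auc, paired = TRUE)$p.value)
  list(diffs = d, mean_diff = mean(d), p_value = p,
       salient_beats_random = mean(d) > 0 && any(d != 0),
       n_positive = sum(d > 0))
}

#' Group-level FNC summary from masked records
#'
#' Mean FNC over the subjects of a group, the strongest `edge_fraction`
#' of edges by `|mean r|` (an edge list suitable for connectogram tools),
#' and — when several groups are given — pairwise difference matrices of
#' the group means.
#'
#' @param groups Named list of lists of (masked) [timecourse_record]s.
#' @param edge_fraction Fraction of the `C (C - 1) / 2` edges to retain
#'   (default 0.10, i.e. 138 edges for C = 53).
#' @return List with `mean_fnc` (per group), `edges` (per group,
#'   data.frame `component_i, component_j, mean_r`), and
#'   `pairwise_diff` (named list of difference matrices).
#' @export
group_fnc_summary <- function(groups, edge_fraction = 0.10) {
  if (!length(groups)) stop("empty group list")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  mean_fnc <- lapply(groups, function(recs) {
    if (!length(recs)) stop("empty group")
    Reduce(`+`, lapply(recs, compute_fnc)) / length(recs)
  })
  C <- nrow(mean_fnc[[1L]])
  n_edges <- round(edge_fraction * C * (C - 1) / 2)
  pairs <- which(upper.tri(mean_fnc[[1L]]), arr.ind = TRUE)
  edges <- lapply(mean_fnc, function(m) {
    r <- m[upper.tri(m)]
    ord <- order(-abs(r), pairs[, 1L], pairs[, 2L])[seq_len(n_edges)]
    data.frame(component_i = pairs[ord, 1L], component_j = pairs[ord, 2L],
               mean_r = r[ord])
  })
  pd <- list()
  gn <- names(groups)
  if (length(gn) > 1L) {
    for (i in seq_along(gn)[-length(gn)]) {
      for (j in (i + 1L):length(gn)) {
        pd[[paste(gn[i], gn[j], sep = "-")]] <-
          mean_fnc[[i]] - mean_fnc[[j]]
      }
    }
  }
  list(mean_fnc = mean_fnc, edges = edges, pairwise_diff = pd)
}

#' End-to-end retain-and-retrain evaluation on a labeled cohort
#'
#' Mirrors the published protocol with the same folds and train/test
#' splits as the deep model: per (fold, repeat), the attention-LSTM
#' classifier is fine-tuned on the training folds, integrated-gradients
#' saliency is computed for every subject from that model, every
#' subject's data is masked to its top-`fraction` signed-salient cells
#' (or to random-permutation cells for the `g^R` baseline), FNC features
#' are recomputed from the masked data, and an independent RBF-SVM is
#' grid-searched (inner 3-fold CV on training subjects only) and scored
#' on the test fold.
#'
#' @param records Labeled cohort.
#' @param k Outer folds (default 5).
#' @param repeats Repetitions with distinct seeds (default 3).
#' @param fraction Retained fraction of cells (default 0.05).
#' @param model_config,config Architecture and fine-tuning settings.
#' @param ig_steps IG path steps used for the saliency maps.
#' @param base_seed Master seed.
#' @return List with `salient` and `random` reports (data.frames with
#'   `fold, rep, auc, accuracy`), the `comparison` from
#'   [compare_estimators()], `folds`, and `saliency` (assembled
#'   test-fold maps from the last repeat, for downstream temporal
#'   analysis; each subject's map comes from the model that did not
#'   train on them).
#' @details For fold `f`, the attributions of *all* subjects — and hence
#'   all retain masks and FNC features the fold-`f` SVM sees — are
#'   computed from the model trained on folds other than `f`, so no
#'   test-fold subject can influence training, masks or SVM grids.
#' @export
rar_evaluate <- function(records, k = 5L, repeats = 3L, fraction = 0.05,
                         model_config = milc_config(),
                         config = train_config(), ig_steps = 32L,
                         base_seed = 1L) {
  labels <- vapply(records, `[[`, 0L, "label")
  if (anyNA(labels)) stop("cohort must be fully labeled")
  folds <- stratified_folds(labels, k, seed = base_seed)
  n <- length(records)
  stride <- config$stride %||% 1L
  cell_seeds <- matrix(derive_seeds(base_seed + 1L, repeats * k),
                       nrow = repeats)
  norm_records <- prep_records(records)
  n_feat <- nrow(records[[1L]]$data) * (nrow(records[[1L]]$data) - 1) / 2

  sal_rows <- list(); ran_rows <- list()
  test_maps <- vector("list", n)
  for (rp in seq_len(repeats)) {
    for (f in seq_len(k)) {
      seed_c <- cell_seeds[rp, f]
      tr_idx <- which(folds != f)
      cfg <- config
      cfg$seed <- seed_c
      cfg$mode <- "finetune_from_scratch"
      m0 <- milc_model(model_config, seed = seed_c)
      mt <- milc_finetune(m0, records[tr_idx], config = cfg)
      sub_seeds <- derive_seeds(seed_c + 1L, n)
      feat_sal <- matrix(0, n, n_feat)
      feat_ran <- matrix(0, n, n_feat)
      for (s in seq_len(n)) {
        ws <- integrated_gradients(mt, records[[s]], steps = ig_steps,
                                   stride = stride)
        map <- assemble_subject_saliency(ws)
        if (folds[s] == f && rp == repeats) test_maps[[s]] <- map
        msk <- select_top_fraction(map, fraction)
        feat_sal[s, ] <- fnc_features(compute_fnc(
          apply_retain_mask(norm_records[[s]], msk)))
        gR <- random_importance(nrow(msk), ncol(msk), seed = sub_seeds[s])
        feat_ran[s, ] <- fnc_features(compute_fnc(
          apply_retain_mask(norm_records[[s]],
                            select_top_fraction(gR, fraction))))
      }
      tr <- folds != f; te <- folds == f
      sg_s <- svm_grid_fold(feat_sal[tr, , drop = FALSE], labels[tr],
                            feat_sal[te, , drop = FALSE], seed = seed_c)
      sg_r <- svm_grid_fold(feat_ran[tr, , drop = FALSE], labels[tr],
                            feat_ran[te, , drop = FALSE], seed = seed_c)
      yte <- labels[te]
      sal_rows[[length(sal_rows) + 1L]] <- data.frame(
        fold = f, rep = rp, auc = binary_auc(yte, sg_s$decision),
        accuracy = mean((sg_s$decision > 0) == (yte == 1L)))
      ran_rows[[length(ran_rows) + 1L]] <- data.frame(
        fold = f, rep = rp, auc = binary_auc(yte, sg_r$decision),
        accuracy = mean((sg_r$decision > 0) == (yte == 1L)))
    }
  }
  salient <- do.call(rbind, sal_rows)
  random <- do.call(rbind, ran_rows)
  list(salient = salient, random = random,
       comparison = compare_estimators(salient, random),
       folds = folds, saliency = test_maps)
}
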