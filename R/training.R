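#' Training configuration
#'
#' @param batch_size Subjects per minibatch (>= 2 for pretraining, since
#'   the other sequences in the batch serve as InfoNCE negatives).
#' @param epochs Number of passes over the training subjects.
#' @param learning_rate Adam step size.
#' @param stride Sliding-window stride (10 for pretraining, 1 for
#'   downstream fine-tuning by default; larger strides trade temporal
#'   resolution for speed in simulation studies).
#' @param patience Early-stopping patience in epochs on the held-out
#'   loss; `Inf` disables early stopping.
#' @param holdout_frac Fraction of the pretraining pool held out for the
#'   pretraining-accuracy estimate.
#' @param seed Seed controlling shuffling and any initialization done by
#'   the training routine; recorded in the history.
#' @param mode Bookkeeping tag: `"pretrain"`, `"finetune_from_pretrained"`
#'   or `"finetune_from_scratch"`.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 16L, epochs = 20L,
                         learning_rate = 1e-4, stride = NULL,
                         patience = Inf, holdout_frac = 0.15, seed = 1L,
                         mode = c("pretrain", "finetune_from_pretrained",
                                  "finetune_from_scratch")) {
  mode <- match.arg(mode)
  stopifnot(batch_size >= 1, epochs >= 0, learning_rate >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 stride = stride, patience = patience,
                 holdout_frac = holdout_frac,
                 seed = as.integer(seed), mode = mode),
            class = "train_config")
}

#' InfoNCE loss for a window/sequence score tensor
#'
#' Given scores `S[i, t, k] = f(z_t^i, c^k)` — window `t` of sequence `i`
#' scored against the sequence embedding of subject `k` — returns the
#' negative InfoNCE bound
#' \deqn{L = -\sum_i \sum_t \log \frac{\exp S[i,t,i]}{\sum_k \exp S[i,t,k]}}
#' computed with a numerically stable log-sum-exp.  With all scores equal
#' the loss is exactly `N * T * log(N)`; it approaches 0 as the positive
#' scores dominate the negatives.
#'
#' @param scores Numeric array `N x T x N` (sequences x windows x
#'   candidate sequences), `N >= 2`.
#' @return Scalar loss (nonnegative).
#' @export
infonce_loss <- function(scores) {
  d <- dim(scores)
  if (is.null(d) || length(d) != 3L || d[1] != d[3]) {
    stop("scores must be an N x T x N array")
  }
  if (d[1] < 2L) stop("need N >= 2 sequences (at least one negative)")
  if (!all(is.finite(scores))) stop("non-finite scores")
  N <- d[1]; Tn <- d[2]
  # flatten to (N*T) x N with rows (i, t)
  flat <- matrix(aperm(scores, c(2L, 1L, 3L)), nrow = N * Tn, ncol = N)
  pos <- rep(seq_len(N), each = Tn)
  sum(logsumexp_rows(flat) - flat[cbind(seq_len(N * Tn), pos)])
}

# Internal: InfoNCE loss + gradients from embeddings.
# z_flat: (B*Tw x dz) subject-major; cmat: (B x dc); phiW: (dc x dz).
infonce_grads <- function(z_flat, cmat, phiW, n_win) {
  B <- nrow(cmat)
  PhiZ <- z_flat %*% t(phiW)                    # (B*Tw x dc)
  S <- PhiZ %*% t(cmat)                         # (B*Tw x B)
  pos <- rep(seq_len(B), each = n_win)
  lse <- logsumexp_rows(S)
  loss <- sum(lse - S[cbind(seq_len(nrow(S)), pos)])
  P <- exp(S - lse)
  dS <- P
  dS[cbind(seq_len(nrow(S)), pos)] <- dS[cbind(seq_len(nrow(S)), pos)] - 1
  dPhiZ <- dS %*% cmat
  dc <- crossprod(dS, PhiZ)
  dphiW <- crossprod(dPhiZ, z_flat)
  dz <- dPhiZ %*% phiW
  acc <- mean(max.col(S, ties.method = "first") == pos)
  list(loss = loss, dz = dz, dc = dc, dphiW = dphiW, accuracy = acc)
}

prep_records <- function(records) lapply(records, normalize_timecourses)

# Evaluate InfoNCE loss/accuracy on a set of subjects (one batch).
infonce_eval <- function(model, wts) {
  st <- stack_window_tensors(wts)
  fwd <- milc_forward_batch(model, st$arr, st$n_win, keep_cache = FALSE)
  g <- infonce_grads(fwd$z, fwd$c, model$par$phi$W, st$n_win)
  list(loss = g$loss, mean_loss = g$loss / (st$B * st$n_win),
       accuracy = g$accuracy)
}

#' Self-supervised pretraining on an unlabeled pool
#'
#' Minimizes the InfoNCE loss over minibatches of subjects: every window
#' embedding is scored against the sequence embeddings of all subjects in
#' the batch, with the other subjects acting as negatives.  A held-out
#' split of the pool provides the pretraining accuracy (fraction of
#' windows whose own sequence achieves the top score).
#'
#' @param model A [milc_model] (weights are updated from its current
#'   state).
#' @param pool List of [timecourse_record]s; labels are ignored.
#' @param config A [train_config]; `config$stride` defaults to 10.
#' @return The trained [milc_model], with `history$pretrain` holding
#'   per-epoch loss, held-out loss and held-out accuracy, plus the seed.
#' @export
milc_pretrain <- function(model, pool, config = train_config()) {
  if (length(pool) < 2L) stop("pretraining pool must have >= 2 subjects")
  if (config$batch_size < 2L) stop("pretraining needs batch_size >= 2")
  stride <- config$stride %||% 10L
  records <- prep_records(pool)
  wts <- lapply(records, make_windows,
                spec = sliding_window_spec(model$config$window_length, stride))

  n <- length(wts)
  n_hold <- max(0L, min(n - 2L, round(config$holdout_frac * n)))
  seeds <- derive_seeds(config$seed, 2L + config$epochs)
  hold_idx <- if (n_hold >= 2L) {
    with_seed(seeds[1L], sample.int(n, n_hold))
  } else integer(0)
  train_idx <- setdiff(seq_len(n), hold_idx)

  opt <- adam_new(model$par, lr = config$learning_rate)
  hist <- list(loss = numeric(0), holdout_loss = numeric(0),
               holdout_accuracy = numeric(0), seed = config$seed)
  best <- list(par = model$par, loss = Inf, since = 0L)

  for (ep in seq_len(config$epochs)) {
    order_ep <- with_seed(seeds[2L + ep], sample(train_idx))
    ep_loss <- 0; ep_pairs <- 0L
    b0 <- 1L
    while (b0 <= length(order_ep)) {
      idx <- order_ep[b0:min(b0 + config$batch_size - 1L, length(order_ep))]
      b0 <- b0 + config$batch_size
      if (length(idx) < 2L) next
      st <- stack_window_tensors(wts[idx])
      fwd <- milc_forward_batch(model, st$arr, st$n_win, keep_cache = TRUE)
      g <- infonce_grads(fwd$z, fwd$c, model$par$phi$W, st$n_win)
      if (!is.finite(g$loss)) stop("non-finite InfoNCE loss at epoch ", ep)
      scale <- 1 / (length(idx) * st$n_win)
      bk <- milc_backward_batch(model, fwd,
                                dc_extra = g$dc * scale,
                                dz_extra = g$dz * scale)
      grads <- bk$grads
      grads$phi$W <- g$dphiW * scale
      stp <- adam_step(opt, model$par, grads)
      opt <- stp$opt; model$par <- stp$params
      ep_loss <- ep_loss + g$loss
      ep_pairs <- ep_pairs + length(idx) * st$n_win
    }
    hist$loss <- c(hist$loss, if (ep_pairs > 0) ep_loss / ep_pairs else NA)
    if (length(hold_idx) >= 2L) {
      ev <- infonce_eval(model, wts[hold_idx])
      hist$holdout_loss <- c(hist$holdout_loss, ev$mean_loss)
      hist$holdout_accuracy <- c(hist$holdout_accuracy, ev$accuracy)
      if (ev$mean_loss < best$loss - 1e-9) {
        best <- list(par = model$par, loss = ev$mean_loss, since = 0L)
      } else {
        best$since <- best$since + 1L
        if (best$since >= config$patience) {
          model$par <- best$par
          break
        }
      }
    }
  }
  model$history$pretrain <- hist
  model
}

#' Held-out pretraining accuracy of a model on a pool
#'
#' @param model A [milc_model].
#' @param pool List of records to evaluate on (treated as one batch of
#'   mutual negatives).
#' @param stride Window stride (default 10, the pretraining stride).
#' @return List with `accuracy` and `mean_loss`.
#' @export
pretraining_accuracy <- function(model, pool, stride = 10L) {
  if (length(pool) < 2L) stop("need >= 2 subjects")
  wts <- lapply(prep_records(pool), make_windows,
                spec = sliding_window_spec(model$config$window_length, stride))
  ev <- infonce_eval(model, wts)
  list(accuracy = ev$accuracy, mean_loss = ev$mean_loss)
}

#' Supervised fine-tuning for patient/control classification
#'
#' Trains the full network end to end with softmax cross-entropy on the
#' two-logit head.  Start from a pretrained checkpoint for the
#' "with pretraining" regime or from a freshly initialized [milc_model]
#' for "without pretraining".
#'
#' @param model A [milc_model].
#' @param labeled List of labeled [timecourse_record]s; both classes must
#'   be present.
#' @param config A [train_config]; `config$stride` defaults to 1.
#' @return The trained [milc_model] with `history$finetune`.
#' @export
milc_finetune <- function(model, labeled, config = train_config()) {
  labels <- vapply(labeled, `[[`, 0L, "label")
  if (anyNA(labels)) stop("all fine-tuning records must be labeled")
  if (length(unique(labels)) < 2L) stop("training set has a single class")
  stride <- config$stride %||% 1L
  records <- prep_records(labeled)
  wts <- lapply(records, make_windows,
                spec = sliding_window_spec(model$config$window_length, stride))

  n <- length(wts)
  seeds <- derive_seeds(config$seed, config$epochs)
  opt <- adam_new(model$par, lr = config$learning_rate)
  hist <- list(loss = numeric(0), seed = config$seed, mode = config$mode)

  for (ep in seq_len(config$epochs)) {
    order_ep <- with_seed(seeds[ep], sample.int(n))
    ep_loss <- 0
    b0 <- 1L
    while (b0 <= n) {
      idx <- order_ep[b0:min(b0 + config$batch_size - 1L, n)]
      b0 <- b0 + config$batch_size
      st <- stack_window_tensors(wts[idx])
      fwd <- milc_forward_batch(model, st$arr, st$n_win, keep_cache = TRUE)
      P <- softmax_rows(fwd$logits)
      Y <- cbind(labels[idx] == 0L, labels[idx] == 1L) + 0
      loss <- -sum(log(pmax(P[Y == 1], 1e-12)))
      if (!is.finite(loss)) stop("non-finite fine-tuning loss at epoch ", ep)
      dlogits <- (P - Y) / length(idx)
      bk <- milc_backward_batch(model, fwd, dlogits = dlogits)
      stp <- adam_step(opt, model$par, bk$grads)
      opt <- stp$opt; model$par <- stp$params
      ep_loss <- ep_loss + loss
    }
    hist$loss <- c(hist$loss, ep_loss / n)
  }
  model$history$finetune <- hist
  model
}

#' Progressive-sample-size cross-validation harness
#'
#' Stratified K-fold cross-validation: for each fold, each training size
#' and each repeat, a class-balanced subsample of the training folds is
#' drawn with a repeat-specific seed, the model is fine-tuned on it, and
#' AUC/accuracy are scored on the untouched test fold.  The
#' `"pretrained"` mode initializes from `pretrained` (a pretrained
#' checkpoint); `"scratch"` initializes fresh random weights.
#'
#' @param records Labeled cohort (list of [timecourse_record]s).
#' @param k Number of folds.
#' @param train_sizes Integer vector of per-class training-set sizes.
#' @param repeats Repetitions per cell with distinct seeds.
#' @param base_seed Master seed from which all cell seeds derive.
#' @param model_config [milc_config] for the network.
#' @param config [train_config] for fine-tuning.
#' @param pretrained Optional pretrained [milc_model] (required for mode
#'   `"pretrained"`).
#' @param modes Character subset of `c("pretrained", "scratch")`.
#' @return A data.frame with columns `mode, train_size, fold, rep, seed,
#'   auc, accuracy`; the fold assignment is in `attr(, "folds")`, the
#'   per-cell training subject indices in `attr(, "train_indices")`
#'   (for leakage auditing), and — when both modes are run — a paired
#'   signed-rank comparison of the two regimes per training size in
#'   `attr(, "mode_comparison")`.
#' @export
milc_cv <- function(records, k = 5L, train_sizes = c(15L), repeats = 10L,
                    base_seed = 1L, model_config = milc_config(),
                    config = train_config(), pretrained = NULL,
                    modes = c("pretrained", "scratch")) {
  modes <- match.arg(modes, c("pretrained", "scratch"), several.ok = TRUE)
  if ("pretrained" %in% modes && is.null(pretrained)) {
    stop("mode 'pretrained' requires a pretrained model")
  }
  labels <- vapply(records, `[[`, 0L, "label")
  if (anyNA(labels)) stop("cohort must be fully labeled")
  folds <- stratified_folds(labels, k, seed = base_seed)

  n_cells <- k * length(train_sizes) * repeats * length(modes)
  cell_seeds <- derive_seeds(base_seed + 1L, n_cells)
  rows <- vector("list", n_cells)
  train_idx_log <- vector("list", n_cells)
  cell <- 0L
  for (fold in seq_len(k)) {
    test_idx <- which(folds == fold)
    pool_idx <- which(folds != fold)
    for (ts in train_sizes) {
      for (rp in seq_len(repeats)) {
        # one subsample per (fold, size, repeat), shared across modes so
        # the w/ vs w/o pretraining comparison is paired
        sub_seed <- cell_seeds[cell + 1L]
        sub <- with_seed(sub_seed, {
          unlist(lapply(c(0L, 1L), function(cls) {
            cand <- pool_idx[labels[pool_idx] == cls]
            if (length(cand) < ts) {
              stop("fold ", fold, ": training pool has ", length(cand),
                   " subjects of class ", cls, ", need ", ts)
            }
            sample(cand, ts)
          }))
        })
        for (mode in modes) {
          cell <- cell + 1L
          seed_c <- cell_seeds[cell]
          cfg <- config
          cfg$seed <- seed_c
          cfg$mode <- if (mode == "pretrained") "finetune_from_pretrained"
                      else "finetune_from_scratch"
          m0 <- if (mode == "pretrained") pretrained
                else milc_model(model_config, seed = seed_c)
          mt <- milc_finetune(m0, records[sub], config = cfg)
          p <- predict(mt, records[test_idx], stride = cfg$stride %||% 1L,
                       type = "prob")
          yte <- labels[test_idx]
          rows[[cell]] <- data.frame(
            mode = mode, train_size = ts, fold = fold, rep = rp,
            seed = seed_c, auc = binary_auc(yte, p),
            accuracy = mean((p > 0.5) == (yte == 1L)))
          train_idx_log[[cell]] <- sub
        }
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(cell)])
  attr(out, "folds") <- folds
  attr(out, "train_indices") <- train_idx_log[seq_len(cell)]
  if (length(modes) == 2L) {
    # paired signed-rank comparison of the two regimes per training size
    cmp <- lapply(train_sizes, function(ts) {
      a <- out[out$mode == "pretrained" & out$train_size == ts, ]
      b <- out[out$mode == "scratch" & out$train_size == ts, ]
      key <- order(a$fold, a$rep); keyb <- order(b$fold, b$rep)
      p <- if (all(a$auc[key] == b$auc[keyb])) 1 else
        suppressWarnings(stats::wilcox.test(a$auc[key], b$auc[keyb],
                                            paired = TRUE)$p.value)
      data.frame(train_size = ts, auc_pretrained = mean(a$auc),
                 auc_scratch = mean(b$auc), signed_rank_p = p)
    })
    attr(out, "mode_comparison") <- do.call(rbind, cmp)
  }
  out
}
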