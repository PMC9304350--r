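#' Architecture configuration for the two-level attention LSTM
#'
#' Defaults reproduce the published architecture: a parameter-shared
#' window encoder (unidirectional LSTM, hidden size 256, additive
#' attention with 64 hidden units over the concatenated 512-dim state
#' pairs), a top-level LSTM over the window embeddings (hidden size 200,
#' attention with 128 hidden units over 400-dim pairs), a bias-free
#' linear pair-scoring map `phi`: 256 -> 200 for the InfoNCE objective,
#' and a 200-hidden-unit feed-forward head for binary classification.
#' Smaller settings are useful for simulation studies where wall time
#' matters more than capacity.
#'
#' @param input_components Number of input components C (rows of each
#'   subject matrix); 53 for the intrinsic-network time courses.
#' @param window_length Sliding-window length fed to the encoder.
#' @param enc_hidden Encoder LSTM hidden size (= window embedding dim).
#' @param enc_attn_hidden Hidden units of the encoder attention scorer.
#' @param top_hidden Top LSTM hidden size (= sequence embedding dim).
#' @param top_attn_hidden Hidden units of the top attention scorer.
#' @param head_hidden Hidden units of the classification head.
#' @return A `milc_config` list.
#' @export
milc_config <- function(input_components = 53L, window_length = 20L,
                        enc_hidden = 256L, enc_attn_hidden = 64L,
                        top_hidden = 200L, top_attn_hidden = 128L,
                        head_hidden = 200L) {
  cfg <- list(input_components = as.integer(input_components),
              window_length = as.integer(window_length),
              enc_hidden = as.integer(enc_hidden),
              enc_attn_hidden = as.integer(enc_attn_hidden),
              top_hidden = as.integer(top_hidden),
              top_attn_hidden = as.integer(top_attn_hidden),
              head_hidden = as.integer(head_hidden),
              n_classes = 2L)
  stopifnot(all(vapply(cfg, function(v) v >= 1L, logical(1))))
  structure(cfg, class = "milc_config")
}

#' Construct a two-level attention-LSTM model with seeded random weights
#'
#' The network encodes each sliding window with a parameter-shared
#' LSTM + attention into a window embedding `z`, runs a second LSTM +
#' attention over the sequence of `z`s to produce a whole-sequence
#' embedding `c`, scores window/sequence pairs via `f(z, c) = phi(z)' c`
#' during self-supervised pretraining, and classifies from `c` through a
#' feed-forward head.  Weights use uniform fan-in initialization drawn
#' from a generator seeded with `seed`, which is recorded on the object.
#'
#' @param config A [milc_config].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `milc_model` with elements `par` (weights),
#'   `config`, `seed`, and `history` (training log, initially empty).
#' @seealso [milc_pretrain()], [milc_finetune()], [predict.milc_model()]
#' @export
milc_model <- function(config = milc_config(), seed = 1L) {
  stopifnot(inherits(config, "milc_config"))
  par <- with_seed(seed, list(
    enc = lstm_init(config$input_components, config$enc_hidden),
    enc_attn = attn_init(config$enc_hidden, config$enc_attn_hidden),
    top = lstm_init(config$enc_hidden, config$top_hidden),
    top_attn = attn_init(config$top_hidden, config$top_attn_hidden),
    phi = list(W = matrix(stats::runif(config$top_hidden * config$enc_hidden,
                                       -1 / sqrt(config$enc_hidden),
                                       1 / sqrt(config$enc_hidden)),
                          config$top_hidden, config$enc_hidden)),
    head = head_init(config$top_hidden, config$head_hidden, 2L)
  ))
  structure(list(par = par, config = config, seed = as.integer(seed),
                 history = list()),
            class = "milc_model")
}

#' @export
print.milc_model <- function(x, ...) {
  cfg <- x$config
  cat("<milc_model>\n")
  cat(sprintf("  encoder LSTM: %d -> %d (attention hidden %d)\n",
              cfg$input_components, cfg$enc_hidden, cfg$enc_attn_hidden))
  cat(sprintf("  top LSTM:     %d -> %d (attention hidden %d)\n",
              cfg$enc_hidden, cfg$top_hidden, cfg$top_attn_hidden))
  cat(sprintf("  head: %d -> %d -> 2 | phi: %d -> %d\n",
              cfg$top_hidden, cfg$head_hidden, cfg$enc_hidden, cfg$top_hidden))
  cat(sprintf("  init seed: %d; trained phases: %s\n", x$seed,
              if (length(x$history)) paste(names(x$history), collapse = ", ")
              else "none"))
  invisible(x)
}

#' @export
summary.milc_model <- function(object, ...) {
  np <- sum(vapply(params_flatten(object$par), length, integer(1)))
  cat(sprintf("milc_model with %d parameters\n", np))
  for (phase in names(object$history)) {
    h <- object$history[[phase]]
    cat(sprintf("  %s: %d epochs, final loss %.6g\n", phase,
                length(h$loss), utils::tail(h$loss, 1)))
  }
  invisible(object)
}

#' @export
coef.milc_model <- function(object, ...) params_flatten(object$par)

# ---- forward building blocks -------------------------------------------

#' Attention pooling of a sequence of hidden states
#'
#' Concatenates each hidden state with the final one, scores the pairs
#' with a two-layer feed-forward network (tanh between the layers),
#' softmax-normalizes the alignment scores into weights `alpha`, and
#' returns the weighted sum of the hidden states.
#'
#' @param hidden_states Numeric matrix, `n` time steps x `d_h`.
#' @param scorer List with `W1` (`2 d_h x k`), `b1`, `w2` (`k`), `b2`.
#' @return List with `pooled` (length `d_h`), `weights` (length `n`,
#'   nonnegative, summing to 1) and `scores` (raw alignment scores).
#' @examples
#' h <- matrix(rnorm(6), 3, 2)
#' sc <- list(W1 = matrix(0, 4, 2), b1 = c(0, 0), w2 = c(1, 1), b2 = 0)
#' attention_pool(h, sc)$weights  # equal scores -> uniform weights
#' @export
attention_pool <- function(hidden_states, scorer) {
  hidden_states <- as.matrix(hidden_states)
  n <- nrow(hidden_states)
  if (n < 1L) stop("need at least one hidden state")
  H_arr <- array(t(hidden_states), dim = c(1L, ncol(hidden_states), n))
  out <- attn_forward(H_arr, scorer, keep_cache = FALSE)
  list(pooled = drop(out$pooled), weights = drop(out$alpha),
       scores = drop(out$scores))
}

#' Encode one sliding window into its local embedding z
#'
#' @param window Numeric matrix `C x window_length`.
#' @param model A [milc_model].
#' @return Numeric vector of length `enc_hidden`.
#' @export
encode_window <- function(window, model) {
  cfg <- model$config
  window <- as.matrix(window)
  if (nrow(window) != cfg$input_components ||
      ncol(window) != cfg$window_length) {
    stop("window is ", nrow(window), "x", ncol(window), ", model expects ",
         cfg$input_components, "x", cfg$window_length)
  }
  arr <- array(0, dim = c(1L, nrow(window), ncol(window)))
  arr[1L, , ] <- window
  drop(encode_windows_batch(arr, model)$z)
}

# Batched window encoder: arr (n, C, w) -> z matrix (n, enc_hidden).
encode_windows_batch <- function(arr, model, keep_cache = FALSE) {
  lf <- lstm_forward(arr, model$par$enc, keep_cache = keep_cache)
  af <- attn_forward(lf$H, model$par$enc_attn, keep_cache = keep_cache)
  list(z = af$pooled, lstm_cache = lf$cache, attn_cache = af$cache)
}

#' Encode a sequence of window embeddings into the context embedding c
#'
#' @param zs Numeric matrix `n_windows x enc_hidden` of window embeddings
#'   in temporal order.
#' @param model A [milc_model].
#' @return Numeric vector of length `top_hidden`.
#' @export
encode_sequence <- function(zs, model) {
  zs <- as.matrix(zs)
  if (nrow(zs) < 1L) stop("need at least one window embedding")
  if (ncol(zs) != model$config$enc_hidden) {
    stop("embeddings have dim ", ncol(zs), ", model expects ",
         model$config$enc_hidden)
  }
  arr <- array(t(zs), dim = c(1L, ncol(zs), nrow(zs)))
  lf <- lstm_forward(arr, model$par$top, keep_cache = FALSE)
  af <- attn_forward(lf$H, model$par$top_attn, keep_cache = FALSE)
  drop(af$pooled)
}

#' Bilinear window/sequence pair score
#'
#' The separable InfoNCE critic `f(z, c) = phi(z)' c`, with `phi` the
#' model's learned bias-free linear map from the window-embedding space
#' to the sequence-embedding space.
#'
#' @param z Window embedding (length `enc_hidden`).
#' @param c_embed Sequence embedding (length `top_hidden`).
#' @param model A [milc_model].
#' @return Scalar score.
#' @export
score_pair <- function(z, c_embed, model) {
  if (length(z) != model$config$enc_hidden) stop("z has wrong length")
  if (length(c_embed) != model$config$top_hidden) stop("c has wrong length")
  as.numeric(crossprod(model$par$phi$W %*% z, c_embed))
}

#' Classification logits from a sequence embedding
#'
#' @param c_embed Sequence embedding (length `top_hidden`) or a matrix of
#'   embeddings in rows.
#' @param model A [milc_model].
#' @return Numeric vector of 2 logits (or a matrix, one row per input
#'   row); class probabilities are `softmax(logits)`.
#' @export
classify_logits <- function(c_embed, model) {
  cm <- if (is.matrix(c_embed)) c_embed else matrix(c_embed, nrow = 1L)
  if (ncol(cm) != model$config$top_hidden) stop("embedding dim mismatch")
  out <- head_forward(cm, model$par$head, keep_cache = FALSE)$logits
  if (is.matrix(c_embed)) out else drop(out)
}

# ---- full-subject forward / backward (internal) ------------------------

# Forward pass for a batch of subjects with identical window counts.
# `win_arr` is (B * n_win, C, w), rows subject-major (subject 1's windows
# first).  Returns embeddings, logits and caches for backprop.
milc_forward_batch <- function(model, win_arr, n_win, keep_cache = FALSE) {
  B <- dim(win_arr)[1] / n_win
  stopifnot(B == round(B))
  enc <- encode_windows_batch(win_arr, model, keep_cache = keep_cache)
  dz <- model$config$enc_hidden
  # reshape z (B*n_win, dz) -> top input (B, dz, n_win)
  top_in <- array(0, dim = c(B, dz, n_win))
  for (t in seq_len(n_win)) {
    top_in[, , t] <- enc$z[(seq_len(B) - 1L) * n_win + t, , drop = FALSE]
  }
  top_l <- lstm_forward(top_in, model$par$top, keep_cache = keep_cache)
  top_a <- attn_forward(top_l$H, model$par$top_attn, keep_cache = keep_cache)
  hd <- head_forward(top_a$pooled, model$par$head, keep_cache = keep_cache)
  list(z = enc$z, c = top_a$pooled, logits = hd$logits, B = B, n_win = n_win,
       caches = if (keep_cache) list(enc = enc, top_l = top_l, top_a = top_a,
                                     head = hd$cache) else NULL)
}

# Backward pass.  Any of dlogits (B x 2), dc_extra (B x top_hidden) and
# dz_extra (B*n_win x enc_hidden) may be supplied; gradients are summed.
# Returns list(grads = parameter gradients, dX = (B*n_win, C, w)).
milc_backward_batch <- function(model, fwd, dlogits = NULL, dc_extra = NULL,
                                dz_extra = NULL, need_dx = FALSE) {
  B <- fwd$B; n_win <- fwd$n_win
  cfg <- model$config
  dc <- matrix(0, B, cfg$top_hidden)
  grads <- list()
  if (!is.null(dlogits)) {
    hb <- head_backward(model$par$head, fwd$caches$head, dlogits)
    dc <- dc + hb$dc
    grads$head <- list(W1 = hb$dW1, b1 = hb$db1, W2 = hb$dW2, b2 = hb$db2)
  } else {
    grads$head <- params_scale(model$par$head, 0)
  }
  if (!is.null(dc_extra)) dc <- dc + dc_extra

  ta <- attn_backward(model$par$top_attn, fwd$caches$top_a$cache, dc)
  grads$top_attn <- list(W1 = ta$dW1, b1 = ta$db1, w2 = ta$dw2, b2 = ta$db2)
  tl <- lstm_backward(model$par$top, fwd$caches$top_l$cache, ta$dH)
  grads$top <- list(Wx = tl$dWx, Wh = tl$dWh, b = tl$db)

  # gradient wrt each window embedding z: (B, dz, n_win) -> (B*n_win, dz)
  dz <- matrix(0, B * n_win, cfg$enc_hidden)
  for (t in seq_len(n_win)) {
    dz[(seq_len(B) - 1L) * n_win + t, ] <- slice3(tl$dX, t)
  }
  if (!is.null(dz_extra)) dz <- dz + dz_extra

  ea <- attn_backward(model$par$enc_attn, fwd$caches$enc$attn_cache, dz)
  grads$enc_attn <- list(W1 = ea$dW1, b1 = ea$db1, w2 = ea$dw2, b2 = ea$db2)
  el <- lstm_backward(model$par$enc, fwd$caches$enc$lstm_cache, ea$dH)
  grads$enc <- list(Wx = el$dWx, Wh = el$dWh, b = el$db)
  grads$phi <- list(W = matrix(0, nrow(model$par$phi$W),
                               ncol(model$par$phi$W)))
  list(grads = grads, dX = if (need_dx) el$dX else NULL)
}

# Stack a list of window tensors (same n_win) into a subject-major array.
stack_window_tensors <- function(wts) {
  n_win <- dim(wts[[1]]$windows)[1]
  C <- dim(wts[[1]]$windows)[2]; w <- dim(wts[[1]]$windows)[3]
  B <- length(wts)
  arr <- array(0, dim = c(B * n_win, C, w))
  for (b in seq_len(B)) {
    if (!identical(dim(wts[[b]]$windows), dim(wts[[1]]$windows))) {
      stop("all subjects must yield the same window-tensor shape")
    }
    arr[(b - 1L) * n_win + seq_len(n_win), , ] <- wts[[b]]$windows
  }
  list(arr = arr, n_win = n_win, B = B)
}

#' Predict classes, probabilities or embeddings for subject records
#'
#' Runs the deterministic forward pass (windowing with the given stride,
#' window encoder, top network, classification head).
#'
#' @param object A trained [milc_model].
#' @param records A list of [timecourse_record]s (or a single record).
#' @param stride Sliding-window stride for the downstream view (default 1).
#' @param type One of `"prob"` (probability of class 1), `"class"`,
#'   `"logits"`, or `"context"` (the sequence embeddings).
#' @param ... Unused.
#' @return Vector or matrix with one row/element per subject.
#' @export
predict.milc_model <- function(object, records, stride = 1L,
                               type = c("prob", "class", "logits", "context"),
                               ...) {
  type <- match.arg(type)
  if (inherits(records, "timecourse_record")) records <- list(records)
  spec <- sliding_window_spec(object$config$window_length, stride)
  wts <- lapply(records, make_windows, spec = spec)
  st <- stack_window_tensors(wts)
  fwd <- milc_forward_batch(object, st$arr, st$n_win, keep_cache = FALSE)
  switch(type,
    prob = {
      p <- softmax_rows(fwd$logits)[, 2L]
      stats::setNames(p, vapply(records, `[[`, "", "subject_id"))
    },
    class = {
      cl <- max.col(fwd$logits, ties.method = "first") - 1L
      stats::setNames(cl, vapply(records, `[[`, "", "subject_id"))
    },
    logits = fwd$logits,
    context = fwd$c)
}

# ---- checkpointing ------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint stores all weights together with the architecture
#' configuration, the initialization seed and the training history.
#' Loading verifies the architecture: if `expected_config` is supplied
#' and differs from the stored one, loading fails loudly.
#'
#' @param model A [milc_model].
#' @param path File path for the checkpoint.
#' @return `save_milc_checkpoint` returns `path` invisibly;
#'   `load_milc_checkpoint` returns the restored [milc_model].
#' @export
save_milc_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "milc_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_milc_checkpoint
#' @param expected_config Optional [milc_config] the caller requires.
#' @export
load_milc_checkpoint <- function(path, expected_config = NULL) {
  model <- readRDS(path)
  if (!inherits(model, "milc_model")) stop("not a milc_model checkpoint: ",
                                           path)
  if (!is.null(expected_config) &&
      !identical(unclass(model$config), unclass(expected_config))) {
    stop("checkpoint architecture mismatch for ", path)
  }
  model
}
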