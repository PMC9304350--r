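# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.  All user-facing randomness flows through
# this so that seeds recorded in results are sufficient to reproduce them.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a stream of child seeds from one parent seed; keeps every derived
# seed strictly below 2^31 so they remain valid R integers.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

# Row-wise numerically stable log(sum(exp(x))).
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1L, max))
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# AUC of `scores` for binary `labels` (1 = positive), fixed direction so a
# score orientation is never auto-flipped in our favour.
binary_auc <- function(labels, scores) {
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

# Extract the (n, d) matrix at time slot t of an (n, d, T) array.
slice3 <- function(a, t) {
  m <- a[, , t, drop = FALSE]
  dim(m) <- dim(a)[1:2]
  m
}

# Stratified fold assignment: returns an integer vector of fold ids in 1..k.
stratified_folds <- function(labels, k, seed) {
  stopifnot(k >= 2)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      if (length(idx) < k) {
        stop("class ", cls, " has fewer subjects (", length(idx),
             ") than folds (", k, ")")
      }
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a
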