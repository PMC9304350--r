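# Post hoc saliency: integrated gradients and smoothgrad on the windowed
# model input, assembly into subject-level maps, random-permutation
# importance baseline, and signed top-fraction retain masks.

# Gradient of the target-class logit wrt the stacked window array.
# path_arr: (B * n_win, C, w) where each block of n_win rows is one
# evaluation point; returns list(dX, logits (B x 2)).
milc_input_gradient <- function(model, path_arr, n_win, target_class) {
  fwd <- milc_forward_batch(model, path_arr, n_win, keep_cache = TRUE)
  B <- fwd$B
  dlogits <- matrix(0, B, 2L)
  dlogits[, target_class + 1L] <- 1
  bk <- milc_backward_batch(model, fwd, dlogits = dlogits, need_dx = TRUE)
  list(dX = bk$dX, logits = fwd$logits)
}

#' Integrated gradients along a straight path (generic core)
#'
#' Riemann approximation of the path integral of gradients: attribution =
#' `(x - baseline) * mean_k grad(baseline + (k/steps) (x - baseline))`,
#' `k = 1..steps`.  Exposed so that closed-form surrogates (e.g. linear
#' models) can be attributed with the identical numerical scheme.
#'
#' @param grad_fn Function taking an input shaped like `x` and returning
#'   the gradient of the scalar of interest at that input.
#' @param x Input array.
#' @param baseline Baseline array of the same shape (default zeros).
#' @param steps Number of path steps (>= 1).
#' @return Attribution array of the same shape as `x`.
#' @export
ig_path_attribution <- function(grad_fn, x, baseline = NULL, steps = 64L) {
  if (is.null(baseline)) baseline <- x * 0
  stopifnot(steps >= 1L)
  diff <- x - baseline
  gsum <- x * 0
  for (k in seq_len(steps)) {
    gsum <- gsum + grad_fn(baseline + (k / steps) * diff)
  }
  diff * (gsum / steps)
}

#' Integrated-gradients saliency for one subject (window level)
#'
#' Computes IG of the target-class logit with respect to every cell of the
#' stride-`stride` windowed view of the subject's (z-scored) time courses,
#' against an all-zero baseline by default.  The straight path is sampled
#' at `steps` points (`k/steps`, `k = 1..steps`); all path points are
#' pushed through the network in batches so the cost is `steps` forward +
#' backward passes.  Completeness — the attributions summing to
#' `F_c(x) - F_c(baseline)` — holds up to the Riemann discretization
#' error, which shrinks as `steps` grows.
#'
#' @param model Trained [milc_model].
#' @param record A [timecourse_record].
#' @param target_class Class whose logit is attributed; default the
#'   model's predicted class for this subject.
#' @param baseline `C x T` baseline matrix (default all zeros, the same
#'   non-informative value the retain-and-retrain masking uses).
#' @param steps Path steps (>= 16 recommended; default 64).
#' @param stride Downstream window stride (default 1).
#' @param normalize Z-score the record first (set `FALSE` if the data are
#'   already on the model's input scale).
#' @param path_chunk Path points evaluated per batched pass (memory knob).
#' @return A `window_saliency` object: `values` (`n_win x C x w` array of
#'   attributions), `start_indices`, `T`, `target_class`, `logit_x`,
#'   `logit_baseline`, `method`.
#' @seealso [assemble_subject_saliency()], [smoothgrad_ig()]
#' @export
integrated_gradients <- function(model, record, target_class = NULL,
                                 baseline = NULL, steps = 64L, stride = 1L,
                                 normalize = TRUE, path_chunk = 64L) {
  stopifnot(steps >= 1L)
  if (normalize) record <- normalize_timecourses(record)
  spec <- sliding_window_spec(model$config$window_length, stride)
  wt <- make_windows(record, spec)
  n_win <- dim(wt$windows)[1]

  base_rec <- record
  base_rec$data <- if (is.null(baseline)) record$data * 0 else {
    stopifnot(identical(dim(baseline), dim(record$data)))
    baseline
  }
  wt0 <- make_windows(base_rec, spec)

  if (is.null(target_class)) {
    fwd <- milc_forward_batch(model, wt$windows, n_win, keep_cache = FALSE)
    target_class <- which.max(fwd$logits[1L, ]) - 1L
  }

  diff <- wt$windows - wt0$windows
  gsum <- array(0, dim = dim(diff))
  logit_x <- NA_real_; logit_b <- NA_real_
  ks <- seq_len(steps)
  for (chunk in split(ks, ceiling(ks / path_chunk))) {
    B <- length(chunk)
    path_arr <- array(0, dim = c(B * n_win, dim(diff)[2], dim(diff)[3]))
    for (j in seq_along(chunk)) {
      path_arr[(j - 1L) * n_win + seq_len(n_win), , ] <-
        wt0$windows + (chunk[j] / steps) * diff
    }
    gr <- milc_input_gradient(model, path_arr, n_win, target_class)
    if (!all(is.finite(gr$dX))) {
      bad <- which(apply(gr$dX, 1L, function(r) any(!is.finite(r))))[1L]
      stop("non-finite gradient at window ", ((bad - 1L) %% n_win) + 1L)
    }
    for (j in seq_along(chunk)) {
      gsum <- gsum + gr$dX[(j - 1L) * n_win + seq_len(n_win), , ,
                           drop = FALSE]
    }
    if (steps %in% chunk) {
      logit_x <- gr$logits[which(chunk == steps), target_class + 1L]
    }
  }
  f0 <- milc_forward_batch(model, wt0$windows, n_win, keep_cache = FALSE)
  logit_b <- f0$logits[1L, target_class + 1L]

  structure(list(values = diff * (gsum / steps),
                 start_indices = wt$start_indices,
                 T = ncol(record$data),
                 subject_id = record$subject_id,
                 target_class = target_class,
                 logit_x = logit_x, logit_baseline = logit_b,
                 method = "IG"),
            class = "window_saliency")
}

#' Smoothgrad on integrated gradients
#'
#' Averages [integrated_gradients()] over `n_samples` noisy copies of the
#' input, `x + e` with `e ~ Normal(0, noise_sd^2)` i.i.d. per cell.  With
#' `noise_sd = 0` this reproduces plain IG exactly.
#'
#' @inheritParams integrated_gradients
#' @param noise_sd Noise standard deviation; `NULL` uses
#'   `0.1 * (max - min)` of the (z-scored) record.
#' @param n_samples Number of noisy replicates (default 25).
#' @param seed Seed for the noise draws.
#' @return A `window_saliency` object with `method = "SGIG"`.
#' @export
smoothgrad_ig <- function(model, record, target_class = NULL,
                          noise_sd = NULL, n_samples = 25L, steps = 64L,
                          stride = 1L, seed = 1L, normalize = TRUE,
                          path_chunk = 64L) {
  stopifnot(n_samples >= 1L)
  if (normalize) record <- normalize_timecourses(record)
  if (is.null(noise_sd)) {
    noise_sd <- 0.1 * (max(record$data) - min(record$data))
  }
  stopifnot(noise_sd >= 0)
  if (is.null(target_class)) {
    p <- predict(model, record, stride = stride, type = "class")
    target_class <- as.integer(p[[1L]])
  }
  if (noise_sd == 0) {
    # degenerate noise: exactly plain IG, independent of n_samples
    ig <- integrated_gradients(model, record, target_class = target_class,
                               steps = steps, stride = stride,
                               normalize = FALSE, path_chunk = path_chunk)
    ig$method <- "SGIG"
    return(ig)
  }
  noise_seeds <- derive_seeds(seed, n_samples)
  acc <- NULL
  for (s in seq_len(n_samples)) {
    noisy <- record
    if (noise_sd > 0) {
      noisy$data <- record$data +
        with_seed(noise_seeds[s],
                  matrix(stats::rnorm(length(record$data), 0, noise_sd),
                         nrow(record$data)))
    }
    ig <- integrated_gradients(model, noisy, target_class = target_class,
                               steps = steps, stride = stride,
                               normalize = FALSE, path_chunk = path_chunk)
    acc <- if (is.null(acc)) ig else {
      acc$values <- acc$values + ig$values
      acc
    }
  }
  acc$values <- acc$values / n_samples
  acc$subject_id <- record$subject_id
  acc$method <- "SGIG"
  acc
}

#' Assemble window-level attributions into a subject-level saliency map
#'
#' Each input cell `(c, t)` may fall in several overlapping windows; its
#' subject-level attribution is the mean of its attribution values across
#' all windows that contain it.  Trailing time points not covered by any
#' full window get 0 and are reported in `uncovered`.
#'
#' @param window_saliency A `window_saliency` object (or a list with
#'   `values` `n_win x C x w`, `start_indices`, `T`).
#' @return A `saliency_map`: list with `values` (`C x T` matrix),
#'   `coverage` (windows covering each time point), `uncovered` (0-based
#'   uncovered time indices), and the method/subject/target metadata.
#' @export
assemble_subject_saliency <- function(window_saliency) {
  v <- window_saliency$values
  starts <- window_saliency$start_indices
  Tn <- window_saliency$T
  n_win <- dim(v)[1]; C <- dim(v)[2]; w <- dim(v)[3]
  if (length(starts) != n_win) stop("start_indices/window count mismatch")
  total <- matrix(0, C, Tn)
  cover <- integer(Tn)
  for (j in seq_len(n_win)) {
    cols <- (starts[j] + 1L):(starts[j] + w)
    total[, cols] <- total[, cols] + v[j, , ]
    cover[cols] <- cover[cols] + 1L
  }
  vals <- total
  covered <- cover > 0L
  vals[, covered] <- sweep(total[, covered, drop = FALSE], 2L,
                           cover[covered], "/")
  vals[, !covered] <- 0
  structure(list(values = vals, coverage = cover,
                 uncovered = which(!covered) - 1L,
                 subject_id = window_saliency$subject_id %||% "",
                 target_class = window_saliency$target_class %||% NA_integer_,
                 method = window_saliency$method %||% "IG"),
            class = "saliency_map")
}

#' Random-permutation importance baseline
#'
#' Assigns importance uniformly at random: a random permutation of the
#' `C * T` input cells is the importance order (rank 1 = most important).
#' Used as the `g^R` baseline against which model-derived saliency is
#' validated.
#'
#' @param C,T Matrix dimensions.
#' @param seed Seed for the permutation.
#' @return An `importance_permutation`: list with `rank` (a `C x T`
#'   integer matrix; each of `1..C*T` appears exactly once) and `seed`.
#' @export
random_importance <- function(C, T, seed = 1L) {
  perm <- with_seed(seed, sample.int(C * T))
  rank <- matrix(0L, C, T)
  rank[perm] <- seq_len(C * T)
  structure(list(rank = rank, seed = as.integer(seed), method = "RANDOM"),
            class = "importance_permutation")
}

#' Select the top fraction of cells by signed importance
#'
#' Retains exactly `round(p * C * T)` cells: those with the largest
#' *signed* attribution values for a saliency map (strongly negative
#' attributions are never retained), or the smallest permutation ranks
#' for a random-importance baseline.  Ties are broken deterministically
#' by (component index, time index).
#'
#' @param importance A `saliency_map`, an `importance_permutation`, or a
#'   plain numeric matrix of importance values.
#' @param p Retained fraction, `0 < p <= 1` (default 0.05).
#' @return Logical `C x T` retain mask with attribute `"fraction" = p`.
#' @export
select_top_fraction <- function(importance, p = 0.05) {
  if (!(p > 0 && p <= 1)) stop("p must be in (0, 1], got ", p)
  v <- if (inherits(importance, "saliency_map")) importance$values
       else if (inherits(importance, "importance_permutation"))
         -importance$rank
       else as.matrix(importance)
  C <- nrow(v); Tn <- ncol(v)
  k <- round(p * C * Tn)
  comp <- rep(seq_len(C), times = Tn)
  tim <- rep(seq_len(Tn), each = C)
  ord <- order(-as.vector(v), comp, tim)
  mask <- matrix(FALSE, C, Tn)
  mask[ord[seq_len(k)]] <- TRUE
  attr(mask, "fraction") <- p
  mask
}
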