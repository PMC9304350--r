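# Vectorized recurrent-network primitives with explicit backward passes.
#
# Everything here operates on a batch in the leading dimension so that the
# sequential (time) loop wraps dense BLAS matrix products.  Shapes:
#   LSTM input:   array (n, d_in, T)
#   LSTM hidden:  array (n, H, T)
# Gate weight layout: Wx (d_in x 4H), Wh (H x 4H), b (4H), gate order
# input, forget, cell-candidate, output.

lstm_init <- function(d_in, H) {
  # uniform fan-in initialization, U(-1/sqrt(H), 1/sqrt(H)) as is standard
  # for recurrent layers
  s <- 1 / sqrt(H)
  list(
    Wx = matrix(stats::runif(d_in * 4 * H, -s, s), d_in, 4 * H),
    Wh = matrix(stats::runif(H * 4 * H, -s, s), H, 4 * H),
    b  = stats::runif(4 * H, -s, s)
  )
}

lstm_forward <- function(x_arr, par, keep_cache = TRUE) {
  n <- dim(x_arr)[1]; Tn <- dim(x_arr)[3]
  H <- nrow(par$Wh)
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  H_arr <- array(0, dim = c(n, H, Tn))
  cache <- if (keep_cache) {
    list(i = array(0, c(n, H, Tn)), f = array(0, c(n, H, Tn)),
         g = array(0, c(n, H, Tn)), o = array(0, c(n, H, Tn)),
         c = array(0, c(n, H, Tn)), tc = array(0, c(n, H, Tn)),
         x = x_arr, n = n, H = H, Tn = Tn)
  } else NULL
  idx_i <- 1:H; idx_f <- H + 1:H; idx_g <- 2 * H + 1:H; idx_o <- 3 * H + 1:H
  for (t in seq_len(Tn)) {
    xt <- slice3(x_arr, t)
    G <- xt %*% par$Wx + h %*% par$Wh
    G <- sweep(G, 2L, par$b, "+")
    i <- sigmoid(G[, idx_i, drop = FALSE])
    f <- sigmoid(G[, idx_f, drop = FALSE])
    g <- tanh(G[, idx_g, drop = FALSE])
    o <- sigmoid(G[, idx_o, drop = FALSE])
    cc <- f * cc + i * g
    tc <- tanh(cc)
    h <- o * tc
    H_arr[, , t] <- h
    if (keep_cache) {
      cache$i[, , t] <- i; cache$f[, , t] <- f; cache$g[, , t] <- g
      cache$o[, , t] <- o; cache$c[, , t] <- cc; cache$tc[, , t] <- tc
    }
  }
  list(H = H_arr, cache = cache)
}

lstm_backward <- function(par, cache, dH_arr) {
  n <- cache$n; H <- cache$H; Tn <- cache$Tn
  dWx <- matrix(0, nrow(par$Wx), ncol(par$Wx))
  dWh <- matrix(0, nrow(par$Wh), ncol(par$Wh))
  db <- numeric(4 * H)
  dX <- array(0, dim = dim(cache$x))
  dh_next <- matrix(0, n, H); dc_next <- matrix(0, n, H)
  for (t in rev(seq_len(Tn))) {
    dh <- slice3(dH_arr, t) + dh_next
    i <- slice3(cache$i, t); f <- slice3(cache$f, t)
    g <- slice3(cache$g, t); o <- slice3(cache$o, t)
    tc <- slice3(cache$tc, t)
    dc <- dh * o * (1 - tc^2) + dc_next
    c_prev <- if (t > 1L) slice3(cache$c, t - 1L) else matrix(0, n, H)
    di <- dc * g * i * (1 - i)
    df <- dc * c_prev * f * (1 - f)
    dg <- dc * i * (1 - g^2)
    do <- dh * tc * o * (1 - o)
    dG <- cbind(di, df, dg, do)
    xt <- slice3(cache$x, t)
    dWx <- dWx + crossprod(xt, dG)
    hp <- if (t > 1L) {
      o_p <- slice3(cache$o, t - 1L); tc_p <- slice3(cache$tc, t - 1L)
      o_p * tc_p
    } else matrix(0, n, H)
    dWh <- dWh + crossprod(hp, dG)
    db <- db + colSums(dG)
    dX[, , t] <- dG %*% t(par$Wx)
    dh_next <- dG %*% t(par$Wh)
    dc_next <- dc * f
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

# Additive attention scorer: a 2-layer feed-forward network applied to the
# concatenation of each hidden state with the final hidden state,
# score_t = w2' tanh(W1' [h_t; h_n] + b1) + b2, softmax-normalized.
attn_init <- function(H, hidden) {
  s1 <- 1 / sqrt(2 * H); s2 <- 1 / sqrt(hidden)
  list(
    W1 = matrix(stats::runif(2 * H * hidden, -s1, s1), 2 * H, hidden),
    b1 = stats::runif(hidden, -s1, s1),
    w2 = stats::runif(hidden, -s2, s2),
    b2 = stats::runif(1, -s2, s2)
  )
}

attn_forward <- function(H_arr, par, keep_cache = TRUE) {
  n <- dim(H_arr)[1]; H <- dim(H_arr)[2]; Tn <- dim(H_arr)[3]
  hn <- slice3(H_arr, Tn)
  scores <- matrix(0, n, Tn)
  U <- if (keep_cache) array(0, c(n, length(par$b1), Tn)) else NULL
  for (t in seq_len(Tn)) {
    A <- cbind(slice3(H_arr, t), hn)
    u <- tanh(sweep(A %*% par$W1, 2L, par$b1, "+"))
    scores[, t] <- u %*% par$w2 + par$b2
    if (keep_cache) U[, , t] <- u
  }
  alpha <- softmax_rows(scores)
  pooled <- matrix(0, n, H)
  for (t in seq_len(Tn)) {
    pooled <- pooled + alpha[, t] * slice3(H_arr, t)
  }
  cache <- if (keep_cache) list(H_arr = H_arr, hn = hn, U = U, alpha = alpha,
                                n = n, H = H, Tn = Tn) else NULL
  list(pooled = pooled, alpha = alpha, scores = scores, cache = cache)
}

attn_backward <- function(par, cache, dpooled) {
  n <- cache$n; H <- cache$H; Tn <- cache$Tn
  alpha <- cache$alpha
  dalpha <- matrix(0, n, Tn)
  dH_arr <- array(0, dim = dim(cache$H_arr))
  for (t in seq_len(Tn)) {
    ht <- slice3(cache$H_arr, t)
    dalpha[, t] <- rowSums(dpooled * ht)
    dH_arr[, , t] <- dH_arr[, , t] + alpha[, t] * dpooled
  }
  # softmax Jacobian
  dS <- alpha * (dalpha - rowSums(dalpha * alpha))
  dW1 <- matrix(0, nrow(par$W1), ncol(par$W1))
  db1 <- numeric(length(par$b1)); dw2 <- numeric(length(par$w2)); db2 <- 0
  dhn <- matrix(0, n, H)
  for (t in seq_len(Tn)) {
    u <- slice3(cache$U, t)
    ds <- dS[, t]
    dw2 <- dw2 + colSums(u * ds)
    db2 <- db2 + sum(ds)
    du <- (ds %o% par$w2) * (1 - u^2)
    A <- cbind(slice3(cache$H_arr, t), cache$hn)
    dW1 <- dW1 + crossprod(A, du)
    db1 <- db1 + colSums(du)
    dA <- du %*% t(par$W1)
    dH_arr[, , t] <- dH_arr[, , t] + dA[, 1:H, drop = FALSE]
    dhn <- dhn + dA[, H + 1:H, drop = FALSE]
  }
  dH_arr[, , Tn] <- dH_arr[, , Tn] + dhn
  list(dH = dH_arr, dW1 = dW1, db1 = db1, dw2 = dw2, db2 = db2)
}

# Two-layer ReLU classification head: logits = relu(c W1 + b1) W2 + b2.
head_init <- function(d_in, hidden, n_out = 2L) {
  s1 <- 1 / sqrt(d_in); s2 <- 1 / sqrt(hidden)
  list(
    W1 = matrix(stats::runif(d_in * hidden, -s1, s1), d_in, hidden),
    b1 = stats::runif(hidden, -s1, s1),
    W2 = matrix(stats::runif(hidden * n_out, -s2, s2), hidden, n_out),
    b2 = stats::runif(n_out, -s2, s2)
  )
}

head_forward <- function(cmat, par, keep_cache = TRUE) {
  a <- sweep(cmat %*% par$W1, 2L, par$b1, "+")
  r <- pmax(a, 0)
  logits <- sweep(r %*% par$W2, 2L, par$b2, "+")
  list(logits = logits,
       cache = if (keep_cache) list(cmat = cmat, a = a, r = r) else NULL)
}

head_backward <- function(par, cache, dlogits) {
  dW2 <- crossprod(cache$r, dlogits)
  db2 <- colSums(dlogits)
  dr <- dlogits %*% t(par$W2)
  da <- dr * (cache$a > 0)
  dW1 <- crossprod(cache$cmat, da)
  db1 <- colSums(da)
  dc <- da %*% t(par$W1)
  list(dc = dc, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

# ---- flat parameter utilities (for the Adam optimizer) ----

params_flatten <- function(p) {
  out <- list()
  walk <- function(x, prefix) {
    if (is.list(x)) {
      for (nm in names(x)) walk(x[[nm]], paste0(prefix, ".", nm))
    } else {
      out[[substring(prefix, 2L)]] <<- x
    }
  }
  walk(p, "")
  out
}

params_apply <- function(p, flat_fun) {
  walk <- function(x, prefix) {
    if (is.list(x)) {
      for (nm in names(x)) x[[nm]] <- walk(x[[nm]], paste0(prefix, ".", nm))
      x
    } else {
      flat_fun(substring(prefix, 2L), x)
    }
  }
  walk(p, "")
}

adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  flat <- params_flatten(params)
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0))
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  gflat <- params_flatten(grads)
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  params <- params_apply(params, function(key, val) {
    g <- gflat[[key]]
    if (is.null(g)) return(val)
    opt$m[[key]] <<- opt$beta1 * opt$m[[key]] + (1 - opt$beta1) * g
    opt$v[[key]] <<- opt$beta2 * opt$v[[key]] + (1 - opt$beta2) * g^2
    val - opt$lr * (opt$m[[key]] / bc1) /
      (sqrt(opt$v[[key]] / bc2) + opt$eps)
  })
  list(opt = opt, params = params)
}

# Elementwise sum of two congruent parameter lists.
params_add <- function(a, b) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- params_add(a[[nm]], b[[nm]])
    a
  } else a + b
}

params_scale <- function(a, s) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- params_scale(a[[nm]], s)
    a
  } else a * s
}
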