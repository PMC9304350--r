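test_that("attention weights are a probability vector and pool convexly", {
  set.seed(5)
  cfg <- tiny_config()
  m <- milc_model(cfg, seed = 9)
  h <- matrix(rnorm(30), 3, 10)
  out <- attention_pool(h, m$par$enc_attn)
  expect_true(all(out$weights >= 0))
  expect_equal(sum(out$weights), 1, tolerance = 1e-6)
  # pooled output lies in the componentwise convex hull of the states
  expect_true(all(out$pooled <= apply(h, 2, max) + 1e-12))
  expect_true(all(out$pooled >= apply(h, 2, min) - 1e-12))
  # singleton: weight 1, pooled = the state itself
  s1 <- attention_pool(h[1, , drop = FALSE], m$par$enc_attn)
  expect_equal(s1$weights, 1)
  expect_equal(s1$pooled, h[1, ])
})

test_that("equal alignment scores give uniform weights and the mean state", {
  # zero first layer makes every score equal b2 regardless of the input
  sc <- list(W1 = matrix(0, 8, 3), b1 = rep(0, 3), w2 = rnorm(3), b2 = 0.7)
  h <- matrix(rnorm(20), 5, 4)
  out <- attention_pool(h, sc)
  expect_equal(out$weights, rep(1 / 5, 5))
  expect_equal(out$pooled, colMeans(h))
})

test_that("hand-built scorer reproduces softmax([0, ln2, ln4]) = (1,2,4)/7", {
  # scorer reads only the first coordinate of h_i: score_i = 10 tanh(h_i1 / 10)
  # h_i1 chosen so that scores are exactly 0, ln 2, ln 4
  sc <- list(W1 = matrix(c(0.1, rep(0, 3)), 4, 1), b1 = 0, w2 = 10, b2 = 0)
  h1 <- 10 * atanh(c(0, log(2) / 10, log(4) / 10))
  h <- unname(cbind(h1, c(1, 2, 3)))
  out <- attention_pool(h, sc)
  expect_equal(out$scores, c(0, log(2), log(4)), tolerance = 1e-12)
  expect_equal(out$weights, c(1, 2, 4) / 7, tolerance = 1e-12)
  expect_equal(out$pooled,
               drop((c(1, 2, 4) / 7) %*% h), tolerance = 1e-12)
})

test_that("window and sequence encoders respect shapes and determinism", {
  cfg <- tiny_config(C = 6, w = 8)
  m <- milc_model(cfg, seed = 2)
  set.seed(1); win <- matrix(rnorm(48), 6, 8)
  z1 <- encode_window(win, m)
  z2 <- encode_window(win, m)
  expect_length(z1, cfg$enc_hidden)
  expect_true(all(is.finite(z1)))
  expect_identical(z1, z2)
  expect_false(isTRUE(all.equal(encode_window(win * 0, m), z1)))
  expect_error(encode_window(matrix(0, 5, 8), m), "expects")

  zs <- matrix(rnorm(5 * cfg$enc_hidden), 5)
  cc <- encode_sequence(zs, m)
  expect_length(cc, cfg$top_hidden)
  # order sensitivity of the recurrence
  expect_false(isTRUE(all.equal(encode_sequence(zs[5:1, ], m), cc)))
})

test_that("pair score is the bilinear form phi(z)' c", {
  cfg <- tiny_config()
  m <- milc_model(cfg, seed = 3)
  z <- rnorm(cfg$enc_hidden); cc <- rnorm(cfg$top_hidden)
  expect_equal(score_pair(z, cc, m),
               as.numeric(t(m$par$phi$W %*% z) %*% cc))
  expect_equal(score_pair(z, cc * 0, m), 0)
  expect_equal(score_pair(z, 3 * cc, m), 3 * score_pair(z, cc, m))
  expect_error(score_pair(z[-1], cc, m), "length")
})

test_that("classification head: hand-evaluated logits and softmax symmetry", {
  cfg <- tiny_config()
  m <- milc_model(cfg, seed = 4)
  # hand-set 2-layer head on a 2-dim embedding inside a padded c
  m$par$head <- list(W1 = matrix(0, cfg$top_hidden, 2), b1 = c(0, 0),
                     W2 = matrix(c(1, 0, 0, -1), 2, 2), b2 = c(0.5, -0.5))
  m$par$head$W1[1, 1] <- 1; m$par$head$W1[2, 2] <- 1
  cc <- rep(0, cfg$top_hidden); cc[1] <- 2; cc[2] <- -3
  # hidden = relu(c(2, -3)) = c(2, 0); logits = (2, 0) %*% W2 + b2
  expect_equal(classify_logits(cc, m), c(2.5, -0.5))
  p <- exp(c(0, 0)) / 2
  expect_equal(dynamilc:::softmax_rows(matrix(0, 1, 2))[1, ], p)
})

test_that("full forward touches every declared dimension", {
  cfg <- milc_config()   # full-scale architecture: 256/200 hidden
  m <- milc_model(cfg, seed = 1)
  rec <- tiny_record(C = 53, T = 140, seed = 10)
  wt <- make_windows(normalize_timecourses(rec), sliding_window_spec(20, 10))
  expect_equal(dim(wt$windows)[1], 13)
  z <- encode_window(wt$windows[1, , ], m)
  expect_length(z, 256)
  zs <- t(vapply(seq_len(13), function(j) encode_window(wt$windows[j, , ], m),
                 numeric(256)))
  cc <- encode_sequence(zs, m)
  expect_length(cc, 200)
  lg <- classify_logits(cc, m)
  expect_length(lg, 2)
  expect_true(all(is.finite(lg)))
})

test_that("checkpoints round-trip and reject architecture mismatches", {
  m <- milc_model(tiny_config(), seed = 11)
  f <- withr::local_tempfile(fileext = ".rds")
  save_milc_checkpoint(m, f)
  back <- load_milc_checkpoint(f, expected_config = tiny_config())
  expect_identical(back$par, m$par)
  expect_error(load_milc_checkpoint(f, expected_config = tiny_config(C = 7)),
               "mismatch")
})
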