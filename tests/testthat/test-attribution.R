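test_that("IG core is exact for linear surrogates and zero for x = baseline", {
  set.seed(21)
  w <- rnorm(12)
  grad_fn <- function(x) w          # F(x) = w . x
  x <- rnorm(12)
  expect_equal(ig_path_attribution(grad_fn, x, steps = 7), w * x,
               tolerance = 1e-12)
  expect_equal(ig_path_attribution(grad_fn, x, baseline = x, steps = 7),
               rep(0, 12))
})

test_that("model IG satisfies completeness with a shrinking Riemann gap", {
  cfg <- tiny_config(C = 6, w = 8)
  ch <- generate_cohort(cohort_spec(n_per_class = 6, C = 6, T = 24,
          event_window = c(8, 16), effect_size = 2.5, seed = 22))
  m <- milc_finetune(milc_model(cfg, seed = 23), ch$records,
         train_config(batch_size = 6, epochs = 10, learning_rate = 3e-3,
                      stride = 4, seed = 24))
  rec <- ch$records[[7]]
  gaps <- vapply(c(8, 32, 128), function(st) {
    ig <- integrated_gradients(m, rec, steps = st, stride = 4)
    abs(sum(ig$values) - (ig$logit_x - ig$logit_baseline))
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))           # monotone shrink
  ig <- integrated_gradients(m, rec, steps = 256, stride = 4)
  ref <- abs(ig$logit_x - ig$logit_baseline)
  expect_lt(abs(sum(ig$values) - ref), 0.02 * max(ref, 1e-8))
})

test_that("smoothgrad with zero noise reproduces IG bit for bit", {
  cfg <- tiny_config(C = 5, w = 6)
  m <- milc_model(cfg, seed = 31)
  rec <- tiny_record(C = 5, T = 18, seed = 32)
  ig <- integrated_gradients(m, rec, target_class = 1L, steps = 16,
                             stride = 6)
  sg <- smoothgrad_ig(m, rec, target_class = 1L, noise_sd = 0,
                      n_samples = 3, steps = 16, stride = 6, seed = 33)
  expect_identical(sg$values, ig$values)
  # seeded single-sample smoothgrad is reproducible
  s1 <- smoothgrad_ig(m, rec, target_class = 1L, noise_sd = 0.2,
                      n_samples = 1, steps = 8, stride = 6, seed = 34)
  s2 <- smoothgrad_ig(m, rec, target_class = 1L, noise_sd = 0.2,
                      n_samples = 1, steps = 8, stride = 6, seed = 34)
  expect_identical(s1$values, s2$values)
  expect_false(identical(s1$values, ig$values))
})

test_that("assembly averages overlapping windows against a brute-force counter", {
  # synthetic window attributions with known values
  C <- 3; w <- 5; T <- 12; starts <- c(0L, 2L, 4L)
  vals <- array(rnorm(3 * C * w), dim = c(3, C, w))
  ws <- list(values = vals, start_indices = starts, T = T)
  sm <- assemble_subject_saliency(ws)
  # brute force: for every cell, average over covering windows
  for (cc in 1:C) for (t in 1:T) {
    cover <- which(starts < t & t <= starts + w)
    expected <- if (length(cover)) {
      mean(vapply(cover, function(j) vals[j, cc, t - starts[j]], numeric(1)))
    } else 0
    expect_equal(sm$values[cc, t], expected, tolerance = 1e-12)
  }
  expect_equal(sm$uncovered, 9:11)    # 0-based trailing uncovered cells
  # disjoint windows: pure concatenation and total conservation
  ws2 <- list(values = vals[1:2, , ], start_indices = c(0L, 5L), T = 10L)
  sm2 <- assemble_subject_saliency(ws2)
  expect_equal(sm2$values[, 1:5], vals[1, , ])
  expect_equal(sm2$values[, 6:10], vals[2, , ])
  expect_equal(sum(sm2$values), sum(vals[1:2, , ]))
  # stride-1 coverage counts match the closed form min(t+1, w, T-t, n_win)
  rec <- tiny_record(C = 4, T = 60, seed = 41)
  m <- milc_model(tiny_config(C = 4, w = 8), seed = 42)
  ig <- integrated_gradients(m, rec, target_class = 0L, steps = 2, stride = 1)
  sm3 <- assemble_subject_saliency(ig)
  t0 <- 0:59
  expect_equal(sm3$coverage, pmin(t0 + 1, 8, 60 - t0, 53))
})

test_that("random importance is a seeded bijection with uniform ranks", {
  g1 <- random_importance(3, 4, seed = 7)
  g2 <- random_importance(3, 4, seed = 7)
  expect_identical(g1$rank, g2$rank)
  expect_setequal(as.vector(g1$rank), 1:12)
  # uniformity: each cell attains rank 1 with frequency 1/12 +- 3 se
  n <- 4000
  first <- vapply(seq_len(n), function(s)
    which(random_importance(3, 4, seed = s)$rank == 1L), integer(1))
  freq <- tabulate(first, 12) / n
  se <- sqrt((1 / 12) * (11 / 12) / n)
  expect_true(all(abs(freq - 1 / 12) < 3.5 * se))
})

test_that("top-fraction selection is exact, signed, and tie-broken deterministically", {
  v <- matrix(0, 10, 10)
  v[c(3, 15, 27, 56, 99)] <- c(5, 4, 3, 2, 1)
  v[c(1, 2)] <- c(-10, -20)
  mask <- select_top_fraction(v, 0.05)
  expect_equal(sum(mask), 5)
  expect_true(all(mask[c(3, 15, 27, 56, 99)]))
  expect_false(any(mask[c(1, 2)]))       # signed: negatives never retained
  # all-equal values: exactly the first k cells in (component, time) order
  u <- matrix(1, 4, 25)
  mu <- select_top_fraction(u, 0.05)
  expect_equal(sum(mu), 5)
  # lexicographic (component, time) tie-break: component 1, times 1..5
  expect_true(all(mu[1, 1:5]))
  expect_equal(sum(select_top_fraction(u, 1)), 100)
  expect_error(select_top_fraction(u, 0), "p must be")
  # random-permutation importance retains the smallest ranks
  g <- random_importance(4, 25, seed = 3)
  mg <- select_top_fraction(g, 0.05)
  expect_equal(sum(mg), 5)
  expect_true(all(g$rank[mg] <= 5))
})
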