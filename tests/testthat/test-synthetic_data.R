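test_that("cohorts are deterministic, labeled, and shaped as specified", {
  sp <- cohort_spec(n_per_class = 4, C = 8, T = 40, event_window = c(10, 30),
                    seed = 71)
  ch1 <- generate_cohort(sp)
  ch2 <- generate_cohort(sp)
  expect_equal(length(ch1$records), 8)
  expect_identical(lapply(ch1$records, `[[`, "data"),
                   lapply(ch2$records, `[[`, "data"))
  expect_equal(vapply(ch1$records, `[[`, 0L, "label"), rep(0:1, each = 4))
  expect_true(all(vapply(ch1$records,
                         function(r) identical(dim(r$data), c(8L, 40L)),
                         logical(1))))
  expect_error(cohort_spec(T = 40, event_window = c(30, 50)), "event_window")
})

test_that("planted connectivity matches the common-factor closed form", {
  # r = e^2 q / (1 + sigma^2 + e^2 q), q = active fraction of the driver
  es <- 1.5; sd <- 0.5
  sp <- cohort_spec(n_per_class = 60, C = 12, T = 400,
                    effect_type = "connectivity_shift",
                    affected_components = 1:5, event_window = c(100, 120),
                    effect_size = es, noise_sd = sd, seed = 72)
  ch <- generate_cohort(sp)
  y <- vapply(ch$records, `[[`, 0L, "label")
  mean_r <- function(recs, rows) {
    mean(vapply(recs, function(r) {
      fn <- compute_fnc(r)
      mean(fn[rows, rows][upper.tri(diag(length(rows)))])
    }, numeric(1)))
  }
  pat <- ch$records[y == 1]
  r_aff <- mean_r(pat, 1:5)
  r_theory <- es^2 / (1 + sd^2 + es^2)
  expect_equal(r_aff, r_theory, tolerance = 0.05)
  expect_lt(abs(mean_r(pat, 6:12)), 0.05)     # unaffected pairs ~ 0
  expect_lt(abs(mean_r(ch$records[y == 0], 1:5)), 0.05)
})

test_that("null cohorts are exchangeable and stationary", {
  sp <- cohort_spec(n_per_class = 10, C = 6, T = 600, effect_size = 0,
                    event_window = c(100, 120), noise_sd = 0.5, seed = 73)
  ch <- generate_cohort(sp)
  expect_true(all(!vapply(ch$ground_truth$masks, any, logical(1))))
  # stationary AR(1) + noise: unit latent variance + noise variance
  vars <- vapply(ch$records, function(r) mean(apply(r$data, 1, var)),
                 numeric(1))
  expect_equal(mean(vars), 1 + 0.25, tolerance = 0.05)
  expect_lt(abs(mean(vapply(ch$records, function(r) mean(r$data),
                            numeric(1)))), 0.05)
})

test_that("ground-truth masks cover the planted cells only", {
  sp <- cohort_spec(n_per_class = 3, C = 10, T = 50,
                    effect_type = "focal_event", affected_components = 2:4,
                    event_window = c(10, 30), seed = 74)
  ch <- generate_cohort(sp)
  y <- vapply(ch$records, `[[`, 0L, "label")
  m <- ch$ground_truth$masks[[which(y == 1)[1]]]
  expect_equal(sum(m), 3 * 20)
  expect_true(all(m[2:4, 11:30]))
  expect_equal(nrow(ch$ground_truth$affected_pairs), 3)
  # flat profile marks whole affected rows
  spf <- cohort_spec(n_per_class = 2, C = 10, T = 50,
                     effect_type = "focal_event", affected_components = 2:4,
                     event_window = c(10, 30), temporal_profile = "flat",
                     seed = 75)
  chf <- generate_cohort(spf)
  yf <- vapply(chf$records, `[[`, 0L, "label")
  expect_equal(sum(chf$ground_truth$masks[[which(yf == 1)[1]]]), 3 * 50)
})

test_that("spiky and flat layouts deposit equal energy, localized vs spread", {
  mk <- function(profile, seed) generate_cohort(cohort_spec(
    n_per_class = 30, C = 10, T = 200, effect_type = "focal_event",
    affected_components = 1:3, event_window = c(80, 100), effect_size = 2.5,
    noise_sd = 0.5, temporal_profile = profile, seed = seed))
  chs <- mk("spiky", 76); chp <- mk("flat", 76)
  y <- vapply(chs$records, `[[`, 0L, "label")
  vtot <- function(ch) mean(vapply(ch$records[y == 1],
    function(r) mean(apply(r$data[1:3, ], 1, var)), numeric(1)))
  expect_equal(vtot(chs), vtot(chp), tolerance = 0.12)
  # spiky: variance inside the window far exceeds outside; flat: comparable
  vwin <- function(ch) {
    mean(vapply(ch$records[y == 1], function(r)
      mean(apply(r$data[1:3, 81:100], 1, var)) /
      mean(apply(r$data[1:3, -(81:100)], 1, var)), numeric(1)))
  }
  expect_gt(vwin(chs), 2)
  expect_lt(vwin(chp), 1.5)
})

test_that("pretraining pool subjects are shaped, unlabeled and reproducible", {
  p1 <- generate_pretraining_pool(4, C = 7, T = 50, seed = 77)
  p2 <- generate_pretraining_pool(4, C = 7, T = 50, seed = 77)
  expect_identical(lapply(p1, `[[`, "data"), lapply(p2, `[[`, "data"))
  expect_true(all(vapply(p1, function(r) is.na(r$label), logical(1))))
  expect_true(all(vapply(p1, function(r)
    identical(dim(r$data), c(7L, 50L)), logical(1))))
})
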