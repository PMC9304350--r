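test_that("InfoNCE closed forms: uniform scores and saturated positives", {
  # all scores equal -> loss = N * T * log N exactly
  S <- array(0.37, dim = c(4, 3, 4))
  expect_equal(infonce_loss(S), 12 * log(4), tolerance = 1e-9)
  # saturated positives -> loss ~ 0
  S2 <- array(0, dim = c(4, 3, 4))
  for (i in 1:4) S2[i, , i] <- 50
  expect_lt(infonce_loss(S2), 1e-3)
  # N = 2, T = 1 hand arithmetic
  S3 <- array(0, dim = c(2, 1, 2))
  S3[1, 1, ] <- c(2, 0); S3[2, 1, ] <- c(1, 3)
  manual <- -(log(exp(2) / (exp(2) + exp(0))) +
              log(exp(3) / (exp(1) + exp(3))))
  expect_equal(infonce_loss(S3), manual, tolerance = 1e-12)
  expect_error(infonce_loss(array(0, dim = c(1, 3, 1))), "N >= 2")
  expect_gte(infonce_loss(array(rnorm(4 * 2 * 4), dim = c(4, 2, 4))), 0)
})

test_that("pretraining is seed-reproducible and a zero learning rate freezes the loss", {
  pool <- generate_pretraining_pool(6, C = 6, T = 40, seed = 3)
  cfg <- tiny_config(C = 6, w = 8)
  # one full batch per epoch so the in-batch negatives are constant
  tc0 <- train_config(batch_size = 6, epochs = 3, learning_rate = 0,
                      stride = 8, seed = 4, holdout_frac = 0)
  m <- milc_pretrain(milc_model(cfg, seed = 5), pool, tc0)
  expect_equal(diff(range(m$history$pretrain$loss)), 0, tolerance = 1e-9)
  tc <- train_config(batch_size = 3, epochs = 3, learning_rate = 1e-3,
                     stride = 8, seed = 4, holdout_frac = 0)
  m1 <- milc_pretrain(milc_model(cfg, seed = 5), pool, tc)
  m2 <- milc_pretrain(milc_model(cfg, seed = 5), pool, tc)
  expect_equal(tail(m1$history$pretrain$loss, 1),
               tail(m2$history$pretrain$loss, 1), tolerance = 1e-6)
})

test_that("fine-tuning fits a separable cohort and refuses single-class data", {
  ch <- generate_cohort(cohort_spec(n_per_class = 8, C = 8, T = 60,
          effect_type = "focal_event", affected_components = 1:3,
          event_window = c(20, 40), effect_size = 3, noise_sd = 0.4,
          seed = 6))
  cfg <- milc_config(input_components = 8, window_length = 10,
                     enc_hidden = 12, enc_attn_hidden = 6, top_hidden = 10,
                     top_attn_hidden = 5, head_hidden = 8)
  tc <- train_config(batch_size = 8, epochs = 25, learning_rate = 3e-3,
                     stride = 5, seed = 7)
  mt <- milc_finetune(milc_model(cfg, seed = 8), ch$records, tc)
  y <- vapply(ch$records, `[[`, 0L, "label")
  p <- predict(mt, ch$records, stride = 5, type = "prob")
  expect_gt(dynamilc:::binary_auc(y, p), 0.95)    # training separability
  # loss decreased
  expect_lt(tail(mt$history$finetune$loss, 1), mt$history$finetune$loss[1])
  expect_error(milc_finetune(milc_model(cfg, 1), ch$records[y == 1], tc),
               "single class")
})

test_that("with learning_rate = 0 fine-tuning returns the checkpoint unchanged", {
  ch <- generate_cohort(cohort_spec(n_per_class = 3, C = 6, T = 30,
          event_window = c(10, 20), seed = 9))
  cfg <- tiny_config(C = 6, w = 8)
  m0 <- milc_model(cfg, seed = 10)
  mt <- milc_finetune(m0, ch$records,
          train_config(batch_size = 3, epochs = 2, learning_rate = 0,
                       stride = 8, seed = 1))
  expect_equal(mt$par, m0$par, tolerance = 1e-12)
})

test_that("cross-validation bookkeeping: grid size, AUC range, fold partition", {
  ch <- generate_cohort(cohort_spec(n_per_class = 12, C = 6, T = 30,
          event_window = c(10, 20), effect_size = 2, seed = 12))
  cfg <- tiny_config(C = 6, w = 8)
  cv <- milc_cv(ch$records, k = 3, train_sizes = c(3, 5), repeats = 2,
                base_seed = 2, model_config = cfg,
                config = train_config(batch_size = 6, epochs = 2,
                                      learning_rate = 1e-3, stride = 8),
                modes = "scratch")
  expect_equal(nrow(cv), 3 * 2 * 2)
  expect_true(all(cv$auc >= 0 & cv$auc <= 1))
  folds <- attr(cv, "folds")
  expect_equal(sort(unique(folds)), 1:3)
  # each subject in exactly one test fold; stratified
  expect_equal(length(folds), 24)
  y <- vapply(ch$records, `[[`, 0L, "label")
  for (f in 1:3) expect_equal(sum(y[folds == f]), 4)
  # both regimes: paired per-size comparison is attached
  pool <- generate_pretraining_pool(4, C = 6, T = 30, seed = 14)
  pre <- milc_pretrain(milc_model(cfg, seed = 15), pool,
           train_config(batch_size = 4, epochs = 1, learning_rate = 1e-3,
                        stride = 8, holdout_frac = 0))
  cv2 <- milc_cv(ch$records, k = 2, train_sizes = 3L, repeats = 2,
                 base_seed = 3, model_config = cfg,
                 config = train_config(batch_size = 6, epochs = 1,
                                       learning_rate = 1e-3, stride = 8),
                 pretrained = pre, modes = c("pretrained", "scratch"))
  cmp <- attr(cv2, "mode_comparison")
  expect_equal(nrow(cmp), 1L)
  expect_named(cmp, c("train_size", "auc_pretrained", "auc_scratch",
                      "signed_rank_p"))
  expect_true(cmp$signed_rank_p >= 0 && cmp$signed_rank_p <= 1)
})

test_that("no test-fold subject influences training (leakage audit)", {
  ch <- generate_cohort(cohort_spec(n_per_class = 9, C = 6, T = 30,
          event_window = c(10, 20), seed = 13))
  cfg <- tiny_config(C = 6, w = 8)
  tc <- train_config(batch_size = 6, epochs = 2, learning_rate = 1e-3,
                     stride = 8)
  cv <- milc_cv(ch$records, k = 3, train_sizes = 4L, repeats = 2,
                base_seed = 5, model_config = cfg, config = tc,
                modes = "scratch")
  folds <- attr(cv, "folds")
  tidx <- attr(cv, "train_indices")
  for (i in seq_len(nrow(cv))) {
    expect_length(intersect(tidx[[i]], which(folds == cv$fold[i])), 0)
  }
  # functional check: corrupting test-fold data does not change training
  f <- cv$fold[1]
  recs2 <- ch$records
  for (s in which(folds == f)) recs2[[s]]$data <- recs2[[s]]$data * 100 + 7
  sub <- tidx[[1]]
  cfg_t <- tc; cfg_t$seed <- cv$seed[1]
  m_a <- milc_finetune(milc_model(cfg, seed = cv$seed[1]), ch$records[sub],
                       cfg_t)
  m_b <- milc_finetune(milc_model(cfg, seed = cv$seed[1]), recs2[sub], cfg_t)
  expect_identical(m_a$par, m_b$par)
})
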