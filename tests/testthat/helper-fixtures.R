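# Small shared fixtures, built in code at test time.

tiny_config <- function(C = 6L, w = 8L) {
  milc_config(input_components = C, window_length = w, enc_hidden = 10L,
              enc_attn_hidden = 5L, top_hidden = 8L, top_attn_hidden = 4L,
              head_hidden = 6L)
}

tiny_record <- function(C = 6L, T = 30L, seed = 1L, label = NA_integer_) {
  set.seed(seed)
  timecourse_record(paste0("t", seed), matrix(rnorm(C * T), C, T),
                    label = label)
}

# Independent 1-D earth mover oracle: greedy mass transport between two
# discrete distributions on 0..T-1 (exact for 1-D optimal transport).
emd_oracle <- function(w1, w2) {
  p <- w1 / sum(w1); q <- w2 / sum(w2)
  cost <- 0; i <- 1; j <- 1
  while (i <= length(p) && j <= length(q)) {
    m <- min(p[i], q[j])
    cost <- cost + m * abs(i - j)
    p[i] <- p[i] - m; q[j] <- q[j] - m
    if (p[i] <= 1e-15) i <- i + 1
    if (q[j] <= 1e-15) j <- j + 1
  }
  cost
}
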