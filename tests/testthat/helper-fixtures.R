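# Shared fixtures, built in code at test time.

phases <- c("exhalation", "inhalation", "nonbreathing")

# Deterministic sine clip
sine_clip <- function(freq, dur_s, rate, amp = 0.5) {
  t <- seq(0, dur_s - 1 / rate, by = 1 / rate)
  audio_clip(amp * sin(2 * pi * freq * t), rate)
}

seeded <- function(seed, expr) {
  set.seed(seed)
  force(expr)
}

# Small separable 3-class Gaussian-cluster embedding problem
gaussian_clusters <- function(n_per_class = 100, dim = 16, margin = 6,
                              noise = 1, seed = 42) {
  seeded(seed, {
    centers <- matrix(0, nrow = 3, ncol = dim)
    centers[1, 1] <- margin
    centers[2, 2] <- margin
    centers[3, 3] <- margin
    X <- do.call(rbind, lapply(1:3, function(k) {
      matrix(rnorm(n_per_class * dim, sd = noise), ncol = dim) +
        matrix(centers[k, ], n_per_class, dim, byrow = TRUE)
    }))
    y <- rep(phases, each = n_per_class)
    ord <- sample(nrow(X))
    list(x = X[ord, ], y = y[ord])
  })
}

# A tiny hand-set head for toy forward-pass checks
toy_head <- function(W1, b1, W2, b2) {
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, init_seed = 0L),
            class = "transfer_head")
}
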