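# shared fixtures and independent brute-force oracles

# random rows on the probability simplex
random_simplex <- function(n, k) {
  m <- matrix(stats::rexp(n * k), n, k)
  m / rowSums(m)
}

# tiny protocol for fast signal-path tests
tiny_protocol <- function(n_channels = 4, reps = 2, active_s = 1,
                          rest_s = 0.5) {
  session_protocol(reps_per_grip = reps, active_s = active_s,
                   rest_s = rest_s, n_channels = n_channels)
}

# exhaustive re-scoring of a pool, independent of the package's selectors
brute_scores <- function(probs, strategy) {
  vapply(seq_len(nrow(probs)), function(i) {
    p <- probs[i, ]
    switch(strategy,
           least_confidence = 1 - max(p),
           margin = {
             s <- sort(p, decreasing = TRUE)
             s[1] - s[2]
           },
           entropy = {
             q <- p[p > 0]
             -sum(q * log(q))
           })
  }, numeric(1))
}

brute_select_single <- function(probs, strategy) {
  sc <- brute_scores(probs, strategy)
  if (strategy == "margin") which.min(sc) else which.max(sc)
}

brute_select_batch <- function(probs, strategy, n) {
  sc <- brute_scores(probs, strategy)
  if (strategy == "margin") sc <- -sc
  order(-sc, seq_along(sc))[seq_len(n)]
}

# literal windowed-median/MAD Hampel, O(n * k), for small oracles
brute_hampel <- function(x, k, n_sigmas) {
  n <- length(x)
  out <- x
  for (i in seq_len(n)) {
    w <- x[max(1, i - k):min(n, i + k)]
    med <- median(w)
    mad_w <- median(abs(w - med))
    if (abs(x[i] - med) > n_sigmas * 1.4826 * mad_w) out[i] <- med
  }
  out
}

# balanced Gaussian train/test pool pair sharing class geometry
gaussian_pool_pair <- function(n_per_class = 60, separation = 3,
                               seed = 1L, n_features = 16) {
  list(T1 = generate_feature_pool(6, n_per_class, n_features, separation,
                                  seed = seed),
       T2 = generate_feature_pool(6, n_per_class, n_features, separation,
                                  seed = seed + 1000L))
}
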