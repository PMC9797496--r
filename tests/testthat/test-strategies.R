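test_that("uncertainty scores match their closed forms", {
  p <- c(0.6, 0.3, 0.1)
  expect_equal(score_least_confidence(p), 0.4)
  expect_equal(score_margin(p), 0.3)
  expect_equal(score_entropy(p), 0.8979, tolerance = 1e-4)

  onehot <- c(1, 0, 0)
  expect_equal(score_least_confidence(onehot), 0)
  expect_equal(score_margin(onehot), 1)
  expect_equal(score_entropy(onehot), 0)

  for (k in c(2, 4, 6, 9)) {
    u <- rep(1 / k, k)
    expect_equal(score_least_confidence(u), 1 - 1 / k)
    expect_equal(score_margin(u), 0)
    expect_equal(score_entropy(u), log(k))
  }

  expect_error(score_entropy(c(0.5, 0.6)), "sum to 1")
  expect_error(score_least_confidence(c(-0.1, 1.1)), "\\[0, 1\\]")
  expect_error(score_margin(matrix(1, 2, 1)), "2 classes")
})

test_that("score ranges hold on random simplex inputs", {
  set.seed(1)
  for (k in c(2, 3, 6, 10)) {
    p <- random_simplex(200, k)
    lc <- score_least_confidence(p)
    expect_true(all(lc >= 0 & lc <= 1 - 1 / k + 1e-12))
    mg <- score_margin(p)
    expect_true(all(mg >= 0 & mg <= 1))
    en <- score_entropy(p)
    expect_true(all(en >= 0 & en <= log(k) + 1e-12))
  }
})

test_that("single selection matches exhaustive scoring and tie rules", {
  set.seed(2)
  for (rep in 1:50) {
    k <- sample(2:10, 1)
    probs <- random_simplex(sample(5:200, 1), k)
    for (st in c("least_confidence", "margin", "entropy"))
      expect_identical(select_single(probs, st),
                       brute_select_single(probs, st))
  }

  # identical rows: ties broken by lowest index
  same <- random_simplex(1, 4)[rep(1, 10), ]
  for (st in c("least_confidence", "margin", "entropy"))
    expect_identical(select_single(same, st), 1L)

  # the unique uniform row dominates one-hot rows for every strategy
  pool <- diag(4)[c(1, 2, 3, 1, 4), ]
  pool <- rbind(pool, rep(0.25, 4))
  for (st in c("least_confidence", "margin", "entropy"))
    expect_identical(select_single(pool, st), 6L)

  expect_error(select_single(matrix(numeric(0), 0, 3), "entropy"),
               "exhausted")
  # the random strategy is seeded and uniform
  i1 <- select_single(random_simplex(30, 3), "random", seed = 5)
  i2 <- select_single(random_simplex(30, 3), "random", seed = 5)
  expect_identical(i1, i2)
})

test_that("naive batches are the exhaustive top-n", {
  set.seed(3)
  probs <- random_simplex(20, 5)
  for (st in c("least_confidence", "margin", "entropy")) {
    expect_identical(select_batch_naive(probs, st, 1),
                     select_single(probs, st))
    expect_identical(select_batch_naive(probs, st, 6),
                     brute_select_batch(probs, st, 6))
    expect_setequal(select_batch_naive(probs, st, 20), 1:20)
  }
  expect_error(select_batch_naive(probs, "entropy", 21), "exhausted")
})

test_that("class-constrained random batches are one-per-class and uniform", {
  labels <- rep(1:6, times = c(3, 5, 2, 8, 4, 1))
  b <- select_batch_random_constrained(labels, seed = 1)
  expect_identical(length(b), 6L)
  expect_identical(sort(unique(labels[b])), 1:6)

  # forced choice when each class has exactly one sample left
  single <- sample(1:6)
  fb <- select_batch_random_constrained(single, seed = 2)
  expect_setequal(fb, seq_along(single))

  # selection frequencies within a class are uniform (3-sigma binomial)
  n_draws <- 3000
  labs <- rep(1:2, each = 4)
  picks <- sapply(seq_len(n_draws), function(s)
    select_batch_random_constrained(labs, seed = s)[1])
  freq <- table(factor(picks, levels = 1:4))
  expected <- n_draws / 4
  tol <- 3 * sqrt(n_draws * 0.25 * 0.75)
  expect_true(all(abs(freq - expected) < tol))

  expect_error(select_batch_random_constrained(c(1, 1, 2), classes = 1:3),
               "exhausted")
  expect_warning(select_batch_random_constrained(c(1, 1, 2), classes = 1:3,
                                                 allow_partial = TRUE),
                 "short")
})

test_that("the ranked-batch score follows its closed form", {
  expect_equal(rbmal_score(u_score = 0.4, phi = 0.2, alpha = 0.5), 0.6)
  expect_equal(rbmal_score(1, 0, 1), 1)
  expect_equal(rbmal_score(0.3, 1, 1), 0)
  expect_equal(rbmal_score(0.3, 0.9, 0), 0.3)
})

test_that("rbmal ranking follows the worked similarity arithmetic", {
  # pool: A at 0 (uniform posterior), B at 10 (confident); labeled at 0.5.
  # alpha = 2/3; u after min-max: A=1, B=0
  # phi(A) = 1/(1+0.5), phi(B) = 1/(1+9.5)
  pool <- matrix(c(0, 10), ncol = 1)
  lab <- matrix(0.5, 1, 1)
  probs <- rbind(c(0.5, 0.5), c(0.9, 0.1))
  rk <- select_batch_rbmal(pool, lab, probs, batch_size = 2,
                           strategy = "least_confidence")
  a <- 2 / 3
  score_A <- a * (1 - 1 / 1.5) + (1 - a) * 1
  score_B <- a * (1 - 1 / 10.5) + (1 - a) * 0
  expect_identical(rk$indices[1], 2L)  # B wins: far from the labeled set
  expect_equal(rk$scores[1], score_B, tolerance = 1e-12)
  expect_equal(score_A, 2 / 9 + 1 / 3, tolerance = 1e-12)
})

test_that("rbmal avoids redundant near-duplicates that naive batches take", {
  feats <- rbind(c(0, 0), c(0, 0), c(3, 0), c(10, 10))
  lab <- matrix(c(2, 2), 1, 2)
  probs <- rbind(c(0.5, 0.5), c(0.5, 0.5), c(0.55, 0.45), c(0.95, 0.05))
  naive <- select_batch_naive(probs, "least_confidence", 2)
  expect_identical(naive, c(1L, 2L))  # both duplicates
  rk <- select_batch_rbmal(feats, lab, probs, 2, "least_confidence")
  expect_identical(rk$indices[1], 1L)
  expect_identical(rk$indices[2], 3L)  # the dissimilar point, not the twin
})

test_that("rbmal with an empty labeled set starts from pure uncertainty", {
  feats <- matrix(rnorm(20), 10, 2)
  probs <- random_simplex(10, 4)
  rk <- select_batch_rbmal(feats, matrix(numeric(0), 0, 2), probs, 1,
                           "entropy")
  expect_identical(rk$indices, brute_select_single(probs, "entropy"))

  expect_error(select_batch_rbmal(matrix(numeric(0), 0, 2),
                                  matrix(numeric(0), 0, 2),
                                  matrix(numeric(0), 0, 4), 3, "entropy"),
               "exhausted")
})

test_that("rbmal scores stay in [0, 1] and the batch is unique", {
  set.seed(4)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    feats <- matrix(rnorm(n * 3), n, 3)
    lab <- matrix(rnorm(15), 5, 3)
    probs <- random_simplex(n, 5)
    rk <- select_batch_rbmal(feats, lab, probs, 6, "margin")
    expect_identical(anyDuplicated(rk$indices), 0L)
    expect_true(all(rk$scores >= 0 & rk$scores <= 1 + 1e-12))
    # exhausting the pool returns everything
    full <- select_batch_rbmal(feats, lab, probs, n + 10, "margin")
    expect_setequal(full$indices, seq_len(n))
  }
})
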