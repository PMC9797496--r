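make_unbalanced_pool <- function(grip_n = 50, rest_n = 200, seed = 1) {
  classes <- c("rest", "power", "lateral", "tripod", "pointer", "open")
  labels <- c(rep(1L, rest_n), rep(2:6, each = grip_n))
  set.seed(seed)
  feats <- matrix(rnorm(length(labels) * 4), ncol = 4) + labels
  feature_pool(feats, labels, classes,
               t_start_ms = (seq_along(labels) - 1) * 50)
}

test_that("balancing under-samples rest down to the grip count", {
  pool <- make_unbalanced_pool(grip_n = 500, rest_n = 2000)
  bal <- balance_pool(pool, seed = 3)
  expect_identical(n_windows(bal), 3000L)
  expect_true(all(class_counts(bal) == 500L))
  # grip windows are untouched
  expect_identical(sum(bal$labels != 1L), sum(pool$labels != 1L))
  # seeded determinism
  bal2 <- balance_pool(pool, seed = 3)
  expect_identical(bal$meta$window_id, bal2$meta$window_id)
  expect_false(identical(bal$meta$window_id,
                         balance_pool(pool, seed = 4)$meta$window_id))
})

test_that("an already balanced pool passes through; deficits error", {
  pool <- make_unbalanced_pool(grip_n = 50, rest_n = 50)
  bal <- balance_pool(pool, seed = 1)
  expect_identical(bal$meta$window_id, pool$meta$window_id)
  small_rest <- make_unbalanced_pool(grip_n = 50, rest_n = 10)
  expect_error(balance_pool(small_rest), "cannot balance")
})

test_that("the initial split takes the chronologically first windows", {
  pool <- generate_feature_pool(6, 60, 8, 2, seed = 1)
  sp <- initial_split(pool, 50)
  expect_identical(length(sp$labeled), 300L)
  expect_identical(length(intersect(sp$labeled, sp$unlabeled)), 0L)
  expect_identical(sort(c(sp$labeled, sp$unlabeled)),
                   seq_len(n_windows(pool)))
  # shuffling the rows does not change which windows are selected
  set.seed(99)
  perm <- sample(seq_len(n_windows(pool)))
  shuffled <- pool_subset(pool, perm)
  sp2 <- initial_split(shuffled, 50)
  expect_setequal(shuffled$meta$window_id[sp2$labeled],
                  pool$meta$window_id[sp$labeled])
  # selected windows are the earliest of each class
  for (cl in 1:6) {
    rows <- which(pool$labels == cl)
    sel <- intersect(sp$labeled, rows)
    expect_true(max(pool$meta$t_start_ms[sel]) <=
                  min(pool$meta$t_start_ms[setdiff(rows, sel)]))
  }
  # exhaustion: per_class equal to the class size empties the pool
  expect_identical(length(initial_split(pool, 60)$unlabeled), 0L)
  expect_error(initial_split(pool, 61), "only")
})

test_that("the query loop conserves and never re-queries windows", {
  pools <- gaussian_pool_pair(n_per_class = 60, separation = 2, seed = 2)
  cfg <- al_config("entropy", "single", n_queries = 40,
                   initial_per_class = 50, eval_every = 10, seed = 7)
  ex <- run_active_learning(pools$T1, pools$T2, cfg)
  expect_identical(anyDuplicated(ex$queries$pool_row), 0L)
  expect_identical(nrow(ex$queries), 40L)
  # |L'| bookkeeping: 300 + t at iteration t
  expect_equal(ex$curve$n_labeled, 300 + ex$curve$iteration)
  expect_identical(length(ex$labeled), 340L)
  # conservation: the labeled set stays a duplicate-free subset of T1
  expect_identical(ex$n_pool, n_windows(pools$T1))
  expect_identical(anyDuplicated(ex$labeled), 0L)
  expect_true(all(ex$labeled %in% seq_len(ex$n_pool)))
  # queried windows never came from the initial labeled set
  sp <- initial_split(pools$T1, 50)
  expect_identical(length(intersect(ex$queries$pool_row, sp$labeled)), 0L)
  # alpha = |U| / (|U| + |L'|) decays monotonically over the run
  alpha <- (ex$n_pool - ex$curve$n_labeled) / ex$n_pool
  expect_true(all(diff(alpha) < 0))
})

test_that("batch modes grow the labeled set by batch_size per iteration", {
  pools <- gaussian_pool_pair(n_per_class = 60, separation = 2, seed = 3)
  for (setup in list(c("random", "batch"), c("margin", "batch"),
                     c("least_confidence", "rbmal"))) {
    cfg <- al_config(setup[1], setup[2], n_queries = 5, batch_size = 6,
                     eval_every = 5, seed = 1)
    ex <- run_active_learning(pools$T1, pools$T2, cfg)
    expect_equal(ex$curve$n_labeled, 300 + 6 * ex$curve$iteration)
    expect_identical(nrow(ex$queries), 30L)
    expect_identical(anyDuplicated(ex$queries$pool_row), 0L)
    if (setup[1] == "random") {
      # the constrained benchmark takes one window of every class per batch
      per_iter <- table(ex$queries$iteration, ex$queries$true_class)
      expect_true(all(per_iter == 1L))
    }
  }
})

test_that("random querying samples classes uniformly", {
  pools <- gaussian_pool_pair(n_per_class = 160, separation = 1, seed = 4)
  cfg <- al_config("random", "single", n_queries = 600,
                   initial_per_class = 50, eval_every = 600, seed = 11)
  ex <- run_active_learning(pools$T1, pools$T2, cfg)
  counts <- query_class_counts(ex)
  # multinomial 3-sigma envelope around 100 per class
  tol <- 3 * sqrt(600 * (1 / 6) * (5 / 6))
  expect_true(all(abs(counts - 100) < tol))
})

test_that("pool exhaustion truncates the run with a warning", {
  pools <- gaussian_pool_pair(n_per_class = 55, separation = 2, seed = 5)
  cfg <- al_config("margin", "single", n_queries = 50,
                   initial_per_class = 50, eval_every = 50, seed = 1)
  expect_warning(ex <- run_active_learning(pools$T1, pools$T2, cfg),
                 "exhausted")
  expect_true(ex$truncated)
  expect_identical(length(ex$labeled), n_windows(pools$T1))
})

test_that("runs are reproducible from the config seed", {
  pools <- gaussian_pool_pair(n_per_class = 55, separation = 2, seed = 6)
  cfg <- al_config("random", "single", n_queries = 20, eval_every = 20,
                   seed = 42)
  e1 <- run_active_learning(pools$T1, pools$T2, cfg)
  e2 <- run_active_learning(pools$T1, pools$T2, cfg)
  expect_identical(e1$queries$pool_row, e2$queries$pool_row)
  expect_identical(e1$curve, e2$curve)
})

test_that("summaries report checkpoints and aggregate over runs", {
  pools <- gaussian_pool_pair(n_per_class = 60, separation = 2, seed = 7)
  cfg <- al_config("entropy", "single", n_queries = 30, eval_every = 10,
                   seed = 2)
  ex <- run_active_learning(pools$T1, pools$T2, cfg)
  s <- summary(ex, checkpoints = c(30))
  expect_true(s$checkpoints$exact)
  expect_identical(s$checkpoints$accuracy,
                   ex$curve$accuracy[ex$curve$iteration == 30])
  # a missing checkpoint falls back to the nearest evaluation, flagged
  s2 <- summary(ex, checkpoints = c(14))
  expect_false(s2$checkpoints$exact)
  expect_identical(s2$checkpoints$iteration, 10L)
  expect_identical(sum(s$query_counts), 30L)

  agg <- summarize_experiments(list(ex, ex), checkpoints = c(10, 30))
  expect_identical(agg$accuracy_sd, c(0, 0))  # identical runs: zero spread
  expect_equal(agg$accuracy_mean[2],
               ex$curve$accuracy[ex$curve$iteration == 30])
})

test_that("test-session windows never influence training", {
  pools <- gaussian_pool_pair(n_per_class = 55, separation = 2, seed = 8)
  shifted <- pools$T2
  shifted$features <- shifted$features + 5  # gross drift
  cfg <- al_config("least_confidence", "single", n_queries = 10,
                   eval_every = 10, seed = 3)
  ex <- run_active_learning(pools$T1, shifted, cfg)
  # normalizer statistics come from labeled T1 rows only
  expect_equal(ex$model$center,
               colMeans(pools$T1$features[ex$labeled, ]))
  # queried window ids all belong to T1
  expect_true(all(ex$queries$pool_row <= n_windows(pools$T1)))
})
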