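#' Uncertainty scores for query selection
#'
#' Given posterior class probabilities `P(y | x)` these functions score how
#' informative annotating a sample would be:
#'
#' * `score_least_confidence()`: `1 - max_y P(y | x)`; selection takes the
#'   pool argmax.
#' * `score_margin()`: `P(y1 | x) - P(y2 | x)` for the two most probable
#'   labels; selection takes the pool argmin (small margins sit near the
#'   decision boundary).
#' * `score_entropy()`: Shannon entropy `-sum_i P(y_i|x) log P(y_i|x)`
#'   (natural log, `0 log 0 = 0`); selection takes the pool argmax.
#'
#' @param p A probability vector on the simplex, or a matrix with one such
#'   vector per row.
#' @return A numeric score per row.
#' @examples
#' score_least_confidence(c(0.6, 0.3, 0.1))  # 0.4
#' score_margin(c(0.6, 0.3, 0.1))            # 0.3
#' score_entropy(c(0.6, 0.3, 0.1))           # 0.8979 (approximately)
#' @name uncertainty_scores
NULL

#' @rdname uncertainty_scores
#' @export
score_least_confidence <- function(p) {
  p <- check_prob_matrix(p)
  1 - p[cbind(seq_len(nrow(p)), max.col(p, ties.method = "first"))]
}

#' @rdname uncertainty_scores
#' @export
score_margin <- function(p) {
  p <- check_prob_matrix(p)
  if (ncol(p) < 2L)
    stop_invalid("margin requires at least 2 classes")
  rows <- seq_len(nrow(p))
  i1 <- max.col(p, ties.method = "first")
  m1 <- p[cbind(rows, i1)]
  p[cbind(rows, i1)] <- -Inf
  m2 <- p[cbind(rows, max.col(p, ties.method = "first"))]
  m1 - m2
}

#' @rdname uncertainty_scores
#' @export
score_entropy <- function(p) {
  p <- check_prob_matrix(p)
  lp <- ifelse(p > 0, log(p), 0)
  -rowSums(p * lp)
}

# orientation helper: larger value = more uncertain, for every strategy
uncertainty_score <- function(p, strategy) {
  switch(strategy,
         least_confidence = score_least_confidence(p),
         margin = 1 - score_margin(p),
         entropy = score_entropy(p),
         stop_invalid("unknown uncertainty strategy `%s`", strategy))
}

query_strategies <- c("random", "least_confidence", "margin", "entropy")

#' Select a single query from the pool
#'
#' Applies a query strategy to the pool's posterior matrix and returns the
#' index of the sample to annotate next: the score arg-optimum for the
#' uncertainty strategies (ties broken by lowest index), or a uniform draw
#' for `"random"`.
#'
#' @param probs Posterior matrix, one row per pool sample.
#' @param strategy One of `"random"`, `"least_confidence"`, `"margin"`,
#'   `"entropy"`.
#' @param seed Optional seed for the random strategy; `NULL` uses the
#'   current RNG stream.
#' @return A single row index into `probs`.
#' @export
select_single <- function(probs, strategy = query_strategies, seed = NULL) {
  strategy <- match.arg(strategy)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  if (nrow(probs) == 0L)
    stop_invalid("unlabeled pool is exhausted")
  if (strategy == "random") {
    draw <- function() sample.int(nrow(probs), 1L)
    return(if (is.null(seed)) draw() else with_seed(seed, draw()))
  }
  which.max(uncertainty_score(probs, strategy))
}

#' Select a naive top-n batch
#'
#' The n best-scoring samples of the single-instance criterion, returned in
#' non-increasing score order (ties broken by lowest index). `n = 1` reduces
#' to [select_single()]; the random strategy draws n samples uniformly
#' without replacement.
#'
#' @inheritParams select_single
#' @param n Batch size; must not exceed the pool size.
#' @return Integer vector of n row indices.
#' @export
select_batch_naive <- function(probs, strategy = query_strategies, n,
                               seed = NULL) {
  strategy <- match.arg(strategy)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  n <- check_scalar_count(n, "n")
  if (n > nrow(probs))
    stop_invalid("batch size %d exceeds pool size %d (pool exhausted)",
                 n, nrow(probs))
  if (strategy == "random") {
    draw <- function() sample.int(nrow(probs), n)
    return(if (is.null(seed)) draw() else with_seed(seed, draw()))
  }
  u <- uncertainty_score(probs, strategy)
  order(-u, seq_along(u))[seq_len(n)]
}

#' Class-constrained random batch
#'
#' The benchmark batch sampler: one sample drawn uniformly from every class,
#' so a batch of 6 for the 5-grips-plus-rest protocol. This is the only
#' selector allowed to see the hidden true labels — it exists to give random
#' sampling an i.i.d., class-balanced footing, not as a deployable strategy.
#'
#' @param labels Hidden true class ids of the pool samples (oracle side).
#' @param classes Class ids the batch must cover; default every class
#'   present in `labels`.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @param allow_partial If `TRUE`, exhausted classes are skipped with a
#'   warning instead of raising an error.
#' @return Integer vector of row indices, one per class (in `classes`
#'   order).
#' @export
select_batch_random_constrained <- function(labels,
                                            classes = sort(unique(labels)),
                                            seed = NULL,
                                            allow_partial = FALSE) {
  labels <- as.integer(labels)
  draw <- function() {
    picks <- integer(0)
    for (cl in classes) {
      avail <- which(labels == cl)
      if (length(avail) == 0L) {
        if (allow_partial) {
          warning(sprintf("class %d exhausted; batch is short", cl),
                  call. = FALSE)
          next
        }
        stop_invalid("class %d has no unlabeled samples left (class exhausted)",
                     cl)
      }
      picks <- c(picks, avail[sample.int(length(avail), 1L)])
    }
    picks
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Ranked batch-mode score
#'
#' The per-candidate score combining exploration and exploitation:
#' `alpha * (1 - phi) + (1 - alpha) * u_score`, where `phi` is the
#' candidate's highest similarity to the expected training set, `u_score`
#' its normalized uncertainty, and `alpha = |U| / (|U| + |L'|)` the
#' pool-depletion weight.
#'
#' @param u_score Normalized uncertainty in \[0, 1\].
#' @param phi Similarity to the expected training set, in \[0, 1\].
#' @param alpha Exploration/exploitation weight in \[0, 1\].
#' @return The ranking score, in \[0, 1\] when the inputs are.
#' @examples
#' rbmal_score(u_score = 0.4, phi = 0.2, alpha = 0.5)  # 0.6
#' @export
rbmal_score <- function(u_score, phi, alpha) {
  alpha * (1 - phi) + (1 - alpha) * u_score
}

#' Ranked batch-mode active learning (RBMAL) selection
#'
#' Builds an optimized ranked batch Q greedily. At each step the candidate
#' score is [rbmal_score()] with: `u_score` the min-max-normalized
#' uncertainty of the configured base strategy over the current pool; `phi`
#' the candidate's maximum similarity `1 / (1 + d)` (Euclidean `d`) to the
#' expected training set `D_estimate` = labeled samples plus the batch
#' chosen so far; and `alpha = |U| / (|U| + |L'|)` recomputed as the pool
#' shrinks and `L'` grows. The arg-max candidate joins Q and leaves U, until
#' Q reaches `batch_size` or U is empty.
#'
#' With an empty labeled set and empty Q, `phi` is 0 for every candidate and
#' the first step's scores tie at `alpha`; ties are broken by higher raw
#' uncertainty, then by lowest index, so the first pick falls back to pure
#' uncertainty sampling.
#'
#' Similarities are meaningful on a common feature scale: pass features
#' already z-scored with the current training statistics.
#'
#' @param pool_features Normalized feature matrix of the unlabeled pool.
#' @param labeled_features Normalized feature matrix of the labeled set
#'   (0-row matrix allowed).
#' @param probs Posterior matrix for the pool rows.
#' @param batch_size Maximum ranking length `|Q|`.
#' @param strategy Base uncertainty strategy for `u_score`.
#' @return An object of class `query_ranking`: list with `indices` (pool row
#'   indices in rank order) and `scores` (the score each sample was selected
#'   at).
#' @export
select_batch_rbmal <- function(pool_features, labeled_features, probs,
                               batch_size,
                               strategy = c("least_confidence", "margin",
                                            "entropy")) {
  strategy <- match.arg(strategy)
  pool_features <- as.matrix(pool_features)
  labeled_features <- as.matrix(labeled_features)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  n_pool <- nrow(pool_features)
  if (n_pool == 0L)
    stop_invalid("unlabeled pool is exhausted")
  if (nrow(probs) != n_pool)
    stop_invalid("`probs` must have one row per pool sample")
  batch_size <- check_scalar_count(batch_size, "batch_size")

  u_raw <- uncertainty_score(probs, strategy)
  rng <- range(u_raw)
  u <- if (diff(rng) > 0) (u_raw - rng[1L]) / diff(rng) else
    rep(0, n_pool)  # degenerate pool: uncertainty carries no signal

  sim_to <- function(x, m) {
    # max similarity 1/(1+d) of each row of x to the rows of m
    if (nrow(m) == 0L) return(rep(0, nrow(x)))
    d2 <- outer(rowSums(x^2), rowSums(m^2), "+") - 2 * tcrossprod(x, m)
    1 / (1 + sqrt(pmax(apply(d2, 1L, min), 0)))
  }

  n_labeled <- nrow(labeled_features)
  phi <- sim_to(pool_features, labeled_features)
  remaining <- seq_len(n_pool)
  picked <- integer(0)
  picked_scores <- numeric(0)

  while (length(picked) < batch_size && length(remaining) > 0L) {
    n_u <- length(remaining)
    n_lp <- n_labeled + length(picked)
    alpha <- n_u / (n_u + n_lp)
    sc <- rbmal_score(u[remaining], phi[remaining], alpha)
    best <- order(-sc, -u_raw[remaining], remaining)[1L]
    idx <- remaining[best]
    picked <- c(picked, idx)
    picked_scores <- c(picked_scores, sc[best])
    remaining <- remaining[-best]
    if (length(remaining) > 0L) {
      d2 <- rowSums(sweep(pool_features[remaining, , drop = FALSE], 2L,
                          pool_features[idx, ])^2)
      phi[remaining] <- pmax(phi[remaining], 1 / (1 + sqrt(pmax(d2, 0))))
    }
  }
  structure(list(indices = picked, scores = picked_scores,
                 batch_size = batch_size, strategy = strategy),
            class = "query_ranking")
}

#' @export
print.query_ranking <- function(x, ...) {
  cat(sprintf("RBMAL ranking (%s): %d of max %d samples\n",
              x$strategy, length(x$indices), x$batch_size))
  print(data.frame(rank = seq_along(x$indices), index = x$indices,
                   score = x$scores))
  invisible(x)
}
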