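#' Active-learning experiment configuration
#'
#' Collects every knob of the query-annotate-retrain-evaluate loop. Defaults
#' follow the offline recalibration design: an initial labeled set of 50
#' windows per class, 1,500 single-instance queries (or 250 batches of 6,
#' the same annotation budget), a fresh z-score + LDA fit at every
#' iteration, and a full test-session evaluation after every query.
#'
#' @param strategy Query strategy: `"random"`, `"least_confidence"`,
#'   `"margin"`, or `"entropy"`.
#' @param mode `"single"` (one query per iteration), `"batch"` (naive top-n;
#'   random uses the class-constrained benchmark batch), or `"rbmal"`
#'   (ranked batch-mode).
#' @param n_queries Number of iterations; default 1500 in single mode, 250
#'   in the batch modes.
#' @param batch_size Samples per batch in the batch modes (default 6, one
#'   per class of the 5-grips-plus-rest protocol).
#' @param initial_per_class Windows per class in the initial labeled set.
#' @param shrinkage LDA covariance shrinkage passed to [fit_decoder()].
#' @param eval_every Iterations between test evaluations.
#' @param seed Seed for every random draw inside the run.
#' @return An object of class `al_config`.
#' @export
al_config <- function(strategy = c("random", "least_confidence", "margin",
                                   "entropy"),
                      mode = c("single", "batch", "rbmal"),
                      n_queries = NULL, batch_size = 6,
                      initial_per_class = 50, shrinkage = 0,
                      eval_every = 1, seed = 1L) {
  strategy <- match.arg(strategy)
  mode <- match.arg(mode)
  if (is.null(n_queries)) n_queries <- if (mode == "single") 1500L else 250L
  n_queries <- check_scalar_count(n_queries, "n_queries")
  batch_size <- check_scalar_count(batch_size, "batch_size")
  initial_per_class <- check_scalar_count(initial_per_class,
                                          "initial_per_class", min = 2L)
  eval_every <- check_scalar_count(eval_every, "eval_every")
  if (mode == "rbmal" && strategy == "random")
    stop_invalid("rbmal mode needs an uncertainty base strategy")
  structure(
    list(strategy = strategy, mode = mode, n_queries = n_queries,
         batch_size = batch_size, initial_per_class = initial_per_class,
         shrinkage = shrinkage, eval_every = eval_every,
         seed = as.integer(seed),
         queries_per_iteration = if (mode == "single") 1L else batch_size,
         total_queries = n_queries *
           (if (mode == "single") 1L else batch_size)),
    class = "al_config")
}

#' @export
print.al_config <- function(x, ...) {
  cat(sprintf("AL config: %s / %s, %d iterations (%d samples), init %d/class, seed %d\n",
              x$strategy, x$mode, x$n_queries, x$total_queries,
              x$initial_per_class, x$seed))
  invisible(x)
}

#' Balance a pool by under-sampling the rest class
#'
#' The rest class appears between every pair of grip repetitions and so
#' dominates the pool; this removes a seeded uniform subsample of rest
#' windows until rest matches the (common) grip-class count. Grip windows
#' are never touched. If grip classes are unequal the pool cannot be fully
#' balanced by removing rest alone; rest is then matched to the largest grip
#' class and a warning is raised.
#'
#' @param pool A [feature_pool()] containing a `"rest"` class.
#' @param seed Seed for the rest subsample.
#' @return A balanced [feature_pool()] with rows in their original order.
#' @export
balance_pool <- function(pool, seed = 1L) {
  stopifnot(inherits(pool, "feature_pool"))
  rest_id <- match("rest", pool$class_names)
  if (is.na(rest_id))
    stop_invalid("pool has no \"rest\" class")
  counts <- class_counts(pool)
  grip_counts <- counts[-rest_id]
  target <- max(grip_counts)
  if (counts[rest_id] < target)
    stop_invalid("rest class (%d windows) is smaller than the largest grip class (%d); cannot balance",
                 counts[rest_id], target)
  # an off-by-one spread is expected from windows clipped at the recording
  # edges; anything larger signals a genuinely lopsided pool
  if (diff(range(grip_counts)) > 1L)
    warning("grip classes are unequal; only rest is under-sampled",
            call. = FALSE)
  rest_rows <- which(pool$labels == rest_id)
  keep_rest <- if (counts[rest_id] == target) rest_rows else
    with_seed(seed, sort(sample(rest_rows, target)))
  keep <- sort(c(which(pool$labels != rest_id), keep_rest))
  pool_subset(pool, keep)
}

#' Chronological initial split
#'
#' Forms the initial labeled set from the chronologically first `per_class`
#' windows of every class (by window start time, ties by window id) —
#' mimicking a user annotating the start of each cue — and leaves everything
#' else as the unlabeled pool.
#'
#' @param pool A [feature_pool()] (the training-session pool).
#' @param per_class Windows per class to label initially.
#' @return A list with integer row-index vectors `labeled` and `unlabeled`.
#' @export
initial_split <- function(pool, per_class = 50) {
  stopifnot(inherits(pool, "feature_pool"))
  per_class <- check_scalar_count(per_class, "per_class")
  classes <- sort(unique(pool$labels))
  labeled <- integer(0)
  for (cl in classes) {
    rows <- which(pool$labels == cl)
    if (length(rows) < per_class)
      stop_invalid("class %s has only %d windows (< %d)",
                   pool$class_names[cl], length(rows), per_class)
    ord <- rows[order(pool$meta$t_start_ms[rows], pool$meta$window_id[rows])]
    labeled <- c(labeled, ord[seq_len(per_class)])
  }
  labeled <- sort(labeled)
  list(labeled = labeled,
       unlabeled = setdiff(seq_len(n_windows(pool)), labeled))
}

#' Run the active-learning recalibration experiment
#'
#' The core loop: starting from the chronological initial labeled set of the
#' training-session pool, each iteration (1) z-scores the current labeled
#' set and fits the LDA decoder on it, (2) computes posteriors over the
#' unlabeled pool, (3) selects one sample (single mode) or a batch to query,
#' (4) reveals the hidden true labels (the simulated annotator) and moves
#' the samples from the pool into the labeled set, then (5) refits and, on
#' evaluation iterations, scores the decoder on the full test-session pool.
#' The strategies never see the hidden pool labels; the class-constrained
#' random batch benchmark is the one flagged exception.
#'
#' @param pool_t1 Training-session [feature_pool()] (balanced; supplies the
#'   initial set and the unlabeled pool).
#' @param pool_t2 Test-session [feature_pool()] with the same features and
#'   classes.
#' @param config An [al_config()].
#' @return An object of class `al_experiment` with elements:
#'   \describe{
#'     \item{curve}{data frame of evaluations: `iteration`, `n_labeled`,
#'       `accuracy`, `f1_avg`, and one `f1_<class>` column per class.}
#'     \item{queries}{per-query log: `iteration`, `pool_row`, `window_id`,
#'       `score`, `true_class`.}
#'     \item{config, labeled, model}{final labeled row indices and decoder.}
#'     \item{truncated}{`TRUE` if the pool ran out before `n_queries`.}
#'   }
#' @seealso [summary.al_experiment()], [plot.al_experiment()]
#' @export
run_active_learning <- function(pool_t1, pool_t2, config = al_config()) {
  stopifnot(inherits(pool_t1, "feature_pool"),
            inherits(pool_t2, "feature_pool"),
            inherits(config, "al_config"))
  if (ncol(pool_t1$features) != ncol(pool_t2$features))
    stop_invalid("T1 and T2 pools have different feature dimensions")
  if (!identical(pool_t1$class_names, pool_t2$class_names))
    stop_invalid("T1 and T2 pools have different class dictionaries")

  split <- initial_split(pool_t1, config$initial_per_class)
  lab <- split$labeled
  unl <- split$unlabeled
  n_classes <- length(pool_t1$class_names)

  fit_now <- function()
    fit_decoder(pool_t1$features[lab, , drop = FALSE], pool_t1$labels[lab],
                shrinkage = config$shrinkage,
                class_names = pool_t1$class_names)

  eval_rows <- list()
  query_rows <- list()
  record_eval <- function(iter, model) {
    ev <- evaluate_decoder(model, pool_t2)
    row <- data.frame(iteration = iter, n_labeled = length(lab),
                      accuracy = ev$accuracy, f1_avg = ev$f1_avg)
    f1 <- as.list(ev$per_class_f1)
    names(f1) <- paste0("f1_", names(ev$per_class_f1))
    eval_rows[[length(eval_rows) + 1L]] <<- cbind(row, as.data.frame(f1))
  }

  truncated <- FALSE
  model <- NULL
  # with_seed evaluates this block in the current frame, so plain `<-`
  # updates the loop state directly
  with_seed(config$seed, {
    model <- fit_now()
    record_eval(0L, model)
    for (t in seq_len(config$n_queries)) {
      if (length(unl) == 0L) {
        warning(sprintf("pool exhausted after %d of %d iterations", t - 1L,
                        config$n_queries), call. = FALSE)
        truncated <- TRUE
        break
      }
      probs <- predict(model, pool_t1$features[unl, , drop = FALSE],
                       type = "prob")
      scores <- rep(NA_real_, 1L)
      if (config$mode == "single") {
        if (config$strategy == "random") {
          chosen <- select_single(probs, "random")
          scores <- NA_real_
        } else {
          u <- uncertainty_score(probs, config$strategy)
          chosen <- which.max(u)   # = select_single(), scored once
          scores <- u[chosen]
        }
      } else if (config$mode == "batch") {
        if (config$strategy == "random") {
          chosen <- select_batch_random_constrained(
            pool_t1$labels[unl], classes = seq_len(n_classes),
            allow_partial = TRUE)
          scores <- rep(NA_real_, length(chosen))
        } else {
          nb <- min(config$batch_size, length(unl))
          chosen <- select_batch_naive(probs, config$strategy, nb)
          scores <- uncertainty_score(probs, config$strategy)[chosen]
        }
      } else { # rbmal
        zf_pool <- decoder_normalize(model,
                                     pool_t1$features[unl, , drop = FALSE])
        zf_lab <- decoder_normalize(model,
                                    pool_t1$features[lab, , drop = FALSE])
        rk <- select_batch_rbmal(zf_pool, zf_lab, probs, config$batch_size,
                                 strategy = config$strategy)
        chosen <- rk$indices
        scores <- rk$scores
      }
      query_rows[[t]] <- data.frame(
        iteration = t,
        pool_row = unl[chosen],
        window_id = pool_t1$meta$window_id[unl[chosen]],
        score = scores,
        true_class = pool_t1$class_names[pool_t1$labels[unl[chosen]]])
      # the oracle reveals the true labels; move U -> L'
      lab <- c(lab, unl[chosen])
      unl <- unl[-chosen]
      model <- fit_now()
      if (t %% config$eval_every == 0L || t == config$n_queries ||
          length(unl) == 0L)
        record_eval(t, model)
    }
  })

  structure(
    list(curve = do.call(rbind, eval_rows),
         queries = do.call(rbind, query_rows),
         config = config, labeled = lab,
         class_names = pool_t1$class_names,
         n_pool = n_windows(pool_t1), n_test = n_windows(pool_t2),
         model = model, truncated = truncated),
    class = "al_experiment")
}

#' @export
print.al_experiment <- function(x, ...) {
  last <- x$curve[nrow(x$curve), ]
  cat(sprintf("Active-learning run: %s / %s\n", x$config$strategy,
              x$config$mode))
  cat(sprintf("  %d iterations, labeled %d -> %d of %d pool windows\n",
              max(x$curve$iteration),
              x$curve$n_labeled[1L], last$n_labeled, x$n_pool))
  cat(sprintf("  test accuracy %.4f -> %.4f, f1_avg %.4f -> %.4f\n",
              x$curve$accuracy[1L], last$accuracy,
              x$curve$f1_avg[1L], last$f1_avg))
  if (x$truncated) cat("  (pool exhausted before the requested budget)\n")
  invisible(x)
}

#' Per-class query counts
#'
#' How many annotations each class received over the run — the class-wise
#' demand profile of a query strategy.
#'
#' @param x An `al_experiment`.
#' @return Named integer vector over all classes.
#' @export
query_class_counts <- function(x) {
  stopifnot(inherits(x, "al_experiment"))
  tab <- table(factor(x$queries$true_class, levels = x$class_names))
  stats::setNames(as.integer(tab), names(tab))
}

#' Summarize a run at annotation-budget checkpoints
#'
#' Reports accuracy and averaged F1 at the requested query checkpoints
#' (default 200 and the final iteration), substituting the nearest recorded
#' evaluation (flagged in the `exact` column) when a checkpoint was not
#' evaluated, plus the per-class query counts.
#'
#' @param object An `al_experiment`.
#' @param checkpoints Iteration numbers to report.
#' @param ... Unused.
#' @return An object of class `summary.al_experiment` with a `checkpoints`
#'   data frame and `query_counts`.
#' @export
summary.al_experiment <- function(object,
                                  checkpoints = c(200L,
                                                  max(object$curve$iteration)),
                                  ...) {
  rows <- lapply(unique(checkpoints), function(cp) {
    i <- which.min(abs(object$curve$iteration - cp))
    data.frame(checkpoint = cp,
               iteration = object$curve$iteration[i],
               exact = object$curve$iteration[i] == cp,
               n_labeled = object$curve$n_labeled[i],
               accuracy = object$curve$accuracy[i],
               f1_avg = object$curve$f1_avg[i])
  })
  structure(list(strategy = object$config$strategy,
                 mode = object$config$mode,
                 checkpoints = do.call(rbind, rows),
                 query_counts = query_class_counts(object)),
            class = "summary.al_experiment")
}

#' @export
print.summary.al_experiment <- function(x, ...) {
  cat(sprintf("Summary of %s / %s run\n", x$strategy, x$mode))
  print(x$checkpoints, row.names = FALSE)
  cat("queries per class:\n")
  print(x$query_counts)
  invisible(x)
}

#' Learning-curve plot
#'
#' Test accuracy (solid) and per-class-averaged F1 (dashed) against the
#' number of query iterations.
#'
#' @param x An `al_experiment`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.al_experiment <- function(x, ...) {
  graphics::plot(x$curve$iteration, x$curve$accuracy, type = "l",
                 xlab = "query iteration", ylab = "test performance",
                 ylim = range(c(x$curve$accuracy, x$curve$f1_avg)),
                 main = sprintf("%s / %s", x$config$strategy, x$config$mode),
                 ...)
  graphics::lines(x$curve$iteration, x$curve$f1_avg, lty = 2)
  graphics::legend("bottomright", c("accuracy", "f1_avg"), lty = 1:2,
                   bty = "n")
  invisible(x)
}

#' @export
predict.al_experiment <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

#' Aggregate several seeded runs at checkpoints
#'
#' Means and (n-1)-denominator standard deviations of accuracy and averaged
#' F1 across a list of runs of the same configuration, at the requested
#' checkpoints.
#'
#' @param runs List of `al_experiment` objects.
#' @param checkpoints Iteration checkpoints (default 200 and the shortest
#'   run's final iteration).
#' @return Data frame with one row per checkpoint: mean/sd accuracy and
#'   f1_avg, and the number of runs.
#' @export
summarize_experiments <- function(runs, checkpoints = NULL) {
  stopifnot(length(runs) >= 1L,
            all(vapply(runs, inherits, logical(1), "al_experiment")))
  if (is.null(checkpoints))
    checkpoints <- c(200L, min(vapply(runs, function(r)
      max(r$curve$iteration), numeric(1))))
  do.call(rbind, lapply(unique(checkpoints), function(cp) {
    vals <- vapply(runs, function(r) {
      i <- which.min(abs(r$curve$iteration - cp))
      c(r$curve$accuracy[i], r$curve$f1_avg[i])
    }, numeric(2))
    data.frame(checkpoint = cp, n_runs = length(runs),
               accuracy_mean = mean(vals[1L, ]),
               accuracy_sd = if (length(runs) > 1L) sd(vals[1L, ]) else 0,
               f1_avg_mean = mean(vals[2L, ]),
               f1_avg_sd = if (length(runs) > 1L) sd(vals[2L, ]) else 0)
  }))
}

#' Simulated-subject pools, end to end
#'
#' Runs the full data path for one simulated subject: generate the drifted
#' two-session recordings, condition them, extract waveform-length features,
#' and balance each session's pool by rest under-sampling. This is the
#' standard entry point for experiments on synthetic data.
#'
#' @inheritParams generate_subject_sessions
#' @param spec A [window_spec()] resolved at the protocol rate.
#' @param preprocess If `TRUE` (default) condition the recordings with
#'   [preprocess_recording()] before feature extraction.
#' @return A list with balanced `T1` and `T2` [feature_pool()]s.
#' @export
make_subject_pools <- function(protocol = session_protocol(),
                               class_snr = NULL, seed = 1L, drift = NULL,
                               spec = window_spec(fs_hz = protocol$fs_hz),
                               preprocess = TRUE, ...) {
  recs <- generate_subject_sessions(protocol, class_snr, seed, drift, ...)
  pools <- lapply(recs, function(r) {
    if (preprocess) r <- preprocess_recording(r, fs_target = spec$fs_hz)
    extract_features(r, spec)
  })
  list(T1 = balance_pool(pools$T1, seed = seed),
       T2 = balance_pool(pools$T2, seed = seed + 1L))
}
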