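#' Fit the grip decoder (z-score normalizer + LDA)
#'
#' Fits the two-stage decoder used at every recalibration iteration: a
#' z-score normalizer learned from the training set only, followed by linear
#' discriminant analysis — Gaussian class-conditional densities with class
#' means, a pooled covariance, and class-frequency priors — on the
#' normalized features. Posterior class probabilities come from the Gaussian
#' model and drive the uncertainty-based query strategies.
#'
#' The pooled covariance can be shrunk toward a scaled identity,
#' `(1 - s) * S + s * mean(diag(S)) * I`. With `shrinkage = 0` and a singular
#' covariance (possible at small n relative to the feature dimension) the
#' smallest power-of-ten shrinkage that restores positive definiteness is
#' applied automatically and reported via a message.
#'
#' @param features Numeric training matrix, samples x features.
#' @param labels Integer class ids, one per row; at least 2 classes, each
#'   with at least 2 samples.
#' @param shrinkage Shrinkage intensity in \[0, 1\].
#' @param class_names Optional class dictionary (names the posterior
#'   columns).
#' @return An object of class `emg_decoder`.
#' @seealso [predict.emg_decoder()], [evaluate_decoder()]
#' @export
fit_decoder <- function(features, labels, shrinkage = 0, class_names = NULL) {
  features <- as.matrix(features)
  if (!is.numeric(features) || any(!is.finite(features)))
    stop_invalid("`features` must be a finite numeric matrix")
  labels <- as.integer(labels)
  if (length(labels) != nrow(features))
    stop_invalid("`labels` must match the number of feature rows")
  if (length(shrinkage) != 1L || !is.finite(shrinkage) ||
      shrinkage < 0 || shrinkage > 1)
    stop_invalid("`shrinkage` must be a single value in [0, 1]")
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop_invalid("at least 2 classes are required")
  tab <- table(labels)
  if (any(tab < 2L))
    stop_invalid("every class needs >= 2 training samples (degenerate class)")

  center <- colMeans(features)
  scale_ <- apply(features, 2L, sd)
  if (any(scale_ <= 0))
    stop_invalid("zero-variance feature(s): %s",
                 paste(which(scale_ <= 0), collapse = ", "))
  z <- sweep(sweep(features, 2L, center), 2L, scale_, "/")

  k <- length(classes)
  p <- ncol(z)
  n <- nrow(z)
  means <- matrix(0, k, p)
  centered <- z
  for (i in seq_len(k)) {
    rows <- labels == classes[i]
    means[i, ] <- colMeans(z[rows, , drop = FALSE])
    centered[rows, ] <- sweep(z[rows, , drop = FALSE], 2L, means[i, ])
  }
  cov_pooled <- crossprod(centered) / (n - k)
  priors <- as.numeric(tab[match(classes, as.integer(names(tab)))]) / n

  shrink_used <- shrinkage
  target <- mean(diag(cov_pooled)) * diag(p)
  regularize <- function(s) (1 - s) * cov_pooled + s * target
  cov_reg <- regularize(shrink_used)
  usable <- function(m) {
    ch <- tryCatch(chol(m), error = function(e) NULL)
    # chol can numerically succeed on a rank-deficient matrix; insist on a
    # workable condition number as well
    if (!is.null(ch) && rcond(m) > 1e-10) ch else NULL
  }
  ch <- usable(cov_reg)
  if (is.null(ch)) {
    for (s in 10^seq(-4, 0)) {
      cand <- max(shrinkage, s)
      ch <- usable(regularize(cand))
      if (!is.null(ch)) { shrink_used <- cand; cov_reg <- regularize(cand); break }
    }
    if (is.null(ch))
      stop_invalid("pooled covariance could not be regularized")
    message(sprintf("fit_decoder: covariance singular, shrinkage %g applied",
                    shrink_used))
  }
  cov_inv <- chol2inv(ch)

  if (is.null(class_names)) class_names <- paste0("class", seq_len(max(classes)))
  structure(
    list(center = center, scale = scale_, means = means,
         cov = cov_reg, cov_inv = cov_inv,
         priors = priors, classes = classes,
         class_names = class_names, shrinkage = shrink_used,
         n_train = n),
    class = "emg_decoder")
}

#' @export
print.emg_decoder <- function(x, ...) {
  cat(sprintf("EMG grip decoder (LDA): %d classes, %d features, n = %d\n",
              length(x$classes), length(x$center), x$n_train))
  cat("  classes:", paste(x$class_names[x$classes], collapse = ", "), "\n")
  if (x$shrinkage > 0)
    cat(sprintf("  covariance shrinkage: %g\n", x$shrinkage))
  invisible(x)
}

#' @export
coef.emg_decoder <- function(object, ...) {
  # linear discriminant weights: W[, k] and intercept b[k] of
  # delta_k(z) = z' W[, k] + b[k] + log prior_k
  w <- object$cov_inv %*% t(object$means)
  b <- -0.5 * colSums(t(object$means) * w) + log(object$priors)
  colnames(w) <- object$class_names[object$classes]
  names(b) <- colnames(w)
  list(weights = w, intercepts = b)
}

# apply the fitted z-score normalizer
decoder_normalize <- function(object, features) {
  features <- as.matrix(features)
  if (ncol(features) != length(object$center))
    stop_invalid("feature dimension mismatch: %d != %d",
                 ncol(features), length(object$center))
  sweep(sweep(features, 2L, object$center), 2L, object$scale, "/")
}

#' Decoder predictions and class posteriors
#'
#' Transforms `newdata` with the training-set normalizer and evaluates the
#' Gaussian-LDA posteriors `P(y | x)`; rows sum to 1 and the predicted class
#' is the posterior argmax.
#'
#' @param object An `emg_decoder`.
#' @param newdata Feature matrix (raw scale; normalization is applied
#'   internally with the training statistics).
#' @param type `"class"` for predicted class ids, `"prob"` for the posterior
#'   matrix (one column per fitted class).
#' @param ... Unused.
#' @return Integer class ids or a posterior probability matrix.
#' @export
predict.emg_decoder <- function(object, newdata, type = c("class", "prob"),
                                ...) {
  type <- match.arg(type)
  z <- decoder_normalize(object, newdata)
  w <- object$cov_inv %*% t(object$means)              # p x k
  b <- -0.5 * colSums(t(object$means) * w) + log(object$priors)
  disc <- z %*% w + rep(b, each = nrow(z))             # n x k
  if (type == "class")
    return(object$classes[max.col(disc, ties.method = "first")])
  disc <- disc - apply(disc, 1L, max)
  post <- exp(disc)
  post <- post / rowSums(post)
  colnames(post) <- object$class_names[object$classes]
  post
}

#' Evaluate a decoder on a test pool
#'
#' Computes window classification accuracy and the per-class-averaged
#' F1-score: F1 is computed per class in a one-vs-all scheme and averaged
#' unweighted across the fitted classes. A class with no true members and no
#' predictions has an undefined F1; it is scored 0 and reported via a
#' message.
#'
#' @param object An `emg_decoder`.
#' @param pool A [feature_pool()] whose labels all index fitted classes.
#' @return A list with `accuracy`, `f1_avg`, and named `per_class_f1`.
#' @export
evaluate_decoder <- function(object, pool) {
  stopifnot(inherits(object, "emg_decoder"), inherits(pool, "feature_pool"))
  if (n_windows(pool) == 0L)
    stop_invalid("test pool is empty")
  if (!all(pool$labels %in% object$classes))
    stop_invalid("test pool contains labels outside the fitted classes")
  pred <- predict(object, pool$features, type = "class")
  truth <- pool$labels
  acc <- mean(pred == truth)
  f1 <- vapply(object$classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    denom <- 2 * tp + fp + fn
    if (denom == 0) NA_real_ else 2 * tp / denom
  }, numeric(1))
  names(f1) <- object$class_names[object$classes]
  if (anyNA(f1)) {
    message("evaluate_decoder: undefined F1 scored as 0 for: ",
            paste(names(f1)[is.na(f1)], collapse = ", "))
    f1[is.na(f1)] <- 0
  }
  list(accuracy = acc, f1_avg = mean(f1), per_class_f1 = f1)
}

#' Serialize / restore a decoder as JSON
#'
#' Stores the normalizer statistics, class means, regularized pooled
#' covariance, priors and class dictionary, so experiment state can be
#' checkpointed as plain text.
#'
#' @param object An `emg_decoder`.
#' @param path JSON file path.
#' @return `write_decoder()` returns `path` invisibly; `read_decoder()`
#'   returns an `emg_decoder`.
#' @export
write_decoder <- function(object, path) {
  stopifnot(inherits(object, "emg_decoder"))
  payload <- list(format = "emgal-decoder-v1",
                  center = object$center, scale = object$scale,
                  means = object$means, cov = object$cov,
                  priors = object$priors, classes = object$classes,
                  class_names = object$class_names,
                  shrinkage = object$shrinkage, n_train = object$n_train)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_decoder
#' @export
read_decoder <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "emgal-decoder-v1"))
    stop_invalid("`%s` is not an emgal decoder file", path)
  cov_reg <- as.matrix(x$cov)
  structure(
    list(center = as.numeric(x$center), scale = as.numeric(x$scale),
         means = as.matrix(x$means), cov = cov_reg,
         cov_inv = chol2inv(chol(cov_reg)),
         priors = as.numeric(x$priors), classes = as.integer(x$classes),
         class_names = as.character(x$class_names),
         shrinkage = x$shrinkage, n_train = x$n_train),
    class = "emg_decoder")
}
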