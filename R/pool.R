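#' Window-by-feature pool
#'
#' The tabular unit the active learner operates on: one row per sliding
#' window, one column per channel feature (waveform length per channel), plus
#' the window's class label and provenance (session tag, window start time).
#'
#' @param features Numeric matrix, windows x features; no non-finite values.
#' @param labels Integer class ids (1-based into `class_names`), one per row.
#' @param class_names Character vector of class labels.
#' @param session Session tag per window (recycled if length 1).
#' @param t_start_ms Start time of each window in ms.
#' @param window_id Stable integer id per window; defaults to the row number.
#'
#' @return An object of class `feature_pool`.
#' @export
feature_pool <- function(features, labels, class_names,
                         session = "T1", t_start_ms = NULL,
                         window_id = NULL) {
  features <- as.matrix(features)
  if (!is.numeric(features) || any(!is.finite(features)))
    stop_invalid("`features` must be a finite numeric matrix")
  n <- nrow(features)
  labels <- as.integer(labels)
  if (length(labels) != n)
    stop_invalid("`labels` must match the number of feature rows")
  if (anyNA(labels) || any(labels < 1L) || any(labels > length(class_names)))
    stop_invalid("every label must index `class_names`")
  if (is.null(t_start_ms)) t_start_ms <- seq_len(n) - 1
  if (is.null(window_id)) window_id <- seq_len(n)
  if (length(session) == 1L) session <- rep(session, n)
  if (length(t_start_ms) != n || length(window_id) != n ||
      length(session) != n)
    stop_invalid("metadata columns must match the number of feature rows")
  if (is.null(colnames(features)))
    colnames(features) <- paste0("ch", seq_len(ncol(features)), "_wl")
  structure(
    list(features = features, labels = labels,
         class_names = as.character(class_names),
         meta = data.frame(window_id = as.integer(window_id),
                           session = as.character(session),
                           t_start_ms = as.numeric(t_start_ms))),
    class = "feature_pool")
}

#' @export
print.feature_pool <- function(x, ...) {
  cat(sprintf("Feature pool: %d windows x %d features [%s]\n",
              nrow(x$features), ncol(x$features),
              paste(unique(x$meta$session), collapse = ",")))
  print(class_counts(x))
  invisible(x)
}

#' Number of windows in a pool
#' @param pool A [feature_pool()].
#' @return Integer count.
#' @export
n_windows <- function(pool) nrow(pool$features)

#' Windows per class
#' @param pool A [feature_pool()].
#' @return Named integer vector over all classes (zeros kept).
#' @export
class_counts <- function(pool) {
  tab <- table(factor(pool$class_names[pool$labels],
                      levels = pool$class_names))
  stats::setNames(as.integer(tab), names(tab))
}

#' Subset a pool by row index
#' @param pool A [feature_pool()].
#' @param idx Integer row indices to keep.
#' @return A [feature_pool()] with the selected windows.
#' @export
pool_subset <- function(pool, idx) {
  structure(
    list(features = pool$features[idx, , drop = FALSE],
         labels = pool$labels[idx],
         class_names = pool$class_names,
         meta = pool$meta[idx, , drop = FALSE]),
    class = "feature_pool")
}

#' Write / read a feature pool as CSV
#'
#' Schema: `window_id, session, class, t_start_ms`, then one column per
#' channel feature. Class labels are written as names, not ids.
#'
#' @param pool A [feature_pool()].
#' @param path CSV file path.
#' @param class_names Optional class dictionary for reading; defaults to the
#'   classes present in the file, in order of first appearance.
#' @return `write_pool()` returns `path` invisibly; `read_pool()` returns a
#'   [feature_pool()].
#' @export
write_pool <- function(pool, path) {
  stopifnot(inherits(pool, "feature_pool"))
  df <- data.frame(window_id = pool$meta$window_id,
                   session = pool$meta$session,
                   class = pool$class_names[pool$labels],
                   t_start_ms = pool$meta$t_start_ms)
  df <- cbind(df, as.data.frame(pool$features))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool
#' @export
read_pool <- function(path, class_names = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("window_id", "session", "class", "t_start_ms")
  if (!all(need %in% names(df)))
    stop_invalid("pool CSV must contain columns %s", paste(need, collapse = ", "))
  if (is.null(class_names)) class_names <- unique(df$class)
  if (!all(df$class %in% class_names))
    stop_invalid("file contains classes missing from `class_names`")
  feat_cols <- setdiff(names(df), need)
  feature_pool(as.matrix(df[feat_cols]),
               labels = match(df$class, class_names),
               class_names = class_names,
               session = df$session,
               t_start_ms = df$t_start_ms,
               window_id = df$window_id)
}
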