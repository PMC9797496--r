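# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream: generators must be pure functions of (args, seed).
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != floor(x))
    stop_invalid("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

check_scalar_pos <- function(x, name, strict = TRUE) {
  if (length(x) != 1L || !is.finite(x) || (strict && x <= 0) || (!strict && x < 0))
    stop_invalid("`%s` must be a single %s number", name,
                 if (strict) "positive" else "non-negative")
  as.numeric(x)
}

# Validate rows of `p` as probability vectors on the simplex.
check_prob_matrix <- function(p, tol = 1e-6) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  p <- as.matrix(p)
  if (!is.numeric(p) || anyNA(p) || any(!is.finite(p)))
    stop_invalid("probabilities must be finite numeric values")
  if (any(p < -tol) || any(p > 1 + tol))
    stop_invalid("probabilities must lie in [0, 1]")
  if (any(abs(rowSums(p) - 1) > tol))
    stop_invalid("probability rows must sum to 1 (tolerance %g)", tol)
  p
}

gcd2 <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}
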