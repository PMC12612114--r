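# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded helpers do not perturb a caller's stream.
#' With `seed = NULL` the expression runs on the current stream unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

stopifnot_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

# Uniform points inside an axis-aligned ellipsoid centred at the origin with
# semi-axes (a, a, c): rejection sampling from the bounding box.
runif_ellipsoid <- function(n, a, c_axis) {
  out <- matrix(NA_real_, nrow = n, ncol = 3)
  filled <- 0L
  while (filled < n) {
    m <- max(2L * (n - filled), 16L)
    x <- stats::runif(m, -a, a)
    y <- stats::runif(m, -a, a)
    z <- stats::runif(m, -c_axis, c_axis)
    keep <- (x / a)^2 + (y / a)^2 + (z / c_axis)^2 <= 1
    k <- min(sum(keep), n - filled)
    if (k > 0) {
      idx <- which(keep)[seq_len(k)]
      out[filled + seq_len(k), ] <- cbind(x[idx], y[idx], z[idx])
      filled <- filled + k
    }
  }
  colnames(out) <- c("x", "y", "z")
  out
}

inside_ellipsoid <- function(x, y, z, a, c_axis) {
  (x / a)^2 + (y / a)^2 + (z / c_axis)^2 <= 1
}
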