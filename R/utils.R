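# Shared internal helpers: interval arithmetic, exact piecewise-linear
# integration, seeded RNG scoping.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Length of the intersection of two closed intervals; 0 if disjoint.
interval_overlap <- function(lo1, hi1, lo2, hi2) {
  pmax(0, pmin(hi1, hi2) - pmax(lo1, lo2))
}

abort_cinnamr <- function(msg, class) {
  rlang::abort(msg, class = paste0("cinnamr_", class))
}

# Cumulative trapezoidal integral of (x, y) evaluated exactly at arbitrary
# query points q inside [x_1, x_n], treating y as piecewise linear. Used by
# both bucketing and region integration so the two agree to machine precision.
cumtrap_at <- function(x, y, q) {
  n <- length(x)
  ct <- c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
  i <- findInterval(q, x, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), n - 1L)
  dx <- x[i + 1L] - x[i]
  t <- (q - x[i]) / dx
  yq <- y[i] + t * (y[i + 1L] - y[i])
  ct[i] + (q - x[i]) * (y[i] + yq) / 2
}

# Exact integral of the piecewise-linear interpolant over [lo, hi].
trap_integral <- function(x, y, lo, hi) {
  vals <- cumtrap_at(x, y, c(lo, hi))
  vals[2] - vals[1]
}

# Evaluate a deterministic expression under a local RNG seed, restoring the
# caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Normal truncated at zero, parameterized by the untruncated location/scale.
# Inverse-CDF sampling; scale 0 collapses to the location point mass.
rnorm_trunc0 <- function(n, location, scale) {
  stopifnot(length(location) == length(scale) || length(scale) == 1L)
  location <- rep_len(location, n)
  scale <- rep_len(scale, n)
  out <- location
  pos <- scale > 0
  if (any(pos)) {
    p0 <- stats::pnorm(0, location[pos], scale[pos])
    u <- stats::runif(sum(pos), p0, 1)
    out[pos] <- stats::qnorm(u, location[pos], scale[pos])
  }
  pmax(out, 0)
}
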