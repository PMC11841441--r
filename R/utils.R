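# Internal helpers shared across modules.

# Run `expr` with a private RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards so generators leave no hidden global state behind.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# microlitres/min -> m^3/s
ul_min_to_m3s <- function(q) q * 1e-9 / 60

um_to_cm <- function(x) x * 1e-4

# complementary error function (used against diffusion similarity solutions)
erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

# quantize intensities in [0, 1] to the 16-bit grid the generators emit
quantize16 <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  round(x * 65535) / 65535
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# polygon/polyline length in pixel units
polyline_length <- function(xy, closed = FALSE) {
  n <- nrow(xy)
  if (n < 2L) return(0)
  if (closed) xy <- rbind(xy, xy[1L, , drop = FALSE])
  sum(sqrt(diff(xy[, 1L])^2 + diff(xy[, 2L])^2))
}

# Douglas-Peucker simplification of an open polyline (pixel coordinates).
# Removes the rasterization staircase while keeping genuine corners, so the
# simplified polyline's length is a nearly unbiased estimate of the underlying
# smooth curve's length.
dp_simplify <- function(xy, eps) {
  n <- nrow(xy)
  if (n < 3L) return(xy)
  a <- xy[1L, ]
  b <- xy[n, ]
  ab <- b - a
  L <- sqrt(sum(ab^2))
  d <- if (L == 0) {
    sqrt(rowSums((xy - matrix(a, n, 2, byrow = TRUE))^2))
  } else {
    abs((xy[, 1L] - a[1L]) * ab[2L] - (xy[, 2L] - a[2L]) * ab[1L]) / L
  }
  i <- which.max(d)
  if (d[i] <= eps) return(xy[c(1L, n), , drop = FALSE])
  left <- dp_simplify(xy[1:i, , drop = FALSE], eps)
  right <- dp_simplify(xy[i:n, , drop = FALSE], eps)
  rbind(left[-nrow(left), , drop = FALSE], right)
}

# Closed-curve variant: split at the two x-extremal vertices so endpoints of
# the two open halves are guaranteed kept, then recombine.
dp_simplify_closed <- function(xy, eps) {
  n <- nrow(xy)
  if (n < 4L) return(xy)
  i1 <- which.min(xy[, 1L])
  i2 <- which.max(xy[, 1L])
  lo <- min(i1, i2); hi <- max(i1, i2)
  if (lo == hi) return(dp_simplify(xy, eps))
  s1 <- dp_simplify(xy[lo:hi, , drop = FALSE], eps)
  s2 <- dp_simplify(xy[c(hi:n, 1:lo), , drop = FALSE], eps)
  rbind(s1[-nrow(s1), , drop = FALSE], s2[-nrow(s2), , drop = FALSE])
}
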