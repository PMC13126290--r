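## Internal numeric helpers shared across modules.

# Lognormal draw parameterized by its arithmetic mean and coefficient of
# variation, so that E[X] = mean exactly (meanlog carries the -sdlog^2/2
# correction). cv = 0 degenerates to the constant `mean`.
rlnorm_mean_cv <- function(n, mean, cv) {
  stopifnot(all(mean > 0), cv >= 0)
  if (cv == 0) return(rep(mean, length.out = n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. seed = NULL leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from (seed, index) staying inside the
# 32-bit integer range.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% .Machine$integer.max)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  invisible(x)
}

check_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && all(is.finite(x)) && if (strict) all(x > 0) else all(x >= 0)
  if (!ok) stop(sprintf("`%s` must be %s", name,
                        if (strict) "positive" else "non-negative"), call. = FALSE)
  invisible(x)
}

# Geometric mean with a positivity floor (geometric mean is undefined at 0).
geometric_mean <- function(x, floor = 1e-3) {
  x <- pmax(x, floor)
  exp(mean(log(x)))
}

# Even-odd (ray casting) point-in-polygon test, vectorized over query points.
# Polygon given as x/y vertex vectors (closed implicitly).
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Rasterize a polygon into a logical matrix of dimension `dim` (rows, cols),
# pixel centers at integer coordinates (row, col).
polygon_mask <- function(dim, vx, vy) {
  grid <- expand.grid(row = seq_len(dim[1]), col = seq_len(dim[2]))
  m <- point_in_polygon(grid$col, grid$row, vx, vy)
  matrix(m, nrow = dim[1], ncol = dim[2])
}
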