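# Fixture builders and independent oracles shared across test files.

# Soma root (radius r_soma at origin) plus a straight chain of `n_edges`
# collinear neurite edges along +x, each of length `len` and radius `r`.
make_path_tree <- function(n_edges = 5, len = 10, r = 0.5, r_soma = 10) {
  nodes <- data.frame(
    node_id = 1L, parent_id = NA_integer_, node_type = "soma",
    x = 0, y = 0, z = 0, radius = r_soma)
  for (i in seq_len(n_edges)) {
    nodes <- rbind(nodes, data.frame(
      node_id = i + 1L, parent_id = i, node_type = "neurite",
      x = i * len, y = 0, z = 0, radius = r))
  }
  ploidyscale:::new_neuron_tree(nodes, neuron_id = "path", ploidy = "diploid")
}

# Symmetric binary tree: a stem of length `stem_len` along +x, then
# `depth` successive bifurcations; every post-stem edge has length
# `seg_len`. Children spread in the xy plane. Radii all equal `r`.
make_binary_tree <- function(depth = 3, stem_len = 10, seg_len = 10,
                             r = 0.5, r_soma = 5) {
  nodes <- data.frame(node_id = 1L, parent_id = NA_integer_,
                      node_type = "soma", x = 0, y = 0, z = 0,
                      radius = r_soma)
  nodes <- rbind(nodes, data.frame(node_id = 2L, parent_id = 1L,
                                   node_type = "neurite", x = stem_len,
                                   y = 0, z = 0, radius = r))
  next_id <- 3L
  frontier <- list(list(id = 2L, x = stem_len, y = 0, angle = 0))
  for (d in seq_len(depth)) {
    nxt <- list()
    for (f in frontier) {
      for (sgn in c(-1, 1)) {
        ang <- f$angle + sgn * pi / 2^(d + 1)
        x <- f$x + seg_len * cos(ang)
        y <- f$y + seg_len * sin(ang)
        nodes <- rbind(nodes, data.frame(node_id = next_id,
                                         parent_id = f$id,
                                         node_type = "neurite",
                                         x = x, y = y, z = 0, radius = r))
        nxt[[length(nxt) + 1]] <- list(id = next_id, x = x, y = y,
                                       angle = ang)
        next_id <- next_id + 1L
      }
    }
    frontier <- nxt
  }
  ploidyscale:::new_neuron_tree(nodes, neuron_id = "binary",
                                ploidy = "diploid")
}

# Quadrature oracle for a linearly tapered tube of end radii r1, r2 and
# axial length l: volume and lateral surface by numeric integration.
frustum_oracle <- function(r1, r2, l) {
  rt <- function(t) r1 + (r2 - r1) * t / l
  vol <- stats::integrate(function(t) pi * rt(t)^2, 0, l,
                          rel.tol = 1e-10)$value
  drdt <- (r2 - r1) / l
  area <- stats::integrate(function(t) 2 * pi * rt(t) * sqrt(1 + drdt^2),
                           0, l, rel.tol = 1e-10)$value
  c(volume = vol, area = area)
}

# Naive reference implementation of the fuzzy-entropy threshold search:
# plain loops, no shared cumulative sums. The implementation under test
# must pick the same minimizing cut.
huang_oracle <- function(image, n_bins = 256) {
  v <- as.numeric(image)
  lo <- min(v); hi <- max(v)
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  bin <- pmin(findInterval(v, breaks, rightmost.closed = TRUE), n_bins)
  h <- tabulate(bin, nbins = n_bins)
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  C <- hi - lo
  best_t <- NA; best_e <- Inf
  for (t in 1:(n_bins - 1)) {
    n0 <- sum(h[1:t]); n1 <- sum(h[(t + 1):n_bins])
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(h[1:t] * centers[1:t]) / n0
    mu1 <- sum(h[(t + 1):n_bins] * centers[(t + 1):n_bins]) / n1
    e <- 0
    for (g in 1:n_bins) {
      if (h[g] == 0) next
      mu <- if (g <= t) mu0 else mu1
      u <- 1 / (1 + abs(centers[g] - mu) / C)
      if (u > 0 && u < 1)
        e <- e - h[g] * (u * log(u) + (1 - u) * log(1 - u))
    }
    if (e < best_e) { best_e <- e; best_t <- t }
  }
  breaks[best_t + 1]
}

# Rigid rotation (about z then y) plus translation of a neuron tree.
rigid_transform <- function(tree, theta = 0.7, phi = 0.3,
                            shift = c(5, -3, 11)) {
  Rz <- matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0,
                 0, 0, 1), 3, 3)
  Ry <- matrix(c(cos(phi), 0, -sin(phi), 0, 1, 0, sin(phi), 0, cos(phi)),
               3, 3)
  xyz <- as.matrix(tree$nodes[, c("x", "y", "z")]) %*% t(Rz %*% Ry)
  tree$nodes$x <- xyz[, 1] + shift[1]
  tree$nodes$y <- xyz[, 2] + shift[2]
  tree$nodes$z <- xyz[, 3] + shift[3]
  tree
}
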