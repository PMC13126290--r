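#' Per-edge segment metrics of a neuron tree
#'
#' Each neurite edge (child node joined to its parent) is modeled as a
#' conical frustum with end radii r1 (parent) and r2 (child) and chord
#' length l:
#' volume `= pi*l/3 * (r1^2 + r1*r2 + r2^2)`, lateral area
#' `= pi*(r1 + r2) * sqrt(l^2 + (r2 - r1)^2)`, mean diameter `= r1 + r2`.
#' Edges attached to a soma node use the child radius at both ends (the
#' soma is modeled separately as a sphere; the stem emerges as a tube).
#' Branch level is centrifugal order: soma-attached stems are level 1 and
#' the level increments after each branch point.
#'
#' @param tree A `neuron_tree`.
#' @return data.frame with one row per neurite edge: `node_id`, `parent_id`,
#'   `length`, `mean_diameter`, `lateral_area`, `volume`, `branch_level`,
#'   `path_origin` (`"stem"` or `"internal"`).
#' @export
segment_metrics <- function(tree) {
  stopifnot(inherits(tree, "neuron_tree"))
  n <- tree$nodes
  child <- which(n$node_type == "neurite")
  if (!length(child)) {
    return(data.frame(node_id = integer(), parent_id = integer(),
                      length = numeric(), mean_diameter = numeric(),
                      lateral_area = numeric(), volume = numeric(),
                      branch_level = integer(), path_origin = character()))
  }
  par <- n$parent_id[child]
  soma_parent <- n$node_type[par] == "soma"
  l <- sqrt((n$x[child] - n$x[par])^2 + (n$y[child] - n$y[par])^2 +
              (n$z[child] - n$z[par])^2)
  r2 <- n$radius[child]
  r1 <- ifelse(soma_parent, r2, n$radius[par])
  vol <- pi * l / 3 * (r1^2 + r1 * r2 + r2^2)
  area <- pi * (r1 + r2) * sqrt(l^2 + (r2 - r1)^2)
  # centrifugal branch order: stems = 1, +1 after each branch point.
  # out-degree among neurite children determines branch points.
  out_deg <- tabulate(par, nbins = nrow(n))
  level <- integer(nrow(n))
  ord <- order(node_depths(n))
  for (i in ord) {
    p <- n$parent_id[i]
    if (is.na(p) || n$node_type[i] != "neurite") next
    level[i] <- if (n$node_type[p] == "soma") 1L
    else level[p] + (out_deg[p] >= 2L)
  }
  data.frame(node_id = n$node_id[child], parent_id = n$node_id[par],
             length = l, mean_diameter = r1 + r2, lateral_area = area,
             volume = vol, branch_level = level[child],
             path_origin = ifelse(soma_parent, "stem", "internal"))
}

#' Per-neuron compartment morphometry
#'
#' Summarizes a neuron into the size and shape parameters used for
#' ploidy-scaling comparisons: soma modeled as a sphere of the root soma
#' radius (multi-node somata use the volume-equivalent sphere), neurite
#' quantities summed over frusta, plus radial extent, terminal point count,
#' and maximum centrifugal branch level. Mean neurite diameter is
#' length-weighted (an unweighted per-segment mean is also reported).
#'
#' @param tree A `neuron_tree`.
#' @return One-row data.frame (a `morphometry_record`): soma/neurite/total
#'   volume and surface, `total_neurite_length`, `mean_neurite_diameter`
#'   (length-weighted), `mean_neurite_diameter_unweighted`, `max_radius`,
#'   `n_terminal_points`, `max_branch_level`, and neurite:soma ratios for
#'   volume, surface, and surface-to-volume.
#' @export
compartment_summary <- function(tree) {
  stopifnot(inherits(tree, "neuron_tree"))
  n <- tree$nodes
  soma <- n[n$node_type == "soma", , drop = FALSE]
  root <- n[is.na(n$parent_id), , drop = FALSE]
  if (nrow(soma) == 1L) {
    r_soma <- soma$radius[1]
  } else {
    # volume-equivalent sphere over soma node spheres
    r_soma <- (sum(soma$radius^3))^(1 / 3)
  }
  soma_volume <- 4 / 3 * pi * r_soma^3
  soma_surface <- 4 * pi * r_soma^2
  centroid <- c(mean(soma$x), mean(soma$y), mean(soma$z))
  seg <- segment_metrics(tree)
  warn_flag <- FALSE
  if (nrow(seg) == 0L) {
    warning("tree has no neurite nodes; neurite fields set to zero")
    warn_flag <- TRUE
    neurite_volume <- neurite_surface <- total_len <- 0
    mean_d <- mean_d_u <- NA_real_
    n_terminal <- 0L; max_level <- 0L
  } else {
    neurite_volume <- sum(seg$volume)
    neurite_surface <- sum(seg$lateral_area)
    total_len <- sum(seg$length)
    mean_d <- sum(seg$length * seg$mean_diameter) / total_len
    mean_d_u <- mean(seg$mean_diameter)
    is_parent <- n$node_id %in% seg$parent_id
    leaves <- n$node_type == "neurite" & !is_parent
    n_terminal <- sum(leaves)
    max_level <- max(seg$branch_level)
  }
  max_radius <- max(sqrt((n$x - centroid[1])^2 + (n$y - centroid[2])^2 +
                           (n$z - centroid[3])^2))
  rec <- data.frame(
    neuron_id = tree$metadata$neuron_id,
    ploidy = tree$metadata$ploidy,
    soma_volume = soma_volume, soma_surface = soma_surface,
    neurite_volume = neurite_volume, neurite_surface = neurite_surface,
    total_volume = soma_volume + neurite_volume,
    total_surface = soma_surface + neurite_surface,
    total_neurite_length = total_len,
    mean_neurite_diameter = mean_d,
    mean_neurite_diameter_unweighted = mean_d_u,
    max_radius = max_radius,
    n_terminal_points = n_terminal,
    max_branch_level = max_level,
    neurite_to_soma_volume_ratio = neurite_volume / soma_volume,
    neurite_to_soma_surface_ratio = neurite_surface / soma_surface,
    neurite_to_soma_av_ratio =
      (neurite_surface / neurite_volume) / (soma_surface / soma_volume),
    no_neurites = warn_flag,
    stringsAsFactors = FALSE)
  class(rec) <- c("morphometry_record", class(rec))
  rec
}

#' Cumulative neurite length distribution over diameter
#'
#' Fraction of total neurite length carried by segments with mean diameter
#' at or below each grid value. A leftward shift of one group's curve means
#' a larger share of its neurite length lives at smaller diameters.
#'
#' @param segments data.frame of segment metrics (possibly pooled across
#'   neurons) with columns `length` and `mean_diameter`.
#' @param grid Ascending diameter grid (micrometres). Default: 100 points
#'   spanning the observed diameters.
#' @return data.frame with `diameter` and `cumulative_length_fraction`
#'   (non-decreasing, ending at 1).
#' @export
length_by_diameter <- function(segments, grid = NULL) {
  if (is.null(segments) || nrow(segments) == 0L)
    stop("no segments supplied", call. = FALSE)
  if (is.null(grid))
    grid <- seq(0, max(segments$mean_diameter), length.out = 100)
  stopifnot(!is.unsorted(grid))
  total <- sum(segments$length)
  frac <- vapply(grid, function(g)
    sum(segments$length[segments$mean_diameter <= g]) / total, numeric(1))
  data.frame(diameter = grid, cumulative_length_fraction = frac)
}

#' Length-weighted two-sample Kolmogorov-Smirnov test
#'
#' D is the maximum vertical distance between the length-weighted cumulative
#' diameter distributions of two segment pools. Because segments within a
#' neuron are dependent, the p-value comes from permuting neuron labels
#' between groups (not segments), two-sided.
#'
#' @param group_a,group_b data.frames with columns `value`, `weight`, and
#'   `unit` (the resampling unit, e.g. neuron id). Equal weights reduce D to
#'   the classical two-sample KS statistic.
#' @param n_perm Number of permutations (warning below 100).
#' @param seed RNG seed for the permutation draw.
#' @return list with `statistic` (D) and `p_value`.
#' @export
weighted_ks <- function(group_a, group_b, n_perm = 10000, seed = 1L) {
  for (g in list(group_a, group_b))
    if (is.null(g) || nrow(g) == 0L) stop("both groups must be non-empty", call. = FALSE)
  if (n_perm < 100) warning("n_perm < 100: permutation p-value will be coarse")
  D <- weighted_ks_stat(group_a$value, group_a$weight,
                        group_b$value, group_b$weight)
  units_a <- unique(group_a$unit); units_b <- unique(group_b$unit)
  units <- c(units_a, units_b)
  na <- length(units_a)
  pooled <- rbind(group_a, group_b)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      lab <- sample(units)
      a <- pooled[pooled$unit %in% lab[seq_len(na)], ]
      b <- pooled[pooled$unit %in% lab[-seq_len(na)], ]
      weighted_ks_stat(a$value, a$weight, b$value, b$weight) >= D - 1e-12
    }, logical(1)))
  })
  list(statistic = D, p_value = (1 + exceed) / (n_perm + 1))
}

weighted_ks_stat <- function(xa, wa, xb, wb) {
  grid <- sort(unique(c(xa, xb)))
  Fa <- weighted_ecdf(xa, wa, grid)
  Fb <- weighted_ecdf(xb, wb, grid)
  max(abs(Fa - Fb))
}

weighted_ecdf <- function(x, w, grid) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  idx <- findInterval(grid, x)
  c(0, cw)[idx + 1L]
}

#' Sholl intersection profile
#'
#' Counts neurite edges crossing concentric spheres centered at the soma
#' centroid, at radii `step, 2*step, ...` up to the neuron's maximal radial
#' extent. An edge whose endpoint distances straddle a radius counts once
#' (crossing when `min < r <= max`).
#'
#' @param tree A `neuron_tree`.
#' @param step Sphere spacing in micrometres (default 5).
#' @return data.frame with `radius` and `intersections`.
#' @export
sholl <- function(tree, step = 5) {
  check_pos(step, "step")
  n <- tree$nodes
  soma <- n[n$node_type == "soma", , drop = FALSE]
  centroid <- c(mean(soma$x), mean(soma$y), mean(soma$z))
  d <- sqrt((n$x - centroid[1])^2 + (n$y - centroid[2])^2 +
              (n$z - centroid[3])^2)
  child <- which(n$node_type == "neurite")
  par <- n$parent_id[child]
  lo <- pmin(d[child], d[par]); hi <- pmax(d[child], d[par])
  radii <- seq(step, max(d) + step / 2, by = step)
  ints <- vapply(radii, function(r) sum(lo < r & hi >= r), integer(1))
  data.frame(radius = radii, intersections = ints)
}

#' Population fold changes with bootstrap confidence intervals
#'
#' For every numeric morphometry property, fold = mean(triploid) /
#' mean(diploid), with a percentile bootstrap CI resampling neurons and a
#' Welch t-test p-value.
#'
#' @param diploid_records,triploid_records data.frames of
#'   [compartment_summary()] rows (>= 2 each).
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed RNG seed.
#' @param properties Columns to compare; defaults to the standard size set.
#' @return data.frame with `property`, `fold`, `ci_lo`, `ci_hi`, `p_welch`,
#'   `n_diploid`, `n_triploid`.
#' @export
population_folds <- function(diploid_records, triploid_records,
                             n_boot = 2000, seed = 1L,
                             properties = c("soma_volume", "soma_surface",
                                            "neurite_volume", "neurite_surface",
                                            "total_volume", "total_surface",
                                            "total_neurite_length",
                                            "mean_neurite_diameter",
                                            "max_radius", "n_terminal_points",
                                            "max_branch_level")) {
  if (nrow(diploid_records) < 2 || nrow(triploid_records) < 2)
    stop("need at least 2 records per group", call. = FALSE)
  res <- with_seed(seed, {
    lapply(properties, function(p) {
      x <- diploid_records[[p]]; y <- triploid_records[[p]]
      fold <- mean(y) / mean(x)
      boots <- vapply(seq_len(n_boot), function(i) {
        mean(sample(y, replace = TRUE)) / mean(sample(x, replace = TRUE))
      }, numeric(1))
      ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
      pt <- tryCatch(stats::t.test(y, x)$p.value, error = function(e) NA_real_)
      data.frame(property = p, fold = fold, ci_lo = ci[1], ci_hi = ci[2],
                 p_welch = pt, n_diploid = length(x), n_triploid = length(y))
    })
  })
  do.call(rbind, res)
}

#' Classify a fold change relative to the ploidy reference
#'
#' A property scales if its fold change matches the reference ploidy fold
#' within tolerance, subscales below, and superscales above. For the
#' diploid-to-triploid comparison the reference fold is the 1.5-fold genome
#' increase: a sphere's surface then subscales (1.5^(2/3) ~ 1.31) while a
#' thinning tube's surface superscales (~1.71).
#'
#' @param fold Observed fold change (> 0).
#' @param reference_fold Reference fold (default 1.5).
#' @param tolerance Half-width of the "scaling" band (default 0.1).
#' @param property_name Optional label carried into the result.
#' @return data.frame with `property_name`, `fold_change`, `reference_fold`,
#'   `tolerance`, `class` in `subscaling`/`scaling`/`superscaling`.
#' @export
classify_scaling <- function(fold, reference_fold = 1.5, tolerance = 0.1,
                             property_name = NA_character_) {
  check_pos(fold, "fold")
  check_pos(tolerance, "tolerance", strict = FALSE)
  eps <- 1e-9 * max(1, reference_fold)  # guard the band boundary against FP
  cls <- if (abs(fold - reference_fold) <= tolerance + eps) "scaling"
  else if (fold < reference_fold) "subscaling"
  else "superscaling"
  data.frame(property_name = property_name, fold_change = fold,
             reference_fold = reference_fold, tolerance = tolerance,
             class = cls, stringsAsFactors = FALSE)
}

#' Trend of the neurite share of volume and surface with neuron size
#'
#' Fits an ordinary least-squares line of the neurite fraction (of total
#' volume and of total surface) against total volume across neurons pooled
#' over ploidies, with a 95% band, and tests parameter stability along
#' increasing total volume with a recursive CUSUM test (Brownian-motion
#' linear-boundary crossing p-value).
#'
#' @param records data.frame of [compartment_summary()] rows (>= 10).
#' @return list with one element per response (`volume_share`,
#'   `surface_share`), each containing `fit` (lm), `slope`, `slope_p`,
#'   `cusum_stat`, `cusum_p`.
#' @export
neurite_share_trend <- function(records) {
  if (nrow(records) < 10) stop("need at least 10 records", call. = FALSE)
  x <- records$total_volume
  if (stats::sd(x) < 1e-12) stop("degenerate total_volume variance", call. = FALSE)
  out <- list()
  for (resp in c("volume_share", "surface_share")) {
    y <- if (resp == "volume_share") records$neurite_volume / records$total_volume
    else records$neurite_surface / records$total_surface
    ord <- order(x)
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)
    cs <- rec_cusum_test(x[ord], y[ord])
    out[[resp]] <- list(fit = fit,
                        slope = stats::coef(fit)[["x"]],
                        slope_p = sm$coefficients["x", 4],
                        cusum_stat = cs$statistic, cusum_p = cs$p_value)
  }
  out
}

# Recursive CUSUM structural-stability test for y ~ 1 + x, observations
# already ordered along the suspected break direction. Statistic is
# max |W(t)| / (1 + 2t); p-value from the crossing probability of standard
# Brownian motion over the line lambda*(1 + 2t).
rec_cusum_test <- function(x, y) {
  n <- length(y)
  k <- 2L
  X <- cbind(1, x)
  w <- numeric(n - k)
  XtX <- crossprod(X[seq_len(k), , drop = FALSE])
  Xty <- crossprod(X[seq_len(k), , drop = FALSE], y[seq_len(k)])
  for (r in (k + 1L):n) {
    beta <- solve(XtX, Xty)
    xr <- X[r, ]
    fr <- 1 + drop(t(xr) %*% solve(XtX, xr))
    w[r - k] <- (y[r] - drop(xr %*% beta)) / sqrt(fr)
    XtX <- XtX + tcrossprod(xr)
    Xty <- Xty + xr * y[r]
  }
  sigma <- stats::sd(w)
  if (sigma < 1e-12) return(list(statistic = 0, p_value = 1))
  W <- cumsum(w) / (sigma * sqrt(n - k))
  tt <- seq_len(n - k) / (n - k)
  stat <- max(abs(W) / (1 + 2 * tt))
  p <- 2 * (1 - stats::pnorm(3 * stat) +
              exp(-4 * stat^2) * stats::pnorm(stat))
  list(statistic = stat, p_value = min(1, max(0, p)))
}
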