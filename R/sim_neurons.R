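#' Parameters for the synthetic neuron generator
#'
#' Defaults emulate small tadpole forebrain neurons and are calibrated
#' (analytically, from the closed-form expectations of the branching
#' process) so that the expected neurite:soma surface partition is about
#' 5:1 and the expected total neurite length about 1.5 mm. The ploidy
#' factors encode the study conditions: a 1.5-fold soma (and neurite)
#' volume increase realized through a 1.95-fold neurite length increase
#' with a sqrt(1.5/1.95) diameter decrease, so that
#' `neurite_length_fold * neurite_diameter_fold^2 = soma_volume_fold`.
#'
#' @param soma_radius_mean Mean soma radius, micrometres (lognormal).
#' @param soma_radius_cv Coefficient of variation of the soma radius.
#' @param n_stems Number of primary neurites leaving the soma.
#' @param branch_prob Probability, after each segment, that the branch
#'   bifurcates (ending the current branch path).
#' @param segment_length_mean,segment_length_cv Lognormal segment length,
#'   micrometres.
#' @param max_branch_level Maximum centrifugal branch order; branches at
#'   this level terminate instead of bifurcating.
#' @param max_segments_per_branch A branch ends after this many segments
#'   even if no bifurcation event occurred (keeps `branch_prob = 0` trees
#'   finite).
#' @param stem_diameter_mean Mean stem diameter, micrometres.
#' @param diameter_cv Lognormal diameter noise per branch.
#' @param taper_ratio Child/parent diameter ratio at bifurcations (Rall-style
#'   multiplicative taper), in (0, 1].
#' @param ploidy_factors List with `soma_volume_fold`, `neurite_length_fold`,
#'   `neurite_diameter_fold` applied to triploid draws.
#' @return A validated `neuron_sim_params` list.
#' @export
neuron_sim_params <- function(soma_radius_mean = 8,
                              soma_radius_cv = 0.1,
                              n_stems = 3,
                              branch_prob = 0.35,
                              segment_length_mean = 12.5,
                              segment_length_cv = 0.35,
                              max_branch_level = 4,
                              max_segments_per_branch = 8,
                              stem_diameter_mean = 1.2,
                              diameter_cv = 0.15,
                              taper_ratio = 0.85,
                              ploidy_factors = list(
                                soma_volume_fold = 1.5,
                                neurite_length_fold = 1.95,
                                neurite_diameter_fold = sqrt(1.5 / 1.95))) {
  check_pos(soma_radius_mean, "soma_radius_mean")
  check_pos(segment_length_mean, "segment_length_mean")
  check_pos(stem_diameter_mean, "stem_diameter_mean")
  check_prob(branch_prob, "branch_prob")
  if (branch_prob >= 1) stop("`branch_prob` must be < 1", call. = FALSE)
  check_pos(soma_radius_cv, "soma_radius_cv", strict = FALSE)
  check_pos(segment_length_cv, "segment_length_cv", strict = FALSE)
  check_pos(diameter_cv, "diameter_cv", strict = FALSE)
  if (taper_ratio <= 0 || taper_ratio > 1)
    stop("`taper_ratio` must be in (0, 1]", call. = FALSE)
  stopifnot(n_stems >= 1, max_branch_level >= 1, max_segments_per_branch >= 1)
  pf <- ploidy_factors
  stopifnot(all(c("soma_volume_fold", "neurite_length_fold",
                  "neurite_diameter_fold") %in% names(pf)))
  check_pos(pf$soma_volume_fold, "soma_volume_fold")
  structure(list(
    soma_radius_mean = soma_radius_mean, soma_radius_cv = soma_radius_cv,
    n_stems = as.integer(n_stems), branch_prob = branch_prob,
    segment_length_mean = segment_length_mean,
    segment_length_cv = segment_length_cv,
    max_branch_level = as.integer(max_branch_level),
    max_segments_per_branch = as.integer(max_segments_per_branch),
    stem_diameter_mean = stem_diameter_mean, diameter_cv = diameter_cv,
    taper_ratio = taper_ratio, ploidy_factors = pf),
    class = "neuron_sim_params")
}

#' Simulate one neuron reconstruction
#'
#' Grows a rooted tree: a spherical soma root plus `n_stems` neurite stems.
#' Each branch is a chain of lognormal-length segments with a slowly
#' wandering direction; after every segment the branch bifurcates with
#' probability `branch_prob` (child diameters shrink by `taper_ratio`),
#' terminating at `max_branch_level` or after `max_segments_per_branch`
#' segments. A triploid draw is the deterministic rescaling of the diploid
#' draw with the same seed: soma radius times `soma_volume_fold^(1/3)`,
#' every segment length times `neurite_length_fold`, every neurite radius
#' times `neurite_diameter_fold` — topology unchanged.
#'
#' @param params A [neuron_sim_params()] object.
#' @param ploidy `"diploid"` or `"triploid"`.
#' @param seed Integer seed; same (params, seed) gives identical output.
#' @param neuron_id Optional identifier stored in metadata.
#' @return A `neuron_tree`.
#' @export
simulate_neuron <- function(params, ploidy = c("diploid", "triploid"),
                            seed = 1L, neuron_id = NULL) {
  stopifnot(inherits(params, "neuron_sim_params"))
  ploidy <- match.arg(ploidy)
  tree <- with_seed(seed, grow_neuron(params))
  if (ploidy == "triploid") tree <- rescale_neuron(tree, params$ploidy_factors)
  if (is.null(neuron_id))
    neuron_id <- sprintf("sim_%s_seed%d", ploidy, as.integer(seed))
  tree$metadata$neuron_id <- neuron_id
  tree$metadata$ploidy <- ploidy
  tree$metadata$brain_region <- "forebrain"
  tree
}

# Grow the diploid draw. Nodes accumulate in a list of rows.
grow_neuron <- function(p) {
  soma_r <- rlnorm_mean_cv(1, p$soma_radius_mean, p$soma_radius_cv)
  nodes <- list(data.frame(node_id = 1L, parent_id = NA_integer_,
                           node_type = "soma", x = 0, y = 0, z = 0,
                           radius = soma_r))
  next_id <- 2L
  # stack of branches to grow: (parent node id, start xyz, direction,
  # diameter, level)
  stack <- vector("list", 0)
  for (s in seq_len(p$n_stems)) {
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    d0 <- p$stem_diameter_mean * rlnorm_mean_cv(1, 1, p$diameter_cv)
    stack[[length(stack) + 1L]] <- list(parent = 1L, at = c(0, 0, 0),
                                        dir = dir, diam = d0, level = 1L)
  }
  while (length(stack)) {
    br <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    parent <- br$parent; at <- br$at; dir <- br$dir
    for (seg in seq_len(p$max_segments_per_branch)) {
      len <- rlnorm_mean_cv(1, p$segment_length_mean, p$segment_length_cv)
      dir <- dir + stats::rnorm(3, sd = 0.3)
      dir <- dir / sqrt(sum(dir^2))
      at <- at + dir * len
      nodes[[length(nodes) + 1L]] <- data.frame(
        node_id = next_id, parent_id = parent, node_type = "neurite",
        x = at[1], y = at[2], z = at[3], radius = br$diam / 2)
      parent <- next_id
      next_id <- next_id + 1L
      if (stats::runif(1) < p$branch_prob) {
        if (br$level < p$max_branch_level) {
          for (k in 1:2) {
            cdir <- dir + stats::rnorm(3, sd = 0.6)
            cdir <- cdir / sqrt(sum(cdir^2))
            cd <- br$diam * p$taper_ratio * rlnorm_mean_cv(1, 1, p$diameter_cv)
            stack[[length(stack) + 1L]] <- list(parent = parent, at = at,
                                                dir = cdir, diam = cd,
                                                level = br$level + 1L)
          }
        }
        break
      }
    }
  }
  new_neuron_tree(do.call(rbind, nodes))
}

# Deterministic triploid rescaling of a diploid tree: walk the tree scaling
# each edge vector by the length fold so directions are preserved.
rescale_neuron <- function(tree, pf) {
  n <- tree$nodes
  root <- which(is.na(n$parent_id))
  a <- pf$neurite_length_fold
  b <- pf$neurite_diameter_fold
  # edge vectors in parent order (root first by construction of the grower;
  # process in increasing depth to ensure parents are placed first)
  new_xyz <- as.matrix(n[, c("x", "y", "z")])
  ord <- order(node_depths(n))
  for (i in ord) {
    p <- n$parent_id[i]
    if (is.na(p)) next
    edge <- as.numeric(n[i, c("x", "y", "z")]) - as.numeric(n[p, c("x", "y", "z")])
    new_xyz[i, ] <- new_xyz[p, ] + edge * a
  }
  n$x <- new_xyz[, 1]; n$y <- new_xyz[, 2]; n$z <- new_xyz[, 3]
  soma <- n$node_type == "soma"
  n$radius[soma] <- n$radius[soma] * pf$soma_volume_fold^(1 / 3)
  n$radius[!soma] <- n$radius[!soma] * b
  tree$nodes <- n
  tree
}

node_depths <- function(nodes) {
  depth <- rep(NA_integer_, nrow(nodes))
  depth[is.na(nodes$parent_id)] <- 0L
  while (anyNA(depth)) {
    reach <- which(is.na(depth) & !is.na(depth[nodes$parent_id]))
    if (!length(reach)) break
    depth[reach] <- depth[nodes$parent_id[reach]] + 1L
  }
  depth
}

#' Simulate a population of neurons for both ploidies
#'
#' Triploid neuron i is the rescaled same-seed draw of diploid neuron i
#' (paired design; isolates the scaling math from sampling noise). Use
#' distinct seeds per ploidy for independent populations.
#'
#' @param params A [neuron_sim_params()].
#' @param n Neurons per ploidy.
#' @param seed Master seed; per-neuron seeds are derived from it.
#' @param paired If `TRUE` (default) triploids reuse the diploid seeds.
#' @return List with elements `diploid` and `triploid`, each a list of
#'   `neuron_tree`s.
#' @export
simulate_neuron_population <- function(params, n = 50, seed = 1L, paired = TRUE) {
  seeds_d <- vapply(seq_len(n), function(i) child_seed(seed, i), integer(1))
  seeds_t <- if (paired) seeds_d else
    vapply(seq_len(n), function(i) child_seed(seed, n + i), integer(1))
  list(
    diploid = lapply(seq_len(n), function(i)
      simulate_neuron(params, "diploid", seeds_d[i],
                      neuron_id = sprintf("dip_%03d", i))),
    triploid = lapply(seq_len(n), function(i)
      simulate_neuron(params, "triploid", seeds_t[i],
                      neuron_id = sprintf("tri_%03d", i)))
  )
}
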