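test_that("cylinder and cone edges match their closed forms", {
  cyl <- make_path_tree(n_edges = 1, len = 1, r = 1)
  m <- segment_metrics(cyl)
  expect_equal(m$volume, pi, tolerance = 1e-12)
  expect_equal(m$lateral_area, 2 * pi, tolerance = 1e-12)
  expect_equal(m$mean_diameter, 2)

  # cone: r1 = 1 at the parent end, r2 -> 0 at the tip, l = 3
  nodes <- data.frame(
    node_id = 1:3, parent_id = c(NA, 1L, 2L),
    node_type = c("soma", "neurite", "neurite"),
    x = c(0, 0, 3), y = 0, z = 0, radius = c(5, 1, 1e-9))
  cone <- ploidyscale:::new_neuron_tree(nodes)
  m2 <- segment_metrics(cone)[2, ]
  expect_equal(m2$volume, pi, tolerance = 1e-6)
  expect_equal(m2$lateral_area, pi * 1 * sqrt(10), tolerance = 1e-6)
})

test_that("frustum volume and area agree with quadrature on 1000 random edges", {
  set.seed(42)
  worst_v <- worst_a <- 0
  for (i in 1:1000) {
    r1 <- runif(1, 0.1, 3); r2 <- runif(1, 0.1, 3); l <- runif(1, 0.5, 30)
    nodes <- data.frame(
      node_id = 1:3, parent_id = c(NA, 1L, 2L),
      node_type = c("soma", "neurite", "neurite"),
      x = c(0, 0, l), y = 0, z = 0, radius = c(5, r1, r2))
    m <- segment_metrics(ploidyscale:::new_neuron_tree(nodes))[2, ]
    o <- frustum_oracle(r1, r2, l)
    worst_v <- max(worst_v, abs(m$volume - o["volume"]) / o["volume"])
    worst_a <- max(worst_a, abs(m$lateral_area - o["area"]) / o["area"])
  }
  expect_lt(worst_v, 1e-6)
  expect_lt(worst_a, 1e-6)
})

test_that("a soma-only tree gives sphere quantities and a warning flag", {
  nodes <- data.frame(node_id = 1L, parent_id = NA_integer_,
                      node_type = "soma", x = 0, y = 0, z = 0, radius = 10)
  tree <- ploidyscale:::new_neuron_tree(nodes)
  expect_warning(rec <- compartment_summary(tree), "no neurite")
  expect_equal(rec$soma_volume, 4188.79, tolerance = 1e-5)
  expect_equal(rec$soma_surface, 1256.64, tolerance = 1e-5)
  expect_true(rec$no_neurites)
  expect_equal(rec$neurite_volume, 0)
})

test_that("a straight path and a symmetric binary tree summarize correctly", {
  path <- make_path_tree(n_edges = 5, len = 10, r = 0.5)
  rec <- compartment_summary(path)
  expect_equal(rec$total_neurite_length, 50)
  expect_equal(rec$n_terminal_points, 1L)
  expect_equal(rec$max_branch_level, 1L)
  expect_equal(rec$max_radius, 50)
  expect_equal(rec$total_volume, rec$soma_volume + rec$neurite_volume)

  bin <- make_binary_tree(depth = 3)
  rec2 <- compartment_summary(bin)
  expect_equal(rec2$n_terminal_points, 8L)
  expect_equal(rec2$max_branch_level, 4L)  # stem level 1 + 3 bifurcations
})

test_that("total = soma + neurite holds exactly on random trees", {
  p <- neuron_sim_params()
  for (s in 1:5) {
    rec <- compartment_summary(simulate_neuron(p, "diploid", seed = s))
    expect_equal(rec$total_volume, rec$soma_volume + rec$neurite_volume,
                 tolerance = 1e-12)
    expect_equal(rec$total_surface, rec$soma_surface + rec$neurite_surface,
                 tolerance = 1e-12)
  }
})

test_that("morphometry is invariant under rigid motion", {
  tree <- simulate_neuron(neuron_sim_params(), "diploid", seed = 9)
  a <- compartment_summary(tree)
  b <- compartment_summary(rigid_transform(tree))
  num <- vapply(a, is.numeric, logical(1))
  expect_equal(as.numeric(a[num]), as.numeric(b[num]), tolerance = 1e-9)
})

test_that("scaling lengths by a and radii by b rescales V by a*b^2 and A by a*b", {
  a <- 1.95; b <- 0.877
  tree <- simulate_neuron(neuron_sim_params(taper_ratio = 1,
                                            diameter_cv = 0),
                          "diploid", seed = 4)
  scaled <- tree
  # scale all edge vectors by a (walk from root), radii of neurites by b
  scaled <- ploidyscale:::rescale_neuron(tree, list(
    soma_volume_fold = 1, neurite_length_fold = a,
    neurite_diameter_fold = b))
  m0 <- segment_metrics(tree); m1 <- segment_metrics(scaled)
  expect_equal(sum(m1$volume) / sum(m0$volume), a * b^2, tolerance = 1e-9)
  # cylinders, so the lateral-area identity is exact
  expect_equal(sum(m1$lateral_area) / sum(m0$lateral_area), a * b,
               tolerance = 1e-9)
})

test_that("sholl counts sphere crossings of straight and branched neurites", {
  path <- make_path_tree(n_edges = 10, len = 10, r = 0.5)
  pr <- sholl(path, step = 10)
  expect_equal(pr$intersections[pr$radius <= 100], rep(1L, 10))

  # stem along +x of length 15, bifurcating into two branches of length 15
  bin <- make_binary_tree(depth = 1, stem_len = 15, seg_len = 15)
  pr2 <- sholl(bin, step = 10)
  expect_equal(pr2$intersections[pr2$radius == 10], 1L)
  expect_equal(pr2$intersections[pr2$radius == 20], 2L)
})

test_that("sholl crossings at fine steps cover every tip path (brute force)", {
  tree <- simulate_neuron(neuron_sim_params(), "diploid", seed = 5)
  pr <- sholl(tree, step = 1)
  rec <- compartment_summary(tree)
  # every tip's path crosses every sphere inside its extent
  expect_gte(sum(pr$intersections), rec$n_terminal_points)
  # brute-force recount per edge
  n <- tree$nodes
  d <- sqrt(n$x^2 + n$y^2 + n$z^2)
  child <- which(n$node_type == "neurite"); par <- n$parent_id[child]
  brute <- vapply(pr$radius, function(r)
    sum(pmin(d[child], d[par]) < r & pmax(d[child], d[par]) >= r),
    integer(1))
  expect_equal(pr$intersections, brute)
})

test_that("cumulative length-by-diameter curves behave as step functions", {
  seg <- data.frame(length = c(10, 10), mean_diameter = c(1, 1))
  lbd <- length_by_diameter(seg, grid = c(0.5, 1, 1.5))
  expect_equal(lbd$cumulative_length_fraction, c(0, 1, 1))

  seg2 <- data.frame(length = c(10, 10), mean_diameter = c(1, 2))
  lbd2 <- length_by_diameter(seg2, grid = c(1, 1.5, 2))
  expect_equal(lbd2$cumulative_length_fraction, c(0.5, 0.5, 1))
  expect_error(length_by_diameter(seg2[0, ]), "no segments")
})

test_that("triploid length-by-diameter curves lie left of diploid", {
  p <- neuron_sim_params()
  grid <- seq(0.1, 3, by = 0.1)
  for (s in 1:5) {
    dip <- segment_metrics(simulate_neuron(p, "diploid", seed = s))
    tri <- segment_metrics(simulate_neuron(p, "triploid", seed = s))
    cd <- length_by_diameter(dip, grid)$cumulative_length_fraction
    ct <- length_by_diameter(tri, grid)$cumulative_length_fraction
    expect_true(all(ct >= cd - 1e-12))
    expect_gt(max(ct - cd), 0)
  }
})

test_that("weighted KS reduces to the classical statistic and handles edge cases", {
  ga <- data.frame(value = c(1, 1), weight = 1, unit = c("a1", "a2"))
  same <- weighted_ks(ga, ga, n_perm = 200, seed = 1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  gb <- data.frame(value = c(5, 6), weight = 1, unit = c("b1", "b2"))
  expect_equal(weighted_ks(ga, gb, n_perm = 200, seed = 1)$statistic, 1)

  set.seed(8)
  xa <- rnorm(40); xb <- rnorm(35, 0.5)
  wa <- data.frame(value = xa, weight = 1, unit = paste0("a", 1:40))
  wb <- data.frame(value = xb, weight = 1, unit = paste0("b", 1:35))
  D_ref <- unname(stats::ks.test(xa, xb)$statistic)
  expect_equal(weighted_ks(wa, wb, n_perm = 100, seed = 1)$statistic, D_ref,
               tolerance = 1e-12)
  expect_warning(weighted_ks(wa, wb, n_perm = 50, seed = 1), "coarse")
})

test_that("scaling classification splits at the reference band", {
  expect_equal(classify_scaling(1.5, 1.5, 0.1)$class, "scaling")
  expect_equal(classify_scaling(1.71, 1.5, 0.1)$class, "superscaling")
  expect_equal(classify_scaling(1.31, 1.5, 0.1)$class, "subscaling")
  expect_equal(classify_scaling(1.6, 1.5, 0.1)$class, "scaling")  # boundary
})

test_that("population folds recover identity and rescaled closed forms", {
  p <- neuron_sim_params()
  pop <- simulate_neuron_population(p, n = 15, seed = 3)
  dip <- do.call(rbind, lapply(pop$diploid, compartment_summary))
  tri <- do.call(rbind, lapply(pop$triploid, compartment_summary))

  self <- population_folds(dip, dip, n_boot = 200, seed = 1)
  expect_true(all(abs(self$fold - 1) < 1e-12))

  folds <- population_folds(dip, tri, n_boot = 500, seed = 1)
  soma_a <- folds[folds$property == "soma_surface", ]
  expect_equal(soma_a$fold, 1.5^(2 / 3), tolerance = 1e-6)
  expect_true(soma_a$ci_lo <= soma_a$fold && soma_a$fold <= soma_a$ci_hi)
  expect_error(population_folds(dip[1, ], tri), "at least 2")
})

test_that("deterministic cylinder-population neurite surface fold is sqrt(1.5*1.95)", {
  p <- neuron_sim_params(taper_ratio = 1, diameter_cv = 0,
                         segment_length_cv = 0, soma_radius_cv = 0)
  pop <- simulate_neuron_population(p, n = 5, seed = 2)
  dip <- do.call(rbind, lapply(pop$diploid, compartment_summary))
  tri <- do.call(rbind, lapply(pop$triploid, compartment_summary))
  fold <- mean(tri$neurite_surface) / mean(dip$neurite_surface)
  expect_equal(fold, sqrt(1.5 * 1.95), tolerance = 1e-6)
})

test_that("neurite share trend: flat input is stable, injected breaks are caught", {
  # constant fractions: slope ~ 0, CUSUM non-significant
  set.seed(13)
  rec <- data.frame(total_volume = runif(60, 5000, 20000))
  rec$neurite_volume <- 0.6 * rec$total_volume + rnorm(60, sd = 50)
  rec$total_surface <- rec$total_volume * 0.9
  rec$neurite_surface <- (0.8 + rnorm(60, sd = 0.01)) * rec$total_surface
  tr <- neurite_share_trend(rec)
  expect_lt(abs(tr$volume_share$slope), 1e-5)
  expect_gt(tr$volume_share$cusum_p, 0.05)

  # breakpoint in the share-size relation: power > 0.8 at n = 100
  hits <- 0
  for (i in 1:25) {
    set.seed(100 + i)
    x <- sort(runif(100, 0, 1))
    share <- ifelse(x < 0.5, 0.5, 0.5 + 1.5 * (x - 0.5)) + rnorm(100, sd = 0.05)
    rec2 <- data.frame(total_volume = x * 10000,
                       neurite_volume = share * x * 10000,
                       neurite_surface = share, total_surface = 1)
    tr2 <- neurite_share_trend(rec2)
    if (tr2$volume_share$cusum_p < 0.05) hits <- hits + 1
  }
  expect_gt(hits / 25, 0.8)
})

test_that("neurite surface share increases with total volume under defaults", {
  p <- neuron_sim_params()
  for (s in 1:3) {
    pop <- simulate_neuron_population(p, n = 25, seed = s)
    rec <- rbind(do.call(rbind, lapply(pop$diploid, compartment_summary)),
                 do.call(rbind, lapply(pop$triploid, compartment_summary)))
    tr <- neurite_share_trend(rec)
    expect_gt(tr$surface_share$slope, 0)
  }
})
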