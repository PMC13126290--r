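test_that("an all-bead input gates into beads only", {
  p <- flow_sim_params(n_cells = 1, bead_count = 500, doublet_fraction = 0,
                       debris_fraction = 0)
  ev <- simulate_flow_sample(p, "diploid", seed = 1)
  ev <- ev[ev$truth_class == "bead", ]
  g <- gate_events(ploidyscale:::as_event_table(
    as.data.frame(ev), "s", "diploid", "c1", 6, "r1"))
  expect_equal(nrow(g$beads), 500L)
  expect_equal(nrow(g$cells), 0L)
})

test_that("default cutoffs remove nearly all doublets and debris (truth labels)", {
  p <- flow_sim_params(n_cells = 10000)
  for (s in 1:5) {
    ev <- simulate_flow_sample(p, "diploid", seed = s)
    g <- gate_events(ev)
    n_doublets <- sum(ev$truth_class == "doublet")
    kept <- sum(g$cells$truth_class == "doublet")
    expect_lt(kept / n_doublets, 0.01)
    expect_equal(sum(g$cells$truth_class == "debris"), 0L)
    # and nearly all real cells survive
    expect_gt(nrow(g$cells) / sum(ev$truth_class == "cell"), 0.99)
  }
})

test_that("gating partitions exhaustively and is idempotent", {
  ev <- simulate_flow_sample(flow_sim_params(n_cells = 5000), "diploid",
                             seed = 2)
  g <- gate_events(ev)
  expect_equal(nrow(g$beads) + nrow(g$cells) + sum(g$discarded), nrow(ev))
  # re-gating the kept events reproduces the same partition
  md <- ploidyscale:::event_metadata(ev)
  kept <- ploidyscale:::as_event_table(
    rbind(as.data.frame(g$beads), as.data.frame(g$cells)),
    md$sample_id, md$ploidy, md$clutch, md$n_brains, md$run_id)
  g2 <- gate_events(kept)
  expect_equal(nrow(g2$beads), nrow(g$beads))
  expect_equal(nrow(g2$cells), nrow(g$cells))
  expect_equal(sum(g2$discarded), 0)
})

test_that("count_cells evaluates the bead formula and is linear", {
  expect_equal(count_cells(20800, 20800, 1), 20800)
  expect_equal(count_cells(10000, 5000, 6), 2 * 20800 / 6, tolerance = 1e-12)
  expect_equal(count_cells(10000, 5000, 6), 6933.333, tolerance = 1e-4)
  expect_equal(count_cells(2 * 10000, 5000, 6),
               2 * count_cells(10000, 5000, 6))
  expect_equal(count_cells(10000, 2 * 5000, 6),
               count_cells(10000, 5000, 6) / 2)
  expect_error(count_cells(100, 0, 1), "undefined")
  # derived constant: beads added per tube
  expect_equal(counting_config()$beads_added, 20800)
})

test_that("event table round trip preserves values", {
  ev <- simulate_flow_sample(flow_sim_params(n_cells = 200), "diploid",
                             seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, f)
  back <- read_events(f, ploidy = "diploid", n_brains = 6)
  for (ch in c("fsc_a", "hoechst", "pcna"))
    expect_equal(back[[ch]], ev[[ch]], tolerance = 1e-9)

  # missing channel is a named format error
  df <- read.csv(f); df$hoechst <- NULL
  write.csv(df, f, row.names = FALSE)
  expect_error(read_events(f), "hoechst")
})

# Build a synthetic gated sample directly: `n_beads` bead events with
# configurable mean/CV plus `n_cells` cell events.
fake_gated <- function(sample_id, clutch, ploidy, n_beads = 6000,
                       n_cells = 12000, bead_fsc_mean = 3e4,
                       bead_hoechst_mean = 500, bead_cv = 0.05,
                       run_id = "r1", seed = 1) {
  set.seed(seed)
  mk <- function(n, means) {
    data.frame(
      fsc_a = pmax(rnorm(n, means[1], bead_cv * means[1]), 0.01),
      fsc_w = pmax(rnorm(n, means[1], bead_cv * means[1]), 0.01),
      ssc_a = rep(1000, n), ssc_w = rep(1000, n),
      hoechst = pmax(rnorm(n, means[2], bead_cv * means[2]), 0.01),
      pcna = rep(10, n), ph3 = rep(10, n), bead_channel = rep(1, n))
  }
  list(beads = ploidyscale:::as_event_table(
    mk(n_beads, c(bead_fsc_mean, bead_hoechst_mean)),
    sample_id, ploidy, clutch, 6, run_id),
    cells = ploidyscale:::as_event_table(
      mk(n_cells, c(5e4, 200)), sample_id, ploidy, clutch, 6, run_id),
    discarded = c(none = 0))
}

test_that("each QC rule can be violated independently and pass is their conjunction", {
  base <- list(
    fake_gated("d1", "c1", "diploid", seed = 1),
    fake_gated("t1", "c1", "triploid", seed = 2),
    fake_gated("d2", "c2", "diploid", seed = 3),
    fake_gated("t2", "c2", "triploid", seed = 4))
  qc <- qc_batch(base)
  expect_true(all(qc$pass))

  # rule a: exactly 5000 bead events fails the strict > threshold
  viol <- base
  viol[[1]] <- fake_gated("d1", "c1", "diploid", n_beads = 5000, seed = 1)
  qc_a <- qc_batch(viol)
  expect_false(qc_a$rule_a[qc_a$sample_id == "d1"])
  expect_false(qc_a$pass[qc_a$sample_id == "d1"])
  expect_true(all(qc_a$pass[qc_a$sample_id != "d1"]))

  # rule b: 10,001 cells passes (strict >), 10,000 fails
  viol[[1]] <- fake_gated("d1", "c1", "diploid", n_cells = 10001, seed = 1)
  expect_true(qc_batch(viol)$rule_b[1])
  viol[[1]] <- fake_gated("d1", "c1", "diploid", n_cells = 10000, seed = 1)
  expect_false(qc_batch(viol)$rule_b[1])

  # rule c: shifting one sample's bead mean by > run CV fails only it
  viol <- base
  viol[[2]] <- fake_gated("t1", "c1", "triploid", bead_fsc_mean = 3e4 * 1.2,
                          seed = 2)
  qc_c <- qc_batch(viol)
  expect_false(qc_c$rule_c[qc_c$sample_id == "t1"])
  expect_true(all(qc_c$rule_c[qc_c$sample_id != "t1"]))

  # rule d: inflating one sample's bead CV fails rule d. The violating
  # sample also inflates the pooled run CV, so the batch must be large
  # enough for the run statistics to stay anchored by the good samples.
  many <- lapply(1:8, function(i)
    fake_gated(sprintf("s%d", i), sprintf("c%d", (i + 1) %/% 2),
               if (i %% 2) "diploid" else "triploid", seed = 10 + i))
  many[[3]] <- fake_gated("s3", "c2", "diploid", bead_cv = 0.30, seed = 13)
  qc_d <- qc_batch(many)
  expect_false(qc_d$rule_d[qc_d$sample_id == "s3"])
  expect_true(all(qc_d$rule_d[qc_d$sample_id != "s3"]))

  # rule e: removing the ploidy partner fails both remaining checks
  qc_e <- qc_batch(base[c(1, 3, 4)])
  expect_false(qc_e$rule_e[qc_e$sample_id == "d1"])
  expect_true(all(qc_e$rule_e[qc_e$sample_id %in% c("d2", "t2")]))
})

test_that("a single-sample run is QC'd against itself with a warning", {
  expect_warning(qc <- qc_batch(list(fake_gated("solo", "c1", "diploid"))),
                 "single sample")
  expect_true(qc$single_sample_run)
  expect_false(qc$rule_e)
})

test_that("count regression accepts exact reverse scaling and rejects identity as fold 1", {
  set.seed(5)
  stages <- rep(c(44, 45, 46), each = 4)
  dip <- data.frame(ploidy = "diploid", stage = stages,
                    cells_per_brain = 5000 + 300 * (stages - 44) +
                      rnorm(12, sd = 100))
  tri <- dip; tri$ploidy <- "triploid"
  tri$cells_per_brain <- dip$cells_per_brain / 1.5
  res <- count_fold_analysis(rbind(dip, tri))
  expect_equal(res$fold, 1.5, tolerance = 1e-12)
  expect_gt(res$scaled_test$p_value, 0.9)  # exact construction: no deviation

  same <- count_fold_analysis(rbind(dip, transform(dip, ploidy = "triploid")))
  expect_equal(same$fold, 1.0)
  expect_error(count_fold_analysis(dip[1:2, ]), "at least 3")
})
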