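#' Gate configuration
#'
#' Cutoffs reproducing the study's gating hierarchy: singlet discrimination
#' by FSC-W/FSC-A, bead separation by bead-channel intensity, and single
#' cell confirmation by SSC-W/SSC-A and a minimum Hoechst intensity.
#' Defaults are calibrated on the synthetic generator (the original gates
#' were drawn by hand in a flow-analysis GUI).
#'
#' @param singlet_wa_ratio_max Maximum FSC-W/FSC-A for singlets.
#' @param bead_channel_min Bead-channel intensity separating beads from
#'   non-beads among singlets.
#' @param ssc_wa_ratio_max Maximum SSC-W/SSC-A for single cells.
#' @param hoechst_min Minimum Hoechst intensity for single cells (excludes
#'   sub-G1 debris).
#' @return A `gate_config` list.
#' @export
gate_config <- function(singlet_wa_ratio_max = 1.3, bead_channel_min = 1e4,
                        ssc_wa_ratio_max = 1.3, hoechst_min = 100) {
  for (nm in c("singlet_wa_ratio_max", "bead_channel_min",
               "ssc_wa_ratio_max", "hoechst_min"))
    check_pos(get(nm), nm)
  structure(list(singlet_wa_ratio_max = singlet_wa_ratio_max,
                 bead_channel_min = bead_channel_min,
                 ssc_wa_ratio_max = ssc_wa_ratio_max,
                 hoechst_min = hoechst_min),
            class = "gate_config")
}

#' Gate an event table into beads, cells, and discarded events
#'
#' Hierarchy: (1) singlets = events with `fsc_w/fsc_a <=
#' singlet_wa_ratio_max` (events with zero FSC-A are discarded with their
#' own reason); (2) beads = singlets with `bead_channel >=
#' bead_channel_min`; (3) cells = remaining singlets passing `ssc_w/ssc_a
#' <= ssc_wa_ratio_max` and `hoechst >= hoechst_min`. The partition of
#' input events into beads, cells, and discarded is exhaustive and
#' disjoint, and gating is idempotent on its own output.
#'
#' @param events An `event_table`.
#' @param cfg A [gate_config()].
#' @return list with `beads` and `cells` (event tables inheriting the
#'   sample metadata) and `discarded`, a named count vector by reason
#'   (`zero_fsc_a`, `fsc_doublet`, `ssc_doublet`, `low_hoechst`).
#' @export
gate_events <- function(events, cfg = gate_config()) {
  stopifnot(inherits(events, "event_table"), inherits(cfg, "gate_config"))
  md <- event_metadata(events)
  df <- as.data.frame(events)
  zero_fsc <- df$fsc_a <= 0
  wa <- ifelse(zero_fsc, Inf, df$fsc_w / df$fsc_a)
  singlet <- !zero_fsc & wa <= cfg$singlet_wa_ratio_max
  is_bead <- singlet & df$bead_channel >= cfg$bead_channel_min
  rest <- singlet & !is_bead
  ssc_ok <- df$ssc_a > 0 & (df$ssc_w / pmax(df$ssc_a, .Machine$double.eps)) <=
    cfg$ssc_wa_ratio_max
  hoechst_ok <- df$hoechst >= cfg$hoechst_min
  is_cell <- rest & ssc_ok & hoechst_ok
  discarded <- c(
    zero_fsc_a = sum(zero_fsc),
    fsc_doublet = sum(!zero_fsc & !singlet),
    ssc_doublet = sum(rest & !ssc_ok),
    low_hoechst = sum(rest & ssc_ok & !hoechst_ok))
  remake <- function(sub) as_event_table(df[sub, , drop = FALSE],
                                         sample_id = md$sample_id,
                                         ploidy = md$ploidy, clutch = md$clutch,
                                         n_brains = md$n_brains,
                                         run_id = md$run_id)
  list(beads = remake(is_bead), cells = remake(is_cell), discarded = discarded)
}

#' Counting-bead configuration
#'
#' The bead stock contains `0.52e5` beads per 50 uL and 20 uL are added to
#' each tube, so every tube receives `0.52e5 * 20 / 50 = 20,800` beads.
#'
#' @param beads_per_stock_aliquot Beads per stock aliquot (default 0.52e5).
#' @param stock_aliquot_volume Stock aliquot volume in uL (default 50).
#' @param added_volume Volume added per tube in uL (default 20).
#' @return A `counting_config` list with derived `beads_added`.
#' @export
counting_config <- function(beads_per_stock_aliquot = 0.52e5,
                            stock_aliquot_volume = 50, added_volume = 20) {
  check_pos(beads_per_stock_aliquot, "beads_per_stock_aliquot")
  check_pos(stock_aliquot_volume, "stock_aliquot_volume")
  check_pos(added_volume, "added_volume")
  structure(list(beads_per_stock_aliquot = beads_per_stock_aliquot,
                 stock_aliquot_volume = stock_aliquot_volume,
                 added_volume = added_volume,
                 beads_added = beads_per_stock_aliquot * added_volume /
                   stock_aliquot_volume),
            class = "counting_config")
}

#' Bead-normalized absolute cell count per brain
#'
#' `N = (n_cell_events / n_bead_events) * (1 / n_brains) *
#' (beads_per_stock_aliquot / stock_aliquot_volume) * added_volume`,
#' i.e. with the default bead stock the recorded cell:bead event ratio
#' times the 20,800 beads added per tube, divided by the number of brains
#' pooled in the tube. Exactly linear in `n_cell_events` and inversely
#' linear in `n_bead_events` and `n_brains`.
#'
#' @param n_cell_events Gated single-cell event count.
#' @param n_bead_events Gated bead event count (> 0).
#' @param n_brains Brains pooled per tube (>= 1).
#' @param cfg A [counting_config()].
#' @return Cells per brain (numeric).
#' @export
count_cells <- function(n_cell_events, n_bead_events, n_brains,
                        cfg = counting_config()) {
  if (any(n_bead_events <= 0))
    stop("n_bead_events must be > 0 (cell:bead ratio undefined)", call. = FALSE)
  if (any(n_brains < 1)) stop("n_brains must be >= 1", call. = FALSE)
  (n_cell_events / n_bead_events) / n_brains * cfg$beads_added
}

#' Post-hoc quality control of gated samples within a run
#'
#' Applies the five acceptance rules per sample: (a) more than 5,000 bead
#' events; (b) more than 10,000 single-cell events; (c) the sample's bead
#' means of FSC-A and Hoechst fall inside `run_mean * (1 +/- run_CV)` for
#' each channel; (d) the sample's bead CVs of those channels are below
#' twice the run CV; (e) a ploidy-matched sample from the same clutch
#' exists in the batch. Run statistics are computed over bead events pooled
#' across all samples of the run. A sample passes only if all five rules
#' hold.
#'
#' @param gated_samples List of [gate_events()] results (each with `beads`
#'   and `cells`).
#' @param min_beads,min_cells Rule a/b thresholds (strict `>`).
#' @return data.frame with one row per sample: event counts, bead channel
#'   statistics, `rule_a` ... `rule_e`, `pass`, and a `single_sample_run`
#'   flag when rules c/d had to be computed against the sample itself.
#' @export
qc_batch <- function(gated_samples, min_beads = 5000, min_cells = 10000) {
  if (!length(gated_samples)) stop("no samples supplied", call. = FALSE)
  meta <- lapply(gated_samples, function(g) event_metadata(g$beads))
  runs <- vapply(meta, `[[`, "", "run_id")
  rows <- vector("list", length(gated_samples))
  for (run in unique(runs)) {
    idx <- which(runs == run)
    pooled_fsc <- unlist(lapply(gated_samples[idx],
                                function(g) g$beads$fsc_a))
    pooled_hoechst <- unlist(lapply(gated_samples[idx],
                                    function(g) g$beads$hoechst))
    run_stats <- list(
      fsc = c(mean = mean(pooled_fsc),
              cv = stats::sd(pooled_fsc) / mean(pooled_fsc)),
      hoechst = c(mean = mean(pooled_hoechst),
                  cv = stats::sd(pooled_hoechst) / mean(pooled_hoechst)))
    single_run <- length(idx) == 1L
    if (single_run)
      warning("run `", run, "` has a single sample; QC rules c/d compared ",
              "against the sample itself")
    for (i in idx) {
      g <- gated_samples[[i]]
      m <- meta[[i]]
      nb <- nrow(g$beads); nc <- nrow(g$cells)
      bf <- g$beads$fsc_a; bh <- g$beads$hoechst
      s_mean <- c(fsc = mean(bf), hoechst = mean(bh))
      s_cv <- c(fsc = stats::sd(bf) / mean(bf),
                hoechst = stats::sd(bh) / mean(bh))
      in_band <- function(ch) {
        rs <- run_stats[[ch]]
        lo <- rs[["mean"]] * (1 - rs[["cv"]]); hi <- rs[["mean"]] * (1 + rs[["cv"]])
        s_mean[[ch]] >= lo && s_mean[[ch]] <= hi
      }
      rule_a <- nb > min_beads
      rule_b <- nc > min_cells
      rule_c <- in_band("fsc") && in_band("hoechst")
      rule_d <- s_cv[["fsc"]] < 2 * run_stats$fsc[["cv"]] &&
        s_cv[["hoechst"]] < 2 * run_stats$hoechst[["cv"]]
      rule_e <- any(vapply(meta[idx], function(o) {
        !identical(o$sample_id, m$sample_id) &&
          identical(o$clutch, m$clutch) && !identical(o$ploidy, m$ploidy)
      }, logical(1)))
      rows[[i]] <- data.frame(
        sample_id = m$sample_id, ploidy = m$ploidy, clutch = m$clutch,
        run_id = m$run_id, n_bead_events = nb, n_cell_events = nc,
        bead_fsc_mean = s_mean[["fsc"]], bead_hoechst_mean = s_mean[["hoechst"]],
        bead_fsc_cv = s_cv[["fsc"]], bead_hoechst_cv = s_cv[["hoechst"]],
        rule_a = rule_a, rule_b = rule_b, rule_c = rule_c, rule_d = rule_d,
        rule_e = rule_e, pass = rule_a && rule_b && rule_c && rule_d && rule_e,
        single_sample_run = single_run, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Developmental count regression and scaled-line comparison
#'
#' Regresses cells-per-brain on stage separately per ploidy and tests, in
#' ANCOVA style, whether the triploid line differs from the diploid line
#' scaled by `1/reference_fold` (the reverse-scaling expectation: triploid
#' counts = diploid counts / 1.5). Also reports the plain diploid/triploid
#' count fold.
#'
#' @param counts data.frame with columns `ploidy` (`diploid`/`triploid`),
#'   `stage` (numeric), `cells_per_brain`.
#' @param reference_fold Expected diploid/triploid fold (default 1.5).
#' @return list with `fold` (mean diploid / mean triploid), `fits` (per
#'   ploidy lm), `scaled_test` (anova comparing triploid data against the
#'   scaled diploid prediction: `p_value` non-significant when the reverse
#'   scaling holds).
#' @export
count_fold_analysis <- function(counts, reference_fold = 1.5) {
  stopifnot(all(c("ploidy", "stage", "cells_per_brain") %in% names(counts)))
  dip <- counts[counts$ploidy == "diploid", ]
  tri <- counts[counts$ploidy == "triploid", ]
  if (nrow(dip) < 3 || nrow(tri) < 3)
    stop("need at least 3 samples per ploidy", call. = FALSE)
  fits <- list(diploid = stats::lm(cells_per_brain ~ stage, data = dip),
               triploid = stats::lm(cells_per_brain ~ stage, data = tri))
  # ANCOVA-style: do triploid counts deviate from diploid/fold? Model the
  # pooled data with triploid counts multiplied back by the reference fold;
  # a ploidy main effect or interaction then signals deviation.
  pooled <- rbind(
    transform(dip, y = cells_per_brain),
    transform(tri, y = cells_per_brain * reference_fold))
  full <- stats::lm(y ~ stage * ploidy, data = pooled)
  red <- stats::lm(y ~ stage, data = pooled)
  an <- stats::anova(red, full)
  list(fold = mean(dip$cells_per_brain) / mean(tri$cells_per_brain),
       fits = fits,
       scaled_test = list(p_value = an[["Pr(>F)"]][2], anova = an))
}
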