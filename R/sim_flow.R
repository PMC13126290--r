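#' Parameters for the synthetic flow-cytometry sample generator
#'
#' Emulates a dissociated-brain tube: singlet cells with phase-dependent
#' Hoechst DNA content, PCNA and pH3 marker intensities drawn from
#' log-normal mixture components tied to the true phase, a spike-in of
#' counting beads, plus doublet and sub-G1 debris nuisance events. A
#' triploid sample multiplies all DNA means by `genome_fold` and divides
#' the number of cells by `count_fold` (fewer cells per brain, the same
#' number of brains per tube).
#'
#' @param n_cells Singlet cell events per (diploid) tube.
#' @param phase_fractions Named probabilities for G0, G1, S, G2, M summing
#'   to 1.
#' @param g1_dna_mean Diploid G1 Hoechst mean (a.u.).
#' @param dna_cv Multiplicative lognormal CV of DNA staining.
#' @param genome_fold Triploid multiplier on DNA means (default 1.5).
#' @param count_fold Diploid/triploid ratio of cells per tube (default 1.5).
#' @param pcna_mixture 3 x 2 matrix (rows neg/diffuse/punctate, columns
#'   log10 mean and sd) of PCNA intensity components.
#' @param ph3_mixture 2 x 2 matrix (rows neg/pos) for pH3.
#' @param phase_to_marker Named list mapping each phase to its PCNA and pH3
#'   component (`G0` is PCNA-negative, `S` PCNA-punctate, `M` pH3-positive,
#'   `G1`/`G2` PCNA-diffuse).
#' @param bead_count Bead events recorded per tube.
#' @param bead_channel_mean Bead channel intensity of beads (a.u.).
#' @param doublet_fraction,debris_fraction Nuisance event rates relative to
#'   `n_cells`.
#' @param n_brains Brains pooled per tube (default 6).
#' @return A validated `flow_sim_params` list.
#' @export
flow_sim_params <- function(n_cells = 20000,
                            phase_fractions = c(G0 = 0.45, G1 = 0.25,
                                                S = 0.15, G2 = 0.10, M = 0.05),
                            g1_dna_mean = 200,
                            dna_cv = 0.05,
                            genome_fold = 1.5,
                            count_fold = 1.5,
                            pcna_mixture = rbind(neg = c(1.0, 0.12),
                                                 diffuse = c(1.8, 0.12),
                                                 punctate = c(2.6, 0.12)),
                            ph3_mixture = rbind(neg = c(1.0, 0.15),
                                                pos = c(2.2, 0.15)),
                            phase_to_marker = list(
                              G0 = c(pcna = "neg", ph3 = "neg"),
                              G1 = c(pcna = "diffuse", ph3 = "neg"),
                              S = c(pcna = "punctate", ph3 = "neg"),
                              G2 = c(pcna = "diffuse", ph3 = "neg"),
                              M = c(pcna = "diffuse", ph3 = "pos")),
                            bead_count = 8000,
                            bead_channel_mean = 1e5,
                            doublet_fraction = 0.05,
                            debris_fraction = 0.05,
                            n_brains = 6) {
  stopifnot(n_cells >= 1, bead_count >= 0, n_brains >= 1)
  if (abs(sum(phase_fractions) - 1) > 1e-9)
    stop("phase_fractions must sum to 1", call. = FALSE)
  stopifnot(setequal(names(phase_fractions), c("G0", "G1", "S", "G2", "M")))
  check_pos(g1_dna_mean, "g1_dna_mean")
  check_pos(dna_cv, "dna_cv", strict = FALSE)
  check_pos(genome_fold, "genome_fold")
  check_pos(count_fold, "count_fold")
  check_prob(doublet_fraction, "doublet_fraction")
  check_prob(debris_fraction, "debris_fraction")
  structure(list(n_cells = as.integer(n_cells),
                 phase_fractions = phase_fractions[c("G0", "G1", "S", "G2", "M")],
                 g1_dna_mean = g1_dna_mean, dna_cv = dna_cv,
                 genome_fold = genome_fold, count_fold = count_fold,
                 pcna_mixture = pcna_mixture, ph3_mixture = ph3_mixture,
                 phase_to_marker = phase_to_marker,
                 bead_count = as.integer(bead_count),
                 bead_channel_mean = bead_channel_mean,
                 doublet_fraction = doublet_fraction,
                 debris_fraction = debris_fraction,
                 n_brains = as.integer(n_brains)),
            class = "flow_sim_params")
}

#' Simulate one flow-cytometry event table
#'
#' Cells draw their DNA content from the phase-dependent mean (G0/G1 at 1x,
#' G2/M at 2x the G1 mean, S uniform between 1x and 2x before noise) times
#' multiplicative lognormal noise of CV `dna_cv`. Doublets are sums of two
#' sampled cells with inflated FSC-W; debris carries sub-G1 DNA. Every row
#' keeps its latent labels in `truth_*` columns so downstream recovery can
#' be asserted against ground truth.
#'
#' @param params A [flow_sim_params()].
#' @param ploidy `"diploid"` or `"triploid"`.
#' @param seed Integer seed.
#' @param sample_id,clutch,run_id Metadata attached to the table.
#' @return An `event_table`: data.frame with channels `fsc_a`, `fsc_w`,
#'   `ssc_a`, `ssc_w`, `hoechst`, `pcna`, `ph3`, `bead_channel`, truth
#'   columns `truth_class` (cell/bead/doublet/debris) and `truth_phase`,
#'   and metadata attributes (`sample_id`, `ploidy`, `clutch`, `n_brains`,
#'   `run_id`).
#' @export
simulate_flow_sample <- function(params, ploidy = c("diploid", "triploid"),
                                 seed = 1L, sample_id = NULL,
                                 clutch = "clutch1", run_id = "run1") {
  stopifnot(inherits(params, "flow_sim_params"))
  ploidy <- match.arg(ploidy)
  p <- params
  dna_scale <- if (ploidy == "triploid") p$genome_fold else 1
  n_cells <- if (ploidy == "triploid") max(1L, round(p$n_cells / p$count_fold))
  else p$n_cells
  tab <- with_seed(seed, {
    phases <- sample(names(p$phase_fractions), n_cells, replace = TRUE,
                     prob = p$phase_fractions)
    base <- p$g1_dna_mean * dna_scale
    dna_mean <- ifelse(phases %in% c("G0", "G1"), base,
                       ifelse(phases %in% c("G2", "M"), 2 * base, NA))
    s_idx <- phases == "S"
    dna_mean[s_idx] <- base * stats::runif(sum(s_idx), 1, 2)
    hoechst <- dna_mean * rlnorm_mean_cv(n_cells, 1, p$dna_cv)
    pcna_k <- vapply(phases, function(ph) p$phase_to_marker[[ph]][["pcna"]], "")
    ph3_k <- vapply(phases, function(ph) p$phase_to_marker[[ph]][["ph3"]], "")
    pcna <- 10^stats::rnorm(n_cells, p$pcna_mixture[pcna_k, 1],
                            p$pcna_mixture[pcna_k, 2])
    ph3 <- 10^stats::rnorm(n_cells, p$ph3_mixture[ph3_k, 1],
                           p$ph3_mixture[ph3_k, 2])
    fsc_a <- rlnorm_mean_cv(n_cells, 5e4, 0.3)
    cells <- data.frame(
      fsc_a = fsc_a,
      fsc_w = fsc_a * stats::rnorm(n_cells, 1, 0.03),
      ssc_a = rlnorm_mean_cv(n_cells, 3e4, 0.3),
      hoechst = hoechst, pcna = pcna, ph3 = ph3,
      bead_channel = rlnorm_mean_cv(n_cells, 100, 0.3),
      truth_class = "cell", truth_phase = phases)
    cells$ssc_w <- cells$ssc_a * stats::rnorm(n_cells, 1, 0.03)

    n_beads <- p$bead_count
    bead_fsc <- rlnorm_mean_cv(n_beads, 3e4, 0.05)
    beads <- data.frame(
      fsc_a = bead_fsc, fsc_w = bead_fsc * stats::rnorm(n_beads, 1, 0.02),
      ssc_a = rlnorm_mean_cv(n_beads, 2e4, 0.05),
      hoechst = rlnorm_mean_cv(n_beads, 500, 0.05),
      pcna = rlnorm_mean_cv(n_beads, 50, 0.2),
      ph3 = rlnorm_mean_cv(n_beads, 50, 0.2),
      bead_channel = rlnorm_mean_cv(n_beads, p$bead_channel_mean, 0.05),
      truth_class = "bead", truth_phase = NA_character_)
    beads$ssc_w <- beads$ssc_a * stats::rnorm(n_beads, 1, 0.02)

    n_dbl <- round(p$doublet_fraction * n_cells)
    doublets <- NULL
    if (n_dbl > 0) {
      i1 <- sample(n_cells, n_dbl, replace = TRUE)
      i2 <- sample(n_cells, n_dbl, replace = TRUE)
      dbl_fsc <- cells$fsc_a[i1] + cells$fsc_a[i2]
      doublets <- data.frame(
        fsc_a = dbl_fsc,
        fsc_w = dbl_fsc * stats::rnorm(n_dbl, 1.8, 0.1),
        ssc_a = cells$ssc_a[i1] + cells$ssc_a[i2],
        hoechst = cells$hoechst[i1] + cells$hoechst[i2],
        pcna = cells$pcna[i1] + cells$pcna[i2],
        ph3 = cells$ph3[i1] + cells$ph3[i2],
        bead_channel = rlnorm_mean_cv(n_dbl, 100, 0.3),
        truth_class = "doublet", truth_phase = NA_character_)
      doublets$ssc_w <- doublets$ssc_a * stats::rnorm(n_dbl, 1.8, 0.1)
    }

    n_deb <- round(p$debris_fraction * n_cells)
    debris <- NULL
    if (n_deb > 0) {
      deb_fsc <- rlnorm_mean_cv(n_deb, 1e4, 0.4)
      debris <- data.frame(
        fsc_a = deb_fsc, fsc_w = deb_fsc * stats::rnorm(n_deb, 1, 0.05),
        ssc_a = rlnorm_mean_cv(n_deb, 8e3, 0.4),
        hoechst = stats::runif(n_deb, 1, 0.3 * p$g1_dna_mean),
        pcna = rlnorm_mean_cv(n_deb, 20, 0.4),
        ph3 = rlnorm_mean_cv(n_deb, 20, 0.4),
        bead_channel = rlnorm_mean_cv(n_deb, 100, 0.3),
        truth_class = "debris", truth_phase = NA_character_)
      debris$ssc_w <- debris$ssc_a * stats::rnorm(n_deb, 1, 0.05)
    }

    all <- rbind(cells, beads, doublets, debris)
    all <- all[sample(nrow(all)), ]
    rownames(all) <- NULL
    # channel values must be non-negative
    chan <- c("fsc_a", "fsc_w", "ssc_a", "ssc_w", "hoechst", "pcna", "ph3",
              "bead_channel")
    all[chan] <- lapply(all[chan], function(v) pmax(v, 0))
    all
  })
  if (is.null(sample_id)) sample_id <- sprintf("%s_seed%d", ploidy, as.integer(seed))
  as_event_table(tab, sample_id = sample_id, ploidy = ploidy, clutch = clutch,
                 n_brains = p$n_brains, run_id = run_id)
}
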