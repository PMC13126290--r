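#' Combine DNA-content, PCNA, and pH3 fits into phase fractions
#'
#' Merges the three deconvolutions into G0/G1/S/G2/M fractions and
#' absolute per-brain counts. The default combination rule takes M from
#' the pH3-positive weight, G0 from the PCNA-negative weight, S from the
#' PCNA-punctate weight, G2 as the DNA-content G2/M weight minus M
#' (floored at zero), and G1 as the remainder (clipped at zero and
#' renormalized; a clip above 0.05 raises an inconsistency warning). With
#' `s_source = "djf"` the S fraction is taken from the DNA-content fit
#' instead of the PCNA punctate component.
#'
#' Confidence intervals, when cell-level data are supplied, come from
#' resampling events: each cell is hard-assigned to a phase using the
#' fitted assignment boundaries (pH3 boundary for M, PCNA boundaries for
#' G0 and S, the midpoint between the fitted G1 and G2 means for G1
#' versus G2), and the multinomial phase fractions are bootstrapped.
#'
#' @param djf A [fit_djf()] result.
#' @param pcna A [fit_log_mixture()] result with k = 3.
#' @param ph3 A [fit_log_mixture()] result with k = 2.
#' @param cells_per_brain Absolute count from [count_cells()].
#' @param events Optional gated cell `event_table` (columns `hoechst`,
#'   `pcna`, `ph3`) for bootstrap CIs.
#' @param s_source `"pcna"` (default) or `"djf"`.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @return data.frame with one row per phase (G0, G1, S, G2, M):
#'   `fraction`, `count`, and (if events were given) `fraction_lo`,
#'   `fraction_hi`, `count_lo`, `count_hi` 95% CIs. Fractions sum to 1 and
#'   counts to `cells_per_brain`.
#' @export
classify_phases <- function(djf, pcna, ph3, cells_per_brain, events = NULL,
                            s_source = c("pcna", "djf"), n_boot = 1000,
                            seed = 1L) {
  stopifnot(inherits(djf, "cellcycle_fit"), inherits(pcna, "mixture_fit"),
            inherits(ph3, "mixture_fit"), pcna$k == 3L, ph3$k == 2L)
  s_source <- match.arg(s_source)
  m_frac <- ph3$weights[2]
  g0_frac <- pcna$weights[1]
  s_frac <- if (s_source == "pcna") pcna$weights[3] else djf$weights$s
  g2_frac <- max(0, djf$weights$g2m - m_frac)
  g1_raw <- 1 - g0_frac - s_frac - g2_frac - m_frac
  if (g1_raw < -0.05)
    warning(sprintf(
      "inconsistent fits: G1 remainder %.3f clipped to zero", g1_raw))
  frac <- c(G0 = g0_frac, G1 = max(0, g1_raw), S = s_frac, G2 = g2_frac,
            M = m_frac)
  frac <- frac / sum(frac)
  out <- data.frame(phase = names(frac), fraction = unname(frac),
                    count = unname(frac) * cells_per_brain,
                    stringsAsFactors = FALSE)
  if (!is.null(events)) {
    assign <- assign_phases(events, djf, pcna, ph3)
    boots <- with_seed(seed, {
      t(vapply(seq_len(n_boot), function(i) {
        s <- sample(assign, replace = TRUE)
        tabulate(factor(s, levels = names(frac)), nbins = 5) / length(s)
      }, numeric(5)))
    })
    ci <- apply(boots, 2, stats::quantile, probs = c(0.025, 0.975))
    out$fraction_lo <- ci[1, ]; out$fraction_hi <- ci[2, ]
    out$count_lo <- ci[1, ] * cells_per_brain
    out$count_hi <- ci[2, ] * cells_per_brain
  }
  out
}

#' Hard phase assignment of gated cells
#'
#' Applies the fitted assignment boundaries event-wise: pH3 above its
#' positive boundary is M; otherwise PCNA below the negative/diffuse
#' boundary is G0 and above the diffuse/punctate boundary is S; the rest
#' split into G1 versus G2 at the midpoint of the fitted DNA-content peak
#' means.
#'
#' @inheritParams classify_phases
#' @param events Gated cell `event_table`.
#' @return Character vector of phases, one per event.
#' @export
assign_phases <- function(events, djf, pcna, ph3) {
  lp <- log10(pmax(events$pcna, 1e-12))
  lh <- log10(pmax(events$ph3, 1e-12))
  m <- lh >= ph3$boundaries[1]
  g0 <- !m & lp < pcna$boundaries[1]
  s <- !m & lp >= pcna$boundaries[2]
  dna_cut <- (djf$g1_mean + djf$g2_mean) / 2
  g2 <- !m & !g0 & !s & events$hoechst >= dna_cut
  phase <- rep("G1", nrow(events))
  phase[m] <- "M"; phase[g0] <- "G0"; phase[s] <- "S"; phase[g2] <- "G2"
  phase
}
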