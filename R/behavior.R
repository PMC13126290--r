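#' Frame-wise speed series of a trajectory
#'
#' Finite-difference displacement over time step, with optional centered
#' moving-average smoothing. Gaps longer than three median frame
#' intervals break the differencing (no teleport speeds across tracking
#' dropouts). Speeds are floored at a small positivity epsilon so that
#' geometric averaging is defined.
#'
#' @param traj A `trajectory` (columns `t_s`, `x_mm`, `y_mm`).
#' @param smooth_window Odd window length for the moving average (1 = no
#'   smoothing).
#' @param floor Positivity floor in mm/s (default 1e-3).
#' @return data.frame with `t_s` (interval midpoint) and `speed` (mm/s).
#' @export
trajectory_speeds <- function(traj, smooth_window = 1, floor = 1e-3) {
  t <- traj$t_s
  if (anyDuplicated(t)) stop("duplicate timestamps in trajectory", call. = FALSE)
  if (length(t) < 2) stop("trajectory needs at least 2 samples", call. = FALSE)
  ord <- order(t)
  t <- t[ord]; x <- traj$x_mm[ord]; y <- traj$y_mm[ord]
  dt <- diff(t)
  sp <- sqrt(diff(x)^2 + diff(y)^2) / dt
  gap <- dt > 3 * stats::median(dt)
  sp[gap] <- NA_real_
  if (smooth_window > 1) {
    k <- rep(1 / smooth_window, smooth_window)
    sp <- stats::filter(sp, k, sides = 2)
    sp <- as.numeric(sp)
  }
  out <- data.frame(t_s = (t[-length(t)] + t[-1]) / 2,
                    speed = pmax(sp, floor))
  out[!is.na(out$speed), ]
}

#' Startle and cruising window speeds of one trajectory
#'
#' Geometric mean of the speed samples inside the startle window (first
#' second after stimulation) and the cruising window (last 60 s of the
#' session). Group comparisons downstream are run on log2 speeds.
#'
#' @param traj A `trajectory`.
#' @param startle_window Numeric `c(from, to)` in seconds (default
#'   `c(0, 1)`).
#' @param cruise_last Length of the cruising window at the end of the
#'   session, s (default 60).
#' @param smooth_window Passed to [trajectory_speeds()].
#' @return One-row data.frame: `animal_id`, `startle_speed`,
#'   `cruising_speed` (mm/s geometric means, `NA` when a window holds no
#'   samples), `active_fraction`, `activity_class`, `first_half_active`.
#' @export
window_speeds <- function(traj, startle_window = c(0, 1), cruise_last = 60,
                          smooth_window = 1) {
  sp <- trajectory_speeds(traj, smooth_window = smooth_window)
  session_end <- max(traj$t_s)
  if (startle_window[2] > session_end || cruise_last > session_end)
    stop("analysis windows exceed the session", call. = FALSE)
  in_startle <- sp$t_s >= startle_window[1] & sp$t_s <= startle_window[2]
  in_cruise <- sp$t_s >= session_end - cruise_last
  gm <- function(v) if (length(v)) geometric_mean(v) else NA_real_
  act <- classify_activity(traj)
  data.frame(animal_id = attr(traj, "animal_id") %||% NA_character_,
             startle_speed = gm(sp$speed[in_startle]),
             cruising_speed = gm(sp$speed[in_cruise]),
             active_fraction = act$active_fraction,
             activity_class = act$activity_class,
             first_half_active = act$first_half_active,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Activity classification of a trajectory
#'
#' A thresholded surrogate for manual activity scoring: the active
#' fraction is the share of speed samples above `speed_threshold`, binned
#' into still (< 0.25), half_active ([0.25, 0.75)), and active (>= 0.75).
#' For half-active animals, `first_half_active` reports whether the
#' majority of their active samples fall in the first half of the
#' session. The thresholds are configurable defaults, not a claim about
#' the original manual criteria.
#'
#' @param traj A `trajectory`.
#' @param speed_threshold Speed above which a sample counts as active,
#'   mm/s (default 1).
#' @param bin_edges Fractions splitting still/half_active/active (default
#'   `c(0.25, 0.75)`).
#' @return list with `active_fraction`, `activity_class`,
#'   `first_half_active` (`NA` unless half_active).
#' @export
classify_activity <- function(traj, speed_threshold = 1,
                              bin_edges = c(0.25, 0.75)) {
  check_pos(speed_threshold, "speed_threshold")
  sp <- trajectory_speeds(traj)
  active <- sp$speed > speed_threshold
  frac <- mean(active)
  cls <- if (frac < bin_edges[1]) "still"
  else if (frac < bin_edges[2]) "half_active"
  else "active"
  first_half <- NA
  if (cls == "half_active" && any(active)) {
    mid <- max(traj$t_s) / 2
    first_half <- mean(sp$t_s[active] <= mid) > 0.5
  }
  list(active_fraction = frac, activity_class = cls,
       first_half_active = first_half)
}

#' Speed trend across stimulation repetitions
#'
#' Linear trend of log2 window speed against repetition index, per
#' swimming mode; a flat, non-significant trend indicates no habituation
#' or sensitization across repeats.
#'
#' @param summaries data.frame with columns `repetition`, `startle_speed`,
#'   `cruising_speed` (one row per animal x repetition).
#' @return data.frame with one row per mode: `mode`, `slope`
#'   (log2 mm/s per repetition), `p_value`, `n`.
#' @export
repetition_trend <- function(summaries) {
  if (length(unique(summaries$repetition)) < 2)
    stop("need at least 2 repetitions", call. = FALSE)
  rows <- lapply(c(startle = "startle_speed", cruising = "cruising_speed"),
                 function(col) {
    d <- summaries[is.finite(summaries[[col]]) & summaries[[col]] > 0, ]
    fit <- stats::lm(log2(d[[col]]) ~ d$repetition)
    sm <- summary(fit)$coefficients
    data.frame(slope = sm[2, 1], p_value = sm[2, 4], n = nrow(d))
  })
  out <- do.call(rbind, rows)
  out$mode <- rownames(out)
  rownames(out) <- NULL
  out[c("mode", "slope", "p_value", "n")]
}

#' Compare window speeds between groups on the log2 scale
#'
#' Speeds are right-skewed, so group comparisons are run on log2 speeds
#' (Welch t-test) and reported back as geometric means and their ratio.
#'
#' @param summaries data.frame of [window_speeds()] rows with a `group`
#'   column (e.g. ploidy).
#' @param mode `"startle"` or `"cruising"`.
#' @param groups Length-2 character vector naming the groups to compare.
#' @return One-row data.frame: `mode`, the two geometric means, the
#'   second/first ratio, and the Welch p-value on log2 speeds.
#' @export
compare_speed_groups <- function(summaries, mode = c("startle", "cruising"),
                                 groups = c("diploid", "triploid")) {
  mode <- match.arg(mode)
  col <- paste0(if (mode == "startle") "startle" else "cruising", "_speed")
  pick <- function(g) {
    v <- summaries[[col]][summaries$group == g]
    v[is.finite(v) & v > 0]
  }
  a <- pick(groups[1]); b <- pick(groups[2])
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 animals per group", call. = FALSE)
  tt <- stats::t.test(log2(b), log2(a))
  data.frame(mode = mode,
             gm_1 = 2^mean(log2(a)), gm_2 = 2^mean(log2(b)),
             ratio = 2^(mean(log2(b)) - mean(log2(a))),
             p_value = tt$p.value, stringsAsFactors = FALSE)
}
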