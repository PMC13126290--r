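#' Parameters for the synthetic swim-trajectory generator
#'
#' Two-mode structure of a post-stimulus recording: a fast startle mode
#' for the first `startle_duration` seconds, then a slower cruising mode
#' for the rest of the session. Session length defaults to the 2-minute
#' recording so that both analysis windows (first second, last 60 s)
#' exist. A `still_fraction` of animals never moves.
#'
#' @param n_animals Animals per session (default 6, one arena).
#' @param startle_speed_mean Mean speed in the startle mode, mm/s.
#' @param startle_duration Duration of the startle mode, s (>= 1 so the
#'   1-s startle window lies inside it).
#' @param cruise_speed_mean Mean speed in the cruising mode, mm/s.
#' @param speed_cv Lognormal CV of frame-wise speeds.
#' @param frame_rate Sampling rate, Hz.
#' @param session_length Recording length, s (>= 61 so both windows exist).
#' @param still_fraction Probability that an animal is still throughout.
#' @return A `swim_sim_params` list.
#' @export
swim_sim_params <- function(n_animals = 6, startle_speed_mean = 20,
                            startle_duration = 3, cruise_speed_mean = 5,
                            speed_cv = 0.3, frame_rate = 30,
                            session_length = 120, still_fraction = 0) {
  stopifnot(n_animals >= 1)
  check_pos(startle_speed_mean, "startle_speed_mean")
  check_pos(cruise_speed_mean, "cruise_speed_mean")
  check_pos(startle_duration, "startle_duration")
  check_pos(frame_rate, "frame_rate")
  check_pos(speed_cv, "speed_cv", strict = FALSE)
  check_prob(still_fraction, "still_fraction")
  if (session_length < 61)
    stop("session_length must be >= 61 s so both analysis windows exist",
         call. = FALSE)
  structure(list(n_animals = as.integer(n_animals),
                 startle_speed_mean = startle_speed_mean,
                 startle_duration = startle_duration,
                 cruise_speed_mean = cruise_speed_mean,
                 speed_cv = speed_cv, frame_rate = frame_rate,
                 session_length = session_length,
                 still_fraction = still_fraction),
            class = "swim_sim_params")
}

#' Simulate a set of swim trajectories
#'
#' Each animal gets a (t, x, y) track: frame-wise speed is lognormal
#' around the startle mean for `t < startle_duration` and around the
#' cruise mean afterwards, with a slowly turning heading; still animals
#' do not move. The latent mode per frame and the still flag are kept as
#' truth columns.
#'
#' @param params A [swim_sim_params()].
#' @param seed Integer seed.
#' @param ploidy,clutch,repetition Metadata stored with each trajectory.
#' @return list of `trajectory` objects: data.frames with `t_s`, `x_mm`,
#'   `y_mm`, `truth_mode` (`startle`/`cruise`/`still`), and metadata
#'   attributes (`animal_id`, `ploidy`, `clutch`, `repetition`,
#'   `truth_still`).
#' @export
simulate_trajectories <- function(params, seed = 1L,
                                  ploidy = NA_character_,
                                  clutch = NA_character_, repetition = 1L) {
  stopifnot(inherits(params, "swim_sim_params"))
  p <- params
  with_seed(seed, {
    lapply(seq_len(p$n_animals), function(a) {
      tt <- seq(0, p$session_length, by = 1 / p$frame_rate)
      nf <- length(tt)
      still <- stats::runif(1) < p$still_fraction
      if (still) {
        x <- rep(50, nf); y <- rep(50, nf)
        mode <- rep("still", nf)
      } else {
        mode <- ifelse(tt < p$startle_duration, "startle", "cruise")
        mean_speed <- ifelse(mode == "startle", p$startle_speed_mean,
                             p$cruise_speed_mean)
        speed <- rlnorm_mean_cv(nf - 1, 1, p$speed_cv) * mean_speed[-1]
        heading <- cumsum(c(stats::runif(1, 0, 2 * pi),
                            stats::rnorm(nf - 2, sd = 0.2)))
        dtv <- diff(tt)
        x <- 50 + cumsum(c(0, speed * dtv * cos(heading)))
        y <- 50 + cumsum(c(0, speed * dtv * sin(heading)))
      }
      structure(data.frame(t_s = tt, x_mm = x, y_mm = y, truth_mode = mode),
                class = c("trajectory", "data.frame"),
                animal_id = sprintf("animal_%02d", a), ploidy = ploidy,
                clutch = clutch, repetition = as.integer(repetition),
                truth_still = still)
    })
  })
}

#' Read a trajectory CSV
#'
#' Expects columns `animal_id`, `t_s`, `x_mm`, `y_mm`; returns one
#' `trajectory` per animal.
#'
#' @param path CSV path.
#' @return list of `trajectory` objects.
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("animal_id", "t_s", "x_mm", "y_mm")
  if (!all(req %in% names(df)))
    stop("trajectory file must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  lapply(split(df, df$animal_id), function(d)
    structure(d[order(d$t_s), c("t_s", "x_mm", "y_mm")],
              class = c("trajectory", "data.frame"),
              animal_id = d$animal_id[1]))
}

#' Write trajectories to CSV
#'
#' @param trajectories list of `trajectory` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  rows <- lapply(trajectories, function(tr)
    cbind(animal_id = attr(tr, "animal_id"),
          as.data.frame(tr)[c("t_s", "x_mm", "y_mm")]))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
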