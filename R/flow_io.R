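FLOW_CHANNELS <- c("fsc_a", "fsc_w", "ssc_a", "ssc_w", "hoechst", "pcna",
                   "ph3", "bead_channel")

# Attach metadata and validate an event table.
as_event_table <- function(df, sample_id, ploidy, clutch, n_brains, run_id) {
  missing <- setdiff(FLOW_CHANNELS, names(df))
  if (length(missing))
    stop("event table missing channel column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (ch in FLOW_CHANNELS) {
    v <- df[[ch]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
      stop("channel `", ch, "` must be finite numeric", call. = FALSE)
    if (any(v < 0))
      stop("channel `", ch, "` contains negative values", call. = FALSE)
  }
  if (n_brains < 1) stop("n_brains must be >= 1", call. = FALSE)
  structure(df, class = c("event_table", class(df)),
            sample_id = sample_id, ploidy = ploidy, clutch = clutch,
            n_brains = as.integer(n_brains), run_id = run_id)
}

event_metadata <- function(events) {
  list(sample_id = attr(events, "sample_id"), ploidy = attr(events, "ploidy"),
       clutch = attr(events, "clutch"), n_brains = attr(events, "n_brains"),
       run_id = attr(events, "run_id"))
}

#' Read a flow-cytometry event table from CSV
#'
#' The canonical on-disk form is a CSV with one row per event, a header
#' naming the channels (`fsc_a`, `fsc_w`, `ssc_a`, `ssc_w`, `hoechst`,
#' `pcna`, `ph3`, `bead_channel`), and optional `truth_*` columns from the
#' simulator.
#'
#' @param path CSV path.
#' @param sample_id,ploidy,clutch,n_brains,run_id Sample metadata.
#' @param channel_map Optional named character vector renaming file columns
#'   to canonical channel names (e.g. from an FCS export),
#'   `c(hoechst = "Pacific.Blue.A")`.
#' @return An `event_table`.
#' @export
read_events <- function(path, sample_id = basename(path),
                        ploidy = NA_character_, clutch = NA_character_,
                        n_brains = 1L, run_id = NA_character_,
                        channel_map = NULL) {
  if (!file.exists(path)) stop("event file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(channel_map)) {
    for (canon in names(channel_map)) {
      src <- channel_map[[canon]]
      if (!src %in% names(df))
        stop("channel_map source column not found: ", src, call. = FALSE)
      names(df)[names(df) == src] <- canon
    }
  }
  as_event_table(df, sample_id = sample_id, ploidy = ploidy, clutch = clutch,
                 n_brains = n_brains, run_id = run_id)
}

#' Write an event table to CSV
#'
#' @param events An `event_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}
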