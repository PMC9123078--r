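# On-disk formats: one recording = three sibling plain-text files sharing a
# stem: <stem>_spikes.csv (header `time_s`, one spike per row),
# <stem>_events.csv (one row per polarizer rotation, epoch rows grouped) and
# <stem>_meta.json (neuron identity, session duration, sign convention,
# free-form metadata). Times are written at 1 microsecond resolution.

EVENT_COLS <- c("epoch_id", "t_on_s", "t_off_s", "dop", "rot_t_start_s",
                "direction", "start_angle_deg", "speed_deg_s", "sweep_deg")

recording_paths <- function(path) {
  stem <- sub("_spikes\\.csv$", "", path)
  list(spikes = paste0(stem, "_spikes.csv"),
       events = paste0(stem, "_events.csv"),
       meta = paste0(stem, "_meta.json"))
}

#' Read a recording from disk
#'
#' @param path the file stem, or the `<stem>_spikes.csv` path itself; the
#'   sibling `<stem>_events.csv` and `<stem>_meta.json` files must exist.
#' @return A validated [recording()].
#' @export
read_recording <- function(path) {
  p <- recording_paths(path)
  for (f in unlist(p))
    if (!file.exists(f)) stop(sprintf("missing recording file: %s", f))
  meta <- jsonlite::read_json(p$meta, simplifyVector = TRUE)
  for (field in c("neuron_id", "cell_type", "session_duration"))
    if (is.null(meta[[field]]))
      stop_validation(field, sprintf("missing from %s", p$meta))

  spk <- utils::read.csv(p$spikes)
  if (!identical(names(spk), "time_s"))
    stop(sprintf("parse error in %s: expected single column `time_s`", p$spikes))
  if (nrow(spk) && anyNA(suppressWarnings(as.numeric(spk$time_s)))) {
    bad <- which(is.na(suppressWarnings(as.numeric(spk$time_s))))[1L]
    stop(sprintf("parse error in %s at data line %d: non-numeric time",
                 p$spikes, bad))
  }
  st <- spike_train(meta$neuron_id, meta$cell_type,
                    as.numeric(spk$time_s), meta$session_duration)

  ev <- utils::read.csv(p$events, colClasses = c(
    epoch_id = "character", direction = "character"))
  if (!identical(names(ev), EVENT_COLS))
    stop(sprintf("parse error in %s: expected columns %s",
                 p$events, paste(EVENT_COLS, collapse = ",")))
  epochs <- list()
  if (nrow(ev)) {
    num_cols <- setdiff(EVENT_COLS, c("epoch_id", "direction"))
    for (cc in num_cols)
      if (anyNA(ev[[cc]]))
        stop(sprintf("parse error in %s at data line %d: bad value in %s",
                     p$events, which(is.na(ev[[cc]]))[1L], cc))
    for (id in unique(ev$epoch_id)) {
      rows <- ev[ev$epoch_id == id, , drop = FALSE]
      rots <- lapply(seq_len(nrow(rows)), function(i)
        polarizer_rotation(rows$rot_t_start_s[i], rows$direction[i],
                           rows$start_angle_deg[i], rows$speed_deg_s[i],
                           rows$sweep_deg[i]))
      epochs[[length(epochs) + 1L]] <-
        stimulus_epoch(rows$t_on_s[1L], rows$t_off_s[1L], rows$dop[1L],
                       rots, label = id)
    }
  }
  extra <- meta$metadata
  if (is.null(extra)) extra <- list()
  recording(st, epochs, metadata = as.list(extra))
}

#' Write a recording to disk
#'
#' Inverse of [read_recording()]: `read_recording()` of the written files
#' reproduces the recording to 1 microsecond time resolution.
#'
#' @param rec a valid [recording()].
#' @param path file stem; the three sibling files are written next to it.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  p <- recording_paths(path)
  dir.create(dirname(p$spikes), recursive = TRUE, showWarnings = FALSE)
  st <- rec$spike_train
  writeLines(c("time_s", sprintf("%.6f", st$spike_times)), p$spikes)

  rows <- character(0)
  for (i in seq_along(rec$epochs)) {
    ep <- rec$epochs[[i]]
    id <- if (nzchar(ep$label)) ep$label else sprintf("epoch%03d", i)
    for (rot in ep$rotations)
      rows <- c(rows, sprintf("%s,%.6f,%.6f,%.12g,%.6f,%s,%.6f,%.12g,%.12g",
                              id, ep$t_on, ep$t_off, ep$dop, rot$t_start,
                              rot$direction, rot$start_angle, rot$speed,
                              rot$sweep))
  }
  writeLines(c(paste(EVENT_COLS, collapse = ","), rows), p$events)

  meta <- list(neuron_id = st$neuron_id, cell_type = st$cell_type,
               session_duration = st$session_duration,
               angle_convention = "CW increases polarizer angle",
               metadata = rec$metadata)
  jsonlite::write_json(meta, p$meta, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
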