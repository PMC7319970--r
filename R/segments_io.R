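# Segment-table I/O and preprocessing: a small CSV dialect emulating
# LENA-derived exports (one file per recording), pitch-missing filtering,
# cohort-wide acoustic standardisation, and subrecording assignment around
# recorder pauses.

.SEGMENT_COLUMNS <- c("infant_id", "age_days", "subrecording_id", "speaker_label",
                      "onset_s", "offset_s", "mean_pitch_hz", "mean_amplitude_db")

#' Write a recording's segment table
#'
#' Writes the package's segment CSV dialect: header
#' `infant_id,age_days,subrecording_id,speaker_label,onset_s,offset_s,mean_pitch_hz,mean_amplitude_db`,
#' UTF-8, missing pitch as an empty field, one file per recording. Numeric
#' fields are written with 17 significant digits so a write/read round trip
#' reproduces them exactly.
#'
#' @param events event data.frame (see [read_segments()]).
#' @param path output file path.
#' @export
write_segments <- function(events, path) {
  df <- events[, .SEGMENT_COLUMNS]
  for (nm in c("onset_s", "offset_s", "mean_pitch_hz", "mean_amplitude_db")) {
    df[[nm]] <- ifelse(is.na(df[[nm]]), "",
                       formatC(df[[nm]], digits = 17, format = "g"))
  }
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a recording's segment table
#'
#' Parses one recording's segment CSV, maps speaker labels outside
#' \{CHNSP, CHN_NSP, FAN, MAN\} to `OTHER`, flags events whose pitch field
#' is empty (`pitch_missing`), and validates the timeline: offsets after
#' onsets, onsets strictly increasing, no overlapping events. Violations
#' raise errors naming the offending data line.
#'
#' @param path path to a segment CSV.
#' @return event data.frame with the dialect's columns plus `pitch_missing`.
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) vf_stop("segment file not found: %s", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(infant_id = "character",
                                   speaker_label = "character")),
    error = function(e) vf_stop("malformed segment file %s: %s", path, conditionMessage(e)))
  missing_cols <- setdiff(.SEGMENT_COLUMNS, names(df))
  if (length(missing_cols)) {
    vf_stop("segment file %s lacks columns: %s", path, paste(missing_cols, collapse = ", "))
  }
  df <- df[, .SEGMENT_COLUMNS]
  for (nm in c("age_days", "subrecording_id", "onset_s", "offset_s",
               "mean_pitch_hz", "mean_amplitude_db")) {
    v <- df[[nm]]
    if (is.character(v)) v[v == ""] <- NA
    df[[nm]] <- suppressWarnings(as.numeric(v))
  }
  bad <- which(is.na(df$onset_s) | is.na(df$offset_s))
  if (length(bad)) vf_stop("parse error in %s: missing onset/offset on line %d", path, bad[1] + 1L)
  df$subrecording_id <- as.integer(df$subrecording_id)
  df$speaker_label[!df$speaker_label %in% .SPEAKER_LABELS] <- "OTHER"
  df$pitch_missing <- is.na(df$mean_pitch_hz)
  validate_events(df, where = path)
  rownames(df) <- NULL
  df
}

# timeline contract shared by read and simulated tables
validate_events <- function(events, where = "events") {
  n <- nrow(events)
  if (n == 0) return(invisible(events))
  bad <- which(events$offset_s <= events$onset_s)
  if (length(bad)) {
    vf_stop("validation error in %s: offset <= onset on line %d", where, bad[1] + 1L)
  }
  if (length(unique(events$infant_id)) != 1 || length(unique(events$age_days)) != 1) {
    vf_stop("validation error in %s: a recording must have a single infant_id and age", where)
  }
  if (n > 1) {
    d_on <- diff(events$onset_s)
    if (any(d_on <= 0)) {
      vf_stop("validation error in %s: onsets not strictly increasing at line %d",
              where, which(d_on <= 0)[1] + 2L)
    }
    ovl <- which(events$onset_s[-1] < events$offset_s[-n])
    if (length(ovl)) {
      vf_stop("validation error in %s: overlapping events at line %d", where, ovl[1] + 2L)
    }
  }
  invisible(events)
}

#' Number of analysable vocal events in a recording
#'
#' The recording-level sample size covariate: the count of `CHNSP`, `FAN`
#' and `MAN` events.
#'
#' @param events event data.frame.
#' @return integer count.
#' @export
sample_size <- function(events) {
  sum(events$speaker_label %in% c("CHNSP", "FAN", "MAN"))
}

#' Remove events with no detectable pitch
#'
#' Utterances for which no pitch could be measured are excluded from all
#' analyses. Removal happens before response coding and step construction,
#' so the consecutive-step structure is recomputed over the survivors; the
#' number removed is attached as attribute `"n_unpitched"`.
#'
#' @param events event data.frame with a `pitch_missing` column (absent
#'   columns are inferred from `mean_pitch_hz`).
#' @return filtered event data.frame.
#' @export
drop_unpitched <- function(events) {
  miss <- if ("pitch_missing" %in% names(events)) events$pitch_missing else is.na(events$mean_pitch_hz)
  out <- events[!miss, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unpitched") <- sum(miss)
  out
}

#' Standardise acoustics cohort-wide
#'
#' Converts log mean pitch and mean amplitude to z-scores using the pooled
#' mean and population SD over every `CHNSP`, `FAN` and `MAN` event of the
#' whole cohort (non-speech infant and `OTHER` events are excluded from the
#' pooling but still receive z-values from the pooled statistics). Raw
#' values are retained; z-columns `pitch_z` (of log pitch) and `amp_z` are
#' added. Standardisation is always computed from the raw columns, so
#' re-running it is idempotent.
#'
#' @param cohort a list of event data.frames, or a single one.
#' @return the same shape with `pitch_z`/`amp_z` columns added and an
#'   attribute `"standardisation"` carrying the pooled statistics.
#' @export
standardise_acoustics <- function(cohort) {
  single <- is.data.frame(cohort)
  recs <- if (single) list(cohort) else cohort
  pool_lp <- unlist(lapply(recs, function(ev) {
    sel <- ev$speaker_label %in% c("CHNSP", "FAN", "MAN") & !is.na(ev$mean_pitch_hz)
    log(ev$mean_pitch_hz[sel])
  }))
  pool_am <- unlist(lapply(recs, function(ev) {
    sel <- ev$speaker_label %in% c("CHNSP", "FAN", "MAN") & !is.na(ev$mean_pitch_hz)
    ev$mean_amplitude_db[sel]
  }))
  if (length(pool_lp) < 2) vf_stop("need at least 2 pitched CHNSP/FAN/MAN events to standardise")
  st <- list(mean_logpitch = mean(pool_lp), sd_logpitch = popsd(pool_lp),
             mean_amp = mean(pool_am), sd_amp = popsd(pool_am),
             n_pooled = length(pool_lp))
  if (st$sd_logpitch <= 0) vf_stop("zero variance in log pitch across cohort")
  if (st$sd_amp <= 0) vf_stop("zero variance in amplitude across cohort")
  recs <- lapply(recs, function(ev) {
    ev$pitch_z <- (log(ev$mean_pitch_hz) - st$mean_logpitch) / st$sd_logpitch
    ev$amp_z <- (ev$mean_amplitude_db - st$mean_amp) / st$sd_amp
    ev
  })
  out <- if (single) recs[[1]] else recs
  attr(out, "standardisation") <- st
  out
}

#' Assign subrecording ids from recorder-pause boundaries
#'
#' Events between consecutive pauses share a `subrecording_id`; steps are
#' never built across ids. A pause overlapping an event is a validation
#' error.
#'
#' @param events event data.frame.
#' @param pauses `NULL` (keep/initialise existing ids) or a data.frame with
#'   `start_s`, `end_s` columns of recorder-off windows.
#' @return events with `subrecording_id` assigned.
#' @export
split_subrecordings <- function(events, pauses = NULL) {
  if (is.null(pauses)) {
    if (!"subrecording_id" %in% names(events) || all(is.na(events$subrecording_id))) {
      events$subrecording_id <- rep(0L, nrow(events))
    }
    return(events)
  }
  stopifnot(all(c("start_s", "end_s") %in% names(pauses)))
  pauses <- pauses[order(pauses$start_s), , drop = FALSE]
  for (k in seq_len(nrow(pauses))) {
    hit <- events$onset_s < pauses$end_s[k] & events$offset_s > pauses$start_s[k]
    if (any(hit)) {
      vf_stop("validation error: pause [%s, %s] overlaps event at line %d",
              format(pauses$start_s[k]), format(pauses$end_s[k]), which(hit)[1] + 1L)
    }
  }
  events$subrecording_id <- findInterval(events$onset_s, pauses$end_s)
  events
}

#' Read a cohort manifest
#'
#' A manifest CSV lists one recording per row: `path,infant_id,age_days`.
#' Paths are resolved relative to the manifest's directory.
#'
#' @param manifest_path path to the manifest CSV.
#' @return named list of event data.frames (names `infantid_age`).
#' @export
read_cohort <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  stopifnot(all(c("path", "infant_id", "age_days") %in% names(man)))
  base <- dirname(manifest_path)
  recs <- list()
  for (k in seq_len(nrow(man))) {
    p <- man$path[k]
    if (!file.exists(p)) p <- file.path(base, man$path[k])
    ev <- read_segments(p)
    key <- sprintf("%s_%03d", man$infant_id[k], as.integer(man$age_days[k]))
    recs[[key]] <- ev
  }
  recs
}
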