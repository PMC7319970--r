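# Response-contingency coding and step construction.
#
# A vocalisation "receives a response" when the other speaker type starts
# vocalising within the response window (default 1 s) after its offset,
# with no intervening same-side vocalisation. When the same speaker type
# vocalises again within the window and nothing from the other side fills
# the gap, the code is "not applicable" (NA): one could not have waited
# long enough to observe a non-response. Steps join consecutive
# vocalisations of the same speaker type (adult = FAN and MAN pooled, not
# necessarily one person) within a subrecording and inherit the first
# event's code as their WR ("with response") / WOR ("without response")
# class.
#
# Boundary conventions (fixed, see the methods vignette): the response
# window is half-open (offset, offset + w]; the NA rule uses a separation
# of <= w; "intervening" means an onset strictly inside the gap.

#' Code receipt of vocal responses
#'
#' Assigns a response code to every `CHNSP` and adult (`FAN`/`MAN`) event:
#' \describe{
#'   \item{Y}{an other-speaker-type onset lies in `(offset, offset + window_s]`
#'     with no same-side onset before it. For adult events the responder
#'     must be a speech-related infant vocalisation (`CHNSP`) and the
#'     blocker any adult onset; for infant events the responder is any
#'     adult onset and the blocker any infant vocalisation (`CHNSP` or
#'     `CHN_NSP`).}
#'   \item{NA}{the next same-side onset is at most `window_s` after the
#'     offset with no other-side onset in the gap (response undeterminable).
#'     A Y-qualifying response takes precedence over NA.}
#'   \item{N}{otherwise.}
#' }
#' Windows never cross subrecording boundaries. `CHN_NSP` and `OTHER`
#' events carry no code, and adding `OTHER` events never changes any code.
#'
#' @param events one recording's event data.frame, sorted, with
#'   `subrecording_id` assigned.
#' @param window_s response window in seconds (default 1).
#' @return the events with a `response_code` column (`"Y"`, `"N"`, `"NA"`,
#'   or `NA` for uncoded speakers).
#' @export
code_responses <- function(events, window_s = 1.0) {
  validate_events(events)
  n <- nrow(events)
  code <- rep(NA_character_, n)
  if (n == 0) {
    events$response_code <- character(0)
    return(events)
  }
  for (sub in unique(events$subrecording_id)) {
    idx <- which(events$subrecording_id == sub)
    on <- events$onset_s[idx]
    off <- events$offset_s[idx]
    lab <- events$speaker_label[idx]
    is_ad <- lab %in% c("FAN", "MAN")
    is_cs <- lab == "CHNSP"
    is_ci <- lab %in% c("CHNSP", "CHN_NSP")

    on_ad <- on[is_ad]; on_cs <- on[is_cs]; on_ci <- on[is_ci]
    next_after <- function(v, t) {
      i <- findInterval(t, v)
      c(v, Inf)[i + 1L]
    }

    if (any(is_ad)) {
      o <- off[is_ad]
      t_cs <- next_after(on_cs, o)   # candidate responder (CHNSP only)
      t_ad <- next_after(on_ad, o)   # same-side blocker / NA partner
      t_ci <- next_after(on_ci, o)   # any infant vocalisation
      y <- t_cs <= o + window_s & t_ad > t_cs
      na <- t_ad - o <= window_s & t_ci >= t_ad
      code[idx[is_ad]] <- ifelse(y, "Y", ifelse(na, "NA", "N"))
    }
    if (any(is_cs)) {
      o <- off[is_cs]
      t_ad <- next_after(on_ad, o)   # candidate responder (any adult)
      t_ci <- next_after(on_ci, o)   # same-side blocker / NA partner
      y <- t_ad <= o + window_s & t_ci > t_ad
      na <- t_ci - o <= window_s & t_ad >= t_ci
      code[idx[is_cs]] <- ifelse(y, "Y", ifelse(na, "NA", "N"))
    }
  }
  events$response_code <- code
  events
}

#' Exhaustive-scan reference coder
#'
#' Independent brute-force implementation of the response-coding rules:
#' for every coded event it walks forward through all later events of the
#' subrecording, tracking the first responder and first blocker onsets
#' explicitly. Used as the oracle in coding-equivalence validation; it
#' shares no logic with [code_responses()].
#'
#' @inheritParams code_responses
#' @return the events with a `response_code` column.
#' @export
code_responses_bruteforce <- function(events, window_s = 1.0) {
  validate_events(events)
  n <- nrow(events)
  code <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    lab_i <- events$speaker_label[i]
    i_adult <- lab_i %in% c("FAN", "MAN")
    i_chnsp <- lab_i == "CHNSP"
    if (!i_adult && !i_chnsp) next
    off_i <- events$offset_s[i]
    sub_i <- events$subrecording_id[i]

    first_responder <- Inf
    first_blocker <- Inf
    first_sameside <- Inf
    first_otherside <- Inf
    j <- i + 1L
    while (j <= n) {
      if (events$subrecording_id[j] != sub_i) break
      on_j <- events$onset_s[j]
      lab_j <- events$speaker_label[j]
      j_adult <- lab_j %in% c("FAN", "MAN")
      j_infant <- lab_j %in% c("CHNSP", "CHN_NSP")
      if (on_j > off_i) {
        if (i_adult) {
          if (lab_j == "CHNSP" && on_j < first_responder) first_responder <- on_j
          if (j_adult && on_j < first_blocker) first_blocker <- on_j
          if (j_adult && on_j < first_sameside) first_sameside <- on_j
          if (j_infant && on_j < first_otherside) first_otherside <- on_j
        } else {
          if (j_adult && on_j < first_responder) first_responder <- on_j
          if (j_infant && on_j < first_blocker) first_blocker <- on_j
          if (j_infant && on_j < first_sameside) first_sameside <- on_j
          if (j_adult && on_j < first_otherside) first_otherside <- on_j
        }
      }
      if (on_j > off_i + window_s &&
          is.finite(first_responder) + is.finite(first_sameside) == 2) break
      j <- j + 1L
    }
    is_y <- is.finite(first_responder) && first_responder <= off_i + window_s &&
      !(first_blocker < first_responder)
    is_na <- is.finite(first_sameside) && first_sameside - off_i <= window_s &&
      !(first_otherside < first_sameside)
    code[i] <- if (is_y) "Y" else if (is_na) "NA" else "N"
  }
  events$response_code <- code
  events
}

#' Build same-speaker-type steps
#'
#' Joins consecutive events of one stream (infant = `CHNSP`; adult = `FAN`
#' and `MAN` pooled) within each subrecording into steps. Each step records
#' the inter-vocalisation interval (second onset minus first offset),
#' non-directional acoustic differences `|d pitch_z|`, `|d amp_z|`, the 2-D
#' Euclidean step `s = sqrt(d_pitch^2 + d_amp^2)`, and the WR/WOR split
#' class inherited from the first event's response code (`Y` -> `WR`,
#' `N` -> `WOR`, `NA` -> `excluded_NA`). `in_split_analysis` flags steps
#' whose interval passes the split-analysis retention filter; unsplit
#' analyses use all steps regardless of it.
#'
#' @param events coded events of one recording (see [code_responses()]),
#'   with `pitch_z`/`amp_z` from [standardise_acoustics()].
#' @param speaker_type `"infant"` or `"adult"`.
#' @param interval_filter `"gt"` (default) keeps intervals strictly greater
#'   than `filter_s` for the split analyses, matching the convention that
#'   intervals of at most 1 s were excluded; `"ge"` keeps `>= filter_s`.
#' @param filter_s retention threshold in seconds (default 1).
#' @return data.frame of steps.
#' @export
build_steps <- function(events, speaker_type = c("infant", "adult"),
                        interval_filter = c("gt", "ge"), filter_s = 1.0) {
  speaker_type <- match.arg(speaker_type)
  interval_filter <- match.arg(interval_filter)
  if (!"response_code" %in% names(events)) {
    vf_stop("events must be coded with code_responses() before building steps")
  }
  if (nrow(events) > 0 && !all(c("pitch_z", "amp_z") %in% names(events))) {
    vf_stop("events must carry pitch_z/amp_z (run standardise_acoustics())")
  }
  labs <- if (speaker_type == "infant") "CHNSP" else c("FAN", "MAN")
  sel <- which(events$speaker_label %in% labs)
  out <- list()
  for (sub in unique(events$subrecording_id[sel])) {
    idx <- sel[events$subrecording_id[sel] == sub]
    m <- length(idx)
    if (m < 2) next
    i1 <- idx[-m]; i2 <- idx[-1]
    interval <- events$onset_s[i2] - events$offset_s[i1]
    d_pitch <- abs(events$pitch_z[i2] - events$pitch_z[i1])
    d_amp <- abs(events$amp_z[i2] - events$amp_z[i1])
    first_code <- events$response_code[i1]
    out[[length(out) + 1L]] <- data.frame(
      infant_id = events$infant_id[i1],
      age_days = events$age_days[i1],
      speaker_type = speaker_type,
      subrecording_id = sub,
      first_index = i1,
      second_index = i2,
      interval_s = interval,
      d_pitch = d_pitch,
      d_amp = d_amp,
      s_2d = sqrt(d_pitch^2 + d_amp^2),
      split_class = ifelse(first_code == "Y", "WR",
                           ifelse(first_code == "N", "WOR", "excluded_NA")),
      in_split_analysis = if (interval_filter == "gt") interval > filter_s else interval >= filter_s,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(infant_id = character(), age_days = numeric(),
                      speaker_type = character(), subrecording_id = integer(),
                      first_index = integer(), second_index = integer(),
                      interval_s = numeric(), d_pitch = numeric(),
                      d_amp = numeric(), s_2d = numeric(),
                      split_class = character(), in_split_analysis = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Preprocess and code a cohort
#'
#' Convenience wrapper for the standard preprocessing order: drop unpitched
#' events, standardise acoustics cohort-wide, then code responses per
#' recording.
#'
#' @param recordings named list of event data.frames.
#' @param window_s response window (s).
#' @return named list of coded, standardised event data.frames.
#' @export
prepare_cohort <- function(recordings, window_s = 1.0) {
  recs <- lapply(recordings, drop_unpitched)
  recs <- standardise_acoustics(recs)
  lapply(recs, code_responses, window_s = window_s)
}

#' Build the pooled step table of a cohort
#'
#' @param coded named list of coded event data.frames ([prepare_cohort()]).
#' @param interval_filter,filter_s see [build_steps()].
#' @return one data.frame of steps for both speaker types, all recordings.
#' @export
cohort_steps <- function(coded, interval_filter = "gt", filter_s = 1.0) {
  pieces <- list()
  for (key in names(coded)) {
    for (sp in c("infant", "adult")) {
      st <- build_steps(coded[[key]], sp, interval_filter = interval_filter,
                        filter_s = filter_s)
      if (nrow(st)) {
        st$recording <- key
        pieces[[length(pieces) + 1L]] <- st
      }
    }
  }
  if (!length(pieces)) vf_stop("no steps could be built from this cohort")
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  res
}
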