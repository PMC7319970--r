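# Per-recording step-distribution summary features: the dependent-variable
# table behind the mixed-effects regressions. One row per
# recording x speaker x split x measure with the empirical median and 90th
# percentile, the AIC-selected family, and the parameters of the
# predominant family for that cell type.

.STEP_MEASURES <- c("interval", "s_2d", "d_pitch", "d_amp")

step_measure_values <- function(steps, measure) {
  switch(measure,
    interval = steps$interval_s,
    s_2d = steps$s_2d,
    d_pitch = steps$d_pitch,
    d_amp = steps$d_amp,
    vf_stop("unknown measure '%s'", measure))
}

#' Per-recording summary features of step distributions
#'
#' For every recording x speaker type x split (WR/WOR) x measure, computes
#' the empirical median and 90th percentile (from the data, not from fits)
#' of the steps retained for split analyses, plus, when `fit_params` is
#' `TRUE`, the AIC-selected family and the fitted parameters of the
#' *predominant* family for that speaker/split/measure cell (the modal
#' best-fit family across recordings). Downstream parameter regressions
#' use only rows whose own best fit equals the predominant family
#' (`use_params`).
#'
#' @param steps pooled step table from [cohort_steps()] (must carry a
#'   `recording` column).
#' @param sample_sizes data.frame `recording, sample_size` of per-recording
#'   CHNSP+FAN+MAN event counts.
#' @param measures which measures to summarise (default all four).
#' @param fit_params fit distribution families per cell (default TRUE).
#' @param min_steps minimum retained steps for a row to be produced.
#' @return data.frame of summary rows.
#' @export
summary_feature_table <- function(steps, sample_sizes, measures = .STEP_MEASURES,
                                  fit_params = TRUE, min_steps = 5) {
  keep <- steps$in_split_analysis & steps$split_class %in% c("WR", "WOR")
  st <- steps[keep, , drop = FALSE]
  if (!nrow(st)) vf_stop("no steps retained for split analyses")
  rows <- list()
  for (sp in unique(st$speaker_type)) {
    for (split in c("WR", "WOR")) {
      sel0 <- st$speaker_type == sp & st$split_class == split
      for (ms in measures) {
        for (rec in unique(st$recording[sel0])) {
          sel <- sel0 & st$recording == rec
          v <- step_measure_values(st[sel, , drop = FALSE], ms)
          if (length(v) < min_steps) next
          sm <- summarize_sample(v)
          row <- data.frame(
            recording = rec,
            infant_id = st$infant_id[sel][1],
            age_days = st$age_days[sel][1],
            speaker_type = sp, split = split, measure = ms,
            median = sm$median, p90 = sm$p90, n_steps = sm$n,
            stringsAsFactors = FALSE)
          if (fit_params) {
            selres <- tryCatch(aic_select(v), error = function(e) NULL)
            row$best_family <- if (is.null(selres)) NA_character_ else selres$best$family
            row$r_squared <- if (is.null(selres)) NA_real_ else fit_r_squared(v, selres$best)
            attr(row, "fits") <- if (is.null(selres)) NULL else selres$fits
            rows[[length(rows) + 1L]] <- row
          } else {
            rows[[length(rows) + 1L]] <- row
          }
        }
      }
    }
  }
  if (!length(rows)) vf_stop("no summary rows could be built")
  fits_by_row <- lapply(rows, attr, "fits")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL

  if (fit_params) {
    out$predominant_family <- NA_character_
    out$use_params <- FALSE
    for (pc in c("meanlog", "sdlog", "xmin", "alpha", "rate")) out[[pc]] <- NA_real_
    cells <- unique(out[, c("speaker_type", "split", "measure")])
    for (k in seq_len(nrow(cells))) {
      sel <- out$speaker_type == cells$speaker_type[k] &
        out$split == cells$split[k] & out$measure == cells$measure[k]
      bf <- out$best_family[sel]
      bf <- bf[!is.na(bf)]
      if (!length(bf)) next
      tab <- sort(table(bf), decreasing = TRUE)
      pred <- names(tab)[1]
      out$predominant_family[sel] <- pred
      idx <- which(sel)
      for (i in idx) {
        f <- fits_by_row[[i]][[pred]]
        if (is.null(f)) next
        for (pn in names(f$params)) out[[pn]][i] <- f$params[[pn]]
        out$use_params[i] <- identical(out$best_family[i], pred)
      }
    }
  }
  out <- merge(out, sample_sizes, by = "recording", all.x = TRUE, sort = FALSE)
  out
}

#' Per-recording sample sizes of a cohort
#'
#' @param recordings named list of event data.frames.
#' @return data.frame `recording, sample_size`.
#' @export
cohort_sample_sizes <- function(recordings) {
  data.frame(recording = names(recordings),
             sample_size = vapply(recordings, sample_size, 0L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Full per-recording distribution-fit table
#'
#' One row per recording x speaker x split (including `unsplit`) x measure
#' x family with parameters, log-likelihood, AIC, R-squared and a selected
#' flag; the export format for fit results.
#'
#' @inheritParams summary_feature_table
#' @param splits which splits to fit (`"WR"`, `"WOR"`, `"unsplit"`).
#' @return data.frame of fits.
#' @export
fit_table <- function(steps, measures = .STEP_MEASURES,
                      splits = c("WR", "WOR", "unsplit"), min_steps = 5) {
  rows <- list()
  for (split in splits) {
    sel0 <- if (split == "unsplit") rep(TRUE, nrow(steps)) else {
      steps$in_split_analysis & steps$split_class == split
    }
    for (rec in unique(steps$recording[sel0])) {
      for (sp in c("infant", "adult")) {
        sel1 <- sel0 & steps$recording == rec & steps$speaker_type == sp
        if (!any(sel1)) next
        for (ms in measures) {
          v <- step_measure_values(steps[sel1, , drop = FALSE], ms)
          if (length(v) < min_steps) next
          selres <- tryCatch(aic_select(v), error = function(e) NULL)
          if (is.null(selres)) next
          for (fam in names(selres$fits)) {
            f <- selres$fits[[fam]]
            rows[[length(rows) + 1L]] <- data.frame(
              recording = rec, speaker_type = sp, measure = ms, split = split,
              family = fam,
              params = paste(sprintf("%s=%.6g", names(f$params), f$params),
                             collapse = ";"),
              loglik = f$loglik, aic = f$aic,
              r_squared = fit_r_squared(v, f),
              n = f$n, n_zero = f$n_zero,
              selected = identical(fam, selres$best$family),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(rows)) vf_stop("no fits could be computed")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
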