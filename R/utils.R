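# Small shared helpers. Conventions fixed here and documented in the
# methods vignette: population (divide-by-n) standard deviations, a fixed
# age-standardisation anchor for the generator, and a deterministic string
# hash for per-recording seeds.

#' Population standard deviation
#'
#' Divide-by-n standard deviation, the convention used for all acoustic
#' z-scoring and regression standardisation in this package.
#'
#' @param x numeric vector.
#' @return scalar standard deviation.
#' @export
popsd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

# z-score with population SD; errors on zero variance
zscore <- function(x, what = "variable") {
  s <- popsd(x)
  if (!is.finite(s) || s <= 0) {
    stop("zero variance in ", what, "; z-score undefined", call. = FALSE)
  }
  (x - mean(x)) / s
}

# Age anchor used by the synthetic generator's response logit: roughly the
# mean/SD (days) of a 3/6/9/18-month recording schedule. Fixed so that a
# single recording can be generated without knowing its cohort.
.AGE_CENTER_DAYS <- 272.5
.AGE_SCALE_DAYS <- 200

age_std <- function(age_days) (age_days - .AGE_CENTER_DAYS) / .AGE_SCALE_DAYS

#' Derive a per-recording seed from a master seed
#'
#' Deterministic 31-bit hash of the master seed and identifying strings, so
#' inserting or removing one recording from a cohort does not perturb the
#' random streams of the others.
#'
#' @param master_seed integer master seed.
#' @param ... identifying components (coerced to character), e.g. infant id
#'   and age in days.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, ...) {
  key <- paste(c(as.character(master_seed), vapply(list(...), as.character, "")),
               collapse = "\r")
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

# fold x into [lo, hi] by reflection (used by the acoustic random walk)
reflect_into <- function(x, lo, hi) {
  width <- hi - lo
  y <- (x - lo) %% (2 * width)
  y <- ifelse(y > width, 2 * width - y, y)
  lo + y
}

# stop() with sprintf-style formatting and no call
vf_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == round(x)
is_scalar_pos <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0
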