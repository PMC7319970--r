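# Maximum-likelihood fitting of step-size / interval samples to the four
# candidate families, AIC model selection, a histogram-based R-squared
# diagnostic, and empirical distribution summaries.
#
# All MLEs are closed form:
#   exponential  lambda = 1 / mean(x)
#   normal       mu = mean(x), sigma = population SD
#   lognormal    mu, sigma = mean and population SD of ln(x)
#   Pareto       xmin = min(x), alpha = n / sum(ln(x / xmin))
# AIC = 2k - 2 loglik with k = 1 (exponential) or 2 (normal, lognormal,
# Pareto; xmin is counted as fitted since it is estimated from the data --
# set `pareto_k = 1` for the sensitivity variant).

.FAMILY_K <- c(exponential = 1, normal = 2, lognormal = 2, pareto = 2)

#' Fit one distribution family by maximum likelihood
#'
#' Closed-form MLE of `family` on a positive sample. Zero values (possible
#' for acoustic step sizes when consecutive acoustics are identical) have
#' no density under the lognormal or Pareto; they are removed before
#' fitting those families and counted in `n_zero`. Exponential and normal
#' fits use the full sample.
#'
#' @param values numeric sample (seconds or z-units).
#' @param family one of `"exponential"`, `"normal"`, `"lognormal"`,
#'   `"pareto"`.
#' @param pareto_k AIC parameter count for the Pareto family (default 2).
#' @return an object of class `vf_fit`: list with `family`, `params`
#'   (named), `loglik`, `aic`, `n`, `n_zero`, `k`.
#' @examples
#' fit_mle(c(1, 2, 3), "exponential")$params # rate = 0.5
#' fit_mle(c(1, exp(1)), "pareto")$params    # xmin = 1, alpha = 2
#' @export
fit_mle <- function(values, family = .VF_FAMILIES, pareto_k = 2) {
  family <- match.arg(family)
  if (!is.numeric(values) || any(!is.finite(values))) {
    vf_stop("values must be finite numeric")
  }
  n_zero <- 0L
  x <- values
  if (family %in% c("lognormal", "pareto")) {
    if (any(x < 0)) vf_stop("negative value in sample: %s fit undefined", family)
    n_zero <- sum(x == 0)
    x <- x[x > 0]
  } else if (family == "exponential" && any(x < 0)) {
    vf_stop("negative value in sample: exponential fit undefined")
  }
  n <- length(x)
  if (n < 2) vf_stop("insufficient data: need at least 2 values, got %d", n)

  fit <- switch(family,
    exponential = {
      rate <- 1 / mean(x)
      ll <- n * log(rate) - rate * sum(x)
      list(params = c(rate = rate), loglik = ll)
    },
    normal = {
      mu <- mean(x); sigma <- popsd(x)
      if (sigma <= 0) vf_stop("zero variance: normal fit degenerate")
      ll <- -n / 2 * log(2 * pi) - n * log(sigma) - sum((x - mu)^2) / (2 * sigma^2)
      list(params = c(mean = mu, sd = sigma), loglik = ll)
    },
    lognormal = {
      l <- log(x)
      mu <- mean(l); sigma <- popsd(l)
      if (sigma <= 0) vf_stop("zero variance of ln(values): lognormal fit degenerate")
      ll <- -sum(l) - n / 2 * log(2 * pi) - n * log(sigma) -
        sum((l - mu)^2) / (2 * sigma^2)
      list(params = c(meanlog = mu, sdlog = sigma), loglik = ll)
    },
    pareto = {
      xmin <- min(x)
      s <- sum(log(x / xmin))
      if (s <= 0) vf_stop("all values identical: pareto fit degenerate")
      alpha <- n / s
      ll <- n * log(alpha) + n * alpha * log(xmin) - (alpha + 1) * sum(log(x))
      list(params = c(xmin = xmin, alpha = alpha), loglik = ll)
    })

  k <- if (family == "pareto") pareto_k else .FAMILY_K[[family]]
  structure(list(family = family, params = fit$params, loglik = fit$loglik,
                 aic = 2 * k - 2 * fit$loglik, n = n, n_zero = n_zero, k = k),
            class = "vf_fit")
}

#' @export
print.vf_fit <- function(x, ...) {
  cat(sprintf("vf_fit: %s (%s); loglik = %.3f, AIC = %.3f, n = %d\n",
              x$family,
              paste(sprintf("%s = %.4g", names(x$params), x$params), collapse = ", "),
              x$loglik, x$aic, x$n))
  invisible(x)
}

#' Select the best-fitting family by AIC
#'
#' Fits all candidate families and returns the one minimising AIC. Exact
#' ties are broken by fewer parameters, then by the fixed family order
#' exponential < normal < lognormal < pareto. Families that cannot be
#' fitted (e.g. negative values for the lognormal) are omitted with the
#' reason recorded; if none can be fitted an error is raised.
#'
#' @param values numeric sample.
#' @param families candidate families (default all four).
#' @param pareto_k see [fit_mle()].
#' @return list with `best` (a `vf_fit`), `fits` (named list of all
#'   successful fits) and `errors` (named character of failures).
#' @export
aic_select <- function(values, families = .VF_FAMILIES, pareto_k = 2) {
  if (length(values) < 3) vf_stop("insufficient data: need at least 3 values for selection")
  fits <- list(); errors <- character(0)
  for (fam in families) {
    res <- tryCatch(fit_mle(values, fam, pareto_k = pareto_k),
                    error = function(e) conditionMessage(e))
    if (inherits(res, "vf_fit")) fits[[fam]] <- res else errors[[fam]] <- res
  }
  if (!length(fits)) {
    vf_stop("no family could be fitted: %s", paste(errors, collapse = "; "))
  }
  aics <- vapply(fits, `[[`, 0, "aic")
  ks <- vapply(fits, `[[`, 0, "k")
  ord <- match(names(fits), .VF_FAMILIES)
  best <- names(fits)[order(aics, ks, ord)][1]
  list(best = fits[[best]], fits = fits, errors = errors)
}

#' Coefficient of determination between data and fitted density
#'
#' Histogram-based goodness diagnostic: the sample is binned into
#' logarithmically spaced bins spanning `[min, max]`, empirical densities
#' are `count / (n * binwidth)`, and `R^2 = 1 - SS_res / SS_tot` compares
#' them with the fitted pdf at the (geometric) bin centres, over occupied
#' bins. May be negative for poor fits. With fewer than 5 occupied bins the
#' diagnostic is undefined and `NA` is returned.
#'
#' @param values the sample the fit was computed on.
#' @param fit a `vf_fit`.
#' @param bins number of logarithmic bins (default 50).
#' @return scalar R-squared, or `NA` if undefined.
#' @export
fit_r_squared <- function(values, fit, bins = 50) {
  stopifnot(inherits(fit, "vf_fit"))
  x <- values[is.finite(values) & values > 0]
  if (length(x) < 2 || min(x) == max(x)) return(NA_real_)
  edges <- exp(seq(log(min(x)), log(max(x)), length.out = bins + 1))
  edges[1] <- edges[1] * (1 - 1e-12)
  edges[length(edges)] <- edges[length(edges)] * (1 + 1e-12)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE), nbins = bins)
  width <- diff(edges)
  centres <- sqrt(edges[-1] * edges[-length(edges)])
  emp <- counts / (length(x) * width)
  mod <- family_density(fit$family, fit$params, centres)
  occ <- counts > 0
  if (sum(occ) < 5) return(NA_real_)
  density_r_squared(emp[occ], mod[occ])
}

#' R-squared between two density vectors
#'
#' `1 - SS_res / SS_tot`, with `SS_tot` about the mean empirical density.
#' Exposed separately so the definition can be checked directly.
#'
#' @param empirical empirical bin densities.
#' @param model model densities at the same bin centres.
#' @return scalar R-squared.
#' @export
density_r_squared <- function(empirical, model) {
  ss_res <- sum((empirical - model)^2)
  ss_tot <- sum((empirical - mean(empirical))^2)
  if (ss_tot == 0) return(if (ss_res == 0) 1 else -Inf)
  1 - ss_res / ss_tot
}

#' Empirical distribution summaries
#'
#' Median and 90th percentile computed from the data (never from fitted
#' distributions), using the linear-interpolation quantile convention
#' (type 7).
#'
#' @param values numeric sample, `n >= 1`.
#' @return list with `median`, `p90`, `n`.
#' @export
summarize_sample <- function(values) {
  if (!length(values)) vf_stop("insufficient data: empty sample")
  list(median = unname(stats::median(values)),
       p90 = unname(stats::quantile(values, 0.9, type = 7)),
       n = length(values))
}
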