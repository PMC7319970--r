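# Candidate step-size / interval distribution families and their samplers.
# The Pareto is the classic power-law form P(x) = alpha * xmin^alpha / x^(alpha+1)
# on [xmin, Inf); with 1 < alpha <= 3 it describes a Levy walk.

.VF_FAMILIES <- c("exponential", "normal", "lognormal", "pareto")

#' Pareto (power-law) distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the Pareto distribution with scale `xmin` and shape `alpha`:
#' `f(x) = alpha * xmin^alpha / x^(alpha + 1)` for `x >= xmin`.
#'
#' @param x,q vector of quantiles.
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param xmin positive scale (lower support bound).
#' @param alpha positive shape. `alpha > 1` gives a finite mean
#'   `alpha * xmin / (alpha - 1)`; `1 < alpha <= 3` is the Levy-walk regime.
#' @return `dpareto` the density, `ppareto` the CDF, `qpareto` quantiles,
#'   `rpareto` random draws.
#' @examples
#' qpareto(0.5, xmin = 1, alpha = 2) # analytic median = sqrt(2)
#' @export
dpareto <- function(x, xmin, alpha) {
  check_pareto_params(xmin, alpha)
  ifelse(x >= xmin, alpha * xmin^alpha / x^(alpha + 1), 0)
}

#' @rdname dpareto
#' @export
ppareto <- function(q, xmin, alpha) {
  check_pareto_params(xmin, alpha)
  ifelse(q >= xmin, 1 - (xmin / q)^alpha, 0)
}

#' @rdname dpareto
#' @export
qpareto <- function(p, xmin, alpha) {
  check_pareto_params(xmin, alpha)
  stopifnot(all(p >= 0 & p <= 1))
  xmin * (1 - p)^(-1 / alpha)
}

#' @rdname dpareto
#' @export
rpareto <- function(n, xmin, alpha) {
  check_pareto_params(xmin, alpha)
  xmin * stats::runif(n)^(-1 / alpha)
}

check_pareto_params <- function(xmin, alpha) {
  if (!is_scalar_pos(xmin) || !is_scalar_pos(alpha)) {
    vf_stop("pareto parameters must be positive scalars (xmin = %s, alpha = %s)",
            format(xmin), format(alpha))
  }
  invisible(TRUE)
}

# Validate a family + parameter list. `params` is a named list/vector:
#   exponential: rate; normal: mean, sd; lognormal: meanlog, sdlog;
#   pareto: xmin, alpha.
check_family <- function(family, params) {
  if (!is.character(family) || length(family) != 1 || !family %in% .VF_FAMILIES) {
    vf_stop("unknown distribution family '%s' (known: %s)",
            paste(family, collapse = ","), paste(.VF_FAMILIES, collapse = ", "))
  }
  p <- as.list(params)
  need <- switch(family,
    exponential = "rate",
    normal = c("mean", "sd"),
    lognormal = c("meanlog", "sdlog"),
    pareto = c("xmin", "alpha"))
  if (!all(need %in% names(p))) {
    vf_stop("family '%s' requires parameters: %s", family, paste(need, collapse = ", "))
  }
  # scale/rate parameters must be positive; spread parameters may be zero
  # (degenerate limits are legal draws)
  pos <- switch(family,
    exponential = "rate", normal = character(), lognormal = character(),
    pareto = c("xmin", "alpha"))
  nonneg <- switch(family,
    exponential = character(), normal = "sd", lognormal = "sdlog", pareto = character())
  for (nm in pos) {
    if (!is_scalar_pos(p[[nm]])) vf_stop("parameter '%s' of %s must be > 0", nm, family)
  }
  for (nm in nonneg) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      vf_stop("parameter '%s' of %s must be >= 0", nm, family)
    }
  }
  p
}

#' Draw inter-vocalisation intervals from a named family
#'
#' Sampler for the interval process of the synthetic generator. Supported
#' families are exponential (`rate`), lognormal (`meanlog`, `sdlog`) and
#' Pareto (`xmin`, `alpha`); all draws are strictly positive durations in
#' seconds. Draws are reproducible through R's global RNG (seed the stream
#' with `set.seed()` before calling).
#'
#' @param family one of `"exponential"`, `"lognormal"`, `"pareto"`.
#' @param params named list or vector of family parameters.
#' @param n number of draws.
#' @return numeric vector of `n` positive durations (seconds).
#' @export
sample_interval <- function(family, params, n = 1) {
  if (identical(family, "normal")) {
    vf_stop("unknown distribution family 'normal' for intervals (intervals must be positive)")
  }
  p <- check_family(family, params)
  switch(family,
    exponential = stats::rexp(n, rate = p$rate),
    lognormal = stats::rlnorm(n, meanlog = p$meanlog, sdlog = p$sdlog),
    pareto = rpareto(n, xmin = p$xmin, alpha = p$alpha))
}

# Magnitude sampler for acoustic-step draws: exponential and lognormal are
# positive already; normal is folded to its absolute value.
sample_step_magnitude <- function(family, params, n = 1) {
  p <- check_family(family, params)
  switch(family,
    exponential = stats::rexp(n, rate = p$rate),
    lognormal = stats::rlnorm(n, meanlog = p$meanlog, sdlog = p$sdlog),
    normal = abs(stats::rnorm(n, mean = p$mean, sd = p$sd)),
    pareto = rpareto(n, xmin = p$xmin, alpha = p$alpha))
}

# Density of a named family (used by the R-squared diagnostic)
family_density <- function(family, params, x) {
  p <- check_family(family, params)
  switch(family,
    exponential = stats::dexp(x, rate = p$rate),
    normal = stats::dnorm(x, mean = p$mean, sd = p$sd),
    lognormal = stats::dlnorm(x, meanlog = p$meanlog, sdlog = p$sdlog),
    pareto = dpareto(x, xmin = p$xmin, alpha = p$alpha))
}
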