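#' Parameter container for the count-distribution families
#'
#' Builds a validated parameter set for one of the seven discrete
#' distributions used to model monthly contrast-enhancing-lesion (CEL)
#' counts: Poisson (`"PS"`), zero-inflated Poisson (`"ZIP"`), generalized
#' Poisson (`"GP"`, Consul-Jain form), negative binomial (`"NB"`, NB2
#' mean-variance form), zero-inflated negative binomial (`"ZINB"`) and a
#' two-component Poisson mixture (`"PMIX"`).
#'
#' @param family Character, one of `"PS"`, `"ZIP"`, `"GP"`, `"NB"`,
#'   `"ZINB"`, `"PMIX"`.
#' @param lam Mean-rate parameter \eqn{\lambda} (counts/month, > 0). For
#'   `"PMIX"` this is the first component rate \eqn{\lambda_1}.
#' @param lam2 Second mixture rate \eqn{\lambda_2} (> 0, `"PMIX"` only).
#' @param p0 Zero-inflation probability \eqn{P_0 \in [0,1]} (`"ZIP"`,
#'   `"ZINB"`).
#' @param pm Mixture probability \eqn{MP \in [0,1]} of the first component
#'   (`"PMIX"`).
#' @param ovdp Overdispersion parameter \eqn{OVDP \ge 0} of the negative
#'   binomial: variance \eqn{\lambda(1 + OVDP\,\lambda)} (`"NB"`, `"ZINB"`).
#' @param delta Generalized-Poisson dispersion \eqn{\delta} in
#'   \eqn{[\max(-1, -\lambda/4), 1)}; positive values give overdispersion,
#'   negative underdispersion (`"GP"`).
#'
#' @return An object of class `count_params`.
#' @examples
#' count_params("NB", lam = 2.32, ovdp = 0.254)
#' count_params("ZIP", lam = 2.4, p0 = 0.0375)
#' @export
count_params <- function(family, lam, lam2 = NULL, p0 = NULL, pm = NULL,
                         ovdp = NULL, delta = NULL) {
  family <- match.arg(family, c("PS", "ZIP", "GP", "NB", "ZINB", "PMIX"))
  chk <- function(x, nm, lo, hi, lo_open = FALSE, hi_open = FALSE) {
    if (is.null(x) || length(x) != 1L || !is.finite(x))
      stop("parameter '", nm, "' must be a single finite number for family ",
           family, call. = FALSE)
    bad <- if (lo_open) x <= lo else x < lo
    bad <- bad || if (hi_open) x >= hi else x > hi
    if (bad)
      stop("parameter '", nm, "' = ", x, " outside its domain for family ",
           family, call. = FALSE)
    x
  }
  lam <- chk(lam, "lam", 0, Inf, lo_open = TRUE)
  p <- list(family = family, lam = lam)
  if (family %in% c("ZIP", "ZINB")) p$p0 <- chk(p0, "p0", 0, 1)
  if (family %in% c("NB", "ZINB")) p$ovdp <- chk(ovdp, "ovdp", 0, Inf)
  if (family == "GP") p$delta <- chk(delta, "delta", max(-1, -lam / 4), 1,
                                     hi_open = TRUE)
  if (family == "PMIX") {
    p$lam2 <- chk(lam2, "lam2", 0, Inf, lo_open = TRUE)
    p$pm <- chk(pm, "pm", 0, 1)
  }
  structure(p, class = "count_params")
}

#' @export
print.count_params <- function(x, ...) {
  vals <- unlist(x[setdiff(names(x), "family")])
  cat("<count_params> family =", x$family, "|",
      paste(names(vals), signif(vals, 4), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

## log pmf of the Consul-Jain generalized Poisson; vectorised over n.
## For delta < 0 the support is truncated at the largest n with
## lam + n*delta > 0 (probability 0 beyond it).
gp_logpmf <- function(n, lam, delta) {
  mu <- lam + n * delta
  out <- rep(-Inf, length(n))
  ok <- mu > 0
  nk <- n[ok]
  out[ok] <- log(lam) + (nk - 1) * log(mu[ok]) - mu[ok] - lgamma(nk + 1)
  out
}

nb_logpmf <- function(n, lam, ovdp) {
  if (ovdp < 1e-12) return(stats::dpois(n, lam, log = TRUE))
  stats::dnbinom(n, size = 1 / ovdp, mu = lam, log = TRUE)
}

## zero-inflated log pmf given the base family's logpmf values
zi_logpmf <- function(n, base_log, p0) {
  if (p0 <= 0) return(base_log)
  out <- log1p(-p0) + base_log
  is0 <- n == 0
  ## log(p0 + (1-p0) * base(0)) computed stably
  out[is0] <- log(p0 + exp(log1p(-p0) + base_log[is0]))
  out
}

#' Probability mass function of a count family
#'
#' @param x Vector of non-negative integer counts.
#' @param params A [count_params()] object.
#' @param log Return the log pmf?
#' @return Vector of probabilities (or log probabilities).
#' @examples
#' dcount(0, count_params("PS", lam = 1))   # exp(-1)
#' @export
dcount <- function(x, params, log = FALSE) {
  stopifnot(inherits(params, "count_params"))
  if (any(!is.finite(x)) || any(x < 0) || any(x != floor(x)))
    stop("counts must be non-negative integers", call. = FALSE)
  lp <- switch(params$family,
    PS = stats::dpois(x, params$lam, log = TRUE),
    ZIP = zi_logpmf(x, stats::dpois(x, params$lam, log = TRUE), params$p0),
    GP = gp_logpmf(x, params$lam, params$delta),
    NB = nb_logpmf(x, params$lam, params$ovdp),
    ZINB = zi_logpmf(x, nb_logpmf(x, params$lam, params$ovdp), params$p0),
    PMIX = {
      a <- log(params$pm) + stats::dpois(x, params$lam, log = TRUE)
      b <- log1p(-params$pm) + stats::dpois(x, params$lam2, log = TRUE)
      m <- pmax(a, b)
      ifelse(is.infinite(m), -Inf, m + log(exp(a - m) + exp(b - m)))
    })
  if (log) lp else exp(lp)
}

#' Closed-form mean and variance of a count family
#'
#' Poisson is equi-dispersed; ZIP has mean \eqn{(1-P_0)\lambda} and variance
#' \eqn{(1-P_0)\lambda(1+P_0\lambda)}; NB has mean \eqn{\lambda} and variance
#' \eqn{\lambda(1+OVDP\,\lambda)}; GP has mean \eqn{\lambda/(1-\delta)} and
#' variance \eqn{\lambda/(1-\delta)^3}; ZINB and PMIX use the standard
#' mixture moments.
#'
#' @param params A [count_params()] object.
#' @return Named numeric vector `c(mean, variance)`.
#' @export
count_moments <- function(params) {
  stopifnot(inherits(params, "count_params"))
  with(params, switch(family,
    PS = c(mean = lam, variance = lam),
    ZIP = c(mean = (1 - p0) * lam,
            variance = (1 - p0) * lam * (1 + p0 * lam)),
    NB = c(mean = lam, variance = lam * (1 + ovdp * lam)),
    ZINB = c(mean = (1 - p0) * lam,
             variance = (1 - p0) * lam * (1 + lam * (ovdp + p0))),
    GP = c(mean = lam / (1 - delta), variance = lam / (1 - delta)^3),
    PMIX = {
      m <- pm * lam + (1 - pm) * lam2
      v <- pm * (lam + lam^2) + (1 - pm) * (lam2 + lam2^2) - m^2
      c(mean = m, variance = v)
    }))
}

## GP sampler by inversion of the cumulative pmf; truncation safeguarded at
## a generous upper bound beyond which the tail mass is negligible.
rgpois <- function(n, lam, delta) {
  mom <- count_moments(count_params("GP", lam = lam, delta = delta))
  kmax <- max(50, ceiling(mom["mean"] + 20 * sqrt(mom["variance"]) + 20))
  k <- 0:kmax
  cdf <- cumsum(exp(gp_logpmf(k, lam, delta)))
  cdf[length(cdf)] <- max(cdf[length(cdf)], 1)  # absorb truncated tail
  findInterval(stats::runif(n), cdf)
}

#' Sample from a count family
#'
#' Uses the R session RNG; set a seed for reproducibility. NB draws use
#' Gamma-Poisson compounding (via [stats::rnbinom()]), zero-inflated
#' families a Bernoulli zero mask, PMIX a per-observation component draw,
#' and GP inversion on the cumulative pmf.
#'
#' @param n Number of draws.
#' @param params A [count_params()] object.
#' @return Integer vector of counts.
#' @export
rcount <- function(n, params) {
  stopifnot(inherits(params, "count_params"))
  out <- with(params, switch(family,
    PS = stats::rpois(n, lam),
    ZIP = ifelse(stats::runif(n) < p0, 0L, stats::rpois(n, lam)),
    NB = if (ovdp < 1e-12) stats::rpois(n, lam) else
      stats::rnbinom(n, size = 1 / ovdp, mu = lam),
    ZINB = ifelse(stats::runif(n) < p0, 0L,
                  if (ovdp < 1e-12) stats::rpois(n, lam) else
                    stats::rnbinom(n, size = 1 / ovdp, mu = lam)),
    GP = rgpois(n, lam, delta),
    PMIX = ifelse(stats::runif(n) < pm, stats::rpois(n, lam),
                  stats::rpois(n, lam2))))
  as.integer(out)
}
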