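## Parameter vocabulary ------------------------------------------------------
## lam0     baseline mean rate (counts/month); the PMAK1 lesion-free rate and
##          the first PMIX component rate reuse this slot
## lam2     second rate: PMAK1 active-history rate / PMIX second component
## th_pdv, th_ppdv, th_pppdv   Markov coefficients on the 1/2/3-month lags
## ovdp     NB overdispersion; delta GP dispersion; p0 zero inflation;
## pm       PMIX mixture probability
## <par>_s  steroid-month replacement value of <par> (shares <par>'s eta)

.re_targets <- c("lam0", "lam2", "th_pdv", "ovdp")
.ster_targets <- c("none", "lam0", "ovdp", "th_pdv", "th_ppdv")

#' Declarative specification of one structural count model
#'
#' A `celdyn_spec` fixes the distribution family, the Markov structure
#' (none, the PMAK1 binary indicator, or lagged-count terms of order 1-3),
#' where the steroid-month covariate acts (as a replacement coefficient
#' `<target>_s` in dosed months, sharing the target's random effect), and
#' which parameters carry log-normal inter-subject random effects
#' (at most two).
#'
#' @param family One of `"PS"`, `"ZIP"`, `"GP"`, `"NB"`, `"ZINB"`, `"PMIX"`.
#' @param markov `"none"`, `"MAK1"` (binary previous-month indicator) or
#'   `"MAK2"` (additive lagged-count terms).
#' @param order Markov order 1-3 (MAK2 only).
#' @param steroid_target Parameter replaced in steroid months, or `"none"`.
#' @param steroid_carryover If `TRUE` the effect applies the month after
#'   administration.
#' @param random_effects Character vector (length 0-2) of parameters with a
#'   multiplicative log-normal random effect: subset of
#'   `"lam0"`, `"lam2"`, `"th_pdv"`, `"ovdp"`.
#' @param label Optional display label.
#' @return A `celdyn_spec` object.
#' @seealso [model_ladder()] for the sixteen named study models.
#' @export
model_spec <- function(family, markov = "none", order = 1L,
                       steroid_target = "none", steroid_carryover = FALSE,
                       random_effects = "lam0", label = NULL) {
  family <- match.arg(family, c("PS", "ZIP", "GP", "NB", "ZINB", "PMIX"))
  markov <- match.arg(markov, c("none", "MAK1", "MAK2"))
  steroid_target <- match.arg(steroid_target, .ster_targets)
  if (markov != "MAK2") order <- 0L
  if (markov == "MAK2" && !order %in% 1:3)
    stop("MAK2 order must be 1, 2 or 3", call. = FALSE)
  if (markov == "MAK1" && family != "PS")
    stop("the MAK1 indicator model is defined for the Poisson family",
         call. = FALSE)
  if (family == "PMIX" && markov != "none")
    stop("PMIX does not combine with Markov terms", call. = FALSE)
  if (length(random_effects) > 2)
    stop("at most two random effects are supported", call. = FALSE)
  if (length(random_effects) && !all(random_effects %in% .re_targets))
    stop("random effects must be on ", paste(.re_targets, collapse = ", "),
         call. = FALSE)
  spec <- structure(list(family = family, markov = markov, order = as.integer(order),
                         steroid_target = steroid_target,
                         steroid_carryover = isTRUE(steroid_carryover),
                         random_effects = as.character(random_effects),
                         label = label %||% NULL),
                    class = "celdyn_spec")
  free <- free_params(spec)
  if (steroid_target != "none" && !steroid_target %in% free)
    stop("steroid_target '", steroid_target,
         "' is not a parameter of this family/markov combination",
         call. = FALSE)
  if (length(random_effects) && !all(random_effects %in% free))
    stop("random effects must be placed on parameters of the model",
         call. = FALSE)
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Free fixed-effect parameter names of a model specification
#'
#' @param spec A [model_spec()].
#' @return Character vector of parameter names, in reporting order.
#' @export
free_params <- function(spec) {
  stopifnot(inherits(spec, "celdyn_spec"))
  p <- "lam0"
  if (spec$markov == "MAK1") p <- c(p, "lam2")
  if (spec$family %in% c("NB", "ZINB")) p <- c(p, "ovdp")
  if (spec$family == "GP") p <- c(p, "delta")
  if (spec$markov == "MAK2") {
    p <- c(p, "th_pdv")
    if (spec$order >= 2) p <- c(p, "th_ppdv")
    if (spec$order >= 3) p <- c(p, "th_pppdv")
  }
  if (spec$steroid_target != "none" && spec$steroid_target %in% p)
    p <- append(p, paste0(spec$steroid_target, "_s"),
                after = match(spec$steroid_target, p))
  if (spec$family %in% c("ZIP", "ZINB")) p <- c(p, "p0")
  if (spec$family == "PMIX") p <- c(p, "lam2", "pm")
  p
}

#' @export
print.celdyn_spec <- function(x, ...) {
  cat("<celdyn_spec>", x$label %||% "", "\n",
      " family:", x$family, " markov:", x$markov,
      if (x$markov == "MAK2") paste0("(order ", x$order, ")") else "", "\n",
      " steroid:", x$steroid_target,
      if (x$steroid_carryover) "(carryover)" else "", "\n",
      " random effects:", paste(x$random_effects, collapse = ", "), "\n",
      " fixed effects:", paste(free_params(x), collapse = ", "), "\n")
  invisible(x)
}

.ladder <- list(
  "PS" = list(family = "PS", markov = "none", re = "lam0"),
  "PMAK1" = list(family = "PS", markov = "MAK1", re = "lam0"),
  "PMAK2" = list(family = "PS", markov = "MAK2", order = 1,
                 re = c("lam0", "th_pdv")),
  "nested PMAK2" = list(family = "PS", markov = "MAK2", order = 2,
                        re = c("lam0", "th_pdv")),
  "nested nested PMAK2" = list(family = "PS", markov = "MAK2", order = 3,
                               re = c("lam0", "th_pdv")),
  "PMIX" = list(family = "PMIX", markov = "none", re = c("lam0", "lam2")),
  "ZIP" = list(family = "ZIP", markov = "none", re = "lam0"),
  "GP" = list(family = "GP", markov = "none", re = "lam0"),
  "GP_MAK2" = list(family = "GP", markov = "MAK2", order = 1,
                   re = c("lam0", "th_pdv")),
  "GP_nested_MAK2" = list(family = "GP", markov = "MAK2", order = 2,
                          re = c("lam0", "th_pdv")),
  "NB" = list(family = "NB", markov = "none", re = c("lam0", "ovdp")),
  "ZINB" = list(family = "ZINB", markov = "none", re = c("lam0", "ovdp")),
  "NB_MAK2" = list(family = "NB", markov = "MAK2", order = 1,
                   re = c("lam0", "th_pdv")),
  "NB_nested MAK2" = list(family = "NB", markov = "MAK2", order = 2,
                          re = c("lam0", "th_pdv")),
  "NB_nested nested MAK2" = list(family = "NB", markov = "MAK2", order = 3,
                                 re = c("lam0", "th_pdv")),
  "NB_nested MAK2 steroids" = list(family = "NB", markov = "MAK2", order = 2,
                                   steroid = "th_pdv",
                                   re = c("lam0", "th_pdv"))
)

.slug <- function(x) gsub("[^a-z0-9]+", "-", tolower(x))

#' The sixteen structural models of the study ladder
#'
#' Returns the [model_spec()] for one of the sixteen evaluated structural
#' models, by its table label (e.g. `"NB_nested MAK2"`) or its slug alias
#' (e.g. `"nb-nested-mak2"`).
#'
#' @param name Model label or slug.
#' @return A `celdyn_spec`.
#' @examples
#' model_ladder("NB_nested MAK2")
#' ladder_names()
#' @export
model_ladder <- function(name) {
  nm <- names(.ladder)
  hit <- if (name %in% nm) name else nm[match(.slug(name), .slug(nm))]
  if (is.na(hit) || !length(hit))
    stop("unknown model '", name, "'; valid models are:\n  ",
         paste(nm, collapse = "\n  "), call. = FALSE)
  d <- .ladder[[hit]]
  model_spec(d$family, d$markov, d$order %||% 1L,
             steroid_target = d$steroid %||% "none",
             random_effects = d$re, label = hit)
}

#' @rdname model_ladder
#' @export
ladder_names <- function() names(.ladder)

## ---------------------------------------------------------------------------

#' Subject-month conditional mean given random effects and lag covariates
#'
#' The MAK2 mean is additive in the lagged counts,
#' \eqn{\lambda_{it} = \lambda_0 e^{\eta_1} + \theta_{PDV} e^{\eta_2} PDV
#' + \theta_{PPDV} PPDV + \theta_{PPPDV} PPPDV}, with the first-order
#' coefficient replaced by its steroid-month value \eqn{\theta_{PDV\_S}}
#' (sharing \eqn{\eta_2}) in dosed months when the model carries a steroid
#' effect. The MAK1 mean selects \eqn{\lambda_1 e^{\eta_1}} or
#' \eqn{\lambda_2} on the previous-month indicator; families without Markov
#' terms return \eqn{\lambda_0 e^{\eta_1}} (for PMIX, the mixture mean).
#'
#' @param fe Named numeric vector of fixed effects (see [free_params()]).
#' @param eta Numeric vector of random effects, aligned with
#'   `spec$random_effects` (recycled zeros if empty).
#' @param lags Data frame from [build_lags()] (one row per month).
#' @param steroid 0/1 effect-month flags (see [steroid_flags()]).
#' @param spec A [model_spec()].
#' @return Numeric vector of conditional means, one per month.
#' @examples
#' sp <- model_ladder("NB_nested MAK2")
#' fe <- c(lam0 = 0.940, ovdp = 0.155, th_pdv = 0.430, th_ppdv = 0.141)
#' conditional_mean(fe, c(0, 0), build_lags(c(0, 2, 1)), c(0, 0, 0), sp)
#' @export
conditional_mean <- function(fe, eta, lags, steroid, spec) {
  cp <- conditional_params(fe, eta, lags, steroid, spec)
  if (spec$family == "PMIX")
    return(fe[["pm"]] * cp$lam + (1 - fe[["pm"]]) * cp$lam2)
  cp$lam
}

## Effective per-month parameters (rates, overdispersion) after applying
## random effects and the steroid replacement. Internal workhorse shared by
## conditional_mean, the R reference likelihood and the simulator.
conditional_params <- function(fe, eta, lags, steroid, spec) {
  re <- spec$random_effects
  if (!length(eta)) eta <- numeric(0)
  stopifnot(length(eta) == length(re))
  mult <- function(par) if (par %in% re) exp(eta[[match(par, re)]]) else 1
  T <- nrow(lags)
  if (length(steroid) == 1L) steroid <- rep(steroid, T)
  eff <- function(par) {
    ## steroid-month replacement value, sharing the target's eta multiplier
    base <- rep(fe[[par]] * mult(par), T)
    if (spec$steroid_target == par) {
      s <- paste0(par, "_s")
      base[steroid == 1] <- fe[[s]] * mult(par)
    }
    base
  }
  lam <- switch(spec$markov,
    none = eff("lam0"),
    MAK1 = ifelse(lags$pmak1_ind == 1, fe[["lam2"]], eff("lam0")),
    MAK2 = {
      l <- eff("lam0") + eff("th_pdv") * lags$pdv
      if (spec$order >= 2) l <- l + eff("th_ppdv") * lags$ppdv
      if (spec$order >= 3) l <- l + eff("th_pppdv") * lags$pppdv
      l
    })
  if (any(lam <= 0)) stop("conditional mean is not positive", call. = FALSE)
  out <- list(lam = lam)
  if (spec$family %in% c("NB", "ZINB")) out$ovdp <- eff("ovdp")
  if (spec$family == "GP") out$delta <- rep(fe[["delta"]], T)
  if (spec$family %in% c("ZIP", "ZINB")) out$p0 <- rep(fe[["p0"]], T)
  if (spec$family == "PMIX") out$lam2 <- rep(fe[["lam2"]] * mult("lam2"), T)
  out
}

#' Subject-conditional log-likelihood (reference implementation)
#'
#' Sums the family log pmf month by month at the conditional mean implied by
#' the fixed effects, random effects and lag covariates. This plain-R
#' implementation defines the likelihood; the compiled marginalization code
#' is tested against it.
#'
#' @param counts Integer vector of monthly counts.
#' @param fe,eta,spec As in [conditional_mean()].
#' @param steroid 0/1 dose flags per month (raw; carryover applied per spec).
#' @param use Optional logical vector of months to include.
#' @return Scalar log-likelihood.
#' @export
subject_loglik <- function(counts, fe, eta, spec, steroid = 0L, use = NULL) {
  lags <- build_lags(counts, max(spec$order, 1L))
  T <- length(counts)
  if (length(steroid) == 1L) steroid <- rep(as.integer(steroid), T)
  sfl <- steroid_flags(steroid, spec$steroid_carryover)
  cp <- conditional_params(fe, eta, lags, sfl, spec)
  lp <- vapply(seq_len(T), function(t) {
    pars <- switch(spec$family,
      PS = count_params("PS", lam = cp$lam[t]),
      ZIP = count_params("ZIP", lam = cp$lam[t], p0 = cp$p0[t]),
      GP = count_params("GP", lam = cp$lam[t], delta = cp$delta[t]),
      NB = count_params("NB", lam = cp$lam[t], ovdp = cp$ovdp[t]),
      ZINB = count_params("ZINB", lam = cp$lam[t], ovdp = cp$ovdp[t],
                          p0 = cp$p0[t]),
      PMIX = count_params("PMIX", lam = cp$lam[t], lam2 = cp$lam2[t],
                          pm = fe[["pm"]]))
    dcount(counts[t], pars, log = TRUE)
  }, numeric(1))
  if (is.null(use)) use <- rep(TRUE, T)
  sum(lp[use])
}
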