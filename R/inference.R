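## Encoding of a celdyn_spec for the compiled core --------------------------

.fam_code <- c(PS = 0L, ZIP = 1L, GP = 2L, NB = 3L, ZINB = 4L, PMIX = 5L)
.ster_code <- c(none = 0L, lam0 = 1L, ovdp = 2L, th_pdv = 3L, th_ppdv = 4L)
.re_code <- c(lam0 = 1L, lam2 = 2L, th_pdv = 3L, ovdp = 4L)

spec_codes <- function(spec, re = spec$random_effects) {
  mk <- switch(spec$markov, none = 0L, MAK1 = 1L, MAK2 = 1L + spec$order)
  c(.fam_code[[spec$family]], mk, .ster_code[[spec$steroid_target]],
    if (length(re) >= 1) .re_code[[re[1]]] else 0L,
    if (length(re) >= 2) .re_code[[re[2]]] else 0L)
}

fe_vector <- function(fe, spec) {
  g <- function(nm, def) if (nm %in% names(fe)) unname(fe[[nm]]) else def
  ss <- if (spec$steroid_target != "none")
    g(paste0(spec$steroid_target, "_s"), 0) else 0
  c(g("lam0", 1), g("lam2", 1), g("th_pdv", 0), g("th_ppdv", 0),
    g("th_pppdv", 0), g("ovdp", 0), g("delta", 0), g("p0", 0), g("pm", 1), ss)
}

## Split a dataset into per-subject vectors with precomputed lag covariates
## and effect-month steroid flags; shared by OFV evaluation and fitting.
prep_subjects <- function(dataset, spec, drop_initial = FALSE) {
  dataset <- as_cel_dataset(dataset)
  ids <- unique(dataset$ID)
  lapply(ids, function(id) {
    d <- dataset[dataset$ID == id, , drop = FALSE]
    d <- d[order(d$MONTH), , drop = FALSE]
    lg <- build_lags(d$DV, max(spec$order, 1L), drop_initial = drop_initial)
    list(y = as.integer(d$DV), pdv = as.integer(lg$pdv),
         ppdv = as.integer(lg$ppdv), pppdv = as.integer(lg$pppdv),
         ind = as.integer(lg$pmak1_ind),
         ster = as.integer(steroid_flags(d$STEROID, spec$steroid_carryover)),
         use = as.integer(lg$use), id = id)
  })
}

## Core dispatcher. omega entries equal to zero are profiled out (their eta
## fixed at 0), so omega = 0 reduces exactly to the fixed-effects -2LL.
marginal_ofv <- function(subjects, fe, omega, spec, nodes = 1L,
                         eta_warm = NULL) {
  re <- spec$random_effects
  om <- rep(0, length(re))
  if (length(re)) {
    if (is.null(names(omega)) && length(omega) == length(re))
      names(omega) <- re
    om <- vapply(re, function(r) {
      v <- if (r %in% names(omega)) omega[[r]] else 0
      if (v < 0) stop("random-effect variances must be >= 0", call. = FALSE)
      v
    }, numeric(1))
  }
  active <- re[om > 0]
  q <- length(active)
  n <- length(subjects)
  if (is.null(eta_warm) || !is.matrix(eta_warm) ||
      nrow(eta_warm) != max(q, 1L) || ncol(eta_warm) != n)
    eta_warm <- matrix(0, max(q, 1L), n)
  gh <- if (nodes > 1) pracma::gaussHermite(nodes) else list(x = 0, w = 1)
  res <- .marginal_ofv_cpp(subjects, fe_vector(fe, spec),
                           spec_codes(spec, active), unname(om[om > 0]),
                           eta_warm, as.integer(nodes), gh$x, gh$w)
  structure(res$ofv, eta = res$eta, converged = all(res$converged),
            active_re = active)
}

#' Laplace-approximate marginal -2 log-likelihood (OFV)
#'
#' For each subject the joint log density of the data and the random effects
#' is maximized over the random effects (safeguarded Newton), and the
#' Laplace correction from the negative inner Hessian is added; the OFV is
#' \eqn{-2\sum_i \log \hat L_i}. With all variances zero this reduces
#' exactly to the fixed-effects \eqn{-2} log-likelihood at \eqn{\eta = 0}.
#'
#' @param dataset A CEL dataset (see [as_cel_dataset()]).
#' @param fe Named vector/list of fixed effects.
#' @param omega Named vector of random-effect variances (log scale), aligned
#'   with `spec$random_effects`.
#' @param spec A [model_spec()].
#' @param drop_initial Exclude the first `order` months of each subject from
#'   the likelihood instead of conditioning on a lesion-free run-in.
#' @return The OFV (numeric scalar) with attributes `eta` (per-subject
#'   empirical-Bayes modes, one column per subject) and `converged`.
#' @export
laplace_ofv <- function(dataset, fe, omega, spec, drop_initial = FALSE) {
  subjects <- prep_subjects(dataset, spec, drop_initial)
  marginal_ofv(subjects, fe, omega, spec, nodes = 1L)
}

#' Adaptive Gauss-Hermite marginal OFV (quadrature oracle)
#'
#' Same marginal -2 log-likelihood as [laplace_ofv()] but integrating the
#' random effects by adaptive Gauss-Hermite quadrature centered and scaled
#' at the per-subject mode. One node reproduces the Laplace approximation
#' exactly; increasing nodes converges to the exact integral. Used as the
#' truth standard when assessing the Laplace approximation.
#'
#' @inheritParams laplace_ofv
#' @param nodes Number of quadrature nodes per dimension (>= 1).
#' @return The OFV, with the same attributes as [laplace_ofv()].
#' @export
agq_ofv <- function(dataset, fe, omega, spec, nodes = 15L,
                    drop_initial = FALSE) {
  if (nodes < 1) stop("nodes must be >= 1", call. = FALSE)
  subjects <- prep_subjects(dataset, spec, drop_initial)
  marginal_ofv(subjects, fe, omega, spec, nodes = as.integer(nodes))
}

## Parameter transforms: positive parameters on the log scale, probabilities
## on the logit scale, the GP dispersion through atanh to (-1, 1).
.transform_of <- function(nm) {
  if (nm %in% c("p0", "pm")) "logit" else if (nm == "delta") "tanh" else "log"
}
.to_t <- function(x, tr) switch(tr, log = log(x), logit = stats::qlogis(x),
                                tanh = atanh(x))
.from_t <- function(x, tr) switch(tr, log = exp(x), logit = stats::plogis(x),
                                  tanh = tanh(x))
.dnat_dt <- function(nat, tr) switch(tr, log = nat, logit = nat * (1 - nat),
                                     tanh = 1 - nat^2)

default_init <- function(dataset, spec) {
  m <- mean(dataset$DV)
  th <- c(th_pdv = 0.3, th_ppdv = 0.1, th_pppdv = 0.05)
  lam0 <- if (spec$markov == "MAK2")
    max(m * (1 - sum(th[seq_len(spec$order)])), 0.05) else max(m, 0.05)
  init <- c(lam0 = lam0, lam2 = max(2 * m, 0.1), ovdp = 0.2, delta = 0.2,
            p0 = 0.05, pm = 0.5, th)
  if (spec$steroid_target != "none") {
    s <- paste0(spec$steroid_target, "_s")
    init[s] <- init[[spec$steroid_target]] / 2
  }
  init[free_params(spec)]
}

#' Fit settings
#'
#' @param iter_max Maximum outer iterations.
#' @param rel_tol Relative OFV convergence tolerance of the outer
#'   quasi-Newton optimization (inner Newton uses gradient tolerance 1e-8).
#' @param lower_t,upper_t Bounds on the transformed (log/logit) scale,
#'   guarding against parameter escape to the boundary.
#' @param compute_se Compute standard errors from a finite-difference
#'   Hessian at the optimum?
#' @return A list of settings for [fit_model()].
#' @export
fit_settings <- function(iter_max = 500L, rel_tol = 1e-8,
                         lower_t = -18, upper_t = 18, compute_se = TRUE) {
  list(iter_max = iter_max, rel_tol = rel_tol, lower_t = lower_t,
       upper_t = upper_t, compute_se = compute_se)
}

#' Fit a count model by Laplace-approximate maximum likelihood
#'
#' Minimizes the Laplace OFV over the transformed parameters (log for
#' positive parameters and variances, logit for probabilities) with a
#' quasi-Newton optimizer. Standard errors come from a finite-difference
#' Hessian of OFV/2 on the transformed scale, mapped back by the delta
#' method; inter-subject variability is reported as CV% = 100 sqrt(omega).
#'
#' @param dataset A CEL dataset.
#' @param spec A [model_spec()] or a ladder name accepted by
#'   [model_ladder()].
#' @param init Optional named list/vector of starting values (natural
#'   scale); entries `omega_<par>` start the variances. Missing entries use
#'   moment-based defaults.
#' @param settings See [fit_settings()].
#' @param drop_initial See [laplace_ofv()].
#' @return An object of class `celdyn_fit`: estimates, `ofv`, `aic`,
#'   standard errors and RSE%, ISV CV%, per-subject empirical-Bayes
#'   `eb_eta`, and convergence diagnostics.
#' @export
fit_model <- function(dataset, spec, init = NULL, settings = fit_settings(),
                      drop_initial = FALSE) {
  if (is.character(spec)) spec <- model_ladder(spec)
  stopifnot(inherits(spec, "celdyn_spec"))
  dataset <- as_cel_dataset(dataset)
  subjects <- prep_subjects(dataset, spec, drop_initial)
  th_names <- free_params(spec)
  om_names <- spec$random_effects

  start <- default_init(dataset, spec)
  om_start <- setNames(rep(0.2, length(om_names)),
                       paste0("omega_", om_names))
  if (!is.null(init)) {
    init <- unlist(init)
    for (nm in names(init)) {
      if (nm %in% th_names) start[nm] <- init[[nm]]
      if (nm %in% names(om_start)) om_start[nm] <- init[[nm]]
    }
  }
  trs <- vapply(th_names, .transform_of, character(1))
  par0 <- c(mapply(.to_t, start[th_names], trs),
            log(pmax(om_start, 1e-6)))
  npar <- length(par0)
  n_th <- length(th_names)

  unpack <- function(par_t) {
    th <- mapply(.from_t, par_t[seq_len(n_th)], trs)
    names(th) <- th_names
    om <- setNames(exp(par_t[n_th + seq_along(om_names)]), om_names)
    list(th = th, om = om)
  }
  objective <- function(par_t) {
    p <- unpack(par_t)
    v <- try(marginal_ofv(subjects, p$th, p$om, spec, nodes = 1L),
             silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) return(1e10)
    as.numeric(v)
  }
  ## central-difference gradient with a step well above the residual noise
  ## of the inner mode search; the optimizer's own tiny-step differences
  ## would sit inside that noise
  gradient <- function(par_t) {
    h <- 1e-3
    vapply(seq_along(par_t), function(j) {
      e <- par_t
      e[j] <- par_t[j] + h
      fp <- objective(e)
      e[j] <- par_t[j] - h
      (fp - objective(e)) / (2 * h)
    }, numeric(1))
  }
  ctrl <- list(iter.max = settings$iter_max,
               eval.max = 10L * settings$iter_max,
               rel.tol = settings$rel_tol, step.max = 1)
  opt <- stats::nlminb(par0, objective, gradient = gradient,
                       lower = settings$lower_t,
                       upper = settings$upper_t, control = ctrl)
  ## polish: restart once from the solution; guards against premature
  ## "false convergence" of the quasi-Newton run
  opt2 <- stats::nlminb(opt$par, objective, gradient = gradient,
                        lower = settings$lower_t,
                        upper = settings$upper_t, control = ctrl)
  if (opt2$objective <= opt$objective) {
    opt2$converged_flag <- opt2$convergence == 0 ||
      opt2$objective >= opt$objective - 1e-4 * (1 + abs(opt$objective))
    opt <- opt2
  } else opt$converged_flag <- opt$convergence == 0
  p <- unpack(opt$par)
  final <- marginal_ofv(subjects, p$th, p$om, spec, nodes = 1L)
  ofv <- as.numeric(final)
  eta <- attr(final, "eta")
  colnames(eta) <- vapply(subjects, function(s) as.character(s$id),
                          character(1))
  rownames(eta) <- if (length(attr(final, "active_re")))
    attr(final, "active_re") else NULL

  se_t <- rep(NA_real_, npar)
  vcov_t <- NULL
  se_note <- NULL
  if (isTRUE(settings$compute_se)) {
    Hh <- try(pracma::hessian(function(pp) objective(pp) / 2, opt$par,
                              h = 1e-3), silent = TRUE)
    if (inherits(Hh, "try-error")) {
      se_note <- paste("hessian failed:", attr(Hh, "condition")$message)
    } else {
      V <- try(solve(Hh), silent = TRUE)
      if (inherits(V, "try-error")) {
        se_note <- "information matrix is singular"
      } else if (!all(is.finite(diag(V))) || any(diag(V) <= 0)) {
        se_note <- "information matrix is not positive definite"
      } else {
        vcov_t <- V
        se_t <- sqrt(diag(V))
      }
    }
  }
  est <- p$th
  se_nat <- se_t[seq_len(n_th)] * abs(mapply(.dnat_dt, est, trs))
  names(se_nat) <- th_names
  se_om <- se_t[n_th + seq_along(om_names)] * p$om  # log-scale delta
  names(se_om) <- om_names

  out <- structure(list(
    spec = spec,
    estimates = est, omega = p$om,
    se = se_nat, se_omega = se_om,
    rse_pct = 100 * se_nat / abs(est),
    isv_cv = isv_cv(p$om),
    rse_omega_pct = 100 * se_om / ifelse(p$om > 0, p$om, NA),
    ofv = ofv, n_params = n_th + length(om_names),
    aic = ofv + 2 * (n_th + length(om_names)),
    eb_eta = eta,
    converged = isTRUE(opt$converged_flag) && attr(final, "converged"),
    message = opt$message, iterations = opt$iterations, se_note = se_note,
    vcov_t = vcov_t, par_t = opt$par, transforms = trs,
    data_fingerprint = dataset_fingerprint(dataset),
    n_subjects = length(subjects), n_obs = nrow(dataset),
    drop_initial = drop_initial, settings = settings),
    class = "celdyn_fit")
  out
}

dataset_fingerprint <- function(dataset) {
  c(n = nrow(dataset), subjects = length(unique(dataset$ID)),
    total = sum(dataset$DV))
}

#' @export
print.celdyn_fit <- function(x, ...) {
  cat("<celdyn_fit>", x$spec$label %||% paste(x$spec$family, x$spec$markov),
      "\n  subjects:", x$n_subjects, " observations:", x$n_obs,
      "\n  OFV (-2LL):", format(x$ofv, digits = 8),
      "  AIC:", format(x$aic, digits = 8),
      "  NP:", x$n_params,
      "\n  converged:", x$converged, "\n\n")
  print(coef_table(x), digits = 4)
  invisible(x)
}

#' Coefficient table of a fit
#'
#' Mirrors the conventional population-model reporting: estimate and RSE%
#' for each fixed effect, ISV CV% (= 100 sqrt(omega)) and its RSE% for
#' parameters carrying a random effect.
#'
#' @param fit A `celdyn_fit`.
#' @return A data.frame.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "celdyn_fit"))
  d <- data.frame(parameter = names(fit$estimates),
                  estimate = unname(fit$estimates),
                  rse_pct = unname(fit$rse_pct))
  d$isv_cv <- NA_real_
  d$isv_rse_pct <- NA_real_
  for (r in names(fit$omega)) {
    i <- match(r, d$parameter)
    d$isv_cv[i] <- fit$isv_cv[[r]]
    ## RSE of CV%: delta method, CV = 100 sqrt(omega)
    d$isv_rse_pct[i] <- 100 * (fit$se_omega[[r]] / (2 * fit$omega[[r]]))
  }
  d
}

#' Chi-square critical value for a likelihood-ratio comparison
#'
#' The study convention: a drop in -2LL of 6.63 for one extra parameter
#' (the 0.99 quantile of chi-square with 1 df) marks a significant
#' improvement between nested models.
#'
#' @param df Degrees of freedom (>= 1).
#' @param alpha Significance level in (0, 1), default 0.01.
#' @return The upper-alpha quantile of chi-square(df).
#' @examples
#' lrt_threshold(1, 0.01)  # 6.63
#' @export
lrt_threshold <- function(df, alpha = 0.01) {
  if (df < 1 || alpha <= 0 || alpha >= 1)
    stop("df must be >= 1 and alpha in (0,1)", call. = FALSE)
  stats::qchisq(1 - alpha, df)
}

#' Compare two fitted models
#'
#' Nested models are compared by the drop in OFV against the chi-square
#' critical value at the difference in parameter count; non-nested models by
#' AIC.
#'
#' @param fit_a,fit_b `celdyn_fit` objects on the same dataset.
#' @param nested Are the models nested?
#' @param alpha Significance level for the nested test.
#' @return A list with `delta_ofv` (smaller minus larger model), `delta_df`,
#'   `threshold`, `significant` / `preferred`, and the AIC difference.
#' @export
compare_fits <- function(fit_a, fit_b, nested = TRUE, alpha = 0.01) {
  stopifnot(inherits(fit_a, "celdyn_fit"), inherits(fit_b, "celdyn_fit"))
  if (!isTRUE(all.equal(fit_a$data_fingerprint, fit_b$data_fingerprint)))
    stop("fits are not on the same dataset", call. = FALSE)
  small <- if (fit_a$n_params <= fit_b$n_params) fit_a else fit_b
  large <- if (fit_a$n_params <= fit_b$n_params) fit_b else fit_a
  delta_ofv <- small$ofv - large$ofv
  delta_df <- large$n_params - small$n_params
  out <- list(delta_ofv = delta_ofv, delta_df = delta_df,
              delta_aic = large$aic - small$aic,
              ofv = c(small = small$ofv, large = large$ofv))
  if (nested) {
    thr <- lrt_threshold(max(delta_df, 1L), alpha)
    out$threshold <- thr
    out$significant <- delta_ofv > thr
    out$preferred <- if (out$significant) large$spec$label %||% "larger"
                     else small$spec$label %||% "smaller"
  } else {
    out$preferred <- if (large$aic < small$aic) large$spec$label %||% "larger"
                     else small$spec$label %||% "smaller"
  }
  out
}

#' Inter-subject variability as a coefficient of variation
#'
#' The reporting convention for a log-normal random effect with variance
#' omega: CV% = 100 sqrt(omega). (Other conventions, e.g.
#' 100 sqrt(exp(omega) - 1), exist; this package uses the square-root form
#' throughout.)
#'
#' @param omega Variance(s) of the log-scale random effect.
#' @return CV% value(s).
#' @examples
#' isv_cv(0.44)   # 66.33
#' @export
isv_cv <- function(omega) {
  if (any(omega < 0)) stop("omega must be >= 0", call. = FALSE)
  100 * sqrt(omega)
}

#' Percent change between two estimates
#'
#' @param from,to The two values.
#' @param denominator Express the change relative to `from` (conventional)
#'   or to `to`.
#' @return Percent change.
#' @export
percent_change <- function(from, to, denominator = c("from", "to")) {
  denominator <- match.arg(denominator)
  100 * (to - from) / if (denominator == "from") from else to
}

#' Steroid-month attenuation of a replaced coefficient
#'
#' For a model where the steroid covariate replaces a coefficient by its
#' steroid-month value, the attenuation is 100 (1 - value_s / value).
#'
#' @param fit A `celdyn_fit` with a steroid effect, or the base coefficient.
#' @param value_s The steroid-month value (when `fit` is numeric).
#' @return Percent attenuation.
#' @export
steroid_attenuation <- function(fit, value_s = NULL) {
  if (inherits(fit, "celdyn_fit")) {
    tg <- fit$spec$steroid_target
    if (tg == "none") stop("fit has no steroid effect", call. = FALSE)
    base <- fit$estimates[[tg]]
    value_s <- fit$estimates[[paste0(tg, "_s")]]
  } else base <- fit
  100 * (1 - value_s / base)
}
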