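## lengths of maximal runs of zero months (runs touching the series
## boundaries count)
zero_runs <- function(counts) {
  r <- rle(counts == 0)
  r$lengths[r$values]
}

#' Dynamic descriptors of a CEL dataset
#'
#' The simulation-based evaluation summarizes a cohort through: the pooled
#' probability of observing 0, 1, ..., 7 or >=8 lesions in a month
#' (`p_k`); each subject's maximum and mean lesion-free elapsed time
#' (lengths of maximal runs of zero-count months, boundary runs included;
#' 0 if a subject has no lesion-free month); cumulative lesions per
#' non-overlapping 12-month year; and each subject's (mean, variance) pair.
#'
#' @param dataset A `cel_dataset`.
#' @return A list of class `cel_descriptors`: `p_k` (named, sums to 1),
#'   `subjects` (per-subject max_free, mean_free, mean, variance, total),
#'   `p_k_subject` (per-subject p_k matrix), `cum_year` (per subject-year),
#'   `n_months`.
#' @examples
#' d <- data.frame(ID = 1, MONTH = 1:7, DV = c(0, 0, 3, 0, 0, 0, 1))
#' cel_descriptors(d)$subjects[, c("max_free", "mean_free")]  # 3, 2.5
#' @export
cel_descriptors <- function(dataset) {
  dataset <- as_cel_dataset(dataset)
  kcap <- pmin(dataset$DV, 8L)
  p_k <- as.numeric(table(factor(kcap, levels = 0:8))) / nrow(dataset)
  names(p_k) <- c(as.character(0:7), ">=8")
  ids <- unique(dataset$ID)
  per <- lapply(ids, function(id) {
    y <- dataset$DV[dataset$ID == id][order(dataset$MONTH[dataset$ID == id])]
    zr <- zero_runs(y)
    data.frame(ID = id,
               max_free = if (length(zr)) max(zr) else 0,
               mean_free = if (length(zr)) mean(zr) else 0,
               mean = mean(y), variance = stats::var(y), total = sum(y))
  })
  subjects <- do.call(rbind, per)
  pks <- t(vapply(ids, function(id) {
    y <- dataset$DV[dataset$ID == id]
    as.numeric(table(factor(pmin(y, 8L), levels = 0:8))) / length(y)
  }, numeric(9)))
  colnames(pks) <- names(p_k)
  cum_year <- do.call(rbind, lapply(ids, function(id) {
    d <- dataset[dataset$ID == id, ]
    y <- d$DV[order(d$MONTH)]
    ny <- length(y) %/% 12
    if (ny == 0) return(NULL)
    data.frame(ID = id, year = seq_len(ny),
               cum = vapply(seq_len(ny), function(k)
                 sum(y[(12 * (k - 1) + 1):(12 * k)]), numeric(1)))
  }))
  structure(list(p_k = p_k, subjects = subjects, p_k_subject = pks,
                 cum_year = cum_year,
                 n_months = max(dataset$MONTH)),
            class = "cel_descriptors")
}

#' @export
print.cel_descriptors <- function(x, ...) {
  cat("<cel_descriptors>", nrow(x$subjects), "subjects,", x$n_months,
      "months\n  P(k):", paste(names(x$p_k), round(x$p_k, 3), sep = "=",
                               collapse = " "), "\n")
  invisible(x)
}

resolve_model <- function(fit) {
  if (inherits(fit, "celdyn_fit"))
    return(list(spec = fit$spec, theta = fit$estimates, omega = fit$omega))
  if (is.list(fit) && !is.null(fit$spec))
    return(list(spec = fit$spec, theta = fit$theta %||% fit$estimates,
                omega = fit$omega))
  stop("supply a celdyn_fit or a list(spec, theta, omega)", call. = FALSE)
}

## per-subject descriptor curves used by vnpc / prediction intervals:
## a named list of numeric vectors, one value per subject (or subject-year)
descriptor_samples <- function(desc) {
  out <- list(max_free = desc$subjects$max_free,
              mean_free = desc$subjects$mean_free,
              cum_year = if (!is.null(desc$cum_year)) desc$cum_year$cum
                         else numeric(0))
  for (k in colnames(desc$p_k_subject))
    out[[paste0("p_", k)]] <- desc$p_k_subject[, k]
  out
}

pct_curve <- function(x, probs) {
  if (!length(x)) return(rep(NA_real_, length(probs)))
  ## linear interpolation between closest ranks (quantile type 7)
  as.numeric(stats::quantile(x, probs / 100, type = 7, names = FALSE))
}

#' Visual numerical predictive check (VNPC)
#'
#' Simulates `n_individuals` trajectories of the observed length from the
#' fitted model and compares, for every dynamic descriptor, the observed
#' percentile curve (5th to 95th in steps of 5 by default) with the
#' simulated one.
#'
#' @param observed A `cel_dataset`.
#' @param fit A `celdyn_fit`, or `list(spec, theta, omega)`.
#' @param n_individuals Number of simulated subjects (default 1000).
#' @param seed Integer seed.
#' @param percentiles Percentile grid.
#' @return A data.frame with columns `descriptor`, `percentile`,
#'   `observed`, `simulated`, of class `cel_vnpc`.
#' @export
vnpc <- function(observed, fit, n_individuals = 1000L, seed,
                 percentiles = seq(5, 95, 5)) {
  observed <- as_cel_dataset(observed)
  m <- resolve_model(fit)
  sim <- simulate_cohort(m$spec, m$theta, m$omega,
                         n_subjects = n_individuals,
                         n_months = max(observed$MONTH), seed = seed)
  dob <- descriptor_samples(cel_descriptors(observed))
  dsi <- descriptor_samples(cel_descriptors(sim))
  out <- do.call(rbind, lapply(names(dob), function(nm)
    data.frame(descriptor = nm, percentile = percentiles,
               observed = pct_curve(dob[[nm]], percentiles),
               simulated = pct_curve(dsi[[nm]], percentiles))))
  class(out) <- c("cel_vnpc", "data.frame")
  out
}

#' Prediction intervals for the VNPC descriptors
#'
#' Simulates `n_studies` replicate studies of `study_size` subjects each,
#' computes every descriptor's percentile curve (10th to 90th in steps of 5)
#' per study, and returns the pointwise 95% envelope (2.5th-97.5th) and
#' median across studies together with the observed curve.
#'
#' @inheritParams vnpc
#' @param n_studies Number of simulated studies (default 1000).
#' @param study_size Subjects per study (default: as observed).
#' @return A data.frame with columns `descriptor`, `percentile`, `observed`,
#'   `lower`, `median`, `upper`, of class `cel_pi`.
#' @export
prediction_intervals <- function(observed, fit, n_studies = 1000L,
                                 study_size = NULL, seed,
                                 percentiles = seq(10, 90, 5)) {
  observed <- as_cel_dataset(observed)
  m <- resolve_model(fit)
  study_size <- study_size %||% length(unique(observed$ID))
  Tm <- max(observed$MONTH)
  sim <- simulate_cohort(m$spec, m$theta, m$omega,
                         n_subjects = n_studies * study_size,
                         n_months = Tm, seed = seed)
  study <- (match(sim$ID, unique(sim$ID)) - 1L) %/% study_size
  dob <- descriptor_samples(cel_descriptors(observed))
  curves <- lapply(split.data.frame(as.data.frame(sim), study), function(d) {
    ds <- descriptor_samples(cel_descriptors(d))
    lapply(ds, pct_curve, probs = percentiles)
  })
  out <- do.call(rbind, lapply(names(dob), function(nm) {
    mat <- do.call(rbind, lapply(curves, `[[`, nm))
    data.frame(descriptor = nm, percentile = percentiles,
               observed = pct_curve(dob[[nm]], percentiles),
               lower = apply(mat, 2, stats::quantile, 0.025, na.rm = TRUE),
               median = apply(mat, 2, stats::median, na.rm = TRUE),
               upper = apply(mat, 2, stats::quantile, 0.975, na.rm = TRUE))
  }))
  rownames(out) <- NULL
  class(out) <- c("cel_pi", "data.frame")
  out
}

#' Predicted interval for variance versus mean of counts
#'
#' Simulates `n_individuals` subjects, computes each subject's (mean,
#' variance) pair over the follow-up window, sorts by mean, bins into 20
#' equal-count intervals, and reports per bin the median mean together with
#' the median and 5th/95th percentiles of the variances. The observed
#' per-subject pairs are attached for overlay.
#'
#' @inheritParams vnpc
#' @return A list of class `cel_varmean`: `bins` (data.frame) and
#'   `observed` (per-subject mean/variance).
#' @export
variance_mean_pi <- function(observed, fit, n_individuals = 1000L, seed) {
  if (n_individuals %% 20 != 0)
    stop("n_individuals must be divisible by 20", call. = FALSE)
  observed <- as_cel_dataset(observed)
  m <- resolve_model(fit)
  sim <- simulate_cohort(m$spec, m$theta, m$omega,
                         n_subjects = n_individuals,
                         n_months = max(observed$MONTH), seed = seed)
  ss <- cel_descriptors(sim)$subjects
  ss <- ss[order(ss$mean), ]
  per_bin <- n_individuals / 20
  bin <- rep(seq_len(20), each = per_bin)
  bins <- do.call(rbind, lapply(split(ss, bin), function(d)
    data.frame(mean_median = stats::median(d$mean),
               var_lower = stats::quantile(d$variance, 0.05, names = FALSE),
               var_median = stats::median(d$variance),
               var_upper = stats::quantile(d$variance, 0.95, names = FALSE),
               n = nrow(d))))
  bins$bin <- seq_len(20)
  obs <- cel_descriptors(observed)$subjects[, c("ID", "mean", "variance")]
  structure(list(bins = bins, observed = obs), class = "cel_varmean")
}

#' External validation against a short-follow-up cohort
#'
#' Compares per-subject maximum, median and mean counts of an external
#' cohort (the validation design: 14 subjects, 6 monthly scans) against the
#' 95% prediction envelope of replicate studies simulated from the fitted
#' model, plus the variance-versus-mean envelope for the same window length.
#'
#' @param observed External `cel_dataset` (typically 6 months).
#' @inheritParams vnpc
#' @param n_studies Number of simulated replicate studies.
#' @return A list of class `cel_validation`: `descriptors` (per-rank
#'   observed value and simulated envelope for max/median/mean) and
#'   `var_mean` (a `cel_varmean`).
#' @export
external_validation <- function(observed, fit, n_studies = 1000L, seed) {
  observed <- as_cel_dataset(observed)
  m <- resolve_model(fit)
  n_sub <- length(unique(observed$ID))
  Tm <- max(observed$MONTH)
  sim <- simulate_cohort(m$spec, m$theta, m$omega,
                         n_subjects = n_studies * n_sub, n_months = Tm,
                         seed = seed)
  stat3 <- function(d) {
    ids <- unique(d$ID)
    t(vapply(ids, function(id) {
      y <- d$DV[d$ID == id]
      c(max = max(y), median = stats::median(y), mean = mean(y))
    }, numeric(3)))
  }
  obs <- apply(stat3(observed), 2, sort)
  study <- (match(sim$ID, unique(sim$ID)) - 1L) %/% n_sub
  sims <- lapply(split.data.frame(as.data.frame(sim), study),
                 function(d) apply(stat3(d), 2, sort))
  desc <- do.call(rbind, lapply(c("max", "median", "mean"), function(st) {
    mat <- do.call(rbind, lapply(sims, function(s) s[, st]))
    data.frame(descriptor = st, rank = seq_len(n_sub),
               observed = obs[, st],
               lower = apply(mat, 2, stats::quantile, 0.025),
               median = apply(mat, 2, stats::median),
               upper = apply(mat, 2, stats::quantile, 0.975))
  }))
  rownames(desc) <- NULL
  vm <- variance_mean_pi(observed, fit, n_individuals = 1000L,
                         seed = seed + 1L)
  structure(list(descriptors = desc, var_mean = vm),
            class = "cel_validation")
}
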