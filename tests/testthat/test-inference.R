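ref <- cohort_reference_params("NB_nested MAK2")
spn <- model_ladder("NB_nested MAK2")

test_that("zero variances reduce the marginal OFV to the fixed-effects -2LL", {
  dat <- simulate_cohort(spn, ref$theta, ref$omega, 9, 48, seed = 3)
  ofv <- laplace_ofv(dat, ref$theta, c(lam0 = 0, th_pdv = 0), spn)
  ## brute-force oracle: plain-R month-by-month log pmf sums at eta = 0
  ll <- sum(vapply(unique(dat$ID), function(id)
    subject_loglik(dat$DV[dat$ID == id], ref$theta, c(0, 0), spn),
    numeric(1)))
  expect_equal(as.numeric(ofv), -2 * ll, tolerance = 1e-10)
  expect_equal(as.numeric(agq_ofv(dat, ref$theta, c(lam0 = 0, th_pdv = 0),
                                  spn, nodes = 15)), -2 * ll,
               tolerance = 1e-10)
})

test_that("one-subject marginal matches adaptive quadrature of the integral", {
  d1 <- data.frame(ID = 1, MONTH = 1, DV = 3, STEROID = 0)
  sp <- model_ladder("PS")
  lam <- 1.2
  om <- 0.5
  exact <- stats::integrate(function(e)
    stats::dpois(3, lam * exp(e)) * stats::dnorm(e, 0, sqrt(om)), -10, 10,
    rel.tol = 1e-12)$value
  expect_equal(as.numeric(agq_ofv(d1, c(lam0 = lam), c(lam0 = om), sp,
                                  nodes = 31)), -2 * log(exact),
               tolerance = 1e-8)
  ## single observation is the hardest case for Laplace; still within 0.5%
  lap <- as.numeric(laplace_ofv(d1, c(lam0 = lam), c(lam0 = om), sp))
  expect_lt(abs(lap + 2 * log(exact)) / abs(2 * log(exact)), 5e-3)
  ## a representative cohort-scale case is within 0.1%
  d2 <- data.frame(ID = 1, MONTH = 1, DV = 3, STEROID = 0)
  exact2 <- stats::integrate(function(e)
    stats::dpois(3, 2 * exp(e)) * stats::dnorm(e, 0, sqrt(0.44)), -10, 10,
    rel.tol = 1e-12)$value
  lap2 <- as.numeric(laplace_ofv(d2, c(lam0 = 2), c(lam0 = 0.44), sp))
  expect_lt(abs(lap2 + 2 * log(exact2)) / abs(2 * log(exact2)), 1e-3)
})

test_that("one quadrature node reproduces the Laplace approximation", {
  dat <- simulate_cohort(spn, ref$theta, ref$omega, 5, 24, seed = 8)
  expect_equal(as.numeric(agq_ofv(dat, ref$theta, ref$omega, spn, nodes = 1)),
               as.numeric(laplace_ofv(dat, ref$theta, ref$omega, spn)))
})

test_that("quadrature converges in the number of nodes", {
  dat <- simulate_cohort(spn, ref$theta, ref$omega, 6, 24, seed = 9)
  o7 <- as.numeric(agq_ofv(dat, ref$theta, ref$omega, spn, nodes = 7))
  o15 <- as.numeric(agq_ofv(dat, ref$theta, ref$omega, spn, nodes = 15))
  o31 <- as.numeric(agq_ofv(dat, ref$theta, ref$omega, spn, nodes = 31))
  expect_lt(abs(o15 - o7), 1e-3)
  expect_lt(abs(o31 - o15), 1e-3)
})

test_that("OFV is invariant to subject order and relabeling", {
  dat <- simulate_cohort(spn, ref$theta, ref$omega, 7, 20, seed = 10)
  base <- as.numeric(laplace_ofv(dat, ref$theta, ref$omega, spn))
  shuffled <- dat[order(rev(seq_len(nrow(dat)))), ]
  shuffled <- shuffled[order(match(shuffled$ID, c(4, 2, 7, 1, 3, 6, 5)),
                             shuffled$MONTH), ]
  expect_equal(as.numeric(laplace_ofv(shuffled, ref$theta, ref$omega, spn)),
               base)
  relabeled <- dat
  relabeled$ID <- paste0("pt", relabeled$ID)
  expect_equal(as.numeric(laplace_ofv(relabeled, ref$theta, ref$omega, spn)),
               base)
})

test_that("chi-square thresholds match the selection convention", {
  expect_equal(lrt_threshold(1, 0.01), 6.63, tolerance = 0.005)
  expect_equal(lrt_threshold(1, 0.05), 3.84, tolerance = 0.005)
  expect_equal(lrt_threshold(2, 0.01), qchisq(0.99, 2))
  expect_error(lrt_threshold(0, 0.01), "df")
  expect_error(lrt_threshold(1, 1.2), "alpha")
})

test_that("model comparison applies the 6.63 rule and AIC ranking", {
  dat <- simulate_cohort(spn, ref$theta, ref$omega, 9, 48, seed = 12)
  mk_fit <- function(ofv, np, label) {
    structure(list(ofv = ofv, aic = ofv + 2 * np, n_params = np,
                   spec = structure(list(label = label),
                                    class = "celdyn_spec"),
                   data_fingerprint = c(n = 1, subjects = 1, total = 1)),
              class = "celdyn_fit")
  }
  ## the published deltas: -8.49 is significant at 1 df, -3.59 is not
  cmp <- compare_fits(mk_fit(1642.85, 5, "NB_MAK2"),
                      mk_fit(1634.36, 6, "NB_nested MAK2"))
  expect_true(cmp$significant)
  expect_equal(cmp$delta_ofv, 8.49)
  cmp2 <- compare_fits(mk_fit(1634.36, 6, "NB_nested MAK2"),
                       mk_fit(1630.77, 7, "NB_nested nested MAK2"))
  expect_false(cmp2$significant)
  cmp3 <- compare_fits(mk_fit(1000, 4, "A"), mk_fit(1000, 4, "B"))
  expect_false(cmp3$significant)
  expect_equal(cmp3$delta_ofv, 0)
  ## non-nested: AIC decides
  cmp4 <- compare_fits(mk_fit(1758.92, 4, "NB"), mk_fit(1867.23, 5, "PMIX"),
                       nested = FALSE)
  expect_equal(cmp4$preferred, "NB")
  fitA <- mk_fit(10, 2, "x")
  fitA$data_fingerprint <- c(n = 2, subjects = 1, total = 5)
  expect_error(compare_fits(fitA, mk_fit(10, 2, "y")), "same dataset")
})

test_that("refitting from the solution is a fixed point", {
  dat <- simulate_cohort(spn, ref$theta, ref$omega, 9, 48, seed = 14)
  f1 <- fit_model(dat, spn, settings = fit_settings(compute_se = FALSE))
  init2 <- c(as.list(f1$estimates),
             as.list(setNames(f1$omega, paste0("omega_", names(f1$omega)))))
  f2 <- fit_model(dat, spn, init = init2,
                  settings = fit_settings(compute_se = FALSE))
  expect_lt(abs(f2$ofv - f1$ofv), 1e-4)
})

test_that("fits are deterministic given init and settings", {
  dat <- simulate_cohort(spn, ref$theta, ref$omega, 6, 24, seed = 15)
  f1 <- fit_model(dat, spn, settings = fit_settings(compute_se = FALSE))
  f2 <- fit_model(dat, spn, settings = fit_settings(compute_se = FALSE))
  expect_identical(f1$ofv, f2$ofv)
  expect_identical(f1$estimates, f2$estimates)
})

test_that("AIC bookkeeping is consistent", {
  dat <- simulate_cohort(spn, ref$theta, ref$omega, 5, 20, seed = 16)
  f <- fit_model(dat, spn, settings = fit_settings(compute_se = FALSE))
  expect_equal(f$n_params, 6)  # 4 fixed effects + 2 variances
  expect_equal(f$aic, f$ofv + 2 * f$n_params)
  expect_true(is.finite(f$ofv))
})

test_that("a plain NB mixed fit agrees with an independent implementation", {
  skip_if_not_installed("glmmTMB")
  sp <- model_spec("NB", random_effects = "lam0")
  dat <- simulate_cohort(sp, c(lam0 = 2.3, ovdp = 0.25), c(lam0 = 0.5),
                         60, 24, seed = 17)
  f <- fit_model(dat, sp, settings = fit_settings(compute_se = FALSE))
  g <- glmmTMB::glmmTMB(DV ~ 1 + (1 | ID), family = glmmTMB::nbinom2,
                        data = as.data.frame(dat))
  ## same Laplace-type marginal likelihood and intercept on the log scale
  expect_equal(f$ofv, -2 * as.numeric(stats::logLik(g)), tolerance = 0.01)
  expect_equal(log(f$estimates[["lam0"]]),
               unname(glmmTMB::fixef(g)$cond[1]), tolerance = 0.02)
  expect_equal(f$estimates[["ovdp"]], 1 / glmmTMB::sigma(g),
               tolerance = 0.05)
})
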