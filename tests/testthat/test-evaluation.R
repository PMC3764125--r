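ref <- cohort_reference_params("NB_nested MAK2")
spn <- model_ladder("NB_nested MAK2")
fit_ref <- list(spec = spn, theta = ref$theta, omega = ref$omega)

test_that("descriptors match hand counts on toy series", {
  d <- cel_descriptors(data.frame(ID = 1, MONTH = 1:7,
                                  DV = c(0, 0, 3, 0, 0, 0, 1)))
  expect_equal(d$subjects$max_free, 3)
  expect_equal(d$subjects$mean_free, 2.5)
  expect_equal(d$subjects$total, 4)
  ## all-zero subject: everything in the zero bucket, one long run
  z <- cel_descriptors(data.frame(ID = "z", MONTH = 1:48, DV = 0))
  expect_equal(unname(z$p_k["0"]), 1)
  expect_equal(z$subjects$max_free, 48)
  expect_equal(z$subjects$mean_free, 48)
  ## no lesion-free month at all
  n0 <- cel_descriptors(data.frame(ID = 1, MONTH = 1:3, DV = c(2, 1, 4)))
  expect_equal(n0$subjects$max_free, 0)
  expect_equal(n0$subjects$mean_free, 0)
})

test_that("count buckets close at >=8 and probabilities sum to one", {
  d <- cel_descriptors(data.frame(ID = 1, MONTH = 1:12,
                                  DV = c(0:7, 8, 9, 20, 0)))
  expect_equal(sum(d$p_k), 1)
  expect_equal(unname(d$p_k[">=8"]), 3 / 12)
  expect_equal(unname(d$p_k["0"]), 2 / 12)
})

test_that("yearly cumulative counts use non-overlapping 12-month blocks", {
  y <- rep(1L, 48)
  y[13] <- 5L
  d <- cel_descriptors(data.frame(ID = 1, MONTH = 1:48, DV = y))
  expect_equal(d$cum_year$cum, c(12, 16, 12, 12))
  ## a 6-month series has no complete year
  d6 <- cel_descriptors(data.frame(ID = 1, MONTH = 1:6, DV = 1))
  expect_null(d6$cum_year)
})

test_that("zero-probability converges to exp(-lam) for a Poisson cohort", {
  sim <- simulate_cohort(model_ladder("PS"), c(lam0 = 1.4), c(lam0 = 0),
                         2000, 12, seed = 31)
  expect_equal(unname(cel_descriptors(sim)$p_k["0"]), exp(-1.4),
               tolerance = 0.02)
})

test_that("descriptor computation ignores subject order", {
  dat <- simulate_cohort(spn, ref$theta, ref$omega, 6, 24, seed = 32)
  rev_dat <- dat[order(-as.integer(dat$ID), dat$MONTH), ]
  a <- cel_descriptors(dat)
  b <- cel_descriptors(rev_dat)
  expect_equal(a$p_k, b$p_k)
  expect_equal(sort(a$subjects$max_free), sort(b$subjects$max_free))
})

test_that("VNPC curves are monotone and self-consistent under the model", {
  obs <- simulate_cohort(spn, ref$theta, ref$omega, 9, 48, seed = 33)
  v <- vnpc(obs, fit_ref, n_individuals = 400, seed = 34)
  for (nm in unique(v$descriptor)) {
    cv <- v[v$descriptor == nm, ]
    expect_false(is.unsorted(cv$simulated), label = paste("sim", nm))
    expect_false(is.unsorted(cv$observed), label = paste("obs", nm))
  }
  ## two simulated cohorts from the same model give nearby curves
  v2 <- vnpc(obs, fit_ref, n_individuals = 400, seed = 35)
  agree <- abs(v$simulated - v2$simulated) <=
    pmax(1, 0.35 * pmax(abs(v$simulated), abs(v2$simulated)))
  expect_gt(mean(agree), 0.9)
})

test_that("prediction intervals cover data generated by the model", {
  obs <- simulate_cohort(spn, ref$theta, ref$omega, 9, 48, seed = 36)
  pi <- prediction_intervals(obs, fit_ref, n_studies = 300, seed = 37)
  expect_true(all(pi$lower <= pi$median + 1e-9))
  expect_true(all(pi$median <= pi$upper + 1e-9))
  inside <- pi$observed >= pi$lower & pi$observed <= pi$upper
  expect_gt(mean(inside), 0.9)
})

test_that("variance-mean envelope uses 20 equal bins and flags dispersion", {
  obs <- simulate_cohort(spn, ref$theta, ref$omega, 9, 48, seed = 38)
  vm <- variance_mean_pi(obs, fit_ref, n_individuals = 1000, seed = 39)
  expect_equal(nrow(vm$bins), 20L)
  expect_true(all(vm$bins$n == 50))
  ## NB-generated data: median variance exceeds the mean in the upper bins
  up <- vm$bins[vm$bins$bin > 10, ]
  expect_true(all(up$var_median > up$mean_median))
  expect_error(variance_mean_pi(obs, fit_ref, n_individuals = 999,
                                seed = 1), "divisible")
  ## Poisson cohort: the envelope straddles the identity line
  ps_fit <- list(spec = model_ladder("PS"), theta = c(lam0 = 2),
                 omega = c(lam0 = 0))
  obs_ps <- simulate_cohort(model_ladder("PS"), c(lam0 = 2), c(lam0 = 0),
                            9, 48, seed = 40)
  vmp <- variance_mean_pi(obs_ps, ps_fit, n_individuals = 1000, seed = 41)
  expect_true(all(vmp$bins$var_lower <= vmp$bins$mean_median))
  expect_true(all(vmp$bins$var_upper >= vmp$bins$mean_median))
})

test_that("external validation flags under-prediction of a hotter cohort", {
  obs <- validation_cohort_preset(seed = 42)
  ev <- external_validation(obs, fit_ref, n_studies = 300, seed = 43)
  expect_equal(sort(unique(ev$descriptors$descriptor)),
               c("max", "mean", "median"))
  ## self-consistency: data from the fitted model stay mostly inside the PI
  inside <- with(ev$descriptors, observed >= lower & observed <= upper)
  expect_gt(mean(inside), 0.85)
  ## a flat series gives identical descriptors
  one <- cel_descriptors(data.frame(ID = 1, MONTH = 1:6, DV = 1))$subjects
  expect_equal(one$mean, 1)
  ## a substantially more active cohort escapes above the envelope
  hot <- ref
  hot$theta["lam0"] <- 3 * hot$theta["lam0"]
  obs_hot <- simulate_cohort(spn, hot$theta, hot$omega, 14, 6, seed = 44)
  ev_hot <- external_validation(obs_hot, fit_ref, n_studies = 300,
                                seed = 45)
  for (st in c("max", "median", "mean")) {
    m <- ev_hot$descriptors[ev_hot$descriptors$descriptor == st, ]
    expect_gte(sum(m$observed > m$median), 12, label = paste("above", st))
  }
  mn <- ev_hot$descriptors[ev_hot$descriptors$descriptor == "mean", ]
  expect_gte(sum(mn$observed > mn$upper), 3)
})
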