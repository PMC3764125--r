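test_that("the sixteen ladder models have the published structure", {
  expect_length(ladder_names(), 16)
  nb2 <- model_ladder("NB_nested MAK2")
  expect_equal(nb2$family, "NB")
  expect_equal(nb2$markov, "MAK2")
  expect_equal(nb2$order, 2L)
  expect_equal(nb2$random_effects, c("lam0", "th_pdv"))
  ps <- model_ladder("PS")
  expect_equal(ps$family, "PS")
  expect_equal(ps$markov, "none")
  expect_equal(ps$random_effects, "lam0")
  zinb <- model_ladder("ZINB")
  expect_equal(zinb$random_effects, c("lam0", "ovdp"))
  st <- model_ladder("NB_nested MAK2 steroids")
  expect_equal(st$steroid_target, "th_pdv")
  expect_true("th_pdv_s" %in% free_params(st))
  ## slug aliases resolve to the same specification
  expect_equal(model_ladder("nb-nested-mak2")$label, "NB_nested MAK2")
  expect_equal(model_ladder("gp-nested-mak2")$label, "GP_nested_MAK2")
  expect_error(model_ladder("nonsense"), "valid models")
  ## every ladder entry has a reference parameter vector covering its
  ## free parameters and random effects
  for (nm in ladder_names()) {
    sp <- model_ladder(nm)
    pr <- cohort_reference_params(nm)
    expect_true(all(free_params(sp) %in% names(pr$theta)), label = nm)
    expect_true(all(sp$random_effects %in% names(pr$omega)), label = nm)
  }
})

test_that("conditional mean follows the additive Markov form", {
  sp <- model_ladder("NB_nested MAK2")
  fe <- c(lam0 = 0.940, ovdp = 0.155, th_pdv = 0.430, th_ppdv = 0.141)
  lags <- data.frame(pdv = 2, ppdv = 1, pppdv = 0, pmak1_ind = 1)
  expect_equal(conditional_mean(fe, c(0, 0), lags, 0, sp),
               0.940 + 0.430 * 2 + 0.141 * 1)
  ## lesion-free history returns the baseline
  lags0 <- data.frame(pdv = 0, ppdv = 0, pppdv = 0, pmak1_ind = 0)
  expect_equal(conditional_mean(fe, c(0, 0), lags0, 0, sp), 0.940)
  ## random effects act multiplicatively on their targets
  expect_equal(conditional_mean(fe, c(log(2), log(3)), lags, 0, sp),
               0.940 * 2 + 0.430 * 3 * 2 + 0.141)
})

test_that("the PMAK1 indicator selects between the two rates", {
  sp <- model_ladder("PMAK1")
  fe <- c(lam0 = 0.932, lam2 = 2.76)
  lags <- data.frame(pdv = c(0, 4), ppdv = 0, pppdv = 0,
                     pmak1_ind = c(0, 1))
  expect_equal(conditional_mean(fe, 0, lags, 0, sp), c(0.932, 2.76))
})

test_that("steroid months replace the first-order coefficient", {
  sp <- model_ladder("NB_nested MAK2 steroids")
  fe <- c(lam0 = 0.923, ovdp = 0.132, th_pdv = 0.447, th_pdv_s = 0.150,
          th_ppdv = 0.145)
  lags <- data.frame(pdv = 3, ppdv = 0, pppdv = 0, pmak1_ind = 1)
  expect_equal(conditional_mean(fe, c(0, 0), lags, 1, sp),
               0.923 + 0.150 * 3)
  expect_equal(conditional_mean(fe, c(0, 0), lags, 0, sp),
               0.923 + 0.447 * 3)
})

test_that("conditional mean is monotone in each lag", {
  sp <- model_ladder("NB_nested nested MAK2")
  fe <- c(lam0 = 0.817, ovdp = 0.157, th_pdv = 0.448, th_ppdv = 0.104,
          th_pppdv = 0.0955)
  set.seed(3)
  for (i in 1:20) {
    l1 <- data.frame(pdv = rpois(1, 3), ppdv = rpois(1, 3),
                     pppdv = rpois(1, 3), pmak1_ind = 1)
    l2 <- l1 + c(sample(0:2, 3, replace = TRUE), 0)
    expect_gte(conditional_mean(fe, c(0, 0), l2, 0, sp),
               conditional_mean(fe, c(0, 0), l1, 0, sp))
  }
})

test_that("subject log-likelihood matches hand computation and is pure", {
  sp <- model_ladder("PS")
  expect_equal(subject_loglik(0L, c(lam0 = 1), 0, sp), -1)
  spn <- model_ladder("NB_nested MAK2")
  fe <- cohort_reference_params()$theta
  y <- c(0L, 2L, 5L, 0L, 1L)
  expect_identical(subject_loglik(y, fe, c(0.2, -0.1), spn),
                   subject_loglik(y, fe, c(0.2, -0.1), spn))
  ## month-by-month oracle: same sum assembled directly from the pmf
  lam <- 0.940 * exp(0.2) + 0.430 * exp(-0.1) * c(0, y[-5]) +
    0.141 * c(0, 0, y[1:3])
  byhand <- sum(vapply(1:5, function(t)
    dcount(y[t], count_params("NB", lam = lam[t], ovdp = 0.155), log = TRUE),
    numeric(1)))
  expect_equal(subject_loglik(y, fe, c(0.2, -0.1), spn), byhand)
})

test_that("zero Markov coefficients reduce MAK2 to the base family", {
  spn <- model_ladder("NB_nested MAK2")
  spb <- model_spec("NB", random_effects = "lam0")
  y <- c(3L, 0L, 1L, 4L, 2L)
  fe0 <- c(lam0 = 0.9, ovdp = 0.2, th_pdv = 0, th_ppdv = 0)
  expect_equal(subject_loglik(y, fe0, c(0.3, 0), spn),
               subject_loglik(y, c(lam0 = 0.9, ovdp = 0.2), 0.3, spb))
})

test_that("equal steroid coefficient makes the steroid model collapse", {
  sps <- model_ladder("NB_nested MAK2 steroids")
  spn <- model_ladder("NB_nested MAK2")
  y <- c(1L, 4L, 0L, 2L, 6L, 0L)
  s <- c(0L, 1L, 0L, 0L, 1L, 0L)
  fe <- c(lam0 = 0.9, ovdp = 0.15, th_pdv = 0.4, th_pdv_s = 0.4,
          th_ppdv = 0.14)
  expect_equal(subject_loglik(y, fe, c(0.1, 0.2), sps, steroid = s),
               subject_loglik(y, fe[names(fe) != "th_pdv_s"],
                              c(0.1, 0.2), spn, steroid = s))
})

test_that("inconsistent specifications are rejected", {
  expect_error(model_spec("NB", steroid_target = "delta"))
  expect_error(model_spec("PS", steroid_target = "ovdp"), "not a parameter")
  expect_error(model_spec("PS", random_effects = c("lam0", "th_pdv")),
               "parameters of the model")
  expect_error(model_spec("NB", markov = "MAK1"), "Poisson")
  expect_error(model_spec("PMIX", markov = "MAK2"), "Markov")
  expect_error(model_spec("PS", random_effects = c("lam0", "lam2", "ovdp")),
               "at most two")
})
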