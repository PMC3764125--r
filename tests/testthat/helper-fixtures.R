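## Small fixtures shared across test files; everything is built in code.

toy_dataset <- function() {
  as_cel_dataset(data.frame(
    ID = rep(c("a", "b"), each = 4),
    MONTH = rep(1:4, 2),
    DV = c(0, 2, 5, 0, 1, 0, 0, 3),
    STEROID = c(0, 1, 0, 0, 0, 0, 1, 0)))
}

## deterministic parameter sets covering every family, for property loops
family_grid <- function() {
  list(
    count_params("PS", lam = 0.744),
    count_params("PS", lam = 4.2),
    count_params("ZIP", lam = 2.4, p0 = 0.0375),
    count_params("ZIP", lam = 1.1, p0 = 0.4),
    count_params("GP", lam = 1.53, delta = 0.393),
    count_params("GP", lam = 4, delta = -0.2),
    count_params("NB", lam = 2.32, ovdp = 0.254),
    count_params("NB", lam = 0.9, ovdp = 1.5),
    count_params("ZINB", lam = 2.32, ovdp = 0.254, p0 = 0.15),
    count_params("PMIX", lam = 2.72, lam2 = 0.4, pm = 0.413))
}

## pmf summed to a negligible tail: support cap chosen adaptively
pmf_total <- function(params, tol = 1e-10) {
  n_max <- 50
  repeat {
    p <- dcount(0:n_max, params)
    if (p[n_max + 1] < tol || n_max > 20000) break
    n_max <- n_max * 2
  }
  list(total = sum(p), support = 0:n_max, pmf = p)
}
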