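# convenience: dataset with a single elastic datum d and a dummy curve,
# paired with parameters whose elastic prediction is exactly F = 100
single_elastic_data <- function(d) {
  fascicle_dataset("one", d, NA_real_, c(0, 1), c(1, 0.99))
}
F100 <- c(100, 42, 100, 0.4, 0.05)  # E_f = E_m = 100 -> q1 = 100 for any f_r
cls_any <- fascicle_class(0.5, 72)

test_that("proportional-error Gaussian log likelihood matches closed form", {
  # datum on the prediction: only the normal constant, sd = sigma_n F = 5
  ll0 <- log_likelihood(F100, single_elastic_data(100), cls_any,
                        observables = "elastic")
  expect_equal(ll0, -log(sqrt(2 * pi) * 5))
  expect_equal(ll0, -2.5286, tolerance = 1e-4)
  # datum 2 proportional sd away: drop of z^2/2 = 2
  ll2 <- log_likelihood(F100, single_elastic_data(110), cls_any,
                        observables = "elastic")
  expect_equal(ll2, ll0 - 2)
  # scale equivariance: doubling d and F changes only the -log F term
  F200 <- c(200, 42, 200, 0.4, 0.05)
  ll_dbl <- log_likelihood(F200, single_elastic_data(220), cls_any,
                           observables = "elastic")
  expect_equal(ll_dbl, ll2 - log(2))
})

test_that("dataset log likelihood factorizes over its individual data", {
  truth <- ref_truth()
  cls <- ref_class()
  d <- generate_dataset(generator_spec(truth, cls, n_time_points = 8,
                                       seed = 31), "fact")
  th <- c(1300, 40, 0.5, 0.45, 0.06)
  total <- log_likelihood(th, d, cls)
  # independent oracle: per-datum normal densities summed by hand
  q1 <- elastic_modulus(th, cls)
  q2 <- poisson_ratio(th, cls)
  q3 <- normalized_relaxation(th, cls, d$times)
  sig <- th[5]
  by_hand <- sum(dnorm(d$elastic_moduli, q1, sig * q1, log = TRUE)) +
    dnorm(d$poisson_value, q2, sig * q2, log = TRUE) +
    sum(dnorm(d$Ebar, q3, sig * q3, log = TRUE))
  expect_equal(total, by_hand)
  # block subsets add up
  blocks <- vapply(c("elastic", "poisson", "relaxation"), function(b)
    log_likelihood(th, d, cls, observables = b), 0)
  expect_equal(sum(blocks), total)
})

test_that("non-positive forward predictions give -Inf with a warning", {
  g_neg <- function(cls) -1
  expect_warning(
    ll <- log_likelihood(F100, single_elastic_data(100), cls_any,
                         observables = "elastic", g = g_neg),
    "non-positive")
  expect_identical(ll, -Inf)
})

test_that("log posterior is prior plus likelihood and -Inf outside the box", {
  sp <- prior_spec()
  truth <- ref_truth()
  cls <- ref_class()
  d <- generate_dataset(generator_spec(truth, cls, seed = 32), "post")
  th <- c(1400, 42, 0.4, 0.4, 0.05)
  expect_equal(log_posterior(th, d, cls, sp),
               log_prior(th, sp) + log_likelihood(th, d, cls))
  expect_identical(log_posterior(c(499, 42, 0.4, 0.4, 0.05), d, cls, sp), -Inf)
  expect_identical(log_posterior(c(1400, 42, 0.4, 0.99, 0.05), d, cls, sp), -Inf)
})

test_that("noise-free truth maximizes the posterior over a coarse grid", {
  truth <- ref_truth(error_scale = 0.001)  # sigma at its prior lower bound
  cls <- ref_class()
  d <- generate_dataset(generator_spec(truth, cls, noise = 0, seed = 33), "nf")
  sp <- prior_spec()
  lp_truth <- log_posterior(pack_truth <- c(1400, 42, 0.4, 0.4, 0.001),
                            d, cls, sp)
  grid <- expand.grid(E_f = c(700, 1100, 1500, 2300),
                      eta_f = c(1, 30, 60, 1000),
                      E_m = c(0.05, 0.5, 2, 4.5),
                      r_inf = c(0.1, 0.4, 0.7, 0.9),
                      sigma_n = c(0.001, 0.05, 0.2))
  lp_grid <- log_posterior(as.matrix(grid), d, cls, sp)
  expect_true(all(lp_grid <= lp_truth))
})

test_that("profile posterior over the fiber modulus matches the 1-D oracle", {
  # elastic-only observables, sigma profiled out analytically:
  # the maximizing E_f equals mean(moduli) / (f_r g) up to the matrix term
  cls <- fascicle_class(0.35, 70)
  d <- fascicle_dataset("prof", c(640, 480, 550), NA_real_, c(0, 1), c(1, 0.99))
  Em_fix <- 0.01
  prof <- function(Ef) {
    FF <- 0.35 * Ef + 0.65 * Em_fix
    z2 <- mean(((d$elastic_moduli - FF) / FF)^2)
    -1.5 * log(z2) - 3 * log(FF)  # n = 3; constants dropped
  }
  opt <- optimize(prof, c(500, 2500), maximum = TRUE)
  expected <- (mean(d$elastic_moduli) - 0.65 * Em_fix) / 0.35
  expect_equal(opt$maximum, expected, tolerance = 1e-4)
  expect_equal(opt$maximum, mean(d$elastic_moduli) / 0.35, tolerance = 1e-4)
  # and the package likelihood agrees with the profile shape: at the fixed
  # profiled sigma, the package's E_f conditional optimum is the same
  sig_hat <- sqrt(mean(((d$elastic_moduli - 0.35 * expected - 0.65 * Em_fix) /
                          (0.35 * expected + 0.65 * Em_fix))^2))
  pkg_prof <- function(Ef)
    log_likelihood(c(Ef, 42, Em_fix, 0.4, sig_hat), d, cls,
                   observables = "elastic")
  opt2 <- optimize(pkg_prof, c(500, 2500), maximum = TRUE)
  expect_equal(opt2$maximum, expected, tolerance = 1e-3)
})
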