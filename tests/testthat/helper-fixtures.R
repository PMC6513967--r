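# Shared test fixtures: the reference ground truth used across recovery and
# sampler tests, and a fast sampler control for unit tests.

ref_truth <- function(error_scale = 0.05)
  material_params(1400, 42, 0.4, retained_fraction = 0.4,
                  error_scale = error_scale, viscosity_unit = "GPa.s")

ref_class <- function() fascicle_class(0.35, 75)

quick_control <- function(seed, n = 500)
  tmcmc_control(samples_per_stage = n, seed = seed)

# uniform box toy target in 1-D: prior U(0, 10), likelihood N(5, 1)
toy_prior_sampler <- function(n) matrix(stats::runif(n, 0, 10), n, 1)
toy_log_prior <- function(th) ifelse(th[, 1] >= 0 & th[, 1] <= 10, -log(10), -Inf)
toy_log_lik <- function(th) stats::dnorm(th[, 1], 5, 1, log = TRUE)
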