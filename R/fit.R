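# The modelling front-end: one Bayesian fit of the material parameters to
# one dataset under one fascicle model class.

#' Fit fiber-scale material parameters to a fascicle dataset
#'
#' Runs TMCMC on the unnormalized posterior of
#' \eqn{(E_f, \eta_f, E_m, r_\infty, \sigma_n)} for one fascicle model class
#' and one observation dataset: uniform priors ([prior_spec()]),
#' proportional-error Gaussian likelihood ([log_likelihood()]) through the
#' forward model, posterior samples and evidence by [run_tmcmc()], and a
#' refined MAP estimate.
#'
#' @param data a [fascicle_dataset()].
#' @param cls a [fascicle_class()].
#' @param priors a [prior_spec()].
#' @param control a [tmcmc_control()]; its `seed` governs the whole fit.
#' @param observables observable blocks entering the likelihood, a subset of
#'   `c("elastic", "poisson", "relaxation")`.
#' @param refine polish the MAP by bounded local search (default `TRUE`).
#' @param g elastic surrogate angle factor (default rule of mixtures).
#' @param kappa,nu_matrix Poisson surrogate constants.
#' @return An object of class `"fascicle_fit"` with components `map` (named
#'   parameter vector in reporting units: MPa, GPa s), `intervals` (95%
#'   central credible intervals), `log_evidence`, `stage_record`,
#'   `ensemble`, plus the inputs.  Methods: `print`, `summary`, `coef`,
#'   `predict`, `plot`, `simulate`, `residuals`, `logLik`.
#' @examples
#' \donttest{
#' truth <- material_params(1400, 42, 0.4, retained_fraction = 0.4,
#'                          viscosity_unit = "GPa.s")
#' cls <- fascicle_class(0.35, 75)
#' d <- generate_dataset(generator_spec(truth, cls, seed = 1))
#' fit <- fit_fascicle(d, cls, control = tmcmc_control(500, seed = 1))
#' coef(fit)
#' }
#' @export
fit_fascicle <- function(data, cls, priors = prior_spec(),
                         control = tmcmc_control(),
                         observables = c("elastic", "poisson", "relaxation"),
                         refine = TRUE, g = g_unity,
                         kappa = DEFAULT_KAPPA, nu_matrix = DEFAULT_NU_M) {
  stopifnot(inherits(data, "fascicle_dataset"), inherits(cls, "fascicle_class"))
  observables <- match.arg(observables, OBSERVABLE_BLOCKS, several.ok = TRUE)
  if ("poisson" %in% observables && is.na(data$poisson_value))
    observables <- setdiff(observables, "poisson")

  lp_fn <- function(theta) log_prior_mat(theta, priors)
  ll_fn <- function(theta) log_lik_mat(theta, data, cls,
                                       observables = observables, g = g,
                                       kappa = kappa, nu_m = nu_matrix)
  sampler <- function(n) prior_sample(priors, n)

  ens <- run_tmcmc(lp_fn, ll_fn, sampler, control)
  b <- priors$bounds
  map <- map_estimate(ens, refine = refine, lower = b[, 1L], upper = b[, 2L])
  ints <- apply(ens$samples, 2L, stats::quantile, probs = c(0.025, 0.975))
  structure(list(map = map$par, map_log_posterior = map$log_posterior,
                 intervals = ints, log_evidence = ens$log_evidence,
                 stage_record = ens$stage_record, ensemble = ens,
                 data = data, class = cls, priors = priors,
                 control = control, observables = observables,
                 g = g, kappa = kappa, nu_matrix = nu_matrix,
                 call = match.call()),
            class = "fascicle_fit")
}

#' @export
print.fascicle_fit <- function(x, ...) {
  cat(sprintf("Fascicle material fit: dataset %s, f_r = %g, theta = %g deg\n",
              x$data$dataset_id, x$class$fiber_content, x$class$helix_angle))
  cat(sprintf("  observables: %s\n", paste(x$observables, collapse = " + ")))
  cat("  MAP (E_f MPa, eta_f GPa s, E_m MPa, r_inf, sigma_n):\n")
  print(signif(x$map, 4))
  cat(sprintf("  log evidence: %.3f over %d stages\n", x$log_evidence,
              nrow(x$stage_record)))
  invisible(x)
}

#' @export
summary.fascicle_fit <- function(object, ...) {
  tab <- data.frame(map = object$map,
                    lower_95 = object$intervals[1L, ],
                    upper_95 = object$intervals[2L, ],
                    prior_lower = object$priors$bounds[, 1L],
                    prior_upper = object$priors$bounds[, 2L])
  structure(list(table = tab, log_evidence = object$log_evidence,
                 stage_record = object$stage_record,
                 dataset_id = object$data$dataset_id, class = object$class,
                 observables = object$observables),
            class = "summary.fascicle_fit")
}

#' @export
print.summary.fascicle_fit <- function(x, ...) {
  cat(sprintf("Fascicle fit summary: dataset %s, f_r = %g, theta = %g deg (%s)\n",
              x$dataset_id, x$class$fiber_content, x$class$helix_angle,
              paste(x$observables, collapse = " + ")))
  print(signif(as.matrix(x$table), 4))
  cat(sprintf("log evidence %.3f; %d tempering stages (final acceptance %.2f)\n",
              x$log_evidence, nrow(x$stage_record),
              x$stage_record$acceptance_rate[nrow(x$stage_record)]))
  invisible(x)
}

#' @export
coef.fascicle_fit <- function(object, ...) object$map

#' @export
logLik.fascicle_fit <- function(object, ...) {
  ll <- max(object$ensemble$log_likelihood)
  n <- length(object$data$elastic_moduli) * ("elastic" %in% object$observables) +
    ("poisson" %in% object$observables) +
    length(object$data$times) * ("relaxation" %in% object$observables)
  structure(ll, df = 5L, nobs = n, class = "logLik")
}

#' Predict fascicle observables from a fit
#'
#' Forward-model prediction at the MAP (default) or at supplied parameters,
#' at the dataset's times or at new times.
#'
#' @param object a [fit_fascicle()] result.
#' @param times evaluation times in seconds (default: the dataset's).
#' @param params parameter vector or [material_params()] (default: MAP).
#' @param ... unused.
#' @return An `"observable_prediction"` (see [predict_observables()]).
#' @export
predict.fascicle_fit <- function(object, times = NULL, params = NULL, ...) {
  if (is.null(times)) times <- object$data$times
  if (is.null(params)) params <- object$map
  predict_observables(params, object$class, times, g = object$g,
                      kappa = object$kappa, nu_matrix = object$nu_matrix)
}

#' Residuals of a fascicle fit
#'
#' Relative residuals `(observed - predicted) / predicted` per observable
#' block at the MAP -- the natural scale for a proportional error model.
#'
#' @param object a [fit_fascicle()] result.
#' @param ... unused.
#' @return Named list with elements `elastic`, `poisson`, `relaxation`
#'   (those present in the fit).
#' @export
residuals.fascicle_fit <- function(object, ...) {
  pred <- predict(object)
  out <- list()
  if ("elastic" %in% object$observables)
    out$elastic <- (object$data$elastic_moduli - pred$elastic_modulus) /
      pred$elastic_modulus
  if ("poisson" %in% object$observables)
    out$poisson <- (object$data$poisson_value - pred$poisson_ratio) /
      pred$poisson_ratio
  if ("relaxation" %in% object$observables)
    out$relaxation <- (object$data$Ebar - pred$curve$Ebar) / pred$curve$Ebar
  out
}

#' Simulate datasets from a fitted model
#'
#' Draws synthetic datasets from the generator at the fitted MAP parameters
#' (including the fitted noise scale \eqn{\sigma_n}), mirroring the dataset
#' the model was fitted to.
#'
#' @param object a [fit_fascicle()] result.
#' @param nsim number of datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return List of [fascicle_dataset()] objects.
#' @export
simulate.fascicle_fit <- function(object, nsim = 1, seed = NULL, ...) {
  truth <- unpack_params(object$map)
  horizon <- max(object$data$times)
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nsim)
  lapply(seq_len(nsim), function(i) {
    gs <- generator_spec(truth, object$class,
                         n_elastic_replicates = length(object$data$elastic_moduli),
                         n_time_points = length(object$data$times),
                         time_horizon = horizon,
                         noise = object$map[["sigma_n"]], seed = seeds[i])
    generate_dataset(gs, dataset_id = sprintf("%s_sim%d", object$data$dataset_id, i))
  })
}

#' Plot a fascicle fit
#'
#' Posterior marginal histograms for the five parameters (MAP marked) and
#' the replayed relaxation curve against the observed points.
#'
#' @param x a [fit_fascicle()] result.
#' @param ... passed to `hist`.
#' @export
plot.fascicle_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  labs <- c("E_f [MPa]", "eta_f [GPa s]", "E_m [MPa]", "r_inf", "sigma_n")
  for (j in seq_along(PARAM_NAMES)) {
    graphics::hist(x$ensemble$samples[, j], breaks = 30, main = labs[j],
                   xlab = labs[j], col = "grey85", border = "grey40", ...)
    graphics::abline(v = x$map[j], col = "red3", lwd = 2)
  }
  pred <- predict(x)
  graphics::plot(x$data$times, x$data$Ebar, pch = 16, cex = 0.7,
                 xlab = "time [s]", ylab = "normalized modulus",
                 main = "relaxation replay")
  graphics::lines(pred$curve$time_s, pred$curve$Ebar, col = "red3", lwd = 2)
  invisible(x)
}
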