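# Proportional-error Gaussian likelihood over the heterogeneous observables
# of one dataset, and the unnormalized log-posterior.

OBSERVABLE_BLOCKS <- c("elastic", "poisson", "relaxation")

# vectorised likelihood over rows of theta (n x 5, reporting units);
# rows with invalid physical parameters get -Inf
log_lik_mat <- function(theta, data, cls,
                        observables = OBSERVABLE_BLOCKS,
                        g = g_unity, kappa = DEFAULT_KAPPA,
                        nu_m = DEFAULT_NU_M) {
  observables <- match.arg(observables, OBSERVABLE_BLOCKS, several.ok = TRUE)
  n <- nrow(theta)
  valid <- theta[, 1L] > 0 & theta[, 2L] > 0 & theta[, 3L] > 0 &
    theta[, 4L] > 0 & theta[, 4L] <= 1 & theta[, 5L] > 0
  ll <- rep(-Inf, n)
  if (!any(valid)) return(ll)
  th <- theta[valid, , drop = FALSE]
  sig <- th[, 5L]
  out <- numeric(nrow(th))

  if ("elastic" %in% observables) {
    q1 <- fwd_elastic(th, cls, g = g)
    bad <- q1 <= 0
    for (d in data$elastic_moduli)
      out <- out + stats::dnorm(d, mean = q1, sd = sig * q1, log = TRUE)
    out[bad] <- -Inf
  }
  if ("poisson" %in% observables) {
    if (is.na(data$poisson_value))
      stop("dataset ", data$dataset_id, " has no Poisson value; drop the ",
           "'poisson' observable block", call. = FALSE)
    q2 <- fwd_poisson(th, cls, kappa = kappa, nu_m = nu_m)
    out <- out + ifelse(q2 > 0,
                        stats::dnorm(data$poisson_value, mean = q2,
                                     sd = sig * q2, log = TRUE),
                        -Inf)
  }
  if ("relaxation" %in% observables) {
    q3 <- fwd_normalized(th, cls, data$times)
    obs <- matrix(data$Ebar, nrow = nrow(th), ncol = length(data$Ebar),
                  byrow = TRUE)
    block <- stats::dnorm(obs, mean = q3, sd = sig * q3, log = TRUE)
    rs <- rowSums(block)
    rs[apply(q3 <= 0, 1L, any)] <- -Inf
    out <- out + rs
  }
  out[is.nan(out)] <- -Inf
  ll[valid] <- out
  ll
}

#' Log likelihood of a fascicle dataset
#'
#' Independent Gaussians with a proportional error model: each datum
#' \eqn{D_i} has mean \eqn{F_i} (the forward prediction) and standard
#' deviation \eqn{\sigma_n F_i}, i.e. variance \eqn{\sigma_n^2 F_i^2}.  The
#' log density is summed over the enabled observable blocks -- the replicate
#' elastic moduli (each compared with \eqn{q_1}), the Poisson value (against
#' \eqn{q_2}) and the relaxation points (against \eqn{q_3} at the dataset's
#' times) -- with a single shared \eqn{\sigma_n}, each datum weighted
#' equally.
#'
#' @param params a [material_params()] or a length-5 parameter vector in
#'   reporting units (or a matrix of such rows).
#' @param data a [fascicle_dataset()].
#' @param cls a [fascicle_class()].
#' @param observables subset of `c("elastic", "poisson", "relaxation")`.
#' @param g elastic surrogate angle factor (default rule of mixtures).
#' @param kappa,nu_matrix Poisson surrogate constants.
#' @return Log likelihood; `-Inf` (with a warning) when a forward prediction
#'   is non-positive, where the proportional error model is undefined.
#' @export
log_likelihood <- function(params, data, cls,
                           observables = OBSERVABLE_BLOCKS,
                           g = g_unity, kappa = DEFAULT_KAPPA,
                           nu_matrix = DEFAULT_NU_M) {
  theta <- as_theta_matrix(params)
  ll <- log_lik_mat(theta, data, cls, observables = observables, g = g,
                    kappa = kappa, nu_m = nu_matrix)
  if (nrow(theta) == 1L && !is.finite(ll))
    warning("non-positive or invalid forward prediction: ",
            "proportional-error likelihood undefined, returning -Inf",
            call. = FALSE)
  if (nrow(theta) == 1L) as.numeric(ll) else ll
}

#' Unnormalized log posterior
#'
#' `log_prior(params) + log_likelihood(params, ...)`; the evidence
#' (normalizing constant) is estimated separately by the TMCMC sampler.
#'
#' @inheritParams log_likelihood
#' @param spec a [prior_spec()].
#' @return Unnormalized log posterior density.
#' @export
log_posterior <- function(params, data, cls, spec = prior_spec(),
                          observables = OBSERVABLE_BLOCKS,
                          g = g_unity, kappa = DEFAULT_KAPPA,
                          nu_matrix = DEFAULT_NU_M) {
  theta <- as_theta_matrix(params)
  lp <- log_prior_mat(theta, spec)
  out <- lp
  fin <- is.finite(lp)
  if (any(fin))
    out[fin] <- lp[fin] + log_lik_mat(theta[fin, , drop = FALSE], data, cls,
                                      observables = observables, g = g,
                                      kappa = kappa, nu_m = nu_matrix)
  if (nrow(theta) == 1L) as.numeric(out) else out
}
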