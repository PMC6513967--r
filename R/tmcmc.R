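# Transitional Markov Chain Monte Carlo: tempered sequence from prior to
# posterior with weight-COV-controlled exponents, multinomial resampling, a
# Metropolis-Hastings move kernel scaled by the weighted sample covariance,
# an evidence estimate from the stage weight means, and MAP extraction.

#' TMCMC sampler settings
#'
#' @param samples_per_stage ensemble size per tempering stage (>= 100).
#' @param target_weight_cov target coefficient of variation of the
#'   plausibility weights controlling the tempering step size.
#' @param proposal_scale scaling \eqn{\beta} of the Gaussian proposal: the
#'   proposal covariance is \eqn{\beta^2} times the weighted sample
#'   covariance.
#' @param max_stages failsafe bound on the number of tempering stages.
#' @param mh_steps Metropolis-Hastings steps applied to each sample after
#'   resampling.  A handful of steps is needed for the resampled ensemble to
#'   equilibrate at each tempering level; a single step leaves the final
#'   ensemble contaminated by the prior.
#' @param seed integer seed making the run fully reproducible.
#' @return An object of class `"tmcmc_control"`.
#' @export
tmcmc_control <- function(samples_per_stage = 1000, target_weight_cov = 1.0,
                          proposal_scale = 0.2, max_stages = 50,
                          mh_steps = 5, seed = NULL) {
  if (samples_per_stage < 100) stop("samples_per_stage must be >= 100",
                                    call. = FALSE)
  if (proposal_scale <= 0 || proposal_scale > 1)
    stop("proposal_scale must lie in (0, 1]", call. = FALSE)
  if (max_stages < 1) stop("max_stages must be >= 1", call. = FALSE)
  if (target_weight_cov <= 0) stop("target_weight_cov must be positive",
                                   call. = FALSE)
  if (mh_steps < 1) stop("mh_steps must be >= 1", call. = FALSE)
  structure(list(samples_per_stage = as.integer(samples_per_stage),
                 target_weight_cov = target_weight_cov,
                 proposal_scale = proposal_scale,
                 max_stages = as.integer(max_stages),
                 mh_steps = as.integer(mh_steps),
                 seed = seed),
            class = "tmcmc_control")
}

weight_cov <- function(dp, logL) {
  a <- dp * logL
  m <- max(a[is.finite(a)])
  w <- exp(a - m)
  w[!is.finite(w)] <- 0
  mw <- mean(w)
  if (mw == 0) return(Inf)
  stats::sd(w) / mw
}

#' Next tempering exponent
#'
#' Finds the largest exponent \eqn{p' \in (p, 1]} such that the coefficient
#' of variation of the plausibility weights
#' \eqn{w_i = \exp((p' - p)\,\log L_i)} does not exceed `target_cov`, by
#' bisection to an absolute tolerance of `1e-10`; returns exactly 1 when a
#' full step keeps the COV within target.
#'
#' @param current_p current exponent in \[0, 1).
#' @param log_likelihoods log-likelihood values of the current ensemble.
#' @param target_cov target weight coefficient of variation.
#' @return The next exponent, in `(current_p, 1]`.
#' @export
next_exponent <- function(current_p, log_likelihoods, target_cov = 1.0) {
  if (length(log_likelihoods) == 0L)
    stop("log_likelihoods must be non-empty", call. = FALSE)
  if (current_p < 0 || current_p >= 1)
    stop("current_p must lie in [0, 1)", call. = FALSE)
  if (!any(is.finite(log_likelihoods)))
    stop("all log-likelihoods are -Inf; posterior has no support in the ensemble",
         call. = FALSE)
  hi <- 1 - current_p
  if (weight_cov(hi, log_likelihoods) <= target_cov) return(1)
  lo <- 0
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (weight_cov(mid, log_likelihoods) <= target_cov) lo <- mid else hi <- mid
  }
  current_p + lo
}

#' Run the TMCMC sampler
#'
#' Starts from prior draws and anneals to the posterior: at each stage the
#' next tempering exponent is chosen by [next_exponent()], plausibility
#' weights are computed and their stage mean recorded (the log evidence is
#' the sum of the log stage-mean weights), the ensemble is
#' multinomially resampled by normalized weight, and each sample is moved by
#' Metropolis-Hastings with a Gaussian proposal whose covariance is
#' `proposal_scale^2` times the weighted sample covariance (regularized by a
#' `1e-10` diagonal jitter).  Proposals falling outside the prior support
#' (log prior `-Inf`) are rejected.  The run is fully reproducible under a
#' fixed `seed`.
#'
#' All three functions are vectorised over ensembles: `log_prior_fn` and
#' `log_likelihood_fn` take an `n x d` parameter matrix and return a
#' length-`n` vector; `prior_sampler(n)` returns an `n x d` matrix.
#'
#' @param log_prior_fn vectorised log prior density.
#' @param log_likelihood_fn vectorised log likelihood.
#' @param prior_sampler function of `n` returning prior draws.
#' @param control a [tmcmc_control()].
#' @return An object of class `"tmcmc_ensemble"`: final equally-weighted
#'   posterior `samples` with their `log_prior` and `log_likelihood`,
#'   a `stage_record` data frame (exponent, weight COV, acceptance rate,
#'   effective sample size per stage), the `log_evidence` estimate, and the
#'   `map` sample with its log posterior.
#' @export
run_tmcmc <- function(log_prior_fn, log_likelihood_fn, prior_sampler,
                      control = tmcmc_control()) {
  if (!is.null(control$seed)) set.seed(control$seed)
  N <- control$samples_per_stage
  theta <- prior_sampler(N)
  if (!is.matrix(theta)) theta <- matrix(theta, nrow = N)
  d <- ncol(theta)
  lp <- log_prior_fn(theta)
  ll <- log_likelihood_fn(theta)
  if (!any(is.finite(ll)))
    stop("all prior samples have zero likelihood; check the model", call. = FALSE)

  p <- 0
  log_evidence <- 0
  rec <- list()
  stage <- 0L
  repeat {
    stage <- stage + 1L
    if (stage > control$max_stages) {
      cond <- simpleError(paste0("TMCMC did not reach exponent 1 within ",
                                 control$max_stages, " stages; last exponent ",
                                 format(p)))
      cond$stage_record <- do.call(rbind, rec)
      stop(cond)
    }
    p_new <- next_exponent(p, ll, control$target_weight_cov)
    dp <- p_new - p
    a <- dp * ll
    m <- max(a[is.finite(a)])
    w <- exp(a - m)
    w[!is.finite(w)] <- 0
    if (all(w == 0))
      stop("all plausibility weights are zero at stage ", stage, call. = FALSE)
    log_evidence <- log_evidence + m + log(mean(w))
    wn <- w / sum(w)
    cov_w <- stats::sd(w) / mean(w)
    ess <- 1 / sum(wn^2)

    # proposal covariance from the weighted ensemble, jittered for degeneracy
    C <- stats::cov.wt(theta, wt = wn, method = "ML")$cov
    C <- control$proposal_scale^2 * C + diag(1e-10, d)
    R <- tryCatch(chol(C), error = function(e) chol(C + diag(1e-6, d)))

    idx <- sample.int(N, N, replace = TRUE, prob = wn)
    theta <- theta[idx, , drop = FALSE]
    lp <- lp[idx]; ll <- ll[idx]

    n_acc <- 0L
    for (s in seq_len(control$mh_steps)) {
      prop <- theta + matrix(stats::rnorm(N * d), N, d) %*% R
      lp_p <- log_prior_fn(prop)
      ll_p <- rep(-Inf, N)
      fin <- is.finite(lp_p)
      if (any(fin))
        ll_p[fin] <- log_likelihood_fn(prop[fin, , drop = FALSE])
      log_r <- (lp_p + p_new * ll_p) - (lp + p_new * ll)
      acc <- is.finite(log_r) & log(stats::runif(N)) < log_r
      theta[acc, ] <- prop[acc, ]
      lp[acc] <- lp_p[acc]; ll[acc] <- ll_p[acc]
      n_acc <- n_acc + sum(acc)
    }
    acc_rate <- n_acc / (N * control$mh_steps)
    if (acc_rate < 0.05 || acc_rate > 0.95)
      message(sprintf("tmcmc: stage %d acceptance rate %.3f outside [0.05, 0.95]",
                      stage, acc_rate))
    rec[[stage]] <- data.frame(stage = stage, exponent = p_new,
                               weight_cov = cov_w, acceptance_rate = acc_rate,
                               ess = ess)
    p <- p_new
    if (p >= 1) break
  }

  lpost <- lp + ll
  map_i <- which.max(lpost)
  structure(list(samples = theta, log_prior = lp, log_likelihood = ll,
                 stage_record = do.call(rbind, rec),
                 log_evidence = log_evidence,
                 map = theta[map_i, ], map_log_posterior = lpost[map_i],
                 control = control,
                 log_prior_fn = log_prior_fn,
                 log_likelihood_fn = log_likelihood_fn),
            class = "tmcmc_ensemble")
}

#' @export
print.tmcmc_ensemble <- function(x, ...) {
  cat(sprintf("TMCMC ensemble: %d samples, %d stages, log evidence %.4f\n",
              nrow(x$samples), nrow(x$stage_record), x$log_evidence))
  cat("MAP sample (log posterior ", format(x$map_log_posterior), "):\n", sep = "")
  print(x$map)
  invisible(x)
}

#' Maximum a-posteriori estimate from a TMCMC ensemble
#'
#' The retained sample with the highest log posterior; with `refine = TRUE`
#' it is polished by a bounded derivative-free local search (Nelder-Mead on
#' the log posterior, with a steep finite penalty outside the given box so
#' the search never leaves the prior support; Brent in one dimension).  The
#' refined point is
#' returned only if it does not decrease the log posterior.
#'
#' @param ensemble a [run_tmcmc()] result.
#' @param refine polish the best sample by local search?
#' @param lower,upper box bounds for the refinement (required if
#'   `refine = TRUE`).
#' @return List with `par` (the MAP parameter vector) and `log_posterior`.
#' @export
map_estimate <- function(ensemble, refine = FALSE, lower = NULL, upper = NULL) {
  stopifnot(inherits(ensemble, "tmcmc_ensemble"))
  par <- ensemble$map
  lpost <- ensemble$map_log_posterior
  if (refine) {
    if (is.null(lower) || is.null(upper))
      stop("refinement needs box bounds 'lower' and 'upper'", call. = FALSE)
    target <- function(th) {
      m <- matrix(th, nrow = 1L)
      as.numeric(ensemble$log_prior_fn(m) + ensemble$log_likelihood_fn(m))
    }
    obj <- function(th) {
      excess <- sum(pmax(lower - th, 0) + pmax(th - upper, 0))
      if (excess > 0) return(-1e15 * (1 + excess))
      v <- target(th)
      if (!is.finite(v)) -1e15 else v
    }
    opt <- if (length(par) == 1L)
      stats::optim(par, obj, method = "Brent", lower = lower, upper = upper,
                   control = list(fnscale = -1))
    else
      stats::optim(par, obj, method = "Nelder-Mead",
                   control = list(fnscale = -1, maxit = 2000,
                                  reltol = 1e-12))
    if (is.finite(opt$value) && opt$value >= lpost &&
        all(opt$par >= lower) && all(opt$par <= upper)) {
      par <- stats::setNames(opt$par, names(ensemble$map))
      lpost <- opt$value
    }
  }
  list(par = par, log_posterior = lpost)
}
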