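# Uniform prior box over the five inferred parameters.

#' Uniform prior specification
#'
#' Independent uniform priors (a closed box) over the inferred parameters.
#' The default bounds for the three physical parameters encompass and exceed
#' the experimentally reported ranges, encoding prior ignorance: fiber
#' modulus 500--2500 MPa, fiber viscosity 0.1--2500 GPa s, matrix modulus
#' 0.01--5 MPa.  The retained fraction and error scale receive wide uniform
#' priors of this package's choosing.
#'
#' @param fiber_modulus bounds for \eqn{E_f} in MPa.
#' @param fiber_viscosity bounds for \eqn{\eta_f} in GPa s.
#' @param matrix_modulus bounds for \eqn{E_m} in MPa.
#' @param retained_fraction bounds for \eqn{r_\infty}.
#' @param error_scale bounds for \eqn{\sigma_n}.
#' @return An object of class `"prior_spec"` with a 5 x 2 `bounds` matrix
#'   (rows in the order E_f, eta_f, E_m, r_inf, sigma_n; reporting units).
#' @export
prior_spec <- function(fiber_modulus = c(500, 2500),
                       fiber_viscosity = c(0.1, 2500),
                       matrix_modulus = c(0.01, 5),
                       retained_fraction = c(0.05, 0.95),
                       error_scale = c(0.001, 0.3)) {
  b <- rbind(E_f = fiber_modulus, eta_f = fiber_viscosity,
             E_m = matrix_modulus, r_inf = retained_fraction,
             sigma_n = error_scale)
  colnames(b) <- c("lower", "upper")
  if (any(!is.finite(b)) || any(b[, 1L] >= b[, 2L]))
    stop("each prior bound pair must satisfy lower < upper", call. = FALSE)
  structure(list(bounds = b), class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("Uniform prior box (reporting units: MPa, GPa s, -, -, -):\n")
  print(x$bounds)
  invisible(x)
}

# rows of theta inside the closed box -> TRUE
in_prior_box <- function(theta, spec) {
  b <- spec$bounds
  ok <- rep(TRUE, nrow(theta))
  for (j in seq_len(ncol(theta)))
    ok <- ok & theta[, j] >= b[j, 1L] & theta[, j] <= b[j, 2L]
  unname(ok)
}

log_prior_mat <- function(theta, spec) {
  const <- -sum(log(spec$bounds[, 2L] - spec$bounds[, 1L]))
  ifelse(in_prior_box(theta, spec), const, -Inf)
}

#' Log prior density
#'
#' The uniform box density: \eqn{-\sum_j \log(u_j - l_j)} inside the closed
#' box, \eqn{-\infty} outside (boundary included).
#'
#' @param params a [material_params()], a length-5 parameter vector in
#'   reporting units, or an n x 5 matrix of such rows.
#' @param spec a [prior_spec()].
#' @return Log density (vector if `params` is a matrix).
#' @export
log_prior <- function(params, spec = prior_spec()) {
  log_prior_mat(as_theta_matrix(params), spec)
}

#' Sample the prior
#'
#' Independent uniform draws inside the prior box.
#'
#' @param spec a [prior_spec()].
#' @param n number of draws.
#' @param seed optional integer seed for reproducibility.
#' @return An `n` x 5 matrix in reporting units with columns
#'   `E_f, eta_f, E_m, r_inf, sigma_n`.
#' @export
prior_sample <- function(spec = prior_spec(), n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  b <- spec$bounds
  m <- vapply(seq_len(nrow(b)),
              function(j) stats::runif(n, b[j, 1L], b[j, 2L]),
              numeric(n))
  m <- matrix(m, nrow = n)
  colnames(m) <- rownames(b)
  m
}
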