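# Forward model: maps material parameters and a fascicle geometry class to
# the three observables -- initial elastic modulus, Poisson's ratio, and the
# normalized stress-relaxation curve.
#
# Internal workhorses operate on an n x 5 parameter matrix in reporting units
# (see PARAM_NAMES) so the sampler can evaluate whole ensembles at once.

DEFAULT_KAPPA <- 4e4   # Poisson surrogate blending constant
DEFAULT_NU_M <- 0.5    # near-incompressible matrix Poisson ratio

# g(theta): angle factor of the elastic surrogate.  The default rule of
# mixtures uses g == 1; a different surrogate can be plugged in through the
# `g` argument of the user-facing functions.
g_unity <- function(cls) 1

# E_fasc(0) = f_r E_f g(theta) + (1 - f_r) E_m, vectorised over rows of theta
fwd_elastic <- function(theta, cls, g = g_unity) {
  fr <- cls$fiber_content
  fr * theta[, 1L] * g(cls) + (1 - fr) * theta[, 3L]
}

# blended helical-constraint Poisson surrogate:
#   nu = nu_m + (nu_h - nu_m) / (1 + kappa x),  nu_h = cot^2(90 - theta),
#   x = (E_m/E_f) (1 - f_r)/f_r
fwd_poisson <- function(theta, cls, kappa = DEFAULT_KAPPA,
                        nu_m = DEFAULT_NU_M) {
  th <- cls$helix_angle
  if (th >= 90) stop("helix angle of 90 degrees gives an undefined ",
                     "rigid-fiber Poisson limit", call. = FALSE)
  nu_h <- tan(th * pi / 180)^2  # cot^2(90 - theta) = tan^2(theta)
  fr <- cls$fiber_content
  x <- (theta[, 3L] / theta[, 1L]) * (1 - fr) / fr
  nu_m + (nu_h - nu_m) / (1 + kappa * x)
}

# absolute relaxation curve, n x length(times) matrix:
#   E_fasc(t) = f_r (E_inf + E_R exp(-(E_R/eta_f) t)) + (1 - f_r) E_m
fwd_relaxation <- function(theta, cls, times) {
  fr <- cls$fiber_content
  Ef <- theta[, 1L]
  eta <- theta[, 2L] * 1000  # GPa s -> MPa s
  Em <- theta[, 3L]
  r <- theta[, 4L]
  Einf <- r * Ef
  ER <- (1 - r) * Ef
  decay <- exp(-outer(ER / eta, times))  # rate 1/tau = E_R / eta_f
  fr * (Einf + ER * decay) + (1 - fr) * Em
}

# normalized curve Ebar(t) = E(t) / E(0); E(0) equals the elastic mixture
fwd_normalized <- function(theta, cls, times) {
  E0 <- fwd_elastic(theta, cls)
  fwd_relaxation(theta, cls, times) / E0
}

#' Fascicle initial elastic modulus
#'
#' Rule-of-mixtures elastic surrogate
#' \eqn{E_{fasc}^0 = f_r E_f g(\theta) + (1 - f_r) E_m} with \eqn{g \equiv 1}
#' by default.  With the default surrogate the result is Voigt-sandwiched
#' between `min(E_f, E_m)` and `max(E_f, E_m)`.
#'
#' @param params a [material_params()] object (or a length-5 parameter
#'   vector in reporting units).
#' @param cls a [fascicle_class()].
#' @param g angle factor function of the elastic surrogate, taking the class
#'   and returning a scalar; the default returns 1 (plain rule of mixtures).
#' @return Initial fascicle elastic modulus in MPa.
#' @examples
#' p <- material_params(1400, 42, 0.4, viscosity_unit = "GPa.s")
#' elastic_modulus(p, fascicle_class(0.35, 70))  # 490.26
#' @export
elastic_modulus <- function(params, cls, g = g_unity) {
  as.numeric(fwd_elastic(as_theta_matrix(params), cls, g = g))
}

#' Fascicle Poisson's ratio surrogate
#'
#' Closed-form stand-in for the volumetric response of a helical
#' fiber-matrix composite:
#' \deqn{\nu = \nu_m + (\nu_h - \nu_m) / (1 + \kappa x),}
#' where \eqn{\nu_h = \cot^2(90^\circ - \theta)} is the rigid-fiber
#' (inextensible helix) limit, \eqn{x = (E_m/E_f)(1 - f_r)/f_r} measures the
#' matrix restraint, and \eqn{\kappa} blends the two.  The surrogate honors
#' the qualitative physics: it decreases strictly in the matrix modulus
#' (softer matrix, larger lateral contraction) and increases strictly in the
#' helix angle, and always lies strictly between \eqn{\nu_m} and
#' \eqn{\nu_h}.
#'
#' @inheritParams elastic_modulus
#' @param kappa blending constant (default `4e4`).
#' @param nu_matrix matrix Poisson ratio \eqn{\nu_m} (default 0.5,
#'   near-incompressible).
#' @return Dimensionless fascicle Poisson's ratio.
#' @examples
#' p <- material_params(1400, 42, 0.4, viscosity_unit = "GPa.s")
#' poisson_ratio(p, fascicle_class(0.35, 75))  # ~1.10
#' @export
poisson_ratio <- function(params, cls, kappa = DEFAULT_KAPPA,
                          nu_matrix = DEFAULT_NU_M) {
  as.numeric(fwd_poisson(as_theta_matrix(params), cls, kappa = kappa,
                         nu_m = nu_matrix))
}

#' Fascicle stress-relaxation modulus
#'
#' Standard-linear-solid relaxation of the embedded fibers with a
#' time-constant elastic matrix:
#' \deqn{E_{fasc}(t) = f_r (E_\infty + E_R e^{-(E_R/\eta_f) t})
#'   + (1 - f_r) E_m,}
#' with \eqn{E_\infty = r_\infty E_f} and \eqn{E_R = (1 - r_\infty) E_f}.
#' At \eqn{t = 0} this reduces exactly to [elastic_modulus()] (default
#' surrogate); it decreases strictly in time whenever \eqn{E_R, \eta_f > 0}.
#' The matrix contribution is held constant in time: its stiffness is
#' orders of magnitude below the fibers', so the fibers dominate the
#' fascicle's relaxation.
#'
#' @inheritParams elastic_modulus
#' @param times non-negative times in seconds.
#' @return Vector of fascicle moduli in MPa, one per time.
#' @export
relaxation_modulus <- function(params, cls, times) {
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and non-negative", call. = FALSE)
  as.numeric(fwd_relaxation(as_theta_matrix(params), cls, times))
}

#' Normalized fascicle relaxation curve
#'
#' \eqn{\bar E(t) = E_{fasc}(t) / E_{fasc}(0)}: starts at exactly 1 at
#' \eqn{t = 0}, is non-increasing, and decays to the asymptote
#' \eqn{(f_r E_\infty + (1 - f_r) E_m) / E_{fasc}(0)}.
#'
#' @inheritParams relaxation_modulus
#' @return Dimensionless vector of normalized moduli.
#' @export
normalized_relaxation <- function(params, cls, times) {
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and non-negative", call. = FALSE)
  theta <- as_theta_matrix(params)
  E0 <- fwd_elastic(theta, cls)
  if (any(E0 <= 0)) stop("initial modulus is non-positive; cannot normalize",
                         call. = FALSE)
  as.numeric(fwd_relaxation(theta, cls, times) / E0)
}

#' Predict the three fascicle observables
#'
#' Bundles the forward model: the initial elastic modulus \eqn{q_1}, the
#' Poisson's ratio \eqn{q_2} and the normalized relaxation curve \eqn{q_3}
#' at the requested times.  The absolute relaxation curve is anchored as
#' \eqn{q_1 \bar E(t)} so that, also under a plugged-in elastic surrogate,
#' the \eqn{t = 0} value of the curve and \eqn{q_1} never disagree.
#'
#' @inheritParams relaxation_modulus
#' @inheritParams poisson_ratio
#' @param g angle factor function of the elastic surrogate (default: rule
#'   of mixtures, \eqn{g \equiv 1}).
#' @return An object of class `"observable_prediction"`: a list with
#'   `elastic_modulus` (MPa), `poisson_ratio`, and `curve` (a data frame
#'   with columns `time_s`, `Ebar`, `E_MPa`).
#' @export
predict_observables <- function(params, cls, times, g = g_unity,
                                kappa = DEFAULT_KAPPA,
                                nu_matrix = DEFAULT_NU_M) {
  q1 <- elastic_modulus(params, cls, g = g)
  q2 <- poisson_ratio(params, cls, kappa = kappa, nu_matrix = nu_matrix)
  q3 <- normalized_relaxation(params, cls, times)
  structure(list(elastic_modulus = q1, poisson_ratio = q2,
                 curve = data.frame(time_s = times, Ebar = q3,
                                    E_MPa = q1 * q3)),
            class = "observable_prediction")
}

#' @export
print.observable_prediction <- function(x, ...) {
  cat(sprintf("Fascicle observables: q1 = %.4g MPa, q2 = %.4g, q3 over %d times (Ebar %0.4g -> %0.4g)\n",
              x$elastic_modulus, x$poisson_ratio, nrow(x$curve),
              x$curve$Ebar[1L], x$curve$Ebar[nrow(x$curve)]))
  invisible(x)
}
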