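# Parameter vector layout used throughout the sampler and likelihood code.
# Reporting units: E_f [MPa], eta_f [GPa s], E_m [MPa], r_inf [-], sigma_n [-].
PARAM_NAMES <- c("E_f", "eta_f", "E_m", "r_inf", "sigma_n")

#' Fascicle model class
#'
#' A fascicle model class fixes the two geometric descriptors of a tendon
#' fascicle: the fiber content \eqn{f_r} (area fraction of the cross-section
#' occupied by fibers, \eqn{A_f/A_t}) and the helix angle \eqn{\theta} of the
#' fibers, measured in degrees from the plane perpendicular to the tendon
#' axis (so the angle from the tendon axis is \eqn{90 - \theta}).
#'
#' @param fiber_content fiber area fraction in (0, 1\]; the pure-fiber value
#'   1 is accepted as a degenerate limit.  The study grid uses 0.35 to 0.65
#'   in steps of 0.05.
#' @param helix_angle helix angle in degrees, in \[0, 90).  The study grid
#'   uses integer angles 70 to 76.
#' @return An object of class `"fascicle_class"`.
#' @examples
#' fascicle_class(0.35, 75)
#' @export
fascicle_class <- function(fiber_content, helix_angle) {
  if (!is.numeric(fiber_content) || length(fiber_content) != 1L ||
      !is.finite(fiber_content) || fiber_content <= 0 || fiber_content > 1)
    stop("fiber_content ", format(fiber_content),
         " is out of range: must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(helix_angle) || length(helix_angle) != 1L ||
      !is.finite(helix_angle) || helix_angle < 0 || helix_angle >= 90)
    stop("helix_angle ", format(helix_angle),
         " is out of range: must lie in [0, 90) degrees", call. = FALSE)
  structure(list(fiber_content = as.numeric(fiber_content),
                 helix_angle = as.numeric(helix_angle)),
            class = "fascicle_class")
}

#' @export
print.fascicle_class <- function(x, ...) {
  cat(sprintf("Fascicle model class: fiber content %.0f%%, helix angle %g deg\n",
              100 * x$fiber_content, x$helix_angle))
  invisible(x)
}

#' Enumerate fascicle model classes over a geometry grid
#'
#' Builds the Cartesian product of fiber contents and helix angles, ordered
#' content-major (all angles for the first content, then the next content).
#' The default grids span the experimentally reported fascicle compositions
#' and helical arrangements and yield 49 classes.
#'
#' @param contents numeric vector of fiber area fractions in (0, 1).
#' @param angles numeric vector of helix angles in degrees, in \[0, 90).
#' @return A list of [fascicle_class()] objects of length
#'   `length(contents) * length(angles)`.
#' @examples
#' length(fascicle_classes())  # 49
#' @export
fascicle_classes <- function(contents = seq(0.35, 0.65, by = 0.05),
                             angles = 70:76) {
  if (length(contents) == 0L || length(angles) == 0L)
    stop("contents and angles must be non-empty", call. = FALSE)
  out <- vector("list", length(contents) * length(angles))
  k <- 0L
  for (fc in contents) for (th in angles) {
    k <- k + 1L
    out[[k]] <- fascicle_class(fc, th)  # validates each value
  }
  out
}

#' Material parameter set for a fascicle model
#'
#' Bundles the physical parameters inferred by the analysis: the fiber
#' elastic modulus \eqn{E_f}, the embedded-fiber viscosity \eqn{\eta_f}, the
#' matrix modulus \eqn{E_m}, the retained-modulus fraction
#' \eqn{r_\infty = E_\infty / E_f} (the fraction of the fiber modulus
#' surviving full relaxation, so the relaxing branch has modulus
#' \eqn{E_R = (1 - r_\infty) E_f}), and the proportional error scale
#' \eqn{\sigma_n} of the observation model.
#'
#' Viscosity is stored internally in MPa s; figures and external reports use
#' GPa s (1 GPa s = 1000 MPa s).
#'
#' @param fiber_modulus \eqn{E_f} in MPa, > 0.
#' @param fiber_viscosity \eqn{\eta_f}, > 0, in the unit given by
#'   `viscosity_unit`.
#' @param matrix_modulus \eqn{E_m} in MPa, > 0.
#' @param retained_fraction \eqn{r_\infty} in (0, 1\]; 1 is accepted as a
#'   degenerate value (no relaxing branch).
#' @param error_scale \eqn{\sigma_n} >= 0, dimensionless.
#' @param viscosity_unit `"MPa.s"` (internal) or `"GPa.s"` (reporting).
#' @return An object of class `"material_params"` with `fiber_viscosity`
#'   in MPa s.
#' @examples
#' material_params(1400, 42, 0.4, retained_fraction = 0.4,
#'                 viscosity_unit = "GPa.s")
#' @export
material_params <- function(fiber_modulus, fiber_viscosity, matrix_modulus,
                            retained_fraction = 0.4, error_scale = 0.05,
                            viscosity_unit = c("MPa.s", "GPa.s")) {
  viscosity_unit <- match.arg(viscosity_unit)
  if (viscosity_unit == "GPa.s") fiber_viscosity <- fiber_viscosity * 1000
  vals <- c(fiber_modulus, fiber_viscosity, matrix_modulus)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("fiber_modulus, fiber_viscosity and matrix_modulus must be strictly positive",
         call. = FALSE)
  if (!is.finite(retained_fraction) || retained_fraction <= 0 ||
      retained_fraction > 1)
    stop("retained_fraction must lie in (0, 1]", call. = FALSE)
  if (!is.finite(error_scale) || error_scale < 0)
    stop("error_scale must be non-negative", call. = FALSE)
  structure(list(fiber_modulus = as.numeric(fiber_modulus),
                 fiber_viscosity = as.numeric(fiber_viscosity),
                 matrix_modulus = as.numeric(matrix_modulus),
                 retained_fraction = as.numeric(retained_fraction),
                 error_scale = as.numeric(error_scale)),
            class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat("Fascicle material parameters:\n")
  cat(sprintf("  E_f     = %g MPa\n", x$fiber_modulus))
  cat(sprintf("  eta_f   = %g GPa s (%g MPa s)\n",
              x$fiber_viscosity / 1000, x$fiber_viscosity))
  cat(sprintf("  E_m     = %g MPa\n", x$matrix_modulus))
  cat(sprintf("  r_inf   = %g  (E_inf = %g MPa, E_R = %g MPa)\n",
              x$retained_fraction,
              x$retained_fraction * x$fiber_modulus,
              (1 - x$retained_fraction) * x$fiber_modulus))
  if (x$retained_fraction < 1)
    cat(sprintf("  tau     = %g s\n", relaxation_time(x)))
  cat(sprintf("  sigma_n = %g\n", x$error_scale))
  invisible(x)
}

#' Relaxation time of the fiber Maxwell arm
#'
#' \eqn{\tau = \eta_f / E_R} with \eqn{E_R = (1 - r_\infty) E_f}.  Unit
#' consistent: MPa s over MPa gives seconds (identically GPa s over GPa).
#'
#' @param params a [material_params()] object.
#' @return Relaxation time in seconds.
#' @export
relaxation_time <- function(params) {
  ER <- (1 - params$retained_fraction) * params$fiber_modulus
  if (ER <= 0) return(Inf)
  params$fiber_viscosity / ER
}

# -- parameter vector <-> object helpers (reporting units) -------------------

# material_params -> named vector c(E_f MPa, eta_f GPa.s, E_m MPa, r_inf, sigma_n)
pack_params <- function(params) {
  stopifnot(inherits(params, "material_params"))
  stats::setNames(c(params$fiber_modulus, params$fiber_viscosity / 1000,
                    params$matrix_modulus, params$retained_fraction,
                    params$error_scale), PARAM_NAMES)
}

# named vector / unnamed length-5 vector -> material_params
unpack_params <- function(theta) {
  theta <- as.numeric(theta)
  stopifnot(length(theta) == 5L)
  material_params(theta[1L], theta[2L], theta[3L],
                  retained_fraction = theta[4L], error_scale = theta[5L],
                  viscosity_unit = "GPa.s")
}

# accepts material_params, named/plain length-5 vector, or 5-col matrix;
# returns an n x 5 matrix in reporting units
as_theta_matrix <- function(x) {
  if (inherits(x, "material_params")) x <- pack_params(x)
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 5L)
    m <- x
  } else {
    stopifnot(length(x) == 5L)
    m <- matrix(as.numeric(x), nrow = 1L)
  }
  colnames(m) <- PARAM_NAMES
  m
}
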