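#' Vacuum permittivity (F/m)
#'
#' CODATA value of the electric constant, used to convert relative
#' permittivities into absolute ones.
#'
#' @export
EPSILON_0 <- 8.8541878128e-12

#' Define a dielectric phase (particle or suspending medium)
#'
#' A homogeneous dielectric is described by its relative permittivity and its
#' electrical conductivity. Together they fix the complex permittivity
#' \eqn{\epsilon^* = \epsilon_r \epsilon_0 - j \sigma / \omega} at any angular
#' frequency \eqn{\omega}.
#'
#' @param eps_r Relative permittivity (dimensionless, >= 1).
#' @param sigma Electrical conductivity in S/m (>= 0).
#'
#' @return An object of class `dielectric_material`.
#' @examples
#' water <- dielectric_material(eps_r = 78.5, sigma = 1e-4)
#' polystyrene <- dielectric_material(eps_r = 2.55, sigma = 1e-16)
#' @export
dielectric_material <- function(eps_r, sigma) {
  stopifnot(is.numeric(eps_r), length(eps_r) == 1L, is.finite(eps_r),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
  if (eps_r < 1)
    stop("`eps_r` must be >= 1 (relative permittivity of a physical dielectric)",
         call. = FALSE)
  if (sigma < 0)
    stop("`sigma` must be >= 0 S/m", call. = FALSE)
  structure(list(eps_r = eps_r, sigma = sigma),
            class = "dielectric_material")
}

#' @export
print.dielectric_material <- function(x, ...) {
  cat(sprintf("<dielectric_material> eps_r = %g, sigma = %g S/m\n",
              x$eps_r, x$sigma))
  invisible(x)
}

#' Define a particle/medium system
#'
#' Bundles the particle and medium dielectrics with the particle radius; this
#' is the object on which the Clausius-Mossotti (CM) dispersion, the DEP force
#' prefactor and the cross-over frequency are defined.
#'
#' For micron-scale latex spheres, surface conduction along the double layer
#' usually dominates the bulk conductivity. When `surface_conductance` (Ks, in
#' siemens) is supplied, the particle conductivity used throughout is the
#' effective value \eqn{\sigma_p = \sigma_{bulk} + 2 K_s / R_p}. The default
#' Ks = 0 leaves the bulk value untouched.
#'
#' @param particle,medium `dielectric_material` objects.
#' @param radius Particle radius in metres (> 0).
#' @param surface_conductance Optional surface conductance Ks in S (>= 0).
#'
#' @return An object of class `particle_system`. The element
#'   `sigma_p_eff` holds the effective particle conductivity actually used.
#' @examples
#' sys <- particle_system(
#'   particle = dielectric_material(2.55, 1e-16),
#'   medium   = dielectric_material(78.5, 1e-4),
#'   radius   = 2.25e-6,
#'   surface_conductance = 1e-9
#' )
#' re_cm(sys, 1e4)
#' @export
particle_system <- function(particle, medium, radius, surface_conductance = 0) {
  stopifnot(inherits(particle, "dielectric_material"),
            inherits(medium, "dielectric_material"),
            is.numeric(radius), length(radius) == 1L, is.finite(radius),
            is.numeric(surface_conductance), length(surface_conductance) == 1L,
            is.finite(surface_conductance))
  if (radius <= 0) stop("`radius` must be > 0 m", call. = FALSE)
  if (surface_conductance < 0)
    stop("`surface_conductance` must be >= 0 S", call. = FALSE)
  structure(list(
    particle = particle,
    medium = medium,
    radius = radius,
    surface_conductance = surface_conductance,
    sigma_p_eff = particle$sigma + 2 * surface_conductance / radius
  ), class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat("<particle_system>\n")
  cat(sprintf("  particle: eps_r = %g, sigma = %g S/m (effective %g S/m)\n",
              x$particle$eps_r, x$particle$sigma, x$sigma_p_eff))
  cat(sprintf("  medium:   eps_r = %g, sigma = %g S/m\n",
              x$medium$eps_r, x$medium$sigma))
  cat(sprintf("  radius:   %g m\n", x$radius))
  co <- crossover_frequency(x)
  if (co$exists)
    cat(sprintf("  cross-over: %.6g Hz (%s below, %s above)\n", co$fco,
                if (co$sign_below > 0) "pDEP" else "nDEP",
                if (co$sign_below > 0) "nDEP" else "pDEP"))
  else
    cat("  cross-over: none (no sign change in RE{CM})\n")
  invisible(x)
}

# Internal: absolute permittivities and effective conductivities of a system.
.sys_params <- function(system) {
  list(ep = system$particle$eps_r * EPSILON_0,
       em = system$medium$eps_r * EPSILON_0,
       sp = system$sigma_p_eff,
       sm = system$medium$sigma)
}

#' Complex permittivity of a dielectric at a given frequency
#'
#' Returns the absolute complex permittivity
#' \eqn{\epsilon^* = \epsilon_r \epsilon_0 - j \sigma / (2\pi f)} in F/m.
#'
#' @param material A `dielectric_material`.
#' @param f Ordinary frequency in Hz (> 0); may be a vector.
#'
#' @return Complex vector of the same length as `f`.
#' @examples
#' complex_permittivity(dielectric_material(78.5, 1e-4), 1e4)
#' @export
complex_permittivity <- function(material, f) {
  stopifnot(inherits(material, "dielectric_material"), is.numeric(f))
  if (any(!is.finite(f)) || any(f <= 0))
    stop("`f` must be finite and > 0 Hz", call. = FALSE)
  complex(real = material$eps_r * EPSILON_0,
          imaginary = -material$sigma / (2 * pi * f))
}

#' Real part of the Clausius-Mossotti factor
#'
#' Evaluates RE\{CM\} for a homogeneous sphere using the rationalised
#' single-relaxation form
#' \deqn{RE\{CM\}(\omega) = \frac{\omega^2(\epsilon_p-\epsilon_m)
#'   (\epsilon_p+2\epsilon_m) + (\sigma_p-\sigma_m)(\sigma_p+2\sigma_m)}
#'   {\omega^2(\epsilon_p+2\epsilon_m)^2 + (\sigma_p+2\sigma_m)^2}}
#' with absolute permittivities \eqn{\epsilon_i = \epsilon_{r,i}\epsilon_0}
#' and the effective particle conductivity (see [particle_system()]). The
#' value lies in \eqn{[-0.5, 1]} and its sign sets the DEP force direction:
#' positive for pDEP (attraction towards field maxima), negative for nDEP.
#'
#' @param system A `particle_system`.
#' @param f Ordinary frequency in Hz (> 0); may be a vector.
#'
#' @return Numeric vector of RE\{CM\} values.
#' @examples
#' sys <- particle_system(dielectric_material(2.55, 0),
#'                        dielectric_material(78.5, 1e-4), 2.25e-6,
#'                        surface_conductance = 1e-9)
#' re_cm(sys, 10^seq(3, 8))
#' @export
re_cm <- function(system, f) {
  stopifnot(inherits(system, "particle_system"), is.numeric(f))
  if (any(!is.finite(f)) || any(f <= 0))
    stop("`f` must be finite and > 0 Hz", call. = FALSE)
  p <- .sys_params(system)
  w2 <- (2 * pi * f)^2
  num <- w2 * (p$ep - p$em) * (p$ep + 2 * p$em) +
    (p$sp - p$sm) * (p$sp + 2 * p$sm)
  den <- w2 * (p$ep + 2 * p$em)^2 + (p$sp + 2 * p$sm)^2
  num / den
}

#' Low- and high-frequency plateaus of RE{CM}
#'
#' The dispersion runs monotonically between the conductivity-dominated DC
#' limit \eqn{(\sigma_p-\sigma_m)/(\sigma_p+2\sigma_m)} and the
#' permittivity-dominated infinite-frequency limit
#' \eqn{(\epsilon_p-\epsilon_m)/(\epsilon_p+2\epsilon_m)}.
#'
#' @param system A `particle_system`.
#' @return Named numeric vector with elements `dc` and `hf`.
#' @export
re_cm_limits <- function(system) {
  stopifnot(inherits(system, "particle_system"))
  p <- .sys_params(system)
  dc <- if (p$sp == 0 && p$sm == 0) 0 else
    (p$sp - p$sm) / (p$sp + 2 * p$sm)
  c(dc = dc, hf = (p$ep - p$em) / (p$ep + 2 * p$em))
}

#' Cross-over frequency of the CM factor
#'
#' Solves RE\{CM\}(fco) = 0. A single-relaxation dispersion changes sign at
#' most once, exactly when the DC and high-frequency plateaus have opposite
#' signs; the root is available in closed form,
#' \deqn{(2\pi f_{co})^2 = -\frac{(\sigma_p-\sigma_m)(\sigma_p+2\sigma_m)}
#'   {(\epsilon_p-\epsilon_m)(\epsilon_p+2\epsilon_m)}.}
#'
#' @param system A `particle_system`.
#'
#' @return An object of class `crossover_result`: a list with `exists`
#'   (logical), `fco` (Hz, `NA` when no crossing) and `sign_below` (+1 or -1,
#'   the sign of RE\{CM\} for f < fco; `NA` when no crossing).
#' @examples
#' sys <- particle_system(dielectric_material(2.55, 0),
#'                        dielectric_material(78.5, 1e-4), 2.25e-6,
#'                        surface_conductance = 1e-9)
#' crossover_frequency(sys)
#' @export
crossover_frequency <- function(system) {
  stopifnot(inherits(system, "particle_system"))
  lim <- re_cm_limits(system)
  # A sign change needs strictly opposite plateau signs; plateaus of equal
  # sign (or zero, the degenerate particle == medium case) never cross zero.
  if (lim["dc"] * lim["hf"] >= 0) {
    return(structure(list(exists = FALSE, fco = NA_real_,
                          sign_below = NA_real_),
                     class = "crossover_result"))
  }
  p <- .sys_params(system)
  w2 <- -((p$sp - p$sm) * (p$sp + 2 * p$sm)) /
    ((p$ep - p$em) * (p$ep + 2 * p$em))
  structure(list(exists = TRUE,
                 fco = sqrt(w2) / (2 * pi),
                 sign_below = unname(sign(lim["dc"]))),
            class = "crossover_result")
}

#' @export
print.crossover_result <- function(x, ...) {
  if (x$exists)
    cat(sprintf("<crossover_result> fco = %.6g Hz, RE{CM} %s below / %s above\n",
                x$fco,
                if (x$sign_below > 0) "positive" else "negative",
                if (x$sign_below > 0) "negative" else "positive"))
  else
    cat("<crossover_result> no cross-over (RE{CM} does not change sign)\n")
  invisible(x)
}

#' DEP force prefactor
#'
#' The time-averaged DEP force on a homogeneous sphere is
#' \eqn{F = 2\pi R_p^3 \epsilon_m RE\{CM\}(f) \, \nabla |E_{rms}|^2}.
#' This function returns everything except the field-geometry term, i.e.
#' \eqn{2\pi R_p^3 \epsilon_m RE\{CM\}(f)} in N m^2/V^2; multiply by a
#' user-supplied field-gradient scalar G (V^2/m^3) to obtain newtons. The sign
#' follows RE\{CM\}.
#'
#' @param system A `particle_system`.
#' @param f Frequency in Hz (> 0); may be a vector.
#'
#' @return Numeric vector, N m^2/V^2.
#' @export
dep_force_prefactor <- function(system, f) {
  stopifnot(inherits(system, "particle_system"))
  2 * pi * system$radius^3 * system$medium$eps_r * EPSILON_0 *
    re_cm(system, f)
}
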