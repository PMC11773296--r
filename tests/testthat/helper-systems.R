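# Shared fixture builders. All fixtures are constructed in code.

# Polystyrene-like bead in a low-conductivity aqueous medium. The bead's
# effective conductivity comes almost entirely from surface conduction.
ps_water_system <- function(radius = 2.25e-6, sigma_m = 1e-4, ks = 1e-9) {
  particle_system(dielectric_material(2.55, 1e-16),
                  dielectric_material(78.5, sigma_m),
                  radius, surface_conductance = ks)
}

# Dispersion with RE{CM} exactly constant at every frequency: equal
# permittivity and conductivity ratios make the numerator of the
# rationalised CM form proportional to its denominator.
flat_system <- function(sign = -1) {
  if (sign < 0)
    particle_system(dielectric_material(40, 5e-4),
                    dielectric_material(80, 1e-3), 1e-6)
  else
    particle_system(dielectric_material(80, 1e-3),
                    dielectric_material(40, 5e-4), 1e-6)
}

# A pDEP-below / nDEP-above system with a prescribed cross-over frequency:
# permittivities fixed (low-permittivity bead in water), particle
# conductivity solved from the closed-form root condition.
crossover_system <- function(fco, sigma_m = 1e-4,
                             eps_p = 2.55, eps_m = 78.5) {
  ep <- eps_p * depwave::EPSILON_0
  em <- eps_m * depwave::EPSILON_0
  C <- -(2 * pi * fco)^2 * (ep - em) * (ep + 2 * em)  # required (sp-sm)(sp+2sm)
  sp <- (-sigma_m + sqrt(sigma_m^2 + 4 * (2 * sigma_m^2 + C))) / 2
  particle_system(dielectric_material(eps_p, sp),
                  dielectric_material(eps_m, sigma_m), 1.25e-6)
}

# Random physically plausible system. About half the draws are biased
# towards the bead-in-water regime that produces a cross-over.
random_system <- function() {
  if (stats::runif(1) < 0.5) {
    particle_system(
      dielectric_material(stats::runif(1, 1.5, 10),
                          10^stats::runif(1, -4, -1)),
      dielectric_material(stats::runif(1, 40, 100),
                          10^stats::runif(1, -6, -4)),
      10^stats::runif(1, -7, -5))
  } else {
    particle_system(
      dielectric_material(stats::runif(1, 1.5, 100),
                          10^stats::runif(1, -6, 0)),
      dielectric_material(stats::runif(1, 1.5, 100),
                          10^stats::runif(1, -6, 0)),
      10^stats::runif(1, -7, -5))
  }
}

# Independent oracle: bracketing root finder on re_cm over log-frequency.
bisect_crossover <- function(system, lower = 1, upper = 1e12) {
  g <- function(x) re_cm(system, 10^x)
  if (g(log10(lower)) * g(log10(upper)) > 0) return(NA_real_)
  10^stats::uniroot(g, c(log10(lower), log10(upper)),
                    tol = 1e-12)$root
}
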