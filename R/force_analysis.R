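#' Per-harmonic DEP force decomposition of a waveform
#'
#' Each spectral line of the drive waveform contributes a time-averaged DEP
#' force proportional to its energy weighted by the CM dispersion at its own
#' frequency,
#' \deqn{F_n = 2\pi R_p^3 \epsilon_m \, RE\{CM\}(n f_0) \, A_n^2 \, G,}
#' where G is a user-supplied field-gradient scalar standing in for
#' \eqn{\nabla |E_{rms}|^2} (the electrode geometry is treated as
#' frequency-independent). Cross terms between distinct frequencies average
#' to zero over a period, so the per-line forces simply add. The harmonic
#' contributions (orders n > 1) are separated by sign into the sums A (same
#' sign as an increase of the net force magnitude is not implied — A collects
#' the positive contributions) and B (the negative ones), mirroring the
#' |A| vs |B| bookkeeping used to reason about when a square wave helps.
#'
#' @section Spectral tail:
#' A truncated rectangular spectrum misses the analytically known energy of
#' the lines above the truncation order. With `tail = "plateau"` (default)
#' that residual energy is added as one extra contribution weighted by the
#' high-frequency plateau of RE\{CM\}, where those lines live; the force
#' total then accounts for the full signal energy. `tail = "none"` keeps the
#' raw partial sum. No tail is added when a bandwidth limit is set (the
#' electronics genuinely remove those lines) or for sine sources.
#'
#' @param system A [particle_system()].
#' @param spectrum A [harmonic_spectrum()].
#' @param field_gradient Field-gradient scalar G in V^2/m^3 (> 0).
#' @param tail `"plateau"` or `"none"`.
#' @param comparison Baseline convention: `"peak"` compares against a
#'   sinusoid of the same peak amplitude V0 (the usual bench comparison at
#'   equal peak-to-peak drive); `"rms"` against a sinusoid of equal RMS
#'   amplitude.
#'
#' @return An object of class `force_decomposition`: `contributions` (per
#'   line: order, frequency, amplitude, energy, RE\{CM\}, force in N),
#'   `fundamental`, `positive_sum` (A >= 0), `negative_sum` (B <= 0),
#'   `tail_force`, `total`, and `sine_baseline` (all N).
#' @examples
#' sys <- particle_system(dielectric_material(2.55, 0),
#'                        dielectric_material(78.5, 1e-4), 2.25e-6,
#'                        surface_conductance = 1e-9)
#' sp <- harmonic_spectrum(waveform_spec("rectangular", 5, 1e4))
#' decompose_force(sys, sp, field_gradient = 1e12)
#' @export
decompose_force <- function(system, spectrum, field_gradient,
                            tail = c("plateau", "none"),
                            comparison = c("peak", "rms")) {
  stopifnot(inherits(system, "particle_system"),
            inherits(spectrum, "harmonic_spectrum"))
  tail <- match.arg(tail)
  comparison <- match.arg(comparison)
  if (!is.numeric(field_gradient) || length(field_gradient) != 1L ||
      !is.finite(field_gradient) || field_gradient <= 0)
    stop("`field_gradient` must be a positive scalar (V^2/m^3)", call. = FALSE)
  if (nrow(spectrum$lines) == 0L)
    stop("`spectrum` has no lines", call. = FALSE)

  K <- 2 * pi * system$radius^3 * system$medium$eps_r * EPSILON_0
  ln <- spectrum$lines
  cm <- re_cm(system, ln$frequency_hz)
  force <- K * field_gradient * ln$amplitude_v^2 * cm
  contributions <- data.frame(
    order = ln$order, frequency_hz = ln$frequency_hz,
    amplitude_v = ln$amplitude_v, energy_v2 = ln$amplitude_v^2,
    re_cm = cm, force_n = force)

  src <- spectrum$source
  tail_force <- 0
  if (tail == "plateau" && src$shape == "rectangular" &&
      is.null(spectrum$bandwidth_limit)) {
    k_incl <- (spectrum$truncation + 1L) %/% 2L  # odd lines included
    tail_energy <- (4 / pi * src$v0)^2 * (pi^2 / 8 - odd_harmonic_sum(k_incl))
    tail_force <- K * field_gradient * tail_energy *
      unname(re_cm_limits(system)["hf"])
  }

  harm <- force[ln$order > 1L]
  pos <- sum(harm[harm > 0]) + max(tail_force, 0)
  neg <- sum(harm[harm < 0]) + min(tail_force, 0)
  fundamental <- sum(force[ln$order == 1L])

  base_amp2 <- switch(comparison,
    peak = src$v0^2,
    rms  = 2 * rms_amplitude(src)^2)
  sine_baseline <- K * field_gradient * base_amp2 * re_cm(system, src$f0)

  structure(list(
    contributions = contributions,
    fundamental = fundamental,
    positive_sum = pos,
    negative_sum = neg,
    tail_force = tail_force,
    total = fundamental + pos + neg,
    sine_baseline = sine_baseline,
    comparison = comparison,
    field_gradient = field_gradient,
    system = system, spectrum = spectrum
  ), class = "force_decomposition")
}

#' @export
print.force_decomposition <- function(x, ...) {
  cat("<force_decomposition>\n")
  cat(sprintf("  fundamental: %+.4e N at %g Hz\n",
              x$fundamental, x$spectrum$source$f0))
  cat(sprintf("  harmonics:   A = %+.4e N, B = %+.4e N (tail %+.3e N)\n",
              x$positive_sum, x$negative_sum, x$tail_force))
  cat(sprintf("  total:       %+.4e N\n", x$total))
  cat(sprintf("  sine baseline (%s-matched): %+.4e N\n",
              x$comparison, x$sine_baseline))
  if (x$sine_baseline != 0)
    cat(sprintf("  gain ratio:  %.4f\n", x$total / x$sine_baseline))
  invisible(x)
}

#' Advise on using a rectangular instead of a sinusoidal waveform
#'
#' Combines two rules. The conservative energy rule: a square wave is
#' guaranteed beneficial when \eqn{f_0 < f_{co}/5}, because the third and
#' fifth harmonics then still lie below the cross-over and carry more than
#' half of all harmonic energy; it is always beneficial when \eqn{f_0 >
#' f_{co}} or when no cross-over exists (every harmonic shares the
#' fundamental's force sign); in between the rule is inconclusive. The exact
#' rule evaluates the full per-harmonic decomposition and declares benefit
#' when the signed total exceeds the sine baseline of matching sign
#' (gain ratio > 1). The energy rule is sufficient but not necessary, so the
#' exact rule may still find a benefit where the energy rule is inconclusive.
#'
#' The rules apply to dispersions with at most one cross-over; the
#' homogeneous-sphere model used here guarantees that. Layered (multishell)
#' particles with several cross-overs are outside this package's scope.
#'
#' @param system A [particle_system()].
#' @param f0 Fundamental frequency in Hz (> 0).
#' @param v0 Peak amplitude in V (default 1; the verdict is amplitude-
#'   invariant, the forces scale with V0^2).
#' @param field_gradient Field-gradient scalar G in V^2/m^3 (default 1).
#' @param max_order,bandwidth_limit,bandwidth_model Passed to
#'   [harmonic_spectrum()].
#' @param tail,comparison Passed to [decompose_force()].
#'
#' @return An object of class `benefit_report`: `energy_rule` (one of
#'   `"beneficial"`, `"not_guaranteed"`, `"always_beneficial"`),
#'   `boundary_frequency` (fco/5, NA when no cross-over), `beneficial_exact`
#'   (logical), `gain_ratio` (total / sine baseline), `rules_agree`, plus
#'   `crossover` and the full `decomposition`.
#' @examples
#' sys <- particle_system(dielectric_material(2.55, 0),
#'                        dielectric_material(78.5, 1e-4), 2.25e-6,
#'                        surface_conductance = 1e-9)
#' advise(sys, f0 = 1e4)
#' @export
advise <- function(system, f0, v0 = 1, field_gradient = 1,
                   max_order = 199, bandwidth_limit = NULL,
                   bandwidth_model = "brickwall",
                   tail = "plateau", comparison = "peak") {
  stopifnot(inherits(system, "particle_system"),
            is.numeric(f0), length(f0) == 1L, is.finite(f0))
  if (f0 <= 0) stop("`f0` must be > 0 Hz", call. = FALSE)

  co <- crossover_frequency(system)
  energy_rule <-
    if (!co$exists || f0 > co$fco) "always_beneficial"
    else if (f0 < co$fco / 5) "beneficial"
    else "not_guaranteed"

  spec <- waveform_spec("rectangular", v0 = v0, f0 = f0)
  dec <- decompose_force(system,
                         harmonic_spectrum(spec, max_order = max_order,
                                           bandwidth_limit = bandwidth_limit,
                                           bandwidth_model = bandwidth_model),
                         field_gradient = field_gradient,
                         tail = tail, comparison = comparison)
  gain_ratio <- if (dec$sine_baseline == 0) NA_real_
                else dec$total / dec$sine_baseline
  beneficial_exact <- if (is.na(gain_ratio)) NA else gain_ratio > 1

  rules_agree <- switch(energy_rule,
    beneficial = ,
    always_beneficial = isTRUE(beneficial_exact),
    not_guaranteed = TRUE)  # inconclusive rule cannot disagree

  structure(list(
    energy_rule = energy_rule,
    boundary_frequency = if (co$exists) co$fco / 5 else NA_real_,
    beneficial_exact = beneficial_exact,
    gain_ratio = gain_ratio,
    rules_agree = rules_agree,
    f0 = f0,
    crossover = co,
    decomposition = dec
  ), class = "benefit_report")
}

#' @export
print.benefit_report <- function(x, ...) {
  cat("<benefit_report> rectangular vs sinusoidal drive\n")
  cat(sprintf("  f0 = %g Hz; cross-over: %s\n", x$f0,
              if (x$crossover$exists) sprintf("%.6g Hz", x$crossover$fco)
              else "none"))
  cat(sprintf("  energy rule (f0 < fco/5): %s%s\n", x$energy_rule,
              if (!is.na(x$boundary_frequency))
                sprintf(" (boundary %.6g Hz)", x$boundary_frequency) else ""))
  cat(sprintf("  exact decomposition: %s (gain ratio %.4f)\n",
              if (isTRUE(x$beneficial_exact)) "beneficial"
              else if (identical(x$beneficial_exact, FALSE)) "detrimental"
              else "undefined (zero baseline)",
              x$gain_ratio))
  if (!x$rules_agree)
    cat("  note: the conservative energy rule disagrees with the exact decomposition;\n",
        "        the exact per-harmonic result governs.\n", sep = "")
  invisible(x)
}

#' Smallest harmonic order carrying a given share of the harmonic energy
#'
#' Scans odd orders m = 3, 5, 7, ... accumulating the normalised line
#' energies 1/m^2 until their sum reaches `energy_threshold` times the total
#' harmonic energy \eqn{\pi^2/8 - 1} of an ideal square wave. For a threshold
#' of one half the answer is 5: the third and fifth harmonics alone carry
#' more than 50% of all harmonic energy, which is what turns the guaranteed-
#' benefit condition into the simple frequency bound f0 < fco / 5.
#'
#' @param energy_threshold Fraction in (0, 1).
#' @return The smallest odd integer order m.
#' @examples
#' smallest_safe_divisor(0.5)   # 5
#' @export
smallest_safe_divisor <- function(energy_threshold) {
  stopifnot(is.numeric(energy_threshold), length(energy_threshold) == 1L,
            is.finite(energy_threshold))
  if (energy_threshold <= 0 || energy_threshold >= 1)
    stop("`energy_threshold` must lie strictly between 0 and 1", call. = FALSE)
  target <- energy_threshold * (pi^2 / 8 - 1)
  acc <- 0
  m <- 1L
  repeat {
    m <- m + 2L
    acc <- acc + 1 / as.numeric(m)^2
    if (acc >= target) return(m)
  }
}
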