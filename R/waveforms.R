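#' Describe a periodic excitation waveform
#'
#' A waveform is given by its shape, its peak amplitude V0 (half the
#' peak-to-peak drive) and its fundamental frequency f0. Only the ideal
#' symmetric (50% duty) rectangular wave and the pure sinusoid are supported;
#' these are the two shapes whose spectral energy budgets the rest of the
#' package compares.
#'
#' @param shape `"sine"` or `"rectangular"`.
#' @param v0 Peak amplitude in volts (> 0).
#' @param f0 Fundamental frequency in Hz (> 0).
#'
#' @return An object of class `waveform_spec`.
#' @examples
#' waveform_spec("rectangular", v0 = 5, f0 = 1e4)
#' @export
waveform_spec <- function(shape = c("sine", "rectangular"), v0, f0) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(v0), length(v0) == 1L, is.finite(v0),
            is.numeric(f0), length(f0) == 1L, is.finite(f0))
  if (v0 <= 0) stop("`v0` must be > 0 V", call. = FALSE)
  if (f0 <= 0) stop("`f0` must be > 0 Hz", call. = FALSE)
  structure(list(shape = shape, v0 = v0, f0 = f0), class = "waveform_spec")
}

#' @export
print.waveform_spec <- function(x, ...) {
  cat(sprintf("<waveform_spec> %s, V0 = %g V, f0 = %g Hz\n",
              x$shape, x$v0, x$f0))
  invisible(x)
}

#' Harmonic line spectrum of a waveform
#'
#' Expands the waveform into its Fourier sine series up to `max_order`. An
#' ideal rectangular wave contains only odd orders with peak amplitude
#' \eqn{A_n = (4/\pi) V_0 / n}; even orders are present in the table with
#' amplitude exactly 0. A sinusoid has a single nonzero line at f0.
#'
#' Real drive electronics are bandwidth-limited. `bandwidth_limit` models
#' this: with `bandwidth_model = "brickwall"` (default) lines above the
#' cutoff are zeroed; with `"firstorder"` every line is attenuated by the
#' single-pole magnitude response \eqn{1/\sqrt{1 + (f/f_c)^2}}.
#'
#' @param spec A [waveform_spec()].
#' @param max_order Highest harmonic order included (integer >= 1). The
#'   default 199 keeps the first 100 odd lines, > 99.7% of the harmonic
#'   energy of an ideal square wave.
#' @param bandwidth_limit Optional cutoff frequency in Hz.
#' @param bandwidth_model `"brickwall"` or `"firstorder"`.
#'
#' @return An object of class `harmonic_spectrum`: a list with `lines` (a
#'   data.frame with columns `order`, `frequency_hz`, `amplitude_v`),
#'   `source` (the spec), `truncation` and `bandwidth_limit`.
#' @examples
#' sp <- harmonic_spectrum(waveform_spec("rectangular", 1, 1e4), max_order = 7)
#' sp$lines
#' @export
harmonic_spectrum <- function(spec, max_order = 199, bandwidth_limit = NULL,
                              bandwidth_model = c("brickwall", "firstorder")) {
  stopifnot(inherits(spec, "waveform_spec"))
  bandwidth_model <- match.arg(bandwidth_model)
  if (!is.numeric(max_order) || length(max_order) != 1L ||
      !is.finite(max_order) || max_order < 1)
    stop("`max_order` must be an integer >= 1", call. = FALSE)
  max_order <- as.integer(max_order)
  n <- seq_len(max_order)
  amp <- switch(spec$shape,
    rectangular = ifelse(n %% 2L == 1L, 4 / pi * spec$v0 / n, 0),
    sine = ifelse(n == 1L, spec$v0, 0)
  )
  freq <- n * spec$f0
  if (!is.null(bandwidth_limit)) {
    stopifnot(is.numeric(bandwidth_limit), length(bandwidth_limit) == 1L,
              is.finite(bandwidth_limit), bandwidth_limit > 0)
    amp <- switch(bandwidth_model,
      brickwall = ifelse(freq > bandwidth_limit, 0, amp),
      firstorder = amp / sqrt(1 + (freq / bandwidth_limit)^2)
    )
  }
  structure(list(
    lines = data.frame(order = n, frequency_hz = freq, amplitude_v = amp),
    source = spec,
    truncation = max_order,
    bandwidth_limit = bandwidth_limit,
    bandwidth_model = if (is.null(bandwidth_limit)) NULL else bandwidth_model
  ), class = "harmonic_spectrum")
}

#' @export
print.harmonic_spectrum <- function(x, ...) {
  nz <- sum(x$lines$amplitude_v != 0)
  cat(sprintf("<harmonic_spectrum> %s, V0 = %g V, f0 = %g Hz; %d lines up to order %d (%d nonzero)\n",
              x$source$shape, x$source$v0, x$source$f0,
              nrow(x$lines), x$truncation, nz))
  if (!is.null(x$bandwidth_limit))
    cat(sprintf("  bandwidth limit: %g Hz (%s)\n",
                x$bandwidth_limit, x$bandwidth_model))
  print(utils::head(x$lines[x$lines$amplitude_v != 0, ], 8), row.names = FALSE)
  invisible(x)
}

#' Root-mean-square amplitude of a waveform
#'
#' \eqn{V_{rms} = V_0/\sqrt{2}} for a sinusoid and \eqn{V_{rms} = V_0} for an
#' ideal rectangular wave. The higher RMS value of the square wave reflects
#' its larger total energy, but says nothing about how that energy is spread
#' over frequency.
#'
#' @param spec A [waveform_spec()].
#' @return RMS amplitude in volts.
#' @export
rms_amplitude <- function(spec) {
  stopifnot(inherits(spec, "waveform_spec"))
  switch(spec$shape, sine = spec$v0 / sqrt(2), rectangular = spec$v0)
}

#' Spectral energy of a harmonic spectrum
#'
#' Per-line energy uses the peak-amplitude-squared convention
#' \eqn{P_n = A_n^2} (no 1/2 factor), so a unit sinusoid carries energy 1 and
#' an ideal unit square wave carries total energy 2. The same convention is
#' used by [time_domain_energy()], so spectral totals and time-domain values
#' agree by Parseval's theorem.
#'
#' @param spectrum A [harmonic_spectrum()].
#' @return A list with `per_line` (the lines data.frame plus an `energy_v2`
#'   column) and `total` (sum over the included lines, V^2).
#' @examples
#' spectral_energy(harmonic_spectrum(waveform_spec("rectangular", 1, 1e3),
#'                                   max_order = 5))$total
#' @export
spectral_energy <- function(spectrum) {
  stopifnot(inherits(spectrum, "harmonic_spectrum"))
  per <- spectrum$lines
  per$energy_v2 <- per$amplitude_v^2
  list(per_line = per, total = sum(per$energy_v2))
}

#' Partial and closed-form sums of the odd-harmonic energy series
#'
#' The normalised energy series of an ideal square wave is
#' \eqn{\sum_{n=1}^{\infty} 1/(2n-1)^2 = \pi^2/8 \approx 1.234}: the
#' fundamental contributes 1 and all higher odd harmonics together contribute
#' \eqn{\pi^2/8 - 1 \approx 0.234}. `max_n` counts series terms, so term n
#' corresponds to harmonic order 2n - 1.
#'
#' @param max_n Number of terms (>= 1), or `Inf` for the closed form.
#' @return The (partial) sum, dimensionless.
#' @examples
#' odd_harmonic_sum(Inf)      # pi^2 / 8
#' odd_harmonic_sum(3)        # 1 + 1/9 + 1/25
#' @export
odd_harmonic_sum <- function(max_n) {
  stopifnot(is.numeric(max_n), length(max_n) == 1L)
  if (is.infinite(max_n)) return(pi^2 / 8)
  if (!is.finite(max_n) || max_n < 1)
    stop("`max_n` must be >= 1 or Inf", call. = FALSE)
  sum(1 / (2 * seq_len(as.integer(max_n)) - 1)^2)
}

#' Synthesize a spectrum in the time domain
#'
#' Evaluates \eqn{V(t) = \sum_n A_n \sin(2\pi f_n t)} at the requested sample
#' times. As the truncation grows, rectangular spectra converge pointwise to
#' the ideal square wave away from the transitions (Gibbs oscillations remain
#' near the edges).
#'
#' @param spectrum A [harmonic_spectrum()].
#' @param times Numeric vector of sample times in seconds (nonempty).
#' @return Numeric vector of signal samples in volts.
#' @export
synthesize <- function(spectrum, times) {
  stopifnot(inherits(spectrum, "harmonic_spectrum"), is.numeric(times),
            length(times) >= 1L, all(is.finite(times)))
  ln <- spectrum$lines[spectrum$lines$amplitude_v != 0, ]
  if (nrow(ln) == 0L) return(numeric(length(times)))
  # outer() over (times x lines) keeps this vectorised; line counts are
  # a few hundred at most so the matrix stays small.
  drop(sin(2 * pi * outer(times, ln$frequency_hz)) %*% ln$amplitude_v)
}

#' Time-domain signal energy over one period
#'
#' Returns twice the mean square of the ideal waveform over one period, the
#' scaling under which the spectral convention \eqn{P_n = A_n^2} and the time
#' domain agree (Parseval): a unit sinusoid gives 1, a unit rectangular wave
#' gives 2 — the square wave carries twice the energy of a sinusoid of equal
#' peak amplitude.
#'
#' @param spec A [waveform_spec()].
#' @return Energy in V^2.
#' @export
time_domain_energy <- function(spec) {
  stopifnot(inherits(spec, "waveform_spec"))
  # mean squares: V0^2/2 (sine), V0^2 (square); reported with the factor 2
  switch(spec$shape, sine = spec$v0^2, rectangular = 2 * spec$v0^2)
}

#' Write / read a spectrum table as CSV
#'
#' The on-disk format has columns `order`, `frequency_hz`, `amplitude_v`,
#' `energy_v2`. `read_spectrum()` restores a `harmonic_spectrum` usable by
#' [decompose_force()]; the source waveform shape/V0/f0 are recovered from a
#' header comment line.
#'
#' @param spectrum A [harmonic_spectrum()].
#' @param path File path.
#' @return `write_spectrum()` returns `path` invisibly; `read_spectrum()`
#'   returns a `harmonic_spectrum`.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "harmonic_spectrum"))
  en <- spectral_energy(spectrum)$per_line
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# depwave spectrum shape=%s v0=%.17g f0=%.17g truncation=%d bandwidth=%s model=%s",
                     spectrum$source$shape, spectrum$source$v0,
                     spectrum$source$f0, spectrum$truncation,
                     if (is.null(spectrum$bandwidth_limit)) "none"
                     else sprintf("%.17g", spectrum$bandwidth_limit),
                     if (is.null(spectrum$bandwidth_model)) "none"
                     else spectrum$bandwidth_model), con)
  # %.17g keeps doubles bit-exact through a parse/serialise round trip
  txt <- data.frame(order = en$order,
                    frequency_hz = sprintf("%.17g", en$frequency_hz),
                    amplitude_v = sprintf("%.17g", en$amplitude_v),
                    energy_v2 = sprintf("%.17g", en$energy_v2))
  utils::write.csv(txt, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "# depwave spectrum"))
    stop("not a depwave spectrum CSV: ", path, call. = FALSE)
  kv <- strsplit(strsplit(sub("^# depwave spectrum ", "", hdr), " ")[[1]], "=")
  meta <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  spec <- waveform_spec(meta[["shape"]], as.numeric(meta[["v0"]]),
                        as.numeric(meta[["f0"]]))
  bw <- if (identical(meta[["bandwidth"]], "none")) NULL
        else as.numeric(meta[["bandwidth"]])
  sp <- harmonic_spectrum(spec, max_order = as.integer(meta[["truncation"]]),
                          bandwidth_limit = bw,
                          bandwidth_model = if (is.null(bw)) "brickwall"
                                            else meta[["model"]])
  tab <- utils::read.csv(path, comment.char = "#")
  # the stored amplitudes are authoritative (they may have been edited)
  sp$lines <- tab[, c("order", "frequency_hz", "amplitude_v")]
  sp
}
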