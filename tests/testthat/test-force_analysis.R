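test_that("flat dispersion doubles the force of an equal-peak sinusoid", {
  for (s in c(-1, 1)) {
    sys <- flat_system(sign = s)
    sp <- harmonic_spectrum(waveform_spec("rectangular", 1, 1e4),
                            max_order = 199)
    dec <- decompose_force(sys, sp, field_gradient = 1e12)
    expect_equal(dec$total / dec$sine_baseline, 2, tolerance = 1e-12)
    # without the spectral tail the ratio is the truncated energy ratio
    dec0 <- decompose_force(sys, sp, field_gradient = 1e12, tail = "none")
    k <- (sp$truncation + 1) %/% 2
    expect_equal(dec0$total / dec0$sine_baseline,
                 16 / pi^2 * odd_harmonic_sum(k), tolerance = 1e-12)
  }
})

test_that("a single-line sine spectrum reproduces the sine baseline", {
  sys <- ps_water_system()
  sp <- harmonic_spectrum(waveform_spec("sine", 5, 2e4), max_order = 50)
  dec <- decompose_force(sys, sp, field_gradient = 3e11)
  expect_equal(dec$total, dec$sine_baseline)
  expect_equal(dec$positive_sum, 0)
  expect_equal(dec$negative_sum, 0)
  expect_error(decompose_force(sys, sp, field_gradient = 0), "field_gradient")
})

test_that("above the cross-over every harmonic deepens the nDEP force", {
  sys <- crossover_system(4e4)
  dec <- decompose_force(sys,
                         harmonic_spectrum(waveform_spec("rectangular", 1, 3.5e5)),
                         field_gradient = 1e12)
  expect_true(all(dec$contributions$force_n[dec$contributions$amplitude_v > 0] < 0))
  expect_equal(dec$positive_sum, 0)
  expect_lt(dec$negative_sum, 0)
  expect_lt(dec$total, dec$sine_baseline)          # both negative, total deeper
  expect_gt(abs(dec$total), abs(dec$sine_baseline))
})

test_that("cross-over between the third and fifth harmonic splits the signs", {
  # fco = 4 f0: fundamental and order 3 aid pDEP, orders >= 5 oppose it
  sys <- crossover_system(4e4)
  dec <- decompose_force(sys,
                         harmonic_spectrum(waveform_spec("rectangular", 1, 1e4)),
                         field_gradient = 1e12)
  ctb <- dec$contributions
  expect_gt(ctb$force_n[ctb$order == 1], 0)
  expect_gt(ctb$force_n[ctb$order == 3], 0)
  odd_hi <- ctb$order >= 5 & ctb$order %% 2 == 1
  expect_true(all(ctb$force_n[odd_hi] < 0))
  expect_gt(dec$positive_sum, 0)
  expect_lt(dec$negative_sum, 0)
})

test_that("decomposition bookkeeping: total = fundamental + A + B, A >= 0 >= B", {
  set.seed(404)
  for (i in 1:1000) {
    sys <- random_system()
    f0 <- 10^stats::runif(1, 2, 7)
    sp <- harmonic_spectrum(waveform_spec("rectangular", 1, f0),
                            max_order = 49)
    dec <- decompose_force(sys, sp, field_gradient = 1e10,
                           tail = sample(c("plateau", "none"), 1))
    expect_gte(dec$positive_sum, 0)
    expect_lte(dec$negative_sum, 0)
    expect_equal(dec$total,
                 dec$fundamental + dec$positive_sum + dec$negative_sum,
                 tolerance = 1e-12)
  }
})

test_that("gain ratio tends to 2 as the dispersion flattens", {
  # conductivity ratio approaches the permittivity ratio => CM flattens
  err <- sapply(10^-(1:6), function(delta) {
    sys <- particle_system(dielectric_material(40, 1e-3 * (0.5 + delta)),
                           dielectric_material(80, 1e-3), 1e-6)
    dec <- decompose_force(sys,
                           harmonic_spectrum(waveform_spec("rectangular", 1, 1e4)),
                           field_gradient = 1e12)
    abs(dec$total / dec$sine_baseline - 2)
  })
  expect_true(all(diff(err) < 0))
  expect_lt(err[6], 1e-5)
})

test_that("the energy rule is sound where opposing harmonics are no stronger than the fundamental", {
  set.seed(505)
  checked <- 0L
  attempts <- 0L
  while (checked < 50L && (attempts <- attempts + 1L) < 5000L) {
    sys <- random_system()
    co <- crossover_frequency(sys)
    if (!co$exists) next
    f0 <- co$fco / stats::runif(1, 5.5, 50)
    rep <- advise(sys, f0 = f0, field_gradient = 1e12)
    expect_identical(rep$energy_rule, "beneficial")
    ctb <- rep$decomposition$contributions
    opposing <- sign(ctb$re_cm) != sign(ctb$re_cm[1]) & ctb$amplitude_v > 0
    if (any(abs(ctb$re_cm[opposing]) > abs(ctb$re_cm[1]))) next
    expect_true(rep$beneficial_exact)
    expect_gt(rep$gain_ratio, 1)
    checked <- checked + 1L
  }
  expect_gte(checked, 50L)
})

test_that("adding same-sign harmonics never weakens the total force", {
  sys <- crossover_system(4e4)
  f0 <- 3.5e5  # above fco: all lines share the nDEP sign
  totals <- sapply(seq(1, 51, by = 2), function(mo)
    abs(decompose_force(sys,
                        harmonic_spectrum(waveform_spec("rectangular", 1, f0),
                                          max_order = mo),
                        field_gradient = 1e12, tail = "none")$total))
  expect_true(all(diff(totals) >= 0))
})

test_that("advisor reproduces the three benchmark scenarios", {
  # trapping filter: fco ~ 260 kHz, drive at 15 kHz -> guaranteed beneficial
  filt <- crossover_system(2.6e5)
  r1 <- advise(filt, f0 = 1.5e4, field_gradient = 1e12)
  expect_identical(r1$energy_rule, "beneficial")
  expect_equal(r1$boundary_frequency, 2.6e5 / 5, tolerance = 1e-9)
  expect_true(r1$beneficial_exact)

  # focusing cell: fco ~ 40 kHz, drive at 10 kHz -> inconclusive rule,
  # mixed-sign decomposition decides
  foc <- crossover_system(4e4)
  r2 <- advise(foc, f0 = 1e4, field_gradient = 1e12)
  expect_identical(r2$energy_rule, "not_guaranteed")
  ctb <- r2$decomposition$contributions
  expect_gt(ctb$force_n[ctb$order == 3], 0)
  expect_lt(ctb$force_n[ctb$order == 5], 0)

  # far above the cross-over -> always beneficial (all-nDEP harmonics)
  r3 <- advise(foc, f0 = 3.5e5, field_gradient = 1e12)
  expect_identical(r3$energy_rule, "always_beneficial")
  expect_true(r3$beneficial_exact)
  expect_gt(r3$gain_ratio, 1)

  # no cross-over at all -> always beneficial as well
  up <- particle_system(dielectric_material(80, 1e-3),
                        dielectric_material(40, 1e-4), 1e-6)
  expect_identical(advise(up, 1e4, field_gradient = 1e12)$energy_rule,
                   "always_beneficial")
  expect_error(advise(filt, f0 = -1), "f0")
})

test_that("smallest_safe_divisor matches a brute-force scan of the energy ledger", {
  expect_identical(smallest_safe_divisor(0.5), 5L)
  expect_identical(smallest_safe_divisor(0.47), 3L)
  expect_error(smallest_safe_divisor(0), "between 0 and 1")
  expect_error(smallest_safe_divisor(1), "between 0 and 1")

  brute <- function(th) {
    m <- seq(3, 2e5, by = 2)
    cum <- cumsum(1 / m^2)
    m[which(cum >= th * (pi^2 / 8 - 1))[1]]
  }
  for (th in c(0.1, 0.3, 0.5, 0.9, 0.999))
    expect_equal(smallest_safe_divisor(th), brute(th))
})
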