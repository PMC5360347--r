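# Single-stimulus PRC measurement, normal form, fitting and the c(g)
# calibration.

test_that("zero conductance produces identically zero resetting", {
  cfg <- ref_network()
  tb <- measure_prc(cfg$neurons$n2, excitatory_synapse(0), cfg$neurons$n1,
                    phases = c(0.1, 0.3, 0.5, 0.7, 0.9))
  expect_lt(max(abs(tb$F)), 1e-5)
})

test_that("measured PRCs respect the sign convention", {
  prcs <- ref_prcs()
  # excitation only advances (F <= 0), inhibition only delays (F >= 0)
  expect_lt(max(prcs$F2_exc$F), 1e-6)
  expect_lt(max(prcs$F3$F), 1e-6)
  expect_gt(min(prcs$F2_inh$F), -1e-6)
  # the perturbed period always stays positive
  expect_true(all(prcs$F3$F > -1))
})

test_that("normal-form evaluation follows the amplitude convention", {
  nf <- normal_form_prc(c = -0.12, Pi = 70)
  expect_identical(normal_form_value(nf, 0), 0)
  expect_equal(normal_form_value(nf, 0.5), 2 * -0.12)
  expect_identical(normal_form_value(normal_form_prc(0, 70), 0.37), 0)
  # 1-periodicity
  expect_equal(normal_form_value(nf, 1.25), normal_form_value(nf, 0.25))
})

test_that("normal-form fit recovers known amplitudes", {
  tb <- make_fixture("prc_table", amplitude = -0.0815, Pi = 70, sigma = 0)
  fit <- fit_normal_form(tb)
  expect_equal(fit$c, -0.0815, tolerance = 1e-10)
  expect_lt(attr(fit, "rms"), 1e-12)
  zero <- prc_table(seq(0.1, 0.9, length.out = 9), rep(0, 9), Pi = 60)
  expect_identical(fit_normal_form(zero)$c, 0)
})

test_that("coupling calibration is exact on affine data and guards inputs", {
  g <- c(0.004, 0.01, 0.02, 0.05)
  cal <- calibrate_coupling_map(g, -6.2 * g + 0.001)
  expect_equal(cal$slope, -6.2, tolerance = 1e-12)
  expect_equal(cal$intercept, 0.001, tolerance = 1e-12)
  expect_equal(coupling_c(cal, 0.03), -6.2 * 0.03 + 0.001)
  expect_error(calibrate_coupling_map(0.01, -0.06), "insufficient points")
  expect_error(calibrate_coupling_map(c(0.01, 0.01, 0.01), c(1, 2, 3)),
               "insufficient points")
})

test_that("PRC slopes match the analytic normal form and a finite-difference oracle", {
  nf <- normal_form_prc(c = -0.09, Pi = 70)
  expect_equal(prc_slope(nf, 0.25), 2 * pi * -0.09)
  expect_equal(prc_slope(nf, 0), 0)
  expect_equal(prc_slope(nf, 0.5), 0, tolerance = 1e-12)
  # spline slope on a measured table vs central finite difference (h = 1e-3)
  tb <- ref_prcs()$F3
  for (phi in c(0.2, 0.4, 0.6, 0.8)) {
    h <- 1e-3
    fd <- (prc_value(tb, phi + h) - prc_value(tb, phi - h)) / (2 * h)
    expect_equal(prc_slope(tb, phi), fd, tolerance = 0.01)
  }
  expect_error(prc_slope(tb, 0.999), "refusing to extrapolate")
})

test_that("weak-coupling tables vanish at the cycle end points", {
  cfg <- ref_network()
  tb <- measure_prc(cfg$neurons$n2, excitatory_synapse(0.004), cfg$neurons$n1,
                    phases = c(0.02, 0.25, 0.5, 0.75, 0.98))
  expect_lt(abs(tb$F[1]), 0.02)
  expect_lt(abs(tb$F[nrow(tb)]), 0.02)
})

test_that("measured resetting depends appreciably on the stimulus waveform", {
  cfg <- ref_network()
  phases <- seq(0.3, 0.7, length.out = 5)
  syn <- excitatory_synapse(0.0275)
  tb_syn <- measure_prc(cfg$neurons$n3, syn, cfg$neurons$n2, phases = phases)
  tb_tri <- measure_prc(cfg$neurons$n3, syn, phases = phases,
                        template = triangular_template(rise = 3, fall = 3))
  # same synapse, different presynaptic waveform: mid-cycle resettings move
  # by several percent of their magnitude, so mode predictions inherit the
  # stimulus protocol
  expect_gt(max(abs(tb_syn$F - tb_tri$F)), 0.005)
})

test_that("fitted amplitude magnitude grows with conductance", {
  cfg <- ref_network()
  gs <- c(0.004, 0.008, 0.012)
  phases <- seq(0.05, 0.95, length.out = 19)
  cs <- vapply(gs, function(g) {
    tb <- measure_prc(cfg$neurons$n2, excitatory_synapse(g), cfg$neurons$n1,
                      phases = phases)
    fit_normal_form(tb)$c
  }, numeric(1))
  expect_true(all(diff(abs(cs)) > 0))
  # and the c(g) relation is close to proportional in this regime
  cal <- calibrate_coupling_map(gs, cs)
  expect_lt(abs(cal$intercept), 0.01)
})
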