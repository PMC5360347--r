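# Model core: derivatives, integration, spike detection, period measurement
# and bias calibration.

test_that("gating derivatives vanish at their fixed points", {
  p <- ml_neuron()
  # at V = Vw_half the steady state is exactly 1/2, so w = 1/2 is a fixed point
  d <- ml_derivatives(c(V = p$Vw_half, w = 0.5), p)
  expect_identical(unname(d[2]), 0)
  # a passive membrane with no currents at all does not move
  p0 <- ml_neuron(gCa = 0, gK = 0, gLeak = 0, I0 = 0)
  d0 <- ml_derivatives(c(V = -0.2, w = 0.3), p0, i_syn = 0)
  expect_identical(unname(d0[1]), 0)
  # synaptic current is subtracted from dV/dt
  d1 <- ml_derivatives(c(V = -0.2, w = 0.3), ml_neuron(), i_syn = 0.05)
  d2 <- ml_derivatives(c(V = -0.2, w = 0.3), ml_neuron(), i_syn = 0)
  expect_equal(unname(d1[1] - d2[1]), -0.05)
})

test_that("synapse kinetics have the expected limits and midpoint", {
  syn <- synapse(0.01)
  expect_equal(transmitter_release(syn$T_half, syn), 0.5)
  # saturated release with all channels open: pure closing at rate beta
  expect_equal(synapse_derivative(1, v_pre = 2, syn), -syn$beta_off,
               tolerance = 1e-6)
  # no release, no open channels: nothing happens
  expect_equal(synapse_derivative(0, v_pre = -2, syn), 0, tolerance = 1e-12)
})

test_that("integrate_system reproduces closed forms and degenerate inputs", {
  harm <- function(t, y) c(y[2], -y[1])
  tr <- integrate_system(harm, c(x = 1, y = 0), duration = 2 * pi,
                         dt = 2 * pi / 1000)
  expect_equal(unlist(tr[nrow(tr), c("x", "y")]), c(x = 1, y = 0),
               tolerance = 1e-6)
  tr0 <- integrate_system(harm, c(x = 1, y = 0), duration = 0)
  expect_equal(nrow(tr0), 1)
  expect_equal(tr0$x, 1)
})

test_that("compiled and R right-hand sides integrate to the same trajectory", {
  n <- ml_neuron()
  rhs <- function(t, y) ml_derivatives(y, n)
  tr_r <- integrate_system(rhs, c(V = -0.3, w = 0.1), duration = 150)
  tr_c <- simulate_neuron(n, 150)
  expect_equal(tr_r$V, tr_c$V, tolerance = 1e-5)
  sp_r <- detect_spikes(tr_r)
  sp_c <- detect_spikes(tr_c)
  expect_equal(length(sp_r), length(sp_c))
  expect_equal(as.numeric(sp_r), as.numeric(sp_c), tolerance = 1e-4)
})

test_that("spike detection interpolates crossings and is idempotent", {
  T <- 10
  tt <- seq(0, 35, by = 0.02)
  tr <- data.frame(time = tt, V = sin(2 * pi * tt / T))
  sp <- detect_spikes(tr)
  expect_equal(as.numeric(sp), c(T, 2 * T, 3 * T), tolerance = 1e-3)
  expect_identical(as.numeric(detect_spikes(tr)), as.numeric(sp))
  # constant subthreshold trace has no crossings
  expect_length(detect_spikes(data.frame(time = 0:10, V = rep(-0.3, 11))), 0)
  # exact two-sample linear interpolation
  expect_equal(as.numeric(detect_spikes(data.frame(time = c(1, 2),
                                                   V = c(-0.1, 0.1)))), 1.5)
})

test_that("free-running period is stationary and initial-condition invariant", {
  n <- ml_neuron()  # I0 = 0.070
  p <- intrinsic_period(n)
  expect_gt(p$period, 0)
  expect_lt(p$spread / p$period, 1e-3)
  # doubling the horizon does not move the period beyond its spread
  p2 <- intrinsic_period(n, horizon = 3200)
  expect_lt(abs(p2$period - p$period), p$spread + p2$spread + 1e-6)
  # two different initial conditions agree to < 0.5 %
  pa <- intrinsic_period(n, init = c(V = -0.05, w = 0.4))$period
  expect_lt(abs(pa - p$period) / p$period, 0.005)
})

test_that("period decreases with bias current and quiescence is reported", {
  periods <- vapply(c(0.070, 0.071, 0.073),
                    function(I0) intrinsic_period(ml_neuron(I0 = I0))$period,
                    numeric(1))
  expect_true(all(diff(periods) < 0))
  expect_error(intrinsic_period(ml_neuron(I0 = 0.05), horizon = 400),
               "not oscillating")
})

test_that("bias calibration round-trips and rejects unreachable targets", {
  n <- ml_neuron()
  target <- intrinsic_period(n)$period
  I0 <- calibrate_bias(n, target)
  expect_equal(I0, 0.070, tolerance = 1e-3)
  # three-period calibration hits each target within 0.05 time units
  cfg <- ref_network()
  for (i in 1:3) {
    got <- intrinsic_period(cfg$neurons[[i]])$period
    expect_lt(abs(got - c(60, 70, 80)[i]), 0.05)
  }
  expect_error(calibrate_bias(n, 10), "target unreachable")
})

test_that("gating variable stays within [0, 1] along trajectories", {
  tr <- simulate_neuron(ml_neuron(), 400, init = c(V = 0.2, w = 0.9))
  expect_true(all(tr$w >= 0 & tr$w <= 1))
})
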