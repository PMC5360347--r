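# Closed-loop simulation, timing extraction, convergence and comparison.

test_that("timing extraction recovers constructed offsets exactly", {
  fx <- make_fixture("spike_trains", period = 60, offsets = c(15, 40),
                     n_cycles = 40)
  m <- extract_mode(fx, discard = 5)
  expect_true(m$converged)
  expect_equal(m$t2sa, 15)
  expect_equal(m$t2sb, 40)
  expect_equal(m$t2r, 20)
  expect_equal(m$period, 60)
})

test_that("pattern mismatches are rejected", {
  fx <- make_fixture("spike_trains", n_cycles = 40)
  fx$n3 <- spike_train(as.numeric(fx$n3)[-25])  # drop one interneuron spike
  expect_error(extract_mode(fx, discard = 5), "pattern mismatch")
})

test_that("convergence criterion follows its definition", {
  const <- rep(3.2, 30)
  cc <- check_convergence(const)
  expect_true(cc$converged)
  expect_equal(cc$value, 3.2)
  # period-2 alternation larger than the tolerance never converges
  alt <- 10 + rep(c(-0.2, 0.2), 15)
  expect_false(check_convergence(alt, tol = 0.05)$converged)
  # geometric decay converges once the residual range is inside tol
  L <- 15; A <- 3.2; r <- 0.5; tol <- 0.05
  x <- L + A * r^(seq_len(25))
  cc <- check_convergence(x, tol = tol, window = 10)
  expect_true(cc$converged)
  expect_equal(cc$value, L, tolerance = tol)
})

test_that("prediction comparison reports absolute and percent errors", {
  fx <- make_fixture("spike_trains", period = 60, offsets = c(15.2, 40.2),
                     n_cycles = 40)
  meas <- extract_mode(fx, discard = 5)
  cmp <- compare_prediction(meas, phase_locked_mode(18.0, 44.1, 60))
  expect_equal(cmp$pct_error[cmp$quantity == "t2sa"], 18.42, tolerance = 0.01)
  expect_equal(cmp$pct_error[cmp$quantity == "t2sb"], 9.70, tolerance = 0.01)
  same <- compare_prediction(meas, phase_locked_mode(15.2, 40.2, 60))
  expect_equal(same$pct_error, c(0, 0), tolerance = 1e-10)
  meas$converged <- FALSE
  expect_error(compare_prediction(meas, phase_locked_mode(18, 44.1, 60)),
               "not converged")
})

test_that("uncoupled network fires at the calibrated intrinsic periods", {
  cfg <- ref_network()
  cfg$g12 <- 0; cfg$g23 <- 0; cfg$g32 <- 0
  set.seed(5)
  sim <- simulate_network(cfg, n_cycles = 40)
  targets <- c(60, 70, 80)
  for (i in 1:3) {
    isi <- diff(as.numeric(sim$trains[[i]]))
    p <- mean(utils::tail(isi, 10))
    expect_lt(abs(p - targets[i]) / targets[i], 0.001)
  }
})

test_that("coupled simulation satisfies the per-cycle timing identities", {
  sim <- ref_sim()
  meas <- ref_measurement()
  expect_true(meas$converged)
  # the network entrains to the master period
  expect_equal(meas$period, 60, tolerance = 0.1)
  s1 <- as.numeric(sim$trains$n1)
  s3 <- as.numeric(sim$trains$n3)
  cyc <- meas$cycles
  n <- nrow(cyc)
  # master period identity: P1 = t2r[n-1] + t2sb[n]
  p1_steady <- mean(utils::tail(diff(s1), 10))
  lhs <- cyc$t2r[-n] + cyc$t2sb[-1]
  expect_true(all(abs(utils::tail(lhs, 10) - p1_steady) < 0.1))
  # interneuron period identity:
  # P3 = t2sb[n] - t2sa[n] + t2r[n] + t2sa[n+1]
  p3_steady <- mean(utils::tail(diff(s3), 10))
  lhs3 <- cyc$t2sb[-n] - cyc$t2sa[-n] + cyc$t2r[-n] + cyc$t2sa[-1]
  expect_true(all(abs(utils::tail(lhs3, 10) - p3_steady) < 0.1))
})

test_that("the converged mode is seed independent and recovers from perturbation", {
  meas <- ref_measurement()
  set.seed(202)
  sim2 <- simulate_network(ref_network(), n_cycles = 70)
  meas2 <- extract_mode(sim2)
  expect_equal(meas2$t2sa, meas$t2sa, tolerance = 0.05)
  expect_equal(meas2$t2sb, meas$t2sb, tolerance = 0.05)
  # transient perturbation of the slave's inhibition decays back to the same
  # mode, consistent with the linear stability verdict
  y <- ref_sim()$final_state
  y[8] <- 0.6   # s32 kicked hard
  sim3 <- simulate_network(ref_network(), n_cycles = 45, init = y)
  meas3 <- extract_mode(sim3, discard = 25)
  expect_true(meas3$converged)
  expect_equal(meas3$t2sa, meas$t2sa, tolerance = 0.05)
  expect_equal(meas3$t2sb, meas$t2sb, tolerance = 0.05)
})

test_that("sub-threshold feedback coupling fails to entrain the interneuron", {
  cfg <- ref_network()
  cfg$g23 <- 0.005   # well under the minimum-coupling threshold
  set.seed(9)
  sim <- simulate_network(cfg, n_cycles = 50)
  n1 <- length(sim$trains$n1)
  n3 <- length(sim$trains$n3)
  expect_gt(abs(n3 / n1 - 1), 0.05)
  # synaptic gating variables stay within [0, 1]
  set.seed(9)
  tr <- simulate_network(cfg, n_cycles = 6, keep_traces = TRUE)$traces
  expect_true(all(tr$s12 >= 0 & tr$s12 <= 1))
  expect_true(all(tr$s23 >= 0 & tr$s23 <= 1))
  expect_true(all(tr$s32 >= 0 & tr$s32 <= 1))
})
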