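# Existence of phase-locked modes: fixed points, closed form, bounds,
# minimum coupling and the solution surface.

test_that("equal master and interneuron periods lock at multiples of the period", {
  nf <- normal_form_prc(-0.2, 60)
  roots <- solve_t2sa(nf, P1i = 60, P3i = 60)
  expect_true(any(abs(roots$t2sa - 60) < 1e-6))
  expect_true(any(abs(roots$t2sa - 0) < 1e-6))
  an <- analytic_t2sa(-0.2, 60, 60)
  expect_true(any(abs(an$t2sa - 60) < 1e-12))
})

test_that("a faster interneuron cannot be entrained by excitation", {
  # excitatory PRC only advances, but entrainment to a slower master would
  # need delays
  expect_error(solve_t2sa(normal_form_prc(-0.2, 70), P1i = 80, P3i = 70),
               "no solution")
  expect_equal(nrow(analytic_t2sa(-0.2, 80, 70)), 0)
})

test_that("strong coupling pushes the lock toward the master period", {
  roots <- solve_t2sa(normal_form_prc(-500, 80), P1i = 60, P3i = 80)
  expect_lt(abs(max(roots$t2sa) - 60), 0.5)
})

test_that("closed-form and numeric interneuron fixed points agree on random cases", {
  set.seed(11)
  n_ok <- 0
  while (n_ok < 100) {
    c23 <- -runif(1, 0.05, 0.5)
    P3i <- runif(1, 62, 110)
    an <- analytic_t2sa(c23, 60, P3i)
    if (!nrow(an)) next   # nonexistent: coupling too weak for this ratio
    nm <- solve_t2sa(normal_form_prc(c23, P3i), 60, P3i, n = 4000)
    expect_equal(sort(nm$t2sa), sort(an$t2sa), tolerance = 1e-6)
    n_ok <- n_ok + 1
  }
})

test_that("existence bounds on the interneuron period follow the PRC minimum", {
  b <- existence_bounds(-0.25, 60)
  expect_equal(unname(b), c(60, 80))
  expect_equal(unname(existence_bounds(-0.5, 60)), c(60, 120))
  # non-negative minimum (no advance capacity): empty open interval
  b0 <- existence_bounds(0, 60)
  expect_lte(b0["upper"], b0["lower"])
})

test_that("the slave fixed point reduces to the single-input case when the inhibition is idle", {
  F2e <- normal_form_prc(-0.12, 70)
  zero <- function(phi) 0
  sb <- solve_t2sb(zero, F2e, P1i = 60, P2i = 70, t2sa = 10)
  expect_equal(attr(sb, "alpha"), 1)
  ## oracle: invert the single-input condition analytically
  rhs <- 1 - (60 / 70 - 1) / -0.12
  phis <- c(acos(rhs) / (2 * pi), 1 - acos(rhs) / (2 * pi))
  expected <- 70 * phis
  expected <- expected[expected > 10 & expected < 60]
  expect_equal(sort(sb$t2sb), sort(expected), tolerance = 1e-8)
})

test_that("unsolvable and degenerate slave conditions are reported", {
  zero <- function(phi) 0
  expect_error(solve_t2sb(zero, zero, P1i = 60, P2i = 70, t2sa = 10),
               "no solution")
  expect_error(solve_t2sb(zero, zero, P1i = 70, P2i = 70, t2sa = 10),
               "degenerate")
})

test_that("found modes satisfy both steady-state conditions when re-evaluated", {
  cfg <- ref_network()
  prcs <- ref_prcs()
  modes <- find_modes(prcs$F2_inh, prcs$F2_exc, prcs$F3,
                      cfg$P1i, cfg$P2i, cfg$P3i)
  expect_gte(length(modes), 1)
  for (m in modes) {
    comp <- compose_two(prcs$F2_inh, prcs$F2_exc, m$t2sa, m$t2sb, cfg$P2i)
    expect_lt(abs(cfg$P2i * (1 + comp$F) - cfg$P1i), 1e-7)
    expect_lt(abs(cfg$P3i * (1 + prc_value(prcs$F3, (cfg$P1i - m$t2sa) / cfg$P3i)) -
                    cfg$P1i), 1e-7)
    # recovery time is pinned by construction
    expect_identical(m$t2r, cfg$P1i - m$t2sb)
  }
})

test_that("minimum coupling reproduces the saturation thresholds", {
  cal <- ref_c23_line()
  expect_equal(minimum_coupling(1.5, cal), 0.024, tolerance = 0.01)
  expect_equal(minimum_coupling(2, cal), 0.036, tolerance = 0.01)
  # threshold grows with the period ratio
  expect_lt(minimum_coupling(1.2, cal), minimum_coupling(1.8, cal))
  # unreachable within the stated conductance range
  expect_identical(minimum_coupling(1.9, cal, g_range = c(0, 0.01)), Inf)
})

test_that("the solution surface respects the existence region and coupling trends", {
  cal <- ref_c23_line()
  s1 <- mode_surface(P3i_values = c(55, 62, 75, 90),
                     g23_values = c(0.01, 0.03, 0.06),
                     cal23 = cal, c12 = ref_c12(), c32 = ref_c32())
  # interneuron at or below the master period: no mode
  expect_true(all(!s1$exists[s1$P3i <= 60]))
  # stronger g23 cannot shrink the existence region
  n_weak <- sum(s1$exists[s1$g23 == 0.01])
  n_strong <- sum(s1$exists[s1$g23 == 0.06])
  expect_gte(n_strong, n_weak)
  # stronger master->slave excitation: larger t2sb and a region at least as wide
  s2 <- mode_surface(P3i_values = c(55, 62, 75, 90),
                     g23_values = c(0.01, 0.03, 0.06),
                     cal23 = cal, c12 = -6.1733 * 0.05 - 0.0003, c32 = ref_c32())
  both <- s1$exists & s2$exists
  expect_gte(sum(s2$exists), sum(s1$exists))
  expect_true(all(s2$t2sb[both] > s1$t2sb[both]))
})
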