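test_that("rest is a fixed point and gates stay in [0, 1]", {
  p <- channel_params()
  # settle to rest, then check the membrane currents balance
  prot0 <- clamp_protocol("current", data.frame(duration_ms = 300,
                                                value = 0))
  sim <- current_clamp(p, prot0, rho = 0)
  expect_identical(nrow(sim$spikes), 0L)
  v_end <- tail(sim$trace$v_mv, 1)
  tot <- with(tail(sim$trace, 1), i_na + i_k + i_a + i_leak)
  expect_lt(abs(tot), 1) # pA; ~0 net current at rest
  st <- hh_state(p, v = v_end)
  s2 <- st
  for (i in 1:50) s2 <- step_hh(s2, p, i_inj = 0, dt = 0.01)
  expect_equal(s2$v, st$v, tolerance = 1e-2)
  # gates bounded through a strong protocol
  prot <- clamp_protocol("current", data.frame(duration_ms = 200,
                                               value = 60))
  for (rho in c(0, 0.5, 1)) {
    tr <- current_clamp(p, prot, rho = rho)$trace
    expect_true(all(is.finite(tr$v_mv)))
  }
})

test_that("a depolarising clamp step separates transient from sustained A-current", {
  prot <- clamp_protocol("voltage",
                         data.frame(duration_ms = c(50, 150),
                                    value = c(-90, 40)),
                         holding = -90)
  tr0 <- voltage_clamp(protocol = prot, rho = 0)
  tr1 <- voltage_clamp(protocol = prot, rho = 1)
  step0 <- dplyr::filter(tr0, .data$time_ms >= 50)
  step1 <- dplyr::filter(tr1, .data$time_ms >= 50)
  # inactivating: decays to a low plateau well below its peak
  expect_lt(tail(step0$i_a, 1), 0.05 * max(step0$i_a))
  # non-inactivating: sustained near its peak
  expect_gt(tail(step1$i_a, 1), 0.95 * max(step1$i_a))
  # rho = 1 removes any dependence on the inactivation state
  expect_equal(tail(step1$i_a, 1), max(step1$i_a), tolerance = 1e-6)
  # peak equality when inactivation is effectively frozen at 1
  frozen <- channel_params(tau_ha = 1e6)
  f0 <- voltage_clamp(frozen, prot, rho = 0)
  f1 <- voltage_clamp(frozen, prot, rho = 1)
  expect_equal(max(f0$i_a), max(f1$i_a), tolerance = 0.03)
})

test_that("removing A-type inactivation raises the firing rate at 20 pA", {
  prot <- clamp_protocol("current", data.frame(duration_ms = 500,
                                               value = 20))
  s0 <- current_clamp(protocol = prot, rho = 0)
  s1 <- current_clamp(protocol = prot, rho = 1)
  expect_gt(nrow(s1$spikes), nrow(s0$spikes))
  expect_lt(mean(diff(s1$spikes$time_ms)), mean(diff(s0$spikes$time_ms)))
  # firing rate nondecreasing in rho over a grid
  counts <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(r)
    nrow(current_clamp(protocol = prot, rho = r)$spikes), 0L)
  expect_true(all(diff(counts) >= 0))
  # slowed-inactivation mode shows the same ordinal effect
  slow <- channel_params(rho_mode = "slow_tau")
  t0 <- current_clamp(slow, prot, rho = 0)
  t1 <- current_clamp(slow, prot, rho = 1)
  expect_gt(nrow(t1$spikes), nrow(t0$spikes))
})

test_that("without the A-conductance rho has no effect (ablation)", {
  p <- channel_params(g_a = 0)
  prot <- clamp_protocol("current", data.frame(duration_ms = 300,
                                               value = 20))
  s0 <- current_clamp(p, prot, rho = 0)
  s1 <- current_clamp(p, prot, rho = 1)
  expect_identical(s0$spikes$time_ms, s1$spikes$time_ms)
  expect_equal(s0$trace$v_mv, s1$trace$v_mv, tolerance = 1e-12)
})

test_that("halving dt moves spike times by less than 0.1 ms", {
  prot <- clamp_protocol("current", data.frame(duration_ms = 150,
                                               value = 20))
  a <- current_clamp(protocol = prot, rho = 1, dt = 0.01)
  b <- current_clamp(protocol = prot, rho = 1, dt = 0.005)
  n <- min(nrow(a$spikes), nrow(b$spikes))
  expect_identical(nrow(a$spikes), nrow(b$spikes))
  expect_lt(max(abs(a$spikes$time_ms[1:n] - b$spikes$time_ms[1:n])), 0.1)
})

test_that("the ROS-to-rho relay is a saturating monotone map from zero", {
  expect_identical(ros_to_rho(0), 0)
  expect_gt(ros_to_rho(1e6), 0.999)
  grid <- seq(0, 5, by = 0.1)
  expect_true(all(diff(ros_to_rho(grid)) >= 0))
  expect_true(all(ros_to_rho(grid) >= 0 & ros_to_rho(grid) < 1))
  expect_error(ros_to_rho(-1), "ros")
})

test_that("ROS-curve shifts emulate the optogenetic manipulations", {
  curve <- ros_vs_baseline_curve(baseline_grid = seq(0.01, 0.08,
                                                     length.out = 8))
  expect_identical(shifted_ros_curve(curve, 0)$ros_ss, curve$ros_ss)
  up <- shifted_ros_curve(curve, 0.2)    # miniSOG-like
  expect_true(all(up$ros_ss >= curve$ros_ss))
  expect_equal(up$ros_ss, curve$ros_ss + 0.2)
  down <- shifted_ros_curve(curve, -2)   # AOX-like, hits the floor
  expect_true(all(down$ros_ss >= 0))
  expect_true(any(down$ros_ss == 0))
})
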