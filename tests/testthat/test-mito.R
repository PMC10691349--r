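test_that("equilibrium ROS formula matches its closed form at forced points", {
  expect_identical(ros_steady_state(1, 1), 1)
  expect_identical(ros_steady_state(1, 0), 0)
  expect_identical(ros_steady_state(0, 1), 0)
  expect_equal(ros_steady_state(0.5, 0.5), 0.125)
  p <- mito_params(f_ret = 2, f_fet = 0.5)
  expect_equal(ros_steady_state(1, 1, p), 8)
  # symmetry under swapping corners and gains
  ps <- mito_params(f_ret = 0.5, f_fet = 2)
  for (am in c(0.1, 0.3, 0.9)) for (psi in c(0.2, 0.7)) {
    expect_equal(ros_steady_state(am, psi, p),
                 ros_steady_state(1 - am, 1 - psi, ps))
  }
  expect_error(ros_steady_state(1.2, 0.5), "atp_m")
  expect_error(ros_steady_state(0.5, -0.1), "delta_psi")
})

test_that("partial monotonicity of equilibrium ROS in each escape route", {
  grid <- seq(0, 1, by = 0.05)
  ret_only <- mito_params(f_fet = 0)
  fet_only <- mito_params(f_ret = 0)
  for (psi in c(0.2, 0.6, 1)) {
    expect_true(all(diff(ros_steady_state(grid, psi, ret_only)) >= 0))
    expect_true(all(diff(ros_steady_state(grid, psi, fet_only)) <= 0))
  }
})

test_that("ROS relaxation follows the exponential closed form", {
  # fixed point
  expect_equal(relax_ros(0.4, 0.4, tau_ros = 10, dt = 0.01), 0.4)
  # monotone approach, bounded by the target
  traj <- Reduce(function(r, i) relax_ros(r, 1, tau_ros = 10, dt = 0.01),
                 1:5000, accumulate = TRUE, init = 0)
  expect_true(all(diff(traj) >= 0))
  expect_true(all(traj <= 1))
  expect_equal(tail(traj, 1), 1, tolerance = 1e-2)
  # tau = 10 ms, 10 ms of integration from 1 toward 0 -> 1/e
  r <- 1
  for (i in 1:1000) r <- relax_ros(r, 0, tau_ros = 10, dt = 0.01)
  expect_equal(r, exp(-1), tolerance = 1e-8)
  expect_error(relax_ros(1, 0, tau_ros = -1, dt = 0.01), "tau_ros")
})

test_that("parameter and state constructors enforce their invariants", {
  expect_error(mito_params(f_ret = -1), "f_ret")
  expect_error(mito_params(tau_ros = 0), "tau_ros")
  expect_error(mito_params(k_leak = -0.1), "k_leak")
  expect_error(mito_state(atp_m = 1.2), "fractions")
  expect_error(mito_state(ros = -1), ">= 0")
  expect_error(energy_budget(q = -1), "q")
  expect_error(energy_budget(q_kernel_duration = 0), "q_kernel_duration")
})

test_that("one integration step conserves pools and stays in bounds", {
  st <- mito_state()
  for (cons in c(0, 0.02, 0.08)) {
    s2 <- step_mito(st, consumption_rate = cons, dt = 0.01)
    # adenine and NAD pools conserved by representation, exactly
    expect_identical(s2$atp_m + (1 - s2$atp_m), 1)
    expect_identical(s2$nadh + (1 - s2$nadh), 1)
    expect_true(all(unlist(s2[, c("nadh", "delta_psi", "atp_m",
                                  "atp_c")]) >= 0))
    expect_true(all(unlist(s2[, c("nadh", "delta_psi", "atp_m",
                                  "atp_c")]) <= 1))
  }
})

test_that("baseline fixed points sit in the expected corners and are monotone", {
  lo <- find_steady_state(budget = energy_budget(baseline_cost = 0))
  expect_gt(lo$atp_m, 0.95)
  expect_gt(lo$delta_psi, 0.9)
  hi <- find_steady_state(budget = energy_budget(baseline_cost = 0.085))
  expect_lt(hi$atp_m, 0.2)
  expect_lt(hi$delta_psi, 0.3)
  # steady ROS self-consistent with the equilibrium formula
  expect_equal(lo$ros, ros_steady_state(lo$atp_m, lo$delta_psi),
               tolerance = 1e-6)
  # determinism
  lo2 <- find_steady_state(budget = energy_budget(baseline_cost = 0))
  expect_identical(as.data.frame(lo), as.data.frame(lo2))
  # monotone in baseline
  b <- c(0.005, 0.02, 0.04, 0.06, 0.08)
  ss <- lapply(b, function(x)
    find_steady_state(budget = energy_budget(baseline_cost = x)))
  atp <- vapply(ss, function(s) s$atp_m, 0)
  psi <- vapply(ss, function(s) s$delta_psi, 0)
  expect_true(all(diff(atp) <= 0))
  expect_true(all(diff(psi) <= 0))
})

test_that("the steady-state ROS curve is V-shaped with one interior minimum", {
  curve <- ros_vs_baseline_curve(baseline_grid = seq(0.002, 0.09,
                                                     length.out = 50))
  d <- sign(diff(curve$ros_ss))
  n_min <- sum(d[-length(d)] < 0 & d[-1] > 0)
  expect_identical(n_min, 1L)
  mn <- ros_curve_minimum(curve)
  expect_gt(curve$ros_ss[1], mn$ros_ss)
  expect_gt(curve$ros_ss[nrow(curve)], mn$ros_ss)
  # argmin stable under grid refinement (within one coarse grid step)
  fine <- ros_vs_baseline_curve(baseline_grid = seq(0.002, 0.09,
                                                    length.out = 99))
  coarse_step <- diff(curve$baseline)[1]
  expect_lt(abs(ros_curve_minimum(fine)$baseline - mn$baseline),
            coarse_step + 1e-12)
})

test_that("spike excursions dip cytosolic ATP and return to baseline", {
  budget <- energy_budget(baseline_cost = 0.01, q = 0.05)
  tr <- spike_excursion(budget = budget, spike_times = c(50, 150),
                        duration = 800)
  ss <- attr(tr, "steady_state")
  expect_lt(min(tr$atp_c), ss$atp_c)
  endpoint <- unlist(tr[nrow(tr), c("pyr", "nadh", "delta_psi",
                                    "atp_m", "atp_c", "ros")])
  expect_equal(unname(endpoint),
               unname(unlist(ss[1, 1:6])), tolerance = 5e-3)
  # no perturbation -> flat trajectory
  null_budget <- energy_budget(baseline_cost = 0.01, q = 0)
  p0 <- mito_params(ca_coupling = 0)
  tr0 <- spike_excursion(p0, null_budget, spike_times = 50,
                         duration = 100)
  expect_lt(max(abs(tr0$atp_c - tr0$atp_c[1])), 1e-9)
  expect_error(spike_excursion(spike_times = 1000, duration = 100),
               "spike_times")
})

test_that("additional spiking quenches RETROS and worsens FETROS", {
  d_ret <- spike_effect_on_ros(
    budget = energy_budget(baseline_cost = 0.01, q = 0.05),
    rate_hz = 50, duration = 4000, transient = 1500)
  expect_lt(d_ret, 0)
  d_fet <- spike_effect_on_ros(
    budget = energy_budget(baseline_cost = 0.08, q = 0.05),
    rate_hz = 50, duration = 4000, transient = 1500)
  expect_gt(d_fet, 0)
  # vanishing per-spike cost at the ROS minimum -> vanishing effect
  curve <- ros_vs_baseline_curve(baseline_grid = seq(0.04, 0.07,
                                                     length.out = 16))
  b_min <- ros_curve_minimum(curve)$baseline
  d0 <- spike_effect_on_ros(
    mito_params(ca_coupling = 0),
    budget = energy_budget(baseline_cost = b_min, q = 1e-5),
    rate_hz = 20, duration = 2000, transient = 1000)
  expect_lt(abs(d0), 1e-4)
})

test_that("halving dt leaves trajectories unchanged within tolerance", {
  budget <- energy_budget(baseline_cost = 0.02, q = 0.05)
  tr1 <- spike_excursion(budget = budget, spike_times = 20,
                         duration = 100, dt = 0.02, record_every = 50)
  tr2 <- spike_excursion(budget = budget, spike_times = 20,
                         duration = 100, dt = 0.01, record_every = 100)
  e1 <- unlist(tr1[nrow(tr1), -1])
  e2 <- unlist(tr2[nrow(tr2), -1])
  expect_lt(max(abs(e1 - e2)), 1e-6)
})

test_that("out-of-bounds states raise an integration error, not a clip", {
  # a pathological parameter set that overshoots the unit cube
  bad <- mito_params(k_synth = 500, k_etc = 500, n_pump = 50)
  expect_error(
    mito_integrate_cpp(as_mito_vec(mito_state()), mito_par_vec(bad),
                       consumption = rep(0, 1000), psi_kick = numeric(1000),
                       dt = 0.5, record_every = 10L),
    "admissible bounds")
})
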