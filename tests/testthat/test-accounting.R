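test_that("metabolic signal is the ROS-weighted ATP surplus", {
  expect_identical(metabolic_signal(2, 1, 0.5), 1)
  expect_identical(metabolic_signal(0, 0.9, 0.5), 0)
  expect_identical(metabolic_signal(1.5, 0.5, 0.5), 0)
  expect_identical(sign(metabolic_signal(0.3, 0.2, 0.5)), -1)
})

test_that("parameter invariants are enforced", {
  expect_error(accounting_params(theta_ret = -0.2, theta_fet = 0.1),
               "theta_ret")
  expect_error(accounting_params(refractory = 0), "refractory")
})

test_that("single-step gating follows the two-threshold rule", {
  p <- accounting_params()
  # high MS, not refractory, no input -> metabolic spike
  st <- accounting_state(atp = 0.9, ros = 0.9, params = p)
  expect_identical(step_accounting(st, p)$spike, "metabolic")
  # refractory suppresses it
  st_r <- accounting_state(atp = 0.9, ros = 0.9,
                           refractory_remaining = 3, params = p)
  expect_identical(step_accounting(st_r, p)$spike, NA_character_)
  # intermediate MS: no spontaneous spike, but drive passes
  st_mid <- accounting_state(atp = 0.55, ros = 0.5, params = p) # MS 0.025
  expect_identical(step_accounting(st_mid, p)$spike, NA_character_)
  expect_identical(step_accounting(st_mid, p, input_drive = TRUE)$spike,
                   "synaptic")
  # MS below the lower threshold blocks even driven spiking
  st_lo <- accounting_state(atp = 0.1, ros = 0.9, params = p) # MS -0.36
  expect_identical(step_accounting(st_lo, p, input_drive = TRUE)$spike,
                   NA_character_)
})

test_that("no spike is ever emitted below theta_fet; metabolic only above theta_ret", {
  p <- accounting_params()
  drive <- rep(c(TRUE, FALSE), length.out = 30000)
  sim <- simulate_accounting(p, duration = 3000, input = drive,
                             record_every = 1L)
  ms_at <- sim$traces$ms[match(round(sim$spikes$time_ms, 4),
                               round(sim$traces$time_ms, 4))]
  expect_true(all(ms_at > p$theta_fet))
  met <- sim$spikes$label == "metabolic"
  expect_true(all(ms_at[met] > p$theta_ret))
  # refractory bound holds for the merged train
  expect_true(all(diff(sim$spikes$time_ms) >= p$refractory - 1e-9))
})

test_that("high baseline costs silence the neuron even under drive", {
  p <- accounting_params(budget = energy_budget(baseline_cost = 0.09,
                                                q = 0.3,
                                                q_kernel_duration = 20))
  sim <- simulate_accounting(p, duration = 2000,
                             input = rep(TRUE, 20000))
  expect_identical(nrow(sim$spikes), 0L)
})

test_that("per-spike cost shapes the firing pattern as expected", {
  mk <- function(q) accounting_params(
    budget = energy_budget(baseline_cost = 0.01, q = q,
                           q_kernel_duration = 20))
  # expensive spikes: isolated, cheap spikes: merged episodes
  sizes <- lapply(c(0.1, 0.3, 1, 2), function(q) {
    sim <- simulate_accounting(mk(q), duration = 5000)
    episode_sizes(sim$spikes$time_ms)
  })
  mean_sizes <- vapply(sizes, mean, 0)
  # nonincreasing in q, up to counting noise at the single-spike floor
  expect_true(all(diff(mean_sizes) <= 0.05))
  expect_lt(mean_sizes[4], 2.5)              # costly: (near-)single spikes
  expect_gt(mean_sizes[1], 4)                # cheap: multi-spike episodes
})

test_that("shorter refractory raises in-burst rate and slows burst turnover", {
  mk <- function(refr) accounting_params(
    refractory = refr,
    budget = energy_budget(baseline_cost = 0.01, q = 0.15,
                           q_kernel_duration = 20))
  s_short <- simulate_accounting(mk(2), duration = 5000)
  s_long <- simulate_accounting(mk(5), duration = 5000)
  in_burst_rate <- function(sim) {
    isi <- diff(sim$spikes$time_ms)
    1000 / median(isi[isi < 15])
  }
  n_episodes <- function(sim) length(episode_sizes(sim$spikes$time_ms))
  expect_gt(in_burst_rate(s_short), in_burst_rate(s_long))
  expect_lte(n_episodes(s_short), n_episodes(s_long))
})

test_that("metabolic spiking lowers time-averaged ROS at a RETROS baseline", {
  p <- accounting_params()
  on <- simulate_accounting(p, duration = 5000)
  off <- simulate_accounting(p, duration = 5000, spiking_enabled = FALSE)
  expect_gt(nrow(on$spikes), 0)
  expect_lt(mean(on$traces$ros), mean(off$traces$ros))
})

test_that("pattern classifier implements its stated rules", {
  expect_identical(classify_pattern(numeric(0), 1000), "silent")
  # sub-0.1 Hz counts as silent even with a stray spike
  expect_identical(classify_pattern(c(500), 20000), "silent")
  # perfectly periodic, below the continuous cutoff -> tonic
  expect_identical(classify_pattern(seq(10, 990, by = 50), 1000), "tonic")
  # short-ISI runs separated by >= 5x median gaps -> bursting
  bursts <- as.vector(outer(seq(0, 20, by = 5), seq(0, 900, by = 100),
                            `+`))
  expect_identical(classify_pattern(bursts, 1000), "bursting")
  # dense regular train above the rate cutoff -> continuous
  expect_identical(classify_pattern(seq(5, 995, by = 10), 1000),
                   "continuous")
  expect_error(classify_pattern(c(-5, 10), 100), "spikes")
})

test_that("phase diagram covers the firing-pattern spectrum deterministically", {
  pd <- phase_diagram(baseline_grid = seq(0.002, 0.05, length.out = 5),
                      q_grid = c(0.02, 0.3, 2), duration = 4000)
  expect_setequal(unique(pd$label[pd$baseline == 0.05]), "silent")
  expect_true(all(c("continuous", "tonic") %in% pd$label))
  pd2 <- phase_diagram(baseline_grid = seq(0.002, 0.05, length.out = 5),
                       q_grid = c(0.02, 0.3, 2), duration = 4000)
  expect_identical(pd$label, pd2$label)
  # near-FETROS baseline without input is silent
  fet <- phase_diagram(baseline_grid = 0.09, q_grid = 0.3,
                       duration = 2000)
  expect_identical(fet$label, "silent")
})

test_that("the full respiration backend drives the same gating logic", {
  p <- accounting_params(theta_ret = 0.03, theta_fet = -0.03,
                         ros_backend = "mito", atp_bar = 0.95)
  dt <- 0.05
  sim <- simulate_accounting(p, duration = 1500, dt = dt)
  expect_gt(nrow(sim$spikes), 5)
  tr <- reconstruct_mito_trace(sim, p, duration = 1500, dt = dt)
  n <- min(nrow(tr), nrow(sim$traces))
  expect_lt(max(abs(tr[1:n, "ros"] - sim$traces$ros[1:n])), 1e-3)
  expect_lt(max(abs(tr[1:n, "atp_c"] - sim$traces$atp[1:n])), 1e-3)
})
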