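test_that("random wiring matches its Bernoulli construction", {
  cfg <- reduced_network_config()
  net <- build_network(cfg, seed = 11)
  n <- cfg$n_exc + cfg$n_inh
  out_deg <- diff(net$adj_ptr)
  # mean out-degree within 3 binomial SDs
  expected <- cfg$p_connect * (n - 1)
  se <- sqrt(n * cfg$p_connect * (1 - cfg$p_connect) / n)
  expect_lt(abs(mean(out_deg) - expected), 3 * se)
  # no autapses: target never equals source
  for (j in c(1, 250, 1000)) {
    idx <- net$adj_idx[(net$adj_ptr[j] + 1):net$adj_ptr[j + 1]] + 1
    expect_false(j %in% idx)
  }
  # identical seed, identical adjacency
  net2 <- build_network(cfg, seed = 11)
  expect_identical(net$adj_idx, net2$adj_idx)
  expect_error(network_config(p_connect = 1.5), "p_connect")
  expect_error(network_config(im_bound = 0), "im_bound")
})

test_that("the metabolic reservoir relaxes, is charged exactly, and is clamped", {
  cfg <- reduced_network_config()
  # fixed point at rest with no events
  expect_equal(ms_update(cfg$ms_rest, config = cfg), cfg$ms_rest,
               tolerance = 1e-12)
  # closed-form exponential recovery from depletion
  ms <- 0.1
  for (i in 1:2000) ms <- ms_update(ms, config = cfg, dt = 1)
  expect_equal(ms, cfg$ms_rest + (0.1 - cfg$ms_rest) * exp(-2),
               tolerance = 1e-3)
  # heavy load drives it monotonically to the floor, never below
  ms <- cfg$ms_rest
  for (i in 1:200) {
    ms2 <- ms_update(ms, n_exc_events = 50, spiked = TRUE, config = cfg)
    expect_true(ms2 <= ms + 1e-12 && ms2 >= 0)
    ms <- ms2
  }
  expect_identical(ms, 0)
})

test_that("the metabolic current is a clipped monotone map", {
  cfg <- reduced_network_config()
  expect_identical(i_m_from_ms(cfg$ms_neutral, cfg), 0)
  expect_identical(i_m_from_ms(cfg$ms_max, cfg), cfg$im_bound)
  expect_identical(i_m_from_ms(0, cfg), -cfg$im_bound)
  grid <- seq(0, cfg$ms_max, length.out = 41)
  expect_true(all(diff(i_m_from_ms(grid, cfg)) >= 0))
  expect_true(all(abs(i_m_from_ms(grid, cfg)) <= cfg$im_bound))
  expect_error(i_m_from_ms(2, cfg), "ms")
})

test_that("simulations are reproducible and their MS stays bounded", {
  net <- tiny_network(seed = 4)
  a <- simulate_network(net, duration = 600, stim_off = 400, seed = 9)
  b <- simulate_network(net, duration = 600, stim_off = 400, seed = 9)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$traces, b$traces)
  expect_true(all(a$spikes$ms >= 0 & a$spikes$ms <= net$config$ms_max))
  expect_true(all(a$traces$ms >= 0 & a$traces$ms <= net$config$ms_max))
  expect_true(all(a$final_ms >= 0 & a$final_ms <= net$config$ms_max))
})

test_that("metabolic charges reconcile exactly with delivered events", {
  net <- tiny_network(seed = 5)
  cfg <- net$config
  sim <- simulate_network(net, duration = 500, stim_off = 300, seed = 2)
  ct <- sim$counters
  # cumulative decrement = bookkeeping identity over the counters
  expected <- ct$exc_events * cfg$cost_e + ct$inh_events * cfg$cost_i +
    ct$ext_events * cfg$cost_e + ct$spikes * cfg$cost_spike
  expect_equal(sim$cum_cost, expected, tolerance = 1e-9)
  # recurrent event counts re-derived from the raster and adjacency
  n <- cfg$n_exc + cfg$n_inh
  sp_per_neuron <- tabulate(sim$spikes$neuron_id, nbins = n)
  exc_expected <- integer(n)
  inh_expected <- integer(n)
  for (j in seq_len(n)) {
    if (sp_per_neuron[j] == 0 || net$adj_ptr[j] == net$adj_ptr[j + 1])
      next
    idx <- net$adj_idx[(net$adj_ptr[j] + 1):net$adj_ptr[j + 1]] + 1
    if (j <= cfg$n_exc)
      exc_expected[idx] <- exc_expected[idx] + sp_per_neuron[j]
    else
      inh_expected[idx] <- inh_expected[idx] + sp_per_neuron[j]
  }
  # spikes in the final step are never delivered; allow that slack
  expect_lte(sum(abs(ct$exc_events - exc_expected)),
             sum(sp_per_neuron) * 0.01 + 50)
  expect_identical(ct$spikes, sp_per_neuron)
})

test_that("the metabolic current turns collapse into self-sustained activity", {
  on <- simulate_network(tiny_network(seed = 1), duration = 6000,
                         stim_off = 2000, seed = 1)
  off <- simulate_network(tiny_network(seed = 1, im_gain = 0),
                          duration = 4000, stim_off = 2000, seed = 1)
  # ablated: activity collapses shortly after drive removal
  expect_lt(max(off$spikes$time_ms), 2500)
  # enabled: firing continues through the end of the run
  expect_gt(max(on$spikes$time_ms), 5900)
  post <- dplyr::filter(on$counts, .data$bin_start_ms >= 4000)
  expect_gt(mean(post$count), 0.5) # sustained population rate
  # self-sustained spikes ride on higher metabolic states
  ms_driven <- mean(on$spikes$ms[on$spikes$time_ms < 2000])
  ms_post <- mean(on$spikes$ms[on$spikes$time_ms > 3500])
  expect_gt(ms_post, ms_driven)
})

test_that("activity summaries recover the statistics of known trains", {
  # periodic neuron: CV exactly 0
  periodic <- tibble::tibble(neuron_id = 1L,
                             time_ms = seq(10, 990, by = 20))
  s <- summarize_activity(periodic, window = c(0, 1000), n_neurons = 2)
  expect_identical(s$cv$cv, 0)
  expect_equal(s$rates$rate_hz, c(50, 0))
  # Poisson surrogates: CV ~ 1, rate ~ nominal
  tr <- poisson_fixture(20, 60000, n_trains = 30, seed = 8) |>
    dplyr::rename(neuron_id = "train")
  s2 <- summarize_activity(tr, window = c(0, 60000), n_neurons = 30)
  expect_equal(mean(s2$cv$cv), 1, tolerance = 0.1)
  expect_equal(mean(s2$rates$rate_hz), 20, tolerance = 1)
  g <- glance(s2)
  expect_equal(g$pop_fano, 1, tolerance = 0.15)
  expect_lt(abs(g$mean_pairwise_corr), 0.05)
  expect_error(summarize_activity(periodic, window = c(5, 5),
                                  n_neurons = 1), "window")
})

test_that("metabolic regulation widens the stable synaptic-weight band", {
  scalings <- tidyr::expand_grid(fe = c(0.7, 1, 1.4), fi = c(0.7, 1.4))
  ok <- function(im_gain) {
    sum(purrr::pmap_lgl(scalings, function(fe, fi) {
      net <- tiny_network(seed = 3, w_ex = 2 * fe, w_in = 20 * fi,
                          im_gain = im_gain)
      sim <- simulate_network(net, duration = 3500, stim_off = 1500,
                              seed = 3)
      post <- dplyr::filter(sim$counts, .data$bin_start_ms >= 3000)
      persistent <- mean(post$count) > 0.1
      saturated <- mean(post$count) > 100 # mean rate above 100 Hz
      persistent && !saturated
    }))
  }
  expect_gt(ok(600), ok(0))
})
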