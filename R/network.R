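#' Configuration of the metabolically regulated spiking network
#'
#' A sparse recurrent network of conductance-based leaky
#' integrate-and-fire neurons (default 8,000 excitatory and 2,000
#' inhibitory, each receiving input from a random 2% of the network)
#' in which every neuron carries a bounded metabolic state `MS` in
#' `[0, ms_max]`. `MS` is charged per incoming synaptic event and per
#' emitted spike and recovers toward `ms_rest` with `tau_ms`; it drives
#' a saturating metabolic membrane current
#' `I_M = clamp(im_gain (MS - ms_neutral), -im_bound, +im_bound)`,
#' depolarising when the neuron has energy to spare and hyperpolarising
#' when it is overdrawn. With `im_gain = 0` the network is a standard
#' balanced sparse network that cannot sustain activity once external
#' drive stops.
#'
#' Neuron and synapse parameters follow the standard sparsely connected
#' conductance-based balanced-network regime; the metabolic parameters
#' were calibrated once at the reduced scale so that the driven network
#' fires irregularly at moderate rates, collapses without the metabolic
#' current when input is removed, and persists indefinitely with it.
#'
#' @param n_exc,n_inh numbers of excitatory/inhibitory neurons, `> 0`.
#' @param p_connect connection probability per ordered pair,
#'   `0 < p < 1`.
#' @param c_m capacitance (pF); `g_leak` leak conductance (nS);
#'   `v_rest`, `v_thresh`, `v_reset` potentials (mV); `refractory` ms.
#' @param e_ex,e_in synaptic reversal potentials (mV).
#' @param tau_ex,tau_in exponential conductance decay constants (ms).
#' @param w_ex,w_in,w_ext synaptic conductance increments (nS) for
#'   recurrent excitation, recurrent inhibition and external events.
#' @param rate_ext external Poisson event rate per neuron (Hz) while
#'   the stimulus is on.
#' @param ms_max,ms_rest,ms_neutral metabolic reservoir bound, resting
#'   (recovery target) level, and the level at which `I_M` crosses
#'   zero.
#' @param tau_ms recovery time constant of `MS` (ms).
#' @param cost_e,cost_i,cost_spike `MS` decrement per excitatory
#'   synaptic event, inhibitory event, and emitted spike.
#' @param im_gain metabolic current gain (pA per unit `MS`).
#' @param im_bound saturation bound of `I_M` (pA), `> 0`.
#' @param ext_costs do external Poisson events also charge `MS`?
#' @param dt simulation step (ms).
#' @return A named list of class `"network_config"`.
#' @seealso [reduced_network_config()] for the 800/200 test-scale
#'   variant.
#' @export
network_config <- function(n_exc = 8000, n_inh = 2000, p_connect = 0.02,
                           c_m = 200, g_leak = 10, v_rest = -60,
                           v_thresh = -50, v_reset = -60, refractory = 5,
                           e_ex = 0, e_in = -80, tau_ex = 5, tau_in = 10,
                           w_ex = 2 / sqrt(10), w_in = 20 / sqrt(10),
                           w_ext = 2 / sqrt(10), rate_ext = 300,
                           ms_max = 1, ms_rest = 0.8, ms_neutral = 0.5,
                           tau_ms = 1000, cost_e = 5e-4, cost_i = 5e-4,
                           cost_spike = 0.01, im_gain = 600,
                           im_bound = 150, ext_costs = TRUE, dt = 0.1) {
  if (n_exc <= 0 || n_inh <= 0)
    stop("network_config: n_exc and n_inh must be > 0", call. = FALSE)
  if (p_connect <= 0 || p_connect >= 1)
    stop("network_config: p_connect must be in (0, 1)", call. = FALSE)
  if (im_bound <= 0)
    stop("network_config: im_bound must be > 0", call. = FALSE)
  if (ms_max <= 0 || ms_rest < 0 || ms_rest > ms_max ||
      ms_neutral < 0 || ms_neutral > ms_max)
    stop("network_config: need 0 <= ms_neutral, ms_rest <= ms_max",
         call. = FALSE)
  structure(list(n_exc = as.integer(n_exc), n_inh = as.integer(n_inh),
                 p_connect = p_connect, c_m = c_m, g_leak = g_leak,
                 v_rest = v_rest, v_thresh = v_thresh, v_reset = v_reset,
                 refractory = refractory, e_ex = e_ex, e_in = e_in,
                 tau_ex = tau_ex, tau_in = tau_in, w_ex = w_ex,
                 w_in = w_in, w_ext = w_ext, rate_ext = rate_ext,
                 ms_max = ms_max, ms_rest = ms_rest,
                 ms_neutral = ms_neutral, tau_ms = tau_ms,
                 cost_e = cost_e, cost_i = cost_i,
                 cost_spike = cost_spike, im_gain = im_gain,
                 im_bound = im_bound, ext_costs = ext_costs, dt = dt),
            class = "network_config")
}

#' Reduced-scale network configuration
#'
#' A 10x smaller network (800 excitatory, 200 inhibitory, same 2%
#' connectivity) with synaptic weights rescaled by the square root of
#' the scale factor to keep input fluctuations comparable. This is the
#' first-class configuration for tests and routine runs.
#'
#' @param ... overrides forwarded to [network_config()].
#' @return A `"network_config"` list.
#' @export
reduced_network_config <- function(...) {
  # scale 10: full-scale weights times sqrt(10)
  defaults <- list(n_exc = 800, n_inh = 200,
                   w_ex = 2, w_in = 20, w_ext = 2)
  args <- utils::modifyList(defaults, list(...))
  do.call(network_config, args)
}

network_par_vec <- function(config) {
  nm <- c("c_m", "g_leak", "v_rest", "v_thresh", "v_reset", "refractory",
          "e_ex", "e_in", "tau_ex", "tau_in", "w_ex", "w_in", "w_ext",
          "rate_ext", "ms_max", "ms_rest", "ms_neutral", "tau_ms",
          "cost_e", "cost_i", "cost_spike", "im_gain", "im_bound")
  v <- unlist(config[nm])
  c(v, ext_costs = as.numeric(config$ext_costs))
}

#' Build the random connectivity
#'
#' Directed Bernoulli(`p_connect`) wiring per ordered pair, no
#' self-connections; reproducible from `seed`. Stored in compressed
#' sparse form (per-presynaptic-neuron target lists).
#'
#' @param config a [network_config()].
#' @param seed integer RNG seed.
#' @return A list of class `"metabolic_network"` with elements
#'   `config`, `adj_ptr`, `adj_idx` (0-based CSR over presynaptic
#'   neurons), and `seed`.
#' @export
#' @examples
#' net <- build_network(reduced_network_config(), seed = 1)
#' mean(diff(net$adj_ptr))  # ~ p_connect * (n - 1)
build_network <- function(config, seed = 1) {
  n <- config$n_exc + config$n_inh
  set.seed(seed)
  targets <- vector("list", n)
  for (j in seq_len(n)) {
    hit <- which(runif(n) < config$p_connect)
    targets[[j]] <- hit[hit != j] - 1L # drop autapse, 0-based
  }
  lens <- lengths(targets)
  net <- list(config = config,
              adj_ptr = c(0L, cumsum(lens)),
              adj_idx = unlist(targets, use.names = FALSE),
              seed = seed)
  class(net) <- "metabolic_network"
  net
}

#' @export
print.metabolic_network <- function(x, ...) {
  n <- x$config$n_exc + x$config$n_inh
  cat("<metabolic_network>", x$config$n_exc, "E /", x$config$n_inh,
      "I neurons,", length(x$adj_idx), "synapses (p =",
      x$config$p_connect, ")\n")
  invisible(x)
}

#' One update of the metabolic reservoir
#'
#' `MS` relaxes toward `ms_rest` and is charged for the step's synaptic
#' events and spike, then clamped to `[0, ms_max]`. Vectorised; mirrors
#' the network simulator's internal update.
#'
#' @param ms current level(s) in `[0, ms_max]`.
#' @param n_exc_events,n_inh_events event counts this step.
#' @param spiked logical (or 0/1): did the neuron spike this step?
#' @param config a [network_config()].
#' @param dt step (ms).
#' @return Updated `MS`, clamped to `[0, ms_max]`.
#' @export
ms_update <- function(ms, n_exc_events = 0, n_inh_events = 0,
                      spiked = FALSE, config = network_config(),
                      dt = config$dt) {
  ms <- ms - n_exc_events * config$cost_e - n_inh_events * config$cost_i -
    as.numeric(spiked) * config$cost_spike
  ms <- ms + dt * (config$ms_rest - ms) / config$tau_ms
  pmin(config$ms_max, pmax(0, ms))
}

#' Metabolic membrane current
#'
#' Monotone, saturating map from the metabolic state to a membrane
#' current: zero at `ms_neutral`, depolarising (positive) above it,
#' hyperpolarising below, clipped at `+/- im_bound`.
#'
#' @param ms metabolic state in `[0, ms_max]` (vectorised).
#' @param config a [network_config()].
#' @return Current in pA.
#' @export
i_m_from_ms <- function(ms, config = network_config()) {
  if (any(ms < 0 | ms > config$ms_max))
    stop("i_m_from_ms: ms must lie in [0, ms_max]", call. = FALSE)
  pmin(config$im_bound,
       pmax(-config$im_bound, config$im_gain * (ms - config$ms_neutral)))
}

#' Simulate the network through the driven-to-self-sustained transition
#'
#' External Poisson drive is applied to every neuron until
#' `stim_off`, then removed. Each neuron integrates leak, recurrent
#' synaptic, and metabolic currents; spike delivery is delayed by one
#' step. The full raster is returned together with the metabolic state
#' of each neuron at its spike times, per-neuron event/spike counters,
#' the exact cumulative metabolic charge, and full traces for a
#' recorded subset.
#'
#' @param network a [build_network()] result.
#' @param duration total simulated time (ms).
#' @param stim_off time (ms) at which external drive stops; must be
#'   `<= duration`.
#' @param seed integer seed controlling initial conditions and the
#'   Poisson drive.
#' @param record_ids neuron ids (1-based) whose `MS` and currents are
#'   traced; default: first 20 excitatory neurons.
#' @param record_every_ms trace resolution (ms).
#' @return A list of class `"network_sim"`: `spikes` (tibble
#'   `neuron_id, time_ms, ms`), `counts` (1-ms binned population
#'   counts: `bin_start_ms, count`), `traces` (long tibble
#'   `time_ms, neuron_id, ms, i_syn, i_m`), `counters` (per-neuron
#'   event/spike counts), `cum_cost`, `config`, `stim_off`, `duration`,
#'   `seed`.
#' @export
simulate_network <- function(network, duration = 10000, stim_off = 5000,
                             seed = 1, record_ids = NULL,
                             record_every_ms = 1) {
  config <- network$config
  if (stim_off > duration)
    stop("stim_off must be <= duration", call. = FALSE)
  n <- config$n_exc + config$n_inh
  if (is.null(record_ids)) record_ids <- seq_len(min(20L, config$n_exc))
  set.seed(seed)
  res <- network_simulate_cpp(config$n_exc, config$n_inh,
                              network$adj_ptr, network$adj_idx,
                              network_par_vec(config),
                              duration, stim_off, config$dt,
                              as.integer(record_ids),
                              max(1L, round(record_every_ms / config$dt)))
  spikes <- tibble::tibble(neuron_id = res$spike_id,
                           time_ms = res$spike_time,
                           ms = res$spike_ms)
  edges <- seq(0, duration, by = 1)
  counts <- tibble::tibble(
    bin_start_ms = head(edges, -1),
    count = as.integer(
      tabulate(findInterval(spikes$time_ms, edges,
                            rightmost.closed = TRUE),
               nbins = length(edges) - 1)))
  k <- length(record_ids)
  traces <- tibble::tibble(
    time_ms = rep(res$rec_times, times = k),
    neuron_id = rep(as.integer(record_ids), each = length(res$rec_times)),
    ms = as.vector(res$ms_traces),
    i_syn = as.vector(res$isyn_traces),
    i_m = as.vector(res$im_traces))
  counters <- tibble::as_tibble(as.data.frame(res$counters))
  counters$neuron_id <- seq_len(n)
  out <- list(spikes = spikes, counts = counts, traces = traces,
              counters = counters, cum_cost = res$cum_cost,
              final_ms = res$final_ms, config = config,
              stim_off = stim_off, duration = duration, seed = seed)
  class(out) <- "network_sim"
  out
}

#' @export
print.network_sim <- function(x, ...) {
  n <- x$config$n_exc + x$config$n_inh
  post <- x$spikes$time_ms > x$stim_off
  cat("<network_sim>", n, "neurons,", x$duration, "ms (drive off at",
      x$stim_off, "ms)\n  spikes:", nrow(x$spikes), "total,",
      sum(post), "after drive removal; last spike at",
      round(max(c(0, x$spikes$time_ms)), 1), "ms\n")
  invisible(x)
}

#' Summarise network activity in a window
#'
#' Per-neuron firing rates, pooled inter-spike intervals, per-neuron
#' coefficients of variation (neurons with at least three spikes in the
#' window), and the metabolic state sampled at each spike. [glance()]
#' on the result gives scalar signatures of the asynchronous-irregular
#' regime: the Fano factor of the 1-ms population counts, the mean
#' pairwise spike-count correlation (5-ms bins, up to 200 sampled
#' active neurons), and the mean CV.
#'
#' @param sim a `"network_sim"`, or a tibble of spikes with columns
#'   `neuron_id` and `time_ms` (then supply `n_neurons`).
#' @param window `c(start, end)` in ms.
#' @param n_neurons total neuron count when `sim` is a plain tibble.
#' @return A list of class `"activity_summary"` with tibbles `rates`,
#'   `isi`, `cv`, `ms_at_spike` (empty when `ms` is unavailable), and
#'   the window.
#' @export
summarize_activity <- function(sim, window = NULL, n_neurons = NULL) {
  if (inherits(sim, "network_sim")) {
    spikes <- sim$spikes
    n_neurons <- sim$config$n_exc + sim$config$n_inh
    if (is.null(window)) window <- c(0, sim$duration)
  } else {
    spikes <- sim
    if (is.null(n_neurons))
      stop("supply n_neurons when passing a raw spike table",
           call. = FALSE)
    if (is.null(window)) window <- range(spikes$time_ms)
  }
  if (diff(window) <= 0) stop("empty window", call. = FALSE)
  sp <- dplyr::filter(spikes, .data$time_ms >= window[1],
                      .data$time_ms < window[2])
  span_s <- diff(window) / 1000

  rates <- tibble::tibble(neuron_id = seq_len(n_neurons)) |>
    dplyr::left_join(dplyr::count(sp, .data$neuron_id),
                     by = "neuron_id") |>
    dplyr::mutate(rate_hz = dplyr::coalesce(.data$n, 0L) / span_s) |>
    dplyr::select("neuron_id", "rate_hz")

  by_neuron <- sp |>
    dplyr::arrange(.data$neuron_id, .data$time_ms) |>
    dplyr::group_by(.data$neuron_id)
  isi <- by_neuron |>
    dplyr::reframe(isi_ms = diff(.data$time_ms))
  cv <- isi |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::filter(dplyr::n() >= 2) |> # >= 3 spikes -> >= 2 ISIs
    dplyr::summarise(cv = sd(.data$isi_ms) / mean(.data$isi_ms),
                     .groups = "drop")

  ms_at_spike <- if ("ms" %in% names(sp)) {
    dplyr::select(sp, "neuron_id", "time_ms", "ms")
  } else {
    tibble::tibble(neuron_id = integer(), time_ms = numeric(),
                   ms = numeric())
  }

  out <- list(rates = rates, isi = isi, cv = cv,
              ms_at_spike = ms_at_spike, window = window,
              n_neurons = n_neurons, spikes = sp)
  class(out) <- "activity_summary"
  out
}

#' @rdname summarize_activity
#' @param x an `"activity_summary"`.
#' @param ... unused.
#' @export
glance.activity_summary <- function(x, ...) {
  edges <- seq(x$window[1], x$window[2], by = 1)
  counts <- tabulate(findInterval(x$spikes$time_ms, edges,
                                  rightmost.closed = TRUE),
                     nbins = length(edges) - 1)
  fano <- if (mean(counts) > 0) var(counts) / mean(counts) else NA_real_

  active <- unique(x$spikes$neuron_id)
  mean_corr <- NA_real_
  if (length(active) >= 2) {
    ids <- sort(active)[seq_len(min(200, length(active)))]
    bins5 <- seq(x$window[1], x$window[2], by = 5)
    m <- sapply(ids, function(id) {
      tabulate(findInterval(
        x$spikes$time_ms[x$spikes$neuron_id == id], bins5,
        rightmost.closed = TRUE), nbins = length(bins5) - 1)
    })
    keep <- apply(m, 2, sd) > 0
    if (sum(keep) >= 2) {
      cc <- cor(m[, keep, drop = FALSE])
      mean_corr <- mean(cc[upper.tri(cc)])
    }
  }
  tibble::tibble(mean_rate_hz = mean(x$rates$rate_hz),
                 frac_active = length(active) / x$n_neurons,
                 mean_cv = mean(x$cv$cv),
                 pop_fano = fano,
                 mean_pairwise_corr = mean_corr,
                 mean_ms_at_spike = if (nrow(x$ms_at_spike))
                   mean(x$ms_at_spike$ms) else NA_real_)
}
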