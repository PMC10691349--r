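#' Parameters of the A-type switching neuron
#'
#' A Connor-Stevens-style point neuron (Na+, delayed-rectifier K+,
#' leak) plus an A-type K+ conductance standing in for the
#' Shaker/Hyperkinetic channel of *Drosophila* dorsal fan-shaped-body
#' neurons. The A-type gate uses Boltzmann activation/inactivation with
#' midpoints placed so the current engages during spikes rather than at
#' rest. Its inactivation is removed continuously by `rho`
#' (see [step_hh()]): `rho = 0` is the fast-inactivating channel,
#' `rho = 1` the ROS-modified, non-inactivating channel. Under high ROS
#' the non-inactivating A-current takes over spike repolarisation from
#' the slower delayed rectifier, shortening inter-spike intervals and
#' raising the firing rate.
#'
#' Conductances are densities (mS/cm^2); injected currents in pA are
#' converted using `area_um2`. Defaults were calibrated once so the
#' ordinal claims hold (sustained vs. decaying clamp current; higher
#' rate at `rho = 1` under identical injection); they are not fits to
#' recordings.
#'
#' @param c_m membrane capacitance (uF/cm^2).
#' @param g_na,g_k,g_a,g_l maximal conductances (mS/cm^2), `>= 0`.
#' @param e_na,e_k,e_a,e_l reversal potentials (mV).
#' @param va,ka A-type activation midpoint (mV) and slope (mV).
#' @param tau_a A-type activation time constant (ms), `> 0`.
#' @param vha,kha A-type inactivation midpoint and slope (mV).
#' @param tau_ha A-type inactivation time constant (ms), `> 0`.
#' @param rho_mode how `rho` removes inactivation: `"gate_removal"`
#'   interpolates the effective gate toward 1 (default); `"slow_tau"`
#'   instead stretches `tau_ha` toward `tau_ha_slow`.
#' @param tau_ha_slow slowed inactivation time constant for
#'   `"slow_tau"` mode (ms).
#' @param area_um2 membrane area (um^2) used to convert pA to current
#'   density.
#' @return A named list of class `"channel_params"`.
#' @export
channel_params <- function(c_m = 1, g_na = 120, g_k = 20, g_a = 60,
                           g_l = 0.3, e_na = 55, e_k = -72, e_a = -75,
                           e_l = -70, va = -25, ka = 6, tau_a = 0.5,
                           vha = -60, kha = 8, tau_ha = 15,
                           rho_mode = c("gate_removal", "slow_tau"),
                           tau_ha_slow = 200, area_um2 = 100) {
  rho_mode <- match.arg(rho_mode)
  if (any(c(g_na, g_k, g_a, g_l) < 0))
    stop("channel_params: conductances must be >= 0", call. = FALSE)
  if (any(c(tau_a, tau_ha, tau_ha_slow, c_m, area_um2) <= 0))
    stop("channel_params: c_m, taus and area must be > 0", call. = FALSE)
  structure(list(c_m = c_m, g_na = g_na, g_k = g_k, g_a = g_a, g_l = g_l,
                 e_na = e_na, e_k = e_k, e_a = e_a, e_l = e_l,
                 va = va, ka = ka, tau_a = tau_a, vha = vha, kha = kha,
                 tau_ha = tau_ha, rho_mode = rho_mode,
                 tau_ha_slow = tau_ha_slow, area_um2 = area_um2),
            class = "channel_params")
}

channel_par_vec <- function(params) {
  c(c_m = params$c_m, g_na = params$g_na, g_k = params$g_k,
    g_a = params$g_a, g_l = params$g_l, e_na = params$e_na,
    e_k = params$e_k, e_a = params$e_a, e_l = params$e_l,
    va = params$va, ka = params$ka, tau_a = params$tau_a,
    vha = params$vha, kha = params$kha, tau_ha = params$tau_ha,
    area_um2 = params$area_um2,
    tau_mode = as.numeric(params$rho_mode == "slow_tau"),
    tau_ha_slow = params$tau_ha_slow)
}

pa_to_density <- function(i_pa, area_um2) i_pa * 1e-6 / (area_um2 * 1e-8)

#' Clamp protocol
#'
#' @param mode `"voltage"` (command in mV) or `"current"` (command in
#'   pA).
#' @param segments data frame with columns `duration_ms` and `value`;
#'   all durations `> 0`.
#' @param holding pre-protocol holding value (mV or pA), used to
#'   initialise the state.
#' @return A list of class `"clamp_protocol"`.
#' @export
#' @examples
#' clamp_protocol("voltage",
#'                data.frame(duration_ms = c(50, 100), value = c(-90, 40)),
#'                holding = -90)
clamp_protocol <- function(mode = c("voltage", "current"), segments,
                           holding = if (mode == "voltage") -90 else 0) {
  mode <- match.arg(mode)
  segments <- as.data.frame(segments)
  if (!all(c("duration_ms", "value") %in% names(segments)))
    stop("segments needs columns duration_ms and value", call. = FALSE)
  if (any(segments$duration_ms <= 0))
    stop("segment durations must be > 0", call. = FALSE)
  structure(list(mode = mode, segments = segments, holding = holding),
            class = "clamp_protocol")
}

protocol_signal <- function(protocol, dt) {
  rep(protocol$segments$value,
      times = pmax(1L, round(protocol$segments$duration_ms / dt)))
}

#' Membrane state of the A-type switching neuron
#'
#' Gating variables at their voltage-dependent steady state for `v`.
#'
#' @param params a [channel_params()] object.
#' @param v membrane potential (mV).
#' @param rho inactivation-removal level in `[0, 1]`.
#' @return One-row tibble `v, m, h, n, a, h_a`.
#' @export
hh_state <- function(params = channel_params(), v = -68, rho = 0) {
  st <- hh_init_cpp(channel_par_vec(params), rho, v)
  tibble::tibble(v = st[1], m = st[2], h = st[3], n = st[4], a = st[5],
                 h_a = st[6])
}

#' One integration step of the membrane equation
#'
#' Advances `C dV/dt = -I_Na - I_K - I_A - I_leak + I_inj` by one Euler
#' step, with `I_A = g_a a^3 hA_eff (V - e_a)` and the effective
#' inactivation `hA_eff = (1 - rho) hA + rho` (gate-removal mode), so
#' at `rho = 1` the A-current no longer depends on its inactivation
#' state.
#'
#' @param state one-row tibble from [hh_state()].
#' @param params a [channel_params()] object.
#' @param i_inj injected current (pA).
#' @param rho inactivation-removal level in `[0, 1]`.
#' @param dt step (ms).
#' @return The advanced one-row state tibble.
#' @export
step_hh <- function(state, params = channel_params(), i_inj = 0, rho = 0,
                    dt = 0.01) {
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]", call. = FALSE)
  iden <- pa_to_density(i_inj, params$area_um2)
  init <- unlist(state[1, c("v", "m", "h", "n", "a", "h_a")])
  res <- hh_current_clamp_cpp(channel_par_vec(params), rho, init,
                              i_inj = iden, dt = dt, record_every = 1L,
                              spike_threshold = 0, dedup_ms = 2)
  st <- res$state
  tibble::tibble(v = st[1], m = st[2], h = st[3], n = st[4], a = st[5],
                 h_a = st[6])
}

#' Voltage-clamp a neuron and separate its potassium currents
#'
#' The membrane potential follows the command exactly while the gates
#' evolve; the A-type and non-A (delayed rectifier) K+ currents are
#' returned separately. With `rho = 0` a depolarising step elicits a
#' transient A-current that inactivates to a low plateau; with
#' `rho = 1` the current is sustained.
#'
#' @param params a [channel_params()] object.
#' @param protocol a voltage-mode [clamp_protocol()].
#' @param rho inactivation-removal level in `[0, 1]`.
#' @param dt step (ms).
#' @param record_every trace thinning factor.
#' @return Tibble `time_ms, v_mv, i_na, i_k, i_a, i_leak` (pA).
#' @export
voltage_clamp <- function(params = channel_params(), protocol, rho = 0,
                          dt = 0.01, record_every = 5L) {
  if (protocol$mode != "voltage")
    stop("voltage_clamp needs a voltage-mode protocol", call. = FALSE)
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]", call. = FALSE)
  init <- hh_init_cpp(channel_par_vec(params), rho, protocol$holding)
  cmd <- protocol_signal(protocol, dt)
  tr <- hh_voltage_clamp_cpp(channel_par_vec(params), rho, init, cmd, dt,
                             as.integer(record_every))
  tibble::as_tibble(as.data.frame(tr))
}

#' Current-clamp a neuron and detect its spikes
#'
#' Spike times are upward crossings of `spike_threshold` separated by
#' at least `dedup_ms` (deduplication of threshold chatter). The state
#' is first settled at the holding current for `settle_ms`.
#'
#' @param params a [channel_params()] object.
#' @param protocol a current-mode [clamp_protocol()] (values in pA).
#' @param rho inactivation-removal level in `[0, 1]`.
#' @param dt step (ms).
#' @param spike_threshold detection threshold (mV).
#' @param dedup_ms refractory window for detection (ms).
#' @param settle_ms pre-protocol settling time at the holding current.
#' @param record_every trace thinning factor.
#' @return A list of class `"clamp_sim"`: `trace` tibble
#'   (`time_ms, v_mv, i_na, i_k, i_a, i_leak`) and `spikes` tibble
#'   (`time_ms`), times relative to protocol onset.
#' @export
#' @examples
#' prot <- clamp_protocol("current", data.frame(duration_ms = 200, value = 20))
#' sim <- current_clamp(protocol = prot, rho = 1, dt = 0.02)
#' nrow(sim$spikes)
current_clamp <- function(params = channel_params(), protocol, rho = 0,
                          dt = 0.01, spike_threshold = 0, dedup_ms = 2,
                          settle_ms = 200, record_every = 5L) {
  if (protocol$mode != "current")
    stop("current_clamp needs a current-mode protocol", call. = FALSE)
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]", call. = FALSE)
  pv <- channel_par_vec(params)
  init <- hh_init_cpp(pv, rho, -68)
  hold <- pa_to_density(protocol$holding, params$area_um2)
  settle <- hh_current_clamp_cpp(pv, rho, init,
                                 rep(hold, round(settle_ms / dt)), dt,
                                 record_every = 1e9L,
                                 spike_threshold = spike_threshold,
                                 dedup_ms = dedup_ms)
  sig <- pa_to_density(protocol_signal(protocol, dt), params$area_um2)
  res <- hh_current_clamp_cpp(pv, rho, settle$state, sig, dt,
                              as.integer(record_every),
                              spike_threshold, dedup_ms)
  out <- list(trace = tibble::as_tibble(as.data.frame(res$trace)),
              spikes = tibble::tibble(time_ms = res$spike_times))
  class(out) <- "clamp_sim"
  out
}

#' @export
print.clamp_sim <- function(x, ...) {
  cat("<clamp_sim>", nrow(x$spikes), "spikes over",
      max(x$trace$time_ms), "ms\n")
  invisible(x)
}

#' Map a ROS level to the inactivation-removal fraction
#'
#' A saturating Hill map standing in for the NADPH/Hyperkinetic relay:
#' zero ROS leaves the channel fully inactivating, high ROS removes
#' inactivation entirely.
#'
#' @param ros ROS level, `>= 0` (vectorised).
#' @param k_d ROS level of half-removal.
#' @param hill Hill coefficient, `> 0`.
#' @return `rho` in `[0, 1)`, monotone nondecreasing in `ros`.
#' @export
#' @examples
#' ros_to_rho(c(0, 0.5, 5))
ros_to_rho <- function(ros, k_d = 0.5, hill = 2) {
  if (any(ros < 0)) stop("ros must be >= 0", call. = FALSE)
  if (k_d <= 0 || hill <= 0)
    stop("k_d and hill must be > 0", call. = FALSE)
  ros^hill / (k_d^hill + ros^hill)
}

#' Shift a ROS-vs-consumption curve
#'
#' Additive offset of the steady-state ROS curve, floored at zero:
#' positive shifts emulate optogenetic ROS delivery (miniSOG-like),
#' negative shifts emulate alternative-oxidase relief (AOX-like).
#'
#' @param curve a `"ros_curve"` tibble from [ros_vs_baseline_curve()].
#' @param shift additive offset applied to `ros_ss`.
#' @return The shifted curve (same class and columns).
#' @export
shifted_ros_curve <- function(curve, shift = 0) {
  curve$ros_ss <- pmax(0, curve$ros_ss + shift)
  curve
}
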