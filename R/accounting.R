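#' Parameters of the metabolic-accounting neuron
#'
#' A minimal neuron that spikes to balance its metabolic books. The
#' metabolic signal `MS = ROS * (ATP - atp_bar)` combines how much ROS
#' the cell is producing with whether it is over- or under-spending
#' relative to the ROS-minimising expenditure. Two thresholds gate
#' firing: `MS > theta_ret` triggers ATP-consuming metabolic spikes
#' (quenching reverse-transport ROS), and `MS < theta_fet` blocks all
#' spiking, including input-driven synaptic spikes (protecting an
#' already overdrawn cell).
#'
#' Two ROS/ATP backends are available. The default phenomenological
#' backend relaxes ATP toward a target set linearly by the current
#' consumption rate (`1 - c / c_max`, clamped to `[0, 1]`, time
#' constant `tau_atp`) and ROS toward a V-shaped function of
#' consumption, `ros_min + v_slope * |c - c_bar|`, with time constant
#' `tau_ros`; it keeps threshold logic decoupled from ODE details and
#' is fast enough for phase-diagram sweeps. `ros_backend = "mito"`
#' drives the same gating logic from the full respiration model of
#' [mito_params()], reading pooled ATP from the cytosolic pool.
#'
#' @param theta_ret MS threshold above which metabolic spiking starts.
#' @param theta_fet MS threshold below which all spiking is blocked;
#'   must satisfy `theta_ret > theta_fet`.
#' @param refractory absolute refractory period (ms), `> 0`.
#' @param budget an [energy_budget()]: baseline cost, per-spike cost Q
#'   and its kernel.
#' @param ros_backend `"phenomenological"` (default) or `"mito"`.
#' @param c_bar consumption rate at the ROS minimum (phenomenological
#'   backend).
#' @param c_max consumption rate at which the ATP target reaches zero.
#' @param tau_atp,tau_ros relaxation time constants (ms).
#' @param ros_min,v_slope floor and limb slope of the V-shaped ROS
#'   curve.
#' @param atp_bar ATP reference of the MS product; `NULL` derives it
#'   from the backend (phenomenological: the ATP target at `c_bar`;
#'   mito: steady cytosolic ATP at the ROS-minimising baseline).
#' @param mito a [mito_params()] object for the `"mito"` backend.
#' @return A named list of class `"accounting_params"`.
#' @export
accounting_params <- function(theta_ret = 0.15, theta_fet = -0.15,
                              refractory = 5,
                              budget = energy_budget(baseline_cost = 0.01,
                                                     q = 0.3,
                                                     q_kernel_duration = 20),
                              ros_backend = c("phenomenological", "mito"),
                              c_bar = 0.05, c_max = 0.1,
                              tau_atp = 50, tau_ros = 100,
                              ros_min = 0.1, v_slope = 20,
                              atp_bar = NULL, mito = mito_params()) {
  ros_backend <- match.arg(ros_backend)
  if (!(theta_ret > theta_fet))
    stop("accounting_params: theta_ret must exceed theta_fet",
         call. = FALSE)
  if (refractory <= 0)
    stop("accounting_params: refractory must be > 0", call. = FALSE)
  if (c_max <= 0 || tau_atp <= 0 || tau_ros <= 0)
    stop("accounting_params: c_max, tau_atp, tau_ros must be > 0",
         call. = FALSE)
  structure(list(theta_ret = theta_ret, theta_fet = theta_fet,
                 refractory = refractory, budget = budget,
                 ros_backend = ros_backend, c_bar = c_bar, c_max = c_max,
                 tau_atp = tau_atp, tau_ros = tau_ros, ros_min = ros_min,
                 v_slope = v_slope, atp_bar = atp_bar, mito = mito),
            class = "accounting_params")
}

accounting_atp_bar <- function(params) {
  if (!is.null(params$atp_bar)) return(params$atp_bar)
  if (params$ros_backend == "phenomenological")
    return(min(1, max(0, 1 - params$c_bar / params$c_max)))
  # mito backend: steady cytosolic ATP at the ROS-minimising baseline
  opt <- optimize(function(b) {
    find_steady_state(params$mito, energy_budget(baseline_cost = b),
                      dt = 0.05)$ros
  }, interval = c(0.005, 0.085))
  find_steady_state(params$mito,
                    energy_budget(baseline_cost = opt$minimum),
                    dt = 0.05)$atp_c
}

accounting_par_vec <- function(params) {
  c(theta_ret = params$theta_ret, theta_fet = params$theta_fet,
    refractory = params$refractory,
    baseline_cost = params$budget$baseline_cost,
    q = params$budget$q,
    q_kernel_duration = params$budget$q_kernel_duration,
    c_bar = params$c_bar, c_max = params$c_max,
    tau_atp = params$tau_atp, tau_ros = params$tau_ros,
    ros_min = params$ros_min, v_slope = params$v_slope,
    exp_kernel = as.numeric(params$budget$q_kernel_shape == "exponential"),
    ca_coupling = params$mito$ca_coupling)
}

#' Metabolic signal
#'
#' `MS = ROS * (ATP - atp_bar)`: positive when the cell is
#' under-spending (ATP above the ideal level) and producing ROS, so a
#' spike would help; negative when the cell is already overdrawn.
#'
#' @param ros ROS level (vectorised).
#' @param atp ATP level (vectorised).
#' @param atp_bar ATP reference at the ROS minimum.
#' @return Signed numeric vector.
#' @export
#' @examples
#' metabolic_signal(ros = 2, atp = 1, atp_bar = 0.5)
metabolic_signal <- function(ros, atp, atp_bar) {
  ros * (atp - atp_bar)
}

#' Single accounting-neuron state
#'
#' One-row tibble used by [step_accounting()]. The spike kernel is
#' represented by `kernel_remaining_ms` (time left on the current
#' rectangular kernel); with the default refractory period at least as
#' long as the kernel, at most one kernel is active at a time.
#'
#' @param atp,ros initial levels; `NULL` uses the no-spiking fixed
#'   point of the phenomenological backend for `params`.
#' @param refractory_remaining ms of refractoriness left, `>= 0`.
#' @param t current time (ms).
#' @param params an [accounting_params()] object.
#' @return A one-row tibble of class `"accounting_state"`.
#' @export
accounting_state <- function(atp = NULL, ros = NULL,
                             refractory_remaining = 0, t = 0,
                             params = accounting_params()) {
  if (refractory_remaining < 0)
    stop("refractory_remaining must be >= 0", call. = FALSE)
  b <- params$budget$baseline_cost
  if (is.null(atp)) atp <- min(1, max(0, 1 - b / params$c_max))
  if (is.null(ros)) ros <- params$ros_min + params$v_slope * abs(b - params$c_bar)
  ms <- metabolic_signal(ros, atp, accounting_atp_bar(params))
  st <- tibble::tibble(atp = atp, ros = ros, ms = ms,
                       refractory_remaining = refractory_remaining,
                       t = t, kernel_remaining_ms = 0)
  class(st) <- c("accounting_state", class(st))
  st
}

#' One step of the accounting neuron
#'
#' Reference single-step implementation of the gating rule: with the
#' refractory clock expired, `MS > theta_ret` emits a metabolic spike;
#' otherwise a synaptic spike is emitted only when `input_drive` is
#' `TRUE` and `MS > theta_fet`. No spike of any kind is emitted while
#' `MS < theta_fet`. Emitting a spike starts the refractory clock and
#' the per-spike cost kernel.
#'
#' @param state an [accounting_state()] tibble.
#' @param params an [accounting_params()] object (phenomenological
#'   backend).
#' @param input_drive logical: is suprathreshold synaptic drive present
#'   during this step?
#' @param dt step size (ms).
#' @return A list with `state` (advanced) and `spike` (`NA_character_`,
#'   `"metabolic"` or `"synaptic"`).
#' @export
step_accounting <- function(state, params = accounting_params(),
                            input_drive = FALSE, dt = 0.1) {
  b <- params$budget
  atp_bar <- accounting_atp_bar(params)
  ms <- metabolic_signal(state$ros, state$atp, atp_bar)

  spike <- NA_character_
  if (state$refractory_remaining <= 0) {
    if (ms > params$theta_ret) spike <- "metabolic"
    else if (input_drive && ms > params$theta_fet) spike <- "synaptic"
  }

  kernel <- state$kernel_remaining_ms
  refr <- max(0, state$refractory_remaining - dt)
  if (!is.na(spike)) {
    refr <- params$refractory
    kernel <- b$q_kernel_duration
  }
  extra <- if (kernel > 0) b$q / b$q_kernel_duration else 0
  c_now <- b$baseline_cost + extra

  atp_target <- min(1, max(0, 1 - c_now / params$c_max))
  ros_target <- params$ros_min + params$v_slope * abs(c_now - params$c_bar)
  atp <- state$atp + dt * (atp_target - state$atp) / params$tau_atp
  ros <- state$ros + dt * (ros_target - state$ros) / params$tau_ros

  new <- tibble::tibble(atp = atp, ros = ros,
                        ms = metabolic_signal(ros, atp, atp_bar),
                        refractory_remaining = refr,
                        t = state$t + dt,
                        kernel_remaining_ms = max(0, kernel - dt))
  class(new) <- c("accounting_state", class(new))
  list(state = new, spike = spike)
}

#' Simulate the accounting neuron
#'
#' Closed-loop run of the metabolic-accounting neuron: ATP and ROS
#' evolve under the chosen backend, the metabolic signal is recomputed
#' each step, and spikes are emitted per the two-threshold rule. The
#' run is deterministic given parameters and inputs.
#'
#' @param params an [accounting_params()] object.
#' @param duration simulated time (ms).
#' @param input external suprathreshold drive: `NULL` (none), a numeric
#'   vector of drive times (ms), a two-column matrix/data frame of
#'   `(start, end)` windows, or a logical vector with one entry per
#'   step.
#' @param dt step size (ms).
#' @param record_every thin the recorded traces to every this many
#'   steps.
#' @param spiking_enabled set `FALSE` to ablate all spiking (used to
#'   measure the homeostatic benefit of metabolic firing).
#' @return A list of class `"accounting_sim"`: `spikes` (tibble
#'   `time_ms, label`), `traces` (tibble
#'   `time_ms, atp, ros, ms, consumption`), `atp_bar`, `params`,
#'   `duration`.
#' @export
#' @examples
#' sim <- simulate_accounting(duration = 1000)
#' nrow(sim$spikes)
simulate_accounting <- function(params = accounting_params(),
                                duration = 2000, input = NULL,
                                dt = 0.1, record_every = 10L,
                                spiking_enabled = TRUE) {
  n_steps <- round(duration / dt)
  drive <- integer(n_steps)
  if (is.logical(input)) {
    if (length(input) != n_steps)
      stop("logical `input` must have one entry per step", call. = FALSE)
    drive <- as.integer(input)
  } else if (is.matrix(input) || is.data.frame(input)) {
    for (r in seq_len(nrow(input))) {
      i0 <- max(1L, floor(input[[1]][r] / dt) + 1L)
      i1 <- min(n_steps, ceiling(input[[2]][r] / dt))
      if (i0 <= i1) drive[i0:i1] <- 1L
    }
  } else if (is.numeric(input) && length(input)) {
    idx <- floor(input / dt) + 1L
    drive[idx[idx >= 1 & idx <= n_steps]] <- 1L
  }

  if (params$ros_backend == "phenomenological") {
    res <- accounting_simulate_cpp(accounting_par_vec(params), duration, dt,
                                   drive, as.integer(record_every),
                                   spiking_enabled)
  } else {
    atp_bar <- accounting_atp_bar(params)
    ss <- find_steady_state(params$mito, params$budget, dt = min(dt, 0.05))
    res <- accounting_simulate_mito_cpp(accounting_par_vec(params),
                                        mito_par_vec(params$mito),
                                        as_mito_vec(ss), atp_bar,
                                        duration, dt, drive,
                                        as.integer(record_every),
                                        spiking_enabled)
  }
  labels <- c("metabolic", "synaptic")[res$spike_labels]
  out <- list(spikes = tibble::tibble(time_ms = res$spike_times,
                                      label = labels),
              traces = tibble::as_tibble(as.data.frame(res$traces)),
              atp_bar = res$atp_bar,
              params = params, duration = duration)
  class(out) <- "accounting_sim"
  out
}

#' @export
print.accounting_sim <- function(x, ...) {
  cat("<accounting_sim>", x$duration, "ms,",
      nrow(x$spikes), "spikes (",
      sum(x$spikes$label == "metabolic"), "metabolic /",
      sum(x$spikes$label == "synaptic"), "synaptic )\n")
  invisible(x)
}

#' Classifier cutoffs for firing patterns
#'
#' @param silent_rate_hz below this rate a train is `silent`.
#' @param continuous_rate_hz minimum rate for `continuous`.
#' @param continuous_gap_factor `continuous` tolerates no inter-spike
#'   interval above this multiple of the median ISI.
#' @param burst_gap_factor an ISI at least this multiple of the median
#'   marks a between-burst gap.
#' @return Named list of cutoffs.
#' @export
pattern_criteria <- function(silent_rate_hz = 0.1,
                             continuous_rate_hz = 50,
                             continuous_gap_factor = 2,
                             burst_gap_factor = 5) {
  list(silent_rate_hz = silent_rate_hz,
       continuous_rate_hz = continuous_rate_hz,
       continuous_gap_factor = continuous_gap_factor,
       burst_gap_factor = burst_gap_factor)
}

#' Classify a spike train's firing pattern
#'
#' Deterministic classification from rate and ISI statistics: `silent`
#' below a minimal rate; `bursting` when at least two between-burst
#' gaps exceed `burst_gap_factor` times the median ISI; `continuous`
#' when the rate clears its cutoff and no ISI exceeds
#' `continuous_gap_factor` times the median; `tonic` otherwise.
#'
#' @param spikes numeric vector of spike times (ms), or the `spikes`
#'   tibble of an `"accounting_sim"`.
#' @param duration observation window length (ms).
#' @param criteria a [pattern_criteria()] list.
#' @return One of `"silent"`, `"tonic"`, `"bursting"`, `"continuous"`.
#' @export
#' @examples
#' classify_pattern(numeric(0), duration = 1000)          # "silent"
#' classify_pattern(seq(10, 990, by = 20), duration = 1000)
classify_pattern <- function(spikes, duration,
                             criteria = pattern_criteria()) {
  if (is.data.frame(spikes)) spikes <- spikes$time_ms
  if (length(spikes) && (min(spikes) < 0 || max(spikes) > duration))
    stop("classify_pattern: spikes must lie in [0, duration]",
         call. = FALSE)
  rate_hz <- length(spikes) / duration * 1000
  if (rate_hz < criteria$silent_rate_hz) return("silent")
  if (length(spikes) < 3) return("tonic")
  isi <- diff(sort(spikes))
  med <- median(isi)
  n_gaps <- sum(isi >= criteria$burst_gap_factor * med)
  if (n_gaps >= 2) return("bursting")
  if (rate_hz >= criteria$continuous_rate_hz &&
      max(isi) < criteria$continuous_gap_factor * med) return("continuous")
  "tonic"
}

#' Firing-pattern phase diagram over (baseline cost, per-spike cost)
#'
#' One simulation and classification per grid cell. The `"retros"`
#' variant runs without input (patterns are purely metabolic); the
#' `"fetros"` variant applies sustained suprathreshold drive, so the
#' diagram shows where the metabolic brake blocks or admits synaptic
#' firing.
#'
#' @param params template [accounting_params()]; its budget's baseline
#'   and `q` are overridden per cell.
#' @param baseline_grid,q_grid numeric grids.
#' @param variant `"retros"` (no input) or `"fetros"` (sustained
#'   drive).
#' @param duration per-cell simulated time (ms).
#' @param dt step size (ms).
#' @param criteria a [pattern_criteria()] list.
#' @return A tibble of class `"phase_diagram"`: `baseline, q, label`.
#' @export
phase_diagram <- function(params = accounting_params(),
                          baseline_grid = seq(0.002, 0.05,
                                              length.out = 10),
                          q_grid = exp(seq(log(0.02), log(2),
                                           length.out = 10)),
                          variant = c("retros", "fetros"),
                          duration = 3000, dt = 0.1,
                          criteria = pattern_criteria()) {
  variant <- match.arg(variant)
  if (!length(baseline_grid) || !length(q_grid))
    stop("phase_diagram: grids must be nonempty", call. = FALSE)
  drive <- if (variant == "fetros") rep(TRUE, round(duration / dt)) else NULL
  grid <- tidyr::expand_grid(baseline = baseline_grid, q = q_grid)
  grid$label <- purrr::pmap_chr(grid, function(baseline, q) {
    p <- params
    p$budget <- energy_budget(baseline_cost = baseline, q = q,
                              q_kernel_duration = params$budget$q_kernel_duration,
                              q_kernel_shape = params$budget$q_kernel_shape)
    sim <- simulate_accounting(p, duration = duration, input = drive,
                               dt = dt, record_every = 100L)
    classify_pattern(sim$spikes$time_ms, duration, criteria)
  })
  class(grid) <- c("phase_diagram", class(grid))
  grid
}
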