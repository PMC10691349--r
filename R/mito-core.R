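#' Steady-state ROS level at a respiratory operating point
#'
#' The equilibrium ROS level is cubic in a weighted sum of the two
#' electron-escape routes:
#' \deqn{ROS_\infty = (ATP_M \Delta\Psi f_{RET} +
#'   (1 - ATP_M)(1 - \Delta\Psi) f_{FET})^3.}
#' Reverse-transport ROS dominates in the upper-right corner of the
#' respiratory state space (full ATP, high gradient: a stalled chain),
#' forward-transport ROS in the lower-left corner (depleted ATP, low
#' gradient: a hard-working chain). The formula is symmetric under the
#' simultaneous swap `atp_m <-> 1 - atp_m`, `delta_psi <-> 1 - delta_psi`,
#' `f_ret <-> f_fet`.
#'
#' @param atp_m mitochondrial ATP fraction in `[0, 1]`; vectorised.
#' @param delta_psi proton-gradient fraction in `[0, 1]`; vectorised.
#' @param params a [mito_params()] object supplying `f_ret` and `f_fet`.
#' @return Non-negative numeric vector of equilibrium ROS levels.
#' @export
#' @examples
#' ros_steady_state(1, 1)              # pure RETROS corner -> 1
#' ros_steady_state(0.5, 0.5)          # mixed midpoint -> 0.125
ros_steady_state <- function(atp_m, delta_psi, params = mito_params()) {
  if (any(atp_m < 0 | atp_m > 1, na.rm = TRUE))
    stop("ros_steady_state: atp_m must lie in [0, 1]", call. = FALSE)
  if (any(delta_psi < 0 | delta_psi > 1, na.rm = TRUE))
    stop("ros_steady_state: delta_psi must lie in [0, 1]", call. = FALSE)
  s <- atp_m * delta_psi * params$f_ret +
    (1 - atp_m) * (1 - delta_psi) * params$f_fet
  s^3
}

#' One relaxation step of the ROS level
#'
#' Advances `dROS/dt = (ROS_inf - ROS) / tau_ros` by `dt` using the same
#' fixed-step fourth-order update as the full integrator; for this
#' linear equation the step agrees with the exact exponential solution
#' to O((dt/tau)^5). The result always lies between `ros` and `ros_inf`.
#'
#' @param ros current ROS level.
#' @param ros_inf target (steady-state) ROS level.
#' @param tau_ros relaxation time constant (ms), `> 0`.
#' @param dt step size (ms), `> 0`.
#' @return Updated ROS level(s); vectorised over `ros` and `ros_inf`.
#' @export
relax_ros <- function(ros, ros_inf, tau_ros, dt) {
  if (tau_ros <= 0) stop("relax_ros: tau_ros must be > 0", call. = FALSE)
  if (dt <= 0) stop("relax_ros: dt must be > 0", call. = FALSE)
  x <- dt / tau_ros
  decay <- 1 - x + x^2 / 2 - x^3 / 6 + x^4 / 24 # RK4 on a linear ODE
  ros_inf + (ros - ros_inf) * decay
}

#' Advance the mitochondrial state by one integration step
#'
#' A single fixed-step fourth-order (RK4) update of the full backbone at
#' a constant cytosolic ATP consumption rate. The adenine and NAD pools
#' are conserved exactly because only `atp_m` and `nadh` are stored; a
#' state variable leaving its admissible range raises an integration
#' error (advising a smaller `dt`) rather than being clipped.
#'
#' @param state a [mito_state()] tibble.
#' @param params a [mito_params()] object.
#' @param consumption_rate cytosolic ATP demand (normalised ATP per ms).
#' @param dt step size in ms (default 0.01).
#' @return The advanced state as a `"mito_state"` tibble.
#' @export
step_mito <- function(state, params = mito_params(), consumption_rate = 0,
                      dt = 0.01) {
  out <- mito_integrate_cpp(as_mito_vec(state), mito_par_vec(params),
                            consumption = consumption_rate,
                            psi_kick = 0, dt = dt, record_every = 1L)
  st <- mito_state()
  st[1, c("pyr", "nadh", "delta_psi", "atp_m", "atp_c", "ros")] <-
    as.list(out[nrow(out), -1])
  st$ca_m <- state$ca_m
  st
}

#' Find the baseline steady state of the respiration model
#'
#' Integrates from a standard mid-range initial condition at the
#' baseline consumption rate until the largest time-derivative falls
#' below `tol`. Two calls with identical inputs return identical
#' output.
#'
#' @param params a [mito_params()] object.
#' @param budget an [energy_budget()]; only `baseline_cost` is used.
#' @param dt integration step (ms).
#' @param tol residual tolerance on `max |d state/dt|`.
#' @param t_max give up (with an error reporting the residual) after
#'   this much simulated time (ms).
#' @param init optional starting [mito_state()].
#' @return A `"mito_state"` tibble with attributes `residual`,
#'   `consumption` and `t_elapsed`.
#' @export
#' @examples
#' ss <- find_steady_state(budget = energy_budget(baseline_cost = 0.02))
#' ss$atp_m
find_steady_state <- function(params = mito_params(),
                              budget = energy_budget(),
                              dt = 0.01, tol = 1e-9, t_max = 4e5,
                              init = mito_state()) {
  res <- mito_steady_cpp(as_mito_vec(init), mito_par_vec(params),
                         consumption = budget$baseline_cost,
                         dt = dt, t_max = t_max, tol = tol)
  if (!res$converged)
    stop(sprintf(paste0("find_steady_state: no fixed point within %g ms ",
                        "(residual %.3g > tol %.3g); the baseline cost may ",
                        "be outside the admissible range"),
                 t_max, res$residual, tol), call. = FALSE)
  st <- mito_state()
  st[1, c("pyr", "nadh", "delta_psi", "atp_m", "atp_c", "ros")] <-
    as.list(res$state)
  attr(st, "residual") <- res$residual
  attr(st, "consumption") <- budget$baseline_cost
  attr(st, "t_elapsed") <- res$t_elapsed
  st
}

# consumption signal (per step) and per-step psi decrements for a spike
# train under a budget; n_steps from duration/dt
spike_consumption <- function(budget, params, spike_times, duration, dt) {
  n_steps <- round(duration / dt)
  cons <- rep(budget$baseline_cost, n_steps)
  kick <- numeric(n_steps)
  k_steps <- max(1L, round(budget$q_kernel_duration / dt))
  for (ts in spike_times) {
    i0 <- floor(ts / dt) + 1L
    if (i0 > n_steps) next
    idx <- i0:min(n_steps, i0 + k_steps - 1L)
    if (budget$q_kernel_shape == "rectangular") {
      cons[idx] <- cons[idx] + budget$q / (k_steps * dt)
    } else {
      tau <- budget$q_kernel_duration / 3
      w <- exp(-(seq_along(idx) - 1) * dt / tau)
      cons[idx] <- cons[idx] + budget$q * w / sum(w) / dt
    }
    kick[i0] <- kick[i0] + params$ca_coupling
  }
  list(cons = cons, kick = kick)
}

#' Respiratory excursion driven by a spike train
#'
#' Starting from the baseline steady state, each spike spends the
#' per-spike cost `q` over its kernel window and decrements the proton
#' gradient by `ca_coupling` (calcium entering the matrix). The
#' trajectory relaxes back toward the steady state once the last kernel
#' has ended.
#'
#' @param params a [mito_params()] object.
#' @param budget an [energy_budget()].
#' @param spike_times spike times in ms, all within `[0, duration]`.
#' @param duration total simulated time (ms).
#' @param dt integration step (ms).
#' @param record_every record every this many steps (thins the output).
#' @return A tibble of class `"respiratory_trajectory"` with columns
#'   `time_ms, pyr, nadh, delta_psi, atp_m, atp_c, ros` and the baseline
#'   steady state attached as attribute `steady_state`.
#' @export
spike_excursion <- function(params = mito_params(),
                            budget = energy_budget(),
                            spike_times = 50, duration = 500,
                            dt = 0.01, record_every = 10L) {
  if (length(spike_times) &&
      (min(spike_times) < 0 || max(spike_times) > duration))
    stop("spike_excursion: spike_times must lie in [0, duration]",
         call. = FALSE)
  ss <- find_steady_state(params, budget, dt = dt)
  sig <- spike_consumption(budget, params, spike_times, duration, dt)
  out <- mito_integrate_cpp(as_mito_vec(ss), mito_par_vec(params),
                            consumption = sig$cons, psi_kick = sig$kick,
                            dt = dt, record_every = as.integer(record_every))
  traj <- tibble::as_tibble(as.data.frame(out))
  attr(traj, "steady_state") <- ss
  class(traj) <- c("respiratory_trajectory", class(traj))
  traj
}

#' Steady-state ROS across a grid of baseline consumption rates
#'
#' Sweeps the baseline (non-spiking) cost and records the fixed point of
#' the respiration model at each value. Over the default grid the ROS
#' column is V-shaped: high at low consumption (stalled chain, RETROS),
#' high at large consumption (overdriven chain, FETROS), with a unique
#' interior minimum. [ros_curve_minimum()] returns the minimising rate,
#' the model's notion of the ideal ATP expenditure.
#'
#' @param params a [mito_params()] object.
#' @param baseline_grid increasing vector of baseline costs to sweep.
#' @param dt,tol,t_max forwarded to [find_steady_state()].
#' @return A tibble of class `"ros_curve"` with columns
#'   `baseline, atp_m_ss, delta_psi_ss, ros_ss`.
#' @export
ros_vs_baseline_curve <- function(params = mito_params(),
                                  baseline_grid = seq(0.002, 0.09,
                                                      length.out = 50),
                                  dt = 0.01, tol = 1e-9, t_max = 4e5) {
  if (is.unsorted(baseline_grid))
    stop("baseline_grid must be increasing", call. = FALSE)
  init <- mito_state()
  rows <- vector("list", length(baseline_grid))
  for (i in seq_along(baseline_grid)) {
    ss <- find_steady_state(params,
                            energy_budget(baseline_cost = baseline_grid[i]),
                            dt = dt, tol = tol, t_max = t_max, init = init)
    rows[[i]] <- tibble::tibble(baseline = baseline_grid[i],
                                atp_m_ss = ss$atp_m,
                                delta_psi_ss = ss$delta_psi,
                                ros_ss = ss$ros)
    init <- ss # warm start: the fixed point moves continuously
  }
  curve <- dplyr::bind_rows(rows)
  class(curve) <- c("ros_curve", class(curve))
  curve
}

#' Locate the ROS minimum of a consumption sweep
#'
#' @param curve a `"ros_curve"` tibble from [ros_vs_baseline_curve()].
#' @return One-row tibble: the grid point with minimal steady-state ROS.
#' @export
ros_curve_minimum <- function(curve) {
  curve[which.min(curve$ros_ss), , drop = FALSE]
}

#' Effect of additional spiking on time-averaged ROS
#'
#' Simulates the model at a fixed baseline with and without extra
#' spiking and returns the difference in mean ROS over the same
#' post-transient window. From a RETROS (low-consumption) baseline the
#' difference is negative (spikes quench ROS); from a FETROS
#' (high-consumption) baseline it is positive.
#'
#' @param params a [mito_params()] object.
#' @param budget an [energy_budget()]; its `baseline_cost` sets the
#'   operating point and `q` the per-spike cost.
#' @param rate_hz spike rate of the added train.
#' @param duration simulated window (ms).
#' @param transient initial portion (ms) discarded before averaging.
#' @param seed if not `NULL`, spike times are drawn as a Poisson train
#'   with this seed; otherwise the train is periodic at `rate_hz`.
#' @param dt integration step (ms).
#' @return Signed scalar: mean ROS with spiking minus mean ROS without.
#' @export
spike_effect_on_ros <- function(params = mito_params(),
                                budget = energy_budget(),
                                rate_hz = 20, duration = 6000,
                                transient = 2000, seed = NULL,
                                dt = 0.01) {
  if (is.null(seed)) {
    period <- 1000 / rate_hz
    spikes <- seq(period, duration - budget$q_kernel_duration, by = period)
  } else {
    tr <- poisson_fixture(rate_hz, duration - budget$q_kernel_duration,
                          n_trains = 1, seed = seed)
    spikes <- tr$time_ms
  }
  ss <- find_steady_state(params, budget, dt = dt)
  sig <- spike_consumption(budget, params, spikes, duration, dt)
  rec <- max(1L, round(1 / dt)) # 1-ms resolution is ample for means
  with_sp <- mito_integrate_cpp(as_mito_vec(ss), mito_par_vec(params),
                                sig$cons, sig$kick, dt, rec)
  without <- mito_integrate_cpp(as_mito_vec(ss), mito_par_vec(params),
                                rep(budget$baseline_cost, length(sig$cons)),
                                numeric(length(sig$cons)), dt, rec)
  keep <- with_sp[, "time_ms"] >= transient
  mean(with_sp[keep, "ros"]) - mean(without[keep, "ros"])
}
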