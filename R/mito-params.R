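#' Parameters of the reduced mitochondrial respiration model
#'
#' The backbone tracks six normalised state variables: a pyruvate pool
#' feeding the TCA cycle, the NADH fraction (NAD+ fraction is
#' `1 - nadh`), the proton gradient `delta_psi` across the inner
#' membrane, the mitochondrial ATP fraction `atp_m` (ADP fraction
#' `1 - atp_m`), cytosolic ATP `atp_c`, and the ROS level. ROS relaxes
#' with time constant `tau_ros` toward a steady state that is cubic in
#' the respiratory operating point: reverse-transport ROS (RETROS)
#' grows with `atp_m * delta_psi` and forward-transport ROS (FETROS)
#' with `(1 - atp_m) * (1 - delta_psi)`, weighted by `f_ret` and
#' `f_fet` respectively (see [ros_steady_state()]).
#'
#' Rate constants are per millisecond and were calibrated once so that
#' (a) the steady-state ROS curve over the default baseline-consumption
#' grid is V-shaped with a unique interior minimum, and (b) spiking from
#' the low-consumption (RETROS) corner of the state space lowers
#' time-averaged ROS. They are not transcriptions of measured kinetics;
#' physical units are out of scope.
#'
#' @param f_ret,f_fet dimensionless gains of RETROS and FETROS
#'   production; both must be non-negative.
#' @param tau_ros ROS relaxation time constant (ms), positive.
#' @param k_pyr pyruvate supply rate toward `pyr_max`.
#' @param pyr_max pyruvate pool ceiling (normalised).
#' @param k_tca rate of pyruvate oxidation producing NADH.
#' @param k_etc rate of NADH oxidation by the electron transport chain.
#' @param n_pump protons pumped per NADH oxidised (gradient gain).
#' @param k_synth ATP-synthase (complex V) rate converting the gradient
#'   and mitochondrial ADP into ATP.
#' @param k_ant adenine nucleotide translocator exchange rate between
#'   mitochondrial ATP and cytosolic ADP.
#' @param k_leak proton leak rate degrading the gradient.
#' @param km_use half-saturation of cytosolic ATP consumption, so
#'   demand tapers off instead of overdrawing the pool.
#' @param ca_coupling decrement of `delta_psi` per spike from calcium
#'   influx into the matrix.
#' @return A named list of class `"mito_params"`.
#' @seealso [energy_budget()], [mito_state()], [find_steady_state()]
#' @export
#' @examples
#' p <- mito_params(f_ret = 1.2)
#' p$f_ret
mito_params <- function(f_ret = 1, f_fet = 1, tau_ros = 200,
                        k_pyr = 0.05, pyr_max = 1, k_tca = 0.1,
                        k_etc = 0.2, n_pump = 2, k_synth = 0.5,
                        k_ant = 1, k_leak = 0.005, km_use = 0.05,
                        ca_coupling = 0.01) {
  p <- list(f_ret = f_ret, f_fet = f_fet, tau_ros = tau_ros,
            k_pyr = k_pyr, pyr_max = pyr_max, k_tca = k_tca,
            k_etc = k_etc, n_pump = n_pump, k_synth = k_synth,
            k_ant = k_ant, k_leak = k_leak, km_use = km_use,
            ca_coupling = ca_coupling)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]]))
      stop("mito_params: `", nm, "` must be a finite numeric scalar",
           call. = FALSE)
  }
  if (f_ret < 0 || f_fet < 0)
    stop("mito_params: f_ret and f_fet must be >= 0", call. = FALSE)
  if (tau_ros <= 0)
    stop("mito_params: tau_ros must be > 0", call. = FALSE)
  rates <- c("k_pyr", "pyr_max", "k_tca", "k_etc", "n_pump", "k_synth",
             "k_ant", "k_leak", "km_use")
  for (nm in rates)
    if (p[[nm]] < 0)
      stop("mito_params: `", nm, "` must be >= 0", call. = FALSE)
  if (ca_coupling < 0)
    stop("mito_params: ca_coupling must be >= 0", call. = FALSE)
  structure(p, class = "mito_params")
}

#' A neuron's ATP budget: baseline cost and per-spike cost
#'
#' The baseline (non-spiking) cost is the slow-varying ATP drain of
#' input processing and maintenance; `q` is the additional transient
#' ATP spent per action potential, spread over `q_kernel_duration`
#' milliseconds rather than applied as an instantaneous decrement so
#' that trajectories stay smooth.
#'
#' @param baseline_cost non-spiking ATP consumption rate (normalised
#'   ATP per ms), `>= 0`.
#' @param q per-spike ATP cost (normalised ATP, total excess over
#'   baseline), `>= 0`.
#' @param q_kernel_duration window (ms) over which `q` is spent, `> 0`.
#' @param q_kernel_shape temporal profile of the spending,
#'   `"rectangular"` (default) or `"exponential"`.
#' @return A named list of class `"energy_budget"`.
#' @export
#' @examples
#' energy_budget(baseline_cost = 0.01, q = 0.05)
energy_budget <- function(baseline_cost = 0.01, q = 0.05,
                          q_kernel_duration = 5,
                          q_kernel_shape = c("rectangular", "exponential")) {
  q_kernel_shape <- match.arg(q_kernel_shape)
  if (baseline_cost < 0) stop("baseline_cost must be >= 0", call. = FALSE)
  if (q < 0) stop("q must be >= 0", call. = FALSE)
  if (q_kernel_duration <= 0)
    stop("q_kernel_duration must be > 0", call. = FALSE)
  structure(list(baseline_cost = baseline_cost, q = q,
                 q_kernel_duration = q_kernel_duration,
                 q_kernel_shape = q_kernel_shape),
            class = "energy_budget")
}

#' Instantaneous mitochondrial state
#'
#' Returns a one-row tibble holding the six integrated variables plus
#' matrix calcium `ca_m` (carried for bookkeeping; calcium acts on the
#' model only through the per-spike `ca_coupling` decrement of
#' `delta_psi`). The adenine and NAD pools are conserved by
#' construction: `adp_m = 1 - atp_m` and `nad = 1 - nadh` at all times.
#'
#' @param pyr,nadh,delta_psi,atp_m,atp_c,ros,ca_m initial values;
#'   fractions must lie in `[0, 1]`, `ros` and `ca_m` must be `>= 0`.
#' @return A one-row tibble of class `"mito_state"`.
#' @export
mito_state <- function(pyr = 0.5, nadh = 0.5, delta_psi = 0.5,
                       atp_m = 0.5, atp_c = 0.5, ros = 0.1, ca_m = 0) {
  for (v in c(nadh, delta_psi, atp_m, atp_c))
    if (v < 0 || v > 1)
      stop("mito_state: fractions must lie in [0, 1]", call. = FALSE)
  if (pyr < 0 || ros < 0 || ca_m < 0)
    stop("mito_state: pyr, ros and ca_m must be >= 0", call. = FALSE)
  st <- tibble::tibble(pyr = pyr, nadh = nadh, delta_psi = delta_psi,
                       atp_m = atp_m, atp_c = atp_c, ros = ros,
                       ca_m = ca_m)
  class(st) <- c("mito_state", class(st))
  st
}

as_mito_vec <- function(state) {
  unlist(state[1, c("pyr", "nadh", "delta_psi", "atp_m", "atp_c", "ros")])
}

mito_par_vec <- function(params) {
  unlist(params[c("k_pyr", "pyr_max", "k_tca", "k_etc", "n_pump",
                  "k_synth", "k_ant", "k_leak", "km_use", "tau_ros",
                  "f_ret", "f_fet")])
}
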