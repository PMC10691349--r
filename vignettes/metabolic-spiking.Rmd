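---
title: "Metabolically regulated spiking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolically regulated spiking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaspike)
library(dplyr)
```

# The idea

Neurons pay for synaptic input processing and for every action
potential in ATP, and their mitochondria match that demand on the fly.
Electron escape from the respiratory chain produces reactive oxygen
species (ROS) at *both* ends of the demand axis: when demand is high
the chain is overdriven and leaks during forward electron transport
(FETROS); when demand is very low, mitochondrial ADP runs out, the
proton gradient saturates, the chain stalls, and reverse electron
transport (RETROS) leaks instead. Between the two lies a consumption
rate at which ROS is minimal. `metaspike` implements a family of four
models built on one hypothesis: neurons sense where they sit on this
V-shaped curve and adjust their excitability to stay near its bottom —
firing "metabolic" spikes to burn surplus ATP when RETROS looms, and
suppressing firing when FETROS looms.

The four models, in increasing integration:

1. a reduced **mitochondrial respiration model** with ROS production
   (`find_steady_state()`, `ros_vs_baseline_curve()`,
   `spike_excursion()`, `spike_effect_on_ros()`);
2. a **metabolic-accounting neuron** that turns the metabolic state
   into firing decisions through two thresholds
   (`simulate_accounting()`, `phase_diagram()`);
3. a **conductance-based neuron with an A-type K⁺ channel** whose
   inactivation is removed by ROS (`voltage_clamp()`,
   `current_clamp()`);
4. a **recurrent spiking network** in which a per-neuron metabolic
   current turns transient, externally driven activity into
   self-sustained activity (`simulate_network()`), analysed with
   avalanche statistics (`detect_avalanches()`, `fit_power_law()`).

# The respiration backbone

The mitochondrial model integrates six normalised variables: pyruvate
`pyr`, the NADH fraction `nadh` (NAD⁺ is `1 - nadh`), the inner-membrane
proton gradient `delta_psi`, the mitochondrial ATP fraction `atp_m`
(ADP is `1 - atp_m`), cytosolic ATP `atp_c`, and `ros`. Fluxes are
mass-action or saturating: pyruvate supply, TCA oxidation of pyruvate
into NADH, NADH oxidation pumping protons (gain `n_pump`), ATP
synthesis by complex V from the gradient and mitochondrial ADP, the
adenine nucleotide translocator exchanging mitochondrial ATP against
cytosolic ADP, a proton leak, and a demand term that consumes
cytosolic ATP at the requested rate with half-saturation `km_use`
(so the pool cannot be overdrawn). Because only one member of each
conserved pair is stored, the adenine and NAD pools are conserved
*exactly*, not approximately.

ROS relaxes with time constant `tau_ros` toward an equilibrium that is
cubic in the operating point,

$$\mathrm{ROS}_\infty = \bigl(\mathrm{ATP}_M\,\Delta\Psi\, f_{RET} +
  (1-\mathrm{ATP}_M)(1-\Delta\Psi)\, f_{FET}\bigr)^3,$$

large in the upper-right corner of the (ATP$_M$, $\Delta\Psi$) plane
(stalled chain, RETROS) and in the lower-left corner (overdriven
chain, FETROS). The product form is read as multiplication by the
gains $f_{RET}$ and $f_{FET}$; both default to 1.

Exact rate laws and constants of the detailed respiration models in
the literature are not reproduced here; the backbone is deliberately
minimal, exposing every rate constant in `mito_params()` so a richer
model can be swapped in. The defaults (`k_pyr = 0.05`, `k_tca = 0.1`,
`k_etc = 0.2`, `n_pump = 2`, `k_synth = 0.5`, `k_ant = 1`,
`k_leak = 0.005`, `km_use = 0.05`, `tau_ros = 200` ms, all per-ms
units) were chosen once so that the fixed-point geometry is correct —
zero demand parks the model at `atp_m ≈ 0.98`, `delta_psi ≈ 0.96`
(RETROS corner), demand near the admissible maximum at
`atp_m ≈ 0.07`, `delta_psi ≈ 0.13` (FETROS corner), and the
steady-state ROS over the default baseline grid
(`seq(0.002, 0.09)` ATP/ms) is V-shaped with a unique interior minimum
near 0.06 ATP/ms — and were not revisited afterwards. They are not
fits to measured kinetics, and physical units (mM, mV) are out of
scope.

Integration is a fixed-step classical Runge–Kutta (RK4) scheme,
default `dt = 0.01` ms. The system is not stiff at these scales; the
test suite checks that halving `dt` moves trajectory endpoints by less
than $10^{-6}$. A state variable leaving its admissible range raises
an error advising a smaller `dt` — never a silent clip — so parameter
pathologies surface in tests rather than being absorbed.

Spike costs enter through `energy_budget()`: a baseline (non-spiking)
consumption rate plus a per-spike cost `q` spread over a kernel
(default rectangular, 5 ms for the respiration model). Spreading the
cost keeps the trajectory smooth; an instantaneous ATP decrement would
defeat the integrator's error behaviour. Each spike also decrements
`delta_psi` by `ca_coupling` (default 0.01), the lumped effect of
calcium entering the matrix during a spike.

`spike_effect_on_ros()` quantifies the central claim at this level:
from a low-demand baseline extra spiking *lowers* time-averaged ROS
(it resupplies ADP and relieves the stall), while from a high-demand
baseline it raises ROS. Spike trains may be periodic or Poisson
(seeded), and the comparison window starts after a transient long
relative to `tau_ros`.

# The accounting neuron

The simplified neuron reduces the metabolic state to a single signed
**metabolic signal** $\mathrm{MS} = \mathrm{ROS}\times(\mathrm{ATP} -
\overline{\mathrm{ATP}})$, where $\overline{\mathrm{ATP}}$ is the ATP
level at the ROS minimum. High ROS with surplus ATP (RETROS) gives a
large positive MS; high ROS with depleted ATP (FETROS) a large
negative one. Two thresholds gate firing:

* `MS > theta_ret` (default 0.15): the neuron fires a *metabolic*
  spike on its own, spending `q` and quenching RETROS;
* `theta_fet < MS < theta_ret`: no intrinsic firing, but
  suprathreshold synaptic drive may elicit spikes;
* `MS < theta_fet` (default −0.15): all spiking, including driven
  spiking, is blocked.

The default ROS/ATP backend is phenomenological: ATP relaxes (`tau_atp`
= 50 ms) toward `1 - c/c_max` and ROS relaxes (`tau_ros` = 100 ms)
toward the V-shaped `ros_min + v_slope |c - c_bar|`, where `c` is the
instantaneous consumption rate. This keeps the threshold logic
decoupled from the ODE and makes 100-cell phase diagrams essentially
free. Setting `ros_backend = "mito"` drives the same gating logic from
the full respiration model (pooled ATP read as cytosolic ATP — the
model carries one effective ATP level; the mitochondrial/cytosolic
distinction is below its resolution); a test verifies that the
backend's ROS trace matches a standalone respiration run given the
same consumption history to $10^{-3}$. The two backends produce MS on
different scales (the cytosolic ATP excursion is an order of magnitude
smaller), so thresholds must be chosen per backend; the defaults
belong to the phenomenological one.

The per-spike kernel (default `q = 0.3` over 20 ms) deliberately
outlasts the refractory period (5 ms). That lag is what creates
discrete firing episodes: during a burst the kernels pile up, MS
overshoots below `theta_ret`, and firing stops until the slower ATP
and ROS variables recover. Expensive spikes (`q` ≳ 1) quench in one or
two spikes (tonic single spiking); intermediate costs give bursts;
very cheap spikes never push MS below threshold and firing is
continuous at the refractory limit. With a kernel no longer than the
refractory period the neuron instead rides the threshold smoothly and
every active regime collapses into continuous firing — a useful
negative control, but not the regime of interest.

`classify_pattern()` makes the qualitative vocabulary operational,
since no quantitative definitions exist for it: *silent* below 0.1 Hz;
*bursting* when at least two inter-spike intervals exceed 5× the
median ISI (two between-burst gaps, hence at least two episode
boundaries); *continuous* at ≥ 50 Hz with no ISI above 2× the median;
*tonic* otherwise. All cutoffs live in `pattern_criteria()`.
`phase_diagram()` sweeps (baseline, `q`); the default grid spans
baseline 0.002–0.05 (the intrinsically active band plus the silent
edge) and `q` 0.02–2 log-spaced. The high-baseline edge is silent
because MS at the V-bottom is zero by construction; all four labels
occur on the default grid.

External drive is represented as suprathreshold drive times (a boolean
per step), not a current: the accounting model has no membrane
equation, so "drive present and not blocked" is the faithful
abstraction.

# The A-type switching neuron

The single-cell conductance model asks whether one documented channel
modification suffices to change firing the way the metabolic theory
needs. In fly sleep-switch neurons, ROS-driven conversion of NADPH to
NADP⁺ strips the inactivation mechanism from the Shaker/Hyperkinetic
A-type K⁺ channel; the fast-inactivating current becomes sustained and
firing increases.

The implementation uses Connor–Stevens Na⁺/delayed-rectifier/leak
kinetics with two deviations, both deliberate. First, the leak
reversal is −70 mV rather than the textbook −17 mV: the original model
balances its depolarising leak with a subthreshold-activating A-type
current, but here the A-type activation must be reserved for spike
repolarisation (below), so the resting state has to be stable without
it. Second, the A-type gates are Boltzmann functions — activation
midpoint −25 mV (slope 6 mV, $\tau$ = 0.5 ms), inactivation midpoint
−60 mV (slope 8 mV, $\tau$ = 15 ms) — i.e. a Kv4-style current that
engages only during the spike upstroke. With the literature's
subthreshold A-type activation, removing inactivation floods the cell
with standing outward current and silences it, which is the opposite
of the observed phenotype; with spike-range activation, removing
inactivation strengthens repolarisation, spares the slower delayed
rectifier, and shortens inter-spike intervals. Every midpoint, slope
and time constant is a `channel_params()` field, so other kinetics can
be imposed.

ROS enters as a continuous removal fraction $\rho \in [0,1]$:
$h_{A,\mathrm{eff}} = (1-\rho)h_A + \rho$ (gate-removal mode, default),
or, under `rho_mode = "slow_tau"`, as a stretching of the inactivation
time constant toward `tau_ha_slow` — the two readings of "slowed
inactivation", both provided, same ordinal behaviour.
`ros_to_rho()` supplies a saturating Hill map (zero at zero ROS) from
ROS level to $\rho$. The claims tested are ordinal only: under a
voltage-clamp step from −90 mV to +40 mV the A-current decays to a low
plateau at $\rho=0$ and is sustained at $\rho=1$; under an identical
20 pA current clamp the spike count at $\rho=1$ exceeds $\rho=0$
(106 vs 97 in 500 ms at defaults, ≈ 9% — modest, as expected for a
single-channel modification), and the rate is nondecreasing in $\rho$.
Currents in pA are converted to densities through a 100 µm² membrane
area (1 pF cell), which puts 20 pA in the repetitive-firing range.
The miniSOG/AOX manipulations (optogenetic ROS delivery, alternative
oxidase relief) are additive shifts of the ROS-vs-consumption curve
floored at zero (`shifted_ros_curve()`).

Integration is forward Euler at `dt = 0.01` ms; spike detection is an
upward 0 mV crossing deduplicated within 2 ms. Halving `dt` moves
spike times by well under 0.1 ms on the protocols used here.

# The network

`simulate_network()` couples 8,000 excitatory and 2,000 inhibitory
conductance-based leaky integrate-and-fire neurons (2% directed random
connectivity, no autapses) with exponential synapses — the standard
sparse balanced-network family: $\tau_m$ = 20 ms, rest/reset −60 mV,
threshold −50 mV, 5 ms refractory, $E_{ex}$ = 0 mV, $E_{in}$ = −80 mV,
$\tau_{ex}$ = 5 ms, $\tau_{in}$ = 10 ms. The routinely exercised
configuration is `reduced_network_config()`: 800/200 neurons at the
same connectivity with weights multiplied by $\sqrt{10}$ to preserve
input fluctuations; all sizes below refer to it. Full scale is
available but costs ~10× the time and memory.

Each neuron carries a metabolic state MS — here a bounded
cost-tracking reservoir in $[0, 1]$, not literally ROS × ∂ATP: it is
decremented by `cost_e` = `cost_i` = 5·10⁻⁴ per synaptic event and
`cost_spike` = 0.01 per emitted spike, and recovers toward
`ms_rest` = 0.8 with $\tau_{MS}$ = 1 s. The mapping to the accounting
model is monotone (low MS ≈ FETROS-side overdraft, high MS ≈
RETROS-side surplus) but not enforced; simulating per-neuron
respiration ODEs at network scale buys nothing for the claims tested.
MS drives a saturating metabolic current
$I_M = \mathrm{clip}(g_{IM}(MS - MS_0), \pm I_{max})$ with neutral
point $MS_0$ = 0.5, gain 600 pA per unit MS and bound 150 pA —
piecewise-linear by default because only sign, monotonicity and
saturation are constrained by the theory. At the leak conductance of
10 nS, +100 pA lifts a resting neuron to threshold, so metabolic
firing ignites when MS recovers past ≈ 0.67.

External drive is an independent Poisson event stream per neuron
(300 Hz, excitatory weight) until `stim_off`. By default external
events are charged to MS like recurrent ones (`ext_costs`), so the
driven network equilibrates at low MS (hyperpolarising $I_M$,
≈ 15 Hz mean rate — the metabolic brake against seizure-like rates).
After the drive stops, recurrence alone cannot sustain activity at
these weights and the network falls silent within tens of
milliseconds; MS then recovers over ~1.5 s, $I_M$ turns depolarising,
and the most-recovered neurons fire metabolic spikes that recruit
their similarly depolarised neighbours — recurring population
avalanches that keep the network active indefinitely. Ablating the
metabolic current (`im_gain = 0`) removes exactly this re-ignition:
the same network, seed and drive collapse permanently. Because spikes
carry their neuron's MS at emission, the two phases separate cleanly
in MS-at-spike (driven ≈ 0.42, self-sustained ≈ 0.63 at defaults).

Synaptic weights (reduced scale: `w_ex` = 2 nS, `w_in` = 20 nS,
external = 2 nS) were calibrated jointly with the drive rate so that
three conditions hold at once — driven activity is irregular at
moderate rate, the ablated network dies after drive removal, and the
enabled network persists — and then frozen. A property test scales
`w_ex` and `w_in` over a small grid and checks that the fraction of
settings with persistent, non-saturated activity is strictly larger
with the metabolic current than without (the self-tuning claim, in
scaled-down form).

Event handling uses a fixed 0.1 ms step, spike delivery delayed by one
step, conductances decaying by precomputed exponential factors, and
forward-Euler membrane updates. All randomness (initial potentials and
MS, Poisson drive) flows through R's RNG, so a seed makes runs
byte-reproducible; per-neuron event counters and the cumulative MS
charge are returned and must reconcile exactly with the raster and
adjacency (an accounting identity the tests recompute independently).
MS itself is clamped to $[0, 1]$; the counters record the nominal
charge.

# Avalanches and power laws

`detect_avalanches()` implements the canonical definition: bin
population spikes at 1 ms, and an avalanche is a maximal run of
nonempty bins bounded by ≥ 1 ms of silence. Duration counts bins (not
first-to-last spike time); size sums counts, so sizes and durations
partition the data exactly and size ≥ duration always. Other bin
widths are supported but labelled non-canonical.

`fit_power_law()` is a Clauset-style discrete fit: for each candidate
cutoff $x_{min}$ the exponent maximises the zeta likelihood
$P(X=k) = k^{-\alpha}/\zeta(\alpha, x_{min})$ (Hurwitz zeta evaluated
by Euler–Maclaurin summation, 64 direct terms plus correction — a test
brackets it between truncated-sum bounds), and $x_{min}$ minimises the
Kolmogorov–Smirnov distance between empirical and fitted tail CDFs,
compared at the observed support points since both are step functions.
Two guards matter in practice. The scan does not consider cutoffs
above the 90th sample percentile or tails below 50 observations:
with an unconstrained scan, *any* light-tailed sample offers some tiny
far tail that fits a power law locally, and the fit degenerates into a
statement about a handful of extreme points. And the `plausible` flag
compares the minimised KS distance against a fixed cutoff (0.03 by
default) — a deliberately simple screen, calibrated once against both
controls (zeta samples at $n = 10^4$ fit with KS ≈ 0.006; geometric
samples across a range of rates fit no better than KS ≈ 0.05), not a
formal hypothesis test; likelihood-ratio model comparison is out of
scope. Parameter recovery is part of the suite: exact inverse-CDF zeta
samples (`rpowerlaw()`) are refit with bias below 0.05 at $n = 10^5$
across exponents 1.3–2.5.

`size_duration_scaling()` regresses mean log-size per duration class
on log-duration — the crackling-noise scaling exponent; imposed
size = duration and size = duration² inputs recover slopes 1 and 2
exactly.

# Reproducibility plumbing

Every stochastic operation takes an explicit seed; `derive_seed()`
splits one run seed into per-component 32-bit streams so module
results do not depend on execution order. YAML run configs
(`load_config()`) reject unknown keys by path, fill defaults, and
round-trip through `save_config()`. Rasters are two-column text
(`neuron_id`, `time_ms`); traces are CSV with numerics printed to 9
significant digits, which makes "same seed, byte-identical file" a
testable contract; both writers drop a JSON sidecar with the seed,
config hash and package version. A thin command-line front end
(`inst/scripts/metaspike`) wraps the main entry points for shell use.

# Problem sizes and what the tests do not show

Routine runs and the test suite use: 50-point baseline grids for the
V-curve; 4–8 s accounting and respiration simulations; 100-cell phase
diagrams at 3–4 s per cell; 500 ms clamp protocols; and the 1,000-
neuron reduced network for 4–8 s of simulated time (about 1–3 s of
wall time each). These sizes make every headline claim testable in
seconds while leaving the full-scale network available through
`network_config()`.

The generators emulate idealised study conditions: homogeneous
parameters across neurons, Poisson externals, Bernoulli wiring, no
synaptic plasticity, no conduction-delay structure, a single lumped
ROS species, and a phenomenological MS in the network. Passing tests
therefore demonstrate that the *mechanisms* — V-shaped ROS, threshold
gating, inactivation-switch rate increase, metabolic self-sustainment
— behave as theorised within these models. They do not validate rate
constants against biochemistry, nor show that real neurons implement
these exact couplings; the models' purpose is to make the theory's
qualitative predictions precise enough to test.

Known limitations worth restating: the respiration backbone is a
minimal stand-in with calibrated (not measured) constants; the
accounting thresholds are backend-specific; the A-type result depends
on spike-range activation, which is a modelling choice motivated above;
the avalanche exponent of the reduced network is an emergent number at
a non-physiological scale and should not be compared quantitatively to
experimental exponents; and the power-law plausibility flag is a
screen, not a test.
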