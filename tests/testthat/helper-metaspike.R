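# Small shared fixtures; everything is generated in code.

tiny_network <- function(seed = 1, ...) {
  build_network(reduced_network_config(...), seed = seed)
}

# consumption/kick reconstruction used by the backend-consistency test
reconstruct_mito_trace <- function(sim, params, duration, dt,
                                   record_every = 10L) {
  ss <- find_steady_state(params$mito, params$budget, dt = dt)
  sig <- spike_consumption(params$budget, params$mito,
                           sim$spikes$time_ms + dt, duration, dt)
  kick <- numeric(length(sig$cons))
  idx <- floor(sim$spikes$time_ms / dt) + 1L
  for (i in idx) kick[i] <- kick[i] + params$mito$ca_coupling
  tr <- mito_integrate_cpp(as_mito_vec(ss), mito_par_vec(params$mito),
                           sig$cons, kick, dt, 1L)
  tr[seq(1, nrow(tr), by = record_every), ]
}

episode_sizes <- function(times, gap_ms = 15) {
  if (!length(times)) return(integer(0))
  splits <- cumsum(c(0, diff(times) > gap_ms))
  as.integer(table(splits))
}
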