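# Shared fixtures: the shipped parameter set, the model variants, and
# cheap simulation settings used across the unit tests.

p_ref <- da_params()
v_full <- model_variant()
v_red <- reduced_variant()
v_ca_k <- reduced_variant(include_sna = FALSE)

# short integration wrapper for tests that only need a rate
quick_rate <- function(params = p_ref, variant = v_full, syn = syn_drive(),
                       i_app = 0, duration = 6000, transient = 1500) {
  steady_rate(params, variant, syn, i_app, duration = duration,
              transient = transient,
              dt = if (variant$include_spike_currents) 0.025 else 0.05)
}

# brute-force merge of pulse intervals (oracle for coincidence_drive)
merge_pulses <- function(onsets, pulse) {
  if (!length(onsets)) return(matrix(numeric(0), ncol = 2))
  onsets <- sort(onsets)
  out <- list()
  st <- onsets[1]; en <- onsets[1] + pulse
  for (t0 in onsets[-1]) {
    if (t0 <= en) en <- t0 + pulse else {
      out[[length(out) + 1]] <- c(st, en)
      st <- t0; en <- t0 + pulse
    }
  }
  out[[length(out) + 1]] <- c(st, en)
  do.call(rbind, out)
}

# internal Wang-Buzsaki rates, used by the gating grid checks
wb_rates_test <- daneuron:::wb_rates
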