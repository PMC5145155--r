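# Heterogeneous DA-neuron populations under correlated NMDA drive, spike
# synchrony, and synaptic dopamine release.

#' Dopamine release / uptake parameters
#'
#' Release of `da_max` uM per spike and Michaelis-Menten uptake with
#' maximal rate `v_max` and transporter affinity `k_m`.
#'
#' @param da_max release per spike (uM).
#' @param v_max maximal uptake rate (uM/ms).
#' @param k_m transporter affinity (uM).
#' @return list of class `da_release_params`.
#' @export
da_release_params <- function(da_max = 0.1, v_max = 0.004, k_m = 0.2) {
  if (any(c(da_max, v_max, k_m) <= 0)) stop("all parameters must be > 0")
  structure(list(da_max = da_max, v_max = v_max, k_m = k_m),
            class = "da_release_params")
}

#' Synaptic dopamine concentration from pooled spikes
#'
#' Integrates `d[DA]/dt = DA_max delta(t - t_spike) - V_max [DA]/(K_m +
#' [DA])`: an instantaneous increment of `da_max` per spike and
#' Michaelis-Menten uptake between spikes.  The concentration never goes
#' negative and, once spiking stops, decays monotonically to 0.
#'
#' At a steady pooled rate f (spikes/s) with `da_max * f < v_max` the
#' time-averaged plateau is `k_m * da_max * f / (v_max - da_max * f)`
#' (flux balance), which the simulation reproduces.
#'
#' @param spikes pooled spike times (ms), any order.
#' @param p a [da_release_params()].
#' @param duration trace length (ms); defaults to just past the last spike.
#' @param dt time step (ms), > 0.
#' @param da0 initial concentration (uM).
#' @return object of class `da_trace`: `time` (ms), `da` (uM),
#'   `cum_release` (uM released up to t), and the source `spikes`.
#' @export
da_release <- function(spikes, p = da_release_params(), duration = NULL,
                       dt = 0.5, da0 = 0) {
  stopifnot(dt > 0)
  spikes <- sort(spikes)
  if (is.null(duration)) {
    duration <- if (length(spikes)) max(spikes) + 500 else 1000
  }
  da <- .da_release_cpp(spikes, duration, dt, p$da_max, p$v_max, p$k_m, da0)
  tg <- seq(0, by = dt, length.out = length(da))
  cum <- p$da_max * vapply(tg, function(t) sum(spikes <= t), numeric(1))
  structure(list(time = tg, da = da, cum_release = cum, spikes = spikes,
                 params = p),
            class = "da_trace")
}

#' Flux-balance dopamine plateau
#'
#' Closed-form time-averaged plateau concentration for regular spiking at
#' rate `f` Hz (valid while `da_max * f` is below the maximal uptake rate).
#'
#' @param f firing rate (Hz).
#' @param p a [da_release_params()].
#' @return plateau concentration (uM).
#' @export
da_plateau <- function(f, p = da_release_params()) {
  rel <- p$da_max * f / 1000   # uM/ms released
  if (any(rel >= p$v_max)) stop("release exceeds maximal uptake: no plateau")
  p$k_m * rel / (p$v_max - rel)
}

#' Specification of a heterogeneous DA-neuron population
#'
#' Heterogeneity is introduced by per-neuron leak conductances drawn
#' uniformly within `leak_spread` of the reference value (a range that
#' keeps every neuron tonically active in control).  All neurons receive
#' correlated fluctuating NMDA drive ([ou_spec()]); the `tonic_tone` and
#' `etoh` conditions additionally apply tonic AMPA and GABA conductances
#' (and, for EtOH, a stronger Ih), balanced so the mean firing rate stays
#' within 10% of control.
#'
#' @param n_neurons population size (>= 2).
#' @param condition `"control"`, `"tonic_tone"`, or `"etoh"`.
#' @param ou an [ou_spec()] for the NMDA drive.
#' @param leak_spread relative half-width of the leak heterogeneity.
#' @param tone list with `g_ampa`, `g_gaba` (tonic conductances) and `g_h`
#'   (absolute Ih conductance) applied in the `tonic_tone` / `etoh`
#'   conditions; `g_h` defaults to the base parameters' value, so the tone
#'   changes only the synaptic background unless EtOH scales it.
#' @param params base [da_params()].
#' @param seed RNG seed (leak draws, initial phases, OU noise).
#' @return list of class `population_spec`.
#' @export
population_spec <- function(n_neurons = 50,
                            condition = c("control", "tonic_tone", "etoh"),
                            ou = ou_spec(mu = 1.5, sigma = 0.5, c = 0.5,
                                         tau = 5),
                            leak_spread = 0.15,
                            tone = NULL,
                            params = da_params(g_h = 2), seed = 1) {
  condition <- match.arg(condition)
  if (n_neurons < 2) stop("n_neurons must be >= 2")
  if (is.null(tone)) tone <- list(g_ampa = 0.4, g_gaba = 1.0,
                                  g_h = params$g_h)
  structure(list(n_neurons = n_neurons, condition = condition, ou = ou,
                 leak_spread = leak_spread, tone = tone, params = params,
                 seed = seed),
            class = "population_spec")
}

#' Simulate a heterogeneous DA population under correlated NMDA drive
#'
#' Each neuron receives the shared-plus-independent OU NMDA conductance of
#' its spec (the NMDA stimulus is applied from `t_stim_on` to the end of
#' the simulation; before that the population fires at its background
#' rate).  Conditions other than control add the tonic AMPA/GABA (and Ih)
#' tone throughout.  Outputs the spike raster, the summed population
#' activity in bins, and the synaptic dopamine trace from the pooled
#' spikes.
#'
#' @param spec a [population_spec()].
#' @param duration total simulated time (ms).
#' @param t_stim_on onset of the fluctuating NMDA input (ms).
#' @param dt integration step (ms).
#' @param bin bin width of the summed activity (ms).
#' @param nmda_drive optional precomputed conductance matrix
#'   (`(duration/dt + 1) x n_neurons`), e.g. from [sine_modulated_ou()];
#'   overrides the spec's OU drive (still gated by `t_stim_on`).
#' @return list of class `population_result`: `raster` (data.frame
#'   `neuron`, `time_ms`), `bins`, `summed` (spike counts per bin),
#'   `da` (a `da_trace`), `rates` (per-neuron Hz over the stimulus
#'   window), `mean_rate`, `spec`.
#' @export
simulate_population <- function(spec, duration = 14000, t_stim_on = 4000,
                                dt = 0.05, bin = 50, nmda_drive = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_neurons
  set.seed(spec$seed)
  gl <- spec$params$g_l * runif(n, 1 - spec$leak_spread,
                                1 + spec$leak_spread)
  v0 <- runif(n, -70, -45)
  nstep <- round(duration / dt)
  if (is.null(nmda_drive)) {
    # OU noise drawn from the spec seed stream: common first, then
    # independent per neuron (order fixes reproducibility)
    a <- exp(-dt / spec$ou$tau)
    b <- sqrt(1 - a^2)
    xc <- ou_unit(nstep, dt, spec$ou$tau, x0 = rnorm(1))
    xi <- matrix(NA_real_, nstep + 1, n)
    for (j in seq_len(n)) xi[, j] <- ou_unit(nstep, dt, spec$ou$tau)
    nmda_drive <- spec$ou$mu + spec$ou$sigma *
      (sqrt(1 - spec$ou$c) * xi + sqrt(spec$ou$c) * xc)
    nmda_drive[nmda_drive < 0] <- 0
  }
  gate <- as.numeric(seq(0, nstep) * dt >= t_stim_on)
  tone_on <- spec$condition %in% c("tonic_tone", "etoh")
  spikes <- vector("list", n)
  for (j in seq_len(n)) {
    p <- within_params(spec$params, g_l = gl[j],
                       g_h = if (tone_on) spec$tone$g_h else spec$params$g_h)
    s <- syn_drive(g_ampa = if (tone_on) spec$tone$g_ampa else 0,
                   g_gaba = if (tone_on) spec$tone$g_gaba else 0)
    s$g_nmda <- nmda_drive[, j] * gate
    sim <- integrate_da(p, model_variant(), s, i_app = 0, duration, dt,
                        init = da_state(v = v0[j]), record_every = 0)
    spikes[[j]] <- sim$spikes
  }
  raster <- data.frame(
    neuron = rep(seq_len(n), lengths(spikes)),
    time_ms = unlist(spikes))
  bins <- seq(0, duration, by = bin)
  summed <- if (nrow(raster)) {
    tabulate(findInterval(raster$time_ms, bins), nbins = length(bins) - 1)
  } else {
    integer(length(bins) - 1)
  }
  stim_ms <- duration - t_stim_on
  rates <- vapply(spikes, function(s) sum(s >= t_stim_on) / stim_ms * 1000,
                  numeric(1))
  pooled <- sort(raster$time_ms)
  structure(list(raster = raster, bins = bins, summed = summed,
                 da = da_release(pooled, duration = duration, dt = 1),
                 rates = rates, mean_rate = mean(rates),
                 t_stim_on = t_stim_on, duration = duration, spec = spec),
            class = "population_result")
}

#' Spike synchrony index of a population raster
#'
#' Variance of the binned population rate normalized by its expectation
#' under independent firing, estimated by circularly shifting each
#' neuron's spike train by a random offset (which preserves every
#' single-neuron statistic while destroying cross-neuron alignment).
#' Values near 1 indicate asynchrony; values well above 1, synchrony.
#'
#' @param raster data.frame with columns `neuron` and `time_ms`.
#' @param t_range analysis window (ms), length 2.
#' @param bin bin width (ms).
#' @param n_shuffle number of shifted surrogates for the null.
#' @param seed RNG seed for the surrogate shifts.
#' @return synchrony index (>= 0; `NA` for an empty raster).
#' @export
synchrony_index <- function(raster, t_range, bin = 20, n_shuffle = 20,
                            seed = 1) {
  if (!nrow(raster)) return(NA_real_)
  ids <- unique(raster$neuron)
  if (length(ids) < 2) stop("need at least 2 neurons")
  edges <- seq(t_range[1], t_range[2], by = bin)
  count_var <- function(times) {
    cnt <- tabulate(findInterval(times, edges), nbins = length(edges) - 1)
    var(cnt)
  }
  keep <- raster$time_ms >= t_range[1] & raster$time_ms < t_range[2]
  obs <- count_var(raster$time_ms[keep])
  span <- diff(t_range)
  set.seed(seed)
  null <- vapply(seq_len(n_shuffle), function(k) {
    sh <- raster
    for (id in ids) {
      off <- runif(1, 0, span)
      i <- sh$neuron == id
      sh$time_ms[i] <- t_range[1] +
        (sh$time_ms[i] - t_range[1] + off) %% span
    }
    kp <- sh$time_ms >= t_range[1] & sh$time_ms < t_range[2]
    count_var(sh$time_ms[kp])
  }, numeric(1))
  obs / mean(null)
}

#' Control vs tonic-synaptic-tone population comparison
#'
#' Runs the same population (same seed, same NMDA drive) with and without
#' the tonic AMPA/GABA background tone, balanced so the mean firing rate
#' matches (within `rate_tol`); errors if the shipped tone is out of
#' balance.  Returns both results with their synchrony indices and
#' cumulative dopamine over the stimulus window.
#'
#' @param spec a [population_spec()] with condition `"tonic_tone"` (its
#'   tone values are used).
#' @param duration,t_stim_on,dt,bin as in [simulate_population()].
#' @param rate_tol admissible relative mean-rate mismatch.
#' @return list of class `population_comparison` with `control`, `tone`,
#'   `sync_control`, `sync_tone`, `da_control`, `da_tone` (cumulative uM
#'   released during the stimulus), `rate_control`, `rate_tone`.
#' @export
tonic_tone_protocol <- function(spec, duration = 14000, t_stim_on = 4000,
                                dt = 0.05, bin = 20, rate_tol = 0.1) {
  stopifnot(inherits(spec, "population_spec"))
  ctrl_spec <- spec; ctrl_spec$condition <- "control"
  tone_spec <- spec; tone_spec$condition <- "tonic_tone"
  ctrl <- simulate_population(ctrl_spec, duration, t_stim_on, dt)
  tone <- simulate_population(tone_spec, duration, t_stim_on, dt)
  if (abs(tone$mean_rate - ctrl$mean_rate) >
      rate_tol * max(ctrl$mean_rate, 1e-9)) {
    stop(sprintf(
      "unbalanced tone: mean rate %.2f Hz (tone) vs %.2f Hz (control)",
      tone$mean_rate, ctrl$mean_rate))
  }
  window <- c(t_stim_on, duration)
  # net rise of the synaptic DA concentration across the stimulus window
  # (uM): with the pooled population drive the uptake runs near saturation,
  # so this tracks the population's burst output
  cum_da <- function(res) {
    i <- res$da$time >= window[1]
    max(res$da$da[i]) - res$da$da[i][1]
  }
  structure(list(control = ctrl, tone = tone,
                 sync_control = synchrony_index(ctrl$raster, window, bin),
                 sync_tone = synchrony_index(tone$raster, window, bin),
                 da_control = cum_da(ctrl), da_tone = cum_da(tone),
                 rate_control = ctrl$mean_rate,
                 rate_tone = tone$mean_rate),
            class = "population_comparison")
}

#' Ethanol (EtOH) condition protocol
#'
#' EtOH enhances Ih and the AMPA and GABA receptor currents.  The protocol
#' runs seed-matched control and EtOH populations under identical
#' sine-modulated NMDA drive; the EtOH condition multiplies the tone's
#' Ih, AMPA and GABA conductances by the given factors (all 1 reproduces
#' the control bit-for-bit).
#'
#' @param spec a [population_spec()].
#' @param base_tone the standing synaptic background both arms receive
#'   before EtOH scaling (defaults to a mild AMPA/GABA tone with the base
#'   Ih); the EtOH arm multiplies it.
#' @param multipliers list with `g_h`, `g_ampa`, `g_gaba` factors (>= 1).
#' @param mod_freq,mod_depth sine modulation of the NMDA mean (Hz, 0-1).
#' @param duration,t_stim_on,dt,bin as in [simulate_population()].
#' @return `population_comparison` (control vs EtOH).
#' @export
etoh_protocol <- function(spec,
                          multipliers = list(g_h = 3.5, g_ampa = 3,
                                             g_gaba = 2.5),
                          base_tone = NULL,
                          mod_freq = 1, mod_depth = 0.8,
                          duration = 14000, t_stim_on = 4000,
                          dt = 0.05, bin = 20) {
  stopifnot(inherits(spec, "population_spec"))
  if (any(unlist(multipliers) < 1)) stop("multipliers must be >= 1")
  if (is.null(base_tone)) {
    base_tone <- list(g_ampa = 0.2, g_gaba = 0.5, g_h = spec$params$g_h)
  }
  drive <- sine_modulated_ou(spec$ou, mod_freq, mod_depth, duration, dt,
                             n_targets = spec$n_neurons)
  ctrl_spec <- spec; ctrl_spec$condition <- "tonic_tone"
  ctrl_spec$tone <- base_tone
  et_spec <- spec; et_spec$condition <- "etoh"
  et_spec$tone <- list(g_ampa = base_tone$g_ampa * multipliers$g_ampa,
                       g_gaba = base_tone$g_gaba * multipliers$g_gaba,
                       g_h = base_tone$g_h * multipliers$g_h)
  ctrl <- simulate_population(ctrl_spec, duration, t_stim_on, dt,
                              nmda_drive = drive)
  et <- simulate_population(et_spec, duration, t_stim_on, dt,
                            nmda_drive = drive)
  window <- c(t_stim_on, duration)
  # net rise of the synaptic DA concentration across the stimulus window
  # (uM): with the pooled population drive the uptake runs near saturation,
  # so this tracks the population's burst output
  cum_da <- function(res) {
    i <- res$da$time >= window[1]
    max(res$da$da[i]) - res$da$da[i][1]
  }
  structure(list(control = ctrl, tone = et,
                 sync_control = synchrony_index(ctrl$raster, window, bin),
                 sync_tone = synchrony_index(et$raster, window, bin),
                 da_control = cum_da(ctrl), da_tone = cum_da(et),
                 rate_control = ctrl$mean_rate, rate_tone = et$mean_rate),
            class = "population_comparison")
}

#' Reward-value coding by type I and type II DA neurons
#'
#' Two-pulse NMDA protocol: a first, fixed pulse (salience) and a second
#' pulse whose conductance scales with the reward value.  The type II
#' configuration adds tonic AMPA with compensating GABA, which switches
#' the neuron's excitability and opens a dead zone at low reward values;
#' the type I configuration responds with a rate that grows continuously
#' from the background.
#'
#' @param reward_values numeric vector in \[0, 1\].
#' @param type `"I"` or `"II"`.
#' @param params a [da_params()].
#' @param g_nmda_salience first-pulse conductance (mS/cm^2).
#' @param g_nmda_max second-pulse conductance at reward value 1.
#' @param type2_tone list with `g_ampa`, `g_gaba` for the type II
#'   configuration.
#' @param pulse_ms pulse length (ms).
#' @param gap_ms gap between pulses (ms).
#' @return data.frame with `value`, `peak_rate` (Hz; instantaneous rate of
#'   the second response), `background_rate`.
#' @export
reward_coding_protocol <- function(reward_values = seq(0, 1, by = 0.1),
                                   type = c("I", "II"),
                                   params = da_params(),
                                   g_nmda_salience = 1.5,
                                   g_nmda_max = 3,
                                   type2_tone = list(g_ampa = 0.6,
                                                     g_gaba = 1.8),
                                   pulse_ms = 500, gap_ms = 1000) {
  type <- match.arg(type)
  dt <- 0.025
  pre <- 3000
  duration <- pre + pulse_ms + gap_ms + pulse_ms + 1000
  nstep <- round(duration / dt)
  tg <- seq(0, nstep) * dt
  p1 <- tg >= pre & tg < pre + pulse_ms
  t2_on <- pre + pulse_ms + gap_ms
  p2 <- tg >= t2_on & tg < t2_on + pulse_ms
  base_syn <- if (type == "II") {
    syn_drive(g_ampa = type2_tone$g_ampa, g_gaba = type2_tone$g_gaba)
  } else {
    syn_drive()
  }
  out <- lapply(reward_values, function(val) {
    s <- base_syn
    s$g_nmda <- g_nmda_salience * p1 + g_nmda_max * val * p2
    sim <- integrate_da(params, model_variant(), s, 0, duration, dt,
                        record_every = 0)
    bg <- firing_stats(sim$spikes[sim$spikes < pre])$rate
    sp2 <- sim$spikes[sim$spikes >= t2_on &
                        sim$spikes < t2_on + pulse_ms + 200]
    peak <- if (length(sp2) >= 2) 1000 / min(diff(sp2)) else
      if (is.na(bg)) 0 else bg
    data.frame(value = val, peak_rate = peak,
               background_rate = ifelse(is.na(bg), 0, bg))
  })
  do.call(rbind, out)
}
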