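# Synthetic-input generators: Poisson glutamate trains, NMDA coincidence
# drive, receptor gating, the GABA interneuron population, and correlated
# Ornstein-Uhlenbeck conductance traces.

#' Poisson glutamate spike trains
#'
#' Independent homogeneous Poisson trains emulating the asynchronous
#' glutamatergic drive (by default 35 trains at ~10 Hz, the configuration
#' that produces near-tonic NMDA receptor activation).
#'
#' @param n number of trains.
#' @param rate rate per train (Hz), > 0.
#' @param duration train length (ms), > 0 (0 is allowed and yields empty
#'   trains).
#' @param seed RNG seed; fixed seed gives bit-identical trains.
#' @return object of class `spike_train_set`: list with `trains` (list of
#'   strictly increasing spike-time vectors, ms), `n`, `rate`, `duration`,
#'   `seed`.
#' @examples
#' ts <- poisson_glu_trains(35, 10, 1000, seed = 1)
#' mean(lengths(ts$trains))  # ~10 spikes per train per second
#' @export
poisson_glu_trains <- function(n = 35, rate = 10, duration, seed = 1) {
  if (rate <= 0) stop("rate must be > 0")
  if (duration < 0) stop("duration must be >= 0")
  set.seed(seed)
  trains <- lapply(seq_len(n), function(i) {
    k <- rpois(1, rate * duration / 1000)
    sort(runif(k, 0, duration))
  })
  structure(list(trains = trains, n = n, rate = rate,
                 duration = duration, seed = seed),
            class = "spike_train_set")
}

#' Coincidence-thresholded binary drive
#'
#' The NMDA receptor in the asynchronous-input protocol is activated only
#' by the coincidence of `k_min` or more presynaptic spikes: whenever at
#' least `k_min` pooled spikes fall within `window` ms of each other, the
#' drive `j(t)` is set to 1 for `pulse` ms (overlapping pulses merge).
#'
#' @param trains a [poisson_glu_trains()] result (or list of spike-time
#'   vectors).
#' @param dt sampling step of the returned signal (ms).
#' @param window coincidence window (ms).
#' @param k_min minimal number of coincident spikes (>= 1).
#' @param pulse pulse length (ms).
#' @param duration signal length (ms); defaults to the train duration.
#' @return binary numeric vector on the `dt` grid (length
#'   `duration/dt + 1`), with the merged pulse intervals in attribute
#'   `"events"` (two-column matrix of onsets/offsets).
#' @export
coincidence_drive <- function(trains, dt, window = 1, k_min = 2, pulse = 1,
                              duration = NULL) {
  if (k_min < 1) stop("k_min must be >= 1")
  if (inherits(trains, "spike_train_set")) {
    if (is.null(duration)) duration <- trains$duration
    trains <- trains$trains
  }
  if (is.null(duration)) stop("duration required for a bare train list")
  pooled <- sort(unlist(trains))
  onset <- numeric(0)
  if (length(pooled) >= k_min) {
    if (k_min == 1) {
      onset <- pooled
    } else {
      i <- seq(k_min, length(pooled))
      hit <- pooled[i] - pooled[i - k_min + 1] <= window
      onset <- pooled[i][hit]
    }
  }
  # merge overlapping pulses
  ev <- matrix(numeric(0), ncol = 2)
  if (length(onset)) {
    st <- onset[1]; en <- onset[1] + pulse
    for (t0 in onset[-1]) {
      if (t0 <= en) {
        en <- t0 + pulse
      } else {
        ev <- rbind(ev, c(st, en))
        st <- t0; en <- t0 + pulse
      }
    }
    ev <- rbind(ev, c(st, en))
  }
  n <- floor(duration / dt) + 1L
  j <- numeric(n)
  if (nrow(ev)) {
    lo <- pmin(n + 1L, pmax(1L, ceiling(ev[, 1] / dt) + 1L))
    hi <- pmin(n, ceiling(ev[, 2] / dt))
    for (r in seq_len(nrow(ev))) {
      if (lo[r] <= hi[r]) j[lo[r]:hi[r]] <- 1
    }
  }
  attr(j, "events") <- ev
  j
}

#' Receptor gating time constants
#'
#' Activation/deactivation time constants per receptor type: AMPA 1/1.6 ms,
#' NMDA 7/170 ms, GABA 0.08/10 ms.
#'
#' @param type `"ampa"`, `"nmda"`, or `"gaba"`.
#' @return list of class `receptor_gating` with `tau_act`, `tau_deact` and
#'   the type.
#' @export
receptor_gating <- function(type = c("nmda", "ampa", "gaba")) {
  type <- match.arg(type)
  tau <- switch(type,
                ampa = c(1, 1.6),
                nmda = c(7, 170),
                gaba = c(0.08, 10))
  structure(list(type = type, tau_act = tau[1], tau_deact = tau[2]),
            class = "receptor_gating")
}

#' Receptor gate driven by a binary input
#'
#' Exact branchwise integration of
#' `ds/dt = j (1 - s)/tau_act - (1 - j) s / tau_deact` over each step on
#' which the binary drive `j` is constant: the gate relaxes toward 1 with
#' `tau_act` while the input is on and decays with `tau_deact` while it is
#' off.  The gate stays in \[0, 1\] for any input sequence.
#'
#' @param gating a [receptor_gating()].
#' @param j binary drive sampled at `dt` (one value per step).
#' @param dt step (ms), > 0.
#' @param s0 initial gate value.
#' @return numeric gate trace of length `length(j) + 1`.
#' @export
gate_trace <- function(gating, j, dt, s0 = 0) {
  stopifnot(dt > 0)
  .gate_from_drive_cpp(as.numeric(j), dt, gating$tau_act, gating$tau_deact,
                       s0)
}

#' One exact gating step
#'
#' Single-step version of [gate_trace()]: returns the gate after `dt` ms of
#' constant binary drive `j`.
#'
#' @param s current gate value in \[0, 1\].
#' @inheritParams gate_trace
#' @param j 0 or 1.
#' @return updated gate value.
#' @export
gating_step <- function(s, j, dt, gating = receptor_gating("nmda")) {
  stopifnot(dt > 0)
  if (j > 0.5) 1 - (1 - s) * exp(-dt / gating$tau_act)
  else s * exp(-dt / gating$tau_deact)
}

#' Normalized drive of a GABA interneuron population
#'
#' Integrates `n_neurons` Wang-Buzsaki interneurons with heterogeneous
#' applied currents (drawn uniformly from `i_range`, an interval calibrated
#' to intrinsic rates of 12-22 Hz) and asynchronous initial phases.  Each
#' neuron drives its own GABA receptor gate through the smooth spike
#' function `gspike(v) = 1/(1+exp(-v/2))`; the population gate is the
#' per-neuron mean, so an asynchronous population provides a quasi-constant
#' level of inhibition while a single neuron produces full-amplitude
#' pulsation.
#'
#' @param n_neurons population size (>= 1).
#' @param duration simulated time (ms).
#' @param dt integration step (ms).
#' @param seed RNG seed (initial phases and applied currents).
#' @param params a [gaba_params()].
#' @param i_range applied-current interval (uA/cm^2) mapped onto the
#'   12-22 Hz band.
#' @param record_every sampling stride of the returned gate trace.
#' @return list with `time`, `s_gaba` (population-mean gate in \[0, 1\]),
#'   `spikes` (per-neuron spike times), `rates` (per-neuron Hz), `i_app`.
#' @export
gaba_population_drive <- function(n_neurons = 30, duration, dt = 0.02,
                                  seed = 1, params = gaba_params(),
                                  i_range = c(-0.23, -0.15),
                                  record_every = 1) {
  stopifnot(n_neurons >= 1, duration > 0)
  set.seed(seed)
  ia <- runif(n_neurons, i_range[1], i_range[2])
  v0 <- runif(n_neurons, -66, -58)
  st <- t(vapply(v0, function(v) as.numeric(gaba_state(v)), numeric(3)))
  g <- receptor_gating("gaba")
  out <- .sim_gaba_pop_cpp(st, pack_gaba_params(params), ia, duration, dt,
                           g$tau_act, g$tau_deact, -20, 2,
                           as.integer(record_every))
  rates <- vapply(out$spikes, function(s) {
    r <- firing_stats(s, transient = min(1000, duration / 4))$rate
    if (is.na(r)) 0 else r
  }, numeric(1))
  list(time = out$time, s_gaba = out$s_gaba, spikes = out$spikes,
       rates = rates, i_app = ia)
}

#' Specification of a correlated Ornstein-Uhlenbeck conductance
#'
#' @param mu mean conductance (mS/cm^2).
#' @param sigma stationary standard deviation (mS/cm^2), >= 0.
#' @param c input correlation in \[0, 1\]: the fraction of conductance
#'   variance shared through a common OU component.
#' @param tau correlation time (ms), > 0.
#' @param seed RNG seed.
#' @return list of class `ou_spec`.
#' @export
ou_spec <- function(mu = 1.5, sigma = 0.5, c = 0.5, tau = 5, seed = 1) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (c < 0 || c > 1) stop("c must lie in [0, 1]")
  if (tau <= 0) stop("tau must be > 0")
  structure(list(mu = mu, sigma = sigma, c = c, tau = tau, seed = seed),
            class = "ou_spec")
}

# unit-variance OU process by exact discretization:
# x_{k+1} = x_k e^{-dt/tau} + sqrt(1 - e^{-2 dt/tau}) N(0,1)
ou_unit <- function(n_steps, dt, tau, x0 = rnorm(1)) {
  a <- exp(-dt / tau)
  b <- sqrt(1 - a^2)
  x <- numeric(n_steps + 1)
  x[1] <- x0
  eps <- rnorm(n_steps)
  for (k in seq_len(n_steps)) x[k + 1] <- a * x[k] + b * eps[k]
  x
}

#' Correlated OU conductance traces
#'
#' Per-target conductance `g_i(t) = mu + sigma (sqrt(1-c) x_i(t) +
#' sqrt(c) x_c(t))` where each `x` is a unit-variance OU process with
#' correlation time `tau` (`x_c` common to all targets, `x_i` independent).
#' The square-root weighting preserves the stationary variance, so `sigma`
#' is the standard deviation of the conductance and `c` the pairwise trace
#' correlation.  The OU recursion uses the exact discretization, so the
#' stationary statistics hold at any `dt` well below `tau`.  Negative
#' excursions are clipped at 0 before use as a conductance.
#'
#' @param spec an [ou_spec()].
#' @param duration trace length (ms).
#' @param dt sampling step (ms), should be well below `spec$tau`.
#' @param n_targets number of target neurons.
#' @param clip clip negative excursions at 0 (the default for use as a
#'   conductance; `FALSE` exposes the raw Gaussian trace).
#' @return numeric matrix `(duration/dt + 1) x n_targets`.
#' @export
ou_trace <- function(spec, duration, dt = 0.05, n_targets = 1,
                     clip = TRUE) {
  stopifnot(inherits(spec, "ou_spec"), dt < spec$tau)
  n <- round(duration / dt)
  set.seed(spec$seed)
  xc <- ou_unit(n, dt, spec$tau)
  g <- matrix(NA_real_, n + 1, n_targets)
  for (i in seq_len(n_targets)) {
    xi <- ou_unit(n, dt, spec$tau)
    g[, i] <- spec$mu + spec$sigma *
      (sqrt(1 - spec$c) * xi + sqrt(spec$c) * xc)
  }
  if (clip) g[g < 0] <- 0
  g
}

#' Sine-modulated OU conductance
#'
#' An OU conductance whose mean is multiplicatively modulated by a sine
#' wave: `g(t) = mu (1 + depth sin(2 pi f t)) + sigma (...)`.  With
#' `mod_depth = 0` the trace is identical to [ou_trace()] under the same
#' seed; over integer periods the time average returns to `mu`.
#'
#' @param spec an [ou_spec()].
#' @param mod_freq modulation frequency (Hz), > 0.
#' @param mod_depth modulation depth (0-1).
#' @inheritParams ou_trace
#' @return numeric matrix as in [ou_trace()].
#' @export
sine_modulated_ou <- function(spec, mod_freq = 1, mod_depth = 0.8,
                              duration, dt = 0.05, n_targets = 1,
                              clip = TRUE) {
  if (mod_freq <= 0) stop("mod_freq must be > 0")
  g <- ou_trace(spec, duration, dt, n_targets, clip = FALSE)
  tg <- seq(0, by = dt, length.out = nrow(g))
  g <- g + spec$mu * mod_depth * sin(2 * pi * mod_freq * tg / 1000)
  if (clip) g[g < 0] <- 0
  g
}

#' Assemble the full asynchronous synaptic drive
#'
#' Builds the time-resolved synaptic gating the in-vivo-like protocol uses:
#' NMDA receptors driven by the coincidence-thresholded pooled Poisson
#' glutamate trains, and GABA receptors by the normalized gate of the
#' simulated interneuron population.  The returned [syn_drive()] carries
#' vector-valued gating (sampled at `dt`) and can be handed directly to
#' [integrate_da()] with the same `dt`.
#'
#' @param g_nmda,g_gaba maximal conductances (mS/cm^2).
#' @param duration drive length (ms).
#' @param dt sampling/integration step (ms).
#' @param seed RNG seed for both input streams.
#' @param n_trains,rate Poisson glutamate configuration.
#' @param k_min coincidence threshold for NMDA activation.
#' @param n_gaba GABA interneuron count.
#' @return a [syn_drive()] whose `s_nmda` and `s_gaba` are gating traces;
#'   attribute `"mean_gates"` holds their time averages (useful to match an
#'   equivalent tonic drive).
#' @export
asynchronous_drive <- function(g_nmda, g_gaba, duration, dt = 0.025,
                               seed = 1, n_trains = 35, rate = 10,
                               k_min = 2, n_gaba = 30) {
  trains <- poisson_glu_trains(n_trains, rate, duration, seed = seed)
  j <- coincidence_drive(trains, dt = dt, k_min = k_min)
  s_nmda <- gate_trace(receptor_gating("nmda"), j[-length(j)], dt)
  gp <- gaba_population_drive(n_gaba, duration, dt = dt, seed = seed + 1)
  s_gaba <- gp$s_gaba
  n <- round(duration / dt) + 1
  s <- syn_drive(g_nmda = g_nmda, g_gaba = g_gaba)
  s$s_nmda <- s_nmda[seq_len(n)]
  s$s_gaba <- s_gaba[seq_len(n)]
  attr(s, "mean_gates") <- c(nmda = mean(s$s_nmda), gaba = mean(s$s_gaba))
  s
}
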