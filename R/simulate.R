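#' Integrate the DA neuron model
#'
#' Fixed-step RK4 integration of any model variant under tonic or
#' time-varying synaptic drive, with online spike detection (threshold
#' upcrossings with a refractory guard).
#'
#' The fields `g_nmda`, `g_ampa`, `g_gaba` of `syn` and `i_app` may each be
#' a scalar (tonic) or a numeric vector sampled on the integration grid
#' (length `duration/dt + 1`); vector drives are treated as the effective
#' conductance (maximal conductance times gating) and held constant across
#' each step.
#'
#' @param params a [da_params()].
#' @param variant a [model_variant()].
#' @param syn a [syn_drive()]; vector-valued conductance fields give
#'   time-varying drive.
#' @param i_app applied current (uA/cm^2), scalar or vector.
#' @param duration simulated time (ms).
#' @param dt integration step (ms).  0.025 resolves the fast Na+ spike; the
#'   reduced model can use 0.05.
#' @param init initial [da_state()].
#' @param record_every record the state every this many steps (0 = record
#'   nothing; spikes are always detected at full resolution).
#' @param refractory minimal separation of detected spikes (ms).
#' @param transient duration (ms) discarded by downstream statistics;
#'   stored in the result.
#' @return an object of class `da_sim`: time grid, state traces, spike
#'   times (ms), final state, and protocol metadata.  If the state became
#'   non-finite, `failed = TRUE` and `fail_time` records when.
#' @examples
#' sim <- integrate_da(da_params(), duration = 3000)
#' length(sim$spikes)
#' @export
integrate_da <- function(params = da_params(), variant = model_variant(),
                         syn = syn_drive(), i_app = 0,
                         duration = 10000, dt = 0.025,
                         init = da_state(), record_every = 20,
                         refractory = 2, transient = 0) {
  stopifnot(duration > 0, dt > 0)
  gn <- syn$g_nmda * syn$s_nmda
  ga <- syn$g_ampa * syn$s_ampa
  gg <- syn$g_gaba * syn$s_gaba
  out <- .sim_da_cpp(as.numeric(init), pack_da_params(params),
                     pack_variant(variant), variant$spike_threshold,
                     refractory, duration, dt,
                     gn, ga, gg, i_app,
                     syn$e_ampa, syn$e_gaba, as.integer(record_every))
  out$params <- params
  out$variant <- variant
  out$dt <- dt
  out$duration <- duration
  out$transient <- transient
  names(out$final_state) <- c("v", "ca", "q", "h", "n")
  class(out) <- "da_sim"
  out
}

#' Detect spikes in a voltage trace
#'
#' Upward crossings of the variant's spike threshold, with a refractory
#' guard suppressing double counts on dense grids.  Subthreshold
#' oscillations never reach the threshold and are not counted.
#'
#' @param v voltage trace (mV).
#' @param time time grid (ms), same length as `v`.
#' @param threshold spike threshold (mV): 0 for the full model, -40 for the
#'   reduced one.  A [model_variant()] may be given instead.
#' @param refractory minimal time between spikes (ms).
#' @return numeric vector of spike times (ms, linearly interpolated).
#' @examples
#' t <- seq(0, 3000, 0.1)
#' detect_spikes(50 * sin(2 * pi * t / 1000), t, threshold = 0)
#' @export
detect_spikes <- function(v, time, threshold = 0, refractory = 2) {
  if (inherits(threshold, "model_variant")) {
    threshold <- threshold$spike_threshold
  }
  up <- which(v[-length(v)] < threshold & v[-1] >= threshold)
  if (!length(up)) return(numeric(0))
  frac <- (threshold - v[up]) / (v[up + 1] - v[up])
  cand <- time[up] + frac * (time[up + 1] - time[up])
  keep <- numeric(0)
  last <- -Inf
  for (tc in cand) {
    if (tc - last >= refractory) {
      keep <- c(keep, tc)
      last <- tc
    }
  }
  keep
}

#' Firing rate and regularity
#'
#' Mean firing rate as the inverse of the mean interspike interval (ISI),
#' and the ISI coefficient of variation computed over 200 ISIs (the most
#' recent 200 when more are available).  Rate requires at least 2 spikes and
#' the CV at least 201; otherwise the corresponding statistic is `NA`.
#'
#' @param spikes spike times (ms).
#' @param transient spikes before this time (ms) are discarded.
#' @param n_isi_cv number of ISIs entering the CV.
#' @return list with `rate` (Hz), `cv`, and `n_spikes`.
#' @examples
#' firing_stats(seq(0, 5000, by = 250))$rate  # 4 Hz, clock-like
#' @export
firing_stats <- function(spikes, transient = 0, n_isi_cv = 200) {
  spikes <- spikes[spikes >= transient]
  n <- length(spikes)
  rate <- if (n >= 2) 1000 / mean(diff(spikes)) else NA_real_
  cv <- NA_real_
  if (n >= n_isi_cv + 1) {
    isi <- diff(spikes)
    isi <- isi[(length(isi) - n_isi_cv + 1):length(isi)]
    cv <- sd(isi) / mean(isi)
  }
  list(rate = rate, cv = cv, n_spikes = n)
}

#' Steady-state firing rate under a given drive
#'
#' Convenience wrapper: integrate, discard the transient, return the rate.
#'
#' @inheritParams integrate_da
#' @return rate in Hz (`NA` if fewer than 2 post-transient spikes).
#' @export
steady_rate <- function(params = da_params(), variant = model_variant(),
                        syn = syn_drive(), i_app = 0, duration = 12000,
                        transient = 2000, dt = 0.025, init = da_state()) {
  sim <- integrate_da(params, variant, syn, i_app, duration, dt,
                      init = init, record_every = 0, transient = transient)
  firing_stats(sim$spikes, transient = transient)$rate
}

#' Depolarization block detection
#'
#' A cell is in depolarization block when, after the transient, it emits no
#' spikes while the membrane sits at a depolarized, nearly constant voltage.
#' Hyperpolarized quiescence is not block.  The published account gives no
#' numeric criterion; the cutoffs (mean voltage above `mean_cutoff`,
#' peak-to-peak amplitude below `amp_cutoff`) are configuration values.
#'
#' @param sim a `da_sim` with recorded voltage (`record_every > 0`).
#' @param transient analysis starts after this time (ms); defaults to the
#'   value stored in `sim`.
#' @param mean_cutoff depolarized mean-voltage cutoff (mV).  The default
#'   -52 sits between the model's depolarization-block states (which rest
#'   at -49 mV and above) and its hyperpolarized rest states (below
#'   -56 mV).
#' @param amp_cutoff peak-to-peak amplitude cutoff (mV).
#' @return logical flag.
#' @export
depolarization_block_detect <- function(sim, transient = NULL,
                                        mean_cutoff = NULL, amp_cutoff = 5) {
  if (is.null(transient)) transient <- sim$transient
  if (!length(sim$v)) stop("sim has no recorded voltage trace")
  if (is.null(mean_cutoff)) mean_cutoff <- -52
  keep <- sim$time >= transient
  v <- sim$v[keep]
  no_spikes <- !any(sim$spikes >= transient)
  no_spikes && mean(v) > mean_cutoff && (max(v) - min(v)) < amp_cutoff
}

#' Firing-rate map over a conductance plane
#'
#' Steady-state rate, ISI CV and depolarization-block status on a grid of
#' two swept parameters (synaptic conductances or applied current).  Each
#' cell is integrated independently from the same initial state; solver
#' failures are recorded in the `failed` mask and the sweep continues.
#'
#' @param params,variant model configuration.
#' @param x,y lists `list(param = "g_nmda", values = ...)`; `param` is one
#'   of `"g_nmda"`, `"g_ampa"`, `"g_gaba"`, `"i_app"`.
#' @param syn baseline [syn_drive()] the swept parameters override.
#' @param duration,transient per-cell integration and discard times (ms).
#' @param dt integration step (ms).
#' @return object of class `heat_map`: `x_values`, `y_values`, matrices
#'   `rate`, `cv`, `block`, `failed` (rows index `x`, columns `y`).
#' @export
conductance_plane_sweep <- function(params = da_params(),
                                    variant = model_variant(),
                                    x, y, syn = syn_drive(),
                                    duration = 10000, transient = 2000,
                                    dt = 0.025) {
  stopifnot(length(x$values) > 0, length(y$values) > 0)
  nx <- length(x$values); ny <- length(y$values)
  rate <- cv <- matrix(NA_real_, nx, ny)
  block <- failed <- matrix(FALSE, nx, ny)
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      s <- syn; ia <- 0
      for (ax in list(list(x$param, x$values[i]),
                      list(y$param, y$values[j]))) {
        if (ax[[1]] == "i_app") ia <- ax[[2]] else s[[ax[[1]]]] <- ax[[2]]
      }
      sim <- integrate_da(params, variant, s, ia, duration, dt,
                          record_every = max(1L, round(0.2 / dt)),
                          transient = transient)
      if (isTRUE(sim$failed)) {
        failed[i, j] <- TRUE
        next
      }
      st <- firing_stats(sim$spikes, transient = transient)
      rate[i, j] <- ifelse(is.na(st$rate) && st$n_spikes < 2, 0, st$rate)
      cv[i, j] <- st$cv
      block[i, j] <- depolarization_block_detect(sim)
    }
  }
  structure(list(x_param = x$param, y_param = y$param,
                 x_values = x$values, y_values = y$values,
                 rate = rate, cv = cv, block = block, failed = failed),
            class = "heat_map")
}

#' Balance line of the low-frequency band
#'
#' Least-squares line `g_nmda = slope * g_gaba + b` through the centers of
#' the conductance-plane cells whose steady rate falls in the given band
#' (the NMDA/GABA-balanced low-frequency region).  The slope is the
#' NMDA/GABA balance ratio.
#'
#' @param map a `heat_map` whose x parameter is `g_nmda` and y parameter
#'   `g_gaba` (or vice versa).
#' @param rate_band numeric length-2 interval (Hz).
#' @return list with `slope`, `intercept`, `residual` (RMS of the fit), and
#'   `n_cells`.
#' @export
balance_line <- function(map, rate_band) {
  stopifnot(inherits(map, "heat_map"))
  pars <- c(map$x_param, map$y_param)
  if (!setequal(pars, c("g_nmda", "g_gaba"))) {
    stop("balance_line needs a g_nmda x g_gaba map")
  }
  gx <- outer(map$x_values, rep(1, length(map$y_values)))
  gy <- outer(rep(1, length(map$x_values)), map$y_values)
  nm <- if (map$x_param == "g_nmda") gx else gy
  gb <- if (map$x_param == "g_gaba") gx else gy
  sel <- !is.na(map$rate) & map$rate >= rate_band[1] & map$rate <= rate_band[2]
  if (sum(sel) < 3) stop("fewer than 3 cells in the rate band")
  fit <- lm(nmda ~ gaba, data = data.frame(nmda = nm[sel], gaba = gb[sel]))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       residual = sqrt(mean(fit$residuals^2)), n_cells = sum(sel))
}

#' F-I (frequency-input) curve
#'
#' Steady-state firing rate as one parameter is swept.  With
#' `warm_start = TRUE` the final state of each point seeds the next,
#' emulating a slowly rising (or, for a decreasing grid, falling) ramp;
#' this is what exposes hysteresis between rising and falling sweeps.
#'
#' @param params,variant model configuration.
#' @param param swept parameter (`"i_app"`, `"g_gaba"`, `"g_nmda"`,
#'   `"g_ampa"`, or `"g_eff"` combined with `e_eff`).
#' @param values monotone grid of parameter values, in sweep order.
#' @param syn baseline synaptic drive.
#' @param e_eff reversal potential used when `param = "g_eff"`.
#' @param duration,transient per-point times (ms).
#' @param dt integration step (ms).
#' @param warm_start seed each point with the previous final state.
#' @param init initial state of the first point.
#' @return data.frame of class `fi_curve` with columns `value` and `rate`
#'   (Hz; 0 when quiescent), and attributes `param` and `direction`.
#' @export
fi_curve <- function(params = da_params(), variant = model_variant(),
                     param = "i_app", values, syn = syn_drive(),
                     e_eff = -90, duration = 10000, transient = 2000,
                     dt = 0.025, warm_start = TRUE, init = da_state()) {
  stopifnot(is.numeric(values), length(values) >= 1)
  rate <- numeric(length(values))
  state <- init
  for (k in seq_along(values)) {
    s <- syn; ia <- 0
    if (param == "i_app") {
      ia <- values[k]
    } else if (param == "g_eff") {
      sp <- ohmic_split(values[k], e_eff)
      s$g_ampa <- sp$g_ampa; s$g_gaba <- sp$g_gaba
    } else {
      s[[param]] <- values[k]
    }
    sim <- integrate_da(params, variant, s, ia, duration, dt, init = state,
                        record_every = 0, transient = transient)
    st <- firing_stats(sim$spikes, transient = transient)
    rate[k] <- if (is.na(st$rate)) 0 else st$rate
    if (warm_start) state <- sim$final_state
  }
  direction <- if (length(values) > 1 && values[length(values)] < values[1]) {
    "falling"
  } else {
    "rising"
  }
  structure(data.frame(value = values, rate = rate),
            class = c("fi_curve", "data.frame"),
            param = param, direction = direction)
}
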