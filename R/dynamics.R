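# Nullclines, equilibria, bifurcation classification (SNIC / Andronov-Hopf /
# saddle-node / limit-cycle fold), the type I / type II excitability verdict,
# and the Bogdanov-Takens boundary.
#
# The approach is simulation-plus-algebra rather than a dedicated
# continuation library: every gating steady state of the model is
# single-valued in v, so all equilibria lie on a branch parameterized by v
# and can be enumerated by a grid scan plus root polishing, with stability
# read off a finite-difference Jacobian.  This keeps each bifurcation
# certificate explicit and testable.

# total membrane current excluding the SK term (uA/cm^2), vectorized over v
current_no_sk <- function(v, params, variant, syn, i_app) {
  p <- params
  iv <- ca_conductance(v, p) * (p$e_ca - v) +
    k_conductance(v, p) * (p$e_k - v) +
    p$g_l * (p$e_l - v) + i_app
  if (variant$include_sna) iv <- iv + sna_conductance(v, p) * (p$e_na - v)
  if (variant$include_ih) {
    iv <- iv + p$g_h * ih_kinetics(v)$q_inf * (p$e_h - v)
  }
  if (variant$include_spike_currents) {
    fr <- fast_na_rates(v)
    dr <- dr_rates(v)
    h_inf <- fr$alpha_h / (fr$alpha_h + fr$beta_h)
    n_inf <- dr$alpha_n / (dr$alpha_n + dr$beta_n)
    iv <- iv + p$gbar_na * fr$m_inf^3 * h_inf * (p$e_na - v) +
      p$gbar_dr * n_inf^4 * (p$e_k - v)
  }
  iv + nmda_conductance(v, syn$g_nmda, p) * syn$s_nmda * (0 - v) +
    syn$g_ampa * syn$s_ampa * (syn$e_ampa - v) +
    syn$g_gaba * syn$s_gaba * (syn$e_gaba - v)
}

# Ca2+ nullcline: the concentration at which pump removal balances influx
ca_nullcline_ca <- function(v, params, variant = reduced_variant()) {
  p <- params
  g_in <- ca_conductance(v, p) +
    if (variant$include_ca_leak) p$ca_leak_frac * p$g_l else 0
  pmax(p$ca_gain * g_in * (p$e_ca - v) / p$ca_pump, 0)
}

# equilibrium residual dv/dt * c_m along the Ca2+ nullcline (all gating
# variables at steady state)
equilibrium_residual <- function(v, params, variant, syn, i_app) {
  ca <- ca_nullcline_ca(v, params, variant)
  current_no_sk(v, params, variant, syn, i_app) +
    sk_conductance(ca, params) * (params$e_k - v)
}

#' Nullclines of the reduced model
#'
#' The v- and Ca2+-nullclines of the two-dimensional subthreshold system
#' (spike-producing currents removed).  The Ca2+ nullcline is single-valued
#' in v; the v-nullcline is computed by solving the SK balance for Ca2+ at
#' each voltage (NA where no Ca2+ >= 0 balances the equation).  With Ih
#' included the curves are drawn with `q` at its voltage steady state.
#'
#' @param params a [da_params()].
#' @param syn tonic [syn_drive()].
#' @param i_app applied current (uA/cm^2).
#' @param v_range voltage window (mV).
#' @param n number of grid points.
#' @param variant a reduced [model_variant()] (spike currents must be off).
#' @return data.frame of class `nullclines` with columns `v`, `ca_vnull`,
#'   `ca_canull`.
#' @export
nullclines <- function(params = da_params(), syn = syn_drive(), i_app = 0,
                       v_range = c(-90, -20), n = 400,
                       variant = reduced_variant()) {
  if (variant$include_spike_currents) {
    stop("nullcline analysis applies to the reduced (no-spike) model only")
  }
  if (diff(v_range) <= 0 || n < 2) stop("empty window")
  v <- seq(v_range[1], v_range[2], length.out = n)
  g_need <- current_no_sk(v, params, variant, syn, i_app) / (v - params$e_k)
  ca_v <- rep(NA_real_, n)
  ok <- g_need > 0 & g_need < params$gbar_kca
  ca_v[ok] <- params$k_sk *
    (g_need[ok] / (params$gbar_kca - g_need[ok]))^(1 / 4)
  ca_v[g_need == 0] <- 0
  structure(data.frame(v = v, ca_vnull = ca_v,
                       ca_canull = ca_nullcline_ca(v, params, variant)),
            class = c("nullclines", "data.frame"))
}

# indices of the dynamically active state variables for a variant
active_dims <- function(params, variant) {
  dims <- c("v", "ca")
  if (variant$include_ih && params$g_h > 0) dims <- c(dims, "q")
  if (variant$include_spike_currents) dims <- c(dims, "h", "n")
  dims
}

# finite-difference Jacobian of the vector field restricted to the active
# dimensions, evaluated at a full 5-component state
rhs_jacobian <- function(state, params, variant, syn, i_app,
                         dims = active_dims(params, variant)) {
  f0 <- da_rhs(state, params, variant, syn, i_app)[dims]
  J <- matrix(NA_real_, length(dims), length(dims),
              dimnames = list(dims, dims))
  for (k in seq_along(dims)) {
    hk <- max(1e-6, 1e-6 * abs(state[[dims[k]]]))
    sp <- sm <- state
    sp[dims[k]] <- sp[[dims[k]]] + hk
    # keep ca and the gates inside their domain (one-sided step at 0)
    sm[dims[k]] <- if (dims[k] == "v") sm[[dims[k]]] - hk else
      max(0, sm[[dims[k]]] - hk)
    J[, k] <- (da_rhs(sp, params, variant, syn, i_app)[dims] -
                 da_rhs(sm, params, variant, syn, i_app)[dims]) /
      (sp[[dims[k]]] - sm[[dims[k]]])
  }
  J
}

#' Equilibria of the model under tonic inputs
#'
#' Enumerates all equilibria in a voltage window.  Every gating steady
#' state is single-valued in v, so equilibria are the roots of the membrane
#' current balance along the Ca2+ nullcline; roots are located by a grid
#' scan plus `uniroot` polishing and certified by their residual.
#' Stability is classified from the eigenvalues of a finite-difference
#' Jacobian restricted to the dynamically active variables.
#'
#' @inheritParams nullclines
#' @param variant any [model_variant()] (tonic/autonomous inputs only).
#' @param n_grid scan resolution.
#' @return data.frame of class `equilibria` with the state at each
#'   equilibrium, the leading eigenvalue (real/imaginary parts), a
#'   `stability` label, and the certified `residual`; the full eigenvalue
#'   sets are in attribute `"eigen"`.  Zero rows when no equilibrium lies
#'   in the window.
#' @export
find_equilibria <- function(params = da_params(),
                            variant = reduced_variant(),
                            syn = syn_drive(), i_app = 0,
                            v_range = c(-100, -10), n_grid = 1200) {
  v <- seq(v_range[1], v_range[2], length.out = n_grid)
  G <- equilibrium_residual(v, params, variant, syn, i_app)
  sgn <- sign(G)
  idx <- which(sgn[-1] * sgn[-n_grid] < 0)
  roots <- vapply(idx, function(i) {
    uniroot(function(x) equilibrium_residual(x, params, variant, syn, i_app),
            c(v[i], v[i + 1]), tol = 1e-10)$root
  }, numeric(1))
  roots <- c(roots, v[G == 0])
  rows <- list()
  eigs <- list()
  for (vr in sort(roots)) {
    st <- da_state(v = vr, ca = ca_nullcline_ca(vr, params, variant))
    dims <- active_dims(params, variant)
    J <- rhs_jacobian(st, params, variant, syn, i_app, dims)
    ev <- eigen(J, only.values = TRUE)$values
    lead <- ev[which.max(Re(ev))]
    res <- abs(equilibrium_residual(vr, params, variant, syn, i_app))
    stability <- if (all(Re(ev) < 0)) {
      if (any(Im(ev) != 0)) "stable focus" else "stable node"
    } else if (all(Im(ev) == 0) && any(Re(ev) > 0) && any(Re(ev) < 0)) {
      "saddle"
    } else if (any(Im(ev) != 0)) "unstable focus" else "unstable node"
    rows[[length(rows) + 1]] <-
      data.frame(v = vr, ca = st[["ca"]], q = st[["q"]], h = st[["h"]],
                 n = st[["n"]], re_lead = Re(lead), im_lead = Im(lead),
                 stability = stability, residual = res)
    eigs[[length(eigs) + 1]] <- ev
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(v = numeric(0), ca = numeric(0), q = numeric(0),
               h = numeric(0), n = numeric(0), re_lead = numeric(0),
               im_lead = numeric(0), stability = character(0),
               residual = numeric(0))
  attr(out, "eigen") <- eigs
  class(out) <- c("equilibria", "data.frame")
  out
}

# build the synaptic drive / applied current at a given value of the sweep
# parameter
sweep_point <- function(param, value, syn, e_eff) {
  ia <- 0
  if (param == "i_app") {
    ia <- value
  } else if (param == "g_eff") {
    sp <- ohmic_split(value, e_eff)
    syn$g_ampa <- sp$g_ampa
    syn$g_gaba <- sp$g_gaba
  } else {
    syn[[param]] <- value
  }
  list(syn = syn, i_app = ia)
}

# Algebraic scan along the sweep parameter: the first parameter value at
# which a stable equilibrium exists, and whether it appeared through a fold
# of the equilibrium branch (equilibria count jump) or through an
# eigenvalue crossing of a persistent equilibrium.
first_stable_event <- function(params, variant, param, p_range,
                               syn = syn_drive(), e_eff = -90,
                               v_range = c(-100, -10), tol = NULL,
                               n_scan = 25) {
  has_stable <- function(p) {
    sp <- sweep_point(param, p, syn, e_eff)
    eq <- find_equilibria(params, variant, sp$syn, sp$i_app, v_range)
    any(grepl("^stable", eq$stability))
  }
  n_equil <- function(p) {
    sp <- sweep_point(param, p, syn, e_eff)
    nrow(find_equilibria(params, variant, sp$syn, sp$i_app, v_range))
  }
  if (is.null(tol)) tol <- diff(p_range) * 1e-4
  grid <- seq(p_range[1], p_range[2], length.out = n_scan)
  st <- vapply(grid, has_stable, logical(1))
  if (st[1] || !any(st)) {
    return(list(p_stab = NA_real_, via_fold = NA,
                reason = if (st[1]) "stable at sweep start" else
                  "no stable equilibrium in range"))
  }
  i <- which(st)[1]
  lo <- grid[i - 1]; hi <- grid[i]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (has_stable(mid)) hi <- mid else lo <- mid
  }
  d <- max(tol, (p_range[2] - p_range[1]) * 1e-3)
  via_fold <- n_equil(hi + d) > n_equil(lo - d)
  list(p_stab = (lo + hi) / 2, via_fold = via_fold, reason = "ok")
}

#' Classify the spiking-to-rest transition
#'
#' Localizes the parameter value at which repetitive firing ends (bisection
#' on simulated spiking) and classifies the bifurcation by explicit
#' certificates:
#' \itemize{
#' \item SNIC: a saddle-node of equilibria appears at the transition and
#'   the onset frequency tends to zero;
#' \item Andronov-Hopf: a persistent equilibrium stabilizes through an
#'   eigenvalue crossing while the cycle amplitude shrinks to zero;
#' \item LCFold: the stable cycle disappears at finite amplitude and
#'   frequency while a stable equilibrium already coexists (hysteresis);
#' \item SaddleNode: a fold of equilibria off the cycle.
#' }
#'
#' @param params,variant model configuration.
#' @param param swept parameter (`"g_gaba"`, `"g_eff"` with `e_eff`,
#'   `"i_app"`, ...).  The grid must run from the spiking side to the
#'   quiescent side (for `i_app` this means decreasing values).
#' @param grid parameter values bracketing the transition, in sweep order.
#' @param syn baseline drive.
#' @param e_eff reversal potential for `param = "g_eff"`.
#' @param eps_hz onset-frequency threshold separating "arbitrarily slow"
#'   from a discontinuous jump (Hz).  The default 0.7 sits between the
#'   minimum sustained rates this model reaches on the SNIC side (~0.5 Hz)
#'   and the smallest Hopf-branch jump (~0.9 Hz).
#' @param duration,transient,dt simulation settings per probe.
#' @param onset_duration longer probe used to resolve the onset frequency.
#' @param n_bisect bisection iterations.
#' @param v_range equilibrium search window.
#' @return list of class `bifurcation_point`: `type`, `param`, `value`
#'   (last spiking parameter), `onset_rate` (Hz), `p_stable` and
#'   `via_fold` from the equilibrium certificates, `amplitude_ratio`
#'   (cycle amplitude near the transition over its value at the sweep
#'   start).
#' @export
classify_transition <- function(params = da_params(),
                                variant = reduced_variant(),
                                param = "g_gaba", grid,
                                syn = syn_drive(), e_eff = -90,
                                eps_hz = 0.7, duration = 6000,
                                transient = 1500, dt = 0.05,
                                onset_duration = 14000, n_bisect = 18,
                                v_range = c(-100, -10)) {
  probe <- function(p, dur = duration, keep_trace = FALSE) {
    sp <- sweep_point(param, p, syn, e_eff)
    sim <- integrate_da(params, variant, sp$syn, sp$i_app, dur, dt,
                        record_every = if (keep_trace) 10 else 0,
                        transient = transient)
    list(sim = sim,
         rate = firing_stats(sim$spikes, transient)$rate,
         spiking = sum(sim$spikes >= transient) >= 2)
  }
  sp_grid <- vapply(grid, function(p) probe(p)$spiking, logical(1))
  if (all(sp_grid) || !sp_grid[1]) {
    return(structure(list(type = "not-found", param = param,
                          value = NA_real_,
                          reason = "grid does not bracket a spiking-to-rest transition"),
                     class = "bifurcation_point"))
  }
  i <- which(!sp_grid)[1]
  lo <- grid[i - 1]; hi <- grid[i]     # lo spiking, hi quiescent
  for (k in seq_len(n_bisect)) {
    mid <- (lo + hi) / 2
    if (probe(mid)$spiking) lo <- mid else hi <- mid
  }
  # refine with long probes: near a SNIC the short probes cannot see the
  # slow spiking just below threshold, which would bias the onset rate up
  for (k in seq_len(5)) {
    mid <- (lo + hi) / 2
    if (probe(mid, dur = onset_duration)$spiking) lo <- mid else hi <- mid
  }
  p_star <- lo
  onset <- probe(p_star, dur = onset_duration)
  onset_rate <- onset$rate
  if (is.na(onset_rate)) onset_rate <- 0

  amp <- function(p) {
    pr <- probe(p, keep_trace = TRUE)
    v <- pr$sim$v[pr$sim$time >= transient]
    max(v) - min(v)
  }
  amp_near <- amp(p_star)
  amp_far <- amp(grid[1])
  fse <- first_stable_event(params, variant, param, range(grid), syn,
                            e_eff, v_range)
  span <- abs(grid[length(grid)] - grid[1])
  near_stab <- !is.na(fse$p_stab) && abs(fse$p_stab - p_star) < 0.05 * span
  type <- if (isTRUE(fse$via_fold) && onset_rate < eps_hz) {
    "SNIC"
  } else if (isTRUE(fse$via_fold)) {
    "SaddleNode"
  } else if (identical(fse$via_fold, FALSE) && near_stab &&
             amp_near < 0.25 * amp_far) {
    "AndronovHopf"
  } else if (identical(fse$via_fold, FALSE)) {
    "LCFold"
  } else {
    "AndronovHopf"
  }
  structure(list(type = type, param = param, value = p_star,
                 onset_rate = onset_rate, p_stable = fse$p_stab,
                 via_fold = fse$via_fold,
                 amplitude_ratio = amp_near / amp_far,
                 e_eff = if (param == "g_eff") e_eff else NA_real_),
            class = "bifurcation_point")
}

#' Type I / type II excitability verdict from an F-I curve
#'
#' Type I neurons fire at arbitrarily low rates near the onset of firing
#' (continuous F-I curve, SNIC); type II neurons jump discontinuously to a
#' minimal frequency (Andronov-Hopf or limit-cycle fold).  The verdict
#' compares the rate at the last spiking point of the sweep against the
#' continuity threshold `epsilon`.
#'
#' @param fi an [fi_curve()] (swept from the spiking side toward
#'   quiescence).
#' @param epsilon onset-frequency threshold (Hz).
#' @return list of class `excitability_verdict`: `type` ("I" or "II"),
#'   `onset_rate`, `jump` (Hz), `value` (parameter at the last spiking
#'   point).
#' @export
excitability_type <- function(fi, epsilon = 0.5) {
  spk <- fi$rate > 0
  if (all(spk)) stop("curve is entirely spiking: onset not spanned")
  if (!any(spk)) stop("curve is entirely quiescent: onset not spanned")
  i_off <- which(!spk)[1]
  if (i_off == 1) stop("sweep must start on the spiking side")
  onset <- fi$rate[i_off - 1]
  structure(list(type = if (onset < epsilon) "I" else "II",
                 onset_rate = onset,
                 jump = onset,
                 value = fi$value[i_off - 1]),
            class = "excitability_verdict")
}

#' Bogdanov-Takens boundary of the excitability type
#'
#' For the reduced model driven by a combined ohmic synapse, the
#' spiking-to-rest transition under growing conductance `g_eff` is a SNIC
#' (type I) at hyperpolarized reversal potentials and an Andronov-Hopf
#' (type II) at more depolarized ones.  The boundary is the reversal
#' potential at which the two codimension-1 curves meet (a Bogdanov-Takens
#' point, double-zero Jacobian eigenvalues).  The verdict at each `e_eff`
#' is whether the first stable equilibrium along the `g_eff` sweep appears
#' through a fold (SNIC side) or an eigenvalue crossing (Hopf side); the
#' flip is bisected in `e_eff`.
#'
#' @param params a [da_params()].
#' @param variant reduced [model_variant()].
#' @param syn baseline drive (set `g_nmda` here to trace the boundary as a
#'   function of NMDA conductance).
#' @param e_range reversal-potential window to bisect (mV), spanning both
#'   transition types.
#' @param g_max upper limit of the `g_eff` sweep (mS/cm^2).
#' @param tol bisection tolerance on `e_eff` (mV).
#' @param v_range equilibrium search window.
#' @return list of class `bt_point`: `e_bt` (mV), `g_eff` at the boundary,
#'   and `eigen` (Jacobian eigenvalues of the transition equilibrium at the
#'   boundary; near a double zero).
#' @export
bt_boundary <- function(params = da_params(),
                        variant = reduced_variant(),
                        syn = syn_drive(), e_range = c(-90, -60),
                        g_max = 3, tol = 0.02, v_range = c(-100, -10)) {
  side <- function(e_eff) {
    fse <- first_stable_event(params, variant, "g_eff", c(0, g_max),
                              syn, e_eff, v_range)
    if (is.na(fse$p_stab)) {
      stop("no spiking-to-rest transition for e_eff = ", e_eff,
           " within g_eff <= ", g_max)
    }
    fse
  }
  lo <- e_range[1]; hi <- e_range[2]
  f_lo <- side(lo); f_hi <- side(hi)
  if (!isTRUE(f_lo$via_fold) || isTRUE(f_hi$via_fold)) {
    stop("e_range does not span the type I / type II flip")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (isTRUE(side(mid)$via_fold)) lo <- mid else hi <- mid
  }
  e_bt <- (lo + hi) / 2
  fse <- side(lo)
  sp <- sweep_point("g_eff", fse$p_stab, syn, e_bt)
  eq <- find_equilibria(params, variant, sp$syn, sp$i_app, v_range)
  ev <- if (nrow(eq)) attr(eq, "eigen")[[which.min(abs(eq$re_lead))]] else
    complex(0)
  structure(list(e_bt = e_bt, g_eff = fse$p_stab, eigen = ev),
            class = "bt_point")
}

#' Hysteresis (bistability) window of the F-I curve
#'
#' Width of the applied-current interval over which a stable limit cycle
#' and a stable rest state coexist, measured from warm-started rising and
#' falling F-I sweeps (slow-ramp emulation).  Zero when the onset and
#' offset currents coincide (no hysteresis, as for a SNIC transition).
#'
#' @param params,variant model configuration (set `g_h` in `params`).
#' @param i_range applied-current window (uA/cm^2), spanning rest at
#'   `i_range[1]` and spiking at `i_range[2]`.
#' @param n grid points per sweep direction.
#' @param syn baseline drive.
#' @param duration,transient,dt per-point settings.
#' @return list with `width` (current units, >= 0), `i_on_rising`,
#'   `i_off_falling`, and both [fi_curve()]s.
#' @export
bistability_window <- function(params = da_params(),
                               variant = reduced_variant(),
                               i_range = c(-6, 0), n = 25,
                               syn = syn_drive(), duration = 6000,
                               transient = 1500, dt = 0.05) {
  up <- seq(i_range[1], i_range[2], length.out = n)
  rest0 <- integrate_da(params, variant, syn, i_range[1], 4000, dt,
                        record_every = 0)$final_state
  fi_up <- fi_curve(params, variant, "i_app", up, syn,
                    duration = duration, transient = transient, dt = dt,
                    init = rest0)
  spike0 <- integrate_da(params, variant, syn, i_range[2], 4000, dt,
                         record_every = 0)$final_state
  fi_dn <- fi_curve(params, variant, "i_app", rev(up), syn,
                    duration = duration, transient = transient, dt = dt,
                    init = spike0)
  i_on <- if (any(fi_up$rate > 0)) min(fi_up$value[fi_up$rate > 0]) else NA
  i_off <- if (any(fi_dn$rate > 0)) min(fi_dn$value[fi_dn$rate > 0]) else NA
  width <- if (is.na(i_on) || is.na(i_off)) NA_real_ else max(0, i_on - i_off)
  list(width = width, i_on_rising = i_on, i_off_falling = i_off,
       rising = fi_up, falling = fi_dn)
}

#' Critical Ih conductance removing the equilibrium-branch folds
#'
#' The equilibrium branch of the reduced model, written as the applied
#' current needed to hold an equilibrium at voltage v, is non-monotone
#' (folded, with two saddle-node points) for weak Ih and becomes monotone
#' above a critical `g_h`: the two folds merge in a cusp and the
#' spiking-to-rest transition switches from a SNIC to a limit-cycle fold.
#' The critical value is bisected on the sign of the minimal branch slope.
#'
#' @param params a [da_params()] (its `g_h` is overridden by the sweep).
#' @param variant reduced [model_variant()] with Ih included.
#' @param syn tonic drive.
#' @param gh_range search interval (mS/cm^2).
#' @param v_range voltage window containing the folds (mV).
#' @param tol bisection tolerance (mS/cm^2).
#' @return list with `gh_crit` and `has_fold(gh)` evaluations at the
#'   bracket ends.
#' @export
critical_gh_fold <- function(params = da_params(),
                             variant = reduced_variant(),
                             syn = syn_drive(), gh_range = c(0, 10),
                             v_range = c(-80, -25), tol = 0.01) {
  min_slope <- function(gh) {
    p <- within_params(params, g_h = gh)
    v <- seq(v_range[1], v_range[2], length.out = 1500)
    i_eq <- -equilibrium_residual(v, p, variant, syn, 0)
    sl <- diff(i_eq) / diff(v)
    # only the hyperpolarizing part of the branch: the saddle-node pair
    # relevant to the spiking-to-rest transition sits at i_app <= 0
    keep <- i_eq[-1] <= 0 & i_eq[-length(i_eq)] <= 0
    if (!any(keep)) return(Inf)
    min(sl[keep])
  }
  lo <- gh_range[1]; hi <- gh_range[2]
  if (min_slope(lo) >= 0 || min_slope(hi) < 0) {
    stop("gh_range does not bracket the fold-vanishing point")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (min_slope(mid) < 0) lo <- mid else hi <- mid
  }
  list(gh_crit = (lo + hi) / 2,
       slope_lo = min_slope(gh_range[1]), slope_hi = min_slope(gh_range[2]))
}

# override fields of a da_params and keep the class/derived fields coherent
within_params <- function(params, ...) {
  ov <- list(...)
  p <- unclass(params)
  p[names(ov)] <- ov
  finalize_da_params(p)
}

#' Export a one-parameter bifurcation diagram as a tidy table
#'
#' For each parameter value: the equilibria (voltage, stability) and, from
#' simulation, the voltage extrema along the stable limit cycle when the
#' model spikes.
#'
#' @inheritParams classify_transition
#' @param values parameter grid.
#' @return tidy data.frame with columns `value`, `branch`
#'   (`"equilibrium"` or `"cycle"`), `v_min`, `v_max`, `stability`.
#' @export
bifurcation_diagram <- function(params = da_params(),
                                variant = reduced_variant(),
                                param = "g_gaba", values,
                                syn = syn_drive(), e_eff = -90,
                                duration = 5000, transient = 1500,
                                dt = 0.05, v_range = c(-100, -10)) {
  rows <- list()
  for (p in values) {
    sp <- sweep_point(param, p, syn, e_eff)
    eq <- find_equilibria(params, variant, sp$syn, sp$i_app, v_range)
    if (nrow(eq)) {
      rows[[length(rows) + 1]] <- data.frame(
        value = p, branch = "equilibrium", v_min = eq$v, v_max = eq$v,
        stability = eq$stability)
    }
    sim <- integrate_da(params, variant, sp$syn, sp$i_app, duration, dt,
                        record_every = 10, transient = transient)
    if (sum(sim$spikes >= transient) >= 2) {
      v <- sim$v[sim$time >= transient]
      rows[[length(rows) + 1]] <- data.frame(
        value = p, branch = "cycle", v_min = min(v), v_max = max(v),
        stability = "stable")
    }
  }
  do.call(rbind, rows)
}
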