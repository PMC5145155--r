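#' Synaptic drive specification
#'
#' Instantaneous synaptic input to the DA neuron: maximal conductances and
#' gating values for the NMDA, AMPA and GABA receptor currents.  Tonic
#' receptor activation corresponds to gating fixed at 1, which is how the
#' dynamic-clamp-like protocols are run.
#'
#' @param g_nmda,g_ampa,g_gaba maximal conductances (mS/cm^2).
#' @param s_nmda,s_ampa,s_gaba gating values in \[0, 1\] (AMPA gating is the
#'   product of its activation and desensitization gates).
#' @param e_ampa,e_gaba reversal potentials (mV); the NMDA reversal is 0 mV.
#' @return a list of class `syn_drive`.
#' @export
syn_drive <- function(g_nmda = 0, g_ampa = 0, g_gaba = 0,
                      s_nmda = 1, s_ampa = 1, s_gaba = 1,
                      e_ampa = 0, e_gaba = -90) {
  if (any(c(g_nmda, g_ampa, g_gaba) < 0)) stop("conductances must be >= 0")
  structure(list(g_nmda = g_nmda, g_ampa = g_ampa, g_gaba = g_gaba,
                 s_nmda = s_nmda, s_ampa = s_ampa, s_gaba = s_gaba,
                 e_ampa = e_ampa, e_gaba = e_gaba),
            class = "syn_drive")
}

#' Represent a combined ohmic synapse as AMPA + GABA conductances
#'
#' Inverse of [effective_ohmic()]: given the total ohmic conductance and its
#' reversal potential, returns the (g_ampa, g_gaba) pair realizing it (with
#' `e_ampa = 0`, `e_gaba = -90`).  Used by the reversal-potential sweeps of
#' the excitability-boundary analysis.
#'
#' @param g_eff total ohmic conductance (mS/cm^2).
#' @param e_eff reversal potential (mV), must lie in \[e_gaba, 0\].
#' @param e_gaba GABA reversal potential (mV).
#' @return a [syn_drive()].
#' @export
ohmic_split <- function(g_eff, e_eff, e_gaba = -90) {
  if (e_eff < e_gaba || e_eff > 0) stop("e_eff must lie in [e_gaba, 0]")
  g_gaba <- g_eff * e_eff / e_gaba
  syn_drive(g_ampa = max(0, g_eff - g_gaba), g_gaba = g_gaba,
            e_gaba = e_gaba)
}

#' Vector field of the DA neuron model
#'
#' Time derivatives of the state (v, ca, q, h, n).  The voltage equation sums
#' the L-type Ca2+, SK, voltage-gated K+, delayed rectifier, subthreshold and
#' fast Na+, leak, Ih and synaptic currents, with currents gated off
#' according to the `variant` flags.  The Ca2+ balance takes influx through
#' the L-type channel plus the Ca2+ component of the leak and first-order
#' pump removal.
#'
#' @param state a [da_state()] (or named vector with v, ca, q, h, n).
#' @param params a [da_params()].
#' @param variant a [model_variant()].
#' @param syn a [syn_drive()].
#' @param i_app applied current (uA/cm^2).
#' @return named numeric vector of derivatives (mV/ms, uM/ms, 1/ms).
#' @examples
#' da_rhs(da_state(), da_params())
#' @export
da_rhs <- function(state, params, variant = model_variant(),
                   syn = syn_drive(), i_app = 0) {
  if (any(!is.finite(state))) stop("non-finite state")
  v <- state[["v"]]; ca <- state[["ca"]]
  q <- state[["q"]]; h <- state[["h"]]; n <- state[["n"]]
  p <- params

  g_ca <- ca_conductance(v, p)
  i_v <- g_ca * (p$e_ca - v) +
    (sk_conductance(ca, p) + k_conductance(v, p)) * (p$e_k - v) +
    p$g_l * (p$e_l - v)
  if (variant$include_sna) {
    i_v <- i_v + sna_conductance(v, p) * (p$e_na - v)
  }
  if (variant$include_spike_currents) {
    fr <- fast_na_rates(v)
    i_v <- i_v + p$gbar_na * fr$m_inf^3 * h * (p$e_na - v) +
      p$gbar_dr * n^4 * (p$e_k - v)
  }
  if (variant$include_ih) i_v <- i_v + p$g_h * q * (p$e_h - v)

  i_v <- i_v +
    nmda_conductance(v, syn$g_nmda, p) * syn$s_nmda * (0 - v) +
    syn$g_ampa * syn$s_ampa * (syn$e_ampa - v) +
    syn$g_gaba * syn$s_gaba * (syn$e_gaba - v) +
    i_app

  g_ca_in <- g_ca + if (variant$include_ca_leak) p$ca_leak_frac * p$g_l else 0
  dca <- p$ca_gain * g_ca_in * (p$e_ca - v) - p$ca_pump * ca

  ihk <- ih_kinetics(v)
  fr <- fast_na_rates(v)
  dr <- dr_rates(v)
  c(v  = i_v / p$c_m,
    ca = dca,
    q  = (ihk$q_inf - q) / ihk$tau_q,
    h  = fr$alpha_h * (1 - h) - fr$beta_h * h,
    n  = dr$alpha_n * (1 - n) - dr$beta_n * n)
}

#' Vector field of the Wang-Buzsaki GABA interneuron
#'
#' Fast-spiking interneuron with instantaneous Na+ activation (`m` replaced
#' by its steady state), first-order inactivation `h` and K+ activation `n`.
#'
#' @param state a [gaba_state()] (named vector v, h, n).
#' @param params a [gaba_params()].
#' @param syn optional [syn_drive()] onto the GABA neuron.
#' @param i_app applied current (uA/cm^2); per-neuron values set the
#'   intrinsic rate in the 12-22 Hz band.
#' @return named numeric vector of derivatives.
#' @export
gaba_wb_rhs <- function(state, params = gaba_params(), syn = NULL,
                        i_app = params$i_app) {
  if (any(!is.finite(state))) stop("non-finite state")
  v <- state[["v"]]; h <- state[["h"]]; n <- state[["n"]]
  p <- params
  r <- wb_rates(v)
  i_v <- p$gbar_na * r$m_inf^3 * h * (p$e_na - v) +
    p$gbar_k * n^4 * (p$e_k - v) +   # canonical Wang-Buzsaki n^4 K+ current

    p$g_l * (p$e_l - v) + i_app
  if (!is.null(syn)) {
    i_v <- i_v + syn$g_ampa * syn$s_ampa * (syn$e_ampa - v) +
      syn$g_gaba * syn$s_gaba * (syn$e_gaba - v) +
      nmda_conductance(v, syn$g_nmda) * syn$s_nmda * (0 - v)
  }
  c(v = i_v / p$c_m,
    h = r$alpha_h * (1 - h) - r$beta_h * h,
    n = r$alpha_n * (1 - n) - r$beta_n * n)
}
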