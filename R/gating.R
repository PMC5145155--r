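# Intrinsic and synaptic gating functions of the DA and GABA neuron models.
# All are total functions of voltage (removable singularities of the
# Hodgkin-Huxley rate forms are evaluated through x/expm1(x), which is
# finite and accurate through the singular point).

# x / (exp(x) - 1), continuous at 0
xexpm1 <- function(x) {
  out <- x / expm1(x)
  out[abs(x) < 1e-12] <- 1
  out
}

#' Instantaneous L-type Ca2+ conductance
#'
#' Activation of the L-type Ca2+ current is instantaneous; its steady state
#' is a sigmoid with half-activation near -50 mV, the characteristically low
#' activation threshold of the L-type current in DA cells.  The slope is a
#' calibrated constant (`k_ca`).
#'
#' @param v membrane voltage (mV), vectorized.
#' @param params a [da_params()] object.
#' @return conductance in \[0, `gbar_ca`\] (mS/cm^2), monotone increasing in `v`.
#' @examples
#' p <- da_params()
#' ca_conductance(p$vhalf_ca, p) == p$gbar_ca / 2
#' @export
ca_conductance <- function(v, params) {
  params$gbar_ca / (1 + exp(-(v - params$vhalf_ca) / params$k_ca))
}

#' SK (Ca2+-dependent K+) conductance
#'
#' Hill function of intracellular Ca2+ with coefficient 4 and
#' half-activation at `k_sk`.
#'
#' @param ca intracellular Ca2+ concentration (uM), must be >= 0.
#' @inheritParams ca_conductance
#' @return conductance in \[0, `gbar_kca`\] (mS/cm^2), monotone in `ca`.
#' @export
sk_conductance <- function(ca, params) {
  if (any(ca < 0)) stop("ca must be >= 0")
  c4 <- ca^4
  params$gbar_kca * c4 / (c4 + params$k_sk^4)
}

#' Voltage-dependent K+ conductance
#'
#' Boltzmann function with midpoint -10 mV and slope 7 mV.
#'
#' @inheritParams ca_conductance
#' @return conductance in \[0, `gbar_k`\] (mS/cm^2).
#' @export
k_conductance <- function(v, params) {
  params$gbar_k / (1 + exp(-(v + 10) / 7))
}

#' Subthreshold (persistent) Na+ conductance
#'
#' Instantaneous sigmoid with midpoint -50 mV and slope 5 mV; there is no
#' associated state variable.
#'
#' @inheritParams ca_conductance
#' @return conductance in \[0, `gbar_sna`\] (mS/cm^2).
#' @export
sna_conductance <- function(v, params) {
  params$gbar_sna / (1 + exp(-(v + 50) / 5))
}

#' Ih activation kinetics
#'
#' Steady-state activation (decreasing in `v`: the current is
#' hyperpolarization-activated, midpoint -95 mV) and its voltage-dependent
#' time constant.
#'
#' @param v membrane voltage (mV), vectorized.
#' @return list with `q_inf` (0-1) and `tau_q` (ms).
#' @examples
#' ih_kinetics(-95)$q_inf       # 0.5 at the midpoint
#' ih_kinetics(-112)$tau_q      # 312.5 ms
#' @export
ih_kinetics <- function(v) {
  list(q_inf = 1 / (1 + exp((v + 95) / 8)),
       tau_q = 625 * exp(0.075 * (v + 112)) / (1 + exp(0.083 * (v + 112))))
}

#' Fast Na+ current rate functions
#'
#' Activation is instantaneous (`m_inf`); inactivation `h` follows
#' first-order kinetics with rates `alpha_h`, `beta_h`.  The removable
#' singularities of the activation rates at v = -39 and v = -4 are handled
#' by their analytic limits.
#'
#' @param v membrane voltage (mV), vectorized.
#' @return list with `m_inf`, `alpha_m`, `beta_m`, `alpha_h`, `beta_h`
#'   (rates in 1/ms).
#' @export
fast_na_rates <- function(v) {
  alpha_m <- 1.28 * xexpm1(-(v + 39) / 4)
  beta_m  <- 1.40 * xexpm1((v + 4) / 5)
  alpha_h <- 0.01 * exp(-(v + 47) / 18)
  beta_h  <- 1.25 / (1 + exp(-(v + 24) / 5))
  list(m_inf = alpha_m / (alpha_m + beta_m),
       alpha_m = alpha_m, beta_m = beta_m,
       alpha_h = alpha_h, beta_h = beta_h)
}

#' Delayed-rectifier K+ rate functions
#'
#' Rates of the activation variable `n`; the removable singularity of
#' `alpha_n` at v = -5 is handled analytically.
#'
#' @param v membrane voltage (mV), vectorized.
#' @return list with `alpha_n`, `beta_n` (1/ms).
#' @export
dr_rates <- function(v) {
  list(alpha_n = 0.032 * xexpm1(-(v + 5) / 10),
       beta_n  = 0.05 * exp(-(v + 10) / 16))
}

#' Voltage-dependent NMDA conductance (Mg2+ block)
#'
#' @param v membrane voltage (mV), vectorized.
#' @param gbar_nmda maximal NMDA conductance (mS/cm^2), >= 0.
#' @inheritParams ca_conductance
#' @return conductance in \[0, `gbar_nmda`\] (mS/cm^2); the block is
#'   relieved at depolarized voltages.
#' @export
nmda_conductance <- function(v, gbar_nmda, params = da_params()) {
  if (any(gbar_nmda < 0)) stop("gbar_nmda must be >= 0")
  gbar_nmda / (1 + 0.1 * params$mg * exp(-params$m_e * v))
}

# Wang-Buzsaki rate functions (GABA interneuron); removable singularities
# at v = -30 (alpha_m) and v = -29 (alpha_n) handled by limits.
wb_rates <- function(v) {
  alpha_m <- 1.0 * xexpm1(-(v + 30) / 10)
  beta_m  <- 4 * exp(-(v + 55) / 18)
  alpha_h <- 0.07 * exp(-(v + 53) / 20)
  beta_h  <- 1 / (1 + exp(-(v + 23) / 10))
  alpha_n <- 0.1 * xexpm1(-(v + 29) / 10)
  beta_n  <- 0.0875 * exp(-(v + 39) / 80)
  list(m_inf = alpha_m / (alpha_m + beta_m),
       alpha_m = alpha_m, beta_m = beta_m,
       alpha_h = alpha_h, beta_h = beta_h,
       alpha_n = alpha_n, beta_n = beta_n)
}

#' Combined ohmic synapse (AMPA + GABA)
#'
#' AMPA and GABA receptor currents are both ohmic; their sum is an ohmic
#' current with conductance `g_eff = g_ampa + g_gaba` and reversal potential
#' equal to the conductance-weighted average of the two reversal potentials
#' (`= g_gaba * e_gaba / (g_gaba + g_ampa)` when `e_ampa = 0`).
#'
#' @param g_ampa,g_gaba conductances (mS/cm^2), >= 0 and not both zero.
#' @param e_ampa,e_gaba reversal potentials (mV).
#' @return list with `g_eff` and `e_eff`.
#' @examples
#' effective_ohmic(1, 1)  # e_eff = -45 mV
#' @export
effective_ohmic <- function(g_ampa, g_gaba, e_ampa = 0, e_gaba = -90) {
  if (any(g_ampa < 0) || any(g_gaba < 0)) stop("conductances must be >= 0")
  if (any(g_ampa + g_gaba == 0)) {
    stop("reversal potential undefined when both conductances are 0")
  }
  list(g_eff = g_ampa + g_gaba,
       e_eff = (g_gaba * e_gaba + g_ampa * e_ampa) / (g_gaba + g_ampa))
}
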