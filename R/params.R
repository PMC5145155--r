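#' Parameters of the dopamine neuron model
#'
#' Constructs the full parameter set of the single-compartment DA neuron:
#' maximal conductances and reversal potentials of the eight intrinsic
#' currents, the Ca2+ handling constants, and the synaptic constants (Mg2+
#' block of the NMDA conductance).  Defaults are the published table values
#' plus the calibrated constants of the Ca2+ subsystem (the L-type activation
#' curve, pump rate and SK half-activation are not tabulated and were fixed by
#' calibrating the model against its reference behaviours: 1-5 Hz background
#' firing, the 1.5 Hz balanced state at `g_nmda = 16.9`, `g_gaba = 5`
#' mS/cm^2, the ~3.4 NMDA/GABA balance slope, the <= 10 Hz AMPA-driven
#' ceiling, the -72.26 mV Bogdanov-Takens reversal potential and the ~7
#' mS/cm^2 Ih cusp; see the methods vignette).
#'
#' Units are mV, ms, mS/cm^2, uF/cm^2 and uM throughout.  Currents are in
#' uA/cm^2.  The Ca2+ balance uses the conversion factor
#' `2*beta_ca/(r*z*F)` folded into the derived field `ca_gain`
#' (uM per ms per uA/cm^2, with `r` converted from um to cm), and the pump
#' term `2*beta_ca*p_ca/r` folded into `ca_pump` (1/ms).
#'
#' @param ... name-value overrides of any field listed below.
#'
#' @section Fields:
#' \describe{
#'   \item{c_m}{membrane capacitance (uF/cm^2)}
#'   \item{gbar_ca, gbar_kca, gbar_k, gbar_sna, gbar_na, gbar_dr, g_l, g_h}{
#'     maximal conductances (mS/cm^2); `g_h = 0` in the control condition}
#'   \item{e_ca, e_k, e_na, e_l, e_h}{reversal potentials (mV)}
#'   \item{beta_ca}{ratio of free to total Ca2+ (dimensionless)}
#'   \item{r}{compartment radius (um)}
#'   \item{z}{Ca2+ valence}
#'   \item{faraday}{Faraday constant (C/mol)}
#'   \item{p_ca}{maximal pump removal rate (cm/ms scale velocity; calibrated)}
#'   \item{k_sk}{Ca2+ concentration of SK half-activation (uM; calibrated)}
#'   \item{mg}{magnesium level entering the NMDA voltage dependence (uM,
#'     implemented exactly as published)}
#'   \item{m_e}{slope of the NMDA voltage dependence (1/mV)}
#'   \item{ca_leak_frac}{fraction of the leak conductance carried by Ca2+}
#'   \item{vhalf_ca, k_ca}{half-activation (mV) and slope (mV) of the
#'     instantaneous L-type Ca2+ activation sigmoid (calibrated; the
#'     activation threshold is ~ -50 mV in DA cells)}
#' }
#'
#' @return an object of class `da_params` (a validated named list with the
#'   derived fields `ca_gain` and `ca_pump`).
#' @examples
#' p <- da_params()
#' p$gbar_ca
#' p2 <- da_params(g_h = 7)  # strong Ih variant
#' @export
da_params <- function(...) {
  p <- list(
    c_m      = 1,
    gbar_ca  = 2.5,
    gbar_kca = 7.8,
    gbar_k   = 1,
    gbar_sna = 0.13,
    gbar_na  = 50,
    gbar_dr  = 2,
    g_l      = 0.18,
    g_h      = 0,
    e_ca     = 50,
    e_k      = -90,
    e_na     = 55,
    e_l      = -35,
    e_h      = -20,
    beta_ca  = 0.05,
    r        = 20,
    z        = 2,
    faraday  = 96485,
    p_ca     = 6.5e-5,
    k_sk     = 1.5,
    mg       = 0.5,
    m_e      = 0.062,
    ca_leak_frac = 0.1,
    vhalf_ca = -41.4,
    k_ca     = 3
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad) || is.null(names(ov)) || any(names(ov) == "")) {
      stop("unknown or unnamed da_params field(s): ",
           paste(bad, collapse = ", "))
    }
    p[names(ov)] <- ov
  }
  p <- finalize_da_params(p)
  validate_da_params(p)
  p
}

finalize_da_params <- function(p) {
  p <- lapply(p, as.numeric)              # YAML may deliver integers
  r_cm <- p$r * 1e-4                      # um -> cm
  p$ca_gain <- 2 * p$beta_ca / (r_cm * p$z * p$faraday)
  p$ca_pump <- 2 * p$beta_ca * p$p_ca / r_cm
  class(p) <- "da_params"
  p
}

validate_da_params <- function(p) {
  g <- c("gbar_ca", "gbar_kca", "gbar_k", "gbar_sna", "gbar_na",
         "gbar_dr", "g_l", "g_h")
  if (any(vapply(p[g], function(x) x < 0, logical(1)))) {
    stop("all conductances must be >= 0")
  }
  if (p$c_m <= 0) stop("c_m must be > 0")
  if (!(p$e_k < p$e_l && p$e_l < p$e_na)) stop("require e_k < e_l < e_na")
  if (p$k_sk <= 0) stop("k_sk must be > 0")
  if (p$ca_leak_frac < 0 || p$ca_leak_frac > 1) {
    stop("ca_leak_frac must lie in [0, 1]")
  }
  invisible(p)
}

#' State of the dopamine neuron model
#'
#' The dynamic variables: membrane voltage `v` (mV), intracellular Ca2+
#' concentration `ca` (uM), Ih activation `q`, fast-Na inactivation `h` and
#' delayed-rectifier activation `n` (all gates in \[0, 1\]).
#'
#' @param v,ca,q,h,n initial values.  The defaults start the cell
#'   hyperpolarized with gates at their steady state for that voltage.
#' @return a named numeric vector of class `da_state`.
#' @examples
#' da_state()
#' da_state(v = -40, ca = 0.5)
#' @export
da_state <- function(v = -60, ca = 1, q = NULL, h = NULL, n = NULL) {
  if (is.null(q)) q <- ih_kinetics(v)$q_inf
  if (is.null(h)) {
    fr <- fast_na_rates(v)
    h <- fr$alpha_h / (fr$alpha_h + fr$beta_h)
  }
  if (is.null(n)) {
    dr <- dr_rates(v)
    n <- dr$alpha_n / (dr$alpha_n + dr$beta_n)
  }
  s <- c(v = v, ca = ca, q = q, h = h, n = n)
  if (ca < 0) stop("ca must be >= 0")
  if (any(s[c("q", "h", "n")] < 0 | s[c("q", "h", "n")] > 1)) {
    stop("gates q, h, n must lie in [0, 1]")
  }
  class(s) <- c("da_state", class(s))
  s
}

#' Model variant switches
#'
#' Controls which current groups enter the voltage equation.  The full model
#' carries the spike-producing currents (fast Na+ and delayed rectifier) and
#' registers spikes at 0 mV; the reduced model used for phase-plane and
#' bifurcation analysis removes them and registers a spike whenever the
#' subthreshold oscillation crosses -40 mV.
#'
#' @param include_spike_currents include fast Na+ and delayed-rectifier K+.
#' @param include_sna include the subthreshold (persistent) Na+ current.
#' @param include_ih include the hyperpolarization-activated cation current
#'   (only matters when `g_h > 0`).
#' @param include_ca_leak include the Ca2+ component of the leak current in
#'   the Ca2+ balance.
#' @param spike_threshold spike registration threshold (mV); defaults to 0
#'   for the full model and -40 for the reduced one.
#' @return an object of class `model_variant`.
#' @examples
#' model_variant()                                  # full model
#' model_variant(include_spike_currents = FALSE)    # reduced model
#' model_variant(include_spike_currents = FALSE, include_sna = FALSE)
#' @export
model_variant <- function(include_spike_currents = TRUE,
                          include_sna = TRUE,
                          include_ih = TRUE,
                          include_ca_leak = TRUE,
                          spike_threshold = NULL) {
  if (is.null(spike_threshold)) {
    spike_threshold <- if (include_spike_currents) 0 else -40
  }
  structure(list(include_spike_currents = include_spike_currents,
                 include_sna = include_sna,
                 include_ih = include_ih,
                 include_ca_leak = include_ca_leak,
                 spike_threshold = spike_threshold),
            class = "model_variant")
}

#' Reduced (no-spike-currents) model variant
#'
#' Convenience wrapper for the two-dimensional (v, Ca) subthreshold system
#' (three-dimensional with Ih) on which nullcline and bifurcation analysis is
#' performed.
#'
#' @param include_sna keep the subthreshold Na+ current (`FALSE` isolates the
#'   pure Ca2+/SK oscillatory mechanism).
#' @param include_ih keep Ih.
#' @inheritParams model_variant
#' @return a `model_variant`.
#' @export
reduced_variant <- function(include_sna = TRUE, include_ih = TRUE,
                            include_ca_leak = TRUE, spike_threshold = -40) {
  model_variant(include_spike_currents = FALSE, include_sna = include_sna,
                include_ih = include_ih, include_ca_leak = include_ca_leak,
                spike_threshold = spike_threshold)
}

#' Parameters of the Wang-Buzsaki GABA interneuron
#'
#' Fast-spiking interneuron used to build the inhibitory population drive.
#' The leak conductance and the applied-current range are calibrated so that
#' the population fires in the 12-22 Hz band.
#'
#' @param ... name-value overrides.
#' @return an object of class `gaba_params`.
#' @examples
#' gaba_params()
#' @export
gaba_params <- function(...) {
  p <- list(
    c_m     = 1,
    gbar_na = 22,
    gbar_k  = 7,
    g_l     = 0.1,
    e_na    = 55,
    e_k     = -90,
    e_l     = -51,
    i_app   = -0.2
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown gaba_params field(s): ",
                          paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  if (any(vapply(p[c("gbar_na", "gbar_k", "g_l")], function(x) x < 0,
                 logical(1)))) {
    stop("conductances must be >= 0")
  }
  class(p) <- "gaba_params"
  p
}

#' GABA neuron state
#'
#' @param v voltage (mV); `h`, `n` default to their steady states at `v`.
#' @param h,n gating variables in \[0, 1\].
#' @return named numeric vector of class `gaba_state`.
#' @export
gaba_state <- function(v = -64, h = NULL, n = NULL) {
  r <- wb_rates(v)
  if (is.null(h)) h <- r$alpha_h / (r$alpha_h + r$beta_h)
  if (is.null(n)) n <- r$alpha_n / (r$alpha_n + r$beta_n)
  if (any(c(h, n) < 0 | c(h, n) > 1)) stop("gates must lie in [0, 1]")
  structure(c(v = v, h = h, n = n), class = "gaba_state")
}

#' Load / save parameter configurations
#'
#' Parameter sets are serialized as flat key-value YAML.  The canonical
#' configuration shipped with the package
#' (`system.file("extdata", "table1.yaml", package = "daneuron")`) mirrors
#' the published parameter table plus the calibrated Ca2+ constants.
#'
#' @param path YAML file of parameter overrides.
#' @return `load_params()` returns a `da_params`; unknown keys are an error.
#' @examples
#' p <- load_params(system.file("extdata", "table1.yaml", package = "daneuron"))
#' @export
load_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(da_params, cfg)
}

#' @rdname load_params
#' @param params a `da_params` object.
#' @export
save_params <- function(params, path) {
  stopifnot(inherits(params, "da_params"))
  keep <- setdiff(names(unclass(params)), c("ca_gain", "ca_pump"))
  yaml::write_yaml(unclass(params)[keep], path)
  invisible(path)
}

# flat parameter vector in the order the C++ kernel expects
pack_da_params <- function(p) {
  c(p$c_m, p$gbar_ca, p$gbar_kca, p$gbar_k, p$gbar_sna, p$gbar_na,
    p$gbar_dr, p$g_l, p$g_h, p$e_ca, p$e_k, p$e_na, p$e_l, p$e_h,
    p$mg, p$m_e, p$ca_leak_frac, p$vhalf_ca, p$k_ca, p$k_sk,
    p$ca_gain, p$ca_pump)
}

pack_variant <- function(variant) {
  as.numeric(c(variant$include_spike_currents, variant$include_sna,
               variant$include_ih, variant$include_ca_leak))
}

pack_gaba_params <- function(p) {
  c(p$c_m, p$gbar_na, p$gbar_k, p$g_l, p$e_na, p$e_k, p$e_l)
}
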