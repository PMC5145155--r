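test_that("intrinsic conductances respect their limits and midpoints", {
  p <- p_ref
  # L-type Ca2+: closed at hyperpolarization, saturates, half at midpoint
  expect_lt(ca_conductance(-200, p), 1e-10)
  expect_equal(ca_conductance(200, p), p$gbar_ca, tolerance = 1e-10)
  expect_equal(ca_conductance(p$vhalf_ca, p), p$gbar_ca / 2)
  expect_true(all(diff(ca_conductance(seq(-100, 40, 0.5), p)) > 0))

  # SK: Hill-4 in Ca2+
  expect_identical(sk_conductance(0, p), 0)
  expect_equal(sk_conductance(p$k_sk, p), p$gbar_kca / 2)
  expect_equal(sk_conductance(2 * p$k_sk, p), p$gbar_kca * 16 / 17)
  expect_error(sk_conductance(-0.1, p), "ca")

  # K+ Boltzmann (midpoint -10 mV, slope 7)
  expect_equal(k_conductance(-10, p), p$gbar_k / 2)
  expect_equal(k_conductance(-3, p), p$gbar_k / (1 + exp(-1)))
  expect_lt(k_conductance(-200, p), 1e-10)

  # subthreshold Na+ (midpoint -50 mV, slope 5)
  expect_equal(sna_conductance(-50, p), p$gbar_sna / 2)
  expect_equal(sna_conductance(-45, p), p$gbar_sna / (1 + exp(-1)))
  expect_equal(sna_conductance(200, p), p$gbar_sna, tolerance = 1e-10)
})

test_that("Ih kinetics are hyperpolarization-activated with the stated law", {
  expect_equal(ih_kinetics(-95)$q_inf, 0.5)
  expect_equal(ih_kinetics(-112)$tau_q, 312.5)
  expect_equal(ih_kinetics(-87)$q_inf, 1 / (1 + exp(1)))
  v <- seq(-120, 60, by = 1)
  expect_true(all(diff(ih_kinetics(v)$q_inf) < 0))  # decreasing in v
})

test_that("fast Na+ and delayed-rectifier rates match their analytic forms", {
  fr <- fast_na_rates(-39)
  expect_equal(fr$alpha_m, 1.28)          # L'Hopital limit at the pole
  expect_equal(fast_na_rates(-4)$beta_m, 1.4)
  expect_equal(fast_na_rates(-47)$alpha_h, 0.01)
  expect_equal(fast_na_rates(-24)$beta_h, 1.25 / 2)
  expect_equal(dr_rates(-5)$alpha_n, 0.032)
  expect_equal(dr_rates(-10)$beta_n, 0.05)
  expect_lt(dr_rates(-200)$alpha_n, 1e-6)
})

test_that("rate functions agree with their analytic limits through the poles", {
  # independent oracle: the Bernoulli series x/(e^x - 1) = 1 - x/2 + x^2/12
  series <- function(x) 1 - x / 2 + x^2 / 12
  cases <- list(
    list(f = function(v) fast_na_rates(v)$alpha_m, v0 = -39,
         map = function(v) -(v + 39) / 4, scale = 1.28),
    list(f = function(v) fast_na_rates(v)$beta_m, v0 = -4,
         map = function(v) (v + 4) / 5, scale = 1.4),
    list(f = function(v) dr_rates(v)$alpha_n, v0 = -5,
         map = function(v) -(v + 5) / 10, scale = 0.032),
    list(f = function(v) wb_rates_test(v)$alpha_m, v0 = -30,
         map = function(v) (v + 30) / 10, scale = 1, inv = TRUE),
    list(f = function(v) wb_rates_test(v)$alpha_n, v0 = -29,
         map = function(v) (v + 29) / 10, scale = 0.1, inv = TRUE)
  )
  for (case in cases) {
    v <- case$v0 + c(-1e-3, -1e-8, 0, 1e-8, 1e-3)
    x <- case$map(v)
    # the WB rates use x/(1 - e^-x) = series(-x)
    expected <- if (isTRUE(case$inv)) case$scale * series(-x) else
      case$scale * series(x)
    expect_true(all(abs(case$f(v) - expected) < 1e-8),
                label = sprintf("analytic limit at v = %g", case$v0))
  }
})

test_that("all gating steady states stay in [0, 1] on a voltage grid", {
  v <- seq(-120, 60, by = 0.5)
  fr <- fast_na_rates(v)
  dr <- dr_rates(v)
  wb <- wb_rates_test(v)
  gates <- cbind(fr$m_inf, fr$alpha_h / (fr$alpha_h + fr$beta_h),
                 dr$alpha_n / (dr$alpha_n + dr$beta_n),
                 ih_kinetics(v)$q_inf,
                 wb$m_inf, wb$alpha_h / (wb$alpha_h + wb$beta_h),
                 wb$alpha_n / (wb$alpha_n + wb$beta_n))
  expect_true(all(gates >= 0 & gates <= 1))
  expect_true(all(ih_kinetics(v)$tau_q > 0))
})

test_that("NMDA Mg2+ block follows the printed voltage dependence", {
  p <- p_ref
  expect_equal(nmda_conductance(0, 1, p), 1 / 1.05)
  expect_equal(nmda_conductance(200, 1, p), 1, tolerance = 1e-4)
  expect_equal(nmda_conductance(-60, 1, p),
               1 / (1 + 0.05 * exp(0.062 * 60)))
  expect_error(nmda_conductance(-60, -1, p), "gbar_nmda")
})

test_that("the combined ohmic synapse has the weighted reversal potential", {
  expect_equal(effective_ohmic(0, 2)$e_eff, -90)
  expect_equal(effective_ohmic(1, 1)$e_eff, -45)
  expect_equal(effective_ohmic(1, 1)$g_eff, 2)
  expect_error(effective_ohmic(0, 0), "undefined")
  # convexity: e_eff between e_gaba and 0 for random mixtures
  set.seed(1)
  ga <- runif(50); gg <- runif(50) + 1e-6
  ee <- effective_ohmic(ga, gg)$e_eff
  expect_true(all(ee >= -90 & ee <= 0))
  # ohmic_split inverts effective_ohmic
  sp <- ohmic_split(2, -45)
  expect_equal(effective_ohmic(sp$g_ampa, sp$g_gaba)$e_eff, -45)
  expect_equal(sp$g_ampa + sp$g_gaba, 2)
})

test_that("Wang-Buzsaki rates match the printed values at anchor voltages", {
  r <- wb_rates_test(-30)
  expect_equal(r$alpha_m, 1)                      # removable-pole limit
  expect_equal(r$beta_m, 4 * exp(-25 / 18))
  expect_equal(r$m_inf, r$alpha_m / (r$alpha_m + r$beta_m))
  expect_equal(wb_rates_test(-23)$beta_h, 0.5)    # sigmoid midpoint
  expect_equal(wb_rates_test(-53)$alpha_h, 0.07)
  expect_equal(wb_rates_test(-39)$beta_n, 0.0875)
})
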