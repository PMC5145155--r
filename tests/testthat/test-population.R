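test_that("dopamine release follows impulsive release with MM uptake", {
  p <- da_release_params()
  # no spikes: identically zero
  tr0 <- da_release(numeric(0), duration = 1000)
  expect_true(all(tr0$da == 0))
  # one spike: jump to da_max then monotone decay toward 0
  tr1 <- da_release(100, duration = 2000, dt = 0.25)
  i_post <- tr1$time > 100
  expect_gt(max(tr1$da), p$da_max - 1e-3)   # within one uptake step
  expect_true(all(diff(tr1$da[i_post]) <= 1e-12))
  expect_true(all(tr1$da >= 0))
  expect_equal(tr1$cum_release[length(tr1$cum_release)], p$da_max)
  # independent oracle: lsoda on the uptake ODE between spikes
  upt <- function(t, y, parms) list(-p$v_max * y / (p$k_m + y))
  ode <- deSolve::lsoda(p$da_max, seq(0, 1900, 1), upt, NULL,
                        rtol = 1e-10, atol = 1e-12)
  sim_at <- approx(tr1$time - 100, tr1$da, xout = seq(0, 1900, 1))$y
  # the impulsive increment lands at the start of its step, so the
  # simulated curve leads the oracle by at most one uptake step
  expect_lt(max(abs(sim_at[-1] - unname(ode[-1, 2]))), 5e-4)
})

test_that("regular spiking settles on the flux-balance plateau", {
  # the closed form holds in the smooth-release limit: same release fluxes
  # as 0.1 uM/spike at 1, 2, 4 Hz, delivered as 10x smaller boluses
  p10 <- da_release_params(da_max = 0.01)
  for (f in c(10, 20, 40)) {
    spikes <- seq(0, 120000, by = 1000 / f)
    tr <- da_release(spikes, p = p10, duration = 120000, dt = 0.5)
    tail_mean <- mean(tr$da[tr$time > 60000])
    expect_lt(abs(tail_mean - da_plateau(f, p10)) / da_plateau(f, p10),
              0.05)
  }
  # with the full 0.1 uM per-spike bolus the sawtooth rides above the
  # smooth-limit plateau by a modest, positive bias
  for (f in c(1, 2, 4)) {
    spikes <- seq(0, 120000, by = 1000 / f)
    tr <- da_release(spikes, duration = 120000, dt = 0.5)
    bias <- mean(tr$da[tr$time > 60000]) / da_plateau(f) - 1
    expect_gt(bias, 0)
    expect_lt(bias, 0.25)
  }
  expect_equal(da_plateau(4), 0.2 * 4e-4 / (0.004 - 4e-4))
  expect_error(da_plateau(100), "uptake")
})

test_that("the synchrony index is calibrated against its shuffle null", {
  set.seed(8)
  # independent Poisson neurons: index near 1
  raster <- data.frame(
    neuron = rep(1:12, each = 200),
    time_ms = as.numeric(replicate(12, sort(runif(200, 0, 20000)))))
  si <- synchrony_index(raster, c(0, 20000), bin = 20)
  expect_gt(si, 0.7)
  expect_lt(si, 1.4)
  # perfectly coincident spiking: far above 1
  co <- data.frame(neuron = rep(1:12, times = 40),
                   time_ms = rep(seq(250, 20000, 500), each = 12))
  expect_gt(synchrony_index(co, c(0, 20000), bin = 20), 3)
  expect_true(is.na(synchrony_index(raster[0, ], c(0, 1000))))
  expect_error(synchrony_index(data.frame(neuron = 1, time_ms = 1),
                               c(0, 10)), "2 neurons")
})

test_that("population simulations are reproducible and well-formed", {
  spec <- population_spec(n_neurons = 6, seed = 21)
  r1 <- simulate_population(spec, duration = 4000, t_stim_on = 1500)
  r2 <- simulate_population(spec, duration = 4000, t_stim_on = 1500)
  expect_identical(r1$raster, r2$raster)        # bit-reproducible
  expect_true(all(r1$da$da >= 0))
  expect_equal(length(r1$summed), length(r1$bins) - 1)
  expect_equal(sum(r1$summed), nrow(r1$raster))
  # heterogeneous leak keeps every neuron active in control
  expect_true(all(r1$rates > 0))
})

test_that("identical multipliers reproduce the control bit for bit", {
  spec <- population_spec(n_neurons = 4, seed = 5)
  et <- etoh_protocol(spec, multipliers = list(g_h = 1, g_ampa = 1,
                                               g_gaba = 1),
                      duration = 4000, t_stim_on = 1500)
  expect_identical(et$control$raster, et$tone$raster)
  expect_error(etoh_protocol(spec, multipliers = list(g_h = 0.5,
                                                      g_ampa = 1,
                                                      g_gaba = 1)),
               "multipliers")
})

test_that("reward coding: type I is graded, type II has a dead zone", {
  vals <- c(0, 0.3, 1)
  r1 <- reward_coding_protocol(vals, type = "I")
  # zero reward responds at background; response non-decreasing in value
  expect_equal(r1$peak_rate[1], r1$background_rate[1], tolerance = 1e-2)
  expect_true(all(diff(r1$peak_rate) > -1e-9))
  r2 <- reward_coding_protocol(vals, type = "II")
  expect_equal(r2$peak_rate[1], 0)
  expect_gt(r2$peak_rate[3], 3)
})
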