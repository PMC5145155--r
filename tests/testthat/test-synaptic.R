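test_that("Poisson trains have the right count statistics and determinism", {
  ts <- poisson_glu_trains(n = 35, rate = 10, duration = 10000, seed = 7)
  counts <- lengths(ts$trains)
  expect_true(abs(mean(counts) - 100) < 3 * sqrt(100) / sqrt(35))
  expect_true(all(vapply(ts$trains, function(x) !is.unsorted(x, strictly = TRUE),
                         logical(1))))
  # pooled superposition rate ~ n * rate
  pooled <- length(unlist(ts$trains)) / 10 # per second
  expect_true(abs(pooled - 350) < 3 * sqrt(3500) / 10)
  # reproducible; empty at zero duration
  ts2 <- poisson_glu_trains(n = 35, rate = 10, duration = 10000, seed = 7)
  expect_identical(ts$trains, ts2$trains)
  expect_true(all(lengths(poisson_glu_trains(5, 10, 0, seed = 1)$trains) == 0))
  expect_error(poisson_glu_trains(5, 0, 100), "rate")
})

test_that("coincidence detection fires on pairs and merges overlaps", {
  # a single isolated spike never triggers with k_min = 2
  j <- coincidence_drive(list(5), dt = 0.1, k_min = 2, duration = 20)
  expect_true(all(j == 0))
  # two spikes 0.2 ms apart give one 1-ms pulse
  j <- coincidence_drive(list(5, 5.2), dt = 0.1, k_min = 2, duration = 20)
  ev <- attr(j, "events")
  expect_equal(nrow(ev), 1)
  expect_equal(sum(j) * 0.1, 1, tolerance = 0.11)
  # k_min = 1: merged pulse intervals match the brute-force oracle
  set.seed(3)
  spikes <- sort(runif(200, 0, 500))
  j <- coincidence_drive(list(spikes), dt = 0.05, k_min = 1, duration = 500)
  oracle <- merge_pulses(spikes, 1)
  expect_equal(attr(j, "events"), oracle, ignore_attr = TRUE)
  expect_equal(sum(j) * 0.05, sum(oracle[, 2] - oracle[, 1]),
               tolerance = 0.05 * nrow(oracle) + 0.1)
})

test_that("receptor gates follow the exact exponential laws", {
  g <- receptor_gating("nmda")
  expect_equal(g$tau_act, 7)
  expect_equal(g$tau_deact, 170)
  expect_equal(receptor_gating("ampa")$tau_deact, 1.6)
  expect_equal(receptor_gating("gaba")$tau_act, 0.08)
  dt <- 0.1
  n <- 2000
  # sustained drive: s(t) = 1 - exp(-t / tau_act)
  s_on <- gate_trace(g, rep(1, n), dt, s0 = 0)
  tt <- seq(0, n) * dt
  expect_equal(s_on, 1 - exp(-tt / g$tau_act), tolerance = 1e-12)
  # pure decay from 1: s(t) = exp(-t / tau_deact)
  s_off <- gate_trace(g, rep(0, n), dt, s0 = 1)
  expect_equal(s_off, exp(-tt / g$tau_deact), tolerance = 1e-12)
  # s = 1 is a fixed point of the on-branch
  expect_identical(gating_step(1, 1, 5, g), 1)
  # any binary drive keeps the gate in [0, 1]
  set.seed(9)
  s_rand <- gate_trace(g, sample(0:1, 5000, TRUE), dt, s0 = 0.5)
  expect_true(all(s_rand >= 0 & s_rand <= 1))
})

test_that("the GABA population provides quasi-constant normalized inhibition", {
  gp <- gaba_population_drive(n_neurons = 30, duration = 5000, seed = 2,
                              record_every = 10)
  s <- gp$s_gaba[gp$time > 1000]
  expect_true(all(s >= 0 & s <= 1))
  expect_lt(sd(s) / mean(s), 0.3)             # quasi-constant
  expect_true(all(gp$rates >= 12 & gp$rates <= 22))
  # a single neuron pulses with far larger relative amplitude
  g1 <- gaba_population_drive(n_neurons = 1, duration = 5000, seed = 2,
                              record_every = 10)
  s1 <- g1$s_gaba[g1$time > 1000]
  expect_gt((max(s1) - min(s1)) / mean(s1),
            3 * (max(s) - min(s)) / mean(s))
})

test_that("OU conductances have the stated stationary statistics", {
  spec <- ou_spec(mu = 5, sigma = 0.5, c = 0, tau = 5, seed = 11)
  g <- ou_trace(spec, duration = 60000, dt = 0.5)
  n <- length(g)
  se <- 0.5 / sqrt(n / (2 * 5 / 0.5))          # effective sample size
  expect_lt(abs(mean(g) - 5), 4 * se)
  expect_lt(abs(sd(g) - 0.5), 0.05)
  # lag autocorrelation decays as exp(-lag/tau)
  x <- (g - mean(g))
  for (lag_ms in c(2.5, 5, 10)) {
    k <- lag_ms / 0.5
    ac <- mean(x[seq_len(n - k)] * x[seq_len(n - k) + k]) / var(as.numeric(g))
    expect_lt(abs(ac - exp(-lag_ms / 5)), 0.05)
  }
  # sigma = 0 gives the constant mean
  flat <- ou_trace(ou_spec(mu = 2, sigma = 0, c = 0, tau = 5), 100, 0.5)
  expect_true(all(flat == 2))
})

test_that("the shared component sets the pairwise trace correlation to c", {
  spec <- ou_spec(mu = 10, sigma = 1, c = 0.5, tau = 5, seed = 4)
  g <- ou_trace(spec, duration = 60000, dt = 0.5, n_targets = 4)
  cors <- cor(g)[upper.tri(diag(4))]
  expect_true(all(abs(cors - 0.5) < 0.08))
  # conductances are clipped at zero
  gneg <- ou_trace(ou_spec(mu = 0.1, sigma = 1, c = 0, tau = 5, seed = 1),
                   5000, 0.5)
  expect_true(all(gneg >= 0))
  expect_true(any(gneg == 0))
  # fixed seed: bit-identical regeneration
  g2 <- ou_trace(spec, duration = 60000, dt = 0.5, n_targets = 4)
  expect_identical(g, g2)
})

test_that("sine modulation shifts power to the modulation frequency", {
  spec <- ou_spec(mu = 2, sigma = 0.3, c = 0, tau = 5, seed = 6)
  plain <- ou_trace(spec, 20000, 1)
  expect_identical(sine_modulated_ou(spec, 1, 0, 20000, 1), plain)
  g <- sine_modulated_ou(spec, mod_freq = 1, mod_depth = 0.8,
                         duration = 20000, dt = 1)
  # average over integer periods returns to the mean
  expect_equal(mean(g), 2, tolerance = 0.1)
  # periodogram peak at 1 Hz
  sp <- stats::spec.pgram(ts(as.numeric(g), frequency = 1000),
                          plot = FALSE, taper = 0)
  low <- sp$freq < 5 / 1000 * 1000 & sp$freq > 0.2
  expect_equal(sp$freq[low][which.max(sp$spec[low])] , 1, tolerance = 0.3)
})

test_that("tonic s = 1 approximates the asynchronous drive at matched gating", {
  s <- asynchronous_drive(10, 4, duration = 9000, seed = 5)
  mg <- attr(s, "mean_gates")
  sim <- integrate_da(p_ref, v_full, s, duration = 9000, record_every = 0)
  r_async <- firing_stats(sim$spikes, 1500)$rate
  r_tonic <- quick_rate(syn = syn_drive(g_nmda = 10 * mg[["nmda"]],
                                        g_gaba = 4 * mg[["gaba"]]),
                        duration = 9000)
  expect_lt(abs(r_async - r_tonic) / r_tonic, 0.2)
})
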