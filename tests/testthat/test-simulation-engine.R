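test_that("spike detection counts threshold upcrossings only", {
  t <- seq(0, 3400, by = 0.1)
  # 1 Hz sinusoid crossing 0 mV once per cycle
  sp <- detect_spikes(50 * sin(2 * pi * t / 1000), t, threshold = 0)
  expect_length(sp, 3)
  expect_equal(diff(sp), c(1000, 1000), tolerance = 1e-6)
  # constant subthreshold trace: nothing
  expect_length(detect_spikes(rep(-20, length(t)), t, 0), 0)
  # synthetic trace with 10 upcrossings, brute-force count
  set.seed(2)
  v <- rep(c(-60, 10), 10) + rnorm(20, 0, 1)
  tt <- seq_along(v) * 10
  expect_length(detect_spikes(v, tt, 0, refractory = 2), 10)
  # refractory guard suppresses double counts on a jittery crossing
  vj <- c(-60, 1, -0.5, 2, -60)
  expect_length(detect_spikes(vj, c(0, 0.5, 1, 1.5, 2), 0, refractory = 2), 1)
  # a model_variant can stand in for the threshold
  expect_length(detect_spikes(50 * sin(2 * pi * t / 1000), t, v_red), 3)
})

test_that("firing statistics follow the ISI definitions with sentinels", {
  sp <- seq(0, 60000, by = 250)              # clock-like 4 Hz
  st <- firing_stats(sp)
  expect_equal(st$rate, 4)
  expect_equal(st$cv, 0)
  expect_true(is.na(firing_stats(c(100))$rate))      # 1 spike: undefined
  expect_true(is.na(firing_stats(sp[1:100])$cv))     # < 201 spikes: no CV
  # Poisson train: CV near 1 (exponential ISIs, 200-ISI window)
  set.seed(5)
  psp <- cumsum(rexp(400, rate = 1 / 100))
  expect_equal(firing_stats(psp)$cv, 1, tolerance = 0.25)
  # transient discard
  expect_equal(firing_stats(c(10, 20, 3000, 3500, 4000), 2500)$rate, 2)
})

test_that("the RK4 kernel is deterministic and convergent in dt", {
  syn <- syn_drive(g_nmda = 2, g_gaba = 0.5)
  s1 <- integrate_da(p_ref, v_full, syn, duration = 10000, dt = 0.025,
                     record_every = 0)
  s2 <- integrate_da(p_ref, v_full, syn, duration = 10000, dt = 0.025,
                     record_every = 0)
  expect_identical(s1$spikes, s2$spikes)     # bit-identical rerun
  s3 <- integrate_da(p_ref, v_full, syn, duration = 10000, dt = 0.0125,
                     record_every = 0)
  expect_lte(abs(length(s1$spikes) - length(s3$spikes)), 1)
})

test_that("the kernel agrees with lsoda on the reduced model", {
  syn <- syn_drive(g_nmda = 1, g_gaba = 0.2)
  ode_rhs <- function(t, y, parms) {
    names(y) <- c("v", "ca", "q", "h", "n")
    list(as.numeric(da_rhs(y, p_ref, v_red, syn)))
  }
  y0 <- as.numeric(da_state())
  out <- deSolve::lsoda(y0, seq(0, 2000, by = 1), ode_rhs, NULL,
                        rtol = 1e-9, atol = 1e-9)
  sim <- integrate_da(p_ref, v_red, syn, duration = 2000, dt = 0.05,
                      record_every = 20)
  expect_equal(sim$v, unname(out[, 2]), tolerance = 5e-3)
  expect_equal(sim$ca, unname(out[, 3]), tolerance = 5e-3)
})

test_that("depolarization block is depolarized quiescence, not rest", {
  mk <- function(v_const) {
    structure(list(time = seq(0, 5000, 5), v = rep(v_const, 1001),
                   spikes = numeric(0), transient = 1000,
                   variant = v_full), class = "da_sim")
  }
  expect_true(depolarization_block_detect(mk(-30)))
  expect_false(depolarization_block_detect(mk(-70)))   # quiescence
  sim <- integrate_da(p_ref, v_full, duration = 5000, record_every = 10,
                      transient = 1000)
  expect_false(depolarization_block_detect(sim))       # tonic firing
  # strong tonic NMDA alone drives the cell into block
  simb <- integrate_da(p_ref, v_full, syn_drive(g_nmda = 16.9),
                       duration = 6000, record_every = 10, transient = 2000)
  expect_true(depolarization_block_detect(simb))
})

test_that("a plane sweep matches standalone integration cell by cell", {
  map <- conductance_plane_sweep(
    p_ref, v_full,
    x = list(param = "g_nmda", values = c(0, 5)),
    y = list(param = "g_gaba", values = c(0, 1)),
    duration = 5000, transient = 1500)
  expect_equal(dim(map$rate), c(2, 2))
  r00 <- quick_rate(duration = 5000)
  expect_equal(map$rate[1, 1], r00, tolerance = 1e-8)
  # background cell fires in the 1-5 Hz band
  expect_gt(map$rate[1, 1], 1)
  expect_lt(map$rate[1, 1], 5)
  # the zero-NMDA column dies with growing GABA
  expect_true(map$rate[1, 2] < map$rate[1, 1])
})

test_that("the balance line recovers a constructed band exactly", {
  gg <- seq(0, 4, length.out = 9)
  gn <- seq(0, 13, length.out = 14)
  rate <- outer(gn, gg, function(n, g) ifelse(abs(n - (3 * g + 1)) < 0.5,
                                              2, 8))
  map <- structure(list(x_param = "g_nmda", y_param = "g_gaba",
                        x_values = gn, y_values = gg, rate = rate,
                        cv = rate * 0, block = rate > 100,
                        failed = rate > 100), class = "heat_map")
  fit <- balance_line(map, c(1.5, 2.5))
  expect_equal(fit$slope, 3, tolerance = 0.1)
  expect_equal(fit$intercept, 1, tolerance = 0.3)
  expect_error(balance_line(map, c(100, 101)), "fewer than 3")
})

test_that("F-I curves are flat for a constant-rate regime and warm-startable", {
  fi <- fi_curve(p_ref, v_full, "i_app", c(0, 0, 0), duration = 5000,
                 transient = 1500)
  expect_lt(diff(range(fi$rate)), 0.15)
  expect_identical(attr(fi, "direction"), "rising")
  fi_dn <- fi_curve(p_ref, v_full, "i_app", c(0, -1), duration = 4000,
                    transient = 1500)
  expect_identical(attr(fi_dn, "direction"), "falling")
})
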