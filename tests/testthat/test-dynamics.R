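test_that("nullclines satisfy their defining equations and cross at equilibria", {
  syn <- syn_drive(g_gaba = 0.1)
  nc <- nullclines(p_ref, syn, v_range = c(-80, -30), n = 300)
  # every Ca2+-nullcline point: d[Ca]/dt = 0 exactly
  ok <- !is.na(nc$ca_canull)
  for (i in which(ok)[c(1, 100, 250)]) {
    st <- da_state(v = nc$v[i], ca = nc$ca_canull[i])
    expect_lt(abs(da_rhs(st, p_ref, v_red, syn)[["ca"]]), 1e-12)
  }
  # every v-nullcline point: dv/dt = 0
  iv <- which(!is.na(nc$ca_vnull))
  for (i in iv[round(seq(1, length(iv), length.out = 4))]) {
    st <- da_state(v = nc$v[i], ca = nc$ca_vnull[i])
    expect_lt(abs(da_rhs(st, p_ref, v_red, syn)[["v"]]), 1e-8)
  }
  # intersections coincide with the equilibrium finder
  eq <- find_equilibria(p_ref, v_red, syn, v_range = c(-80, -30))
  for (i in seq_len(nrow(eq))) {
    j <- which.min(abs(nc$v - eq$v[i]))
    expect_lt(abs(nc$ca_canull[j] - eq$ca[i]), 0.05)
  }
  expect_error(nullclines(p_ref, variant = v_full), "reduced")
  expect_error(nullclines(p_ref, v_range = c(-30, -30)), "empty")
})

test_that("growing GABA conductance shifts the v-nullcline downward", {
  nc0 <- nullclines(p_ref, syn_drive(g_gaba = 0), v_range = c(-70, -35))
  nc1 <- nullclines(p_ref, syn_drive(g_gaba = 0.3), v_range = c(-70, -35))
  both <- !is.na(nc0$ca_vnull) & !is.na(nc1$ca_vnull)
  # at every voltage the Ca2+ needed for balance is smaller under GABA
  expect_true(all(nc1$ca_vnull[both] <= nc0$ca_vnull[both] + 1e-12))
})

test_that("the leak-only system has a unique equilibrium at E_l", {
  p <- da_params(gbar_ca = 0, gbar_kca = 0, gbar_k = 0, gbar_sna = 0,
                 gbar_na = 0, gbar_dr = 0, g_h = 0, ca_leak_frac = 0)
  eq <- find_equilibria(p, v_red, v_range = c(-100, -10))
  expect_equal(nrow(eq), 1)
  expect_equal(eq$v, p$e_l, tolerance = 1e-6)
  expect_match(eq$stability, "stable")
})

test_that("past the SNIC two new equilibria appear, one stable one saddle", {
  # g_gaba just beyond the transition of the reduced model
  eq <- find_equilibria(p_ref, v_red, syn_drive(g_gaba = 0.24),
                        v_range = c(-90, -20))
  expect_gte(nrow(eq), 3)
  expect_true(any(grepl("^stable", eq$stability)))
  expect_true(any(eq$stability == "saddle"))
  # before the transition: no stable equilibrium (tonic firing)
  eq0 <- find_equilibria(p_ref, v_red, syn_drive(g_gaba = 0.1),
                         v_range = c(-90, -20))
  expect_false(any(grepl("^stable", eq0$stability)))
})

test_that("the theta model reproduces the SNIC normal form", {
  fi <- theta_model_fi(c(0.5, 1.001, 1.01, 1.05, 1.2), dt = 5e-4,
                       duration = 4000)
  expect_equal(fi$rate, fi$rate_exact, tolerance = 0.05)
  expect_identical(fi$rate[1], 0)
  # square-root scaling of the rate with the distance to threshold
  d <- c(1e-3, 1e-2)
  f <- theta_model_fi(1 + d, dt = NULL)$rate_exact
  slope <- diff(log(f)) / diff(log(d))
  expect_equal(slope, 0.5, tolerance = 0.02)
})

test_that("the excitability verdict applies the onset-frequency threshold", {
  mk <- function(rates) {
    structure(data.frame(value = seq_along(rates), rate = rates),
              class = c("fi_curve", "data.frame"), param = "g_gaba",
              direction = "rising")
  }
  v1 <- excitability_type(mk(c(4, 2, 0.3, 0)), epsilon = 0.5)
  expect_identical(v1$type, "I")
  v2 <- excitability_type(mk(c(6, 4, 3, 0)), epsilon = 0.5)
  expect_identical(v2$type, "II")
  expect_equal(v2$jump, 3)
  expect_error(excitability_type(mk(c(1, 2, 3))), "entirely spiking")
  expect_error(excitability_type(mk(c(0, 0))), "entirely quiescent")
})

test_that("the subthreshold Na+ current sets the bifurcation class", {
  # with sNa: stability arrives through a fold of equilibria (SNIC route)
  a <- daneuron:::first_stable_event(p_ref, v_red, "g_gaba", c(0, 2))
  expect_true(a$via_fold)
  # pure Ca2+/SK mechanism: a persistent equilibrium stabilizes instead
  b <- daneuron:::first_stable_event(p_ref, v_ca_k, "g_gaba", c(0, 2))
  expect_false(b$via_fold)
})

test_that("classified transitions are reproduced on a refined grid", {
  grid1 <- seq(0.05, 0.5, length.out = 6)
  bp1 <- classify_transition(p_ref, v_red, "g_gaba", grid1,
                             duration = 4000, transient = 1000,
                             onset_duration = 12000, n_bisect = 14)
  bp2 <- classify_transition(p_ref, v_red, "g_gaba",
                             seq(0.05, 0.5, length.out = 12),
                             duration = 4000, transient = 1000,
                             onset_duration = 12000, n_bisect = 14)
  expect_identical(bp1$type, "SNIC")
  expect_identical(bp2$type, "SNIC")
  expect_lt(abs(bp1$value - bp2$value), 0.01)
  # a grid that never reaches quiescence is flagged
  nf <- classify_transition(p_ref, v_red, "g_gaba", c(0.01, 0.05),
                            duration = 3000, transient = 1000)
  expect_identical(nf$type, "not-found")
})

test_that("the equilibrium-branch fold criterion brackets its critical Ih", {
  cr <- critical_gh_fold(p_ref, v_red, gh_range = c(0, 20), tol = 0.05)
  expect_lt(cr$slope_lo, 0)                   # folded at gh = 0
  expect_gte(cr$slope_hi, 0)                  # monotone at the top
  expect_gt(cr$gh_crit, 0)
  expect_error(critical_gh_fold(p_ref, v_red, gh_range = c(0, 1)),
               "bracket")
})
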