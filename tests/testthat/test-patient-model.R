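test_that("the patient table loads all 17 parameter sets as printed", {
  pts <- ivp_patients()
  expect_equal(nrow(pts), 17L)
  expect_equal(names(pts), c("id", "BW", "GEZI", "EGP", "CI", "SI",
                             "tau1", "tau2", "p2", "VG"))
  # spot checks across the table, at printed precision
  expect_equal(pts$BW[1], 89)
  expect_equal(pts$GEZI[1], 3.87e-8)
  expect_equal(pts$SI[3], 9.64e-5)
  expect_equal(pts$CI[9], 588)
  expect_equal(pts$tau1[12], 131)
  expect_equal(pts$EGP[16], 3.45)
  expect_equal(pts$VG[17], 204)
  expect_equal(pts$p2[6], 8.14e-3)
  # invariants: strictly positive except GEZI >= 0
  expect_true(all(pts$GEZI >= 0))
  for (col in c("BW", "EGP", "CI", "SI", "tau1", "tau2", "p2", "VG")) {
    expect_true(all(pts[[col]] > 0), info = col)
  }
  # every row passes validation
  for (i in 1:17) expect_s3_class(ivp_patient(i), "ivp_patient")
  expect_error(ivp_patient(18), "unknown patient id")
})

test_that("ivp_derivatives matches hand-evaluated special cases", {
  p <- toy_patient(GEZI = 0.001, EGP = 1.0)
  # zero-insulin case: dG = -GEZI*G + EGP
  d <- ivp_derivatives(patient_state(G = 100, IEFF = 0, IP = 0, ISC = 0), p)
  expect_equal(d[["dG"]], -0.001 * 100 + 1.0)
  # u = 0, ISC = 0 is the equilibrium of the subcutaneous compartment
  expect_equal(d[["dISC"]], 0)
  # insulin-effect kinetics, hand evaluation
  p2 <- toy_patient(p2 = 0.01, SI = 5e-4)
  d2 <- ivp_derivatives(patient_state(G = 150, IEFF = 0.002, IP = 10, ISC = 0), p2)
  expect_equal(d2[["dIEFF"]], -0.01 * 0.002 + 0.01 * 5e-4 * 10)
  expect_equal(d2[["dIEFF"]], 3e-5)
  # invalid inputs
  expect_error(ivp_derivatives(patient_state(), p, u = -1), "non-negative")
  s <- patient_state(); s[["G"]] <- NaN
  expect_error(ivp_derivatives(s, p), "non-finite")
})

test_that("meal glucose appearance has the gamma-kernel peak and mass", {
  meals <- meal_schedule(t_min = 0, grams = 50)
  # peak at t = tauD with value 1000*d*exp(-1)/(VG*tauD)
  peak <- meal_ra(40, meals, VG = 200, tauD = 40)
  expect_equal(peak, 1000 * 50 * exp(-1) / (200 * 40), tolerance = 1e-12)
  tg <- seq(0, 39.9, by = 0.1)
  expect_true(all(meal_ra(tg, meals, VG = 200, tauD = 40) <= peak))
  # total appearance integrates to 1000*d/VG (trapezoid over a long horizon)
  t <- seq(0, 2000, by = 0.25)
  ra <- meal_ra(t, meals, VG = 200, tauD = 40)
  mass <- sum((ra[-1] + ra[-length(ra)]) / 2) * 0.25
  expect_equal(mass, 1000 * 50 / 200, tolerance = 1e-3)
  # before the first meal and with no meals at all: zero
  expect_equal(meal_ra(c(0, 5), meal_schedule(t_min = 10, grams = 30), VG = 200), c(0, 0))
  expect_equal(meal_ra(100, meal_schedule(), VG = 200), 0)
  expect_error(meal_ra(-1, meals, VG = 200), ">= 0")
})

test_that("step_patient holds the zero-insulin fixed point G* = EGP/GEZI", {
  p <- toy_patient(GEZI = 2e-3, EGP = 1.2)
  s <- patient_state(G = p$EGP / p$GEZI, IEFF = 0, IP = 0, ISC = 0)
  s2 <- step_patient(s, p, u = 0, duration = 60, dt = 1)
  expect_equal(s2[["G"]], p$EGP / p$GEZI, tolerance = 1e-10)
  expect_equal(s2[["t"]], 60)
})

test_that("the simulated insulin chain matches its matrix-exponential solution", {
  skip_if_not_installed("Matrix")
  p <- ivp_patient(1)  # tau1 = 49, tau2 = 47: distinct rates
  u <- insulin_Uh_to_uUmin(1.5)
  s <- patient_state(G = 120)
  for (k in 1:12) s <- step_patient(s, p, u = u, duration = 5, dt = 1)
  exact <- insulin_chain_exact(p, u, t = 60)
  sim <- c(s[["ISC"]], s[["IP"]], s[["IEFF"]])
  expect_lt(max(abs(sim - exact) / exact), 1e-6)
  # also with equal time constants (tau1 = tau2), where naive eigen
  # decompositions degenerate but expm and RK4 both remain valid
  p2 <- ivp_patient(10)
  s2 <- patient_state(G = 120)
  for (k in 1:12) s2 <- step_patient(s2, p2, u = u, duration = 5, dt = 1)
  exact2 <- insulin_chain_exact(p2, u, t = 60)
  sim2 <- c(s2[["ISC"]], s2[["IP"]], s2[["IEFF"]])
  expect_lt(max(abs(sim2 - exact2) / exact2), 1e-6)
})

test_that("halving the integration step barely changes a 24 h trajectory", {
  p <- ivp_patient(1)
  meals <- meal_schedule(t_min = c(420, 720, 1100), grams = c(60, 80, 70))
  u <- insulin_Uh_to_uUmin(1)
  s1 <- patient_state(G = 120); s2 <- patient_state(G = 120)
  for (k in 1:288) s1 <- step_patient(s1, p, u = u, meals = meals, duration = 5, dt = 1)
  for (k in 1:288) s2 <- step_patient(s2, p, u = u, meals = meals, duration = 5, dt = 0.5)
  expect_lt(abs(s1[["G"]] - s2[["G"]]), 0.1)
})

test_that("greater insulin sensitivity never raises glucose", {
  base <- list(BW = 70, GEZI = 1e-3, EGP = 1, CI = 1000, SI = 4e-4,
               tau1 = 50, tau2 = 40, p2 = 0.01, VG = 200)
  lo <- ivp_patient(x = base)
  hi <- ivp_patient(x = modifyList(base, list(SI = 8e-4)))
  meals <- meal_schedule(t_min = 300, grams = 50)
  u <- insulin_Uh_to_uUmin(0.8)
  s_lo <- patient_state(G = 120); s_hi <- patient_state(G = 120)
  for (k in 1:144) {
    s_lo <- step_patient(s_lo, lo, u = u, meals = meals, duration = 5)
    s_hi <- step_patient(s_hi, hi, u = u, meals = meals, duration = 5)
    expect_lte(s_hi[["G"]], s_lo[["G"]] + 1e-12)
  }
})

test_that("integration is deterministic and clamps are safe", {
  p <- ivp_patient(2)
  meals <- meal_schedule(t_min = 100, grams = 40)
  run <- function() {
    s <- patient_state(G = 110)
    for (k in 1:50) s <- step_patient(s, p, u = 2e4, meals = meals, duration = 5)
    s
  }
  expect_identical(run(), run())
  # heavy overdose drives glucose to the floor, never below
  s <- patient_state(G = 60)
  for (k in 1:200) s <- step_patient(s, p, u = insulin_Uh_to_uUmin(25), duration = 5)
  expect_gte(s[["G"]], 0)
})

test_that("basal steady state is an equilibrium of the insulin chain", {
  p <- ivp_patient(4)
  ss <- ivp_basal_steady_state(p, u_Uh = 1.2)
  s <- patient_state(G = 120, IEFF = ss[["IEFF"]], IP = ss[["IP"]], ISC = ss[["ISC"]])
  s2 <- step_patient(s, p, u = insulin_Uh_to_uUmin(1.2), duration = 30)
  expect_equal(s2[["ISC"]], ss[["ISC"]], tolerance = 1e-9)
  expect_equal(s2[["IP"]], ss[["IP"]], tolerance = 1e-9)
  expect_equal(s2[["IEFF"]], ss[["IEFF"]], tolerance = 1e-9)
})
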