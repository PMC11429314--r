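# Closed-form solution of the linear insulin cascade (ISC, IP, IEFF) under a
# constant infusion u (uU/min), via the matrix exponential: an integrator-
# independent reference for the simulated chain.
insulin_chain_exact <- function(p, u, x0 = c(0, 0, 0), t) {
  A <- rbind(c(-1 / p$tau1, 0, 0),
             c(1 / p$tau2, -1 / p$tau2, 0),
             c(0, p$p2 * p$SI, -p$p2))
  b <- c(u / (p$tau1 * p$CI), 0, 0)
  eAt <- as.matrix(Matrix::expm(A * t))
  xin <- solve(A, (eAt - diag(3)) %*% b)
  as.numeric(eAt %*% x0 + xin)
  # returns (ISC, IP, IEFF)
}

# a fully synthetic parameter set for unit tests that need round numbers
toy_patient <- function(GEZI = 1e-3, EGP = 1, CI = 1000, SI = 5e-4,
                        tau1 = 50, tau2 = 40, p2 = 0.01, VG = 200, BW = 70,
                        tauD = 40) {
  ivp_patient(x = list(BW = BW, GEZI = GEZI, EGP = EGP, CI = CI, SI = SI,
                       tau1 = tau1, tau2 = tau2, p2 = p2, VG = VG, id = NA),
              tauD = tauD)
}

# simulate a G trajectory under a constant action, returning the log
run_constant_action <- function(env, a, seed = 1, schedule = meal_schedule()) {
  run_episode(env, constant_policy(a), seed = seed, schedule = schedule)
}
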