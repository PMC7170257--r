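test_that("derived fields match direct substitution", {
  p <- default_parameters()
  # no TNF-alpha, no drug: PD-L1 has no upregulation factor
  st <- make_uniform_state(list(D = 0, T = 1e-3, C = 0, I12 = 0, Ta = 0,
                                P = 0, A = 0, B = 0))
  d <- derived_fields(st, p)
  expect_equal(d$L, rep(3.25e-10, 21))
  expect_equal(d$G, rep(0, 21))
  # Ta at half-saturation and saturating anti-PD-1:
  # TM = rho_M T (1 + 1/2 alpha_T (1 + alpha_MA)) = rho_M T * 2.5
  st2 <- make_uniform_state(list(D = 0, T = 1e-3, C = 0, I12 = 0,
                                 Ta = p$K_Ta, P = 0, A = 1e6, B = 0))
  d2 <- derived_fields(st2, p)
  expect_equal(d2$TM, rep(1.5e-10 * 2.5, 21), tolerance = 1e-9)
  # complex product at the inhibition constant halves activation
  Lval <- p$rho_L * (1e-3 + 0)           # T only, no upregulation
  st3 <- make_uniform_state(list(D = 0, T = 1e-3, C = 0, I12 = 0, Ta = 0,
                                 P = p$K_TQ1 / Lval, A = 0, B = 0))
  d3 <- derived_fields(st3, p)
  expect_equal(d3$fQ1, rep(0.5, 21))
  expect_true(all(d3$fQ2 == 1))
})

test_that("inhibition factors are monotone and vanish with the complexes", {
  p <- default_parameters()
  st <- make_uniform_state(list(D = 1e-4, T = 1e-3, C = 0.4, I12 = 1e-10,
                                Ta = 1e-11, P = 2.49e-10, A = 0, B = 0))
  d <- derived_fields(st, p)
  expect_true(all(d$fQ1 > 0 & d$fQ1 <= 1))
  # increasing P strictly decreases fQ1
  st2 <- st; st2$fields$P <- st$fields$P * 2
  expect_true(all(derived_fields(st2, p)$fQ1 < d$fQ1))
  # K_TQ -> Inf recovers the no-checkpoint limit
  p2 <- p; p2$K_TQ1 <- 1e30; p2$K_TQ2 <- 1e30
  d2 <- derived_fields(st, p2)
  expect_equal(d2$fQ1, rep(1, 21))
  expect_equal(d2$fQ2, rep(1, 21))
})

test_that("anti-TNF-alpha lowers TIM-3 and PD-L1 through Ta suppression", {
  p <- default_parameters()
  base <- list(D = 1e-4, T = 5e-4, C = 0.4, I12 = 1e-10, Ta = 2e-11,
               P = 1e-10, A = 1e-11, B = 0)
  lo <- derived_fields(make_uniform_state(base), p)
  suppressed <- base; suppressed$Ta <- 1e-12   # what more B does to Ta
  hi <- derived_fields(make_uniform_state(suppressed), p)
  expect_true(all(hi$TM < lo$TM))
  expect_true(all(hi$L < lo$L))
})

test_that("reaction terms honor the closure balances and special cases", {
  p <- closure_params()
  st <- closure_state(p)
  d <- derived_fields(st, p)
  Fx <- reaction_terms(st, d, c(0, 0), p)
  # DC and IL-12 balances vanish identically at the targets
  expect_equal(max(abs(Fx$F_D)), 0, tolerance = 1e-20)
  expect_equal(max(abs(Fx$F_I12)), 0, tolerance = 1e-22)
  # TNF-alpha balance vanishes with the closure production rate
  expect_lt(max(abs(Fx$F_Ta)) / (p$d_Ta * 3e-11), 1e-10)
  # cancer balance vanishes (eta = 328, lambda_C = 0.996)
  expect_lt(max(abs(Fx$F_C)) / (p$d_C * 0.4), 1e-10)
  # T balance vanishes when the checkpoint factors equal the assumed
  # steady inhibition 1/1.8 (imposed here by rescaling K_TQ1; with the
  # published K_TQ values the emergent inhibition is ~0.09, not 1/1.8)
  p18 <- p
  p18$K_TQ1 <- d$PL[1] / 0.8
  p18$K_TQ2 <- 1e30
  d18 <- derived_fields(st, p18)
  expect_equal(d18$fQ1 * d18$fQ2, rep(1 / 1.8, 21))
  F18 <- reaction_terms(st, d18, c(0, 0), p18)
  expect_lt(max(abs(F18$F_T)) / (p$d_T * 1e-3), 1e-10)
})

test_that("reaction terms: no cancer means pure DC decay; P tracks T", {
  p <- default_parameters()
  st <- make_uniform_state(list(D = 3e-4, T = 2e-4, C = 0, I12 = 5e-10,
                                Ta = 1e-11, P = p$rho_P * 2e-4, A = 0,
                                B = 0))
  d <- derived_fields(st, p)
  Fx <- reaction_terms(st, d, c(0, 0), p)
  expect_equal(Fx$F_D, -p$d_D * st$fields$D)
  # P = rho_P T with A = 0 gives F_P = rho_P F_T exactly
  expect_equal(Fx$F_P, p$rho_P * Fx$F_T)
  expect_error(reaction_terms({
    bad <- st; bad$fields$D[2] <- -1; bad
  }, d, c(0, 0), p), "negative")
})

test_that("velocity field solves the radial closure", {
  p <- default_parameters()
  r <- seq(0, 0.5, length.out = 41)
  expect_equal(velocity_field(rep(0, 41), r, p), rep(0, 41))
  # constant source: u = s r / (3 rho_tot), exact for the quadrature
  s <- 0.02
  u <- velocity_field(rep(s, 41), r, p)
  expect_equal(u, s * r / (3 * p$rho_tot), tolerance = 1e-12)
  # nonuniform mesh too
  set.seed(101)
  rn <- c(0, sort(stats::runif(30, 0, 0.5)), 0.5)
  expect_equal(velocity_field(rep(s, 32), rn, p),
               s * rn / (3 * p$rho_tot), tolerance = 1e-12)
  expect_error(velocity_field(1, 0.1, p), "2 nodes")
})

test_that("boundary conditions implement Robin influx and conservation", {
  p <- default_parameters()
  # equilibrium boundary values are fixed points of the Robin conditions
  st <- make_uniform_state(list(D = 1e-4, T = p$T_hat, C = 0.4,
                                I12 = p$K_I12, Ta = 1e-11,
                                P = p$rho_P * p$T_hat, A = 0, B = 0))
  out <- apply_boundary_conditions(st, p)
  n <- length(out$r)
  expect_equal(out$fields$T[n], p$T_hat)
  expect_equal(out$fields$P[n], p$rho_P * p$T_hat)
  expect_equal(out$fields$C[n],
               p$rho_tot - out$fields$D[n] - out$fields$T[n])
  # influx gate: sigma_T(0) = 0, sigma_T(K_I12) = sigma0/2
  expect_equal(sigma_T(0, p), 0)
  expect_equal(sigma_T(p$K_I12, p), p$sigma0 / 2)
  # no IL-12: boundary T collapses to the Neumann value (influx off)
  st$fields$I12 <- rep(0, n)
  out0 <- apply_boundary_conditions(st, p)
  expect_equal(out0$fields$T[n], out0$fields$T[n - 1])
})

test_that("initial state satisfies the stated constraints", {
  p <- default_parameters()
  st <- initial_state(0.5, p, 50)
  sum3 <- st$fields$D + st$fields$T + st$fields$C
  expect_equal(sum3, rep(0.4014, 51))
  expect_equal(st$fields$P, rep(2.49e-11, 51))
  expect_equal(4 / 3 * pi * 0.5^3, 0.5236, tolerance = 1e-4)
  expect_error(initial_state(-1, p), "positive")
})

test_that("volume_average is exact for linear data and constants", {
  r <- seq(0, 2, length.out = 81)
  expect_equal(volume_average(rep(3.5, 81), r), 3.5)
  # x = r: (3/R^3) int r^3 = 3R/4
  expect_equal(volume_average(r, r), 3 * 2 / 4, tolerance = 1e-12)
})
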