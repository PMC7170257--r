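test_that("stable_timestep applies the h^2/(2D) bound", {
  p <- default_parameters()
  p$delta_Ta <- 8.64e-2              # make D_max the reference 8.64e-2
  r <- seq(0, 1, by = 0.01)
  expect_equal(stable_timestep(r, p, safety = 1), 5.787e-4,
               tolerance = 1e-4)
  # halving h quarters tau; safety scales linearly
  r2 <- seq(0, 1, by = 0.005)
  expect_equal(stable_timestep(r2, p, safety = 1),
               stable_timestep(r, p, safety = 1) / 4)
  expect_equal(stable_timestep(r, p, safety = 0.5),
               stable_timestep(r, p, safety = 1) / 2)
  expect_error(stable_timestep(c(0, 0, 1), p), "degenerate")
})

test_that("nonuniform stencils reduce to central differences and are
           polynomial-exact", {
  # uniform mesh: exact central-difference reduction
  h <- 0.037
  x <- c(1.2, 0.7, 1.9)
  d <- nonuniform_derivatives(x[1], x[2], x[3], h, -h)
  expect_equal(d[1], (x[3] - x[1]) / (2 * h))
  expect_equal(d[2], (x[3] - 2 * x[2] + x[1]) / h^2)
  # arbitrary spacings: exact for quadratics (hence constants/linears)
  set.seed(7)
  for (k in 1:20) {
    h1 <- stats::runif(1, 0.01, 0.1)
    hm1 <- -stats::runif(1, 0.01, 0.1)
    r0 <- stats::runif(1, 0.2, 1)
    f <- function(r) 2.5 - 1.3 * r + 0.8 * r^2
    fp <- function(r) -1.3 + 1.6 * r
    d <- nonuniform_derivatives(f(r0 + hm1), f(r0), f(r0 + h1), h1, hm1)
    expect_equal(d[1], fp(r0), tolerance = 1e-10)
    expect_equal(d[2], 1.6, tolerance = 1e-8)
  }
  expect_error(nonuniform_derivatives(1, 2, 3, -0.1, -0.1), "h1 > 0")
})

test_that("the discrete radial Laplacian of r^2 equals 6 exactly", {
  set.seed(11)
  r <- c(0, sort(stats::runif(40, 0, 1)), 1)
  lap <- tumorfb:::.radial_laplacian(r^2, r)
  n <- length(r)
  expect_equal(lap[2:(n - 1)], rep(6, n - 2), tolerance = 1e-9)
  expect_equal(lap[1], 6, tolerance = 1e-9)  # symmetry node
})

test_that("euler_step reduces to scalar explicit Euler without transport", {
  p <- default_parameters()
  # uniform fields: Laplacians vanish; pick A with P = 0 so F_A = -d_A A
  st <- make_uniform_state(list(D = 1e-4, T = 1e-4, C = 0.4012,
                                I12 = 1e-10, Ta = 1e-11, P = 0,
                                A = 2e-10, B = 3e-7))
  tau <- 1e-4
  out <- euler_step(st, p, tau)
  n <- length(st$r)
  expect_equal(out$state$fields$A[1:(n - 1)],
               rep(2e-10 * (1 - p$d_A * tau), n - 1), tolerance = 1e-9)
  # B decays at d_B + mu_TaB * Ta
  kB <- p$d_B + p$mu_TaB * 1e-11
  expect_equal(out$state$fields$B[1:(n - 1)],
               rep(3e-7 * (1 - kB * tau), n - 1), tolerance = 1e-9)
})

test_that("one step preserves the total cell density to roundoff", {
  p <- default_parameters()
  st <- initial_state(0.5, p, 100)
  tau <- stable_timestep(st$r, p)
  out <- euler_step(st, p, tau)
  sum3 <- out$state$fields$D + out$state$fields$T + out$state$fields$C
  expect_lt(max(abs(sum3 - p$rho_tot)), 1e-6)   # spec tolerance
  expect_lt(max(abs(sum3 - p$rho_tot)), 1e-12)  # actual: exact by design
  # and the boundary moved with u(R) > 0 for the growing tumor
  expect_gt(out$state$r[101], st$r[101])
})

test_that("compiled loop equals the composed R reference step", {
  p <- default_parameters()
  sch <- build_mouse_schedule(c(0.001, 2), gamma_A = 1e-10,
                              gamma_B = 1e-6, t_end = 30)
  st <- initial_state(0.5, p, 24)
  tau <- 5e-4
  nsteps <- 30
  stR <- st
  for (k in seq_len(nsteps)) {
    dr <- c(dose_rate(stR$t, sch, "anti-PD-1"),
            dose_rate(stR$t, sch, "anti-TNF-alpha"))
    stR <- euler_step(stR, p, tau, dr)$state
  }
  evA <- schedule_events(sch, "anti-PD-1")
  evB <- schedule_events(sch, "anti-TNF-alpha")
  res <- tumorfb:::cpp_simulate(
    st$r, st$fields$D, st$fields$T, st$fields$C, st$fields$I12,
    st$fields$Ta, st$fields$P, st$fields$A, st$fields$B, unclass(p),
    active_lambda_C(p), evA$day, evA$gamma, evB$day, evB$gamma, sch$beta,
    out_times = c(0, 1e6), N = 24L, safety = 0.9, regrid_ratio = 1.5,
    regrid_growth = 0.1, cons_tol = 0.01, r_min = 0.001, eps_T = 1e-12,
    fixed_tau = tau, max_steps = nsteps, do_regrid = FALSE)
  expect_equal(res$r_final, stR$r, tolerance = 1e-12)
  for (i in seq_along(stR$fields)) {
    expect_equal(res$fields_final[[i]], stR$fields[[i]],
                 tolerance = 1e-10)
  }
})

test_that("regrid is exact for linear fields and conserves mass", {
  p <- default_parameters()
  set.seed(5)
  r <- c(0, sort(stats::runif(38, 0, 0.5)), 0.5)
  lin <- function(r) 0.1 + 0.3 * r
  fields <- list(D = lin(r), T = lin(r), C = lin(r), I12 = lin(r),
                 Ta = lin(r), P = lin(r), A = lin(r), B = lin(r))
  st <- tfb_state(r, fields)
  rg <- regrid(st, 40)
  expect_equal(rg$fields$D, lin(rg$r), tolerance = 1e-12)
  # already uniform: unchanged
  st2 <- initial_state(0.5, p, 30)
  rg2 <- regrid(st2)
  expect_equal(rg2$fields, st2$fields, tolerance = 1e-14)
  # curved field from a real run: volume integral moves < 0.1%
  ctrl <- run_control(p, 0.5, 5, tfb_settings(N = 40))
  stc <- ctrl$final_state
  rgc <- regrid(stc)
  for (nm in c("C", "T", "I12")) {
    m0 <- volume_average(stc$fields[[nm]], stc$r)
    m1 <- volume_average(rgc$fields[[nm]], rgc$r)
    expect_lt(abs(m1 - m0) / m0, 1e-3)
  }
})

test_that("simulate is deterministic and conserves over 30 days", {
  p <- default_parameters()
  s <- tfb_settings(N = 50)
  a <- run_control(p, 0.5, 10, s)
  b <- run_control(p, 0.5, 10, s)
  expect_identical(a$avg, b$avg)
  expect_identical(a$R, b$R)
  expect_lt(max(a$consdev), s$cons_tol * p$rho_tot)
  # control tumor grows; log V approximately linear over the last days
  expect_true(all(diff(a$V) > 0))
  last <- a$times >= 5
  fit <- stats::lm(log(a$V[last]) ~ a$times[last])
  expect_gt(summary(fit)$r.squared, 0.98)
})

test_that("degenerate zero-growth model keeps the radius fixed", {
  p <- default_parameters()
  eps <- 1e-30   # validation requires strict positivity
  p$lambda_C_mouse <- eps; p$lambda_C_human <- eps / 2
  p$d_C <- eps; p$eta <- eps
  p$lambda_DC_D0 <- eps; p$lambda_TI12_T0 <- eps; p$d_D <- eps
  p$d_T <- eps; p$A_Ta <- eps; p$lambda_TaT <- eps; p$lambda_I12D <- eps
  r <- simulate(p, NULL, 0.5, tfb_settings(N = 24, t_end = 2))
  expect_equal(r$R, rep(0.5, length(r$R)), tolerance = 1e-9)
})

test_that("PD-1 stays on the rho_P * T manifold without anti-PD-1", {
  p <- default_parameters()
  res <- run_control(p, 0.5, 10, tfb_settings(N = 50))
  st <- res$final_state
  expect_equal(st$fields$P, p$rho_P * st$fields$T, tolerance = 1e-8)
})
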