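#' Tumor state on a radial mesh
#'
#' A state bundles the eight evolved fields -- dendritic cells `D`,
#' cytotoxic T cells `T`, cancer cells `C` (g/cm^3 cell densities),
#' cytokines IL-12 `I12` and TNF-alpha `Ta`, checkpoint receptor PD-1 `P`,
#' and the two drugs anti-PD-1 `A` and anti-TNF-alpha `B` -- as per-node
#' vectors on an ordered radial mesh `r[1] = 0 <= ... <= r[N+1] = R(t)`.
#'
#' @param r strictly increasing node positions (cm), first node at 0.
#' @param fields named list of the eight per-node field vectors.
#' @param t time (day).
#' @return An object of class `tfb_state`.
#' @export
tfb_state <- function(r, fields, t = 0) {
  stopifnot(is.numeric(r), length(r) >= 2, r[1] == 0, all(diff(r) > 0))
  stopifnot(setequal(names(fields), .tfb_fields))
  fields <- fields[.tfb_fields]
  lens <- vapply(fields, length, 1L)
  stopifnot(all(lens == length(r)))
  structure(list(r = r, t = t, fields = fields), class = "tfb_state")
}

#' @export
print.tfb_state <- function(x, ...) {
  cat("<tfb_state> t = ", format(x$t), " day, R = ",
      format(x$r[length(x$r)]), " cm, ", length(x$r), " nodes\n", sep = "")
  invisible(x)
}

#' Initial interior densities
#'
#' The uniform field values at t = 0: the cell densities sum to the
#' conservation constant 0.4014 g/cm^3 and PD-1 starts on its no-drug exact
#' manifold `P = rho_P * T`.
#'
#' @param params a `tfb_params` object (only `rho_P` is used).
#' @return Named list of the eight initial values (g/cm^3).
#' @export
initial_densities <- function(params = default_parameters()) {
  list(D = 2e-4, T = 1e-4, C = 0.4011, I12 = 1e-10, Ta = 1e-11,
       P = params$rho_P * 1e-4, A = 0, B = 0)
}

#' Initial tumor state
#'
#' Uniform fields on a uniform mesh of `N + 1` nodes on `[0, R0]`.
#'
#' @param R0 initial radius (cm), typically 0.5 (mouse) or 0.5/1 (human).
#' @param params a `tfb_params` object.
#' @param N number of mesh intervals.
#' @return A `tfb_state`.
#' @export
initial_state <- function(R0, params = default_parameters(), N = 100) {
  if (!is.numeric(R0) || length(R0) != 1 || R0 <= 0)
    stop("R0 must be a positive radius in cm")
  r <- seq(0, R0, length.out = N + 1)
  ic <- initial_densities(params)
  fields <- lapply(ic, rep, times = N + 1)
  tfb_state(r, fields, t = 0)
}

#' Algebraic checkpoint/ligand fields
#'
#' Evaluates the quasi-steady surface-protein relations per node:
#' PD-L1 `L = rho_L (T + eps_C C)(1 + alpha_L Ta/(K_Ta + Ta))` (upregulated
#' by TNF-alpha), TIM-3
#' `TM = rho_M T [1 + alpha_T Ta/(K_Ta + Ta) (1 + alpha_MA A/(K_A + A))]`
#' (upregulated by TNF-alpha, further enhanced by anti-PD-1 -- the modelled
#' resistance mechanism), Gal-9 `G = rho_G C`, and the two T-cell
#' inhibition factors `f_Q1 = 1/(1 + P L / K_TQ1)`,
#' `f_Q2 = 1/(1 + TM G / K_TQ2)` from the fast-equilibrium checkpoint
#' complexes.
#'
#' @param state a `tfb_state`.
#' @param params a `tfb_params`.
#' @return List with per-node vectors `L`, `TM`, `G`, `PL`, `TMG`, `fQ1`,
#'   `fQ2`.
#' @export
derived_fields <- function(state, params) {
  f <- state$fields
  satTa <- f$Ta / (params$K_Ta + f$Ta)
  L  <- params$rho_L * (f$T + params$eps_C * f$C) *
        (1 + params$alpha_L * satTa)
  TM <- params$rho_M * f$T *
        (1 + params$alpha_T * satTa *
             (1 + params$alpha_MA * f$A / (params$K_A + f$A)))
  G  <- params$rho_G * f$C
  PL  <- f$P * L
  TMG <- TM * G
  list(L = L, TM = TM, G = G, PL = PL, TMG = TMG,
       fQ1 = 1 / (1 + PL / params$K_TQ1),
       fQ2 = 1 / (1 + TMG / params$K_TQ2))
}

#' Reaction right-hand sides
#'
#' Transport-free rates of change (g/cm^3/day) per node.  T-cell
#' activation is driven by IL-12 and throttled by both checkpoint factors;
#' cancer cells grow logistically and are killed by T cells; PD-1 follows
#' the T-cell dynamics scaled by the current P/T ratio and is depleted by
#' anti-PD-1; drugs enter as spatially uniform pulse-decay sources and are
#' consumed by their targets.
#'
#' @param state a `tfb_state`.
#' @param derived output of [derived_fields()] for the same state.
#' @param dose_rates numeric `c(gA, gB)`: current dose rates (g/cm^3/day).
#' @param params a `tfb_params`.
#' @param eps_T floor on T in the P/T ratio (numerical guard only).
#' @return Named list of per-node reaction vectors `F_D`, ..., `F_B`.
#' @export
reaction_terms <- function(state, derived, dose_rates = c(0, 0), params,
                           eps_T = 1e-12) {
  f <- state$fields
  if (any(vapply(f, function(x) any(x < 0), TRUE)))
    stop("reaction_terms: negative field values")
  act_T <- params$lambda_TI12_T0 * f$I12 / (params$K_I12 + f$I12) *
           derived$fQ1 * derived$fQ2
  F_D <- params$lambda_DC_D0 * f$C / (params$K_C + f$C) - params$d_D * f$D
  F_T <- act_T - params$d_T * f$T
  F_C <- active_lambda_C(params) * f$C * (1 - f$C / params$C_M) -
         params$eta * f$T * f$C - params$d_C * f$C
  F_I12 <- params$lambda_I12D * f$D - params$d_I12 * f$I12
  F_Ta  <- params$A_Ta + params$lambda_TaT * f$T -
           params$mu_TaB * f$Ta * f$B - params$d_Ta * f$Ta
  F_P <- f$P / pmax(f$T, eps_T) * F_T - params$mu_PA * f$P * f$A
  F_A <- dose_rates[1] - params$mu_PA * f$P * f$A - params$d_A * f$A
  F_B <- dose_rates[2] - params$mu_TaB * f$Ta * f$B - params$d_B * f$B
  list(F_D = F_D, F_T = F_T, F_C = F_C, F_I12 = F_I12, F_Ta = F_Ta,
       F_P = F_P, F_A = F_A, F_B = F_B)
}

#' Cell velocity from the incompressibility closure
#'
#' Constant total cell density turns the summed cell equations into the
#' velocity equation `(1/r^2) d(r^2 u)/dr = S` with
#' `S = (F_D + F_T + F_C)/rho_tot` (diffusion drops out: the cells share
#' one diffusivity and D + T + C is constant).  Solved by cumulative
#' radial quadrature, exact for piecewise-linear `S`, with `u(0) = 0`.
#'
#' @param reaction_sum per-node `F_D + F_T + F_C` (g/cm^3/day).
#' @param r mesh node positions (cm).
#' @param params a `tfb_params` (uses `rho_tot`).
#' @return Per-node velocity `u` (cm/day).
#' @export
velocity_field <- function(reaction_sum, r, params) {
  n <- length(r)
  if (n < 2) stop("mesh must have at least 2 nodes")
  S <- reaction_sum / params$rho_tot
  # cumulative integral of S(s) s^2 with S piecewise linear
  I <- numeric(n)
  for (i in 2:n) {
    a <- r[i - 1]; b <- r[i]
    Sa <- S[i - 1]; Sb <- S[i]
    h <- b - a
    seg <- Sa * (b^3 - a^3) / 3 +
           (Sb - Sa) / h * ((b^4 - a^4) / 4 - a * (b^3 - a^3) / 3)
    I[i] <- I[i - 1] + seg
  }
  u <- numeric(n)
  u[-1] <- I[-1] / r[-1]^2
  u
}

#' Apply boundary conditions in place
#'
#' At the free boundary `r = R(t)`: Robin influx conditions for T cells and
#' PD-1, `dT/dr + sigma_T(I12)(T - T_hat) = 0` and
#' `dP/dr + sigma_T(I12)(P - rho_P T_hat) = 0`, with influx gate
#' `sigma_T = sigma0 I12/(K_I12 + I12)` (new T cells are only recruited
#' when IL-12 is present); homogeneous Neumann for `D`, `I12`, `Ta`, `A`,
#' `B`; and `C` closed algebraically by the conservation constraint
#' `C = rho_tot - D - T`.  The Robin conditions are discretized with the
#' first-order one-sided difference of the interior scheme.  The symmetry
#' condition at `r = 0` is built into the interior stencils.
#'
#' @param state a `tfb_state` whose boundary-node values are to be set.
#' @param params a `tfb_params`.
#' @return The state with boundary node values replaced.
#' @export
apply_boundary_conditions <- function(state, params) {
  f <- state$fields
  n <- length(state$r)
  h <- state$r[n] - state$r[n - 1]
  for (nm in c("D", "I12", "Ta", "A", "B"))
    f[[nm]][n] <- f[[nm]][n - 1]
  sigT <- params$sigma0 * f$I12[n] / (params$K_I12 + f$I12[n])
  f$T[n] <- (f$T[n - 1] + h * sigT * params$T_hat) / (1 + h * sigT)
  f$P[n] <- (f$P[n - 1] + h * sigT * params$rho_P * params$T_hat) /
            (1 + h * sigT)
  f$C[n] <- params$rho_tot - f$D[n] - f$T[n]
  state$fields <- f
  state
}

#' Boundary influx gate
#'
#' @param I12 IL-12 concentration at the boundary (g/cm^3).
#' @param params a `tfb_params`.
#' @return `sigma0 * I12/(K_I12 + I12)` in 1/cm.
#' @export
sigma_T <- function(I12, params) {
  params$sigma0 * I12 / (params$K_I12 + I12)
}

#' Volume average of a radial field
#'
#' `(3/R^3) * integral_0^R x(r) r^2 dr`, exact for piecewise-linear `x`.
#'
#' @param x per-node values.
#' @param r node positions (cm).
#' @return The volume-averaged value.
#' @export
volume_average <- function(x, r) {
  n <- length(r)
  I <- 0
  for (i in 2:n) {
    a <- r[i - 1]; b <- r[i]
    h <- b - a
    I <- I + x[i - 1] * (b^3 - a^3) / 3 +
      (x[i] - x[i - 1]) / h * ((b^4 - a^4) / 4 - a * (b^3 - a^3) / 3)
  }
  3 * I / r[n]^3
}

#' Export a state as tidy CSV-ready data
#'
#' @param state a `tfb_state`.
#' @return A data frame with columns `time`, `r`, `field`, `value`.
#' @export
state_to_df <- function(state) {
  n <- length(state$r)
  do.call(rbind, lapply(.tfb_fields, function(nm) {
    data.frame(time = state$t, r = state$r, field = nm,
               value = state$fields[[nm]])
  }))
}
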