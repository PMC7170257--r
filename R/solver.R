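#' Solver settings
#'
#' @param N number of mesh intervals (N + 1 nodes), at least 8.
#' @param safety CFL safety factor in (0, 1].
#' @param regrid_ratio max/min node-spacing ratio that triggers a regrid.
#' @param regrid_growth relative boundary displacement since the last
#'   regrid that triggers a regrid.
#' @param cons_tol conservation tolerance as a fraction of `rho_tot`;
#'   exceeding it aborts the run.
#' @param t_end end time (day).
#' @param out_dt output cadence (day).
#' @param r_min radius floor (cm): a tumor shrinking below it is treated
#'   as eliminated and the state frozen for the remaining output times.
#' @param eps_T floor on T in the P/T ratio (g/cm^3).
#' @return A list of class `tfb_settings`.
#' @export
tfb_settings <- function(N = 100, safety = 0.9, regrid_ratio = 1.5,
                         regrid_growth = 0.1, cons_tol = 0.01,
                         t_end = 30, out_dt = 0.5, r_min = 0.01,
                         eps_T = 1e-12) {
  stopifnot(N >= 8, safety > 0, safety <= 1, regrid_ratio > 1,
            regrid_growth > 0, cons_tol > 0, t_end > 0, out_dt > 0,
            r_min > 0, eps_T > 0)
  structure(list(N = as.integer(N), safety = safety,
                 regrid_ratio = regrid_ratio, regrid_growth = regrid_growth,
                 cons_tol = cons_tol, t_end = t_end, out_dt = out_dt,
                 r_min = r_min, eps_T = eps_T), class = "tfb_settings")
}

#' Diffusion-stable time step
#'
#' Explicit-Euler diffusion bound on a (possibly nonuniform) mesh:
#' `tau = safety * min(h)^2 / (2 D_max)` with `D_max` the largest
#' diffusivity among all fields (a cytokine/drug value, ~8.5e-2 cm^2/day).
#'
#' @param r mesh node positions (cm).
#' @param params a `tfb_params`.
#' @param safety CFL safety factor.
#' @return Time step in days.
#' @export
stable_timestep <- function(r, params, safety = 0.9) {
  h <- diff(r)
  if (any(h <= 0)) stop("degenerate mesh: nonpositive spacing")
  Dmax <- max(params$delta_D, params$delta_T, params$delta_C,
              params$delta_I12, params$delta_Ta, params$delta_A,
              params$delta_B)
  safety * min(h)^2 / (2 * Dmax)
}

#' Three-point derivatives on a nonuniform mesh
#'
#' First and second derivative at a node from its two neighbours, with
#' signed spacings `h1 = r[i+1] - r[i] > 0` and `hm1 = r[i-1] - r[i] < 0`.
#' On a uniform mesh these reduce exactly to the central differences
#' `(X[i+1] - X[i-1])/(2h)` and `(X[i+1] - 2X[i] + X[i-1])/h^2`, and they
#' are exact for quadratics on any mesh.
#'
#' @param x_m,x_c,x_p values at nodes i-1, i, i+1.
#' @param h1 spacing to the next node (positive).
#' @param hm1 spacing to the previous node (negative).
#' @return `c(first, second)` derivative estimates.
#' @export
nonuniform_derivatives <- function(x_m, x_c, x_p, h1, hm1) {
  if (any(h1 <= 0) || any(hm1 >= 0))
    stop("spacings must satisfy h1 > 0 > hm1")
  # sign of the x_c term: +(h1^2 - hm1^2), the unique choice exact for
  # constants and linears on nonuniform meshes (see vignette)
  Xr <- (hm1^2 * x_p - h1^2 * x_m + (h1^2 - hm1^2) * x_c) /
        (h1 * (hm1^2 - h1 * hm1))
  Xrr <- 2 * (hm1 * x_p - h1 * x_m + (h1 - hm1) * x_c) /
         (h1 * (h1 * hm1 - hm1^2))
  c(Xr, Xrr)
}

# Radial Laplacian d2/dr2 + (2/r) d/dr at all interior nodes; at r = 0 the
# symmetry limit 3 d2/dr2 with a mirrored ghost gives 6 (X[2]-X[1])/h1^2.
# The boundary node entry is 0 (set by boundary conditions, not the PDE).
.radial_laplacian <- function(x, r) {
  n <- length(r)
  lap <- numeric(n)
  lap[1] <- 6 * (x[2] - x[1]) / (r[2] - r[1])^2
  for (i in 2:(n - 1)) {
    d <- nonuniform_derivatives(x[i - 1], x[i], x[i + 1],
                                r[i + 1] - r[i], r[i - 1] - r[i])
    lap[i] <- d[2] + 2 / r[i] * d[1]
  }
  lap
}

#' One explicit-Euler step of the moving-mesh scheme
#'
#' Advances all eight fields by `tau` in Lagrangian (total-derivative)
#' form.  Cell fields (D, T, C and PD-1, which rides on T cells) gain
#' `tau * (delta * Lap X + F_X - X * div u)`, advection being absorbed by
#' the node motion `r <- r + u tau`; the free boundary moves with
#' `u(R)`.  Cytokines and drugs, whose advection is neglected, are updated
#' on the fixed mesh and re-interpolated to the moved nodes.  Boundary
#' conditions are re-applied on the new mesh and negative undershoots are
#' clipped to zero (counted).
#'
#' This pure-R implementation is the reference for the compiled core used
#' by [simulate()]; the two are cross-checked in the test suite.
#'
#' @param state a `tfb_state`.
#' @param params a `tfb_params`.
#' @param tau time step (day), must satisfy [stable_timestep()].
#' @param dose_rates numeric `c(gA, gB)` at the current time.
#' @param eps_T numerical floor for the P/T ratio.
#' @return List with the advanced `state`, the velocity `u`, the velocity
#'   divergence `S` and the number of clipped values `clips`.
#' @export
euler_step <- function(state, params, tau, dose_rates = c(0, 0),
                       eps_T = 1e-12) {
  r <- state$r
  n <- length(r)
  der <- derived_fields(state, params)
  Fx <- reaction_terms(state, der, dose_rates, params, eps_T)
  S <- (Fx$F_D + Fx$F_T + Fx$F_C) / params$rho_tot
  u <- velocity_field(Fx$F_D + Fx$F_T + Fx$F_C, r, params)
  r_new <- r + u * tau

  f <- state$fields
  new <- f
  deltas <- c(D = params$delta_D, T = params$delta_T, C = params$delta_C,
              P = params$delta_T)
  Fmap <- c(D = "F_D", T = "F_T", C = "F_C", P = "F_P",
            I12 = "F_I12", Ta = "F_Ta", A = "F_A", B = "F_B")
  idx <- seq_len(n - 1)
  for (nm in c("D", "T", "C", "P")) {
    lap <- .radial_laplacian(f[[nm]], r)
    upd <- f[[nm]] + tau * (deltas[nm] * lap + Fx[[Fmap[nm]]] -
                            f[[nm]] * S)
    new[[nm]][idx] <- upd[idx]
  }
  cyto_deltas <- c(I12 = params$delta_I12, Ta = params$delta_Ta,
                   A = params$delta_A, B = params$delta_B)
  for (nm in c("I12", "Ta", "A", "B")) {
    lap <- .radial_laplacian(f[[nm]], r)
    tmp <- f[[nm]] + tau * (cyto_deltas[nm] * lap + Fx[[Fmap[nm]]])
    tmp[n] <- tmp[n - 1]                       # Neumann on the old mesh
    new[[nm]] <- stats::approx(r, tmp, xout = r_new, rule = 2)$y
  }

  out <- tfb_state(r_new, new, t = state$t + tau)
  out <- apply_boundary_conditions(out, params)
  clips <- 0L
  for (nm in .tfb_fields) {
    neg <- out$fields[[nm]] < 0
    clips <- clips + sum(neg)
    out$fields[[nm]][neg] <- 0
  }
  list(state = out, u = u, S = S, clips = clips)
}

#' Interpolate a state onto a fresh uniform mesh
#'
#' Monotone piecewise-linear interpolation of every field onto `N + 1`
#' uniformly spaced nodes on `[0, R]`.
#'
#' @param state a `tfb_state`.
#' @param N number of intervals of the new mesh.
#' @return The regridded `tfb_state`.
#' @export
regrid <- function(state, N = length(state$r) - 1L) {
  r_new <- seq(0, state$r[length(state$r)], length.out = N + 1)
  fields <- lapply(state$fields, function(x)
    stats::approx(state$r, x, xout = r_new, rule = 2)$y)
  tfb_state(r_new, fields, t = state$t)
}

#' Run a full simulation
#'
#' Advances the model from the standard initial state to `t_end` with the
#' moving-mesh explicit-Euler scheme (compiled core), recording
#' volume-averaged fields, the free-boundary radius, tumor volume and
#' conservation diagnostics at the output cadence.  The time step is the
#' diffusion bound of [stable_timestep()], additionally capped by the
#' fastest reaction rate (the TNF-alpha turnover, possibly accelerated by
#' drug blocking) so the explicit update stays stable on coarse meshes.
#'
#' @param params a `tfb_params`.
#' @param schedule a `tfb_schedule`, or `NULL` for the control (no drugs).
#' @param R0 initial radius (cm).
#' @param settings a [tfb_settings()] list; its `t_end` is overridden by
#'   the schedule's treatment end when a schedule is given.
#' @return An object of class `tfb_result` with elements `times`, `avg`
#'   (matrix of volume-averaged fields), `R`, `V`, `consdev`, `clips`,
#'   `n_steps`, `n_regrids`, `collapsed`, `tvrr`, `final_state`.
#' @export
simulate <- function(params = default_parameters(), schedule = NULL,
                     R0 = 0.5, settings = tfb_settings()) {
  validate_parameters(params)
  stopifnot(inherits(settings, "tfb_settings"))
  t_end <- settings$t_end
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "tfb_schedule"))
    t_end <- schedule$t_end
  }
  out_times <- unique(c(seq(0, t_end, by = settings$out_dt), t_end))

  st <- initial_state(R0, params, settings$N)
  evA <- schedule_events(schedule, "anti-PD-1")
  evB <- schedule_events(schedule, "anti-TNF-alpha")
  beta <- if (is.null(schedule)) 1 else schedule$beta

  res <- cpp_simulate(
    r = st$r,
    D = st$fields$D, Tc = st$fields$T, C = st$fields$C,
    I12 = st$fields$I12, Ta = st$fields$Ta, P = st$fields$P,
    A = st$fields$A, B = st$fields$B,
    par = unclass(params), lambda_C = active_lambda_C(params),
    daysA = evA$day, gammaA = evA$gamma,
    daysB = evB$day, gammaB = evB$gamma, beta = beta,
    out_times = out_times,
    N = settings$N, safety = settings$safety,
    regrid_ratio = settings$regrid_ratio,
    regrid_growth = settings$regrid_growth,
    cons_tol = settings$cons_tol, r_min = settings$r_min,
    eps_T = settings$eps_T,
    fixed_tau = 0.0, max_steps = 0.0, do_regrid = TRUE)

  avg <- res$avg
  colnames(avg) <- .tfb_fields
  V <- 4 / 3 * pi * res$R^3
  tv <- if (is.null(schedule)) NA_real_ else tvrr(V[1], V[length(V)])
  final <- tfb_state(res$r_final,
                     stats::setNames(res$fields_final, .tfb_fields),
                     t = out_times[length(out_times)])
  structure(list(times = out_times, avg = avg, R = res$R, V = V,
                 consdev = res$consdev, clips = res$clips,
                 n_steps = res$n_steps, n_regrids = res$n_regrids,
                 collapsed = res$collapsed, tvrr = tv,
                 final_state = final, params = params,
                 schedule = schedule, settings = settings),
            class = "tfb_result")
}

#' @export
print.tfb_result <- function(x, ...) {
  nt <- length(x$times)
  cat("<tfb_result> ", nt, " outputs to t = ", x$times[nt], " day\n",
      sep = "")
  cat(sprintf("  R: %.4g -> %.4g cm, V: %.4g -> %.4g cm^3\n",
              x$R[1], x$R[nt], x$V[1], x$V[nt]))
  if (!is.na(x$tvrr)) cat(sprintf("  TVRR = %.2f%%\n", x$tvrr))
  cat(sprintf("  steps = %d, regrids = %d, clips = %d, max |D+T+C-rho| = %.3g\n",
              x$n_steps, x$n_regrids, x$clips, max(x$consdev)))
  invisible(x)
}

#' Time series of a simulation result as a data frame
#'
#' @param x a `tfb_result`.
#' @param ... unused.
#' @return Data frame with time, averaged fields, radius, volume and the
#'   conservation diagnostic.
#' @export
as.data.frame.tfb_result <- function(x, ...) {
  data.frame(time = x$times, x$avg, R = x$R, V = x$V,
             consdev = x$consdev, check.names = FALSE)
}

#' Write a simulation result to CSV (time series) and JSON (scalars)
#'
#' @param result a `tfb_result`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_result <- function(result, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(result), csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(
      tvrr = result$tvrr, R_final = result$R[length(result$R)],
      V_final = result$V[length(result$V)],
      n_steps = result$n_steps, n_regrids = result$n_regrids,
      clips = result$clips, max_consdev = max(result$consdev),
      collapsed = result$collapsed),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(csv = csv_path, json = json_path))
}
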