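#' Control (no-drug) simulation
#'
#' Runs the untreated mouse model and returns the full result; this is the
#' baseline whose volume-averaged fields approach their quasi-steady
#' values while the tumor volume grows exponentially.
#'
#' @param params a `tfb_params` (mouse defaults).
#' @param R0 initial radius (cm).
#' @param days simulation length (day).
#' @param settings a [tfb_settings()]; `t_end` is replaced by `days`.
#' @return A `tfb_result`.
#' @export
run_control <- function(params = default_parameters(), R0 = 0.5,
                        days = 30, settings = tfb_settings()) {
  settings$t_end <- days
  simulate(params, schedule = NULL, R0 = R0, settings = settings)
}

#' TVRR efficacy map over a dose grid
#'
#' One simulation per (gamma_A, gamma_B) grid point under the given
#' 3-week-cycle schedule variant, with the human growth rate.
#'
#' @param variant `"S1"`, `"S2"` or `"S3"`.
#' @param R0 initial radius (cm).
#' @param n_cycles number of 21-day cycles.
#' @param gamma_A_grid,gamma_B_grid dose amplitude grids (g/cm^3/day).
#' @param params a `tfb_params`; coerced to the human growth rate.
#' @param settings a [tfb_settings()].
#' @return An object of class `tfb_efficacy_map`: list with the grids and
#'   the TVRR matrix (rows = gamma_A, cols = gamma_B), in percent.
#' @export
efficacy_map <- function(variant, R0 = 1, n_cycles = 5,
                         gamma_A_grid = seq(0.1, 1, length.out = 4) * 1e-11,
                         gamma_B_grid = seq(0.1, 1, length.out = 4) * 1e-6,
                         params = default_parameters("human"),
                         settings = tfb_settings()) {
  if (length(gamma_A_grid) == 0 || length(gamma_B_grid) == 0)
    stop("dose grids must be nonempty")
  attr(params, "species") <- "human"
  m <- matrix(NA_real_, length(gamma_A_grid), length(gamma_B_grid),
              dimnames = list(signif(gamma_A_grid, 3),
                              signif(gamma_B_grid, 3)))
  for (i in seq_along(gamma_A_grid)) {
    for (j in seq_along(gamma_B_grid)) {
      sch <- build_human_schedule(variant, n_cycles,
                                  gamma_A = gamma_A_grid[i],
                                  gamma_B = gamma_B_grid[j],
                                  beta = params$beta)
      res <- simulate(params, sch, R0 = R0, settings = settings)
      m[i, j] <- res$tvrr
    }
  }
  structure(list(variant = variant, R0 = R0, n_cycles = n_cycles,
                 gamma_A = gamma_A_grid, gamma_B = gamma_B_grid,
                 tvrr = m), class = "tfb_efficacy_map")
}

#' @export
print.tfb_efficacy_map <- function(x, ...) {
  cat("<tfb_efficacy_map> ", x$variant, ", R0 = ", x$R0, " cm, ",
      x$n_cycles, " cycles\n", sep = "")
  print(round(x$tvrr, 2))
  invisible(x)
}

#' Write an efficacy map as CSV (long format)
#'
#' @param map a `tfb_efficacy_map`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_efficacy_map <- function(map, path) {
  df <- expand.grid(gamma_A = map$gamma_A, gamma_B = map$gamma_B)
  df$tvrr <- as.vector(map$tvrr)
  df$variant <- map$variant
  df$R0 <- map$R0
  df$n_cycles <- map$n_cycles
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Latin hypercube sample
#'
#' Stratified design: for each parameter the unit interval is split into
#' `n` equal strata, one uniform draw is taken per stratum, and the strata
#' are randomly permuted independently per dimension, then scaled to the
#' requested ranges.
#'
#' @param ranges named list of `c(low, high)` per parameter.
#' @param n number of samples (>= 2).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return An `n` x `p` matrix with one column per parameter.
#' @export
lhs_sample <- function(ranges, n, seed) {
  stopifnot(n >= 2, length(ranges) >= 1)
  lows <- vapply(ranges, `[`, numeric(1), 1)
  highs <- vapply(ranges, `[`, numeric(1), 2)
  if (any(lows >= highs)) stop("invalid range: low must be < high")
  set.seed(seed)
  p <- length(ranges)
  m <- matrix(NA_real_, n, p, dimnames = list(NULL, names(ranges)))
  for (j in seq_len(p)) {
    strata <- (sample.int(n) - stats::runif(n)) / n
    m[, j] <- lows[j] + strata * (highs[j] - lows[j])
  }
  m
}

#' Partial rank correlation coefficients
#'
#' Rank-transforms all columns; the PRCC of parameter `j` is the Pearson
#' correlation of the residuals of the parameter ranks and the output
#' ranks after linearly regressing out all other parameters.  p-values use
#' the t statistic `prcc * sqrt(df / (1 - prcc^2))` with
#' `df = n - 2 - (p - 1)`.
#'
#' @param samples `n` x `p` parameter matrix.
#' @param outputs length-`n` output vector.
#' @return An object of class `tfb_sensitivity`: data frame with
#'   `parameter`, `prcc`, `p_value`, plus attributes `n` and `df`.
#' @export
prcc <- function(samples, outputs) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  p <- ncol(samples)
  stopifnot(length(outputs) == n, n > p + 2)
  if (!all(is.finite(outputs))) stop("outputs must be finite")
  const <- apply(samples, 2, function(x) stats::sd(x) == 0)
  rk <- apply(samples, 2, rank)
  ry <- rank(outputs)
  df <- n - 2 - (p - 1)
  out <- data.frame(parameter = colnames(samples) %||%
                      paste0("x", seq_len(p)),
                    prcc = NA_real_, p_value = NA_real_)
  for (j in seq_len(p)) {
    if (const[j]) next  # constant column: PRCC undefined, left NA
    others <- rk[, -j, drop = FALSE]
    if (ncol(others) > 0) {
      Z <- cbind(1, others)
      rx <- stats::lm.fit(Z, rk[, j])$residuals
      ryr <- stats::lm.fit(Z, ry)$residuals
    } else {
      rx <- rk[, j] - mean(rk[, j])
      ryr <- ry - mean(ry)
    }
    rho <- sum(rx * ryr) / sqrt(sum(rx^2) * sum(ryr^2))
    tstat <- rho * sqrt(df / (1 - rho^2))
    out$prcc[j] <- rho
    out$p_value[j] <- 2 * stats::pt(-abs(tstat), df)
  }
  structure(out, class = c("tfb_sensitivity", "data.frame"),
            n = n, df = df)
}

# default sensitivity parameter list: the production parameters, the two
# drug blocking rates and the kill rate
.tfb_sensitivity_params <- c("lambda_DC_D0", "lambda_TI12_T0",
                             "lambda_C_mouse", "lambda_I12D",
                             "lambda_TaT", "A_Ta", "mu_TaB", "mu_PA",
                             "eta")

#' Global sensitivity analysis (LHS + PRCC)
#'
#' Samples the production parameters, drug blocking rates and kill rate in
#' +/- 50% ranges around the mouse baseline by Latin hypercube, runs the
#' model for each sample, and computes PRCCs of the tumor radius at
#' `days`.  The mouse treatment schedule (both drugs at days 6, 10, 13) is
#' applied by default so that the drug blocking rates `mu_PA` and
#' `mu_TaB` are exercised.
#'
#' @param n number of LHS samples.
#' @param seed RNG seed (mandatory).
#' @param days output day for the tumor radius.
#' @param rel_range half-width of the sampling range, relative to baseline.
#' @param params baseline `tfb_params` (mouse).
#' @param schedule treatment applied during the sampled runs: the mouse
#'   protocol by default (`"mouse"`, injections at days 6/10/13, truncated
#'   to days before `days`), a `tfb_schedule`, or `NULL` for none.
#' @param settings a [tfb_settings()].
#' @param param_names which parameters to sample.
#' @return A `tfb_sensitivity` data frame (see [prcc()]) with attributes
#'   `samples`, `outputs`, `seed`, `ranges`.
#' @export
sensitivity_analysis <- function(n = 200, seed = 1, days = 30,
                                 rel_range = 0.5,
                                 params = default_parameters(),
                                 schedule = "mouse",
                                 settings = tfb_settings(N = 50),
                                 param_names = .tfb_sensitivity_params) {
  stopifnot(n > length(param_names) + 2)
  if (identical(schedule, "mouse")) {
    inj <- c(6, 10, 13)
    inj <- inj[inj < days]
    schedule <- if (length(inj) > 0)
      build_mouse_schedule(inj, beta = params$beta, t_end = days)
    else NULL
  }
  base <- unlist(params[param_names])
  ranges <- lapply(param_names, function(k)
    params[[k]] * c(1 - rel_range, 1 + rel_range))
  names(ranges) <- param_names
  X <- lhs_sample(ranges, n, seed)
  settings$t_end <- days
  if (!is.null(schedule)) schedule$t_end <- days
  out <- numeric(n)
  for (i in seq_len(n)) {
    p <- params
    for (k in param_names) p[[k]] <- X[i, k]
    if ("lambda_C_mouse" %in% param_names)  # keep mouse >= human invariant
      p$lambda_C_human <- params$lambda_C_human *
        X[i, "lambda_C_mouse"] / params$lambda_C_mouse
    res <- simulate(p, schedule, R0 = 0.5, settings = settings)
    out[i] <- res$R[length(res$R)]
  }
  ans <- prcc(X, out)
  attr(ans, "samples") <- X
  attr(ans, "outputs") <- out
  attr(ans, "seed") <- seed
  attr(ans, "ranges") <- ranges
  ans
}

#' Write a sensitivity result to CSV
#'
#' @param sens a `tfb_sensitivity` data frame.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_sensitivity <- function(sens, path) {
  utils::write.csv(as.data.frame(sens), path, row.names = FALSE)
  invisible(path)
}
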