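#' Model constants and their derivation rules
#'
#' The simulator works in units of g/cm^3 (densities and concentrations),
#' cm (length) and day (time).  A parameter set holds every constant of the
#' tumor--immune model: diffusion coefficients, production/death rates,
#' half-saturations, checkpoint expression ratios, drug blocking rates and
#' the dosing decay constant.  The helpers in this file implement the rules
#' by which most of those constants were derived in the first place:
#' cube-root molecular-weight scaling for protein diffusivities
#' ([young_diffusion()]), half-life conversion ([rate_from_half_life()]) and
#' steady-state closures ([derive_closure_rates()]).
#'
#' @name tumorfb-parameters
NULL

# Fields D, T, C advect with the common cell velocity; cytokines and drugs
# (I12, Ta, A, B) diffuse fast and their advection is neglected.
.tfb_fields <- c("D", "T", "C", "I12", "Ta", "P", "A", "B")

.tfb_param_defaults <- function() {
  list(
    # diffusion coefficients, cm^2/day
    delta_D   = 8.64e-7,  delta_T = 8.64e-7, delta_C = 8.64e-7,
    delta_I12 = 7.17e-2,  delta_Ta = 8.46e-2,
    delta_A   = 4.76e-2,  delta_B = 4.75e-2,
    # boundary flux rate of T cells, 1/cm
    sigma0 = 1,
    # kill / blocking rates, cm^3/(g day)
    eta = 328.55, mu_PA = 1.03e7, mu_TaB = 2.56e8,
    # expression ratios and upregulation factors (dimensionless)
    rho_P = 2.49e-7, rho_L = 3.25e-7, rho_M = 1.5e-7, rho_G = 2e-8,
    eps_C = 0.1, alpha_L = 1, alpha_T = 1, alpha_MA = 2,
    # lumped production rates
    lambda_DC_D0   = 8e-5,     # g/(cm^3 day)
    lambda_TI12_T0 = 6.48e-4,  # g/(cm^3 day)
    lambda_C_mouse = 1.295,    # 1/day
    lambda_C_human = 0.895,    # 1/day
    lambda_I12D    = 2.76e-6,  # 1/day
    lambda_TaT     = 5.36e-6,  # 1/day, closure-derived default (see below)
    A_Ta           = 1.12e-9,  # g/(cm^3 day), macrophage TNF-a source
    # death / degradation rates, 1/day
    d_D = 0.1, d_T = 0.197, d_C = 0.17, d_I12 = 1.38, d_Ta = 216,
    d_A = 0.046, d_B = 0.069,
    # half-saturations, g/cm^3
    K_D = 4e-4, K_T = 1e-3, K_C = 0.4, K_I12 = 8e-10, K_Ta = 3e-11,
    K_A = 1e-10,
    # checkpoint-complex inhibition constants, g^2/cm^6
    K_TQ1 = 1.36e-18, K_TQ2 = 1.365e-18,
    # carrying capacity and boundary T-cell density, g/cm^3
    C_M = 0.8, T_hat = 2e-3,
    # dose pulse decay, 1/day
    beta = 1.55,
    # total cell density constant D + T + C, g/cm^3
    rho_tot = 0.4014
  )
}

.tfb_param_provenance <- function() {
  prov <- c(
    delta_D = "table", delta_T = "table", delta_C = "table",
    delta_I12 = "table", delta_Ta = "table", delta_A = "table",
    delta_B = "table", sigma0 = "table", eta = "table",
    mu_PA = "table", mu_TaB = "table", rho_P = "table", rho_L = "table",
    rho_M = "table", rho_G = "table", eps_C = "table", alpha_L = "table",
    alpha_T = "table", alpha_MA = "table", lambda_DC_D0 = "table",
    lambda_TI12_T0 = "table", lambda_C_mouse = "table",
    lambda_C_human = "table", lambda_I12D = "table",
    lambda_TaT = "derived", A_Ta = "text", d_D = "table", d_T = "table",
    d_C = "table", d_I12 = "table", d_Ta = "table", d_A = "table",
    d_B = "table", K_D = "table", K_T = "table", K_C = "table",
    K_I12 = "table", K_Ta = "table", K_A = "default", K_TQ1 = "table",
    K_TQ2 = "table", C_M = "table", T_hat = "table", beta = "table",
    rho_tot = "text"
  )
  prov
}

# Printed alternatives for the TNF-a production rate by T cells.  The three
# sources disagree; the closure value is the default because it is the only
# one consistent with the half-saturation rule K_Ta = Ta^0 (see vignette).
.tfb_lambda_TaT_values <- c(closure = 5.36e-6, text = 1.08e-6,
                            table = 6.48e-4)

#' Default parameter set
#'
#' Returns the full set of model constants (mouse defaults).  `species`
#' selects which cancer-cell growth rate `lambda_C` is active in
#' simulations; both variants are always stored.
#'
#' @param species `"mouse"` or `"human"`.
#' @param lambda_TaT_source which printed value of the TNF-alpha production
#'   rate to use: `"closure"` (default, 5.36e-6/day), `"text"` (1.08e-6/day)
#'   or `"table"` (6.48e-4/day).
#' @return An object of class `tfb_params`: a named list of constants with
#'   `species` and per-parameter provenance attributes.
#' @examples
#' p <- default_parameters()
#' p$rho_tot
#' @export
default_parameters <- function(species = c("mouse", "human"),
                               lambda_TaT_source = c("closure", "text",
                                                     "table")) {
  species <- match.arg(species)
  lambda_TaT_source <- match.arg(lambda_TaT_source)
  p <- .tfb_param_defaults()
  p$lambda_TaT <- unname(.tfb_lambda_TaT_values[lambda_TaT_source])
  structure(p, class = "tfb_params", species = species,
            provenance = .tfb_param_provenance(),
            lambda_TaT_source = lambda_TaT_source)
}

#' Active cancer-cell growth rate
#'
#' @param params a `tfb_params` object.
#' @return `lambda_C_mouse` or `lambda_C_human` according to the set's
#'   species attribute.
#' @export
active_lambda_C <- function(params) {
  if (identical(attr(params, "species"), "human")) params$lambda_C_human
  else params$lambda_C_mouse
}

#' Validate a parameter set
#'
#' Checks strict positivity of every constant, the squared-unit inhibition
#' constants, the mouse >= human growth-rate ordering, and that `rho_tot`
#' equals the sum of the default initial cell densities.
#'
#' @param params a `tfb_params` object.
#' @return `params` invisibly; errors on violation.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "tfb_params"))
  vals <- unlist(params)
  bad <- names(vals)[!is.finite(vals) | vals <= 0]
  if (length(bad) > 0)
    stop("invalid parameter(s), must be strictly positive: ",
         paste(bad, collapse = ", "))
  if (params$lambda_C_mouse < params$lambda_C_human)
    stop("invalid parameters: mouse lambda_C must be >= human lambda_C")
  ic <- initial_densities()
  if (abs(params$rho_tot - (ic$D + ic$T + ic$C)) > 1e-12)
    stop("rho_tot must equal the sum of the initial cell densities")
  invisible(params)
}

#' @export
print.tfb_params <- function(x, ...) {
  cat("<tfb_params> ", length(x), " constants, species = ",
      attr(x, "species"), "\n", sep = "")
  cat("  active lambda_C = ", active_lambda_C(x), " /day\n", sep = "")
  invisible(x)
}

#' Protein diffusivity from molecular weight
#'
#' Cube-root molecular-weight scaling anchored at VEGF (24 kDa,
#' 8.64e-2 cm^2/day): `D_p = D_ref * (M_ref / M_p)^(1/3)`.
#'
#' @param molecular_weight protein molecular weight, kDa.
#' @param M_ref,D_ref anchor weight (kDa) and diffusivity (cm^2/day).
#' @return Diffusion coefficient in cm^2/day.
#' @examples
#' young_diffusion(143.6)  # anti-PD-1 IgG -> 4.76e-2
#' @export
young_diffusion <- function(molecular_weight, M_ref = 24, D_ref = 8.64e-2) {
  if (!is.numeric(molecular_weight) || any(molecular_weight <= 0) ||
      M_ref <= 0 || D_ref <= 0)
    stop("invalid parameter: molecular weights must be positive")
  D_ref * (M_ref / molecular_weight)^(1 / 3)
}

#' Convert a half-life to a first-order rate
#'
#' @param half_life half-life in days.
#' @return Rate `ln 2 / half_life` in 1/day.
#' @export
rate_from_half_life <- function(half_life) {
  if (!is.numeric(half_life) || any(half_life <= 0))
    stop("invalid parameter: half-life must be positive")
  log(2) / half_life
}

#' @rdname rate_from_half_life
#' @param rate first-order rate, 1/day.
#' @export
rate_to_half_life <- function(rate) {
  if (!is.numeric(rate) || any(rate <= 0))
    stop("invalid parameter: rate must be positive")
  log(2) / rate
}

#' Steady-state closure targets
#'
#' The densities/concentrations each species is assumed to approach in the
#' untreated tumor, used by the half-saturation rule `K_X = X^0` and the
#' production-rate closures.  `inhibition` is the assumed combined
#' checkpoint inhibition factor at steady state; `depletion_fraction` is
#' the fraction of each drug consumed by target blocking (the rest
#' degrades/washes out).
#'
#' @return A named list of class `tfb_closure_targets`.
#' @export
closure_targets <- function() {
  structure(list(
    D0 = 4e-4, T0 = 1e-3, C0 = 0.4,
    I120 = 8e-10, Ta0 = 3e-11, P0 = 2.49e-10,
    inhibition = 1 / 1.8, depletion_fraction = 0.1
  ), class = "tfb_closure_targets")
}

#' Derive the lumped production and blocking rates
#'
#' Implements the steady-state closures: each dynamic equation is set to
#' zero with every species at its closure target and every half-saturation
#' at that target (so activation factors equal 1/2), and solved for the
#' production rate.  Drug blocking rates follow from the assumed 10%
#' depletion fraction.
#'
#' @param targets a [closure_targets()] list.
#' @param fixed named list of the fixed constants entering the closures;
#'   defaults to the estimation-section values, which differ from the
#'   simulation defaults for `d_T` (0.18 vs 0.197) and `eta` (328 vs
#'   328.55).
#' @return A data frame with one row per derived rate: `parameter`,
#'   `derived`, `printed` (the Table 2 value) and `rel_discrepancy`.
#' @examples
#' derive_closure_rates()
#' @export
derive_closure_rates <- function(targets = closure_targets(),
                                 fixed = list()) {
  fx <- utils::modifyList(list(
    d_D = 0.1, K_D = 4e-4, d_T = 0.18, eta = 328, K_T = 1e-3, d_C = 0.17,
    d_I12 = 1.38, K_I12 = 8e-10, d_Ta = 216, K_Ta = 3e-11, A_Ta = 1.12e-9,
    d_A = 0.046, d_B = 0.069
  ), fixed)
  f <- targets$depletion_fraction
  if (f <= 0 || f >= 1) stop("depletion fraction must be in (0, 1)")
  blocked_ratio <- (1 - f) / f   # = 9 for f = 0.1

  lam_TaT <- (fx$d_Ta * fx$K_Ta - targets$A_Ta %||% fx$A_Ta) / fx$K_T
  if (lam_TaT < 0)
    stop("closure infeasible: A_Ta exceeds d_Ta * K_Ta, ",
         "lambda_TaT would be negative")

  derived <- c(
    lambda_DC_D0   = 2 * fx$d_D * fx$K_D,
    lambda_TI12_T0 = 2 * (1 / targets$inhibition) * fx$d_T * targets$T0,
    lambda_C       = 2 * (fx$eta * fx$K_T + fx$d_C),
    lambda_I12D    = fx$d_I12 * fx$K_I12 / fx$K_D,
    lambda_TaT     = lam_TaT,
    mu_TaB         = fx$d_B / (blocked_ratio * fx$K_Ta),
    mu_PA          = fx$d_A / (blocked_ratio * targets$P0)
  )
  if (any(derived < 0))
    stop("closure infeasible: negative derived rate for ",
         paste(names(derived)[derived < 0], collapse = ", "))
  printed <- c(lambda_DC_D0 = 8e-5, lambda_TI12_T0 = 6.48e-4,
               lambda_C = 0.996, lambda_I12D = 2.76e-6,
               lambda_TaT = 6.48e-4, mu_TaB = 2.56e8, mu_PA = 1.03e7)
  data.frame(parameter = names(derived),
             derived = unname(derived),
             printed = unname(printed[names(derived)]),
             rel_discrepancy = unname(abs(derived - printed[names(derived)])
                                      / printed[names(derived)]),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a parameter set from a key = value config file
#'
#' The config is a flat structured-text file, one `key = value` per line,
#' `#` comments allowed.  Keys are the ASCII transliterations of the model
#' symbols (`delta_D`, `lambda_C_mouse`, `K_TQ1`, ...) plus the meta keys
#' `species` (mouse/human) and `lambda_TaT_source` (closure/text/table).
#' Unknown keys and nonpositive values are rejected.  Values deviating by
#' more than 5% from their closure-derived counterparts are recorded in the
#' attached validation log.
#'
#' @param path path to the config file, or a character vector of lines.
#' @return A validated `tfb_params` object with a `validation_log`
#'   attribute (character vector of logged deviations).
#' @export
load_parameters <- function(path = character()) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path)
           else as.character(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  species <- "mouse"
  lam_src <- "closure"
  overrides <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("config parse error, expected 'key = value': ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (key == "species") {
      if (!val %in% c("mouse", "human"))
        stop("config error: species must be mouse or human, got ", val)
      species <- val
    } else if (key == "lambda_TaT_source") {
      if (!val %in% names(.tfb_lambda_TaT_values))
        stop("config error: unknown lambda_TaT_source ", val)
      lam_src <- val
    } else {
      if (!key %in% names(.tfb_param_defaults()))
        stop("config error: unknown parameter key '", key, "'")
      num <- suppressWarnings(as.numeric(val))
      if (!is.finite(num))
        stop("config error: non-numeric value for ", key, ": ", val)
      overrides[[key]] <- num
    }
  }

  p <- default_parameters(species = species, lambda_TaT_source = lam_src)
  prov <- attr(p, "provenance")
  for (key in names(overrides)) {
    p[[key]] <- overrides[[key]]
    prov[key] <- "config"
  }
  attr(p, "provenance") <- prov
  validate_parameters(p)

  # log values deviating >5% from the closure-derived rates
  log <- character()
  cl <- derive_closure_rates()
  for (i in seq_len(nrow(cl))) {
    nm <- cl$parameter[i]
    key <- if (nm == "lambda_C") "lambda_C_mouse" else nm
    cur <- if (nm == "lambda_C") active_lambda_C(p) else p[[nm]]
    rel <- abs(cur - cl$derived[i]) / cl$derived[i]
    if (rel > 0.05)
      log <- c(log, sprintf(
        "%s = %.4g deviates %.1f%% from closure-derived %.4g",
        nm, cur, 100 * rel, cl$derived[i]))
  }
  attr(p, "validation_log") <- log
  p
}

#' Export a validated parameter set as JSON with provenance tags
#'
#' @param params a `tfb_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_parameters <- function(params, path) {
  validate_parameters(params)
  prov <- attr(params, "provenance")
  out <- list(
    species = attr(params, "species"),
    lambda_TaT_source = attr(params, "lambda_TaT_source") %||% "closure",
    parameters = lapply(names(.tfb_param_defaults()), function(k) {
      list(name = k, value = params[[k]],
           provenance = unname(prov[k]) %||% "default")
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Re-import a JSON parameter export
#'
#' @param path path written by [export_parameters()].
#' @return A `tfb_params` object identical to the exported one.
#' @export
import_parameters <- function(path) {
  doc <- jsonlite::read_json(path)
  p <- default_parameters(species = doc$species,
                          lambda_TaT_source = doc$lambda_TaT_source)
  prov <- attr(p, "provenance")
  for (entry in doc$parameters) {
    p[[entry$name]] <- entry$value
    prov[entry$name] <- entry$provenance
  }
  attr(p, "provenance") <- prov
  validate_parameters(p)
}
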