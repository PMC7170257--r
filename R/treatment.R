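.tfb_drugs <- c("anti-PD-1", "anti-TNF-alpha")

#' Dosing schedule
#'
#' A schedule is a list of dose events (drug, injection day, pulse
#' amplitude gamma in g/cm^3/day) plus the shared exponential decay
#' constant `beta` (1/day) and the treatment end day `t_e`.  Each event
#' contributes `gamma * exp(-beta (t - t_i))` to the dose rate for
#' `t > t_i`.
#'
#' @param events data frame with columns `drug` (one of `"anti-PD-1"`,
#'   `"anti-TNF-alpha"`), `day` and `gamma`.
#' @param beta pulse decay constant (1/day).
#' @param t_end treatment end day.
#' @return An object of class `tfb_schedule`.
#' @export
tfb_schedule <- function(events, beta = 1.55, t_end) {
  events <- as.data.frame(events)
  stopifnot(all(c("drug", "day", "gamma") %in% names(events)))
  if (!all(events$drug %in% .tfb_drugs))
    stop("unknown drug; use ", paste(.tfb_drugs, collapse = " or "))
  if (any(events$day < 0)) stop("injection days must be nonnegative")
  if (any(events$gamma < 0)) stop("dose amplitudes must be nonnegative")
  if (beta <= 0) stop("beta must be positive")
  if (any(events$day >= t_end))
    stop("all injection days must precede the treatment end day")
  events <- events[order(events$day), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, beta = beta, t_end = t_end),
            class = "tfb_schedule")
}

#' @export
print.tfb_schedule <- function(x, ...) {
  cat("<tfb_schedule> ", nrow(x$events), " events, beta = ", x$beta,
      "/day, t_end = ", x$t_end, " day\n", sep = "")
  print(x$events)
  invisible(x)
}

#' Events of one drug in a schedule
#'
#' @param schedule a `tfb_schedule` or `NULL`.
#' @param drug drug name.
#' @return Data frame with `day` and `gamma` columns (possibly empty).
#' @export
schedule_events <- function(schedule, drug) {
  if (is.null(schedule))
    return(data.frame(day = numeric(), gamma = numeric()))
  ev <- schedule$events[schedule$events$drug == drug, c("day", "gamma")]
  rownames(ev) <- NULL
  ev
}

#' Pulse-decay dose rate
#'
#' `gamma(t) = sum over events with t_i < t of gamma_i exp(-beta (t - t_i))`
#' (strict inequality: an injection contributes only after its day).
#'
#' @param t time (day), may be a vector.
#' @param schedule a `tfb_schedule`.
#' @param drug which drug's events to sum.
#' @return Dose rate(s) in g/cm^3/day.
#' @export
dose_rate <- function(t, schedule, drug = .tfb_drugs) {
  drug <- match.arg(drug)
  ev <- schedule_events(schedule, drug)
  vapply(t, function(tt) {
    act <- ev$day < tt
    sum(ev$gamma[act] * exp(-schedule$beta * (tt - ev$day[act])))
  }, numeric(1))
}

#' Mouse treatment schedule
#'
#' Both drugs injected on every listed day.
#'
#' @param days injection days (e.g. `c(6, 10, 13)`).
#' @param gamma_A,gamma_B pulse amplitudes (g/cm^3/day).
#' @param beta pulse decay constant (1/day).
#' @param t_end treatment end day (default: simulate to day 30).
#' @return A `tfb_schedule`.
#' @export
build_mouse_schedule <- function(days, gamma_A = 1e-10, gamma_B = 1e-6,
                                 beta = 1.55, t_end = 30) {
  if (length(days) == 0) stop("day list must be nonempty")
  if (any(days < 0)) stop("injection days must be nonnegative")
  events <- rbind(
    data.frame(drug = "anti-PD-1", day = days, gamma = gamma_A),
    data.frame(drug = "anti-TNF-alpha", day = days, gamma = gamma_B))
  tfb_schedule(events, beta = beta, t_end = t_end)
}

#' Human 3-week-cycle schedules S1/S2/S3
#'
#' 21-day cycles starting at simulation day 0.  S1: both drugs on day 0 of
#' each cycle; S2: anti-PD-1 on day 0 and anti-TNF-alpha on day 7; S3: the
#' inverse order.  Treatment (and simulation) ends at `21 * n_cycles`
#' days.
#'
#' @param variant `"S1"`, `"S2"` or `"S3"`.
#' @param n_cycles number of 3-week cycles (>= 1).
#' @param gamma_A,gamma_B pulse amplitudes (g/cm^3/day).
#' @param beta pulse decay constant (1/day).
#' @return A `tfb_schedule`.
#' @export
build_human_schedule <- function(variant = c("S1", "S2", "S3"), n_cycles,
                                 gamma_A = 1e-11, gamma_B = 1e-6,
                                 beta = 1.55) {
  variant <- match.arg(variant)
  stopifnot(n_cycles >= 1)
  starts <- 21 * (seq_len(n_cycles) - 1)
  off <- switch(variant,
                S1 = c(A = 0, B = 0),
                S2 = c(A = 0, B = 7),
                S3 = c(A = 7, B = 0))
  events <- rbind(
    data.frame(drug = "anti-PD-1", day = starts + off["A"],
               gamma = gamma_A),
    data.frame(drug = "anti-TNF-alpha", day = starts + off["B"],
               gamma = gamma_B))
  tfb_schedule(events, beta = beta, t_end = 21 * n_cycles)
}

#' Tumor volume reduction rate
#'
#' `TVRR = (V(0) - V(t_e)) / V(0) * 100%`, the treatment-efficacy
#' endpoint.  Negative values mean the tumor grew.
#'
#' @param V0 initial tumor volume (cm^3), positive.
#' @param Ve end-point tumor volume (cm^3), nonnegative.
#' @return TVRR in percent (at most 100).
#' @export
tvrr <- function(V0, Ve) {
  if (any(V0 <= 0)) stop("initial volume must be positive")
  if (any(Ve < 0)) stop("end-point volume must be nonnegative")
  (V0 - Ve) / V0 * 100
}

#' Serialize / deserialize a schedule as JSON
#'
#' @param schedule a `tfb_schedule`.
#' @param path output (or input) file path.
#' @return `path` invisibly for write; a `tfb_schedule` for read.
#' @export
write_schedule <- function(schedule, path) {
  jsonlite::write_json(list(
    events = schedule$events, beta = schedule$beta,
    t_end = schedule$t_end), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  tfb_schedule(doc$events, beta = doc$beta, t_end = doc$t_end)
}
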