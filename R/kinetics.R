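#' Integrate the diffusion-coalescence kinetics
#'
#' Solves the two-equation model of Y-motif depletion in a well-mixed
#' droplet,
#' \deqn{dN_u/dt = -a N_u - b N_u^2, \qquad dN_g/dt = b N_u^2,}
#' together with the bookkeeping equation `dN_lost/dt = a N_u` for the
#' cumulative diffusive loss, so that `N_u + N_g + N_lost` is conserved.
#' Binding is irreversible within a round and the model is isothermal.
#'
#' @param rates A [rate_constants()] object.
#' @param N0 Initial unbound motif count (>= 0).
#' @param t_end Final time, seconds (> 0).
#' @param rel_tol Relative tolerance of the adaptive integrator
#'   (default 1e-9).
#' @param abs_tol Absolute tolerance in motif counts (default 1e-3; far
#'   below one molecule, so depletion endpoints are resolved).
#' @param times Optional vector of output times (seconds, sorted,
#'   starting at 0). Default: 400 points mixing a log-spaced early grid
#'   with a linear late grid, which resolves both the fast coalescence
#'   transient and the slow diffusive tail.
#' @return A `gelwell_trajectory`: a data.frame with columns
#'   `t_s`, `N_u`, `N_g`, `N_lost`, carrying the rates and `N0` as
#'   attributes.
#' @seealso [closed_form_unbound()] for the analytic solution of `N_u(t)`,
#'   [final_gel_count()] for the `t -> Inf` limit of `N_g`.
#' @export
solve_kinetics <- function(rates, N0, t_end, rel_tol = 1e-9, times = NULL,
                           abs_tol = 1e-3) {
  stopifnot(inherits(rates, "rate_constants"))
  if (!is.numeric(N0) || length(N0) != 1 || N0 < 0)
    stop("`N0` must be a single non-negative count")
  if (!is.numeric(t_end) || t_end <= 0)
    stop("`t_end` must be positive (seconds)")
  a <- rates$loss_rate_a
  b <- rates$coalescence_rate_b

  if (is.null(times)) {
    ## log grid from well below the fastest timescale, then linear to t_end
    rate0 <- a + b * N0
    t_min <- if (rate0 > 0) min(1e-4 / rate0, t_end / 1e6) else t_end / 1e6
    times <- unique(sort(c(0,
      exp(seq(log(t_min), log(t_end), length.out = 300)),
      seq(0, t_end, length.out = 101))))
  } else {
    if (times[1] != 0) times <- c(0, times)
    if (is.unsorted(times, strictly = TRUE))
      stop("`times` must be strictly increasing")
  }

  if (N0 == 0) {
    out <- data.frame(t_s = times, N_u = 0, N_g = 0, N_lost = 0)
    return(new_trajectory(out, rates, N0))
  }

  deriv <- function(t, y, parms) {
    nu <- y[1]
    list(c(-a * nu - b * nu^2, b * nu^2, a * nu))
  }
  sol <- deSolve::lsoda(y = c(N_u = N0, N_g = 0, N_lost = 0),
                        times = times, func = deriv, parms = NULL,
                        rtol = rel_tol, atol = abs_tol)
  diag <- attr(sol, "istate")
  if (!is.null(diag) && diag[1] < 0)
    stop(structure(
      class = c("gelwell_integration_error", "error", "condition"),
      list(message = sprintf(
             "ODE integration failed (lsoda istate = %d); a = %g, b = %g, N0 = %g",
             diag[1], a, b, N0),
           call = sys.call(-1), istate = diag)))
  out <- as.data.frame(sol)
  names(out) <- c("t_s", "N_u", "N_g", "N_lost")
  ## solver can undershoot zero by ~atol near complete depletion
  out$N_u <- pmax(out$N_u, 0)
  new_trajectory(out, rates, N0)
}

new_trajectory <- function(df, rates, N0) {
  structure(df, class = c("gelwell_trajectory", "data.frame"),
            rates = rates, N0 = N0)
}

#' @export
print.gelwell_trajectory <- function(x, ...) {
  n <- nrow(x)
  N0 <- attr(x, "N0")
  cat(sprintf("<gelwell_trajectory> %d time points, t in [0, %.4g] s, N0 = %.4g\n",
              n, x$t_s[n], N0))
  if (N0 > 0)
    cat(sprintf("  final: N_u/N0 = %.4g, N_g/N0 = %.4g, N_lost/N0 = %.4g\n",
                x$N_u[n] / N0, x$N_g[n] / N0, x$N_lost[n] / N0))
  invisible(x)
}

#' Closed-form unbound motif count
#'
#' Analytic solution of `dN_u/dt = -a N_u - b N_u^2` (a Riccati/logistic-type
#' equation with negative quadratic term):
#' \deqn{N_u(t) = \frac{a N_0 e^{-a t}}{a + b N_0 (1 - e^{-a t})},}
#' with the pure-coalescence limit `N0 / (1 + b N0 t)` when `a = 0` and the
#' constant `N0` when `a = b = 0`. Used as the independent oracle for
#' [solve_kinetics()].
#'
#' @param a First-order loss rate, 1/s (>= 0).
#' @param b Second-order coalescence rate, 1/(s count) (>= 0).
#' @param N0 Initial count.
#' @param t Time(s), seconds (vectorised).
#' @return `N_u(t)`, same length as `t`.
#' @export
closed_form_unbound <- function(a, b, N0, t) {
  stopifnot(a >= 0, b >= 0, N0 >= 0, all(t >= 0))
  if (a == 0 && b == 0) return(rep(N0, length(t)))
  if (a == 0) return(N0 / (1 + b * N0 * t))
  ## exp(-a t) form is overflow-safe for large a*t
  e <- exp(-a * t)
  a * N0 * e / (a + b * N0 * (1 - e))
}

#' Final gelled motif count (t -> Inf)
#'
#' Closed-form limit of the gelled count:
#' \deqn{N_g(\infty) = N_0 - \frac{a}{b}\,\ln\!\left(1 + \frac{b N_0}{a}\right),}
#' obtained by integrating `b N_u(t)^2` over the closed-form trajectory.
#' Limits: everything gels as `a -> 0` (`N_g -> N0`); nearly everything
#' diffuses away when `b N0 << a`.
#'
#' @inheritParams closed_form_unbound
#' @return The asymptotic gelled motif count.
#' @export
final_gel_count <- function(a, b, N0) {
  stopifnot(a >= 0, b >= 0, N0 >= 0)
  if (N0 == 0) return(0)
  if (b == 0) return(0)
  if (a == 0) return(N0)
  N0 - (a / b) * log1p(b * N0 / a)
}

## Integrate one round until the gelation flux is negligible:
## |dN_g/dt| * t / N0 = b N_u^2 t / N0 < qss_tol, doubling the horizon as
## needed. Returns the trajectory of the round.
solve_to_steady <- function(rates, N0, rel_tol = 1e-9, qss_tol = 1e-6,
                            max_doublings = 60) {
  a <- rates$loss_rate_a
  b <- rates$coalescence_rate_b
  if (N0 == 0 || (a == 0 && b == 0))
    return(solve_kinetics(rates, N0, t_end = 1, rel_tol = rel_tol))
  t_end <- 10 / (a + b * N0)
  traj <- NULL
  for (i in seq_len(max_doublings)) {
    traj <- solve_kinetics(rates, N0, t_end = t_end, rel_tol = rel_tol)
    nu_end <- traj$N_u[nrow(traj)]
    ## remaining gelation flux, scaled by the elapsed horizon
    if (b * nu_end^2 * t_end / N0 < qss_tol) return(traj)
    t_end <- t_end * 2
  }
  traj
}

#' Annealing schedule
#'
#' Describes the thermal protocol applied to the device: each round heats
#' the sample (which fully dissociates the aggregates) and then lets it
#' cool exponentially back to ambient, after which gelation kinetics run
#' again. The kinetic model itself is isothermal at ambient temperature;
#' the schedule's temperatures feed only [cooling_profile()].
#'
#' @param n_rounds Number of annealing rounds (>= 1). Default 2.
#' @param hot_temperature Peak temperature, kelvin. Default 348.15 (75 C).
#' @param hold_seconds Hold time at the peak, seconds. Default 60.
#' @param cool_seconds Cooling interval, seconds. Default 180.
#' @param cooling_time_constant Exponential cooling time constant tau,
#'   seconds. Default 30.
#' @param ambient_temperature Ambient temperature, kelvin. Default 298.
#' @param round_seconds Optional fixed kinetic duration per round, seconds.
#'   `NULL` (default) integrates each round to quasi-steady state.
#' @return An object of class `annealing_schedule`.
#' @export
annealing_schedule <- function(n_rounds = 2, hot_temperature = 348.15,
                               hold_seconds = 60, cool_seconds = 180,
                               cooling_time_constant = 30,
                               ambient_temperature = 298,
                               round_seconds = NULL) {
  if (!is.numeric(n_rounds) || n_rounds < 1 || n_rounds != round(n_rounds))
    stop("`n_rounds` must be an integer >= 1")
  for (nm in c("hot_temperature", "hold_seconds", "cool_seconds",
               "cooling_time_constant", "ambient_temperature")) {
    if (get(nm) <= 0) stop(sprintf("`%s` must be positive", nm))
  }
  if (!is.null(round_seconds) && round_seconds <= 0)
    stop("`round_seconds` must be positive when given")
  structure(
    list(n_rounds = as.integer(n_rounds),
         hot_temperature = hot_temperature,
         hold_seconds = hold_seconds, cool_seconds = cool_seconds,
         cooling_time_constant = cooling_time_constant,
         ambient_temperature = ambient_temperature,
         round_seconds = round_seconds),
    class = "annealing_schedule")
}

#' Exponential cooling profile
#'
#' Device temperature during one cooling interval,
#' `T(t) = T_ambient + (T_hot - T_ambient) exp(-t / tau)`, as observed by
#' thermal imaging of the device. Purely descriptive: the gelation model is
#' isothermal at ambient and does not consume this profile.
#'
#' @param schedule An [annealing_schedule()].
#' @param t Time(s) since the start of cooling, seconds (>= 0).
#' @return Temperature(s) in kelvin.
#' @export
cooling_profile <- function(schedule, t) {
  stopifnot(inherits(schedule, "annealing_schedule"))
  if (schedule$cooling_time_constant <= 0)
    stop("`cooling_time_constant` must be positive")
  if (any(t < 0)) stop("`t` must be >= 0")
  schedule$ambient_temperature +
    (schedule$hot_temperature - schedule$ambient_temperature) *
    exp(-t / schedule$cooling_time_constant)
}

#' Run repeated annealing rounds
#'
#' Each round integrates the gelation kinetics (by default to quasi-steady
#' state, since gelation is far faster than the cooling interval); at each
#' round boundary the aggregate fully dissociates (`N_u <- N_u + N_g`,
#' `N_g <- 0`) and kinetics restart. Motifs already lost to the PEG phase
#' never return, so each extra round exposes the re-dissociated motifs to
#' further diffusive loss.
#'
#' @inheritParams solve_kinetics
#' @param schedule An [annealing_schedule()].
#' @return A `gelwell_trajectory` concatenated over rounds, with an extra
#'   `round` column. The dissociation reset appears as a repeated time
#'   point at each round boundary.
#' @export
run_annealing <- function(rates, N0, schedule = annealing_schedule(),
                          rel_tol = 1e-9) {
  stopifnot(inherits(schedule, "annealing_schedule"))
  pieces <- vector("list", schedule$n_rounds)
  nu <- N0
  offset <- 0
  lost <- 0
  for (k in seq_len(schedule$n_rounds)) {
    traj <- if (is.null(schedule$round_seconds)) {
      solve_to_steady(rates, nu, rel_tol = rel_tol)
    } else {
      solve_kinetics(rates, nu, t_end = schedule$round_seconds,
                     rel_tol = rel_tol)
    }
    piece <- as.data.frame(traj)
    piece$t_s <- piece$t_s + offset
    piece$N_lost <- piece$N_lost + lost
    piece$round <- k
    pieces[[k]] <- piece
    last <- piece[nrow(piece), ]
    offset <- last$t_s
    lost <- last$N_lost
    nu <- last$N_u + last$N_g  # full dissociation at the round boundary
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  new_trajectory(out, rates, N0)
}
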