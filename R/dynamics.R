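#' Phosphorylation dynamics scenario
#'
#' The linear model of reversible phosphorylation of a protein Y whose
#' unphosphorylated form is not rate-limiting: `dY^P/dt = k - p * Y^P`,
#' with kinase activity rate `k` (amount per unit time) and phosphatase
#' activity rate `p` (per unit time). The derived steady state is
#' `k / p` and the response time (time to reach half the steady state,
#' starting from zero) is `ln(2) / p`, independent of `k`.
#'
#' @param k kinase activity rate, `>= 0`.
#' @param p phosphatase activity rate, `> 0`.
#' @param label scenario label.
#' @return an object of class `dynamics_scenario` with elements `k`, `p`,
#'   `steady_state`, `t_half`, `label`.
#' @export
dynamics_scenario <- function(k, p, label = sprintf("k=%g, p=%g", k, p)) {
  if (!is.numeric(k) || is.na(k) || k < 0) stop("dynamics_scenario: k must be >= 0")
  structure(
    list(k = k, p = p, steady_state = steady_state(k, p),
         t_half = response_time(p), label = label),
    class = "dynamics_scenario"
  )
}

#' @export
print.dynamics_scenario <- function(x, ...) {
  cat(sprintf("scenario '%s': k=%g, p=%g, steady state=%g, t_1/2=%g\n",
              x$label, x$k, x$p, x$steady_state, x$t_half))
  invisible(x)
}

#' Steady-state level of the phosphorylated protein
#'
#' @param k kinase activity rate.
#' @param p phosphatase activity rate, `> 0`.
#' @return `k / p`.
#' @export
steady_state <- function(k, p) {
  if (!is.numeric(p) || is.na(p) || p <= 0) stop("steady_state: p must be > 0")
  k / p
}

#' Response time of the phosphorylation system
#'
#' Time at which the phosphorylated level reaches half its steady state when
#' accumulating from zero: `ln(2) / p`. Independent of the kinase rate `k`.
#'
#' @param p phosphatase activity rate, `> 0`.
#' @return `log(2) / p`.
#' @export
response_time <- function(p) {
  if (!is.numeric(p) || is.na(p) || p <= 0) stop("response_time: p must be > 0")
  log(2) / p
}

new_trajectory <- function(time, yp, provenance, scenario) {
  structure(
    data.frame(time = time, yp = yp),
    provenance = provenance, scenario = scenario,
    class = c("trajectory", "data.frame")
  )
}

check_grid <- function(t_grid, from_zero = TRUE) {
  if (length(t_grid) < 2 || any(diff(t_grid) <= 0)) {
    stop("time grid must be strictly increasing")
  }
  if (from_zero && t_grid[1] != 0) stop("time grid must start at 0")
  invisible(t_grid)
}

#' Closed-form accumulation trajectory
#'
#' The analytic solution of `dY^P/dt = k - p Y^P` starting from zero:
#' `Y^P(t) = (k/p) * (1 - exp(-p t))`.
#'
#' @param scenario a [dynamics_scenario()].
#' @param t_grid strictly increasing time grid starting at 0.
#' @return a `trajectory` data frame with columns `time` and `yp`.
#' @export
analytic_trajectory <- function(scenario, t_grid) {
  stopifnot(inherits(scenario, "dynamics_scenario"))
  check_grid(t_grid)
  yp <- scenario$steady_state * (1 - exp(-scenario$p * t_grid))
  new_trajectory(t_grid, yp, "analytic", scenario)
}

rk4_step <- function(f, y, h) {
  k1 <- f(y)
  k2 <- f(y + h / 2 * k1)
  k3 <- f(y + h / 2 * k2)
  k4 <- f(y + h * k3)
  y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

rk4_at_grid <- function(f, y0, t_grid, substeps) {
  yp <- numeric(length(t_grid))
  yp[1] <- y <- y0
  for (i in seq_len(length(t_grid) - 1)) {
    h <- (t_grid[i + 1] - t_grid[i]) / substeps
    for (s in seq_len(substeps)) y <- rk4_step(f, y, h)
    yp[i + 1] <- y
  }
  yp
}

#' Numerically integrated trajectory
#'
#' Fixed-step classical fourth-order Runge-Kutta integration of
#' `dY^P/dt = k - p Y^P` from an arbitrary initial value. The substep count
#' is doubled until halving the step changes no grid value by more than
#' `tol`; failure to converge (divergent values) raises an error.
#'
#' @param scenario a [dynamics_scenario()].
#' @param t_grid strictly increasing time grid.
#' @param y0 initial phosphorylated level, `>= 0`.
#' @param tol step-halving convergence tolerance.
#' @return a `trajectory` data frame.
#' @export
numeric_trajectory <- function(scenario, t_grid, y0 = 0, tol = 1e-9) {
  stopifnot(inherits(scenario, "dynamics_scenario"))
  check_grid(t_grid, from_zero = FALSE)
  if (!is.numeric(y0) || is.na(y0) || y0 < 0) {
    stop("numeric_trajectory: y0 must be >= 0")
  }
  f <- function(y) scenario$k - scenario$p * y
  substeps <- 1L
  yp <- rk4_at_grid(f, y0, t_grid, substeps)
  repeat {
    yp2 <- rk4_at_grid(f, y0, t_grid, substeps * 2L)
    if (any(!is.finite(yp2))) stop("numeric_trajectory: integration diverged")
    if (max(abs(yp2 - yp)) <= tol) break
    substeps <- substeps * 2L
    yp <- yp2
    if (substeps > 2^16) stop("numeric_trajectory: step instability, no convergence")
  }
  new_trajectory(t_grid, yp2, "numeric", scenario)
}

#' Empirical half-rise time of a trajectory
#'
#' Time at which the trajectory first crosses half the steady state (or half
#' an explicit target level), located by linear interpolation between the
#' bracketing grid points.
#'
#' @param trajectory a `trajectory` data frame.
#' @param level level whose half is sought; defaults to the scenario steady
#'   state.
#' @return interpolated crossing time.
#' @export
half_rise_time <- function(trajectory, level = NULL) {
  stopifnot(inherits(trajectory, "trajectory"))
  scen <- attr(trajectory, "scenario")
  level <- level %||% scen$steady_state
  target <- level / 2
  yp <- trajectory$yp
  tt <- trajectory$time
  i <- which(yp >= target)[1]
  if (is.na(i)) stop("half_rise_time: trajectory never reaches half the level")
  if (i == 1) return(tt[1])
  t0 <- tt[i - 1]
  t1 <- tt[i]
  y0 <- yp[i - 1]
  y1 <- yp[i]
  t0 + (target - y0) / (y1 - y0) * (t1 - t0)
}

#' Compare two dynamics scenarios
#'
#' Contrasts a baseline and a variant scenario: the steady-state fold change
#' and response-time ratio, both analytically and as measured on numerically
#' integrated trajectories (empirical half-rise by linear interpolation).
#' Doubling the kinase rate doubles the steady state at unchanged response
#' time; halving the phosphatase rate doubles both.
#'
#' @param baseline,variant [dynamics_scenario()] objects.
#' @param t_grid optional shared time grid; defaults to 2001 points spanning
#'   ten response times of the slower scenario.
#' @return list with `steady_state_fold`, `t_half_ratio`,
#'   `empirical_t_half_ratio`, and the per-scenario empirical half-rise
#'   times.
#' @export
compare_scenarios <- function(baseline, variant, t_grid = NULL) {
  stopifnot(inherits(baseline, "dynamics_scenario"),
            inherits(variant, "dynamics_scenario"))
  if (is.null(t_grid)) {
    horizon <- 10 / min(baseline$p, variant$p)
    t_grid <- seq(0, horizon, length.out = 2001)
  }
  tb <- numeric_trajectory(baseline, t_grid)
  tv <- numeric_trajectory(variant, t_grid)
  hb <- half_rise_time(tb)
  hv <- half_rise_time(tv)
  list(
    baseline = baseline$label,
    variant = variant$label,
    steady_state_fold = variant$steady_state / baseline$steady_state,
    t_half_ratio = variant$t_half / baseline$t_half,
    empirical_t_half_baseline = hb,
    empirical_t_half_variant = hv,
    empirical_t_half_ratio = hv / hb
  )
}

#' Write a trajectory as a two-column TSV
#'
#' @param trajectory a `trajectory`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_trajectory <- function(trajectory, path) {
  write.table(as.data.frame(trajectory), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
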