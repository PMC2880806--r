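#' Configuration of the bistable double-well stochastic-resonance model
#'
#' Overdamped Langevin dynamics in a reflection-symmetric quartic potential
#' `U(x) = -c2 x^2 / 2 + c4 x^4 / 4` with weak periodic forcing:
#' `dx/dt = -U'(x) + A sin(omega t + phi) + xi(t)`. With the canonical
#' coefficients `c2 = c4 = 1` the stable minima sit at `x = -1, +1` and the
#' barrier height between them is `DeltaU = c2^2 / (4 c4) = 1/4`.
#'
#' @param A forcing amplitude, `>= 0`.
#' @param omega angular forcing frequency (rad per time unit).
#' @param phi initial phase.
#' @param noise a [noise_spec()].
#' @param x0 initial position.
#' @param grid a [time_grid()].
#' @param c2,c4 quartic coefficients, both `> 0`.
#' @return object of class `double_well_config`.
#' @export
double_well_config <- function(A = 0.1, omega = 0.1, phi = 0,
                               noise = noise_spec("white", sd = 0),
                               x0 = 1, grid = time_grid(0.01, 10000),
                               c2 = 1, c4 = 1) {
  if (!is.finite(c2) || c2 <= 0 || !is.finite(c4) || c4 <= 0)
    stop_param("'c2' and 'c4' must be positive (double-well shape)")
  if (!is.finite(A) || A < 0) stop_param("'A' must be >= 0")
  stopifnot(inherits(noise, "noise_spec"), inherits(grid, "time_grid"))
  structure(list(A = A, omega = omega, phi = phi, noise = noise,
                 x0 = x0, grid = grid, c2 = c2, c4 = c4),
            class = "double_well_config")
}

#' Quartic double-well potential
#'
#' `U(x) = -c2 x^2/2 + c4 x^4/4`; reflection-symmetric, `U(x) = U(-x)`, with
#' stable minima at `x = +- sqrt(c2/c4)`.
#'
#' @param cfg a [double_well_config()].
#' @param x position(s).
#' @return potential value(s).
#' @export
#' @examples
#' cfg <- double_well_config()
#' dw_potential(cfg, c(-1, 0, 1)) # c(-1/4, 0, -1/4)
dw_potential <- function(cfg, x) {
  stopifnot(inherits(cfg, "double_well_config"))
  -cfg$c2 * x^2 / 2 + cfg$c4 * x^4 / 4
}

#' Stable minima and barrier height of the double well
#' @param cfg a [double_well_config()].
#' @return list with `minima` (the two stable positions), `barrier`
#'   (`U(0) - U(minima)`).
#' @export
dw_geometry <- function(cfg) {
  xm <- sqrt(cfg$c2 / cfg$c4)
  list(minima = c(-xm, xm),
       barrier = dw_potential(cfg, 0) - dw_potential(cfg, xm))
}

# drift of Eq.-type dx/dt = -U'(x) + A sin(omega t + phi)
dw_drift <- function(cfg) {
  force(cfg)
  function(t, x) {
    cfg$c2 * x - cfg$c4 * x^3 + cfg$A * sin(cfg$omega * t + cfg$phi)
  }
}

#' Simulate the double-well Langevin system
#'
#' Fixed-step RK4 on the deterministic drift with the step's noise value held
#' constant within the step (see [integrate_fixed_step()]).
#'
#' @param cfg a [double_well_config()].
#' @param seed integer RNG seed for the noise path.
#' @return a `trajectory` with one state column `x`.
#' @export
simulate_double_well <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "double_well_config"))
  xi <- noise_path(cfg$noise, cfg$grid, seed)
  n <- cfg$grid$n_steps
  dt <- cfg$grid$dt
  h2 <- dt / 2
  c2 <- cfg$c2; c4 <- cfg$c4; A <- cfg$A; om <- cfg$omega; ph <- cfg$phi
  xs <- numeric(n + 1L)
  x <- cfg$x0
  xs[1L] <- x
  t <- cfg$grid$t0
  f <- function(t, x) c2 * x - c4 * x^3 + A * sin(om * t + ph)
  for (k in seq_len(n)) {
    e <- xi[k]
    k1 <- f(t, x) + e
    k2 <- f(t + h2, x + h2 * k1) + e
    k3 <- f(t + h2, x + h2 * k2) + e
    k4 <- f(t + dt, x + dt * k3) + e
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!is.finite(x) || abs(x) > 1e6)
      stop("integration diverged at step ", k, call. = FALSE)
    xs[k + 1L] <- x
    t <- cfg$grid$t0 + k * dt
  }
  trajectory(cfg$grid, matrix(xs, ncol = 1L), labels = "x")
}

#' Detect well-to-well transitions with two-threshold hysteresis
#'
#' A transition is recorded when the trajectory, last seen beyond one
#' threshold, crosses beyond the opposite one; excursions that stay between
#' the thresholds (intra-well jitter) are ignored.
#'
#' @param traj one-dimensional `trajectory`.
#' @param thresholds length-2 numeric `c(lo, hi)` with `lo < 0 < hi`
#'   (default `c(-0.5, 0.5)`, half the canonical minimum).
#' @return data frame with columns `time` and `sign` (+1 for an upward,
#'   -1 for a downward transition); zero rows when no transition occurs.
#' @export
well_transitions <- function(traj, thresholds = c(-0.5, 0.5)) {
  stopifnot(inherits(traj, "trajectory"))
  if (ncol(traj$states) != 1L) stop_param("expected a 1-D trajectory")
  lo <- thresholds[1]; hi <- thresholds[2]
  if (!(lo < 0 && hi > 0)) stop_param("thresholds must straddle 0")
  x <- traj$states[, 1L]
  tt <- grid_times(traj$grid)
  # side: +1 above hi, -1 below lo, 0 in the dead band
  side <- ifelse(x >= hi, 1L, ifelse(x <= lo, -1L, 0L))
  times <- numeric(0); signs <- integer(0)
  cur <- side[which(side != 0L)[1]]
  if (is.na(cur)) return(data.frame(time = numeric(0), sign = integer(0)))
  for (i in seq_along(x)) {
    s <- side[i]
    if (s != 0L && s != cur) {
      times <- c(times, tt[i]); signs <- c(signs, s)
      cur <- s
    }
  }
  data.frame(time = times, sign = signs)
}

#' Spectral amplification at the forcing frequency
#'
#' Periodogram power of the trajectory at the bin nearest the forcing
#' frequency, divided by the median periodogram power over the local
#' background band (bins within +-20 percent of the forcing frequency,
#' excluding the signal bin). A unitless stochastic-resonance response:
#' about 1 for pure noise, large when power concentrates at the forcing
#' frequency.
#'
#' @param traj one-dimensional `trajectory` covering at least ~20 forcing
#'   periods for a usable estimate.
#' @param omega angular forcing frequency (rad per time unit); must lie in
#'   the resolvable band (above one cycle per record, below Nyquist).
#' @return single numeric response value.
#' @export
spectral_amplification <- function(traj, omega) {
  stopifnot(inherits(traj, "trajectory"))
  if (ncol(traj$states) != 1L) stop_param("expected a 1-D trajectory")
  x <- traj$states[, 1L]
  n <- length(x)
  dt <- traj$grid$dt
  f_target <- omega / (2 * pi)            # cycles per time unit
  f_min <- 1 / (n * dt)
  f_nyq <- 1 / (2 * dt)
  if (!is.finite(f_target) || f_target < f_min || f_target > f_nyq)
    stop_param("omega outside the resolvable band [2*pi/T, pi/dt]")
  x <- x - mean(x)
  p <- Mod(stats::fft(x))^2 / n^2
  k <- seq_len(floor(n / 2))              # positive-frequency bins
  freq <- k / (n * dt)
  pk <- p[k + 1L]
  i_sig <- which.min(abs(freq - f_target))
  band <- which(freq >= 0.8 * f_target & freq <= 1.2 * f_target)
  band <- setdiff(band, i_sig)
  if (length(band) < 3L) {                # widen for very short records
    band <- setdiff(order(abs(freq - f_target))[1:8], i_sig)
  }
  bg <- stats::median(pk[band])
  if (bg <= 0) return(Inf)
  pk[i_sig] / bg
}
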