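#' Uniform time grid for fixed-step integration
#'
#' @param dt step size in model time units (ms for the neuron models,
#'   arbitrary for the double well); must be positive.
#' @param n_steps number of integration steps (at least 1).
#' @param t0 start time (default 0).
#' @return an object of class `time_grid` with fields `dt`, `n_steps`, `t0`.
#' @export
#' @examples
#' g <- time_grid(dt = 0.02, n_steps = 1000)
#' head(grid_times(g))
time_grid <- function(dt, n_steps, t0 = 0) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop_param("'dt' must be a single positive number")
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1L)
    stop_param("'n_steps' must be a positive integer")
  structure(list(dt = dt, n_steps = n_steps, t0 = t0), class = "time_grid")
}

#' Times of a grid
#' @param grid a [time_grid()].
#' @return numeric vector `t0 + k*dt`, `k = 0..n_steps`.
#' @export
grid_times <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  grid$t0 + grid$dt * (0:grid$n_steps)
}

#' Noise process specification
#'
#' Describes the noise forcing injected into a simulator. `white` noise is a
#' sequence of independent zero-mean Gaussians whose standard deviation `sd`
#' is the per-step value of the forcing term, in the force/current units of
#' the driven state equation (the term is held constant within each step; see
#' [integrate_fixed_step()]). `ou` noise is a stationary Ornstein-Uhlenbeck
#' process with intensity `D` and correlation time `tau`, autocovariance
#' `(D/tau) * exp(-lag/tau)`.
#'
#' @param kind `"white"` or `"ou"`.
#' @param sd per-step standard deviation (white noise).
#' @param D intensity of the coloured noise (ou).
#' @param tau correlation time (ou), must be positive.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("white", "ou"), sd = 0, D = 0, tau = 1) {
  kind <- match.arg(kind)
  if (kind == "white") {
    if (!is.finite(sd) || sd < 0) stop_param("'sd' must be >= 0")
  } else {
    if (!is.finite(D) || D < 0) stop_param("'D' must be >= 0")
    if (!is.finite(tau) || tau <= 0) stop_param("'tau' must be > 0")
  }
  structure(list(kind = kind, sd = sd, D = D, tau = tau), class = "noise_spec")
}

#' Seeded white-noise path
#'
#' One independent zero-mean Gaussian draw per integration step. The standard
#' deviation is a per-step value in the units of the forcing term it is added
#' to; no sqrt(dt) scaling is applied (the per-step convention is documented
#' in [integrate_fixed_step()]).
#'
#' @param grid a [time_grid()].
#' @param sd standard deviation, `>= 0`.
#' @param seed integer RNG seed; identical `(grid, sd, seed)` give identical
#'   sequences.
#' @return numeric vector of length `n_steps`.
#' @export
white_noise_path <- function(grid, sd, seed) {
  stopifnot(inherits(grid, "time_grid"))
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0)
    stop_param("'sd' must be a single nonnegative number")
  if (sd == 0) return(numeric(grid$n_steps))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  stats::rnorm(grid$n_steps, mean = 0, sd = sd)
}

#' Seeded stationary Ornstein-Uhlenbeck path
#'
#' Exact discretization of `dx = -(x/tau) dt + sqrt(2D)/tau ... ` scaled so
#' the stationary variance is `D/tau` and the autocovariance at lag `l` is
#' `(D/tau) * exp(-l/tau)`. The initial value is drawn from the stationary
#' distribution, so the whole path is stationary.
#'
#' @inheritParams white_noise_path
#' @param D noise intensity, `>= 0`.
#' @param tau correlation time, `> 0`.
#' @return numeric vector of length `n_steps`.
#' @export
ou_path <- function(grid, D, tau, seed) {
  stopifnot(inherits(grid, "time_grid"))
  if (!is.finite(tau) || tau <= 0) stop_param("'tau' must be > 0")
  if (!is.finite(D) || D < 0) stop_param("'D' must be >= 0")
  n <- grid$n_steps
  if (D == 0) return(numeric(n))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  rho <- exp(-grid$dt / tau)
  sig_st <- sqrt(D / tau)              # stationary sd
  sig_in <- sig_st * sqrt(1 - rho^2)   # innovation sd (exact update)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sig_st)
  if (n > 1) {
    eps <- stats::rnorm(n - 1, 0, sig_in)
    for (k in 2:n) x[k] <- rho * x[k - 1] + eps[k - 1]
  }
  x
}

#' Realize a noise spec on a grid
#' @param noise a [noise_spec()].
#' @param grid a [time_grid()].
#' @param seed integer seed.
#' @return numeric vector of length `n_steps`.
#' @export
noise_path <- function(noise, grid, seed) {
  stopifnot(inherits(noise, "noise_spec"))
  switch(noise$kind,
    white = white_noise_path(grid, noise$sd, seed),
    ou    = ou_path(grid, noise$D, noise$tau, seed)
  )
}

#' Fixed-step Runge-Kutta integration with per-step additive noise
#'
#' Classical fourth-order Runge-Kutta on the deterministic drift. The noise
#' enters as a piecewise-constant additive term on the state derivative: the
#' step's noise value is held fixed across the four RK stages of that step
#' (the convention used by the stochastic neuron simulations in this
#' package). Two implementations sharing a noise sequence therefore agree to
#' floating-point roundoff. Results depend on the step size convention: the
#' per-step noise value has the units of the drift, not of the state.
#'
#' @param drift function `f(t, x)` returning the state derivative (numeric
#'   vector of the state dimension).
#' @param grid a [time_grid()].
#' @param x0 initial state (numeric vector).
#' @param noise `NULL` (no noise) or a numeric matrix with `n_steps` rows and
#'   one column per state coordinate, added to the drift during each step. A
#'   vector is accepted for one-dimensional states.
#' @param labels optional state-variable names.
#' @param bound divergence guard: integration aborts with an error naming the
#'   step when any `|state|` exceeds this or becomes non-finite.
#' @return a `trajectory` object: list with `grid`, `states` (matrix of
#'   `n_steps + 1` rows), `labels`.
#' @export
#' @examples
#' g <- time_grid(0.02, 1000)
#' tr <- integrate_fixed_step(function(t, x) -x, g, x0 = 1)
#' abs(tail(tr$states[, 1], 1) - exp(-20)) < 1e-8
integrate_fixed_step <- function(drift, grid, x0, noise = NULL,
                                 labels = NULL, bound = 1e6) {
  stopifnot(inherits(grid, "time_grid"), is.function(drift))
  x0 <- as.numeric(x0)
  d <- length(x0)
  n <- grid$n_steps
  dt <- grid$dt
  if (!is.null(noise)) {
    if (is.null(dim(noise))) noise <- matrix(noise, ncol = 1L)
    if (nrow(noise) < n || ncol(noise) != d)
      stop_param("noise must have >= n_steps rows and one column per state")
  }
  states <- matrix(NA_real_, n + 1L, d)
  states[1L, ] <- x0
  x <- x0
  t <- grid$t0
  h2 <- dt / 2
  for (k in seq_len(n)) {
    xi <- if (is.null(noise)) 0 else noise[k, ]
    k1 <- drift(t, x) + xi
    k2 <- drift(t + h2, x + h2 * k1) + xi
    k3 <- drift(t + h2, x + h2 * k2) + xi
    k4 <- drift(t + dt, x + dt * k3) + xi
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(x)) || any(abs(x) > bound))
      stop("integration diverged at step ", k, " (t = ", signif(t + dt, 6), ")",
           call. = FALSE)
    states[k + 1L, ] <- x
    t <- grid$t0 + k * dt
  }
  trajectory(grid, states, labels = labels %||% paste0("x", seq_len(d)))
}

#' Trajectory container
#'
#' @param grid a [time_grid()].
#' @param states numeric matrix with `n_steps + 1` rows (one per grid time)
#'   and one column per state variable; all entries finite.
#' @param labels character vector of column names.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(grid, states, labels = NULL) {
  stopifnot(inherits(grid, "time_grid"))
  states <- as.matrix(states)
  if (nrow(states) != grid$n_steps + 1L)
    stop_param("states must have n_steps + 1 rows")
  if (any(!is.finite(states))) stop_param("states must be finite")
  labels <- labels %||% colnames(states) %||% paste0("x", seq_len(ncol(states)))
  colnames(states) <- labels
  structure(list(grid = grid, states = states, labels = labels),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", ncol(x$states), " state variable(s) [",
      paste(x$labels, collapse = ", "), "], ",
      x$grid$n_steps, " steps, dt = ", x$grid$dt, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time = grid_times(x$grid), x$states, check.names = FALSE)
}

#' @export
plot.trajectory <- function(x, which = 1L, ...) {
  graphics::plot(grid_times(x$grid), x$states[, which], type = "l",
                 xlab = "time", ylab = x$labels[which], ...)
}

#' Write a trajectory as TSV (time column + one column per state)
#' @param traj a `trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(as.data.frame(traj), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
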