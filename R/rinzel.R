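#' Rinzel-reduced Hodgkin-Huxley neuron: model constants
#'
#' Two-variable (voltage V, recovery R) reduction of the Hodgkin-Huxley
#' equations. Voltage is dimensionless (units of ~100 mV), time in ms:
#' \deqn{C dV/dt = -(a + b V + c V^2)(V - E_{Na}) - d R (V - E_K) + I(t)}
#' \deqn{dR/dt = (-R + R_\infty(V)) / \tau_R,\qquad R_\infty(V) = r_0 + r_1 V.}
#' Defaults are the published simulation constants: `a = 17.81`, `b = 47.71`,
#' `c = 32.63`, `d = 26`, `E_Na = 0.55`, `E_K = -0.92`, `C = 0.8`,
#' `tau_R = 1.9` ms, integration step `dt = 0.02` ms, and the affine
#' steady-state recovery law `R_inf(V) = 1.03 + 1.35 V`.
#'
#' @param a,b,c,d polynomial conductance coefficients.
#' @param E_Na,E_K sodium / potassium equilibrium potentials (`E_K < E_Na`).
#' @param C membrane capacitance-like constant, `> 0`.
#' @param tau_R recovery time constant (ms), `> 0`.
#' @param dt integration step (ms), `> 0`.
#' @param r0,r1 coefficients of the affine recovery law `R_inf(V) = r0 + r1 V`.
#' @return object of class `rinzel_config`.
#' @export
rinzel_config <- function(a = 17.81, b = 47.71, c = 32.63, d = 26,
                          E_Na = 0.55, E_K = -0.92, C = 0.8,
                          tau_R = 1.9, dt = 0.02, r0 = 1.03, r1 = 1.35) {
  if (C <= 0) stop_param("'C' must be > 0")
  if (tau_R <= 0) stop_param("'tau_R' must be > 0")
  if (dt <= 0) stop_param("'dt' must be > 0")
  if (E_K >= E_Na) stop_param("'E_K' must be below 'E_Na'")
  structure(list(a = a, b = b, c = c, d = d, E_Na = E_Na, E_K = E_K,
                 C = C, tau_R = tau_R, dt = dt, r0 = r0, r1 = r1),
            class = "rinzel_config")
}

#' Sinusoidal drive plus current noise
#'
#' The stimulus `I(t) = A sin(2 pi freq_hz t / 1000 + phi)` (t in ms) with
#' zero-mean Gaussian current noise added per integration step. Defaults are
#' the published drive: amplitude 0.035 (a.u.) at 200 Hz (period 5 ms),
#' initial phase 0.
#'
#' @param A stimulus amplitude, `>= 0`.
#' @param freq_hz drive frequency in Hz, `> 0`.
#' @param phi initial phase (rad).
#' @param noise a [noise_spec()]; default white with `sd = 0`.
#' @return object of class `drive_spec`.
#' @export
drive_spec <- function(A = 0.035, freq_hz = 200, phi = 0,
                       noise = noise_spec("white", sd = 0)) {
  if (!is.finite(A) || A < 0) stop_param("'A' must be >= 0")
  if (!is.finite(freq_hz) || freq_hz <= 0) stop_param("'freq_hz' must be > 0")
  stopifnot(inherits(noise, "noise_spec"))
  structure(list(A = A, freq_hz = freq_hz, phi = phi, noise = noise),
            class = "drive_spec")
}

#' State derivatives of the Rinzel-reduced neuron
#'
#' @param cfg a [rinzel_config()].
#' @param V membrane voltage (dimensionless).
#' @param R recovery variable.
#' @param I instantaneous injected current.
#' @return numeric `c(dV, dR)` in per-ms units.
#' @export
rinzel_derivatives <- function(cfg, V, R, I = 0) {
  stopifnot(inherits(cfg, "rinzel_config"))
  dV <- (-(cfg$a + cfg$b * V + cfg$c * V^2) * (V - cfg$E_Na) -
           cfg$d * R * (V - cfg$E_K) + I) / cfg$C
  dR <- (-R + cfg$r0 + cfg$r1 * V) / cfg$tau_R
  c(dV, dR)
}

#' Resting equilibrium of the zero-drive neuron
#'
#' Root of the voltage nullcline with `R = R_inf(V)`, located numerically on
#' the hyperpolarized branch.
#'
#' @param cfg a [rinzel_config()].
#' @param interval search interval for the resting voltage.
#' @return numeric `c(V, R)` at rest.
#' @export
rinzel_resting_state <- function(cfg, interval = c(-1, 0)) {
  f <- function(V) {
    R <- cfg$r0 + cfg$r1 * V
    -(cfg$a + cfg$b * V + cfg$c * V^2) * (V - cfg$E_Na) -
      cfg$d * R * (V - cfg$E_K)
  }
  Vr <- stats::uniroot(f, interval, tol = 1e-12)$root
  c(V = Vr, R = cfg$r0 + cfg$r1 * Vr)
}

#' Simulate the noise-driven Rinzel neuron
#'
#' RK4 at the configured step with the step's noise value added to the
#' stimulus current and held constant within the step (same scheme as
#' [integrate_fixed_step()], inlined for speed; the two paths agree to
#' floating-point roundoff on a shared noise sequence). The initial state is
#' the numerically located resting equilibrium.
#'
#' @param cfg a [rinzel_config()].
#' @param drive a [drive_spec()].
#' @param duration simulated span (ms); at least 100 ms for ISI statistics.
#' @param seed integer RNG seed for the current noise.
#' @return `trajectory` with columns `V` and `R`.
#' @export
#' @examples
#' cfg <- rinzel_config()
#' tr <- simulate_rinzel(cfg, drive_spec(noise = noise_spec(sd = 0.19)),
#'                       duration = 200, seed = 1)
simulate_rinzel <- function(cfg, drive, duration = 2000, seed = 1L) {
  stopifnot(inherits(cfg, "rinzel_config"), inherits(drive, "drive_spec"))
  n <- round(duration / cfg$dt)
  grid <- time_grid(cfg$dt, n)
  eta <- noise_path(drive$noise, grid, seed)
  omega <- 2 * pi * drive$freq_hz / 1000   # rad per ms
  a <- cfg$a; b <- cfg$b; cc <- cfg$c; d <- cfg$d
  ENa <- cfg$E_Na; EK <- cfg$E_K; C <- cfg$C
  tauR <- cfg$tau_R; r0 <- cfg$r0; r1 <- cfg$r1
  A <- drive$A; phi <- drive$phi
  dt <- cfg$dt; h2 <- dt / 2
  rest <- rinzel_resting_state(cfg)
  V <- numeric(n + 1L); R <- numeric(n + 1L)
  V[1L] <- rest[1]; R[1L] <- rest[2]
  v <- rest[[1]]; r <- rest[[2]]
  t <- 0
  for (k in seq_len(n)) {
    e <- eta[k]
    I1 <- A * sin(omega * t + phi) + e
    I2 <- A * sin(omega * (t + h2) + phi) + e
    I4 <- A * sin(omega * (t + dt) + phi) + e
    k1v <- (-(a + b * v + cc * v^2) * (v - ENa) - d * r * (v - EK) + I1) / C
    k1r <- (-r + r0 + r1 * v) / tauR
    v2 <- v + h2 * k1v; r2 <- r + h2 * k1r
    k2v <- (-(a + b * v2 + cc * v2^2) * (v2 - ENa) - d * r2 * (v2 - EK) + I2) / C
    k2r <- (-r2 + r0 + r1 * v2) / tauR
    v3 <- v + h2 * k2v; r3 <- r + h2 * k2r
    k3v <- (-(a + b * v3 + cc * v3^2) * (v3 - ENa) - d * r3 * (v3 - EK) + I2) / C
    k3r <- (-r3 + r0 + r1 * v3) / tauR
    v4 <- v + dt * k3v; r4 <- r + dt * k3r
    k4v <- (-(a + b * v4 + cc * v4^2) * (v4 - ENa) - d * r4 * (v4 - EK) + I4) / C
    k4r <- (-r4 + r0 + r1 * v4) / tauR
    v <- v + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
    r <- r + dt / 6 * (k1r + 2 * k2r + 2 * k3r + k4r)
    if (!is.finite(v) || !is.finite(r) || abs(v) > 1e6 || abs(r) > 1e6)
      stop("integration diverged at step ", k, call. = FALSE)
    V[k + 1L] <- v; R[k + 1L] <- r
    t <- k * dt
  }
  trajectory(grid, cbind(V = V, R = R))
}

#' Spike train container
#' @param spike_times strictly increasing spike times (ms).
#' @param duration simulated span (ms).
#' @param flag optional warning flag (e.g. threshold outside trace range).
#' @return object of class `spike_train` with `spike_times`, `isis`,
#'   `duration`.
#' @export
spike_train <- function(spike_times, duration, flag = NULL) {
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times, strictly = TRUE) && length(spike_times) > 1L)
    stop_param("spike times must be strictly increasing")
  if (length(spike_times) && (min(spike_times) < 0 ||
                              max(spike_times) > duration))
    stop_param("spike times must lie within [0, duration]")
  structure(list(spike_times = spike_times,
                 isis = diff(spike_times),
                 duration = duration, flag = flag),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat("<spike_train> ", length(x$spike_times), " spikes over ",
      x$duration, " ms (rate ",
      signif(1000 * length(x$spike_times) / x$duration, 3), " Hz)\n", sep = "")
  invisible(x)
}

#' Detect spikes by upward threshold crossing with a refractory interval
#'
#' @param traj a `trajectory` whose first (or named `V`) column is voltage.
#' @param threshold crossing level (default 0, dimensionless voltage units).
#' @param refractory minimum spike separation (ms, default 1.5).
#' @return a [spike_train()]. When the threshold lies outside the trace's
#'   dynamic range an empty train is returned with `flag =
#'   "threshold_outside_range"`.
#' @export
detect_spikes <- function(traj, threshold = 0, refractory = 1.5) {
  stopifnot(inherits(traj, "trajectory"))
  col <- if ("V" %in% traj$labels) "V" else 1L
  v <- traj$states[, col]
  tt <- grid_times(traj$grid)
  dur <- tt[length(tt)] - tt[1]
  if (threshold >= max(v) || threshold < min(v)) {
    # outside [min(v), max(v)): no upward crossing can exist
    return(spike_train(numeric(0), dur, flag = "threshold_outside_range"))
  }
  up <- which(v[-1L] > threshold & v[-length(v)] <= threshold)
  if (!length(up)) return(spike_train(numeric(0), dur))
  st <- tt[up + 1L]
  keep <- st[1]
  if (length(st) > 1L) {
    last <- st[1]
    for (s in st[-1L]) {
      if (s - last >= refractory) { keep <- c(keep, s); last <- s }
    }
  }
  spike_train(keep, dur)
}

#' Inter-spike-interval statistics
#'
#' Histogram of ISIs with bins centered on integer multiples of `bin_width`
#' (breaks at `(k - 1/2) * bin_width`), so a 5-ms mode is reported as exactly
#' 5 with 1-ms bins. The locking fraction is the share of ISIs within
#' `tolerance` of any positive integer multiple of `period`.
#'
#' @param train a [spike_train()].
#' @param bin_width histogram bin width (ms).
#' @param period forcing period (ms) for the locking fraction (default 5).
#' @param tolerance locking tolerance (ms, default `bin_width / 2`).
#' @return list with `counts`, `centers`, `modal_isi` (center of the
#'   highest-count bin; `NA` with fewer than 2 spikes), `locking_fraction`,
#'   `n_isi`. Empty or singleton trains give a defined empty result.
#' @export
isi_statistics <- function(train, bin_width = 1, period = 5,
                           tolerance = bin_width / 2) {
  isis <- if (inherits(train, "spike_train")) train$isis else as.numeric(train)
  if (length(isis) < 1L) {
    return(list(counts = integer(0), centers = numeric(0),
                modal_isi = NA_real_, locking_fraction = NA_real_,
                n_isi = 0L))
  }
  kmax <- ceiling(max(isis) / bin_width + 0.5)
  breaks <- (seq_len(kmax + 1L) - 1.5) * bin_width  # centers 0, bw, 2bw, ...
  h <- graphics::hist(isis, breaks = breaks, plot = FALSE)
  centers <- (seq_len(kmax) - 1) * bin_width
  counts <- h$counts
  modal <- centers[which.max(counts)]
  mult <- pmax(1, round(isis / period))
  lock <- mean(abs(isis - mult * period) <= tolerance)
  list(counts = counts, centers = centers, modal_isi = modal,
       locking_fraction = lock, n_isi = length(isis))
}

#' Phase locking of a spike train to a periodic drive
#'
#' Vector strength `VS = |mean(exp(2 pi i t_spike / period))|` (1 = every
#' spike at the same drive phase, 0 = phases uniform) together with the mean
#' number of spikes per drive cycle. Their product, `locked_per_cycle`, is
#' the stochastic-resonance response used to compare noise regimes: it
#' vanishes when the neuron is silent, grows as noise recruits phase-locked
#' spikes, and falls again when noise fires the neuron at arbitrary phases.
#' (The ISI-multiple locking fraction of [isi_statistics()] is blind to the
#' latter degradation, because recovery dynamics produce period-length ISIs
#' at any phase.)
#'
#' @param train a [spike_train()].
#' @param period drive period (ms).
#' @return list with `vector_strength`, `spikes_per_cycle`,
#'   `locked_per_cycle`; all 0 for an empty train.
#' @export
phase_locking <- function(train, period) {
  stopifnot(inherits(train, "spike_train"), period > 0)
  sp <- train$spike_times
  n_cycles <- train$duration / period
  if (!length(sp)) {
    return(list(vector_strength = 0, spikes_per_cycle = 0,
                locked_per_cycle = 0))
  }
  vs <- Mod(mean(exp(2i * pi * sp / period)))
  spc <- length(sp) / n_cycles
  list(vector_strength = vs, spikes_per_cycle = spc,
       locked_per_cycle = vs * spc)
}

#' Sweep the current-noise level and tabulate spiking metrics
#'
#' For each noise SD, `reps` independent realizations are simulated with
#' deterministic child seeds; spike rate, modal ISI (on the pooled ISIs) and
#' locking fraction are reported per SD. A diverged replicate is excluded
#' and counted in `n_diverged`.
#'
#' @param cfg a [rinzel_config()].
#' @param drive a [drive_spec()] (its noise SD is overridden per grid value).
#' @param sd_grid numeric vector of noise SDs.
#' @param duration per-replicate span (ms).
#' @param reps replicates per SD.
#' @param seed master seed; child seeds are derived deterministically.
#' @param threshold,refractory spike-detection settings.
#' @param bin_width,period ISI-statistic settings.
#' @return data frame with one row per SD: `sd`, `spike_rate_hz`,
#'   `modal_isi`, `locking_fraction` (ISI-multiple share), `vector_strength`
#'   and `locked_per_cycle` (phase locking pooled over replicates; see
#'   [phase_locking()]), `n_spikes`, `n_diverged`.
#' @export
noise_sweep <- function(cfg, drive, sd_grid, duration = 2000, reps = 1L,
                        seed = 1L, threshold = 0, refractory = 1.5,
                        bin_width = 1, period = NULL) {
  stopifnot(length(sd_grid) >= 1L, reps >= 1L)
  period <- period %||% (1000 / drive$freq_hz)
  rows <- vector("list", length(sd_grid))
  for (i in seq_along(sd_grid)) {
    sdv <- sd_grid[i]
    d_i <- drive
    d_i$noise <- noise_spec("white", sd = sdv)
    isis <- numeric(0); phases <- complex(0)
    n_sp <- 0L; n_div <- 0L; span <- 0
    for (r in seq_len(reps)) {
      s <- child_seed(seed, (i - 1L) * reps + r)
      tr <- tryCatch(simulate_rinzel(cfg, d_i, duration, seed = s),
                     error = function(e) NULL)
      if (is.null(tr)) { n_div <- n_div + 1L; next }
      st <- detect_spikes(tr, threshold, refractory)
      isis <- c(isis, st$isis)
      phases <- c(phases, exp(2i * pi * st$spike_times / period))
      n_sp <- n_sp + length(st$spike_times)
      span <- span + st$duration
    }
    stats <- isi_statistics(isis, bin_width = bin_width, period = period)
    vs <- if (n_sp > 0) Mod(mean(phases)) else 0
    spc <- if (span > 0) n_sp / (span / period) else 0
    rows[[i]] <- data.frame(
      sd = sdv,
      spike_rate_hz = if (span > 0) 1000 * n_sp / span else NA_real_,
      modal_isi = stats$modal_isi,
      locking_fraction = stats$locking_fraction,
      vector_strength = vs,
      locked_per_cycle = vs * spc,
      n_spikes = n_sp,
      n_diverged = n_div)
  }
  do.call(rbind, rows)
}
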