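cfg <- rinzel_config()

test_that("derivatives vanish at the numerically located resting point", {
  rest <- rinzel_resting_state(cfg)
  d <- rinzel_derivatives(cfg, rest["V"], rest["R"], I = 0)
  expect_lt(max(abs(d)), 1e-8)
  # independent oracle: bisection on the zero-drive nullcline
  f <- function(V) rinzel_derivatives(cfg, V, cfg$r0 + cfg$r1 * V, 0)[1]
  lo <- -1; hi <- 0
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
  }
  expect_equal(unname(rest["V"]), (lo + hi) / 2, tolerance = 1e-10)
})

test_that("derivative algebra: sodium cancellation and 1/C linearity", {
  d <- rinzel_derivatives(cfg, V = cfg$E_Na, R = 0, I = 0)
  expect_equal(d[1], 0)
  cfg2 <- rinzel_config(C = 2 * cfg$C)
  d1 <- rinzel_derivatives(cfg, -0.3, 0.2, I = 0.1)
  d2 <- rinzel_derivatives(cfg2, -0.3, 0.2, I = 0.1)
  expect_equal(d2[1], d1[1] / 2)
  expect_equal(d2[2], d1[2]) # recovery unaffected by C
})

test_that("inlined neuron integrator matches the generic RK4 to roundoff", {
  g <- time_grid(cfg$dt, 5000)
  eta <- white_noise_path(g, 0.19, seed = 11)
  tr1 <- simulate_rinzel(cfg, drive_spec(noise = noise_spec(sd = 0.19)),
                         duration = 100, seed = 11)
  drift <- function(t, x)
    rinzel_derivatives(cfg, x[1], x[2], 0.035 * sin(2 * pi * 0.2 * t))
  tr2 <- integrate_fixed_step(drift, g, rinzel_resting_state(cfg),
                              noise = cbind(eta / cfg$C, 0))
  expect_lt(max(abs(tr1$states - tr2$states)), 1e-12)
})

test_that("resting stability: quiescent neuron stays at rest for 500 ms", {
  tr <- simulate_rinzel(cfg, drive_spec(A = 0), duration = 500, seed = 1)
  rest <- rinzel_resting_state(cfg)
  expect_lt(max(abs(tr$states[, 1] - rest["V"])), 1e-6)
  expect_lt(max(abs(tr$states[, 2] - rest["R"])), 1e-6)
})

test_that("voltage stays within the physiological band under strong drive", {
  for (sdv in c(0.19, 0.5)) {
    tr <- simulate_rinzel(cfg, drive_spec(noise = noise_spec(sd = sdv)),
                          duration = 500, seed = 2)
    expect_gt(min(tr$states[, 1]), cfg$E_K - 0.2)
    expect_lt(max(tr$states[, 1]), cfg$E_Na + 0.2)
  }
})

test_that("spike detection handles fixtures, plateaus and bad thresholds", {
  g <- time_grid(0.1, 999)
  flat <- trajectory(g, matrix(-0.7, 1000, 1), labels = "V")
  st <- detect_spikes(flat)
  expect_length(st$spike_times, 0)
  expect_equal(st$flag, "threshold_outside_range")
  # two well-separated 1-ms pulses above threshold
  v <- rep(-0.7, 1000)
  v[200:210] <- 0.4
  v[700:710] <- 0.4
  tr <- trajectory(g, matrix(v, ncol = 1), labels = "V")
  st2 <- detect_spikes(tr)
  expect_equal(st2$spike_times, c(20.0, 70.0), tolerance = 0.02)
  # one pulse with a brief sub-threshold dip: refractory suppresses recount
  v3 <- rep(-0.7, 1000)
  v3[500:505] <- 0.4; v3[506] <- -0.1; v3[507:512] <- 0.4
  expect_length(detect_spikes(trajectory(g, matrix(v3, ncol = 1),
                                         labels = "V"))$spike_times, 1)
})

test_that("ISI statistics on constructed trains", {
  st <- spike_train(c(0, 5, 10, 15), duration = 20)
  s <- isi_statistics(st, bin_width = 1, period = 5, tolerance = 0.5)
  expect_equal(s$modal_isi, 5)
  expect_equal(s$locking_fraction, 1.0)
  s2 <- isi_statistics(c(5, 5, 10, 20), bin_width = 1, period = 5)
  expect_equal(s2$locking_fraction, 1.0)
  expect_equal(s2$modal_isi, 5)
  # empty and singleton trains give defined empty results
  e <- isi_statistics(spike_train(numeric(0), 100))
  expect_equal(e$n_isi, 0L)
  expect_true(is.na(e$modal_isi))
  e1 <- isi_statistics(spike_train(3, 100))
  expect_equal(e1$n_isi, 0L)
})

test_that("phase locking metrics behave on constructed trains", {
  # perfectly periodic at the drive period
  st <- spike_train(seq(0, 95, by = 5), duration = 100)
  pl <- phase_locking(st, period = 5)
  expect_equal(pl$vector_strength, 1)
  expect_equal(pl$spikes_per_cycle, 1)
  # empty train: zero response
  e <- phase_locking(spike_train(numeric(0), 100), period = 5)
  expect_equal(e$locked_per_cycle, 0)
  # phases spread uniformly over the cycle: vanishing vector strength
  u <- spike_train(seq(0, 99.9, by = 5.5555555), duration = 100)
  expect_lt(phase_locking(u, period = 5)$vector_strength, 0.35)
})

test_that("published anchors: silence at SD = 0.01, 5-ms ISI mode at 0.19", {
  tr <- simulate_rinzel(cfg, drive_spec(noise = noise_spec(sd = 0.01)),
                        duration = 2000, seed = 3)
  expect_length(detect_spikes(tr)$spike_times, 0)
  isis <- c()
  for (s in 1:4) {
    tr <- simulate_rinzel(cfg, drive_spec(noise = noise_spec(sd = 0.19)),
                          duration = 2000, seed = child_seed(3, s))
    isis <- c(isis, detect_spikes(tr)$isis)
  }
  expect_equal(isi_statistics(isis, bin_width = 1, period = 5)$modal_isi, 5)
})

test_that("noise alone (no periodic drive) does not produce firing", {
  tr <- simulate_rinzel(cfg, drive_spec(A = 0, noise = noise_spec(sd = 0.04)),
                        duration = 2000, seed = 4)
  expect_length(detect_spikes(tr)$spike_times, 0)
})

test_that("full-sweep SR signature: interior locking maximum, ISI mass at 5 ms", {
  sw <- noise_sweep(cfg, drive_spec(), sd_grid = seq(0.01, 0.5, by = 0.01),
                    duration = 1000, reps = 1, seed = 6)
  i_max <- which.max(sw$locked_per_cycle)
  expect_gt(i_max, 1)
  expect_lt(i_max, nrow(sw))
  # ISI mass at integer multiples of the 5-ms forcing period at the peak
  dr <- drive_spec(noise = noise_spec(sd = sw$sd[i_max]))
  isis <- c()
  for (s in 1:4) {
    tr <- simulate_rinzel(cfg, dr, duration = 1000, seed = child_seed(7, s))
    isis <- c(isis, detect_spikes(tr)$isis)
  }
  mass <- isi_statistics(isis, bin_width = 1, period = 5,
                         tolerance = 1)$locking_fraction
  expect_gt(mass, 0.75)
  # forcing-period consistency: 200 Hz drive = 5 ms period = modal ISI bin
  expect_equal(1000 / drive_spec()$freq_hz, 5)
  expect_equal(isi_statistics(isis, bin_width = 1, period = 5)$modal_isi, 5)
})

test_that("noise sweep is deterministic and reports per-SD metrics", {
  dr <- drive_spec()
  sw1 <- noise_sweep(cfg, dr, c(0.01, 0.19), duration = 300, reps = 2,
                     seed = 5)
  sw2 <- noise_sweep(cfg, dr, c(0.01, 0.19), duration = 300, reps = 2,
                     seed = 5)
  expect_identical(sw1, sw2)
  expect_equal(sw1$n_spikes[1], 0)
  expect_gt(sw1$n_spikes[2], 10)
  expect_equal(sw1$n_diverged, c(0L, 0L))
})
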