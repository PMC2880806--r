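#' Acquisition geometry and timing of the emulated resting-state scan
#'
#' Defaults emulate a typical single-subject resting-state EPI protocol:
#' 256 time frames at TR = 2 s. The default voxel grid (16 x 16 x 8 with an
#' ellipsoidal in-brain mask) is a desk-scale stand-in for a full 64 x 64 x 25
#' acquisition matrix, which remains available as a configuration choice.
#'
#' @param TR sampling interval (s), `> 0`.
#' @param n_frames number of frames, at least 8.
#' @param grid_dims length-3 integer voxel grid.
#' @param mask logical array of `grid_dims` marking in-brain voxels; default
#'   an ellipsoid inscribed in the grid.
#' @return object of class `acquisition_spec` with `TR`, `n_frames`,
#'   `grid_dims`, `mask`, and `voxels` (the masked voxel coordinates, x
#'   fastest, fixing the map-to-matrix linearization).
#' @export
acquisition_spec <- function(TR = 2, n_frames = 256,
                             grid_dims = c(16, 16, 8), mask = NULL) {
  if (TR <= 0) stop_param("'TR' must be > 0")
  if (n_frames < 8) stop_param("'n_frames' must be >= 8")
  grid_dims <- as.integer(grid_dims)
  stopifnot(length(grid_dims) == 3L, all(grid_dims >= 1L))
  if (is.null(mask)) {
    ctr <- (grid_dims + 1) / 2
    ax <- pmax(grid_dims / 2, 0.5)
    g <- expand.grid(x = seq_len(grid_dims[1]), y = seq_len(grid_dims[2]),
                     z = seq_len(grid_dims[3]))
    inside <- ((g$x - ctr[1]) / ax[1])^2 + ((g$y - ctr[2]) / ax[2])^2 +
      ((g$z - ctr[3]) / ax[3])^2 <= 1
    mask <- array(inside, dim = grid_dims)
  }
  stopifnot(identical(dim(mask), grid_dims) || identical(as.integer(dim(mask)), grid_dims))
  if (!any(mask)) stop_param("mask must contain at least one voxel")
  vox <- which(mask, arr.ind = TRUE) # arr.ind is x-fastest (column-major)
  structure(list(TR = TR, n_frames = n_frames, grid_dims = grid_dims,
                 mask = mask, voxels = vox, n_voxels = nrow(vox)),
            class = "acquisition_spec")
}

#' @export
print.acquisition_spec <- function(x, ...) {
  cat("<acquisition_spec> ", paste(x$grid_dims, collapse = " x "),
      " grid, ", x$n_voxels, " in-mask voxels, ", x$n_frames,
      " frames at TR = ", x$TR, " s\n", sep = "")
  invisible(x)
}

#' Compact Gaussian-blob source maps
#'
#' Each of the K spatial "network" maps is a sum of 3-D Gaussian blobs on the
#' masked grid. By default one blob per map, centers drawn inside the mask
#' with enforced pairwise separation of at least twice the blob width, so the
#' maps are mutually near-orthogonal by construction (a warning is issued if
#' separation cannot be achieved).
#'
#' @param spec an [acquisition_spec()].
#' @param K number of maps, `>= 1`.
#' @param centers optional K x 3 matrix of blob centers (voxel units).
#' @param widths blob SD in voxels (recycled to K, default 2).
#' @param amplitudes blob peak amplitudes (recycled, default 1).
#' @param seed integer seed for random center placement.
#' @return matrix `K x n_voxels` of masked map values, with attribute
#'   `"centers"`.
#' @export
make_source_maps <- function(spec, K, centers = NULL, widths = 2,
                             amplitudes = 1, seed = 1L) {
  stopifnot(inherits(spec, "acquisition_spec"), K >= 1)
  widths <- rep_len(widths, K)
  amplitudes <- rep_len(amplitudes, K)
  dims <- spec$grid_dims
  if (is.null(centers)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    centers <- matrix(NA_real_, K, 3)
    min_sep <- 2 * max(widths)
    cand <- spec$voxels
    # keep centers away from the mask edge by ~1 width
    for (k in seq_len(K)) {
      ok <- FALSE
      for (try in seq_len(2000)) {
        ci <- cand[sample.int(nrow(cand), 1L), ]
        if (k == 1L ||
            min(sqrt(rowSums((centers[seq_len(k - 1L), , drop = FALSE] -
                              matrix(ci, k - 1L, 3, byrow = TRUE))^2))) >= min_sep) {
          centers[k, ] <- ci; ok <- TRUE; break
        }
      }
      if (!ok) {
        warning("could not enforce center separation >= 2 x width",
                call. = FALSE)
        centers[k, ] <- cand[sample.int(nrow(cand), 1L), ]
      }
    }
  } else {
    centers <- as.matrix(centers)
    stopifnot(nrow(centers) == K, ncol(centers) == 3L)
    if (any(centers < 1) || any(centers > matrix(dims, K, 3, byrow = TRUE)))
      stop_param("blob center outside the voxel grid")
    d2 <- as.matrix(stats::dist(centers))
    if (K > 1 && min(d2[upper.tri(d2)]) < 2 * max(widths))
      warning("blob centers closer than 2 x width: maps may overlap",
              call. = FALSE)
  }
  S <- matrix(0, K, spec$n_voxels)
  for (k in seq_len(K)) {
    d2 <- (spec$voxels[, 1] - centers[k, 1])^2 +
      (spec$voxels[, 2] - centers[k, 2])^2 +
      (spec$voxels[, 3] - centers[k, 3])^2
    S[k, ] <- amplitudes[k] * exp(-d2 / (2 * widths[k]^2))
  }
  if (any(apply(S, 1, stats::var) == 0))
    stop_param("degenerate source map (zero spatial variance)")
  attr(S, "centers") <- centers
  S
}

#' Canonical double-gamma hemodynamic impulse response
#'
#' Difference of two gamma densities: response peaking near `peak` seconds
#' with an undershoot near `undershoot` seconds of relative amplitude
#' `1/ratio`. Sampled at `dt`-second resolution and truncated at `len`
#' seconds; the kernel integrates to a positive value.
#'
#' @param dt sampling step (s).
#' @param peak,undershoot gamma shape positions (s); defaults 6 and 16.
#' @param ratio peak-to-undershoot amplitude ratio (default 6).
#' @param len kernel length (s, default 32).
#' @return numeric vector of kernel weights.
#' @export
hrf_double_gamma <- function(dt, peak = 6, undershoot = 16, ratio = 6,
                             len = 32) {
  t <- seq(0, len, by = dt)
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    stats::dgamma(t, shape = undershoot, rate = 1) / ratio
  if (sum(h) * dt <= 0) stop_param("kernel must integrate to a positive value")
  h
}

#' Network-model source time courses for the generator
#'
#' Simulates the K-node linear resting-state network at a fast neural step,
#' convolves each node with the hemodynamic kernel (or passes through),
#' samples every TR for `n_frames`, and standardizes each course to zero mean
#' and unit variance. With the default relaxation and kernel the resulting
#' courses concentrate their periodogram power below 0.1 Hz, the signature of
#' resting-state BOLD fluctuations.
#'
#' @param K number of courses.
#' @param spec an [acquisition_spec()].
#' @param network_cfg a [network_config()] with `K` nodes simulated at step
#'   `network_cfg$dt` seconds; default a weakly coupled ring with inverse
#'   relaxation time 0.1 per s at a 0.1-s step.
#' @param hemo `"double_gamma"` (default) or `"passthrough"`.
#' @param seed integer seed.
#' @return matrix `n_frames x K` of standardized courses.
#' @export
make_source_timecourses <- function(K, spec, network_cfg = NULL,
                                    hemo = c("double_gamma", "passthrough"),
                                    seed = 1L) {
  stopifnot(inherits(spec, "acquisition_spec"))
  hemo <- match.arg(hemo)
  if (is.null(network_cfg)) {
    W <- matrix(0, K, K)
    if (K > 1) {
      for (k in seq_len(K)) W[k, k %% K + 1L] <- 0.02
      W <- (W + t(W)) / 2
    }
    network_cfg <- network_config(W, alpha = 0.1, dt = 0.1, noise_sds = 1)
  }
  stopifnot(network_cfg$n == K, network_cfg$dt < spec$TR)
  ndt <- network_cfg$dt
  total_s <- spec$n_frames * spec$TR
  burn <- ceiling(10 / (network_cfg$alpha * ndt)) # several relaxation times
  T_steps <- burn + ceiling(total_s / ndt) + ceiling(40 / ndt)
  prop <- build_propagator(network_cfg$W, network_cfg$alpha, ndt)
  u <- simulate_linear(prop, network_cfg$noise_sds, T_steps, seed = seed)
  u <- u[(burn + 1L):nrow(u), , drop = FALSE]
  if (hemo == "double_gamma") {
    h <- hrf_double_gamma(ndt)
    u <- apply(u, 2, function(x) {
      stats::convolve(x, rev(h), type = "open")[seq_along(x)] * ndt
    })
  }
  stride <- round(spec$TR / ndt)
  idx <- seq(1L, by = stride, length.out = spec$n_frames)
  A <- u[idx, , drop = FALSE]
  A <- scale(A)
  if (any(!is.finite(A)))
    stop("degenerate (constant) source time course", call. = FALSE)
  attr(A, "scaled:center") <- NULL
  attr(A, "scaled:scale") <- NULL
  A
}

#' Assemble the observed 4-D dataset from maps and courses
#'
#' `X = A S + E` with `E` i.i.d. Gaussian of SD `noise_sd`: rows of `X` are
#' time frames, columns the masked voxels (x-fastest linearization). Ground
#' truth (maps, courses, noise level, seed) travels with the data.
#'
#' @param maps `K x n_voxels` source maps ([make_source_maps()]).
#' @param courses `n_frames x K` time courses ([make_source_timecourses()]).
#' @param spec the [acquisition_spec()] the maps were built on.
#' @param noise_sd observation-noise SD (default 0.5, i.e. half the unit
#'   blob amplitude).
#' @param seed integer seed for the noise.
#' @return object of class `fmri_dataset`: list with `X` (frames x voxels),
#'   `spec`, and `ground_truth` (list `S_true`, `A_true`, `noise_sd`,
#'   `seed`).
#' @export
assemble_dataset <- function(maps, courses, spec, noise_sd = 0.5, seed = 1L) {
  stopifnot(inherits(spec, "acquisition_spec"))
  maps <- as.matrix(maps); courses <- as.matrix(courses)
  if (ncol(maps) != spec$n_voxels)
    stop_param("maps do not match the acquisition mask")
  if (nrow(courses) != spec$n_frames)
    stop_param("courses do not match n_frames")
  if (ncol(courses) != nrow(maps))
    stop_param("number of maps and courses disagree")
  X <- courses %*% maps
  if (noise_sd > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    X <- X + matrix(stats::rnorm(length(X), 0, noise_sd), nrow(X), ncol(X))
  }
  structure(list(X = X, spec = spec,
                 ground_truth = list(S_true = maps, A_true = courses,
                                     noise_sd = noise_sd, seed = seed)),
            class = "fmri_dataset")
}

#' @export
print.fmri_dataset <- function(x, ...) {
  cat("<fmri_dataset> ", nrow(x$X), " frames x ", ncol(x$X),
      " masked voxels (grid ", paste(x$spec$grid_dims, collapse = " x "),
      "), K = ", ncol(x$ground_truth$A_true), " true sources, noise sd = ",
      x$ground_truth$noise_sd, "\n", sep = "")
  invisible(x)
}

#' Generate a complete synthetic resting-state dataset
#'
#' Convenience wrapper: maps, network time courses, and mixing with noise,
#' all from one master seed (stage seeds are derived deterministically).
#'
#' @param spec an [acquisition_spec()].
#' @param K number of sources (default 5).
#' @param noise_sd observation-noise SD (default 0.5).
#' @param seed master seed.
#' @param ... passed to [make_source_maps()].
#' @return an `fmri_dataset`.
#' @export
generate_fmri <- function(spec = acquisition_spec(), K = 5, noise_sd = 0.5,
                          seed = 1L, ...) {
  s <- child_seed(seed, 1:3)
  maps <- make_source_maps(spec, K, seed = s[1], ...)
  courses <- make_source_timecourses(K, spec, seed = s[2])
  assemble_dataset(maps, courses, spec, noise_sd = noise_sd, seed = s[3])
}

#' Reshape a masked voxel vector to the 3-D grid
#' @param values length-`n_voxels` vector.
#' @param spec the [acquisition_spec()].
#' @param fill value for out-of-mask voxels.
#' @return 3-D array of `grid_dims`.
#' @export
unmask <- function(values, spec, fill = 0) {
  a <- array(fill, dim = spec$grid_dims)
  a[spec$mask] <- values
  a
}

#' Write / read a dataset as NIfTI-1
#'
#' The 4-D volume (out-of-mask voxels zero) is written with the TR recorded
#' in the header timing field.
#'
#' @param ds an `fmri_dataset`.
#' @param path output `.nii` / `.nii.gz` path.
#' @param spec acquisition spec used to re-mask on reading.
#' @return `write_fmri_nifti`: `path`; `read_fmri_matrix`: the
#'   frames-by-voxels matrix.
#' @export
write_fmri_nifti <- function(ds, path) {
  stopifnot(inherits(ds, "fmri_dataset"))
  dims <- ds$spec$grid_dims
  vol <- array(0, dim = c(dims, ds$spec$n_frames))
  for (i in seq_len(ds$spec$n_frames)) {
    vol[, , , i] <- unmask(ds$X[i, ], ds$spec)
  }
  attr(vol, "pixdim") <- c(1, 1, 1, ds$spec$TR) # TR in the timing slot
  img <- RNifti::asNifti(vol)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write spatial maps as one 3-D NIfTI volume per component
#'
#' @param maps `K x n_voxels` matrix of masked map values (source maps or
#'   Z-maps).
#' @param spec the [acquisition_spec()] defining the grid and mask.
#' @param prefix output path prefix; files are `<prefix>_comp<k>.nii.gz`.
#' @return character vector of the written paths, invisibly.
#' @export
write_maps_nifti <- function(maps, spec, prefix) {
  maps <- as.matrix(maps)
  stopifnot(ncol(maps) == spec$n_voxels)
  paths <- character(nrow(maps))
  for (k in seq_len(nrow(maps))) {
    paths[k] <- paste0(prefix, "_comp", k, ".nii.gz")
    RNifti::writeNifti(RNifti::asNifti(unmask(maps[k, ], spec)), paths[k])
  }
  invisible(paths)
}

#' @rdname write_fmri_nifti
#' @export
read_fmri_matrix <- function(path, spec) {
  vol <- RNifti::readNifti(path)
  stopifnot(length(dim(vol)) == 4L)
  n_frames <- dim(vol)[4]
  X <- matrix(NA_real_, n_frames, spec$n_voxels)
  for (i in seq_len(n_frames)) X[i, ] <- vol[, , , i][spec$mask]
  X
}

#' Periodogram with variance normalization
#'
#' One-sided periodogram of a de-meaned series: the returned powers sum to
#' the series variance (denominator `n`), so Parseval's identity holds
#' exactly. Frequencies run over `k / (n TR)` up to the Nyquist `1/(2 TR)`.
#'
#' @param course numeric series of at least 8 samples.
#' @param TR sampling interval (s).
#' @param segments number of non-overlapping segments to average (Bartlett);
#'   1 (default) gives the raw periodogram. Averaging trades frequency
#'   resolution for lower bin variance.
#' @return data frame with columns `freq` (Hz) and `power`.
#' @export
power_spectrum <- function(course, TR, segments = 1L) {
  course <- as.numeric(course)
  n <- length(course)
  if (n < 8) stop_param("need at least 8 samples")
  segments <- as.integer(segments)
  m <- n %/% segments
  if (segments < 1L || m < 8L)
    stop_param("too many segments for the series length")
  one_sided <- function(x) {
    x <- x - mean(x)
    p <- Mod(stats::fft(x))^2 / m^2
    k <- seq_len(floor(m / 2))
    dbl <- if (m %% 2 == 0) c(rep(2, length(k) - 1L), 1) else rep(2, length(k))
    p[k + 1L] * dbl
  }
  pow <- rowMeans(vapply(seq_len(segments), function(s)
    one_sided(course[((s - 1L) * m + 1L):(s * m)]),
    numeric(floor(m / 2))))
  data.frame(freq = seq_len(floor(m / 2)) / (m * TR), power = pow)
}

#' Fraction of spectral power below a frequency cutoff
#' @param course numeric series.
#' @param TR sampling interval (s).
#' @param cutoff_hz cutoff (default 0.1 Hz).
#' @return fraction in `[0, 1]`.
#' @export
low_freq_fraction <- function(course, TR, cutoff_hz = 0.1) {
  ps <- power_spectrum(course, TR)
  sum(ps$power[ps$freq < cutoff_hz]) / sum(ps$power)
}
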