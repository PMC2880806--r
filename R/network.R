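#' Wilson-Cowan-type network configuration
#'
#' Continuous-time rate dynamics for `n` neural masses:
#' `du_i/dt = -alpha u_i + sum_j W_ij Theta(u_j) + I_i(t) + xi_i(t)`,
#' where `alpha` is the inverse relaxation time, `W` the connection-strength
#' matrix (`W[i, j]` = influence of node j on node i), `Theta` a saturation
#' applied to presynaptic activity, and `xi_i` per-node Gaussian noise. In the
#' resting state the inputs vanish and `Theta` is the identity, so the
#' Euler-discretized system is the linear recursion of [simulate_linear()].
#'
#' @param W square connection matrix.
#' @param alpha inverse relaxation time, `> 0`.
#' @param dt discretization step.
#' @param noise_sds per-node per-step noise SDs (recycled to length n).
#' @param saturation `"identity"` or a function `Theta(x)` (e.g. a sigmoid).
#' @param external_input `NULL` (zero), a length-n vector, or a function
#'   `I(t)` returning a length-n vector.
#' @return object of class `network_config`.
#' @export
network_config <- function(W, alpha = 1, dt = 0.1, noise_sds = 0,
                           saturation = "identity", external_input = NULL) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop_param("'W' must be square")
  if (!is.finite(alpha) || alpha <= 0) stop_param("'alpha' must be > 0")
  n <- nrow(W)
  noise_sds <- rep_len(noise_sds, n)
  if (any(noise_sds < 0)) stop_param("noise SDs must be >= 0")
  structure(list(W = W, alpha = alpha, dt = dt, noise_sds = noise_sds,
                 saturation = saturation, external_input = external_input,
                 n = n),
            class = "network_config")
}

#' Linear one-step propagator of the discretized resting-state network
#'
#' `A = (1 - alpha dt) I + W dt`; the recursion `u(t + dt) = A u(t) + xi(t)`
#' is stable when the spectral radius of `A` is below 1.
#'
#' @param W square connection matrix.
#' @param alpha inverse relaxation time.
#' @param dt time step (a warning is given when `alpha * dt >= 1`).
#' @return object of class `linear_propagator` with fields `A`,
#'   `spectral_radius`, `stable`, plus `W`, `alpha`, `dt`, `n`.
#' @export
#' @examples
#' p <- build_propagator(matrix(c(0, .5, .5, 0), 2), alpha = 1, dt = 0.1)
#' p$spectral_radius # 0.95
build_propagator <- function(W, alpha, dt) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop_param("'W' must be square")
  if (alpha * dt >= 1)
    warning("alpha * dt >= 1: the Euler discretization is coarse",
            call. = FALSE)
  n <- nrow(W)
  A <- diag(1 - alpha * dt, n) + W * dt
  sr <- max(Mod(eigen(A, only.values = TRUE)$values))
  structure(list(A = A, spectral_radius = sr, stable = sr < 1,
                 W = W, alpha = alpha, dt = dt, n = n),
            class = "linear_propagator")
}

#' @export
print.linear_propagator <- function(x, ...) {
  cat("<linear_propagator> n = ", x$n, ", spectral radius = ",
      signif(x$spectral_radius, 6), if (x$stable) " (stable)" else " (UNSTABLE)",
      "\n", sep = "")
  invisible(x)
}

# shared noise-matrix draw so linear and nonlinear paths can be bit-identical
.draw_network_noise <- function(T, n, noise_sds, seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  matrix(stats::rnorm(T * n), T, n, byrow = TRUE) *
    rep(rep_len(noise_sds, n), each = T)
}

#' Simulate the linear resting-state recursion
#'
#' Iterates `u(t + dt) = A u(t) + xi(t)` with independent per-node Gaussian
#' noise each step. Refuses unstable propagators unless `override = TRUE`.
#' The update is computed as `(1 - alpha dt) u + dt (W u) + xi`, which equals
#' `A u + xi` and is arithmetically identical to [simulate_nonlinear()] with
#' identity saturation on the same noise stream.
#'
#' @param prop a [build_propagator()] result.
#' @param noise_sds per-node per-step noise SD (recycled).
#' @param T number of steps.
#' @param u0 initial state (default 0).
#' @param seed integer seed.
#' @param override simulate despite instability.
#' @return numeric matrix of `T + 1` rows (including `u0`) by `n` columns.
#' @export
simulate_linear <- function(prop, noise_sds, T, u0 = NULL, seed = 1L,
                            override = FALSE) {
  stopifnot(inherits(prop, "linear_propagator"))
  if (!prop$stable && !override)
    stop("propagator is unstable (spectral radius ",
         signif(prop$spectral_radius, 6), "); pass override = TRUE to force",
         call. = FALSE)
  n <- prop$n
  u0 <- if (is.null(u0)) numeric(n) else rep_len(u0, n)
  eps <- .draw_network_noise(T, n, noise_sds, seed)
  out <- matrix(NA_real_, T + 1L, n)
  out[1L, ] <- u0
  u <- u0
  decay <- 1 - prop$alpha * prop$dt
  Wdt_t <- t(prop$W) # use u %*% t(W) == (W u)^T for row-vector updates
  for (k in seq_len(T)) {
    u <- decay * u + prop$dt * drop(u %*% Wdt_t) + eps[k, ]
    out[k + 1L, ] <- u
  }
  out
}

#' Simulate the saturating (nonlinear) network
#'
#' Euler-Maruyama discretization of the rate equations with the saturation
#' applied to presynaptic activity: `u <- (1 - alpha dt) u +
#' dt W Theta(u) + dt I(t) + xi`. With identity saturation and zero input the
#' result is bitwise-equal to [simulate_linear()] under the same seed.
#'
#' @param cfg a [network_config()].
#' @param T number of steps.
#' @param u0 initial state (default 0).
#' @param seed integer seed.
#' @param bound divergence guard on `max |u|`.
#' @return numeric matrix of `T + 1` rows by `n` columns.
#' @export
simulate_nonlinear <- function(cfg, T, u0 = NULL, seed = 1L, bound = 1e6) {
  stopifnot(inherits(cfg, "network_config"))
  n <- cfg$n
  u0 <- if (is.null(u0)) numeric(n) else rep_len(u0, n)
  theta <- if (identical(cfg$saturation, "identity")) identity
           else cfg$saturation
  stopifnot(is.function(theta))
  inp <- cfg$external_input
  input_at <- if (is.null(inp)) function(t) 0
              else if (is.function(inp)) inp
              else function(t) inp
  eps <- .draw_network_noise(T, n, cfg$noise_sds, seed)
  out <- matrix(NA_real_, T + 1L, n)
  out[1L, ] <- u0
  u <- u0
  decay <- 1 - cfg$alpha * cfg$dt
  Wt <- t(cfg$W)
  for (k in seq_len(T)) {
    tk <- (k - 1) * cfg$dt
    u <- decay * u + cfg$dt * drop(theta(u) %*% Wt) +
      cfg$dt * input_at(tk) + eps[k, ]
    if (any(!is.finite(u)) || max(abs(u)) > bound)
      stop("network simulation diverged at step ", k, call. = FALSE)
    out[k + 1L, ] <- u
  }
  out
}

# sign convention: largest-|entry| coordinate positive; ties -> lowest index
.fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which(abs(V[, j]) == max(abs(V[, j])))[1]
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Covariance eigenmodes container
#' @param C symmetric covariance matrix.
#' @return object of class `covariance_modes` with `C`, `eigenvalues`
#'   (descending), `eigenvectors` (orthonormal columns, sign-fixed so each
#'   vector's largest-magnitude entry is positive).
#' @export
covariance_modes <- function(C) {
  C <- as.matrix(C)
  if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C))))
    stop_param("'C' must be symmetric")
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  structure(list(C = C, eigenvalues = e$values,
                 eigenvectors = .fix_signs(e$vectors)),
            class = "covariance_modes")
}

#' @export
print.covariance_modes <- function(x, ...) {
  lam <- x$eigenvalues
  cat("<covariance_modes> n = ", length(lam), "; eigenvalue shares: ",
      paste(signif(lam / sum(lam), 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Stationary covariance of the linear recursion (discrete Lyapunov)
#'
#' Solves `C = A C A^T + Sigma_xi` (with `Sigma_xi = diag(noise_sds^2)`) by
#' fixed-point iteration from `C = 0` to a max-norm tolerance, then
#' eigen-decomposes the result. For a stable `A` the iteration converges
#' geometrically at rate `spectral_radius(A)^2`.
#'
#' @param prop a stable [build_propagator()] result.
#' @param noise_sds per-node per-step noise SD (recycled).
#' @param tol max-norm convergence tolerance (default 1e-10).
#' @param max_iter iteration cap (default 1e5).
#' @return a [covariance_modes()] object.
#' @export
stationary_covariance <- function(prop, noise_sds, tol = 1e-10,
                                  max_iter = 1e5) {
  stopifnot(inherits(prop, "linear_propagator"))
  if (!prop$stable)
    stop("no stationary covariance: propagator unstable (spectral radius ",
         signif(prop$spectral_radius, 6), ")", call. = FALSE)
  n <- prop$n
  Sig <- diag(rep_len(noise_sds, n)^2, n)
  A <- prop$A
  C <- matrix(0, n, n)
  for (i in seq_len(max_iter)) {
    Cn <- A %*% C %*% t(A) + Sig
    delta <- max(abs(Cn - C))
    C <- Cn
    if (delta < tol) return(covariance_modes(C))
  }
  stop("Lyapunov fixed-point iteration did not converge (residual ",
       signif(delta, 3), ")", call. = FALSE)
}

#' Empirical covariance eigenmodes of a simulated series
#'
#' Sample covariance of the post-burn-in rows (de-meaned; the linear resting
#' model has zero mean, so this matches the uncentered definition up to
#' sampling error) followed by the eigen-decomposition and sign convention of
#' [covariance_modes()].
#'
#' @param series matrix of states (rows = time).
#' @param burn_in rows dropped from the start.
#' @return a [covariance_modes()] object. A constant (degenerate) series
#'   gives a rank-deficiency warning; zero eigenvalues are retained.
#' @export
empirical_modes <- function(series, burn_in = 0L) {
  series <- as.matrix(series)
  if (nrow(series) <= burn_in + ncol(series))
    stop_param("series too short for the requested burn-in")
  X <- series[(burn_in + 1L):nrow(series), , drop = FALSE]
  C <- stats::cov(X)
  if (any(diag(C) == 0))
    warning("degenerate series: some nodes are constant", call. = FALSE)
  covariance_modes(C)
}

#' Fraction of time each covariance mode dominates
#'
#' At each time step the state is projected on the (orthonormal) eigenvectors
#' and the mode with the largest squared projection is counted as occupied.
#' Also reports each mode's projection-variance share `lambda_k / sum(lambda)`.
#'
#' @param series matrix of states (rows = time).
#' @param modes a [covariance_modes()] of matching dimension.
#' @return list with `occupancy` (fractions summing to 1) and
#'   `variance_share`.
#' @export
mode_occupancy <- function(series, modes) {
  stopifnot(inherits(modes, "covariance_modes"))
  series <- as.matrix(series)
  if (ncol(series) != nrow(modes$eigenvectors))
    stop_param("dimension mismatch between series and modes")
  P <- series %*% modes$eigenvectors
  dom <- max.col(P^2, ties.method = "first")
  occ <- tabulate(dom, nbins = ncol(P)) / nrow(P)
  lam <- pmax(modes$eigenvalues, 0)
  list(occupancy = occ, variance_share = lam / sum(lam))
}

#' Kuramoto synchronization index
#'
#' `r(t) = | (1/n) sum_j exp(i theta_j(t)) |`: 1 for identical phases, 0 for
#' phases balanced around the circle.
#'
#' @param phases matrix (rows = time, columns = nodes) of phases in radians.
#' @return numeric vector `r(t)` in `[0, 1]`.
#' @export
kuramoto_index <- function(phases) {
  phases <- as.matrix(phases)
  Mod(rowMeans(exp(1i * phases)))
}

#' Instantaneous phases via the analytic signal
#'
#' Each column is de-meaned and its analytic signal formed from the one-sided
#' spectrum (negative frequencies zeroed, positive doubled); the phase is the
#' argument of the result. Constant columns have no defined phase and are
#' returned as `NA` with a warning.
#'
#' @param series matrix (rows = time, columns = nodes) of real signals.
#' @return matrix of phases (radians) of the same shape.
#' @export
extract_phases <- function(series) {
  series <- as.matrix(series)
  n <- nrow(series)
  out <- matrix(NA_real_, n, ncol(series))
  h <- numeric(n) # spectral weights of the analytic-signal construction
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  bad <- logical(ncol(series))
  for (j in seq_len(ncol(series))) {
    x <- series[, j] - mean(series[, j])
    if (all(x == 0)) { bad[j] <- TRUE; next }
    z <- stats::fft(h * stats::fft(x), inverse = TRUE) / n
    out[, j] <- Arg(z)
  }
  if (any(bad))
    warning("constant node(s) have undefined phase: ",
            paste(which(bad), collapse = ", "), call. = FALSE)
  out
}

#' Write covariance modes as TSV
#'
#' One row per mode: eigenvalue, weight share `lambda_k / sum(lambda)`, and
#' the eigenvector entries.
#'
#' @param modes a [covariance_modes()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_modes <- function(modes, path) {
  stopifnot(inherits(modes, "covariance_modes"))
  lam <- modes$eigenvalues
  d <- data.frame(eigenvalue = lam, weight_share = lam / sum(lam),
                  t(modes$eigenvectors))
  names(d)[-(1:2)] <- paste0("v", seq_along(lam))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a connection matrix as delimited text
#'
#' A square numeric matrix without header, or a labeled variant whose first
#' row holds node names.
#'
#' @param path file path.
#' @param W matrix to write.
#' @param labeled write/read node names as a header row.
#' @return `read_connectivity`: the matrix; `write_connectivity`: `path`.
#' @export
read_connectivity <- function(path, labeled = FALSE) {
  if (labeled) {
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
    W <- as.matrix(d)
    rownames(W) <- colnames(W)
  } else {
    W <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t"))
    dimnames(W) <- NULL
  }
  if (nrow(W) != ncol(W)) stop_param("connectivity file is not square")
  W
}

#' @rdname read_connectivity
#' @export
write_connectivity <- function(W, path, labeled = FALSE) {
  utils::write.table(W, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = labeled)
  invisible(path)
}
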