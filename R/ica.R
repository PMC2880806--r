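#' Preprocess an fMRI data matrix for spatial ICA
#'
#' The standard resting-state preprocessing: restrict columns to the in-brain
#' mask, de-mean each voxel's time course, and normalize it to unit variance.
#' Voxels with zero temporal variance cannot be normalized and are dropped
#' (reported in the result). The operation is idempotent.
#'
#' @param X_raw numeric matrix, rows = time points, columns = voxels.
#' @param mask optional logical vector over the columns (default all).
#' @return object of class `fmri_data_matrix`: list with `X` (processed
#'   matrix), `kept` (column indices of `X_raw` retained), `dropped`
#'   (zero-variance columns), and flags `demeaned`, `variance_normalized`.
#' @export
preprocess_fmri <- function(X_raw, mask = NULL) {
  X_raw <- as.matrix(X_raw)
  keep <- if (is.null(mask)) rep(TRUE, ncol(X_raw)) else as.logical(mask)
  stopifnot(length(keep) == ncol(X_raw))
  idx <- which(keep)
  X <- X_raw[, idx, drop = FALSE]
  v <- apply(X, 2, stats::var)
  dropped <- idx[v == 0]
  ok <- v > 0
  if (!any(ok)) stop("all voxels are degenerate (zero variance)",
                     call. = FALSE)
  X <- X[, ok, drop = FALSE]
  ctr <- colMeans(X)
  scl <- sqrt(v[ok])
  X <- scale(X, center = ctr, scale = scl)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  structure(list(X = X, kept = idx[ok], dropped = dropped,
                 center = ctr, scale = scl,
                 demeaned = TRUE, variance_normalized = TRUE),
            class = "fmri_data_matrix")
}

#' @export
print.fmri_data_matrix <- function(x, ...) {
  cat("<fmri_data_matrix> ", nrow(x$X), " time points x ", ncol(x$X),
      " voxels (", length(x$dropped), " zero-variance voxel(s) dropped)\n",
      sep = "")
  invisible(x)
}

#' PCA whitening and dimension reduction
#'
#' Eigen-decomposition of the temporal covariance `X X^T / n`; the data are
#' projected on the top-K eigenvectors and scaled so the whitened rows have
#' identity covariance. The back-projection needed to express results in the
#' original time basis is retained, together with explained-variance
#' fractions.
#'
#' @param Xp an [preprocess_fmri()] result or a plain matrix (rows = time).
#' @param K target dimension, `1 <= K <=` numerical rank.
#' @return object of class `whitened_data`: `Y` (`K x n` whitened spatial
#'   data), `E` (`p x K` eigenvectors), `lambda` (top-K eigenvalues),
#'   `explained` (full explained-variance fractions), `n`.
#' @export
pca_whiten <- function(Xp, K) {
  X <- if (inherits(Xp, "fmri_data_matrix")) Xp$X else as.matrix(Xp)
  p <- nrow(X); n <- ncol(X)
  if (K < 1 || K > min(p, n)) stop_param("'K' must be in [1, min(p, n)]")
  Ct <- X %*% t(X) / n
  e <- eigen(Ct, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  rank <- sum(lam > max(lam) * 1e-10)
  if (K > rank)
    stop("K = ", K, " exceeds the numerical rank (", rank, ")", call. = FALSE)
  E <- e$vectors[, seq_len(K), drop = FALSE]
  lamK <- lam[seq_len(K)]
  Y <- diag(1 / sqrt(lamK), K) %*% t(E) %*% X
  structure(list(Y = Y, E = E, lambda = lamK,
                 explained = lam / sum(lam), n = n),
            class = "whitened_data")
}

#' @export
print.whitened_data <- function(x, ...) {
  cat("<whitened_data> K = ", length(x$lambda), ", explains ",
      signif(100 * sum(x$explained[seq_along(x$lambda)]), 4),
      "% of variance\n", sep = "")
  invisible(x)
}

# symmetric orthonormalization U <- (U U^T)^{-1/2} U
.sym_orth <- function(U) {
  e <- eigen(U %*% t(U), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, .Machine$double.eps)),
                     nrow(U)) %*% t(e$vectors) %*% U
}

#' Spatial ICA by symmetric fixed-point iteration
#'
#' Fits the generative model `X = A S` (independent non-Gaussian spatial
#' sources `S`, mixing time courses in `A`) on a preprocessed data matrix:
#' PCA whitening to `K` dimensions followed by the symmetric fixed-point
#' (FastICA-type) update with the chosen contrast nonlinearity and symmetric
#' orthonormalization each sweep. Components are identifiable up to
#' permutation and scaling; each estimated map's sign is fixed so its
#' skewness is positive, making thresholded maps reproducible.
#'
#' This is the package's model-fitting entry point; the returned fit supports
#' `print`, `summary`, `coef` (component time courses) and `fitted`
#' (the rank-K reconstruction).
#'
#' @param X data: an `fmri_dataset`, an `fmri_data_matrix`, or a plain
#'   matrix (rows = time points, columns = voxels). Plain matrices and
#'   datasets are preprocessed first (see `preprocess`).
#' @param K number of components.
#' @param nonlinearity contrast derivative: `"tanh"` (default) or `"cubic"`.
#' @param tol convergence tolerance on the maximum absolute change in any
#'   unmixing direction, up to sign (default 1e-5).
#' @param max_iter sweep cap (default 500).
#' @param seed integer seed for the random orthonormal start.
#' @param preprocess apply [preprocess_fmri()] first (default TRUE for plain
#'   input; an `fmri_data_matrix` is used as is).
#' @return object of class `spatial_ica`: `S_hat` (`K x n` source estimates
#'   in the whitened/normalized space, mutually decorrelated), `maps` (`K x
#'   n` final spatial maps: least-squares fit of the component time courses
#'   to the de-meaned data, scaled by the voxel-wise residual noise SD),
#'   `A_hat` (`p x K` component time courses), `W_hat` (`K x K` unmixing in
#'   whitened space), `W_total` (`K x p` overall unmixing from the
#'   preprocessed data), `whitening`, `K`, `convergence` (list: `iterations`,
#'   `final_change`, `converged`), `kept` voxel indices.
#' @export
#' @examples
#' set.seed(1)
#' S <- rbind(stats::rexp(2000) * sign(stats::rnorm(2000)),
#'            stats::rexp(2000) * sign(stats::rnorm(2000)))
#' A <- matrix(stats::rnorm(100 * 2), 100, 2)
#' fit <- spatial_ica(A %*% S, K = 2, seed = 1)
#' fit
spatial_ica <- function(X, K, nonlinearity = c("tanh", "cubic"),
                        tol = 1e-5, max_iter = 500L, seed = 1L,
                        preprocess = TRUE) {
  nonlinearity <- match.arg(nonlinearity)
  if (inherits(X, "fmri_dataset")) X <- X$X
  if (inherits(X, "fmri_data_matrix")) {
    pre <- X
  } else if (preprocess) {
    pre <- preprocess_fmri(X)
  } else {
    pre <- structure(list(X = as.matrix(X), kept = seq_len(ncol(X)),
                          dropped = integer(0)),
                     class = "fmri_data_matrix")
  }
  wh <- pca_whiten(pre, K)
  Y <- wh$Y
  n <- ncol(Y)
  g <- switch(nonlinearity,
              tanh = list(f = function(u) tanh(u),
                          df = function(u) 1 - tanh(u)^2),
              cubic = list(f = function(u) u^3,
                           df = function(u) 3 * u^2))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  U <- .sym_orth(matrix(stats::rnorm(K * K), K, K))
  converged <- FALSE
  change <- NA_real_
  for (it in seq_len(max_iter)) {
    S <- U %*% Y
    GU <- g$f(S) %*% t(Y) / n - diag(rowMeans(g$df(S)), K) %*% U
    U_new <- .sym_orth(GU)
    # change up to sign: |diag(U_new U^T)| should approach 1
    change <- max(abs(1 - abs(rowSums(U_new * U))))
    U <- U_new
    if (change < tol) { converged <- TRUE; break }
  }
  S_hat <- U %*% Y
  # sign convention: positive spatial skewness per component
  sk <- rowMeans(S_hat^3)
  flip <- ifelse(sk < 0, -1, 1)
  S_hat <- S_hat * flip
  U <- U * flip
  A_hat <- wh$E %*% diag(sqrt(wh$lambda), K) %*% t(U)
  W_total <- U %*% diag(1 / sqrt(wh$lambda), K) %*% t(wh$E)
  # final maps in data units: least-squares fit of the component time
  # courses to the de-meaned (not variance-normalized) data, each voxel
  # divided by the SD of its residual noise
  Xd <- if (!is.null(pre$scale))
    sweep(pre$X, 2, pre$scale, "*")
  else
    scale(pre$X, scale = FALSE)
  S_glm <- solve(crossprod(A_hat), crossprod(A_hat, Xd))
  res_sd <- sqrt(pmax(colMeans((Xd - A_hat %*% S_glm)^2),
                      .Machine$double.eps))
  maps <- sweep(S_glm, 2, res_sd, "/")
  maps <- maps * ifelse(rowMeans(maps^3) < 0, -1, 1) # positive skewness
  structure(list(S_hat = S_hat, A_hat = A_hat, maps = maps, W_hat = U,
                 W_total = W_total, whitening = wh, K = K,
                 nonlinearity = nonlinearity,
                 convergence = list(iterations = it, final_change = change,
                                    converged = converged),
                 kept = pre$kept),
            class = "spatial_ica")
}

#' @export
print.spatial_ica <- function(x, ...) {
  cat("<spatial_ica> K = ", x$K, " components, ", ncol(x$S_hat),
      " voxels; ", if (x$convergence$converged) "converged" else
        "NOT converged", " in ", x$convergence$iterations,
      " iteration(s)\n", sep = "")
  invisible(x)
}

#' @export
summary.spatial_ica <- function(object, tau = 2, ...) {
  zfrac <- apply(object$S_hat, 1, function(s) {
    z <- (s - mean(s)) / stats::sd(s)
    mean(abs(z) > tau)
  })
  out <- data.frame(
    component = seq_len(object$K),
    explained_variance = object$whitening$explained[seq_len(object$K)],
    suprathreshold_fraction = zfrac)
  structure(list(table = out, tau = tau,
                 convergence = object$convergence),
            class = "summary.spatial_ica")
}

#' @export
print.summary.spatial_ica <- function(x, ...) {
  cat("Spatial ICA fit (", nrow(x$table), " components), |Z| > ", x$tau,
      " threshold\n", sep = "")
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.spatial_ica <- function(object, ...) object$A_hat

#' @export
fitted.spatial_ica <- function(object, ...) object$A_hat %*% object$S_hat

#' @export
plot.spatial_ica <- function(x, which = 1L, ...) {
  graphics::plot(x$A_hat[, which], type = "l", xlab = "frame",
                 ylab = paste0("component ", which, " time course"), ...)
}

#' Z-score and threshold an estimated spatial map
#'
#' The map is standardized over masked voxels to zero mean and unit variance
#' and thresholded at `|Z| > tau`.
#'
#' @param s_row estimated map values (one component).
#' @param tau threshold (default 2.0).
#' @return object of class `thresholded_map`: `Z`, `tau`, `supra` (indices
#'   with `|Z| > tau`).
#' @export
zscore_threshold <- function(s_row, tau = 2.0) {
  s_row <- as.numeric(s_row)
  sdv <- stats::sd(s_row)
  if (!is.finite(sdv) || sdv == 0)
    stop("zero-variance map cannot be Z-scored", call. = FALSE)
  Z <- (s_row - mean(s_row)) / sdv
  structure(list(Z = Z, tau = tau, supra = which(abs(Z) > tau)),
            class = "thresholded_map")
}

#' @export
print.thresholded_map <- function(x, ...) {
  cat("<thresholded_map> |Z| > ", x$tau, ": ", length(x$supra), " of ",
      length(x$Z), " voxels (", signif(100 * length(x$supra) / length(x$Z), 3),
      "%)\n", sep = "")
  invisible(x)
}

#' Amari separation index
#'
#' Permutation- and scale-invariant distance between an estimated unmixing
#' and a true mixing, computed from `P = W_est %*% A_true` and normalized to
#' `[0, 1]`; 0 means perfect separation (P a scaled permutation). Rows of
#' `|P|` are first normalized to unit maximum, which fixes the scaling
#' ambiguity of the estimated components and makes the index exactly
#' invariant under signed permutation and rescaling of the estimates.
#'
#' @param P square cross-talk matrix.
#' @return single numeric index.
#' @export
amari_index <- function(P) {
  P <- abs(as.matrix(P))
  K <- nrow(P)
  stopifnot(ncol(P) == K, K >= 2)
  P <- P / apply(P, 1, max)
  rows <- sum(rowSums(P) - 1)
  cols <- sum(colSums(t(t(P) / apply(P, 2, max))) - 1)
  (rows + cols) / (2 * K * (K - 1))
}

#' Match estimated components to ground truth
#'
#' Greedy assignment of estimated to true components by largest absolute
#' spatial correlation (ties broken by lower index), plus the Amari index of
#' the product of the overall estimated unmixing with the true mixing in the
#' shared subspace. Invariant under signed permutation and positive
#' rescaling of the estimated components.
#'
#' @param est a [spatial_ica()] fit.
#' @param truth ground truth: list with `S_true` (`K x n` maps over the same
#'   voxels the fit used) and `A_true` (`p x K` courses), as produced by
#'   [assemble_dataset()].
#' @return list with `permutation` (for each true component, the index of the
#'   matched estimate), `correlations` (absolute spatial correlations in true
#'   order), `amari`.
#' @export
match_components <- function(est, truth) {
  stopifnot(inherits(est, "spatial_ica"))
  S_true <- as.matrix(truth$S_true)[, est$kept, drop = FALSE]
  if (ncol(S_true) != ncol(est$S_hat))
    stop_param("voxel spaces of estimate and truth do not match")
  K_true <- nrow(S_true)
  if (nrow(est$S_hat) < K_true)
    stop_param("fewer estimated than true components")
  S_est <- est$maps %||% est$S_hat
  R <- abs(stats::cor(t(S_true), t(S_est))) # K_true x K_est
  perm <- integer(K_true); cors <- numeric(K_true)
  Rw <- R
  for (step in seq_len(K_true)) {
    ij <- which(Rw == max(Rw), arr.ind = TRUE)[1, ]
    perm[ij[1]] <- ij[2]
    cors[ij[1]] <- R[ij[1], ij[2]]
    Rw[ij[1], ] <- -Inf
    Rw[, ij[2]] <- -Inf
  }
  A_true <- as.matrix(truth$A_true)
  # shared K-dim subspace: overall unmixing applied to the true courses
  P <- est$W_total %*% A_true
  am <- if (K_true >= 2 && nrow(P) >= K_true)
    amari_index(P[seq_len(K_true), seq_len(K_true), drop = FALSE])
  else NA_real_
  list(permutation = perm, correlations = cors, amari = am)
}
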