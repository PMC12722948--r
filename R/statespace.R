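#' Signal ensembles of complex random oscillations
#'
#' A `ql_ensemble` holds zero-mean (or centerable) complex-valued recordings
#' from `N` oscillatory node-circuits: either an ensemble of independent
#' realizations of the random vector `z in C^N`, or a single multichannel
#' time series whose rows are time points.  Rows index realizations or time
#' points; columns index channels (circuits).
#'
#' @param data numeric or complex matrix, `n x N` (realizations/time points
#'   by channels).  Vectors are treated as a single channel.
#' @param mode `"ensemble"` (rows are independent draws) or `"timeseries"`
#'   (rows are successive samples; covariance estimation then relies on
#'   stationarity and ergodicity).
#' @param centered logical; declare the data already centered.  Verified:
#'   each channel mean must have magnitude below `1e-10 * (RMS + 1)`.
#' @return An object of class `ql_ensemble` with fields `data`, `mode`,
#'   `centered`, `n`, `n_channels`.
#' @seealso [estimate_covariance()], [compound_ensemble()]
#' @export
signal_ensemble <- function(data, mode = c("ensemble", "timeseries"),
                            centered = FALSE) {
  mode <- match.arg(mode)
  if (is.vector(data)) data <- matrix(data, ncol = 1)
  data <- as_complex_matrix(data)
  check_finite(data, "signal data")
  if (ncol(data) < 1) stop("need at least one channel")
  if (nrow(data) < 2) stop("need at least 2 realizations/time points")
  if (centered) {
    mu <- colMeans(data)
    rms <- sqrt(colMeans(Mod(data)^2))
    if (any(Mod(mu) >= 1e-10 * (rms + 1))) {
      stop("ensemble declared centered but channel means are not ~0")
    }
  }
  structure(
    list(data = data, mode = mode, centered = centered,
         n = nrow(data), n_channels = ncol(data)),
    class = "ql_ensemble"
  )
}

#' @export
print.ql_ensemble <- function(x, ...) {
  cat(sprintf("<ql_ensemble> %d x %d (%s%s)\n", x$n, x$n_channels, x$mode,
              if (x$centered) ", centered" else ""))
  invisible(x)
}

#' Center a signal ensemble
#'
#' Subtracts each channel's sample mean, giving the zero-mean signals the
#' covariance-to-density construction assumes.
#'
#' @param signals a [signal_ensemble()].
#' @return A centered `ql_ensemble`.
#' @export
center_ensemble <- function(signals) {
  stopifnot(inherits(signals, "ql_ensemble"))
  d <- sweep(signals$data, 2, colMeans(signals$data))
  signal_ensemble(d, mode = signals$mode, centered = TRUE)
}

#' Estimate the covariance matrix of complex oscillations
#'
#' Second-moment estimator `c_km = (1/n) * sum_i z_k(i) * conj(z_m(i))`,
#' after optional mean subtraction.  The divisor is `n`, matching the
#' time-average definition `Cov(x,y) = (1/T) sum_t x(t) conj(y(t))`.  The
#' result is Hermitized (averaged with its conjugate transpose) so it is
#' Hermitian by construction, and positive semidefinite up to roundoff.
#'
#' @param signals a [signal_ensemble()].
#' @param center subtract channel means first (default `TRUE`).
#' @return A `ql_cov` object: fields `matrix` (complex `N x N` Hermitian
#'   PSD), `n_samples`, `estimation_mode`.
#' @export
estimate_covariance <- function(signals, center = TRUE) {
  stopifnot(inherits(signals, "ql_ensemble"))
  Z <- signals$data
  check_finite(Z, "signal data")
  n <- nrow(Z)
  if (n < 2) stop("need at least 2 samples to estimate a covariance")
  if (center) Z <- sweep(Z, 2, colMeans(Z))
  C <- hermitize(t(Z) %*% Conj(Z) / n)
  ql_cov(C, n_samples = n, estimation_mode = signals$mode)
}

#' Covariance matrix container
#'
#' Validates Hermiticity (relative tolerance `1e-10`), non-negative trace,
#' and eigenvalues `>= -1e-10 * trace`.
#'
#' @param matrix complex `N x N` matrix.
#' @param n_samples number of samples behind the estimate (`NA` for
#'   analytically specified targets).
#' @param estimation_mode provenance tag (`"ensemble"`, `"timeseries"`,
#'   `"analytic"`).
#' @return A `ql_cov` object.
#' @export
ql_cov <- function(matrix, n_samples = NA_integer_,
                   estimation_mode = "analytic") {
  M <- as_complex_matrix(matrix)
  if (nrow(M) != ncol(M)) stop("covariance matrix must be square")
  if (!is_hermitian(M)) stop("covariance matrix is not Hermitian")
  M <- hermitize(M)
  tr <- re_trace(M)
  if (tr < 0) stop("covariance trace is negative")
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(tr, 1)) {
    stop("covariance matrix has a significantly negative eigenvalue: ",
         format(min(ev)))
  }
  structure(list(matrix = M, n_samples = n_samples,
                 estimation_mode = estimation_mode),
            class = "ql_cov")
}

#' @export
print.ql_cov <- function(x, ...) {
  cat(sprintf("<ql_cov> %dx%d, trace %.6g (%s, n = %s)\n",
              nrow(x$matrix), ncol(x$matrix), re_trace(x$matrix),
              x$estimation_mode, format(x$n_samples)))
  invisible(x)
}

#' Density matrix container
#'
#' A trace-one Hermitian positive-semidefinite matrix, optionally tagged
#' with a bipartition `dims = c(N1, N2)` (with `N1 * N2 = N`) declaring the
#' tensor-factor structure used by the entanglement functions.  Eigenvalues
#' in `[-1e-10, 0)` are clipped to zero (with trace renormalization); more
#' negative eigenvalues are an error.
#'
#' @param matrix complex `N x N` matrix.
#' @param dims optional integer pair `c(N1, N2)`.
#' @return A `ql_density` object with fields `matrix` and `dims`.
#' @export
density_matrix <- function(matrix, dims = NULL) {
  M <- as_complex_matrix(matrix)
  if (nrow(M) != ncol(M)) stop("density matrix must be square")
  if (!is_hermitian(M)) stop("density matrix is not Hermitian")
  M <- hermitize(M)
  N <- nrow(M)
  ed <- eigen(M, symmetric = TRUE)
  ev <- ed$values
  if (min(ev) < -1e-10) {
    stop("density matrix has a significantly negative eigenvalue: ",
         format(min(ev)))
  }
  if (any(ev < 0)) {                     # clip roundoff negatives
    ev <- pmax(ev, 0)
    M <- hermitize(ed$vectors %*% (ev * Conj(t(ed$vectors))))
    M <- M / sum(ev)
  }
  tr <- re_trace(M)
  if (abs(tr - 1) > 1e-10) stop("density matrix trace is not 1: ", format(tr))
  if (!is.null(dims)) {
    dims <- as.integer(dims)
    if (length(dims) != 2 || prod(dims) != N) {
      stop("dims must be a pair (N1, N2) with N1 * N2 = ", N)
    }
  }
  structure(list(matrix = M, dims = dims), class = "ql_density")
}

#' @export
print.ql_density <- function(x, ...) {
  d <- purity_diagnostics(x)
  cat(sprintf("<ql_density> %dx%d%s, purity %.4f, rank %d\n",
              nrow(x$matrix), ncol(x$matrix),
              if (!is.null(x$dims)) sprintf(" [%d x %d]", x$dims[1], x$dims[2]) else "",
              d$purity, d$rank))
  invisible(x)
}

#' Trace-normalize a covariance matrix into a QL state
#'
#' The central map of the framework: `rho = C / Tr(C)`.  The trace must
#' exceed `1e-12 * N` (all circuits inactive otherwise); the map is scale
#' invariant, `normalize_to_density(a * C) == normalize_to_density(C)` for
#' every `a > 0`.
#'
#' @param C a [ql_cov()] or a plain Hermitian PSD matrix.
#' @param dims optional bipartition passed to [density_matrix()].
#' @return A `ql_density`.
#' @export
normalize_to_density <- function(C, dims = NULL) {
  M <- if (inherits(C, "ql_cov")) C$matrix else as_complex_matrix(C)
  N <- nrow(M)
  tr <- re_trace(M)
  if (tr <= 1e-12 * N) {
    stop("covariance trace ", format(tr),
         " is below the activity threshold (all circuits inactive?)")
  }
  density_matrix(M / tr, dims = dims)
}

#' Pure-state density matrix from an amplitude vector
#'
#' `rho_v = |psi><psi|` with `psi = v / ||v||`: the QL state of random
#' oscillations concentrated on the one-dimensional subspace spanned by `v`.
#'
#' @param v non-zero complex vector.
#' @param dims optional bipartition.
#' @return A rank-1 idempotent `ql_density`.
#' @export
pure_state_density <- function(v, dims = NULL) {
  v <- as.complex(v)
  check_finite(v, "state vector")
  nv <- sqrt(Re(hs_inner(v, v)))
  if (nv <= 0) stop("cannot normalize the zero vector")
  psi <- v / nv
  density_matrix(outer(psi, Conj(psi)), dims = dims)
}

#' Purity, rank and spectrum of a QL state
#'
#' @param rho a [density_matrix()].
#' @param tol rank tolerance on eigenvalues.
#' @return List with `purity` (`Tr rho^2`, in `(1/N, 1]` for genuinely mixed
#'   through pure states), `rank`, and `eigenvalues` (descending).
#' @export
purity_diagnostics <- function(rho, tol = 1e-10) {
  stopifnot(inherits(rho, "ql_density"))
  ev <- eigen(rho$matrix, symmetric = TRUE, only.values = TRUE)$values
  list(purity = sum(ev^2), rank = sum(ev > tol), eigenvalues = ev)
}
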