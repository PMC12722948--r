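#' Quadratic-Hamiltonian specification for coupled oscillators
#'
#' A network of `N` coupled harmonic oscillators with the symplectically
#' invariant Hamiltonian `H(q,p) = 1/2 [ (Rp,p) + 2(Tp,q) + (Rq,q) ]`,
#' where `R` is real symmetric and `T` real antisymmetric.  The phase flow
#' is linear, `x' = A x` with `x = (q, p)`, and complexifies to a
#' Schrodinger equation with Hermitian Hamiltonian `H = R - iT` acting on
#' `psi = q + ip`.
#'
#' @param R real symmetric `N x N` matrix (stiffness/energy block).
#' @param T real antisymmetric `N x N` matrix (gyroscopic coupling block).
#' @return A `ql_hamiltonian` object with fields `R`, `T`, `n`.
#' @export
hamiltonian_spec <- function(R, T) {
  R <- as.matrix(R); T <- as.matrix(T)
  if (!is.numeric(R) || !is.numeric(T)) stop("R and T must be real matrices")
  if (any(dim(R) != dim(T)) || nrow(R) != ncol(R)) {
    stop("R and T must be square matrices of the same size")
  }
  if (max(abs(R - t(R))) >= 1e-12 * mat_scale(R)) {
    stop("R must be symmetric")
  }
  if (max(abs(T + t(T))) >= 1e-12 * mat_scale(T)) {
    stop("T must be antisymmetric")
  }
  structure(list(R = R, T = T, n = nrow(R)), class = "ql_hamiltonian")
}

#' @export
print.ql_hamiltonian <- function(x, ...) {
  cat(sprintf("<ql_hamiltonian> N = %d oscillators\n", x$n))
  invisible(x)
}

#' Drift matrix of the linear phase flow
#'
#' Assembles the `2N x 2N` block matrix `A = [[-T, R], [-R, -T]]` so that
#' the Hamilton equations read `x' = A x` for `x = (q, p)`.  For a
#' positive-definite Hamiltonian its spectrum is purely imaginary,
#' `{± i E_k}` with `E_k` the eigenvalues of `R - iT`.
#'
#' @param spec a [hamiltonian_spec()].
#' @return Real `2N x 2N` matrix.
#' @export
build_drift_matrix <- function(spec) {
  stopifnot(inherits(spec, "ql_hamiltonian"))
  rbind(cbind(-spec$T, spec$R), cbind(-spec$R, -spec$T))
}

#' Hermitian Hamiltonian of the complexified dynamics
#'
#' `H = R - iT`, the complexification under which `i dpsi/dt = H psi` with
#' `psi = q + ip` reproduces the phase flow `x' = A x` exactly.
#'
#' @param spec a [hamiltonian_spec()].
#' @return Complex Hermitian `N x N` matrix.
#' @export
complex_hamiltonian <- function(spec) {
  stopifnot(inherits(spec, "ql_hamiltonian"))
  spec$R - 1i * spec$T
}

#' Oscillation mode frequencies
#'
#' Eigenvalues of the Hermitian Hamiltonian in ascending order; these equal
#' the magnitudes of the purely imaginary drift-matrix eigenvalue pairs.
#' Requires a positive-semidefinite Hamiltonian: an indefinite one has no
#' well-defined positive mode frequencies and is rejected rather than
#' silently folded to `|eig|`.
#'
#' @param spec a [hamiltonian_spec()].
#' @param tol negativity tolerance relative to the matrix scale.
#' @return Sorted numeric vector of length `N`.
#' @export
mode_frequencies <- function(spec, tol = 1e-10) {
  H <- complex_hamiltonian(spec)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * mat_scale(H)) {
    stop("indefinite Hamiltonian: smallest eigenvalue ", format(min(ev)),
         "; mode frequencies are undefined")
  }
  sort(ev)
}

#' Second-order (coupled-oscillator) form of the dynamics
#'
#' Eliminating the momenta from `x' = A x` gives
#' `q'' + Cmat q' + Kmat q = 0` with velocity coupling
#' `Cmat = T + R T R^-1` and stiffness `Kmat = R^2 + R T R^-1 T`.
#'
#' @param spec a [hamiltonian_spec()]; `R` must be invertible.
#' @return List with matrices `Cmat` and `Kmat`.
#' @export
second_order_matrices <- function(spec) {
  stopifnot(inherits(spec, "ql_hamiltonian"))
  R <- spec$R; T <- spec$T
  Rinv <- tryCatch(solve(R), error = function(e) {
    stop("R is singular; the second-order reduction needs R^-1")
  })
  RTRinv <- R %*% T %*% Rinv
  list(Cmat = T + RTRinv, Kmat = R %*% R + RTRinv %*% T)
}

new_trajectory <- function(times, states, kind) {
  times <- as.numeric(times)
  if (length(times) < 1 || any(diff(times) <= 0)) {
    stop("times must be a strictly increasing grid")
  }
  structure(list(times = times, states = states, kind = kind),
            class = "ql_trajectory")
}

#' @export
print.ql_trajectory <- function(x, ...) {
  cat(sprintf("<ql_trajectory> %s, %d time points, dim %d\n",
              x$kind, length(x$times), ncol(x$states)))
  invisible(x)
}

#' @export
plot.ql_trajectory <- function(x, channel = 1, ...) {
  s <- x$states[, channel]
  if (is.complex(s)) {
    plot(Re(s), Im(s), type = "l", xlab = "Re", ylab = "Im",
         main = sprintf("channel %d phase portrait", channel), ...)
  } else {
    plot(x$times, s, type = "l", xlab = "t", ylab = "state",
         main = sprintf("component %d", channel), ...)
  }
  invisible(x)
}

# exp(t*A) x0 on a grid via eigendecomposition of A. A = J*Hess with Hess
# symmetric is similar to a skew-Hermitian matrix, hence diagonalizable.
expAt_apply <- function(A, x0, times) {
  ed <- eigen(A)
  c0 <- solve(ed$vectors, as.complex(x0))
  t(vapply(times,
           function(t) drop(ed$vectors %*% (exp(ed$values * t) * c0)),
           complex(length(x0))))
}

#' Propagate the classical phase flow
#'
#' Evaluates `x(t) = exp(t A) x0` on a user-supplied time grid by
#' eigendecomposition of the drift matrix (exact up to eigensolver
#' precision; no ODE stepping).  Energy `(x, Hess x)/2` is conserved along
#' the flow.
#'
#' @param spec a [hamiltonian_spec()].
#' @param q0,p0 real initial coordinate and momentum vectors of length `N`.
#' @param times strictly increasing time grid.
#' @return A `ql_trajectory`; `states` is a real matrix with columns
#'   `(q_1..q_N, p_1..p_N)`.
#' @export
propagate_phase <- function(spec, q0, p0, times) {
  stopifnot(inherits(spec, "ql_hamiltonian"))
  q0 <- as.numeric(q0); p0 <- as.numeric(p0)
  if (length(q0) != spec$n || length(p0) != spec$n) {
    stop("q0 and p0 must have length N = ", spec$n)
  }
  check_finite(c(q0, p0), "initial phase state")
  A <- build_drift_matrix(spec)
  X <- expAt_apply(A, c(q0, p0), times)
  if (max(abs(Im(X))) > 1e-8 * max(1, max(abs(Re(X))))) {
    stop("phase propagation produced a non-negligible imaginary part")
  }
  new_trajectory(times, Re(X), kind = "phase")
}

#' Propagate the Schrodinger dynamics
#'
#' `psi(t) = exp(-i t H) psi0` with `H = R - iT`, evaluated on the grid via
#' the spectral decomposition of `H`.  The evolution is unitary: the norm
#' of `psi` is preserved.
#'
#' @param spec a [hamiltonian_spec()].
#' @param psi0 complex initial vector of length `N`.
#' @param times strictly increasing time grid.
#' @return A `ql_trajectory`; `states` is a complex matrix, rows indexed by
#'   time.
#' @export
propagate_schrodinger <- function(spec, psi0, times) {
  stopifnot(inherits(spec, "ql_hamiltonian"))
  psi0 <- as.complex(psi0)
  if (length(psi0) != spec$n) stop("psi0 must have length N = ", spec$n)
  check_finite(psi0, "initial state")
  ed <- eigen(complex_hamiltonian(spec), symmetric = TRUE)
  c0 <- Conj(t(ed$vectors)) %*% psi0
  Psi <- t(vapply(times,
                  function(t) drop(ed$vectors %*% (exp(-1i * ed$values * t) * c0)),
                  complex(spec$n)))
  new_trajectory(times, Psi, kind = "schrodinger")
}

#' Unitary (von Neumann) evolution of a QL state
#'
#' `rho(t) = U rho0 U^H` with `U = exp(-i t H)`: the density-matrix image
#' of the oscillator flow.  Trace, eigenvalues, purity and entropy are all
#' preserved.
#'
#' @param spec a [hamiltonian_spec()].
#' @param rho0 a [density_matrix()] of size `N`.
#' @param t single evolution time.
#' @return A `ql_density`.
#' @export
evolve_density <- function(spec, rho0, t) {
  stopifnot(inherits(spec, "ql_hamiltonian"), inherits(rho0, "ql_density"))
  if (nrow(rho0$matrix) != spec$n) stop("state dimension must equal N = ", spec$n)
  ed <- eigen(complex_hamiltonian(spec), symmetric = TRUE)
  U <- ed$vectors %*% (exp(-1i * ed$values * t) * Conj(t(ed$vectors)))
  density_matrix(U %*% rho0$matrix %*% Conj(t(U)), dims = rho0$dims)
}
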