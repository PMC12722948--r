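# Shared fixtures and independent oracles.  Everything here uses base R
# linear algebra directly (eigen/svd/kronecker), so oracle values never go
# through the code paths they are meant to check.

rand_complex <- function(n, m = n) {
  matrix(complex(real = rnorm(n * m), imaginary = rnorm(n * m)), n, m)
}

rand_hermitian <- function(n) {
  M <- rand_complex(n)
  (M + Conj(t(M))) / 2
}

rand_unitary <- function(n) {
  qr.Q(qr(rand_complex(n)))
}

rand_pure <- function(n) {
  v <- complex(real = rnorm(n), imaginary = rnorm(n))
  v / sqrt(sum(Mod(v)^2))
}

rand_density_matrix <- function(n, rank = n) {
  V <- rand_complex(n, rank)
  M <- V %*% Conj(t(V))
  M / Re(sum(diag(M)))
}

# Worked coupled-oscillator system used across the dynamics tests.
worked_spec <- function() {
  hamiltonian_spec(R = diag(c(1, 4)),
                   T = matrix(c(0, 0.5, -0.5, 0), 2, 2))  # [[0,-0.5],[0.5,0]]
}

# Random valid Hamiltonian blocks (R symmetric, T antisymmetric).
rand_spec <- function(n) {
  R <- matrix(rnorm(n * n), n, n); R <- (R + t(R)) / 2
  T <- matrix(rnorm(n * n), n, n); T <- (T - t(T)) / 2
  hamiltonian_spec(R, T)
}

# The 4x4 singlet covariance pattern on channels 2 and 3 (row-major 2x2).
singlet_cov <- function(variance = 1) {
  C <- matrix(0i, 4, 4)
  C[2, 2] <- C[3, 3] <- variance
  C[2, 3] <- C[3, 2] <- -variance
  C
}

singlet_projector <- function() {
  psi <- c(0, 1, -1, 0) / sqrt(2)
  outer(psi, Conj(psi)) + 0i
}

# Werner family: p * singlet + (1-p) * I/4.
werner_state <- function(p) {
  density_matrix(p * singlet_projector() + (1 - p) * diag(4) / 4,
                 dims = c(2, 2))
}

# Separable-by-construction random mixture sum_k p_k rho_k1 (x) rho_k2.
rand_separable_mixture <- function(N1, N2, k = 4) {
  w <- runif(k); w <- w / sum(w)
  M <- matrix(0i, N1 * N2, N1 * N2)
  for (i in seq_len(k)) {
    M <- M + w[i] * kronecker(rand_density_matrix(N1, sample(N1, 1)),
                              rand_density_matrix(N2, sample(N2, 1)))
  }
  density_matrix(M, dims = c(N1, N2))
}

# Fidelity between a density matrix and a pure-state projector.
fidelity_with_pure <- function(rho, psi) {
  Re(Conj(psi) %*% rho %*% psi)[1]
}

expect_close <- function(actual, expected, tol = 1e-10) {
  expect_lt(max(abs(actual - expected)), tol)
}
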