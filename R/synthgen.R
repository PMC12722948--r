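# Seeded generators for every statistical structure the analyses assume.
# All generators are bit-reproducible from (parameters, seed), and all
# Gaussian draws are circularly symmetric (E[z_k z_m] = 0, only the
# Hermitian second moment is non-zero): the covariance-to-density map only
# constrains E[z conj(z)], and circularity makes the Wick factorization of
# compound fourth moments exact.

# Circular standard-normal complex matrix: E[|z|^2] = 1 per entry.
cn_matrix <- function(n, N) {
  matrix(complex(real = stats::rnorm(n * N), imaginary = stats::rnorm(n * N)),
         n, N) / sqrt(2)
}

# Factor L with L L^H = C, via eigendecomposition (handles rank-deficient
# targets that Cholesky would reject).
psd_factor <- function(C, tol = 1e-10) {
  C <- as_complex_matrix(C)
  if (!is_hermitian(C)) stop("target covariance must be Hermitian")
  ed <- eigen(hermitize(C), symmetric = TRUE)
  if (min(ed$values) < -tol * max(1, max(abs(ed$values)))) {
    stop("target covariance is not positive semidefinite")
  }
  ev <- ed$values
  ev[ev < tol * max(abs(ev), 1)] <- 0   # exact rank deficiency for clipped modes
  ed$vectors %*% diag(sqrt(ev), nrow(C))
}

#' Circular complex Gaussian ensemble with a target covariance
#'
#' Draws `n` independent realizations of a circularly symmetric complex
#' Gaussian vector with `E[z conj(z)^T] = C_target`.  The sample covariance
#' converges to the target at the Monte-Carlo rate `1/sqrt(n)`.
#'
#' @param C_target Hermitian PSD target covariance (`N x N`).
#' @param n number of realizations (`>= 2`).
#' @param seed integer RNG seed (mandatory: generators are reproducible by
#'   construction).
#' @return A [signal_ensemble()] in `"ensemble"` mode.
#' @export
gaussian_ensemble <- function(C_target, n, seed) {
  set.seed(seed)
  L <- psd_factor(C_target)
  Z <- cn_matrix(n, nrow(L)) %*% t(L)
  signal_ensemble(Z, mode = "ensemble")
}

#' Perfectly anti-correlated circuit pair (singlet generator)
#'
#' The four-channel construction behind the singlet state: one complex
#' Gaussian amplitude `z` per realization is written to channel `(+,-)`
#' and `-z` to channel `(-,+)`; channels `(+,+)` and `(-,-)` stay silent.
#' The population covariance is the pattern `c_kk = c_mm = variance`,
#' `c_km = c_mk = -variance` on the two active channels, whose normalized
#' QL state is exactly the singlet projector.
#'
#' @param n number of realizations.
#' @param seed integer RNG seed.
#' @param variance per-channel variance of the active circuits.
#' @return A 4-channel [signal_ensemble()] (row-major `2 x 2` channel
#'   order `++, +-, -+, --`).
#' @export
singlet_ensemble <- function(n, seed, variance = 1) {
  if (variance <= 0) stop("variance must be positive")
  set.seed(seed)
  z <- sqrt(variance) * cn_matrix(n, 1)[, 1]
  Z <- cbind(0i, z, -z, 0i)
  signal_ensemble(Z, mode = "ensemble")
}

#' Two independent factor networks
#'
#' Generates paired but statistically independent ensembles for two
#' networks with covariances `C1` and `C2`.  Their [compound_ensemble()]
#' has population covariance `C1 (x) C2` (Kronecker), hence a product QL
#' state with zero negativity.
#'
#' @param C1,C2 Hermitian PSD target covariances.
#' @param n number of paired realizations.
#' @param seed integer RNG seed.
#' @return List with ensembles `e1` and `e2`.
#' @export
product_networks <- function(C1, C2, n, seed) {
  set.seed(seed)
  L1 <- psd_factor(C1); L2 <- psd_factor(C2)
  e1 <- signal_ensemble(cn_matrix(n, nrow(L1)) %*% t(L1), mode = "ensemble")
  e2 <- signal_ensemble(cn_matrix(n, nrow(L2)) %*% t(L2), mode = "ensemble")
  list(e1 = e1, e2 = e2)
}

#' Cross-correlated factor networks
#'
#' Paired draws `(z1, z2)` from a joint circular Gaussian with block
#' covariance `[[C1, cross], [cross^H, C2]]`: the inter-network Hermitian
#' cross-covariance `cross[i, j] = E[z1_i conj(z2_j)]` models statistical
#' coupling between the two networks.  Note that the compound product
#' state built from such pairs remains separable for every admissible
#' `cross` (the compound covariance is a positive mixture of products);
#' entangled compound states require channel signals, see
#' [channel_coupled_ensemble()].
#'
#' @param C1,C2 Hermitian PSD covariances of the factor networks.
#' @param cross complex `N1 x N2` cross-covariance; the joint block matrix
#'   must be PSD.
#' @param n number of paired realizations.
#' @param seed integer RNG seed.
#' @return List with ensembles `e1`, `e2` and the joint target `joint`.
#' @export
correlated_networks <- function(C1, C2, cross, n, seed) {
  C1 <- as_complex_matrix(C1); C2 <- as_complex_matrix(C2)
  cross <- as_complex_matrix(cross)
  if (nrow(cross) != nrow(C1) || ncol(cross) != nrow(C2)) {
    stop("cross must be N1 x N2")
  }
  joint <- rbind(cbind(C1, cross), cbind(Conj(t(cross)), C2))
  ens <- gaussian_ensemble(joint, n, seed)  # PSD checked by the factoring
  N1 <- nrow(C1)
  list(
    e1 = signal_ensemble(ens$data[, seq_len(N1), drop = FALSE],
                         mode = "ensemble"),
    e2 = signal_ensemble(ens$data[, N1 + seq_len(nrow(C2)), drop = FALSE],
                         mode = "ensemble"),
    joint = joint
  )
}

#' Channel-coupled compound network (entangling generator)
#'
#' Compound circuits are triples (factor circuit, signaling channel,
#' factor circuit): each realization superposes the product background
#' `z1_i * z2_j` of two independent unit-variance factor networks with a
#' shared channel signal carrying perfect anti-correlation between the
#' `(1,2)` and `(2,1)` compound circuits (the singlet pattern), scaled by
#' `gain`.  The population covariance is
#' `C1 (x) C2 + 2 gain^2 P_singlet`, giving population negativity
#' `(gain^2 - 1) / (4 + 2 gain^2)` for identity factor covariances: the
#' state is NPT (entangled) whenever `gain > 1`.  The default `gain = 2`
#' is the strong-coupling condition (negativity 0.25).
#'
#' @param n number of realizations.
#' @param seed integer RNG seed.
#' @param gain channel amplitude relative to the unit product background.
#' @return A 4-channel [signal_ensemble()] on the compound network
#'   (row-major `2 x 2` channel order).
#' @export
channel_coupled_ensemble <- function(n, seed, gain = 2) {
  set.seed(seed)
  w1 <- cn_matrix(n, 2)
  w2 <- cn_matrix(n, 2)
  e <- cn_matrix(n, 1)[, 1]
  Z <- cbind(w1[, 1] * w2[, 1],
             w1[, 1] * w2[, 2] + gain * e,
             w1[, 2] * w2[, 1] - gain * e,
             w1[, 2] * w2[, 2])
  signal_ensemble(Z, mode = "ensemble")
}

#' Ensembles of propagated oscillator realizations
#'
#' Draws `n` random initial vectors `psi0 ~ CN(0, init_cov)` and propagates
#' each through the Schrodinger flow of `spec`, returning the ensemble at
#' every requested time.  The sample covariance at time `t` estimates
#' `U(t) C0 U(t)^H`; its trace is conserved, so with `Tr C0 = 1` the
#' covariance stays a density matrix along the evolution.
#'
#' @param spec a [hamiltonian_spec()].
#' @param init_cov Hermitian PSD initial covariance (`N x N`).
#' @param times strictly increasing time grid.
#' @param n number of realizations.
#' @param seed integer RNG seed.
#' @return List with `times` and `ensembles` (one [signal_ensemble()] per
#'   time point).
#' @export
oscillator_realizations <- function(spec, init_cov, times, n, seed) {
  stopifnot(inherits(spec, "ql_hamiltonian"))
  set.seed(seed)
  L <- psd_factor(init_cov)
  if (nrow(L) != spec$n) stop("init_cov must be N x N with N = ", spec$n)
  Z0 <- cn_matrix(n, spec$n) %*% t(L)
  ed <- eigen(complex_hamiltonian(spec), symmetric = TRUE)
  ensembles <- lapply(times, function(t) {
    U <- ed$vectors %*% (exp(-1i * ed$values * t) * Conj(t(ed$vectors)))
    signal_ensemble(Z0 %*% t(U), mode = "ensemble")
  })
  list(times = as.numeric(times), ensembles = ensembles)
}
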