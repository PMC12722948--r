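# Internal numerical helpers shared across modules.

# Spectral-norm-ish scale used to make tolerances relative.
mat_scale <- function(M) max(1, max(abs(M)))

#' Symmetrize a matrix into its Hermitian part
#'
#' Replaces `M` by `(M + M^H)/2`.  All eigen-analyses in the package go
#' through this step first so that roundoff never produces complex
#' eigenvalues of nominally Hermitian operators.
#'
#' @param M square numeric or complex matrix.
#' @return The Hermitian part of `M`.
#' @export
hermitize <- function(M) (M + Conj(t(M))) / 2

is_hermitian <- function(M, tol = 1e-10) {
  max(abs(M - Conj(t(M)))) <= tol * mat_scale(M)
}

# Hilbert-space inner product <v|w> = sum(conj(v) * w): conjugation on the
# first argument, so that <v|Av> is real for Hermitian A.
hs_inner <- function(v, w) sum(Conj(v) * w)

# Real trace of a (nominally Hermitian) matrix, with a residue check.
re_trace <- function(M, tol = 1e-8) {
  tr <- sum(diag(M))
  if (abs(Im(tr)) > tol * (abs(tr) + 1)) {
    stop("trace has a non-negligible imaginary part: ", format(Im(tr)))
  }
  Re(tr)
}

# Eigen-decomposition of a Hermitian matrix (values descending, like eigen()).
heigen <- function(M, tol = 1e-8) {
  if (!is_hermitian(M, tol)) stop("matrix is not Hermitian within tolerance")
  eigen(hermitize(M), symmetric = TRUE)
}

# Frobenius norm.
fnorm <- function(M) sqrt(sum(Mod(M)^2))

# Kronecker product retaining complex mode.
kron <- function(A, B) kronecker(A, B)

as_complex_matrix <- function(M) {
  M <- as.matrix(M)
  if (!is.complex(M)) storage.mode(M) <- "complex"
  M
}

check_finite <- function(x, what = "input") {
  if (!all(is.finite(Re(x))) || !all(is.finite(Im(x)))) {
    stop("non-finite values in ", what)
  }
  invisible(x)
}

#' Pauli matrices
#'
#' The three 2x2 Pauli matrices plus the identity, used to build dichotomous
#' observables, spin-flip conjugations (concurrence) and CHSH settings.
#'
#' @param which one of `"x"`, `"y"`, `"z"`, `"I"`.
#' @return A complex 2x2 matrix.
#' @export
pauli <- function(which = c("x", "y", "z", "I")) {
  which <- match.arg(which)
  switch(which,
    x = matrix(c(0, 1, 1, 0), 2, 2) + 0i,
    y = matrix(c(0, 1i, -1i, 0), 2, 2),
    z = matrix(c(1, 0, 0, -1), 2, 2) + 0i,
    I = diag(2) + 0i
  )
}
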