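#' Spectral decomposition of a Hermitian observable
#'
#' Decomposes `M = sum_a a * E(a)` into distinct eigenvalues and orthogonal
#' projectors onto their eigenspaces.  Eigenvalues closer than
#' `degeneracy_tol` are merged into a single degenerate projector; the
#' projector family is idempotent, mutually orthogonal and complete.
#'
#' @param M complex Hermitian matrix.
#' @param degeneracy_tol merging tolerance; default `1e-8 * max(1, max|M|)`.
#' @return A `ql_observable`: fields `matrix`, `values` (distinct
#'   eigenvalues, descending), `projectors` (list of matrices).
#' @export
spectral_decompose <- function(M, degeneracy_tol = NULL) {
  M <- as_complex_matrix(M)
  if (!is_hermitian(M)) stop("observable must be Hermitian")
  if (is.null(degeneracy_tol)) degeneracy_tol <- 1e-8 * mat_scale(M)
  ed <- heigen(M)
  ev <- ed$values                       # descending
  grp <- cumsum(c(1, diff(ev) < -degeneracy_tol))
  values <- as.numeric(tapply(ev, grp, mean))
  projectors <- lapply(split(seq_along(ev), grp), function(idx) {
    V <- ed$vectors[, idx, drop = FALSE]
    V %*% Conj(t(V))
  })
  names(projectors) <- NULL
  structure(list(matrix = hermitize(M), values = values,
                 projectors = projectors),
            class = "ql_observable")
}

#' @export
print.ql_observable <- function(x, ...) {
  rk <- vapply(x$projectors, function(P) round(re_trace(P)), 0)
  cat(sprintf("<ql_observable> %dx%d, outcomes {%s} with multiplicities {%s}\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(signif(x$values, 6), collapse = ", "),
              paste(rk, collapse = ", ")))
  invisible(x)
}

as_observable <- function(A) {
  if (inherits(A, "ql_observable")) A else spectral_decompose(A)
}

state_matrix <- function(state) {
  if (inherits(state, "ql_density")) return(state$matrix)
  if (is.matrix(state)) return(density_matrix(state)$matrix)
  # vector: pure state
  pure_state_density(state)$matrix
}

#' Born-rule expectation value
#'
#' `<A>_rho = Tr(rho A)`.  The imaginary residue (roundoff only, for valid
#' inputs) is checked and discarded.
#'
#' @param rho a [density_matrix()].
#' @param A Hermitian matrix or [spectral_decompose()] result.
#' @return Real expectation value.
#' @export
born_average <- function(rho, A) {
  A <- as_observable(A)
  r <- state_matrix(rho)
  if (nrow(r) != nrow(A$matrix)) stop("state/observable dimension mismatch")
  tr <- sum(diag(r %*% A$matrix))
  if (abs(Im(tr)) > 1e-10 * (abs(tr) + 1)) {
    stop("Born average has a non-negligible imaginary part")
  }
  Re(tr)
}

#' Outcome probabilities of a projective measurement
#'
#' For a density matrix, `P(A = a) = Tr(rho E(a))`; for a pure state,
#' `P(A = a) = ||E(a) psi||^2`.  For a non-degenerate observable and
#' `rho = C/Tr C`, this reduces to `c_aa / sum_j c_jj` in the eigenbasis of
#' `A`: outcome probabilities are diagonal covariance weights.
#'
#' @param state a [density_matrix()], a plain density matrix, or a complex
#'   state vector.
#' @param A Hermitian matrix or `ql_observable`.
#' @return Named numeric vector of probabilities (names = eigenvalues),
#'   summing to 1.
#' @export
outcome_probabilities <- function(state, A) {
  A <- as_observable(A)
  r <- state_matrix(state)
  p <- vapply(A$projectors, function(E) Re(sum(diag(r %*% E))), 0)
  p <- pmin(pmax(p, 0), 1)
  if (abs(sum(p) - 1) > 1e-10) stop("probabilities do not sum to 1")
  stats::setNames(p, signif(A$values, 12))
}

#' Projection-postulate state update
#'
#' Observing outcome `alpha` updates the state to
#' `E(alpha) rho E(alpha) / Tr(E(alpha) rho)` (Lueders rule).  Repeating
#' the same measurement then returns `alpha` with probability 1.
#'
#' @param rho a [density_matrix()].
#' @param A Hermitian matrix or `ql_observable`.
#' @param alpha observed eigenvalue (matched to the nearest spectral value).
#' @return A `ql_measurement` record: fields `outcome`, `probability`,
#'   `post_state`.
#' @export
measurement_update <- function(rho, A, alpha) {
  A <- as_observable(A)
  r <- state_matrix(rho)
  i <- which.min(abs(A$values - alpha))
  if (abs(A$values[i] - alpha) > 1e-6 * (1 + abs(alpha))) {
    stop("alpha = ", alpha, " is not in the spectrum")
  }
  E <- A$projectors[[i]]
  p <- Re(sum(diag(r %*% E)))
  if (p <= 1e-14) stop("zero-probability outcome: conditional state undefined")
  post <- density_matrix(E %*% r %*% E / p,
                         dims = if (inherits(rho, "ql_density")) rho$dims else NULL)
  structure(list(outcome = A$values[i], probability = p, post_state = post),
            class = "ql_measurement")
}

#' @export
print.ql_measurement <- function(x, ...) {
  cat(sprintf("<ql_measurement> outcome %.6g with probability %.6g\n",
              x$outcome, x$probability))
  invisible(x)
}

#' Joint probability of two sequential measurements
#'
#' Probability of observing `A = alpha` first, then `B = beta`:
#' `P(A=alpha, B=beta) = Tr[E_B(beta) E_A(alpha) rho E_A(alpha)]`.
#' The measurement of `A` updates the state before `B` is asked, so for
#' non-commuting projectors the order matters.
#'
#' @param rho a [density_matrix()].
#' @param A,B Hermitian matrices or `ql_observable`s.
#' @param alpha,beta outcomes of `A` and `B`.
#' @return Joint probability in `[0, 1]`.
#' @export
sequential_joint_probability <- function(rho, A, alpha, B, beta) {
  A <- as_observable(A); B <- as_observable(B)
  r <- state_matrix(rho)
  if (nrow(A$matrix) != nrow(B$matrix) || nrow(r) != nrow(A$matrix)) {
    stop("dimension mismatch between state and observables")
  }
  ia <- which.min(abs(A$values - alpha))
  ib <- which.min(abs(B$values - beta))
  EA <- A$projectors[[ia]]; EB <- B$projectors[[ib]]
  p <- Re(sum(diag(EB %*% EA %*% r %*% EA)))
  min(max(p, 0), 1)
}

#' Order-effect asymmetry matrix
#'
#' Entry `(alpha, beta)` is `P(A=alpha, B=beta) - P(B=beta, A=alpha)`: the
#' signature of question-order dependence.  The matrix is identically zero
#' when every pair of projectors commutes; its entries always sum to zero
#' since both joint distributions are normalized.
#'
#' @param rho a [density_matrix()].
#' @param A,B Hermitian matrices or `ql_observable`s.
#' @return Numeric matrix, rows labeled by `A`'s outcomes, columns by `B`'s.
#' @export
order_effect_asymmetry <- function(rho, A, B) {
  A <- as_observable(A); B <- as_observable(B)
  out <- matrix(0, length(A$values), length(B$values),
                dimnames = list(signif(A$values, 12), signif(B$values, 12)))
  for (i in seq_along(A$values)) {
    for (j in seq_along(B$values)) {
      out[i, j] <-
        sequential_joint_probability(rho, A, A$values[i], B, B$values[j]) -
        sequential_joint_probability(rho, B, B$values[j], A, A$values[i])
    }
  }
  out
}

#' Ensemble average of a quadratic-form observable
#'
#' The classical counterpart of a QL observable `A` is the quadratic form
#' `Q_A(z) = <Az|z>`.  Its ensemble average satisfies the algebraic (not
#' statistical) identity `E_z[Q_A] = Tr(Chat A)` where `Chat` is the
#' uncentered sample covariance; dividing by `Tr Chat` gives the Born
#' average in the state `rho = Chat / Tr Chat`.
#'
#' @param signals a [signal_ensemble()].
#' @param A Hermitian matrix.
#' @return Real average of `Q_A` over the realizations.
#' @export
quadratic_form_average <- function(signals, A) {
  stopifnot(inherits(signals, "ql_ensemble"))
  A <- as_complex_matrix(A)
  if (!is_hermitian(A)) stop("A must be Hermitian")
  Z <- signals$data
  if (ncol(Z) != nrow(A)) stop("channel/observable dimension mismatch")
  q <- rowSums(Conj(Z) * (Z %*% t(A)))  # z^H A z per realization
  mean(Re(q))
}

#' Correlation of two compatible (commuting) observables
#'
#' `<A1 A2>_rho = Tr(rho A1 A2) = Tr(rho A2 A1)`, defined only for
#' commuting pairs (the product is then itself Hermitian).  Non-commuting
#' input is an explicit error: the formula has no meaning for incompatible
#' observables.
#'
#' @param rho a [density_matrix()].
#' @param A1,A2 Hermitian matrices.
#' @param tol commutator tolerance relative to the operator scales.
#' @return Real correlation value.
#' @export
commuting_correlation <- function(rho, A1, A2, tol = 1e-10) {
  A1 <- as_complex_matrix(A1); A2 <- as_complex_matrix(A2)
  comm <- A1 %*% A2 - A2 %*% A1
  if (max(abs(comm)) > tol * mat_scale(A1) * mat_scale(A2)) {
    stop("observables do not commute; their joint correlation is undefined")
  }
  born_average(rho, hermitize(A1 %*% A2))
}
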