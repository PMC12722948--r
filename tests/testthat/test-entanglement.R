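test_that("compound ensembles of independent networks factorize as Kronecker products", {
  set.seed(3)
  C1 <- rand_density_matrix(2) * 2
  C2 <- rand_density_matrix(2) * 2
  nets <- product_networks(C1, C2, n = 4e4, seed = 5)
  comp <- compound_ensemble(nets$e1, nets$e2)
  Chat <- estimate_covariance(comp, center = FALSE)$matrix
  expect_lt(sqrt(sum(Mod(Chat - kronecker(C1, C2))^2)), 10 / sqrt(4e4))
  rho <- normalize_to_density(Chat, dims = c(2, 2))
  expect_lt(negativity(rho)$negativity, 0.01)
})

test_that("a deterministic unit second factor pads the first network's covariance", {
  set.seed(7)
  e1 <- gaussian_ensemble(diag(2) + 0i, 500, seed = 9)
  e2 <- signal_ensemble(matrix(1 + 0i, 500, 2))
  comp <- compound_ensemble(e1, e2)
  C1 <- estimate_covariance(e1, center = FALSE)$matrix
  Chat <- estimate_covariance(comp, center = FALSE)$matrix
  # Z_(i,j) = z1_i for every j: covariance is C1 spread over the index map
  for (i in 1:2) for (k in 1:2) for (j in 1:2) for (m in 1:2) {
    expect_equal(Chat[(i - 1) * 2 + j, (k - 1) * 2 + m], C1[i, k],
                 tolerance = 1e-12)
  }
  expect_error(compound_ensemble(e1, signal_ensemble(matrix(1, 10, 2))),
               "equal sample counts")
})

test_that("commuting degenerate observables induce the tensor basis", {
  A1 <- kronecker(pauli("z"), diag(2))
  A2 <- kronecker(diag(2), pauli("z"))
  tb <- tensor_basis_from_observables(A1, A2)
  expect_equal(as.integer(tb$dims), c(2L, 2L))
  # computational basis recovered up to phases
  expect_close(Mod(tb$basis), diag(4), 1e-10)
  # joint eigenvector property: A1|ij> = a1_i |ij>, A2|ij> = a2_j |ij>
  for (i in 1:2) for (j in 1:2) {
    v <- tb$basis[, (i - 1) * 2 + j]
    expect_close(A1 %*% v, tb$values1[i] * v, 1e-10)
    expect_close(A2 %*% v, tb$values2[j] * v, 1e-10)
  }
  # conjugated pair: basis = columns of U up to phases
  set.seed(11)
  U <- rand_unitary(4)
  tbU <- tensor_basis_from_observables(U %*% A1 %*% Conj(t(U)),
                                       U %*% A2 %*% Conj(t(U)))
  overlap <- Mod(Conj(t(U)) %*% tbU$basis)
  expect_close(overlap[overlap > 0.5], rep(1, 4), 1e-8)
  expect_close(sort(overlap), c(rep(0, 12), rep(1, 4)), 1e-8)
  expect_error(tensor_basis_from_observables(pauli("z"), pauli("x")),
               "commute")
  expect_error(tensor_basis_from_observables(kronecker(pauli("z"), pauli("z")),
                                             kronecker(diag(2), diag(2))),
               "incompatible|one-dimensional")
})

test_that("Schmidt analysis separates product from entangled pure states", {
  s00 <- is_separable_pure(c(1, 0, 0, 0), c(2, 2))
  expect_true(s00$separable)
  ssing <- is_separable_pure(singlet_state(), c(2, 2))
  expect_false(ssing$separable)
  expect_close(ssing$schmidt, c(1, 1) / sqrt(2), 1e-12)
  set.seed(13)
  for (i in 1:10) {
    psi1 <- rand_pure(2); psi2 <- rand_pure(3)
    prod <- kronecker(psi1, psi2)      # row-major (i-1)*N2+j layout
    expect_true(is_separable_pure(prod, c(2, 3))$separable)
  }
})

test_that("partial traces give marginals satisfying the local-operator duality", {
  r1 <- rand_density_matrix(2); r2 <- rand_density_matrix(3)
  rho <- density_matrix(kronecker(r1, r2), dims = c(2, 3))
  expect_close(partial_trace(rho, keep = 1)$matrix, r1, 1e-12)
  expect_close(partial_trace(rho, keep = 2)$matrix, r2, 1e-12)
  singlet <- pure_state_density(singlet_state(), dims = c(2, 2))
  expect_close(partial_trace(singlet, keep = 1)$matrix, diag(2) / 2, 1e-12)
  expect_close(partial_trace(singlet, keep = 2)$matrix, diag(2) / 2, 1e-12)
  set.seed(17)
  for (i in 1:5) {
    rho <- density_matrix(rand_density_matrix(6), dims = c(2, 3))
    a1 <- rand_hermitian(2)
    lhs <- sum(diag(partial_trace(rho, keep = 1)$matrix %*% a1))
    rhs <- sum(diag(rho$matrix %*% kronecker(a1, diag(3))))
    expect_equal(Re(lhs), Re(rhs), tolerance = 1e-10)
  }
})

test_that("partial transposition is a Hermitian trace-preserving involution", {
  set.seed(19)
  rho <- density_matrix(rand_density_matrix(6), dims = c(2, 3))
  pt <- partial_transpose(rho)
  expect_close(pt, Conj(t(pt)), 1e-12)
  expect_equal(Re(sum(diag(pt))), 1, tolerance = 1e-12)
  expect_close(partial_transpose(pt, dims = c(2, 3)), rho$matrix, 1e-12)
  # product states stay PSD; the singlet picks up eigenvalue -1/2
  prod <- density_matrix(kronecker(rand_density_matrix(2),
                                   rand_density_matrix(2)), dims = c(2, 2))
  expect_gte(min(eigen(partial_transpose(prod), symmetric = TRUE,
                       only.values = TRUE)$values), -1e-12)
  evs <- eigen(partial_transpose(pure_state_density(singlet_state(),
                                                    dims = c(2, 2))),
               symmetric = TRUE, only.values = TRUE)$values
  expect_close(sort(evs), c(-0.5, 0.5, 0.5, 0.5), 1e-12)
})

test_that("negativity is zero on separable mixtures and 1/2 on the singlet", {
  set.seed(23)
  for (i in 1:10) {
    rho <- rand_separable_mixture(2, sample(2:3, 1))
    nn <- negativity(rho)
    expect_lt(nn$negativity, 1e-10)
    expect_equal(nn$log_negativity, log2(2 * nn$negativity + 1),
                 tolerance = 1e-12)
  }
  nsing <- negativity(pure_state_density(singlet_state(), dims = c(2, 2)))
  expect_equal(nsing$negativity, 0.5, tolerance = 1e-12)
  expect_equal(nsing$log_negativity, 1, tolerance = 1e-12)
  # Werner family: PT eigenvalue (1 - 3p)/4 crosses zero at p = 1/3
  expect_lt(negativity(werner_state(1 / 3))$negativity, 1e-12)
  for (p in c(0.5, 0.8, 1)) {
    expect_equal(negativity(werner_state(p))$negativity, (3 * p - 1) / 4,
                 tolerance = 1e-10)
  }
})

test_that("two-qubit concurrence matches its closed forms", {
  expect_equal(concurrence(pure_state_density(c(1, 0, 0, 0), dims = c(2, 2))),
               0, tolerance = 1e-10)
  expect_equal(concurrence(pure_state_density(singlet_state(), dims = c(2, 2))),
               1, tolerance = 1e-10)
  for (p in c(1 / 3, 0.5, 0.75, 1)) {
    expect_equal(concurrence(werner_state(p)), max(0, (3 * p - 1) / 2),
                 tolerance = 1e-8)
  }
  expect_error(concurrence(density_matrix(diag(6) / 6, dims = c(2, 3))), "2, 2|4x4")
})

test_that("entropies and mutual information behave on pure, singlet and product states", {
  pure <- pure_state_density(rand_pure(4), dims = c(2, 2))
  expect_equal(entropies(pure)$S, 0, tolerance = 1e-8)
  es <- entropies(pure_state_density(singlet_state(), dims = c(2, 2)))
  expect_equal(es$S_A, 1, tolerance = 1e-10)
  expect_equal(es$S_B, 1, tolerance = 1e-10)
  expect_equal(es$mutual_information, 2, tolerance = 1e-10)
  set.seed(29)
  prod <- density_matrix(kronecker(rand_density_matrix(2),
                                   rand_density_matrix(3)), dims = c(2, 3))
  expect_equal(entropies(prod)$mutual_information, 0, tolerance = 1e-8)
})

test_that("PPT verdicts are conclusive only where the dimension theorem allows", {
  expect_equal(ppt_verdict(pure_state_density(singlet_state(), dims = c(2, 2))),
               "entangled")
  expect_equal(ppt_verdict(density_matrix(diag(4) / 4, dims = c(2, 2))),
               "separable")
  expect_equal(ppt_verdict(density_matrix(diag(9) / 9, dims = c(3, 3))),
               "undetermined")
})

test_that("pure-state entanglement detectors agree (negativity, Schmidt, entropy)", {
  set.seed(31)
  for (i in 1:15) {
    psi <- rand_pure(4)
    rho <- pure_state_density(psi, dims = c(2, 2))
    n <- negativity(rho)$negativity
    sep <- is_separable_pure(psi, c(2, 2))
    sa <- entropies(rho)$S_A
    if (sep$separable) {
      expect_lt(n, 1e-8); expect_lt(sa, 1e-6)
    } else {
      expect_gt(n, 1e-8); expect_gt(sa, 1e-8)
    }
  }
})

test_that("all measures are nondecreasing in the Werner mixing weight", {
  ps <- seq(1 / 3, 1, length.out = 7)
  vals <- sapply(ps, function(p) {
    w <- werner_state(p)
    c(negativity(w)$negativity, concurrence(w),
      entropies(w)$mutual_information)
  })
  for (r in 1:3) expect_true(all(diff(vals[r, ]) > -1e-9))
})

test_that("CHSH respects classical and Tsirelson bounds", {
  s <- chsh_optimal_settings()
  singlet <- pure_state_density(singlet_state(), dims = c(2, 2))
  expect_equal(chsh_expectation(singlet, s$A, s$Ap, s$B, s$Bp), 2 * sqrt(2),
               tolerance = 1e-10)
  # oracle: direct 4x4 trace algebra
  S_direct <- sum(vapply(list(list(s$A, s$B), list(s$A, s$Bp),
                              list(s$Ap, s$B)), function(ab) {
    Re(sum(diag(singlet$matrix %*% kronecker(ab[[1]], ab[[2]]))))
  }, 0)) - Re(sum(diag(singlet$matrix %*% kronecker(s$Ap, s$Bp))))
  expect_equal(S_direct, 2 * sqrt(2), tolerance = 1e-10)
  set.seed(37)
  for (i in 1:10) {
    prod <- density_matrix(kronecker(rand_density_matrix(2),
                                     rand_density_matrix(2)), dims = c(2, 2))
    expect_lte(abs(chsh_expectation(prod, s$A, s$Ap, s$B, s$Bp)), 2 + 1e-10)
  }
  # Werner: S scales linearly with p
  svals <- vapply(c(0.2, 0.5, 0.9), function(p) {
    chsh_expectation(werner_state(p), s$A, s$Ap, s$B, s$Bp)
  }, 0)
  expect_close(svals, 2 * sqrt(2) * c(0.2, 0.5, 0.9), 1e-10)
  expect_error(chsh_expectation(singlet, pauli("z") * 2, s$Ap, s$B, s$Bp),
               "dichotomous")
})

test_that("the entanglement report aggregates consistently", {
  rep_s <- entanglement_report(pure_state_density(singlet_state(),
                                                  dims = c(2, 2)))
  expect_equal(rep_s$negativity, 0.5, tolerance = 1e-10)
  expect_equal(rep_s$log_negativity, 1, tolerance = 1e-10)
  expect_equal(rep_s$concurrence, 1, tolerance = 1e-10)
  expect_equal(rep_s$entanglement_entropy, 1, tolerance = 1e-10)
  expect_equal(rep_s$mutual_information, 2, tolerance = 1e-10)
  expect_equal(rep_s$ppt_verdict, "entangled")
  set.seed(41)
  prod <- pure_state_density(kronecker(rand_pure(2), rand_pure(2)),
                             dims = c(2, 2))
  rep_p <- entanglement_report(prod)
  expect_lt(rep_p$negativity, 1e-10)
  expect_lt(rep_p$concurrence, 1e-7)
  expect_equal(rep_p$ppt_verdict, "separable")
  rep_m <- entanglement_report(density_matrix(diag(4) / 4, dims = c(2, 2)))
  expect_equal(rep_m$negativity, 0, tolerance = 1e-12)
  expect_null(rep_m$entanglement_entropy)
  expect_equal(rep_m$ppt_verdict, "separable")
  # covariance input is normalized on the way in
  rep_c <- entanglement_report(ql_cov(singlet_cov()), dims = c(2, 2))
  expect_equal(rep_c$negativity, 0.5, tolerance = 1e-10)
})
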