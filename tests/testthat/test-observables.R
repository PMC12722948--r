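test_that("spectral decomposition merges degeneracies and reconstructs the operator", {
  obs <- spectral_decompose(diag(c(1, 1, 2)))
  expect_equal(sort(obs$values), c(1, 2))
  ranks <- sort(vapply(obs$projectors, function(P) Re(sum(diag(P))), 0))
  expect_equal(ranks, c(1, 2))
  px <- spectral_decompose(pauli("x"))
  for (P in px$projectors) {            # projectors onto (1, +-1)/sqrt(2)
    v <- c(1, sign(Re(P[1, 2]))) / sqrt(2)
    expect_close(P, outer(v, Conj(v)), 1e-12)
  }
  set.seed(2)
  for (i in 1:5) {
    M <- rand_hermitian(5)
    obs <- spectral_decompose(M)
    recon <- Reduce(`+`, Map(function(a, E) a * E, obs$values, obs$projectors))
    expect_close(recon, M, 1e-12)
    compl <- Reduce(`+`, obs$projectors)
    expect_close(compl, diag(5) + 0i, 1e-12)
    for (j in seq_along(obs$projectors)) {
      for (k in seq_along(obs$projectors)) {
        prod <- obs$projectors[[j]] %*% obs$projectors[[k]]
        expect_close(prod, if (j == k) obs$projectors[[j]] else 0 * prod, 1e-10)
      }
    }
  }
  expect_error(spectral_decompose(matrix(c(0, 1, 0, 0), 2, 2)), "Hermitian")
})

test_that("Born averages match the probability-weighted spectrum", {
  expect_equal(born_average(density_matrix(diag(2) / 2), pauli("z")), 0,
               tolerance = 1e-12)
  expect_equal(born_average(pure_state_density(c(1, 0)), pauli("z")), 1,
               tolerance = 1e-12)
  set.seed(13)
  for (i in 1:10) {
    rho <- density_matrix(rand_density_matrix(4))
    A <- spectral_decompose(rand_hermitian(4))
    p <- outcome_probabilities(rho, A)
    expect_equal(born_average(rho, A), sum(A$values * p), tolerance = 1e-10)
    expect_equal(sum(p), 1, tolerance = 1e-10)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("outcome probabilities are diagonal covariance weights", {
  p <- outcome_probabilities(c(1, 1) / sqrt(2), diag(c(1, -1)))
  expect_close(sort(as.numeric(p)), c(0.5, 0.5), 1e-12)
  # rho = C / Tr C for diagonal C: probabilities c_ii / sum c_jj
  rho <- normalize_to_density(diag(c(1, 3)))
  p <- outcome_probabilities(rho, diag(c(5, 7)))
  expect_equal(as.numeric(p[order(names(p))]), c(0.25, 0.75),
               tolerance = 1e-12)      # eigenvalue 5 pairs with c_11 = 1
})

test_that("sampled outcomes follow the Born distribution", {
  set.seed(29)
  rho <- density_matrix(rand_density_matrix(3))
  A <- spectral_decompose(diag(c(1, 2, 3)))
  p <- outcome_probabilities(rho, A)
  n <- 1e5
  draws <- sample(A$values, n, replace = TRUE, prob = p)
  freq <- vapply(A$values, function(a) mean(draws == a), 0)
  expect_lt(max(abs(freq - as.numeric(p))), 4 * sqrt(0.25 / n))
})

test_that("the projection postulate updates states idempotently", {
  rho0 <- pure_state_density(c(1, 0))
  up <- measurement_update(rho0, pauli("z"), 1)
  expect_close(up$post_state$matrix, rho0$matrix, 1e-12)
  expect_equal(up$probability, 1, tolerance = 1e-12)
  mixed <- density_matrix(diag(2) / 2)
  up2 <- measurement_update(mixed, pauli("z"), 1)
  expect_close(up2$post_state$matrix, diag(c(1, 0)) + 0i, 1e-12)
  expect_equal(up2$probability, 0.5, tolerance = 1e-12)
  # Lueders repeatability: re-measuring returns the same outcome w.p. 1
  set.seed(37)
  for (i in 1:5) {
    rho <- density_matrix(rand_density_matrix(4))
    A <- spectral_decompose(rand_hermitian(4))
    a <- A$values[2]
    up <- measurement_update(rho, A, a)
    p2 <- outcome_probabilities(up$post_state, A)
    expect_equal(as.numeric(p2[which.min(abs(A$values - a))]), 1,
                 tolerance = 1e-10)
    again <- measurement_update(up$post_state, A, a)
    expect_close(again$post_state$matrix, up$post_state$matrix, 1e-10)
  }
  expect_error(measurement_update(pure_state_density(c(1, 0)), pauli("z"), -1),
               "zero-probability")
})

test_that("sequential z-then-x and x-then-z probabilities differ as computed by hand", {
  rho <- pure_state_density(c(1, 0))
  # oracle by direct 2x2 algebra: Ez+ = |0><0|, Ex+ = |+><+|
  Ez <- diag(c(1, 0)) + 0i
  Ex <- matrix(0.5, 2, 2) + 0i
  r <- rho$matrix
  expect_equal(Re(sum(diag(Ex %*% Ez %*% r %*% Ez))), 0.5)
  expect_equal(Re(sum(diag(Ez %*% Ex %*% r %*% Ex))), 0.25)
  expect_equal(sequential_joint_probability(rho, pauli("z"), 1, pauli("x"), 1),
               0.5, tolerance = 1e-12)
  expect_equal(sequential_joint_probability(rho, pauli("x"), 1, pauli("z"), 1),
               0.25, tolerance = 1e-12)
  asym <- order_effect_asymmetry(rho, pauli("z"), pauli("x"))
  expect_equal(asym["1", "1"], 0.25, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sum(asym), 0, tolerance = 1e-12)
})

test_that("sequential joint probabilities normalize and marginalize correctly", {
  set.seed(43)
  rho <- density_matrix(rand_density_matrix(3))
  A <- spectral_decompose(rand_hermitian(3))
  B <- spectral_decompose(rand_hermitian(3))
  total <- 0
  for (a in A$values) {
    marg <- 0
    for (b in B$values) {
      pj <- sequential_joint_probability(rho, A, a, B, b)
      total <- total + pj
      marg <- marg + pj
    }
    expect_equal(marg, as.numeric(outcome_probabilities(rho, A)[
      which.min(abs(A$values - a))]), tolerance = 1e-10)
  }
  expect_equal(total, 1, tolerance = 1e-10)
})

test_that("order-effect asymmetry vanishes exactly for commuting observables", {
  set.seed(47)
  for (i in 1:20) {
    n <- sample(2:4, 1)
    U <- rand_unitary(n)
    A <- U %*% diag(rnorm(n)) %*% Conj(t(U))
    B <- U %*% diag(rnorm(n)) %*% Conj(t(U))   # shared eigenbasis: commute
    rho <- density_matrix(rand_density_matrix(n))
    asym <- order_effect_asymmetry(rho, hermitize(A), hermitize(B))
    expect_lt(max(abs(asym)), 1e-10)
  }
})

test_that("the quadratic-form average equals Tr(C A) algebraically", {
  set.seed(53)
  for (i in 1:10) {
    N <- sample(2:5, 1)
    e <- signal_ensemble(rand_complex(40, N))
    A <- rand_hermitian(N)
    lhs <- quadratic_form_average(e, A)
    Chat <- estimate_covariance(e, center = FALSE)$matrix
    expect_equal(lhs, Re(sum(diag(Chat %*% A))), tolerance = 1e-10)
    # normalized version is the Born average in the estimated state
    rho <- normalize_to_density(Chat)
    expect_equal(lhs / Re(sum(diag(Chat))), born_average(rho, A),
                 tolerance = 1e-10)
  }
  e <- signal_ensemble(rand_complex(30, 3))
  expect_equal(quadratic_form_average(e, diag(3)),
               mean(rowSums(Mod(e$data)^2)), tolerance = 1e-10)
})

test_that("correlations of compatible observables match quantum and classical routes", {
  expect_equal(commuting_correlation(density_matrix(diag(2) / 2),
                                     pauli("z"), pauli("z")), 1,
               tolerance = 1e-12)
  singlet <- pure_state_density(singlet_state(), dims = c(2, 2))
  Z1 <- kronecker(pauli("z"), diag(2))
  Z2 <- kronecker(diag(2), pauli("z"))
  expect_equal(commuting_correlation(singlet, Z1, Z2), -1, tolerance = 1e-10)
  expect_error(commuting_correlation(density_matrix(diag(2) / 2),
                                     pauli("z"), pauli("x")), "commute")
  # classical route: average of Q_{A1A2} over a matched Gaussian ensemble
  set.seed(59)
  Ct <- rand_density_matrix(4) * 4
  n <- 2e4
  e <- gaussian_ensemble(Ct, n, seed = 61)
  rho_hat <- normalize_to_density(estimate_covariance(e, center = FALSE))
  q <- quadratic_form_average(e, hermitize(Z1 %*% Z2))
  trC <- Re(sum(diag(estimate_covariance(e, center = FALSE)$matrix)))
  expect_equal(q / trC, commuting_correlation(rho_hat, Z1, Z2),
               tolerance = 1e-8)
})
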