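# msm_kinetics: rate conversion, counting, propagation, tICA, k-centers,
# and the cis/trans combination rule

test_that("rate_to_probability limits and precision", {
  expect_equal(rate_to_probability(0, 1), 0)
  expect_equal(rate_to_probability(1e9, 1), 1, tolerance = 1e-12)
  # tiny k*t handled via expm1 (no catastrophic cancellation)
  p <- rate_to_probability(0.01, 1e-6)
  expect_equal(p, 1e-8 - 0.5e-16, tolerance = 1e-10)
  expect_error(rate_to_probability(-1, 1), ">=")
  expect_error(rate_to_probability(1, 0), "> 0")
})

test_that("transition counting: alternation, constant, recovery", {
  T1 <- estimate_transition_matrix(rep(c(0L, 1L), 50), lag_steps = 1)
  expect_equal(T1$T, rbind(c(0, 1), c(1, 0)))

  Tc <- estimate_transition_matrix(rep(3L, 40), lag_steps = 1)
  expect_equal(Tc$T, matrix(1, 1, 1))
  expect_equal(Tc$labels, "3")

  # recover a known 3-state chain from 1e5 sampled steps
  Ttrue <- rbind(c(0.90, 0.08, 0.02),
                 c(0.05, 0.90, 0.05),
                 c(0.10, 0.10, 0.80))
  traj <- with_seed(5, {
    x <- integer(1e5)
    x[1] <- 1L
    for (i in 2:1e5) x[i] <- sample.int(3, 1, prob = Ttrue[x[i - 1], ])
    x
  })
  Th <- estimate_transition_matrix(traj, lag_steps = 1)
  expect_lt(max(abs(Th$T - Ttrue)), 0.02)

  # two non-communicating states (beyond a single observed state) error
  expect_error(estimate_transition_matrix(list(rep(1L, 10), rep(2L, 10)),
                                          lag_steps = 1), "connected")
})

test_that("propagation: identity, fixed point, analytic 2-state relaxation", {
  p0 <- population_vector(c(0.2, 0.3, 0.5))
  Tid <- transition_matrix(diag(3), lag = 1)
  expect_equal(as.numeric(propagate(Tid, p0, 100)), as.numeric(p0))

  a <- 0.2; b <- 0.05
  T2 <- transition_matrix(rbind(c(1 - a, a), c(b, 1 - b)), lag = 1)
  pi_ <- stationary_distribution(T2)
  expect_equal(as.numeric(propagate(T2, pi_, 50)), as.numeric(pi_),
               tolerance = 1e-10)
  # closed form: p1(n) = pi1 + (p1(0) - pi1) (1 - a - b)^n
  n_steps <- 17
  p <- propagate(T2, population_vector(c(1, 0)), n_steps)
  pi1 <- b / (a + b)
  expect_equal(p[1], pi1 + (1 - pi1) * (1 - a - b)^n_steps, tolerance = 1e-6)

  # population conservation for random stochastic matrices
  set.seed(6)
  for (rep in 1:5) {
    M <- matrix(runif(25), 5, 5)
    M <- M / rowSums(M)
    Tm <- transition_matrix(M, lag = 2)
    p0 <- runif(5); p0 <- p0 / sum(p0)
    pt <- propagate(Tm, population_vector(p0), 2 * 64)
    expect_lt(abs(sum(pt) - 1), 1e-10)
    expect_true(all(pt >= -1e-12))
  }

  expect_warning(propagate(T2, population_vector(c(1, 0)), 1.4), "lag multiple")
  expect_error(propagate(T2, population_vector(c(1, 0, 0)), 1), "mismatch")
})

test_that("tICA finds the slow coordinate and matches a dense solver", {
  # two independent AR(1) processes with distinct relaxation times
  gen_ar <- function(n, phi, seed) with_seed(seed, {
    x <- numeric(n)
    for (i in 2:n) x[i] <- phi * x[i - 1] + rnorm(1)
    x
  })
  slow <- gen_ar(20000, 0.99, 31) # timescale ~ -1/log(0.99) ~ 100
  fast <- gen_ar(20000, 0.60, 32)
  X <- cbind(fast, slow)
  res <- tica_decompose(X, lag_steps = 5)
  v1 <- res$components[, 1]
  expect_gt(abs(v1[2]) / sqrt(sum(v1^2)), 0.95)
  expect_true(all(diff(res$timescales) <= 1e-9)) # non-increasing

  # duplicated feature column: regularization guards rank deficiency
  expect_no_error(tica_decompose(cbind(X, X[, 2]), lag_steps = 5))

  # eigenvalues match a direct generalized solve on a tiny dataset
  set.seed(33)
  Y <- matrix(rnorm(200 * 3), 200, 3) %*% matrix(c(1, .5, 0, 0, 1, .3, 0, 0, 1), 3)
  lag <- 2; eps <- 1e-6
  res2 <- tica_decompose(Y, lag_steps = lag, eps = eps)
  Yc <- sweep(Y, 2, colMeans(Y))
  A <- Yc[1:(200 - lag), ]; B <- Yc[(1 + lag):200, ]
  C0 <- (crossprod(A) + crossprod(B)) / (2 * nrow(A)) + eps * diag(3)
  Ct <- (crossprod(A, B) + crossprod(B, A)) / (2 * nrow(A))
  lam_oracle <- sort(Re(eigen(solve(C0, Ct))$values), decreasing = TRUE)
  expect_equal(res2$eigenvalues, lam_oracle, tolerance = 1e-8)
})

test_that("k-centers: exact limits, 2x covering bound, blob separation", {
  set.seed(44)
  X <- matrix(rnorm(30), 15, 2)
  res <- kcenters_cluster(X, k = 15, seed = 1)
  expect_equal(res$covering_radius, 0)
  expect_equal(sort(res$centers), 1:15)

  # 12-point 1-D sets: greedy radius <= 2x brute-force optimum
  for (rep in 1:4) {
    x <- matrix(sort(runif(12, 0, 10)), ncol = 1)
    for (k in 2:4) {
      got <- kcenters_cluster(x, k, seed = rep)$covering_radius
      combs <- utils::combn(12, k)
      opt <- min(apply(combs, 2, function(cs)
        max(apply(abs(outer(x[, 1], x[cs, 1], "-")), 1, min))))
      expect_lte(got, 2 * opt + 1e-12)
    }
  }

  blobs <- rbind(matrix(rnorm(40, 0, .3), 20, 2),
                 matrix(rnorm(40, 20, .3), 20, 2))
  res2 <- kcenters_cluster(blobs, 2, seed = 3)
  expect_equal(sort(unique((res2$centers > 20) * 1L)), c(0L, 1L))
  expect_error(kcenters_cluster(blobs, 0, seed = 1), "positive")
})

test_that("combine_isomer_models: decoupled limit and stochasticity", {
  tr <- generate_two_regime_msm(n = 3, m = 3, k = 0, seed = 9)
  M0 <- combine_isomer_models(tr$T_cis, tr$T_trans, isomer_coupling(0))
  expect_equal(M0$T[1:3, 1:3], tr$T_cis$T)
  expect_equal(M0$T[4:6, 4:6], tr$T_trans$T)
  expect_true(all(M0$T[1:3, 4:6] == 0))

  tr2 <- generate_two_regime_msm(n = 3, m = 4, k = 0.01, lag = 1e-3, seed = 10)
  M <- combine_isomer_models(tr2$T_cis, tr2$T_trans, tr2$coupling,
                             tr2$structures_cis, tr2$structures_trans)
  expect_true(all(abs(rowSums(M$T) - 1) < 1e-10))
  expect_equal(unname(attr(M, "pairs")), unname(tr2$designed_pairs))

  expect_error(combine_isomer_models(
    transition_matrix(diag(2), lag = 1),
    transition_matrix(diag(2), lag = 2), isomer_coupling(0)), "lag")
})

test_that("2-cis/2-trans toy pairing matches a hand-enumerated rule", {
  # hand-placed geometries: trans1 ~ cis1 (tiny pair RMSD, kept); trans2 is
  # closer to its own trans neighbour than to any cis state, so its pair
  # fails the kinetic-plausibility filter and is dropped
  zig <- function(amp) cbind(seq(0, 3.8 * 7, by = 3.8), amp * c(0, 1, 0, 1, 0, 1, 0, 1), 0)
  cis1 <- bead_structure(zig(1.0))
  cis2 <- bead_structure(zig(6.0))
  trans1 <- bead_structure(zig(1.05))
  trans2 <- bead_structure(zig(1.2))
  scis <- list(cis1, cis2); strans <- list(trans1, trans2)
  Tc <- transition_matrix(rbind(c(.9, .1), c(.1, .9)), lag = 1)
  Tt <- transition_matrix(rbind(c(.9, .1), c(.1, .9)), lag = 1)

  # oracle: enumerate all RMSDs and apply the rule manually
  R <- function(a, b) rmsd_superposed(a, b, "CA")
  keep <- list()
  for (j in 1:2) {
    rj <- c(R(strans[[j]], scis[[1]]), R(strans[[j]], scis[[2]]))
    i_star <- which.min(rj)
    r_tt <- R(strans[[j]], strans[[setdiff(1:2, j)]])
    r_cc <- R(scis[[i_star]], scis[[setdiff(1:2, i_star)]])
    if (rj[i_star] < r_tt && rj[i_star] < r_cc) keep[[length(keep) + 1]] <- c(j, i_star)
  }
  oracle_pairs <- do.call(rbind, keep)

  M <- combine_isomer_models(Tc, Tt, isomer_coupling(k = 0.05), scis, strans)
  expect_equal(unname(attr(M, "pairs")), unname(oracle_pairs))
  # the kept pair gets p = 1 - exp(-k t) in both directions
  p <- rate_to_probability(0.05, 1)
  jt <- 2 + oracle_pairs[1, 1]; ic <- oracle_pairs[1, 2]
  expect_equal(M$T[jt, ic], p)
  expect_equal(M$T[ic, jt], p)
  expect_true(all(abs(rowSums(M$T) - 1) < 1e-10))
})

test_that("coupled two-regime model conserves and relaxes regime mass", {
  tr <- generate_two_regime_msm(n = 3, m = 3, k = 0, lag = 1e-6, seed = 12)
  M0 <- combine_isomer_models(tr$T_cis, tr$T_trans, isomer_coupling(0))
  p0 <- population_vector(c(tr$pi_cis, rep(0, 3)))
  pt <- propagate(M0, p0, 1e-6 * 500)
  expect_equal(sum(pt[1:3]), 1, tolerance = 1e-10) # k = 0: no crossing

  # with k > 0, cis-block mass relaxes at ~ k (2-regime analytic model)
  k <- 0.01; lag <- 1e-3
  tr2 <- generate_two_regime_msm(n = 3, m = 3, k = k, lag = lag, seed = 12)
  M <- combine_isomer_models(tr2$T_cis, tr2$T_trans, tr2$coupling,
                             tr2$structures_cis, tr2$structures_trans)
  steps <- 2000
  pt2 <- propagate(M, p0, lag * steps)
  cis_mass <- sum(pt2[1:3])
  # symmetric coupling relaxes toward 1/2 with rate ~ 2k * (coupled fraction)
  expect_lt(cis_mass, 1 - 1e-4)
  expect_gt(cis_mass, 0.5 - 1e-6)
})

test_that("two-regime generator hits its designed stationary targets", {
  tr <- generate_two_regime_msm(n = 5, m = 4, seed = 3)
  expect_equal(as.numeric(stationary_distribution(tr$T_cis)), tr$pi_cis,
               tolerance = 1e-8)
  expect_equal(as.numeric(stationary_distribution(tr$T_trans)), tr$pi_trans,
               tolerance = 1e-8)
  # bit-identical rerun
  tr_again <- generate_two_regime_msm(n = 5, m = 4, seed = 3)
  expect_identical(tr$T_cis$T, tr_again$T_cis$T)
  expect_identical(coords(tr$structures_trans[[2]]),
                   coords(tr_again$structures_trans[[2]]))
})
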