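# eros_refine: objective, annealing, theta scan, stability, ablation

test_that("ensemble profile: delta weights, means, loop oracle", {
  fx <- easy_fixture()
  profs <- fx$ens$profiles
  N <- length(profs)
  w <- rep(0, N); w[3] <- 1
  expect_equal(ensemble_profile(profs, w)$I, profs[[3]]$I)

  w2 <- c(0.5, 0.5, rep(0, N - 2))
  expect_equal(ensemble_profile(profs, w2)$I, (profs[[1]]$I + profs[[2]]$I) / 2)

  wr <- with_seed(2, { x <- runif(N); x / sum(x) })
  loop <- 0 * profs[[1]]$I
  for (k in seq_len(N)) loop <- loop + wr[k] * profs[[k]]$I
  expect_equal(ensemble_profile(profs, wr)$I, loop, tolerance = 1e-12)
})

test_that("objective G: vanishing penalty at prior, theta = 0, hand value", {
  fx <- easy_fixture()
  profs <- fx$ens$profiles[1:3]
  expt <- fx$expt$observed
  w0 <- ensemble_weights(rep(1 / 3, 3))
  g <- objective_G(w0, profs, expt, theta = 5)
  expect_equal(g$penalty, 0)
  expect_equal(g$G, g$chi2)

  w <- ensemble_weights(c(.5, .3, .2))
  g0 <- objective_G(w, profs, expt, theta = 0)
  expect_equal(g0$G, g0$chi2)

  # hand arithmetic: sum w ln(3 w) for w = (.5, .3, .2)
  hand <- .5 * log(1.5) + .3 * log(0.9) + .2 * log(0.6)
  expect_equal(hand, 0.06895927, tolerance = 1e-6)
  g1 <- objective_G(w, profs, expt, theta = 2)
  expect_equal(g1$penalty, hand, tolerance = 1e-10)
  expect_equal(g1$G, g1$chi2 + 2 * hand, tolerance = 1e-10)

  wz <- ensemble_weights(c(.5, .5, 0), prior = c(.5, .4, .1))
  expect_equal(objective_G(wz, profs, expt, theta = 1)$penalty,
               .5 * log(1) + .5 * log(.5 / .4)) # 0 log 0 term dropped
  expect_error(objective_G(ensemble_weights(c(.5, .3, .2), prior = c(.5, .5, 0)),
                           profs, expt, theta = 1), "infinite penalty")
})

test_that("annealing is bit-reproducible and traces satisfy invariants", {
  fx <- easy_fixture()
  cfg <- refinement_config(theta = 0.5, seed = 77, max_sweeps = 300)
  r1 <- anneal_refine(ensemble_weights(rep(1 / 6, 6)), fx$ens$profiles,
                      fx$expt$observed, cfg)
  r2 <- anneal_refine(ensemble_weights(rep(1 / 6, 6)), fx$ens$profiles,
                      fx$expt$observed, cfg)
  expect_identical(r1$weights$w, r2$weights$w)
  expect_identical(r1$trace, r2$trace)

  # weights on the simplex
  expect_equal(sum(r1$weights$w), 1, tolerance = 1e-10)
  expect_true(all(r1$weights$w >= 0))
  # G decomposition identity at every recorded point
  expect_lt(max(abs(r1$trace$G - (r1$trace$chi2 + 0.5 * r1$trace$penalty))), 1e-8)
  # best-visited G non-increasing along the trace
  expect_true(all(diff(r1$trace$G) <= 1e-12))
  expect_equal(r1$G, r1$chi2 + 0.5 * r1$penalty, tolerance = 1e-10)
})

test_that("huge theta pins the refined weights to the prior", {
  fx <- easy_fixture()
  prior <- ensemble_weights(fx$ens$weights, fx$ens$weights)
  r <- anneal_refine(prior, fx$ens$profiles, fx$expt$observed,
                     refinement_config(theta = 1e6, seed = 5))
  tv <- 0.5 * sum(abs(r$weights$w - prior$prior))
  expect_lt(tv, 1e-3)
})

test_that("noiseless ground truth is recovered at theta = 0", {
  fx <- std_fixture()
  r <- anneal_refine(ensemble_weights(rep(1 / 20, 20)), fx$ens$profiles,
                     fx$noiseless$observed, refinement_config(theta = 0, seed = 101))
  expect_lt(r$chi2, 0.01)
  expect_gt(cor(r$weights$w, fx$ens$weights), 0.9)
})

test_that("theta scan: chi2 non-decreasing in theta within tolerance", {
  fx <- easy_fixture()
  prior <- ensemble_weights(rep(1 / 6, 6))
  # stochastic tolerance: spread of converged chi2 across reruns at theta 0
  reruns <- vapply(1:3, function(i)
    anneal_refine(prior, fx$ens$profiles, fx$expt$observed,
                  refinement_config(theta = 0, seed = 300 + i))$chi2, numeric(1))
  tol <- 2 * max(diff(range(reruns)), 0.02)
  sc <- theta_scan(prior, fx$ens$profiles, fx$expt$observed,
                   thetas = c(0, 0.1, 0.5, 2, 10),
                   cfg = refinement_config(seed = 55))
  expect_true(all(diff(sc$table$chi2) >= -tol))
  expect_true(all(sc$table$chi2[1] <= sc$table$chi2 + tol))
  expect_true(is.finite(sc$elbow_theta) || is.na(sc$elbow_theta))
})

test_that("stability: identical seeds give zero spread, reordering is moot", {
  fx <- easy_fixture()
  prior <- ensemble_weights(rep(1 / 6, 6))
  cfg <- refinement_config(theta = 0.5, seed = 9)
  st <- stability_check(prior, fx$ens$profiles, fx$expt$observed, cfg,
                        n_runs = 3, seeds = c(4L, 4L, 4L))
  expect_equal(st$max_fraction, 0)
  st2 <- stability_check(prior, fx$ens$profiles, fx$expt$observed, cfg,
                         n_runs = 4, seeds = c(1L, 2L, 3L, 4L))
  st3 <- stability_check(prior, fx$ens$profiles, fx$expt$observed, cfg,
                         n_runs = 4, seeds = c(4L, 3L, 2L, 1L))
  expect_equal(st2$max_fraction, st3$max_fraction, tolerance = 1e-12)
  expect_equal(st2$mean_fraction, st3$mean_fraction, tolerance = 1e-12)
})

test_that("ablation: empty mask is identity; degeneracy vs necessity", {
  fx <- easy_fixture()
  profs <- fx$ens$profiles
  cfg <- refinement_config(theta = 0, seed = 404)
  prior <- ensemble_weights(rep(1 / 6, 6))
  none <- ablate_and_refine(prior, profs, fx$expt$observed, cfg,
                            remove_states = integer(0))
  expect_identical(none$result$weights$w, none$full_result$weights$w)
  expect_equal(none$delta_chi2, 0)

  # SAXS-degenerate construction: states 7, 8 duplicate states 1, 2 exactly
  profs_dup <- c(profs, profs[1:2])
  w_true <- c(0.25, 0.20, 0.15, 0.15, 0.10, 0.05, 0.05, 0.05)
  expt <- generate_synthetic_experiment(profs_dup, w_true, noise = 0.03, seed = 71)
  prior8 <- ensemble_weights(rep(1 / 8, 8))
  noise_scale <- {
    runs <- vapply(1:3, function(i)
      anneal_refine(prior8, profs_dup, expt$observed,
                    refinement_config(theta = 0, seed = 500 + i))$chi2, numeric(1))
    max(diff(range(runs)), 0.05)
  }
  degen <- ablate_and_refine(prior8, profs_dup, expt$observed,
                             refinement_config(theta = 0, seed = 42),
                             remove_states = c(7L, 8L))
  expect_lt(abs(degen$delta_chi2), 3 * noise_scale)

  # necessity construction: state 4 (an extended state) carries half the
  # weight and is the only large state retained in the pool
  w_need <- c(0.15, 0.15, 0.1, 0.5, 0, 0.1)
  expt2 <- generate_synthetic_experiment(profs, w_need, noise = 0.03, seed = 72)
  need <- ablate_and_refine(ensemble_weights(rep(1 / 6, 6)), profs,
                            expt2$observed,
                            refinement_config(theta = 0, seed = 43),
                            remove_states = c(4L, 5L))
  expect_gt(need$delta_chi2, 10 * noise_scale)

  expect_error(ablate_and_refine(prior, profs, fx$expt$observed, cfg,
                                 remove_states = 1:5), "at least 2")
})
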