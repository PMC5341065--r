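# Maximum-entropy-regularized ensemble reweighting against SAXS data:
# objective G = chi2 + theta * sum_k w_k log(w_k / w0_k), minimized by
# simulated annealing over the weight simplex.

#' Construct ensemble weights with a prior
#'
#' @param w current weights (non-negative, sum to 1 within 1e-10).
#' @param prior prior weights, same constraints; default uniform.
#' @return an `ensemble_weights` object.
#' @export
ensemble_weights <- function(w, prior = NULL) {
  w <- as.numeric(w)
  if (is.null(prior)) prior <- rep(1 / length(w), length(w))
  prior <- as.numeric(prior)
  if (length(prior) != length(w)) stop("prior length mismatch")
  for (v in list(w, prior)) {
    if (any(v < -1e-12)) stop("weights must be non-negative")
    if (abs(sum(v) - 1) > 1e-10) stop("weights must sum to 1 within 1e-10")
  }
  obj <- list(w = pmax(w, 0), prior = pmax(prior, 0))
  class(obj) <- "ensemble_weights"
  obj
}

#' @export
print.ensemble_weights <- function(x, ...) {
  cat(sprintf("ensemble_weights: %d states, max weight %.3g\n",
              length(x$w), max(x$w)))
  invisible(x)
}

# profiles: list of saxs_profile on a common grid -> nq x N intensity matrix
.profile_matrix <- function(profiles, q = NULL) {
  q0 <- profiles[[1]]$q
  for (p in profiles) if (!.same_grid(p$q, q0)) stop("profiles are not on a common q grid")
  I <- vapply(profiles, function(p) p$I, numeric(length(q0)))
  if (!is.null(q)) {
    eps <- 1e-9
    if (min(q) < min(q0) - eps || max(q) > max(q0) + eps)
      stop("extrapolation outside the simulated q range is not allowed")
    I <- apply(I, 2, function(col) stats::approx(q0, col, xout = q)$y)
    q0 <- q
  }
  list(q = q0, I = matrix(I, nrow = length(q0)))
}

#' Population-weighted ensemble SAXS profile
#'
#' `I_ens(q) = sum_k w_k I_k(q)` over per-state profiles on a common grid.
#'
#' @param profiles list of [saxs_profile()] on one q grid.
#' @param w an [ensemble_weights()] or plain simplex vector.
#' @return a [saxs_profile()].
#' @export
ensemble_profile <- function(profiles, w) {
  w <- if (inherits(w, "ensemble_weights")) w$w else as.numeric(w)
  if (length(w) != length(profiles)) stop("one weight per profile required")
  pm <- .profile_matrix(profiles)
  saxs_profile(pm$q, as.numeric(pm$I %*% w))
}

# relative entropy sum w log(w / w0) with 0 log 0 := 0
.rel_entropy <- function(w, w0) {
  if (any(w0 == 0 & w > 0))
    stop("prior weight is zero where refined weight is positive: infinite penalty")
  nz <- w > 0
  sum(w[nz] * log(w[nz] / w0[nz]))
}

#' EROS objective function
#'
#' `G = chi2(ensemble profile, experiment) + theta * sum w log(w / w0)`,
#' with the chi-squared evaluated after an optimal scale/offset fit.
#'
#' @param w an [ensemble_weights()].
#' @param profiles list of per-state [saxs_profile()].
#' @param exp experimental [saxs_profile()] with `sigma`.
#' @param theta regularization strength, >= 0.
#' @return list with `G`, `chi2`, `penalty`.
#' @export
objective_G <- function(w, profiles, exp, theta) {
  if (theta < 0) stop("theta must be >= 0")
  if (!inherits(w, "ensemble_weights")) stop("w must be ensemble_weights")
  chi2 <- chi_squared(ensemble_profile(profiles, w), exp)
  pen <- .rel_entropy(w$w, w$prior)
  list(G = chi2 + theta * pen, chi2 = chi2, penalty = pen)
}

#' Refinement configuration
#'
#' @param theta regularization strength (>= 0).
#' @param t0 initial annealing temperature; NULL (default) calibrates it so
#'   roughly half of the initial trial moves would be accepted.
#' @param cooling geometric cooling factor per sweep, in (0, 1). Default 0.95.
#' @param move_scale sd of the Gaussian log-weight perturbation. Default 0.3.
#' @param max_sweeps hard cap on cooling sweeps. Default 600 (by then the
#'   geometric schedule has cooled by ~1e-13 and the chain is frozen).
#' @param patience stop when the best G improves by less than `tol` over
#'   this many sweeps. Default 50.
#' @param tol convergence tolerance on best-G improvement. Default 1e-7.
#' @param quench append a zero-temperature polish with geometrically
#'   shrinking move scale after the cooling stage. Default TRUE.
#' @param seed integer RNG seed.
#' @return a `refinement_config` object.
#' @export
refinement_config <- function(theta = 0, t0 = NULL, cooling = 0.95,
                              move_scale = 0.3, max_sweeps = 600,
                              patience = 50, tol = 1e-7, quench = TRUE,
                              seed = 1L) {
  if (theta < 0) stop("theta must be >= 0")
  if (cooling <= 0 || cooling >= 1) stop("cooling factor must be in (0, 1)")
  cfg <- list(theta = theta, t0 = t0, cooling = cooling,
              move_scale = move_scale, max_sweeps = max_sweeps,
              patience = patience, tol = tol, quench = quench,
              seed = as.integer(seed))
  class(cfg) <- "refinement_config"
  cfg
}

# chi2 of intensities s against exp (precomputed weights), optimal (c, f)
.chi2_vec <- function(s, y, w) {
  cf <- .wls_scale_offset(s, y, w)
  if (is.null(cf) || cf$c <= 0) {
    f_ <- sum(w * (y - s)) / sum(w)
    return(mean(w * (s + f_ - y)^2))
  }
  mean(w * (cf$c * s + cf$f - y)^2)
}

#' Maximum-entropy ensemble refinement by simulated annealing
#'
#' Metropolis annealing over the weight simplex. A move multiplies one
#' uniformly chosen state's weight by `exp(delta)`, `delta ~ N(0,
#' move_scale)`, and renormalizes. Temperature cools geometrically per
#' sweep (one sweep = N moves); after the stop rule fires, an optional
#' zero-temperature quench with shrinking move scale polishes the
#' minimum. Fully reproducible given `cfg$seed`.
#'
#' @param prior an [ensemble_weights()] (its `w` is the starting point and
#'   its `prior` the entropy reference) or a plain simplex vector.
#' @param profiles list of per-state [saxs_profile()] on one q grid.
#' @param exp experimental [saxs_profile()] with `sigma`.
#' @param cfg a [refinement_config()].
#' @return a `refinement_result`: list with `weights`
#'   ([ensemble_weights()]), `G`, `chi2`, `penalty`, `trace` (data.frame of
#'   best G/chi2/penalty per sweep), `seed`, `config`.
#' @export
anneal_refine <- function(prior, profiles, exp, cfg = refinement_config()) {
  if (!inherits(prior, "ensemble_weights"))
    prior <- ensemble_weights(prior, prior)
  N <- length(prior$w)
  if (N < 2) stop("need at least 2 states to refine")
  pm <- .profile_matrix(profiles, q = exp$q)
  if (is.null(exp$sigma) || any(exp$sigma <= 0)) stop("experiment must carry sigma > 0")
  wq <- 1 / exp$sigma^2
  y <- exp$I
  theta <- cfg$theta

  # sufficient statistics of the sigma-weighted least-squares problem:
  # with them the objective of any single-move candidate costs O(1)
  # instead of O(N_q)
  nq <- length(y)
  Sw <- sum(wq); Sy <- sum(wq * y); Syy <- sum(wq * y^2)
  SI <- as.numeric(crossprod(pm$I, wq))        # sum_q wq I_k
  SIy <- as.numeric(crossprod(pm$I, wq * y))   # sum_q wq I_k y
  G_ <- crossprod(pm$I, wq * pm$I)             # Gram, N x N
  dG <- diag(G_)
  chi2_from <- function(Sx, Sxx, Sxy) {
    den <- Sw * Sxx - Sx^2
    c_ <- (Sw * Sxy - Sx * Sy) / den
    f_ <- (Sy - c_ * Sx) / Sw
    bad <- !is.finite(c_) | c_ <= 0
    if (any(bad)) { # degenerate direction: fix c = 1, fit f only
      f1 <- (Sy - Sx) / Sw
      chi1 <- (Sxx + f1^2 * Sw + Syy + 2 * f1 * Sx - 2 * Sxy -
                 2 * f1 * Sy) / nq
      c_[bad] <- 1; f_[bad] <- f1[bad]
    }
    chi <- (c_^2 * Sxx + f_^2 * Sw + Syy + 2 * c_ * f_ * Sx -
              2 * c_ * Sxy - 2 * f_ * Sy) / nq
    if (any(bad)) chi[bad] <- chi1[bad]
    pmax(chi, 0)
  }
  pterm <- function(x, x0) ifelse(x <= 0, 0,
                                  ifelse(x0 <= 0, Inf, x * log(x / x0)))

  eval_G <- function(w, Iens) {
    chi2 <- .chi2_vec(Iens, y, wq)
    pen <- .rel_entropy(w, prior$prior)
    c(chi2 + theta * pen, chi2, pen)
  }

  with_seed(cfg$seed, {
    w <- prior$w
    # multiplicative moves cannot revive a zero weight: nudge zero-start
    # weights with positive prior onto the open simplex
    revive <- w == 0 & prior$prior > 0
    if (any(revive)) {
      w[revive] <- 1e-10
      w <- w / sum(w)
    }
    g <- eval_G(w, as.numeric(pm$I %*% w))
    if (!all(is.finite(g))) stop("non-finite objective at the starting weights")
    best_w <- w; best_g <- g

    # running statistics of the current point
    Sx <- sum(SI * w); Sxy <- sum(SIy * w)
    Gw <- as.numeric(G_ %*% w); Sxx <- sum(w * Gw)
    pen <- g[3]; cur <- g[1]

    # candidate statistics for multiplying state k's weight by fac and
    # renormalizing; everything O(1)
    propose_stats <- function(k, fac) {
      dwk <- (fac - 1) * w[k]
      s <- 1 + dwk
      Sx2 <- (Sx + dwk * SI[k]) / s
      Sxy2 <- (Sxy + dwk * SIy[k]) / s
      Sxx2 <- (Sxx + 2 * dwk * Gw[k] + dwk^2 * dG[k]) / s^2
      A2 <- pen - pterm(w[k], prior$prior[k]) +
        pterm(w[k] * fac, prior$prior[k])
      pen2 <- A2 / s - log(s)
      chi2_2 <- chi2_from(Sx2, Sxx2, Sxy2)
      list(g = chi2_2 + theta * pen2, chi2 = chi2_2, pen = pen2,
           Sx = Sx2, Sxy = Sxy2, Sxx = Sxx2, dwk = dwk, s = s)
    }

    # calibrate t0 from the positive part of the initial move distribution
    t0 <- cfg$t0
    if (is.null(t0)) {
      dgs <- replicate(64, {
        k <- sample.int(N, 1)
        propose_stats(k, exp(stats::rnorm(1, 0, cfg$move_scale)))$g - cur
      })
      pos <- dgs[dgs > 0 & is.finite(dgs)]
      t0 <- if (length(pos)) mean(pos) / log(2) else 1e-3
    }

    temp <- t0
    trace <- matrix(NA_real_, cfg$max_sweeps, 3)
    last_best <- best_g[1]
    last_improve_sweep <- 0
    sweeps_done <- 0
    for (sw in seq_len(cfg$max_sweeps)) {
      for (mv in seq_len(N)) {
        k <- sample.int(N, 1)
        fac <- exp(stats::rnorm(1, 0, cfg$move_scale))
        pr <- propose_stats(k, fac)
        dg <- pr$g - cur
        if (dg <= 0 || stats::runif(1) < exp(-dg / temp)) {
          w <- w / pr$s
          w[k] <- w[k] * fac
          Gw <- (Gw + pr$dwk * G_[, k]) / pr$s
          Sx <- pr$Sx; Sxy <- pr$Sxy; Sxx <- pr$Sxx
          pen <- pr$pen; cur <- pr$g
          if (cur < best_g[1]) { best_g <- c(cur, pr$chi2, pr$pen); best_w <- w }
        }
      }
      sweeps_done <- sw
      trace[sw, ] <- best_g
      temp <- temp * cfg$cooling
      if (sw %% 50 == 0) { # refresh statistics against floating-point drift
        w <- w / sum(w)
        Sx <- sum(SI * w); Sxy <- sum(SIy * w)
        Gw <- as.numeric(G_ %*% w); Sxx <- sum(w * Gw)
        pen <- .rel_entropy(w, prior$prior)
        cur <- chi2_from(Sx, Sxx, Sxy) + theta * pen
      }
      if (last_best - best_g[1] > cfg$tol) {
        last_best <- best_g[1]
        last_improve_sweep <- sw
      } else if (sw - last_improve_sweep >= cfg$patience) break
    }

    if (cfg$quench) {
      # T = 0 polish: pairwise weight transfers (moves along simplex
      # edges) with shrinking step size. These follow the narrow valleys
      # of an ill-conditioned chi2 surface far better than single-state
      # multiplicative moves.
      w <- best_w / sum(best_w)
      Sx <- sum(SI * w); Sxy <- sum(SIy * w)
      Gw <- as.numeric(G_ %*% w); Sxx <- sum(w * Gw)
      pen <- .rel_entropy(w, prior$prior)
      cur <- chi2_from(Sx, Sxx, Sxy) + theta * pen
      scale <- min(cfg$move_scale, 0.5)
      while (scale > 1e-5) {
        improved <- FALSE
        for (k in seq_len(N)) {
          if (w[k] <= 0) next
          t_amt <- scale * w[k]
          Sx_c <- Sx + t_amt * (SI - SI[k])
          Sxy_c <- Sxy + t_amt * (SIy - SIy[k])
          Sxx_c <- Sxx + 2 * t_amt * (Gw - Gw[k]) +
            t_amt^2 * (dG - 2 * G_[, k] + dG[k])
          pen_c <- pen - pterm(w[k], prior$prior[k]) - pterm(w, prior$prior) +
            pterm(w[k] - t_amt, prior$prior[k]) +
            pterm(w + t_amt, prior$prior)
          g_c <- chi2_from(Sx_c, Sxx_c, Sxy_c) + theta * pen_c
          g_c[k] <- Inf
          l <- which.min(g_c)
          if (g_c[l] < cur - 1e-15) {
            pen <- pen_c[l]
            w[k] <- w[k] - t_amt; w[l] <- w[l] + t_amt
            Sx <- Sx_c[l]; Sxy <- Sxy_c[l]; Sxx <- Sxx_c[l]
            Gw <- Gw + t_amt * (G_[, l] - G_[, k])
            cur <- g_c[l]
            improved <- TRUE
          }
        }
        if (!improved) scale <- scale * 0.6
      }
      g_fin <- eval_G(w, as.numeric(pm$I %*% w)) # exact recompute
      if (g_fin[1] < best_g[1]) { best_g <- g_fin; best_w <- w }
    }

    trace <- as.data.frame(trace[seq_len(sweeps_done), , drop = FALSE])
    names(trace) <- c("G", "chi2", "penalty")
    res <- list(weights = ensemble_weights(best_w / sum(best_w), prior$prior),
                G = best_g[1], chi2 = best_g[2], penalty = best_g[3],
                trace = trace, seed = cfg$seed, config = cfg)
    class(res) <- "refinement_result"
    res
  })
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("refinement_result: %d states, G = %.4g (chi2 = %.4g, penalty = %.4g), %d sweeps\n",
              length(x$weights$w), x$G, x$chi2, x$penalty, nrow(x$trace)))
  invisible(x)
}

#' Scan the regularization strength theta
#'
#' Runs one refinement per theta (seeds derived from `cfg$seed` and the
#' theta index) and tabulates converged chi2 and penalty. A discrete
#' elbow suggestion (largest positive curvature of chi2 vs theta index) is
#' returned, but selection remains the user's decision.
#'
#' @param prior an [ensemble_weights()].
#' @param profiles list of per-state [saxs_profile()].
#' @param exp experimental [saxs_profile()] with `sigma`.
#' @param thetas non-negative, sorted theta grid.
#' @param cfg a [refinement_config()] (its `theta` is ignored).
#' @return list with `table` (data.frame theta/chi2/penalty/G) and
#'   `elbow_theta`.
#' @export
theta_scan <- function(prior, profiles, exp, thetas, cfg = refinement_config()) {
  if (any(thetas < 0)) stop("thetas must be non-negative")
  if (is.unsorted(thetas)) stop("thetas must be sorted increasing")
  rows <- lapply(seq_along(thetas), function(i) {
    ci <- cfg
    ci$theta <- thetas[i]
    ci$seed <- derive_seed(cfg$seed, paste0("theta-scan-", i))
    r <- anneal_refine(prior, profiles, exp, ci)
    data.frame(theta = thetas[i], chi2 = r$chi2, penalty = r$penalty, G = r$G)
  })
  tab <- do.call(rbind, rows)
  elbow <- NA_real_
  if (nrow(tab) >= 3) {
    curv <- diff(diff(tab$chi2))
    elbow <- tab$theta[which.max(curv) + 1]
  }
  list(table = tab, elbow_theta = elbow)
}

#' Run-to-run stability of the refinement
#'
#' Repeats the refinement with distinct seeds and reports the per-q
#' standard deviation across the converged, scale/offset-fitted ensemble
#' profiles, as a fraction of the experimental sigma.
#'
#' @param prior an [ensemble_weights()].
#' @param profiles list of per-state [saxs_profile()].
#' @param exp experimental [saxs_profile()] with `sigma`.
#' @param cfg a [refinement_config()].
#' @param n_runs number of independent runs (>= 2). Default 20.
#' @param seeds optional explicit seeds (length `n_runs`); defaults to
#'   seeds derived from `cfg$seed`.
#' @return list with `max_fraction`, `mean_fraction`, `sd_q`,
#'   `weights` (runs x states matrix), `chi2` per run.
#' @export
stability_check <- function(prior, profiles, exp, cfg = refinement_config(),
                            n_runs = 20, seeds = NULL) {
  if (n_runs < 2) stop("n_runs must be >= 2")
  if (is.null(seeds))
    seeds <- vapply(seq_len(n_runs), function(i)
      derive_seed(cfg$seed, paste0("stability-", i)), integer(1))
  if (length(seeds) != n_runs) stop("need one seed per run")
  pm <- .profile_matrix(profiles, q = exp$q)
  fits <- matrix(NA_real_, length(exp$q), n_runs)
  W <- matrix(NA_real_, n_runs, length(prior$w))
  chi2s <- numeric(n_runs)
  for (i in seq_len(n_runs)) {
    ci <- cfg; ci$seed <- seeds[i]
    r <- anneal_refine(prior, profiles, exp, ci)
    ens <- saxs_profile(pm$q, as.numeric(pm$I %*% r$weights$w))
    cf <- fit_scale_offset(ens, exp)
    fits[, i] <- cf$c * ens$I + cf$f
    W[i, ] <- r$weights$w
    chi2s[i] <- r$chi2
  }
  sd_q <- apply(fits, 1, stats::sd)
  frac <- sd_q / exp$sigma
  list(max_fraction = max(frac), mean_fraction = mean(frac), sd_q = sd_q,
       weights = W, chi2 = chi2s)
}

#' Ablate states and re-refine
#'
#' Removes the masked states, renormalizes the prior over the survivors,
#' refines, and reports the chi-squared change relative to the unablated
#' refinement run with the same configuration.
#'
#' @param prior an [ensemble_weights()].
#' @param profiles list of per-state [saxs_profile()].
#' @param exp experimental [saxs_profile()] with `sigma`.
#' @param cfg a [refinement_config()].
#' @param remove_states integer indices of states to remove (may be empty).
#' @return list with `result` (the ablated `refinement_result`),
#'   `full_result`, `delta_chi2` (= ablated chi2 - full chi2), and
#'   `kept` indices.
#' @export
ablate_and_refine <- function(prior, profiles, exp, cfg = refinement_config(),
                              remove_states = integer(0)) {
  N <- length(prior$w)
  keep <- setdiff(seq_len(N), remove_states)
  if (length(keep) < 2) stop("ablation must leave at least 2 states")
  full <- anneal_refine(prior, profiles, exp, cfg)
  if (!length(remove_states))
    return(list(result = full, full_result = full, delta_chi2 = 0, kept = keep))
  pr2 <- ensemble_weights(prior$w[keep] / sum(prior$w[keep]),
                          prior$prior[keep] / sum(prior$prior[keep]))
  abl <- anneal_refine(pr2, profiles[keep], exp, cfg)
  list(result = abl, full_result = full,
       delta_chi2 = abl$chi2 - full$chi2, kept = keep)
}
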