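# Markov state model estimation (tICA, k-centers, transition counting),
# population propagation, and coupling of two slowly interconverting
# prolyl cis/trans regimes into one block-structured model.

#' Construct a transition matrix object
#'
#' @param T square row-stochastic matrix (rows sum to 1 within 1e-10).
#' @param lag lag time (> 0, in the caller's time unit, typically seconds).
#' @param labels optional state labels.
#' @return a `transition_matrix` object.
#' @export
transition_matrix <- function(T, lag, labels = NULL) {
  T <- as.matrix(T)
  if (nrow(T) != ncol(T)) stop("transition matrix must be square")
  if (any(T < -1e-12) || any(T > 1 + 1e-12)) stop("entries must lie in [0, 1]")
  if (any(abs(rowSums(T) - 1) > 1e-10)) stop("rows must sum to 1 within 1e-10")
  if (!is.numeric(lag) || lag <= 0) stop("lag time must be > 0")
  if (is.null(labels)) labels <- as.character(seq_len(nrow(T)))
  obj <- list(T = unname(T), lag = lag, labels = labels)
  class(obj) <- "transition_matrix"
  obj
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("transition_matrix: %d states, lag = %g\n", nrow(x$T), x$lag))
  invisible(x)
}

#' Construct a population vector
#'
#' @param p non-negative populations summing to 1 within 1e-10.
#' @return a numeric vector of class `population_vector`.
#' @export
population_vector <- function(p) {
  p <- as.numeric(p)
  if (any(p < -1e-12)) stop("populations must be non-negative")
  if (abs(sum(p) - 1) > 1e-10) stop("populations must sum to 1 within 1e-10")
  class(p) <- "population_vector"
  p
}

#' First-order rate constant to jump probability at a lag time
#'
#' `p = 1 - exp(-k t)`, the probability that at least one event of a
#' Poisson process with rate `k` occurs within the lag `t`.
#'
#' @param k rate constant (1/s), >= 0.
#' @param t lag time (s), > 0.
#' @return probability in `[0, 1)`.
#' @export
rate_to_probability <- function(k, t) {
  if (any(k < 0)) stop("rate constant must be >= 0")
  if (any(t <= 0)) stop("lag time must be > 0")
  -expm1(-k * t)
}

#' Estimate a transition matrix from discrete trajectories
#'
#' Sliding-window transition counts at the given lag, restricted to the
#' largest strongly connected component of the count graph, then row
#' normalized (with optional pseudocount).
#'
#' @param trajs list of integer state sequences (or a single vector).
#' @param lag_steps lag in trajectory steps (>= 1).
#' @param lag_time physical lag time for the resulting model (default
#'   `lag_steps`, i.e. trajectory-step units).
#' @param pseudocount added to every in-component count (default 0).
#' @param symmetrize use `(C + t(C))/2` before normalizing (default FALSE).
#' @return a [transition_matrix()]; `labels` carry the original state ids.
#' @export
estimate_transition_matrix <- function(trajs, lag_steps, lag_time = lag_steps,
                                       pseudocount = 0, symmetrize = FALSE) {
  if (!is.list(trajs)) trajs <- list(trajs)
  if (!.is_count(lag_steps) || lag_steps < 1) stop("lag_steps must be a positive integer")
  states <- sort(unique(unlist(trajs)))
  ns <- length(states)
  if (ns == 1L) {
    tm <- transition_matrix(matrix(1, 1, 1), lag_time, labels = as.character(states))
    return(tm)
  }
  C <- matrix(0, ns, ns)
  for (tr in trajs) {
    if (length(tr) <= lag_steps) next
    from <- match(tr[seq_len(length(tr) - lag_steps)], states)
    to <- match(tr[seq_len(length(tr) - lag_steps) + lag_steps], states)
    C <- C + matrix(tabulate(from + ns * (to - 1L), nbins = ns * ns), ns, ns)
  }
  if (all(C == 0)) stop("trajectories shorter than the lag; no transitions counted")
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- tabulate(comp$membership)
  big <- which.max(sizes)
  keep <- which(comp$membership == big)
  if (length(keep) < 2) stop("no strongly connected component with >= 2 states")
  C <- C[keep, keep, drop = FALSE]
  if (symmetrize) C <- (C + t(C)) / 2
  C <- C + pseudocount
  T <- C / rowSums(C)
  transition_matrix(T, lag_time, labels = as.character(states[keep]))
}

# matrix power by repeated squaring
.matpow <- function(M, k) {
  R <- diag(nrow(M))
  while (k > 0) {
    if (k %% 2 == 1) R <- R %*% M
    M <- M %*% M
    k <- k %/% 2
  }
  R
}

#' Propagate a population vector forward in time
#'
#' Computes `p0 %*% T^(duration / lag)`. The duration is rounded to the
#' nearest integer multiple of the lag time, with a warning if the
#' remainder is non-negligible.
#'
#' @param T a [transition_matrix()].
#' @param p0 a [population_vector()] (or plain numeric simplex vector).
#' @param duration propagation time in the model's lag-time unit.
#' @return a [population_vector()].
#' @export
propagate <- function(T, p0, duration) {
  p0 <- population_vector(unclass(p0))
  if (length(p0) != nrow(T$T)) stop("dimension mismatch: ", length(p0),
                                    " populations vs ", nrow(T$T), " states")
  steps <- round(duration / T$lag)
  if (abs(duration - steps * T$lag) > 1e-9 * max(T$lag, abs(duration)))
    warning(sprintf("duration %g is not a lag multiple; using %d steps", duration, steps))
  if (steps < 0) stop("duration must be non-negative")
  p <- as.numeric(p0 %*% .matpow(T$T, steps))
  population_vector(p / sum(p))
}

#' Stationary distribution of an ergodic transition matrix
#' @param T a [transition_matrix()].
#' @return a [population_vector()].
#' @export
stationary_distribution <- function(T) {
  e <- eigen(t(T$T))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  population_vector(v / sum(v))
}

#' Construct a cis/trans isomer coupling
#'
#' @param k experimental isomerization rate constant (1/s), >= 0.
#' @param pairs optional 2-column matrix of (trans state, cis state) index
#'   pairs allowed to interconvert; when NULL, [combine_isomer_models()]
#'   derives them with the RMSD pairing rule.
#' @return an `isomer_coupling` object.
#' @export
isomer_coupling <- function(k, pairs = NULL) {
  if (k < 0) stop("rate constant must be >= 0")
  if (!is.null(pairs)) pairs <- matrix(as.integer(pairs), ncol = 2)
  obj <- list(k = k, pairs = pairs)
  class(obj) <- "isomer_coupling"
  obj
}

# mean RMSD of state i to its direct neighbours (T[i, j] > 0, j != i)
.mean_neighbor_rmsd <- function(i, T, structures, sel) {
  nb <- which(T[i, ] > 0)
  nb <- setdiff(nb, i)
  if (!length(nb)) return(Inf) # isolated state: filter cannot reject
  mean(vapply(nb, function(j)
    rmsd_superposed(structures[[i]], structures[[j]], sel), numeric(1)))
}

#' Combine cis and trans Markov models into one coupled model
#'
#' Assembles the `(n + m) x (n + m)` block-diagonal transition matrix
#' (cis block first) and adds off-diagonal-block entries for kinetically
#' plausible trans/cis pairs. Each trans state is paired with its
#' argmin-RMSD cis state (ties broken by lowest cis index); the pair is
#' kept iff its trans-cis RMSD is smaller than the mean RMSD of the trans
#' state to its direct trans neighbours AND smaller than the same quantity
#' for the cis state. Kept pairs receive a symmetric jump probability
#' `p = 1 - exp(-k t)` in both directions, with the diagonal absorbing
#' `-p` so rows stay stochastic.
#'
#' @param T_cis,T_trans [transition_matrix()] objects with equal lag times.
#' @param coupling an [isomer_coupling()]; if its `pairs` is NULL the RMSD
#'   pairing rule is applied to the representative structures.
#' @param structures_cis,structures_trans representative [structure3d()]
#'   per state (needed only when pairs are derived).
#' @param atom_selection atom selection for RMSD (default "CA").
#' @return a [transition_matrix()] with attributes `pairs` (kept pairs as a
#'   2-column trans,cis matrix) and `n_cis`.
#' @export
combine_isomer_models <- function(T_cis, T_trans, coupling,
                                  structures_cis = NULL, structures_trans = NULL,
                                  atom_selection = "CA") {
  if (abs(T_cis$lag - T_trans$lag) > 1e-12 * max(T_cis$lag, T_trans$lag))
    stop("lag-time mismatch between cis and trans models")
  n <- nrow(T_cis$T); m <- nrow(T_trans$T)
  lag <- T_cis$lag
  p <- rate_to_probability(coupling$k, lag)
  if (coupling$k * lag >= 1)
    warning("k * t >= 1: the one-jump probability interpretation breaks down")
  pairs <- coupling$pairs
  if (is.null(pairs) && p > 0) {
    if (is.null(structures_cis) || is.null(structures_trans))
      stop("representative structures are required to derive coupling pairs")
    sel <- atom_selection
    pairs <- NULL
    for (j in seq_len(m)) {
      r <- vapply(seq_len(n), function(i)
        rmsd_superposed(structures_trans[[j]], structures_cis[[i]], sel),
        numeric(1))
      i_star <- which(r == min(r))[1] # lowest index on ties
      r_pair <- r[i_star]
      r_tt <- .mean_neighbor_rmsd(j, T_trans$T, structures_trans, sel)
      r_cc <- .mean_neighbor_rmsd(i_star, T_cis$T, structures_cis, sel)
      if (r_pair < r_tt && r_pair < r_cc)
        pairs <- rbind(pairs, c(j, i_star))
    }
  }
  M <- matrix(0, n + m, n + m)
  M[seq_len(n), seq_len(n)] <- T_cis$T
  M[n + seq_len(m), n + seq_len(m)] <- T_trans$T
  if (p > 0 && !is.null(pairs) && nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      jt <- n + pairs[r, 1]; ic <- pairs[r, 2]
      M[jt, ic] <- M[jt, ic] + p
      M[ic, jt] <- M[ic, jt] + p
      M[jt, jt] <- M[jt, jt] - p
      M[ic, ic] <- M[ic, ic] - p
      if (M[jt, jt] < 0 || M[ic, ic] < 0)
        stop("diagonal would go negative absorbing the coupling probability; ",
             "reduce k * t or the number of pairs per state")
    }
  }
  out <- transition_matrix(M, lag,
                           labels = c(paste0("cis", seq_len(n)),
                                      paste0("trans", seq_len(m))))
  attr(out, "pairs") <- pairs
  attr(out, "n_cis") <- n
  out
}

#' Time-lagged independent component analysis (tICA)
#'
#' Solves the symmetrized generalized eigenproblem
#' `C(tau) v = lambda (C(0) + eps I) v` over mean-free features and orders
#' components by decreasing eigenvalue. Implied timescales are
#' `-tau / log(lambda)`.
#'
#' @param trajs list of numeric matrices (frames x features), or one matrix.
#' @param lag_steps lag in frames.
#' @param n_components number of components to keep (default: all).
#' @param eps ridge regularization added to C(0) (default 1e-6).
#' @return list with `components` (features x k), `eigenvalues`,
#'   `timescales` (in frames), and the feature `mean`.
#' @export
tica_decompose <- function(trajs, lag_steps, n_components = NULL, eps = 1e-6) {
  if (!is.list(trajs)) trajs <- list(trajs)
  trajs <- lapply(trajs, as.matrix)
  if (!.is_count(lag_steps) || lag_steps < 1) stop("lag_steps must be a positive integer")
  if (all(vapply(trajs, nrow, 1L) <= lag_steps))
    stop("all trajectories are shorter than the lag")
  d <- ncol(trajs[[1]])
  mu <- colMeans(do.call(rbind, trajs))
  C0 <- matrix(0, d, d); Ct <- matrix(0, d, d); npair <- 0
  for (X in trajs) {
    if (nrow(X) <= lag_steps) next
    Xc <- sweep(X, 2, mu)
    A <- Xc[seq_len(nrow(X) - lag_steps), , drop = FALSE]
    B <- Xc[seq_len(nrow(X) - lag_steps) + lag_steps, , drop = FALSE]
    C0 <- C0 + crossprod(A) + crossprod(B)
    Ct <- Ct + crossprod(A, B) + crossprod(B, A)
    npair <- npair + nrow(A)
  }
  C0 <- C0 / (2 * npair) + eps * diag(d)
  Ct <- Ct / (2 * npair)
  # whiten: solve via C0^(-1/2) Ct C0^(-1/2)
  e0 <- eigen(C0, symmetric = TRUE)
  W <- e0$vectors %*% diag(1 / sqrt(pmax(e0$values, 1e-300)), d) %*% t(e0$vectors)
  ew <- eigen(W %*% Ct %*% W, symmetric = TRUE)
  lambda <- ew$values
  if (any(lambda >= 1)) {
    warning("tICA eigenvalue(s) >= 1; clamping")
    lambda <- pmin(lambda, 1 - 1e-12)
  }
  V <- W %*% ew$vectors
  k <- if (is.null(n_components)) d else min(n_components, d)
  lk <- lambda[seq_len(k)]
  ts <- rep(NA_real_, k) # negative eigenvalues have no timescale
  ts[lk > 0] <- -lag_steps / log(lk[lk > 0])
  list(components = V[, seq_len(k), drop = FALSE],
       eigenvalues = lambda[seq_len(k)], timescales = ts, mean = mu)
}

#' Greedy k-centers clustering
#'
#' Gonzalez's farthest-point algorithm: the first center is a random point
#' (seeded); each subsequent center is the point farthest from the current
#' center set. Guarantees a covering radius within 2x of optimal.
#'
#' @param X numeric matrix (points x features).
#' @param k number of centers (1 <= k <= n).
#' @param seed integer seed (selects the first center).
#' @return list with `labels`, `centers` (row indices into X),
#'   `covering_radius`.
#' @export
kcenters_cluster <- function(X, k, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (!.is_count(k) || k < 1) stop("k must be a positive integer")
  if (k > n) stop("k must not exceed the number of points")
  centers <- integer(k)
  centers[1] <- with_seed(seed, sample.int(n, 1))
  d2 <- rowSums(sweep(X, 2, X[centers[1], ])^2)
  labels <- rep(1L, n)
  if (k > 1) for (c_i in 2:k) {
    centers[c_i] <- which.max(d2)
    d2new <- rowSums(sweep(X, 2, X[centers[c_i], ])^2)
    upd <- d2new < d2
    d2[upd] <- d2new[upd]
    labels[upd] <- c_i
  }
  list(labels = labels, centers = centers, covering_radius = sqrt(max(d2)))
}
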