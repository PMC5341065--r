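# Synthetic-data generators: toy structural ensembles with known
# ground-truth weights, per-state SAXS profiles, noisy synthetic
# experiments, and two-regime kinetic models. Everything is a pure
# function of its spec + seed, so the whole pipeline is testable without
# external downloads.

.DEFAULT_Q <- seq(0.01, 2.0, by = 0.01)

# near-linear chain, optionally curled into an arc (curl in [0, 1]; 0 is
# straight), with a gentle seeded wiggle: the "extended" archetype.
# Varying curl gives each extended state its own size and shape, keeping
# the states spectrally distinct.
.chain_extended <- function(n, seed, curl = 0) {
  ph <- with_seed(seed, stats::runif(2, 0, 2 * pi))
  i <- seq_len(n)
  ang <- curl * 0.25 * (seq_len(n - 1) - 1) # bond direction angles (arc)
  x <- cumsum(c(0, 3.8 * cos(ang)))
  y <- cumsum(c(0, 3.8 * sin(ang)))
  cbind(x, y + 1.0 * sin(0.7 * i + ph[1]), 1.0 * cos(0.9 * i + ph[2]))
}

# confined random walk with bond length 3.8 A inside a sphere: the
# "compact / collapsed" archetype. radius_factor scales the confinement;
# stiffness in [0, 1) adds directional persistence, letting compact states
# occupy a ladder of sizes between a collapsed blob and a loose coil.
.chain_compact <- function(n, seed, radius_factor = 3.2, stiffness = 0) {
  R <- radius_factor * n^(1 / 3)
  with_seed(seed, {
    xyz <- matrix(0, n, 3)
    uprev <- c(1, 0, 0)
    for (i in 2:n) {
      for (try in 1:60) {
        u <- stiffness * uprev + (1 - stiffness) * stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        cand <- xyz[i - 1, ] + 3.8 * u
        if (sqrt(sum(cand^2)) <= R) break
        if (try == 60) {
          u <- -xyz[i - 1, ] / sqrt(sum(xyz[i - 1, ]^2))
          cand <- xyz[i - 1, ] + 3.8 * u
        }
      }
      xyz[i, ] <- cand
      uprev <- u
    }
    xyz
  })
}

# compact start iteratively deformed until the requested residue pairs are
# within contact distance: the "feature-bearing" archetype
.chain_feature <- function(n, pairs, seed, target = 4.0, iters = 400,
                           radius_factor = 3.2, stiffness = 0) {
  if (any(abs(pairs[, 1] - pairs[, 2]) < 3))
    stop("feature pairs must have sequence separation >= 3")
  if (any(pairs > n)) stop("feature pair indices exceed chain length")
  xyz <- .chain_compact(n, seed, radius_factor = radius_factor,
                        stiffness = stiffness)
  # position-based dynamics: alternate symmetric pair-distance projections
  # with Gauss-Seidel bond-length projections until both are satisfied
  project <- function(xyz, i, j, d0, frac = 1) {
    v <- xyz[j, ] - xyz[i, ]
    d <- sqrt(sum(v^2))
    if (d > 1e-9) {
      corr <- frac * 0.5 * (d - d0) / d
      xyz[i, ] <- xyz[i, ] + corr * v
      xyz[j, ] <- xyz[j, ] - corr * v
    }
    xyz
  }
  for (it in seq_len(iters)) {
    for (r in seq_len(nrow(pairs)))
      xyz <- project(xyz, pairs[r, 1], pairs[r, 2], target)
    for (sweep in 1:4)
      for (i in 2:n) xyz <- project(xyz, i - 1, i, 3.8)
  }
  xyz
}

.bead_structure <- function(xyz) {
  n <- nrow(xyz)
  structure3d(data.frame(element = "C", name = "CA", resid = seq_len(n),
                         resname = "GLY", chain = "A",
                         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

#' Specify a toy structural ensemble
#'
#' Coarse chains with one pseudo-atom per residue (carbon form factor).
#' Archetypes: `"compact"` (confined random walk; an optional `radius`
#' element scales the confinement), `"extended"` (near-linear), and
#' `"feature"` (compact chain deformed to realize a given non-native
#' contact pair set).
#'
#' @param n_residues chain length (default 30).
#' @param archetypes list of per-state lists, each with `type` and, for
#'   feature states, `pairs` (2-column matrix); for compact states an
#'   optional `radius` factor.
#' @param weights ground-truth weights (default: seeded Dirichlet(2)).
#' @param seed integer seed.
#' @return a `toy_ensemble_spec` object.
#' @export
toy_ensemble_spec <- function(n_residues = 30, archetypes, weights = NULL,
                              seed = 1L) {
  n_states <- length(archetypes)
  if (is.null(weights)) {
    weights <- with_seed(derive_seed(seed, "weights"),
                         stats::rgamma(n_states, shape = 2))
    weights <- weights / sum(weights)
  }
  if (length(weights) != n_states) stop("one weight per archetype required")
  weights <- weights / sum(weights)
  obj <- list(n_residues = n_residues, n_states = n_states,
              archetypes = archetypes, weights = weights, seed = seed)
  class(obj) <- "toy_ensemble_spec"
  obj
}

#' The standard 20-state test fixture specification
#'
#' 30 residues, 20 states across 3 archetypes (8 compact of varying
#' confinement, 6 extended, 6 bearing a non-native contact feature between
#' two chain segments), seeded ground-truth weights. Sized so a full
#' refinement converges in well under two minutes.
#'
#' @param seed integer seed (default 1).
#' @param feature_pairs residue pairs realized by the feature states
#'   (default `(8,25), (9,24), (10,23)`).
#' @return a [toy_ensemble_spec()].
#' @export
standard_fixture_spec <- function(seed = 1L,
                                  feature_pairs = cbind(c(8, 9, 10), c(25, 24, 23))) {
  arch <- c(
    lapply(seq_len(8), function(i) list(type = "compact",
                                        radius = 1.5 + 0.45 * i,
                                        stiffness = 0.12 * (i - 1))),
    lapply(seq_len(8), function(i) list(type = "extended",
                                        curl = 0.80 - 0.11 * (i - 1))),
    lapply(seq_len(4), function(i) list(type = "feature", pairs = feature_pairs,
                                        radius = 1.7 + 0.8 * i,
                                        stiffness = 0.15 * (i - 1)))
  )
  toy_ensemble_spec(n_residues = 30, archetypes = arch, seed = seed)
}

#' A small 6-state fixture for fast stability and pipeline tests
#'
#' Three compact states of increasing size, two extended states and one
#' feature-bearing state. Small enough that a full refinement takes about
#' a second, so 20-run stability checks stay cheap.
#'
#' @param seed integer seed (default 1).
#' @return a [toy_ensemble_spec()].
#' @export
easy_fixture_spec <- function(seed = 1L) {
  arch <- c(
    lapply(seq_len(3), function(i) list(type = "compact",
                                        radius = 1.6 + 0.9 * i,
                                        stiffness = 0.25 * (i - 1))),
    lapply(seq_len(2), function(i) list(type = "extended",
                                        curl = 0.5 * (i - 1))),
    list(list(type = "feature", pairs = cbind(c(8, 9, 10), c(25, 24, 23))))
  )
  toy_ensemble_spec(n_residues = 30, archetypes = arch, seed = seed)
}

#' Generate a toy structural ensemble
#'
#' Deterministic given the spec's seed. Returns one structure, contact map
#' and SAXS profile per state, plus the ground-truth weights.
#'
#' @param spec a [toy_ensemble_spec()].
#' @param q q grid for the per-state Debye profiles (default
#'   `seq(0.005, 0.3, 0.005)`).
#' @param cutoff,min_seq_sep contact definition (defaults 4.5 A, 3).
#' @return list with `structures`, `contact_maps`, `profiles`, `weights`,
#'   `spec`, `q`.
#' @export
generate_toy_ensemble <- function(spec, q = .DEFAULT_Q, cutoff = 4.5,
                                  min_seq_sep = 3) {
  n <- spec$n_residues
  structures <- vector("list", spec$n_states)
  for (k in seq_len(spec$n_states)) {
    a <- spec$archetypes[[k]]
    sk <- derive_seed(spec$seed, paste0("state-", k))
    xyz <- switch(a$type,
      compact = .chain_compact(n, sk, radius_factor = a$radius %||% 3.2,
                               stiffness = a$stiffness %||% 0),
      extended = .chain_extended(n, sk, curl = a$curl %||% 0),
      feature = .chain_feature(n, a$pairs, sk,
                               radius_factor = a$radius %||% 3.2,
                               stiffness = a$stiffness %||% 0),
      stop("unknown archetype: ", a$type))
    structures[[k]] <- .bead_structure(xyz)
    if (a$type == "feature") {
      cm <- contact_map(structures[[k]], cutoff = cutoff, min_seq_sep = min_seq_sep)
      if (!all(cm$map[a$pairs] > 0))
        stop("unrealizable feature geometry for state ", k)
    }
  }
  maps <- lapply(structures, contact_map, cutoff = cutoff,
                 min_seq_sep = min_seq_sep)
  profiles <- lapply(structures, debye_profile, q = q)
  list(structures = structures, contact_maps = maps, profiles = profiles,
       weights = spec$weights, spec = spec, q = q)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a noisy synthetic SAXS "experiment" with known ground truth
#'
#' The clean profile is the weight-averaged ensemble profile; Gaussian
#' noise with per-point sd `noise * I_clean` is added and the same sd is
#' reported as the experimental sigma. With `noise = 0` the observation
#' equals the clean profile and sigma falls back to `sigma_floor *
#' I_clean` so chi-squared stays defined.
#'
#' @param profiles list of per-state [saxs_profile()].
#' @param true_weights simplex weights used as ground truth.
#' @param noise relative noise level (default 0.03).
#' @param seed integer seed.
#' @param sigma_floor relative sigma used when `noise = 0` (default 0.01).
#' @return a `synthetic_experiment`: list with `observed`
#'   ([saxs_profile()] with sigma), `clean`, `true_weights`, `noise`,
#'   `seed`.
#' @export
generate_synthetic_experiment <- function(profiles, true_weights, noise = 0.03,
                                          seed = 1L, sigma_floor = 0.01) {
  true_weights <- true_weights / sum(true_weights)
  clean <- ensemble_profile(profiles, true_weights)
  sd_rel <- if (noise > 0) noise else sigma_floor
  sigma <- sd_rel * abs(clean$I)
  obs_I <- if (noise > 0)
    clean$I + with_seed(seed, stats::rnorm(length(sigma), 0, sigma))
  else clean$I
  obj <- list(observed = saxs_profile(clean$q, obs_I, sigma),
              clean = clean, true_weights = true_weights,
              noise = noise, seed = seed)
  class(obj) <- "synthetic_experiment"
  obj
}

# Metropolis chain on the complete graph with target stationary pi,
# slowed by `rate` in (0, 1]: T = I + rate * (T_metropolis - I).
.metropolis_chain <- function(pi, rate) {
  ns <- length(pi)
  T <- matrix(0, ns, ns)
  for (i in seq_len(ns)) for (j in seq_len(ns)) if (i != j)
    T[i, j] <- pmin(1, pi[j] / pi[i]) / (ns - 1)
  diag(T) <- 1 - rowSums(T)
  diag(ns) + rate * (T - diag(ns))
}

#' Generate a two-regime (cis/trans) kinetic model with known truth
#'
#' Two ergodic row-stochastic blocks with designed stationary
#' distributions (Metropolis construction, so the targets are exact) and
#' representative bead structures arranged so the RMSD pairing rule has a
#' known answer: trans state j is a small jitter of cis state
#' `((j - 1) mod n) + 1`, while distinct cis states are distinct random
#' chains, so the designed pairing is known exactly for every trans state.
#'
#' @param n,m number of cis and trans states (>= 2).
#' @param intra_rate within-block kinetic scale in (0, 1] (default 0.2).
#' @param k isomerization rate constant in 1/s (default 0.01, i.e. the
#'   ~100 s prolyl cis/trans timescale).
#' @param lag MSM lag time in seconds (default 1e-6).
#' @param n_residues chain length of the representative structures.
#' @param jitter coordinate jitter (A) between paired cis/trans
#'   representatives (default 0.1).
#' @param seed integer seed.
#' @return list with `T_cis`, `T_trans` ([transition_matrix()]),
#'   `coupling` ([isomer_coupling()] without preset pairs), `pi_cis`,
#'   `pi_trans`, `structures_cis`, `structures_trans`, `designed_pairs`.
#' @export
generate_two_regime_msm <- function(n = 4, m = 4, intra_rate = 0.2, k = 0.01,
                                    lag = 1e-6, n_residues = 20, jitter = 0.1,
                                    seed = 1L) {
  if (n < 2 || m < 2) stop("need at least 2 states per regime")
  pi_c <- with_seed(derive_seed(seed, "pi-cis"), stats::rgamma(n, 2))
  pi_c <- pi_c / sum(pi_c)
  pi_t <- with_seed(derive_seed(seed, "pi-trans"), stats::rgamma(m, 2))
  pi_t <- pi_t / sum(pi_t)
  T_cis <- transition_matrix(.metropolis_chain(pi_c, intra_rate), lag)
  T_trans <- transition_matrix(.metropolis_chain(pi_t, intra_rate), lag)
  base <- lapply(seq_len(n), function(i)
    .chain_compact(n_residues, derive_seed(seed, paste0("geom-", i))))
  str_cis <- lapply(seq_len(n), function(i) .bead_structure(base[[i]]))
  partner <- ((seq_len(m) - 1L) %% n) + 1L
  str_trans <- lapply(seq_len(m), function(j) {
    xyz <- base[[partner[j]]] +
      with_seed(derive_seed(seed, paste0("jit-", j)),
                matrix(stats::rnorm(n_residues * 3, 0, jitter),
                       n_residues, 3))
    .bead_structure(xyz)
  })
  list(T_cis = T_cis, T_trans = T_trans, coupling = isomer_coupling(k),
       pi_cis = pi_c, pi_trans = pi_t,
       structures_cis = str_cis, structures_trans = str_trans,
       designed_pairs = cbind(trans = seq_len(m), cis = partner),
       lag = lag, seed = seed)
}

#' Write the standard fixture set to a directory
#'
#' Emits per-state PDB files and SAXS profiles, the noisy synthetic
#' experiment, ground-truth weights and contact maps — the same formats
#' the pipeline consumes.
#'
#' @param dir output directory (created if missing).
#' @param seed integer seed.
#' @param noise relative experimental noise (default 0.03).
#' @return the directory path, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1L, noise = 0.03) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ens <- generate_toy_ensemble(standard_fixture_spec(seed = seed))
  for (k in seq_along(ens$structures)) {
    write_pdb(ens$structures[[k]], file.path(dir, sprintf("state%02d.pdb", k)))
    write_saxs(ens$profiles[[k]], file.path(dir, sprintf("state%02d.dat", k)))
    write_contact_map(ens$contact_maps[[k]],
                      file.path(dir, sprintf("state%02d.contacts", k)))
  }
  expt <- generate_synthetic_experiment(ens$profiles, ens$weights,
                                        noise = noise,
                                        seed = derive_seed(seed, "experiment"))
  write_saxs(expt$observed, file.path(dir, "experiment.dat"))
  utils::write.table(data.frame(state = seq_along(ens$weights),
                                weight = ens$weights),
                     file.path(dir, "true_weights.tsv"),
                     row.names = FALSE, sep = "\t", quote = FALSE)
  invisible(dir)
}
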