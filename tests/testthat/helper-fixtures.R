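# Shared fixtures and independent oracles. The standard fixture is built
# once per test run and memoized; all expensive objects come from here.

.fixture_env <- new.env(parent = emptyenv())

std_fixture <- function() {
  if (is.null(.fixture_env$std)) {
    ens <- generate_toy_ensemble(standard_fixture_spec(seed = 1))
    noiseless <- generate_synthetic_experiment(ens$profiles, ens$weights,
                                               noise = 0, seed = 11)
    noisy <- generate_synthetic_experiment(ens$profiles, ens$weights,
                                           noise = 0.03, seed = 11)
    .fixture_env$std <- list(ens = ens, noiseless = noiseless, noisy = noisy)
  }
  .fixture_env$std
}

easy_fixture <- function() {
  if (is.null(.fixture_env$easy)) {
    ens <- generate_toy_ensemble(easy_fixture_spec(seed = 2))
    expt <- generate_synthetic_experiment(ens$profiles, ens$weights,
                                          noise = 0.03, seed = 21)
    .fixture_env$easy <- list(ens = ens, expt = expt)
  }
  .fixture_env$easy
}

# plain bead chain as a structure3d (one carbon pseudo-atom per residue)
bead_structure <- function(xyz, name = "CA", element = "C") {
  n <- nrow(xyz)
  structure3d(data.frame(element = element, name = name, resid = seq_len(n),
                         resname = "GLY", chain = "A",
                         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

# a small all-atom-ish synthetic peptide with a PHE at a chosen position,
# used for mutation tests (coordinates arbitrary but valid)
synthetic_phe_structure <- function(phe_at = 3, n_res = 5) {
  rows <- list()
  at <- 0
  for (r in seq_len(n_res)) {
    resn <- if (r == phe_at) "PHE" else "ALA"
    atoms <- residue_atoms(resn)
    for (a in atoms) {
      at <- at + 1
      elem <- substr(a, 1, 1)
      rows[[at]] <- data.frame(element = elem, name = a, resid = r,
                               resname = resn, chain = "A",
                               x = 3.8 * r + 0.3 * at %% 7,
                               y = 0.9 * (at %% 5), z = 0.7 * (at %% 3))
    }
  }
  structure3d(do.call(rbind, rows))
}

# independent quaternion-method RMSD oracle (Kearsley/Horn eigenvalue form)
rmsd_quaternion_oracle <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  M <- crossprod(Xc, Yc) # 3x3 correlation matrix
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  e <- sum(Xc^2) + sum(Yc^2) - 2 * lam
  sqrt(max(e, 0) / nrow(X))
}

# naive O(n^2) Debye oracle: explicit double loop, no shortcuts
debye_oracle <- function(s, q) {
  a <- s$atoms
  xyz <- coords(s)
  n <- nrow(xyz)
  f <- lapply(seq_len(n), function(i) form_factor(a$element[i], q))
  I <- numeric(length(q))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    x <- q * d
    sc <- ifelse(x < 1e-12, 1, sin(x) / x)
    I <- I + f[[i]] * f[[j]] * sc
  }
  I
}

# random rigid transform applied to a coordinate matrix
random_rigid <- function(X, seed) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(A)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t(R %*% t(X)) + matrix(rnorm(3, 0, 10), nrow(X), 3, byrow = TRUE)
}
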