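# Accessible-volume (AV) dye modelling and single-molecule FRET
# efficiency prediction with shot-noise histograms.
#
# The AV1 variant is used: one dye radius for steric clashes of the dye
# position, a thinner linker width for the flexible tether's path. Dye
# positions are grid cells within geodesic (through-space, obstacle-
# avoiding) linker length of the attachment atom.

.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                H = 1.20, SE = 1.90, FE = 1.50)

#' Specify a FRET dye and its linker
#'
#' @param residue attachment residue index (1-based).
#' @param atom attachment atom name (default "CB").
#' @param linker_length linker length L in Angstrom (default 15, a standard
#'   (CH2)5 linker).
#' @param linker_width linker diameter in Angstrom used for pathfinding
#'   (default 4.5).
#' @param dye_radius dye radius in Angstrom (default 3.5).
#' @param role "donor" or "acceptor".
#' @return a `dye_spec` object.
#' @export
dye_spec <- function(residue, atom = "CB", linker_length = 15,
                     linker_width = 4.5, dye_radius = 3.5,
                     role = c("donor", "acceptor")) {
  if (linker_length <= 0) stop("linker_length must be > 0")
  if (dye_radius <= 0) stop("dye_radius must be > 0")
  obj <- list(residue = residue, atom = toupper(atom),
              linker_length = linker_length, linker_width = linker_width,
              dye_radius = dye_radius, role = match.arg(role))
  class(obj) <- "dye_spec"
  obj
}

#' Specify a FRET donor/acceptor pair
#'
#' @param donor,acceptor [dye_spec()] objects.
#' @param R0 Forster radius in Angstrom (> 0); any orientation factor
#'   (kappa^2 = 2/3) is assumed to be folded into R0 by the caller.
#' @return a `fret_pair` object.
#' @export
fret_pair <- function(donor, acceptor, R0) {
  if (R0 <= 0) stop("R0 must be > 0")
  obj <- list(donor = donor, acceptor = acceptor, R0 = R0)
  class(obj) <- "fret_pair"
  obj
}

# gcd-reduced integer offsets with max-norm <= 3: a 7x7x7 chamfer stencil
# keeps the geodesic within ~1% of Euclidean in free space
.av_stencil <- function() {
  off <- as.matrix(expand.grid(dx = -3:3, dy = -3:3, dz = -3:3))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  g <- apply(abs(off), 1, function(v) {
    v <- v[v > 0]
    if (!length(v)) return(0L)
    Reduce(function(a, b) { while (b) { t <- b; b <- a %% b; a <- t }; a }, v)
  })
  off[g == 1, , drop = FALSE]
}

#' Accessible volume of a tethered dye
#'
#' Builds a cubic grid of side `2 L` centred on the attachment atom. A
#' cell is path-allowed if no protein heavy atom lies within
#' `linker_width / 2 +` vdW radius — atoms close enough to the attachment
#' to bury it (the attachment atom itself and its covalent neighbours) are
#' transparent to the path — and dye-allowed if no heavy atom at all lies
#' within `dye_radius +` vdW radius. Dye positions are dye-allowed cells
#' whose geodesic distance from the attachment through path-allowed cells
#' (Dijkstra on a 7x7x7 stencil) is at most `L`.
#'
#' @param s a [structure3d()].
#' @param dye a [dye_spec()].
#' @param spacing grid spacing in Angstrom (default 1.0).
#' @param vdw_radii named vector of per-element van der Waals radii;
#'   defaults to a standard table. Unknown elements fall back to 1.7.
#' @return an `av_cloud`: list with `positions` (n x 3 matrix),
#'   `mean_position`, `spacing`, `attachment`, `geodesic` distances.
#' @export
accessible_volume <- function(s, dye, spacing = 1.0, vdw_radii = .VDW_RADII) {
  a <- s$atoms
  sel <- a$resid == dye$residue & a$name == dye$atom
  if (!any(sel)) stop("attachment atom ", dye$atom, " of residue ",
                      dye$residue, " not found")
  att_i <- which(sel)[1]
  att <- as.numeric(coords(s)[att_i, ])
  L <- dye$linker_length
  ax <- seq(-L, L, by = spacing)
  grid <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  grid <- sweep(grid, 2, -att) # grid in absolute coordinates
  ncell <- nrow(grid)
  dims <- rep(length(ax), 3)

  r_euclid <- sqrt(rowSums(sweep(grid, 2, att)^2))
  inside <- r_euclid <= L + 1e-9

  vr <- vdw_radii[a$element]
  vr[is.na(vr)] <- 1.7
  path_ok <- rep(TRUE, ncell)
  dye_ok <- rep(TRUE, ncell)
  xyz <- coords(s)
  half_w <- dye$linker_width / 2
  # atoms so close to the attachment that they would bury it (covalently
  # bonded neighbours) are transparent to the linker path, never to the dye
  d_att <- sqrt(rowSums(sweep(xyz, 2, att)^2))
  path_transparent <- d_att < half_w + vr
  for (i in seq_len(nrow(xyz))) {
    lim <- max(dye$dye_radius, half_w) + vr[i]
    # cheap bounding-box precheck
    dvec <- abs(sweep(grid, 2, xyz[i, ]))
    cand <- which(dvec[, 1] <= lim & dvec[, 2] <= lim & dvec[, 3] <= lim)
    if (!length(cand)) next
    d <- sqrt(rowSums(dvec[cand, , drop = FALSE]^2))
    dye_ok[cand[d < dye$dye_radius + vr[i]]] <- FALSE
    if (!path_transparent[i]) path_ok[cand[d < half_w + vr[i]]] <- FALSE
  }
  path_ok <- path_ok & inside

  # Dijkstra over path-allowed cells
  idx <- which(path_ok)
  if (!length(idx)) stop("attachment of residue ", dye$residue, " is fully buried")
  rank_of <- integer(ncell)
  rank_of[idx] <- seq_along(idx)
  nx <- dims[1]
  coord3 <- cbind((seq_len(ncell) - 1) %% nx,
                  ((seq_len(ncell) - 1) %/% nx) %% nx,
                  (seq_len(ncell) - 1) %/% (nx * nx))
  off <- .av_stencil()
  edges <- NULL
  wts <- NULL
  for (r in seq_len(nrow(off))) {
    o <- off[r, ]
    if (o[3] < 0 || (o[3] == 0 && (o[2] < 0 || (o[2] == 0 && o[1] < 0))))
      next # undirected: keep one of each +/- pair
    c2 <- coord3[idx, , drop = FALSE] + matrix(o, length(idx), 3, byrow = TRUE)
    ok <- c2[, 1] >= 0 & c2[, 1] < nx & c2[, 2] >= 0 & c2[, 2] < nx &
      c2[, 3] >= 0 & c2[, 3] < nx
    tgt <- c2[ok, 1] + nx * c2[ok, 2] + nx * nx * c2[ok, 3] + 1
    src <- idx[ok]
    valid <- path_ok[tgt]
    if (!any(valid)) next
    edges <- c(edges, rbind(rank_of[src[valid]], rank_of[tgt[valid]]))
    wts <- c(wts, rep(spacing * sqrt(sum(o^2)), sum(valid)))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, edges, weight = wts)
  # sources: path-allowed cells within ~1.75 cells of the attachment point,
  # entered at their Euclidean distance from the attachment
  src_d <- sqrt(rowSums(sweep(grid[idx, , drop = FALSE], 2, att)^2))
  sources <- which(src_d <= 1.75 * spacing)
  if (!length(sources)) stop("attachment of residue ", dye$residue, " is fully buried")
  D <- igraph::distances(g, v = sources, algorithm = "dijkstra")
  geo <- apply(D + src_d[sources], 2, min)

  allowed <- geo <= L + 1e-9 & dye_ok[idx]
  if (!any(allowed)) stop("accessible volume of residue ", dye$residue, " is empty")
  pos <- grid[idx[allowed], , drop = FALSE]
  obj <- list(positions = unname(pos), mean_position = colMeans(pos),
              spacing = spacing, attachment = att,
              geodesic = unname(geo[allowed]))
  class(obj) <- "av_cloud"
  obj
}

#' @export
print.av_cloud <- function(x, ...) {
  cat(sprintf("av_cloud: %d grid positions, spacing %.2f A, volume ~ %.0f A^3\n",
              nrow(x$positions), x$spacing, nrow(x$positions) * x$spacing^3))
  invisible(x)
}

#' Write an AV cloud as PDB pseudo-atoms (for visualization)
#' @param av an `av_cloud`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_av_cloud <- function(av, path) {
  n <- nrow(av$positions)
  df <- data.frame(element = "C", name = "AV", resid = 1L, resname = "DYE",
                   chain = "X", x = av$positions[, 1], y = av$positions[, 2],
                   z = av$positions[, 3])
  write_pdb(structure3d(df), path)
}

#' Forster efficiency from a donor-acceptor distance
#' @param r distance in Angstrom.
#' @param R0 Forster radius in Angstrom.
#' @return efficiency `1 / (1 + (r / R0)^6)`.
#' @export
efficiency_from_distance <- function(r, R0) 1 / (1 + (r / R0)^6)

#' Distance from a Forster efficiency
#' @param E efficiency in (0, 1).
#' @param R0 Forster radius in Angstrom.
#' @return distance `R0 (1/E - 1)^(1/6)` in Angstrom.
#' @export
distance_from_efficiency <- function(E, R0) {
  if (any(E <= 0) || any(E >= 1)) stop("E must lie strictly in (0, 1)")
  R0 * (1 / E - 1)^(1 / 6)
}

#' Mean FRET efficiency between two dye clouds
#'
#' Efficiency-averaged over sampled donor/acceptor position pairs (dyes
#' assumed to explore their clouds quickly relative to the conformational
#' event): `E = mean 1 / (1 + (r / R0)^6)`. When both clouds are small the
#' exact all-pairs average is returned instead of a Monte-Carlo estimate.
#'
#' @param donor,acceptor `av_cloud` objects.
#' @param R0 Forster radius in Angstrom.
#' @param n_samples Monte-Carlo sample size (default 10000).
#' @param seed integer seed.
#' @param exact force the exact all-pairs average.
#' @return list with `mean_E`, `sd_E`, `mean_distance`.
#' @export
fret_efficiency <- function(donor, acceptor, R0, n_samples = 10000,
                            seed = 1L, exact = FALSE) {
  nd <- nrow(donor$positions); na <- nrow(acceptor$positions)
  if (nd < 1 || na < 1) stop("dye clouds must be non-empty")
  if (exact || as.double(nd) * na <= n_samples) {
    ii <- rep(seq_len(nd), times = na)
    jj <- rep(seq_len(na), each = nd)
  } else {
    s <- with_seed(seed, list(i = sample.int(nd, n_samples, replace = TRUE),
                              j = sample.int(na, n_samples, replace = TRUE)))
    ii <- s$i; jj <- s$j
  }
  r <- sqrt(rowSums((donor$positions[ii, , drop = FALSE] -
                       acceptor$positions[jj, , drop = FALSE])^2))
  E <- efficiency_from_distance(r, R0)
  list(mean_E = mean(E), sd_E = stats::sd(E), mean_distance = mean(r))
}

#' Shot-noise-limited FRET efficiency histogram of an ensemble
#'
#' For each simulated burst: draw a conformation according to the ensemble
#' weights, take its AV-averaged efficiency E, and observe
#' `Binomial(photons, E) / photons`. Structures whose accessible volume
#' cannot be computed are skipped with a warning and the weights
#' renormalized.
#'
#' @param structures list of [structure3d()].
#' @param weights simplex weights over structures.
#' @param pair a [fret_pair()].
#' @param photons photons per data point (default 50).
#' @param n_events number of simulated bursts (default 2000).
#' @param n_samples_av position-pair samples per structure (default 5000).
#' @param spacing AV grid spacing (default 1.0 A).
#' @param seed integer seed.
#' @param breaks histogram breaks on [0, 1] (default width 0.02).
#' @return list with `mean`, `sd`, `bin_centers`, `density`,
#'   `per_state_E`, `efficiencies` (per event).
#' @export
ensemble_fret_histogram <- function(structures, weights, pair, photons = 50,
                                    n_events = 2000, n_samples_av = 5000,
                                    spacing = 1.0, seed = 1L,
                                    breaks = seq(0, 1, by = 0.02)) {
  stopifnot(length(structures) == length(weights))
  w <- weights / sum(weights)
  Es <- rep(NA_real_, length(structures))
  for (k in seq_along(structures)) {
    Ek <- tryCatch({
      dav <- accessible_volume(structures[[k]], pair$donor, spacing = spacing)
      aav <- accessible_volume(structures[[k]], pair$acceptor, spacing = spacing)
      fret_efficiency(dav, aav, pair$R0, n_samples = n_samples_av,
                      seed = derive_seed(seed, paste0("av-", k)))$mean_E
    }, error = function(e) {
      warning("skipping structure ", k, ": ", conditionMessage(e))
      NA_real_
    })
    Es[k] <- Ek
  }
  ok <- is.finite(Es)
  if (!any(ok)) stop("accessible volume failed for every structure")
  w <- w[ok] / sum(w[ok])
  Eok <- Es[ok]
  out <- with_seed(derive_seed(seed, "events"), {
    ks <- sample.int(length(Eok), n_events, replace = TRUE, prob = w)
    stats::rbinom(n_events, photons, Eok[ks]) / photons
  })
  h <- graphics::hist(out, breaks = breaks, plot = FALSE)
  list(mean = mean(out), sd = stats::sd(out), bin_centers = h$mids,
       density = h$density, per_state_E = Es, efficiencies = out)
}
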