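# Structure representation, PDB I/O, geometry and in-silico mutation.
#
# A structure3d is a light S3 wrapper around an atom table, the way ape
# wraps trees in plain lists: element, atom name, residue index/name,
# chain, xyz in Angstrom.

# Heavy (non-hydrogen) side-chain atom names for the 20 standard residues.
# Backbone N/CA/C/O (+ terminal OXT) is shared by all; GLY has no CB.
.SIDECHAIN_ATOMS <- list(
  ALA = c("CB"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)
.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

.ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  P = 30.974, S = 32.06, SE = 78.971, FE = 55.845)

#' Heavy-atom names of a standard residue type
#'
#' @param resname three-letter residue name (upper case).
#' @return character vector of heavy atom names (backbone + side chain).
#' @export
residue_atoms <- function(resname) {
  resname <- toupper(resname)
  sc <- .SIDECHAIN_ATOMS[[resname]]
  if (is.null(sc)) stop("unknown residue name: ", resname)
  c(setdiff(.BACKBONE_ATOMS, "OXT"), sc)
}

#' Construct a molecular structure
#'
#' @param atoms data.frame with columns `element`, `name`, `resid`
#'   (1-based residue index), `resname`, `chain`, `x`, `y`, `z` (Angstrom).
#'   An optional `nh` column gives implicit hydrogen counts per heavy atom
#'   (used by [debye_profile()]).
#' @return an object of class `structure3d`.
#' @export
structure3d <- function(atoms) {
  need <- c("element", "name", "resid", "resname", "chain", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table missing columns: ",
                         paste(miss, collapse = ", "))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  for (ch in unique(atoms$chain)) {
    r <- atoms$resid[atoms$chain == ch]
    if (is.unsorted(r)) stop("residue indices must be non-decreasing within chain ", ch)
  }
  atoms$element <- toupper(atoms$element)
  atoms$name <- toupper(atoms$name)
  atoms$resname <- toupper(atoms$resname)
  s <- list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE))
  class(s) <- "structure3d"
  s
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d: %d atoms, %d residues, %d chain(s)\n",
              nrow(x$atoms), n_residues(x), length(unique(x$atoms$chain))))
  invisible(x)
}

#' Number of residues in a structure
#' @param s a [structure3d()].
#' @return integer residue count.
#' @export
n_residues <- function(s) {
  length(unique(paste(s$atoms$chain, s$atoms$resid)))
}

#' Atom coordinates as a matrix
#' @param s a [structure3d()].
#' @return numeric matrix n_atoms x 3.
#' @export
coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

.set_coords <- function(s, xyz) {
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

.guess_element <- function(atom_name) {
  # PDB columns 13-14 carry the element for standard records; fall back to
  # the first alphabetic character of the stripped atom name.
  nm <- gsub("[^A-Za-z]", "", atom_name)
  two <- toupper(substr(nm, 1, 2))
  ifelse(two %in% c("SE", "FE", "ZN", "MG", "MN", "CL", "NA", "CA") &
           nchar(atom_name) == 4, two, toupper(substr(nm, 1, 1)))
}

#' Read a PDB file
#'
#' Parses ATOM records (HETATM optionally; waters always excluded) using
#' fixed PDB column positions. Models delimited by MODEL/ENDMDL records are
#' returned separately when `multi_model = TRUE`.
#'
#' @param path file path.
#' @param multi_model if TRUE return a list of structures, one per MODEL;
#'   otherwise only the first model is returned.
#' @param include_hetatm include non-water HETATM records.
#' @return a [structure3d()] or a list of them.
#' @export
read_pdb <- function(path, multi_model = FALSE, include_hetatm = FALSE) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty PDB file: ", path)
  rec <- substr(lines, 1, 6)
  keep <- rec == "ATOM  " | (include_hetatm & rec == "HETATM")
  model_id <- cumsum(rec == "MODEL ")
  model_id[model_id == 0] <- 1L
  idx <- which(keep)
  if (!length(idx)) stop("no ATOM records in ", path)
  parse_block <- function(ii) {
    ln <- lines[ii]
    altloc <- substr(ln, 17, 17)
    ok_alt <- altloc %in% c(" ", "A", "1")
    ln <- ln[ok_alt]; ii <- ii[ok_alt]
    x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
    resid <- suppressWarnings(as.integer(substr(ln, 23, 26)))
    bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z) | is.na(resid))
    if (length(bad))
      stop("malformed PDB record at line ", ii[bad[1]], ": ",
           trimws(lines[ii[bad[1]]]))
    name <- trimws(substr(ln, 13, 16))
    resname <- trimws(substr(ln, 18, 20))
    elem <- trimws(substr(ln, 77, 78))
    elem <- ifelse(elem == "", .guess_element(substr(ln, 13, 16)), toupper(elem))
    df <- data.frame(element = elem, name = name, resid = resid,
                     resname = resname, chain = substr(ln, 22, 22),
                     x = x, y = y, z = z, stringsAsFactors = FALSE)
    df <- df[df$resname != "HOH", , drop = FALSE]
    df <- df[df$element != "H", , drop = FALSE]
    if (!nrow(df)) stop("no usable atoms parsed from ", path)
    structure3d(df)
  }
  models <- sort(unique(model_id[idx]))
  if (!multi_model) return(parse_block(idx[model_id[idx] == models[1]]))
  lapply(models, function(m) parse_block(idx[model_id[idx] == m]))
}

#' Write a structure as a PDB file
#'
#' @param s a [structure3d()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  a <- s$atoms
  name4 <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
                  sprintf(" %-3s", a$name))
  lines <- sprintf(
    "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)) %% 100000, name4, substr(a$resname, 1, 3),
    substr(a$chain, 1, 1), a$resid, a$x, a$y, a$z, 1, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Point mutation by side-chain truncation
#'
#' Renames the residue and removes side-chain atoms that the target residue
#' type does not share with the source; backbone atoms and CB are always
#' kept, and no atoms are added (no rotamer building).
#'
#' @param s a [structure3d()].
#' @param residue_index 1-based residue index.
#' @param new_residue_name target three-letter residue name.
#' @param chain chain id; default first chain containing the residue.
#' @return the mutated [structure3d()].
#' @export
mutate_residue <- function(s, residue_index, new_residue_name, chain = NULL) {
  new_residue_name <- toupper(new_residue_name)
  target_sc <- .SIDECHAIN_ATOMS[[new_residue_name]]
  if (is.null(target_sc)) stop("unknown residue name: ", new_residue_name)
  a <- s$atoms
  sel <- a$resid == residue_index
  if (!is.null(chain)) sel <- sel & a$chain == chain
  if (!any(sel)) stop("residue ", residue_index, " not found")
  keep_names <- c(.BACKBONE_ATOMS, "CB", target_sc)
  drop <- sel & !(a$name %in% keep_names)
  a$resname[sel] <- new_residue_name
  a <- a[!drop, , drop = FALSE]
  rownames(a) <- NULL
  structure3d(a)
}

#' Radius of gyration
#'
#' Root-mean-square distance of atoms from their (optionally mass-weighted)
#' centroid, in Angstrom.
#'
#' @param s a [structure3d()].
#' @param mass_weighted weight atoms by atomic mass (default FALSE: uniform).
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(s, mass_weighted = FALSE) {
  xyz <- coords(s)
  if (nrow(xyz) < 2) stop("need at least 2 atoms")
  w <- if (mass_weighted) {
    m <- .ATOMIC_MASS[s$atoms$element]
    if (anyNA(m)) stop("no mass for element(s): ",
                       paste(unique(s$atoms$element[is.na(m)]), collapse = ", "))
    m / sum(m)
  } else rep(1 / nrow(xyz), nrow(xyz))
  ctr <- colSums(xyz * w)
  d2 <- rowSums((xyz - matrix(ctr, nrow(xyz), 3, byrow = TRUE))^2)
  sqrt(sum(w * d2))
}

.select_xyz <- function(s, atom_selection) {
  a <- s$atoms
  if (is.null(atom_selection)) return(coords(s))
  if (is.character(atom_selection)) {
    keep <- a$name %in% toupper(atom_selection)
  } else keep <- atom_selection
  coords(s)[keep, , drop = FALSE]
}

#' Minimal RMSD after optimal superposition (Kabsch)
#'
#' Rigid-body least-squares superposition via SVD with determinant
#' correction to exclude reflections.
#'
#' @param a,b structures with matched atom ordering.
#' @param atom_selection NULL (all atoms), a character vector of atom names
#'   (e.g. "CA"), or a logical/integer index applied to both structures.
#' @return RMSD in Angstrom.
#' @export
rmsd_superposed <- function(a, b, atom_selection = NULL) {
  X <- .select_xyz(a, atom_selection)
  Y <- .select_xyz(b, atom_selection)
  if (nrow(X) != nrow(Y)) stop("mismatched atom counts: ", nrow(X), " vs ", nrow(Y))
  if (nrow(X) < 1) stop("empty atom selection")
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  sv <- svd(crossprod(Yc, Xc))
  d <- sign(det(sv$u %*% t(sv$v)))
  sig <- c(1, 1, d)
  # E = sum|X|^2 + sum|Y|^2 - 2 * trace(S * Sigma)
  e <- sum(Xc^2) + sum(Yc^2) - 2 * sum(sv$d * sig)
  sqrt(max(e, 0) / nrow(X))
}

#' Residue-residue contact map
#'
#' Entry (i, j) is 1 iff the minimum heavy-atom distance between residues i
#' and j is below `cutoff` and the sequence separation is at least
#' `min_seq_sep`. The diagonal band `|i - j| < min_seq_sep` is forced to 0.
#'
#' @param s a [structure3d()].
#' @param cutoff distance cutoff in Angstrom (default 4.5).
#' @param min_seq_sep minimum |i - j| (default 3).
#' @return a `contact_map` object (fields `n`, `map`, `type`).
#' @export
contact_map <- function(s, cutoff = 4.5, min_seq_sep = 3) {
  a <- s$atoms
  key <- paste(a$chain, a$resid)
  rid <- match(key, unique(key)) # 1..n in chain order
  n <- max(rid)
  xyz <- coords(s)
  D <- as.matrix(stats::dist(xyz))
  m <- matrix(0, n, n)
  # min heavy-atom distance per residue pair
  grp <- split(seq_len(nrow(xyz)), rid)
  for (i in seq_len(n - 1)) {
    ii <- grp[[i]]
    for (j in seq((i + 1), n)) {
      if (j - i < min_seq_sep) next
      if (min(D[ii, grp[[j]]]) < cutoff) { m[i, j] <- 1; m[j, i] <- 1 }
    }
  }
  new_contact_map(m, type = "binary")
}

#' Construct a contact map object
#'
#' @param m symmetric numeric matrix; binary indicators or densities in
#'   `[0, 1]`, or a signed difference map in `[-1, 1]`.
#' @param type one of "binary", "density", "difference".
#' @return a `contact_map` object.
#' @export
new_contact_map <- function(m, type = c("binary", "density", "difference")) {
  type <- match.arg(type)
  if (!isSymmetric(unname(m), tol = 1e-12)) stop("contact map must be symmetric")
  rng <- range(m)
  lo <- if (type == "difference") -1 else 0
  if (rng[1] < lo - 1e-12 || rng[2] > 1 + 1e-12)
    stop("contact map values out of range for type ", type)
  obj <- list(n = nrow(m), map = unname(m), type = type)
  class(obj) <- "contact_map"
  obj
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map (%s): %d residues, %d nonzero upper-triangle entries\n",
              x$type, x$n, sum(x$map[upper.tri(x$map)] != 0)))
  invisible(x)
}

#' Write a contact map as whitespace-delimited text
#' @param cm a `contact_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(cm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# contact_map n=%d type=%s", cm$n, cm$type), con)
  utils::write.table(cm$map, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a contact map written by [write_contact_map()]
#' @param path input path.
#' @return a `contact_map`.
#' @export
read_contact_map <- function(path) {
  hdr <- readLines(path, n = 1)
  type <- sub(".*type=", "", hdr)
  m <- as.matrix(utils::read.table(path, skip = 1))
  new_contact_map(unname(m), type = type)
}
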