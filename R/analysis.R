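# Weighted ensemble contact densities, difference maps, and feature-based
# state classification (e.g. "contains beta2-3 contacts").

#' Define a structural feature as a set of residue contacts
#'
#' @param name feature name.
#' @param pairs 2-column matrix (or data.frame) of residue index pairs.
#' @param threshold fraction of the pair set that must be in contact for a
#'   state to "contain" the feature, in (0, 1]. No default is silently
#'   assumed: the caller must choose.
#' @return a `feature_definition` object.
#' @export
feature_definition <- function(name, pairs, threshold) {
  pairs <- matrix(as.integer(as.matrix(pairs)), ncol = 2)
  if (!nrow(pairs)) stop("feature needs at least one residue pair")
  if (any(pairs < 1)) stop("residue indices must be >= 1")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  obj <- list(name = name, pairs = pairs, threshold = threshold)
  class(obj) <- "feature_definition"
  obj
}

#' Read a feature definition from JSON
#' @param path JSON file with fields `name`, `pairs` (n x 2), `threshold`.
#' @return a [feature_definition()].
#' @export
read_feature <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  feature_definition(j$name, j$pairs, j$threshold)
}

#' Write a feature definition as JSON
#' @param feature a [feature_definition()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature <- function(feature, path) {
  jsonlite::write_json(list(name = feature$name, pairs = feature$pairs,
                            threshold = feature$threshold),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' Population-weighted ensemble contact density
#'
#' `density(i, j) = sum_k w_k c_k(i, j)` over per-state contact maps.
#'
#' @param maps list of `contact_map` objects with equal residue counts.
#' @param w an [ensemble_weights()] or plain simplex vector.
#' @return a `contact_map` of type "density".
#' @export
weighted_contact_density <- function(maps, w) {
  w <- if (inherits(w, "ensemble_weights")) w$w else as.numeric(w)
  if (length(w) != length(maps)) stop("one weight per contact map required")
  n <- maps[[1]]$n
  acc <- matrix(0, n, n)
  for (k in seq_along(maps)) {
    if (maps[[k]]$n != n) stop("contact map dimension mismatch at state ", k)
    acc <- acc + w[k] * maps[[k]]$map
  }
  new_contact_map(acc, type = "density")
}

#' Signed difference of two contact density maps
#'
#' Elementwise `a - b`; values lie in `[-1, 1]`.
#'
#' @param a,b `contact_map` objects of equal dimension.
#' @return a `contact_map` of type "difference".
#' @export
difference_map <- function(a, b) {
  if (a$n != b$n) stop("contact map dimension mismatch")
  new_contact_map(a$map - b$map, type = "difference")
}

#' Classify states by a contact feature
#'
#' A state contains the feature iff at least `threshold` of the feature's
#' residue pairs are in contact in that state. The ensemble feature
#' fraction is the total weight of containing states.
#'
#' @param maps list of per-state `contact_map` objects.
#' @param feature a [feature_definition()].
#' @param w optional weights (default uniform) for the ensemble fraction.
#' @return list with `contains` (logical per state) and `fraction`.
#' @export
classify_states <- function(maps, feature, w = NULL) {
  n <- maps[[1]]$n
  if (any(feature$pairs > n)) stop("feature pairs exceed residue count")
  if (is.null(w)) w <- rep(1 / length(maps), length(maps))
  w <- if (inherits(w, "ensemble_weights")) w$w else as.numeric(w)
  contains <- vapply(maps, function(cm) {
    hit <- cm$map[feature$pairs] > 0
    mean(hit) >= feature$threshold
  }, logical(1))
  list(contains = contains, fraction = sum(w[contains]))
}

#' Approximate helical content from a contact map
#'
#' Fraction of residues i with an (i, i+4) contact — a contact-pattern
#' proxy for DSSP-style helix assignment, documented as an approximation.
#'
#' @param cm a `contact_map` (binary or density).
#' @return scalar in `[0, 1]`.
#' @export
helix_content <- function(cm) {
  n <- cm$n
  if (n <= 4) return(0)
  i <- seq_len(n - 4)
  mean(cm$map[cbind(i, i + 4)])
}
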