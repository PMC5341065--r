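# Debye-equation SAXS forward model, Guinier analysis, scale/offset
# fitting and chi-squared against experiment.

# Cromer-Mann 4-Gaussian form-factor coefficients (International Tables,
# X-ray): f(q) = sum_i a_i exp(-b_i (q/4pi)^2) + c, with f(0) = Z.
.CROMER_MANN <- list(
  H = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
           b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305),
  C = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
           b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
           b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
           b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  P = list(a = c(6.43450, 4.17910, 1.78000, 1.49080),
           b = c(1.90670, 27.1570, 0.526000, 68.1645), c = 1.11490),
  S = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
           b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900)
)

#' X-ray atomic form factor
#'
#' Cromer-Mann 4-Gaussian parameterization; `f(0)` equals the electron
#' count Z. Available elements: H, C, N, O, P, S.
#'
#' @param element element symbol.
#' @param q momentum transfer grid (1/Angstrom).
#' @return numeric vector `f(q)`.
#' @export
form_factor <- function(element, q) {
  cm <- .CROMER_MANN[[toupper(element)]]
  if (is.null(cm)) stop("no form factor for element: ", element)
  s2 <- (q / (4 * pi))^2
  out <- rep(cm$c, length(q))
  for (i in 1:4) out <- out + cm$a[i] * exp(-cm$b[i] * s2)
  out
}

#' Construct a SAXS profile
#'
#' @param q momentum transfer grid (1/Angstrom), strictly increasing, >= 0.
#' @param I intensities (arbitrary units), finite.
#' @param sigma optional per-point uncertainties, > 0 where present.
#' @return a `saxs_profile` object.
#' @export
saxs_profile <- function(q, I, sigma = NULL) {
  if (any(q < 0) || any(diff(q) <= 0)) stop("q must be strictly increasing and >= 0")
  if (length(I) != length(q) || !all(is.finite(I))) stop("I must be finite, same length as q")
  if (!is.null(sigma)) {
    if (length(sigma) != length(q)) stop("sigma length mismatch")
    if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("sigma must be > 0")
  }
  p <- list(q = as.numeric(q), I = as.numeric(I),
            sigma = if (is.null(sigma)) NULL else as.numeric(sigma))
  class(p) <- "saxs_profile"
  p
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat(sprintf("saxs_profile: %d points, q in [%.4g, %.4g]%s\n", length(x$q),
              min(x$q), max(x$q), if (is.null(x$sigma)) "" else ", with sigma"))
  invisible(x)
}

#' Read a 3-column SAXS profile (q, I, sigma)
#'
#' Whitespace-delimited text with optional '#' comment lines (the common
#' .dat dialect). The third column is optional.
#'
#' @param path input path.
#' @return a [saxs_profile()].
#' @export
read_saxs <- function(path) {
  m <- utils::read.table(path, comment.char = "#")
  sig <- if (ncol(m) >= 3 && !anyNA(m[[3]])) m[[3]] else NULL
  saxs_profile(m[[1]], m[[2]], sig)
}

#' Write a SAXS profile as 3-column text
#' @param p a [saxs_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_saxs <- function(p, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (is.null(p$sigma)) {
    writeLines("# q I", con)
    writeLines(sprintf("%.8g %.10g", p$q, p$I), con)
  } else {
    writeLines("# q I sigma", con)
    writeLines(sprintf("%.8g %.10g %.10g", p$q, p$I, p$sigma), con)
  }
  invisible(path)
}

# sin(x)/x with series fallback near 0
.sinc <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  out[small] <- 1 - x[small]^2 / 6
  out[!small] <- sin(x[!small]) / x[!small]
  out
}

#' Debye-equation SAXS profile of a structure
#'
#' Exact orientationally averaged scattering of a rigid atom set,
#' `I(q) = sum_ij f_i(q) f_j(q) sin(q d_ij)/(q d_ij)`, with tabulated
#' atomic form factors; `I(0) = (sum_i f_i(0))^2`. If the structure's atom
#' table has an `nh` column, that many hydrogen form factors are folded
#' into each heavy atom (united-atom approximation). No hydration shell or
#' excluded-volume term is modelled.
#'
#' @param s a [structure3d()].
#' @param q momentum transfer grid (1/Angstrom).
#' @return a [saxs_profile()] (no sigma).
#' @export
debye_profile <- function(s, q) {
  a <- s$atoms
  unknown <- setdiff(unique(a$element), names(.CROMER_MANN))
  if (length(unknown)) stop("no form factor for element(s): ",
                            paste(unknown, collapse = ", "))
  xyz <- coords(s)
  n <- nrow(xyz)
  nh <- if ("nh" %in% names(a)) a$nh else rep(0, n)
  # per-atom effective form factor on the q grid: nq x n
  F <- vapply(seq_len(n), function(i)
    form_factor(a$element[i], q) + nh[i] * form_factor("H", q),
    numeric(length(q)))
  F <- matrix(F, nrow = length(q))
  I <- rowSums(F^2) # self terms
  if (n > 1) {
    pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    d <- sqrt(rowSums((xyz[pr[, 1], , drop = FALSE] -
                         xyz[pr[, 2], , drop = FALSE])^2))
    # chunk over q to bound memory at ~ n^2/2 doubles per step
    for (iq in seq_along(q)) {
      fq <- F[iq, ]
      I[iq] <- I[iq] + 2 * sum(fq[pr[, 1]] * fq[pr[, 2]] * .sinc(q[iq] * d))
    }
  }
  saxs_profile(q, I)
}

#' Guinier fit of the low-q region
#'
#' Linear fit of `ln I` versus `q^2`; `Rg = sqrt(-3 slope)`. The fit window
#' is iterated to self-consistency with the rule `q_max * Rg <= qmax_rg`
#' (default 1.3), at most `max_iter` times.
#'
#' @param p a [saxs_profile()].
#' @param qmax_rg Guinier window rule (default 1.3).
#' @param min_points minimum points in the fitted region (default 5).
#' @param max_iter maximum window iterations (default 20).
#' @return list with `rg`, `I0`, `qmax`, `n_points`.
#' @export
guinier_rg <- function(p, qmax_rg = 1.3, min_points = 5, max_iter = 20) {
  fit_region <- function(qmax) {
    keep <- p$q <= qmax & p$q > 0
    if (sum(keep) < min_points)
      stop("Guinier region collapsed below ", min_points, " points")
    if (any(p$I[keep] <= 0)) stop("non-positive intensities in Guinier region")
    co <- stats::coef(stats::lm(log(p$I[keep]) ~ I(p$q[keep]^2)))
    if (co[2] >= 0) stop("non-negative Guinier slope; no Rg")
    list(rg = sqrt(-3 * co[2]), I0 = exp(co[1]), n = sum(keep))
  }
  qmax <- max(p$q)
  f <- fit_region(qmax)
  for (i in seq_len(max_iter)) {
    qnew <- min(qmax_rg / f$rg, max(p$q))
    if (abs(qnew - qmax) < 1e-12) break
    qmax <- qnew
    f <- fit_region(qmax)
  }
  list(rg = unname(f$rg), I0 = unname(f$I0), qmax = qmax, n_points = f$n)
}

#' Interpolate a simulated profile onto an experimental q grid
#'
#' Linear interpolation in q; extrapolation outside the simulated q range
#' is an error.
#'
#' @param p a [saxs_profile()].
#' @param q_target target grid.
#' @return a [saxs_profile()] on `q_target`.
#' @export
interpolate_profile <- function(p, q_target) {
  eps <- 1e-9
  if (min(q_target) < min(p$q) - eps || max(q_target) > max(p$q) + eps)
    stop("extrapolation outside the simulated q range is not allowed")
  saxs_profile(q_target, stats::approx(p$q, p$I, xout = q_target, rule = 1)$y)
}

# weighted least squares for I_exp ~ c * I_sim + f; returns list(c, f)
.wls_scale_offset <- function(s, y, w) {
  sw <- sum(w); sx <- sum(w * s); sy <- sum(w * y)
  sxx <- sum(w * s^2); sxy <- sum(w * s * y)
  den <- sw * sxx - sx^2
  if (!is.finite(den) || abs(den) < 1e-12 * max(sw * sxx, 1)) return(NULL)
  c_ <- (sw * sxy - sx * sy) / den
  f_ <- (sy - c_ * sx) / sw
  list(c = c_, f = f_)
}

#' Fit scale and offset of a simulated profile to experiment
#'
#' Finds `(c, f)` minimizing `sum ((c I_sim + f - I_exp) / sigma)^2` by
#' weighted linear least squares (closed form). The simulated profile is
#' first interpolated onto the experimental grid.
#'
#' @param sim simulated [saxs_profile()].
#' @param exp experimental [saxs_profile()] with `sigma`.
#' @return list with `c`, `f`, `chi2` (reduced, per point).
#' @export
fit_scale_offset <- function(sim, exp) {
  if (is.null(exp$sigma)) stop("experimental profile must carry sigma")
  if (any(exp$sigma == 0)) stop("sigma contains zeros")
  s <- if (.same_grid(sim$q, exp$q)) sim$I else interpolate_profile(sim, exp$q)$I
  w <- 1 / exp$sigma^2
  cf <- .wls_scale_offset(s, exp$I, w)
  if (is.null(cf)) {
    warning("degenerate (constant) simulated profile; fixing c = 1")
    cf <- list(c = 1, f = sum(w * (exp$I - s)) / sum(w))
  } else if (cf$c <= 0) {
    warning("non-positive fitted scale; fixing c = 1")
    cf <- list(c = 1, f = sum(w * (exp$I - s)) / sum(w))
  }
  resid <- (cf$c * s + cf$f - exp$I) / exp$sigma
  list(c = cf$c, f = cf$f, chi2 = mean(resid^2))
}

#' Reduced chi-squared between simulated and experimental profiles
#'
#' `(1/N_q) sum ((c I_sim + f - I_exp)^2 / sigma^2)`, by default after the
#' optimal scale/offset fit; pass `c` and `f` to force them.
#'
#' @param sim simulated [saxs_profile()].
#' @param exp experimental [saxs_profile()] with `sigma`.
#' @param c,f optional fixed scale and offset (both must be given).
#' @return chi-squared (dimensionless).
#' @export
chi_squared <- function(sim, exp, c = NULL, f = NULL) {
  if (is.null(c) != is.null(f)) stop("give both c and f, or neither")
  if (is.null(c)) return(fit_scale_offset(sim, exp)$chi2)
  if (is.null(exp$sigma)) stop("experimental profile must carry sigma")
  if (any(exp$sigma == 0)) stop("sigma contains zeros")
  s <- if (.same_grid(sim$q, exp$q)) sim$I else interpolate_profile(sim, exp$q)$I
  mean(((c * s + f - exp$I) / exp$sigma)^2)
}
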