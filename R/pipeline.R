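# Orchestration of the three-step inference: refine a uniform prior
# against unfolded-state SAXS data (E_U), propagate it with the MSM to the
# observation time (E_MSM), and refine again against the refolded-state
# SAXS data (E_SAXS).

#' Pipeline configuration
#'
#' @param profiles list of per-state [saxs_profile()] (or a directory of
#'   `*.dat` files).
#' @param exp_unfolded experimental [saxs_profile()] of the denatured
#'   state (or a file path).
#' @param exp_refolded experimental [saxs_profile()] at the observation
#'   time (or a file path).
#' @param T a [transition_matrix()] over the same states.
#' @param duration propagation time, in the transition matrix's lag unit
#'   (e.g. 5e-3 s for a 5 ms observation).
#' @param theta_unfolded,theta_excited regularization strengths for the
#'   two refinements.
#' @param seed master seed; stage seeds are derived as named substreams
#'   ("refine-unfolded", "refine-excited").
#' @param contact_maps optional list of per-state `contact_map` objects;
#'   if given, stage density maps and the E_SAXS - E_MSM difference map
#'   are computed.
#' @param anneal a [refinement_config()] used as the template for both
#'   refinements (its `theta` and `seed` are overridden per stage).
#' @param outdir optional output directory for the report files.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(profiles, exp_unfolded, exp_refolded, T, duration,
                            theta_unfolded = 0, theta_excited = 0, seed = 1L,
                            contact_maps = NULL, anneal = refinement_config(),
                            outdir = NULL) {
  if (is.character(profiles)) {
    files <- sort(list.files(profiles, pattern = "\\.dat$", full.names = TRUE))
    files <- files[!grepl("experiment", basename(files))]
    if (!length(files)) stop("no *.dat state profiles found in ", profiles)
    profiles <- lapply(files, read_saxs)
  }
  if (is.character(exp_unfolded)) exp_unfolded <- read_saxs(exp_unfolded)
  if (is.character(exp_refolded)) exp_refolded <- read_saxs(exp_refolded)
  if (duration <= 0) stop("propagation duration must be positive")
  if (nrow(T$T) != length(profiles))
    stop("transition matrix states (", nrow(T$T), ") do not match the number ",
         "of state profiles (", length(profiles), ")")
  cfg <- list(profiles = profiles, exp_unfolded = exp_unfolded,
              exp_refolded = exp_refolded, T = T, duration = duration,
              theta_unfolded = theta_unfolded, theta_excited = theta_excited,
              seed = as.integer(seed), contact_maps = contact_maps,
              anneal = anneal, outdir = outdir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the three-step excited-state inference
#'
#' 1. Refine a uniform prior against the unfolded-state experiment (E_U).
#' 2. Propagate E_U with the kinetic model for `duration` (E_MSM).
#' 3. Refine E_MSM against the refolded-state experiment (E_SAXS).
#'
#' Fully determined by the configuration, seeds included.
#'
#' @param cfg a [pipeline_config()].
#' @return a `pipeline_result`: list with `E_U`, `E_MSM`, `E_SAXS`
#'   (weight vectors), the two `refinement_result`s, per-stage `chi2`,
#'   optional density/difference maps, and the `config`.
#' @export
run_inference <- function(cfg) {
  N <- length(cfg$profiles)
  uniform <- ensemble_weights(rep(1 / N, N))

  cfg_u <- cfg$anneal
  cfg_u$theta <- cfg$theta_unfolded
  cfg_u$seed <- derive_seed(cfg$seed, "refine-unfolded")
  stage <- "refine-unfolded"
  res_u <- tryCatch(anneal_refine(uniform, cfg$profiles, cfg$exp_unfolded, cfg_u),
                    error = function(e) stop("stage ", stage, " failed: ",
                                             conditionMessage(e)))
  E_U <- res_u$weights$w

  stage <- "propagate"
  E_MSM <- tryCatch(as.numeric(propagate(cfg$T, population_vector(E_U),
                                         cfg$duration)),
                    error = function(e) stop("stage ", stage, " failed: ",
                                             conditionMessage(e)))

  cfg_x <- cfg$anneal
  cfg_x$theta <- cfg$theta_excited
  cfg_x$seed <- derive_seed(cfg$seed, "refine-excited")
  stage <- "refine-excited"
  prior_x <- ensemble_weights(E_MSM, E_MSM)
  res_x <- tryCatch(anneal_refine(prior_x, cfg$profiles, cfg$exp_refolded, cfg_x),
                    error = function(e) stop("stage ", stage, " failed: ",
                                             conditionMessage(e)))
  E_SAXS <- res_x$weights$w

  chi2 <- c(
    E_U = res_u$chi2,
    E_MSM = chi_squared(ensemble_profile(cfg$profiles, E_MSM), cfg$exp_refolded),
    E_SAXS = res_x$chi2)

  out <- list(E_U = E_U, E_MSM = E_MSM, E_SAXS = E_SAXS,
              refine_unfolded = res_u, refine_excited = res_x,
              chi2 = chi2, config = cfg)
  if (!is.null(cfg$contact_maps)) {
    out$density_E_U <- weighted_contact_density(cfg$contact_maps, E_U)
    out$density_E_MSM <- weighted_contact_density(cfg$contact_maps, E_MSM)
    out$density_E_SAXS <- weighted_contact_density(cfg$contact_maps, E_SAXS)
    out$difference_E_SAXS_minus_E_MSM <-
      difference_map(out$density_E_SAXS, out$density_E_MSM)
  }
  class(out) <- "pipeline_result"
  if (!is.null(cfg$outdir)) write_pipeline_result(out, cfg$outdir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:\n")
  cat(sprintf("  chi2: E_U = %.4g, E_MSM = %.4g, E_SAXS = %.4g\n",
              x$chi2[["E_U"]], x$chi2[["E_MSM"]], x$chi2[["E_SAXS"]]))
  invisible(x)
}

#' Write a pipeline report to a directory
#'
#' Emits per-stage weights as TSV, a JSON report (chi2, seeds, thetas),
#' and contact density / difference maps when present.
#'
#' @param res a `pipeline_result`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  W <- data.frame(state = seq_along(res$E_U), E_U = res$E_U,
                  E_MSM = res$E_MSM, E_SAXS = res$E_SAXS)
  utils::write.table(W, file.path(dir, "weights.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  report <- list(
    chi2 = as.list(res$chi2),
    theta = list(unfolded = res$config$theta_unfolded,
                 excited = res$config$theta_excited),
    duration = res$config$duration,
    seed = res$config$seed,
    seeds = list(refine_unfolded = derive_seed(res$config$seed, "refine-unfolded"),
                 refine_excited = derive_seed(res$config$seed, "refine-excited")),
    n_states = length(res$E_U))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in c("density_E_U", "density_E_MSM", "density_E_SAXS",
               "difference_E_SAXS_minus_E_MSM")) {
    if (!is.null(res[[nm]]))
      write_contact_map(res[[nm]], file.path(dir, paste0(nm, ".txt")))
  }
  invisible(dir)
}

# ---- minimal command-line front end -------------------------------------

.cli_args_to_list <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (i + 1 <= length(args) && !startsWith(args[i + 1], "--")) {
      out[[key]] <- args[i + 1]; i <- i + 2
    } else { out[[key]] <- TRUE; i <- i + 1 }
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `refine` (EROS refinement of profiles against an
#' experiment), `fret` (AV-FRET histogram for one PDB), `make-fixtures`
#' (emit the standard synthetic fixture set). Invoked by the
#' `inst/cli/saxsens` script; exposed as a function for testing.
#'
#' @param args character vector, e.g.
#'   `c("refine", "--profiles", dir, "--exp", f, "--theta", "1", "--seed",
#'   "7", "--out", "res.json")`.
#' @return exit code, invisibly (0 success, 2 usage/config error).
#' @export
saxsens_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: saxsens <refine|fret|make-fixtures> [--flags]")
    return(invisible(2L))
  }
  cmd <- args[1]
  opt <- .cli_args_to_list(args[-1])
  num <- function(x, d = NULL) if (is.null(x)) d else as.numeric(x)
  if (cmd == "make-fixtures") {
    if (is.null(opt$out)) { message("make-fixtures needs --out DIR"); return(invisible(2L)) }
    make_fixtures(opt$out, seed = num(opt$seed, 1))
    return(invisible(0L))
  }
  if (cmd == "refine") {
    if (is.null(opt$profiles) || is.null(opt$exp)) {
      message("refine needs --profiles DIR --exp FILE"); return(invisible(2L))
    }
    files <- sort(list.files(opt$profiles, pattern = "^state.*\\.dat$",
                             full.names = TRUE))
    profiles <- lapply(files, read_saxs)
    expp <- read_saxs(opt$exp)
    N <- length(profiles)
    prior <- if (is.null(opt$prior) || identical(opt$prior, "uniform"))
      ensemble_weights(rep(1 / N, N))
    else {
      w <- utils::read.table(opt$prior, header = TRUE)$weight
      ensemble_weights(w / sum(w), w / sum(w))
    }
    cfg <- refinement_config(theta = num(opt$theta, 0),
                             seed = num(opt$seed, 1))
    res <- anneal_refine(prior, profiles, expp, cfg)
    out <- list(weights = res$weights$w, G = res$G, chi2 = res$chi2,
                penalty = res$penalty, theta = cfg$theta, seed = cfg$seed,
                trace_G = res$trace$G)
    jsonlite::write_json(out, opt$out %||% "refine.json",
                         auto_unbox = TRUE, digits = NA)
    return(invisible(0L))
  }
  if (cmd == "fret") {
    need <- c("pdb", "donor", "acceptor", "r0")
    if (any(vapply(need, function(k) is.null(opt[[k]]), logical(1)))) {
      message("fret needs --pdb FILE --donor RES --acceptor RES --r0 X")
      return(invisible(2L))
    }
    s <- read_pdb(opt$pdb)
    pair <- fret_pair(dye_spec(as.integer(opt$donor), role = "donor",
                               linker_length = num(opt$linker, 15)),
                      dye_spec(as.integer(opt$acceptor), role = "acceptor",
                               linker_length = num(opt$linker, 15)),
                      R0 = num(opt$r0))
    h <- ensemble_fret_histogram(list(s), 1, pair,
                                 photons = num(opt$photons, 50),
                                 seed = num(opt$seed, 1))
    tab <- data.frame(bin_center = h$bin_centers, density = h$density)
    utils::write.table(tab, opt$out %||% "fret_hist.tsv", sep = "\t",
                       row.names = FALSE, quote = FALSE)
    return(invisible(0L))
  }
  message("unknown subcommand: ", cmd)
  invisible(2L)
}
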