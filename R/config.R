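#' Analysis run configuration
#'
#' Bundles every tunable threshold of the pipeline with the defaults used in
#' the flowering-time study: markers kept at minor allele frequency > 0.05,
#' genome-wide significance at -log10 p = 7 (above the Bonferroni 6.2 for
#' 78,427 tests at alpha 0.05), LD summarized up to 500 kb, diversity and
#' Fst in 100 kb windows sliding by 10 kb, homology hits kept at > 80\%
#' identity and > 70 bp alignment, and the epistasis search run for 1,000,000
#' MCMC iterations with 990,000 burn-in and a 0.5 posterior threshold.
#'
#' @param maf_threshold minimum minor allele frequency (strict >).
#' @param significance_neglogp genome-wide significance cut-off on the
#'   -log10 p scale (strict >).
#' @param alpha type-I error rate for the Bonferroni threshold.
#' @param ld_max_distance maximum pair distance (bp) for LD decay.
#' @param window_size,window_step window and slide size (bp) for windowed
#'   diversity and Fst.
#' @param homology_min_identity,homology_min_length strict lower bounds for
#'   homology-hit filtering (percent identity; alignment positions).
#' @param mcmc_iterations,mcmc_burnin MCMC chain length and burn-in.
#' @param posterior_threshold minimum posterior probability for a reported
#'   interaction group.
#' @param random_seed integer seed used by every stochastic stage.
#' @return A list of class \code{"run_config"}.
#' @export
run_config <- function(maf_threshold = 0.05, significance_neglogp = 7.0,
                       alpha = 0.05, ld_max_distance = 500000L,
                       window_size = 100000L, window_step = 10000L,
                       homology_min_identity = 80, homology_min_length = 70,
                       mcmc_iterations = 1000000L, mcmc_burnin = 990000L,
                       posterior_threshold = 0.5, random_seed = 1L) {
  cfg <- list(maf_threshold = maf_threshold,
              significance_neglogp = significance_neglogp, alpha = alpha,
              ld_max_distance = as.integer(ld_max_distance),
              window_size = as.integer(window_size),
              window_step = as.integer(window_step),
              homology_min_identity = homology_min_identity,
              homology_min_length = homology_min_length,
              mcmc_iterations = as.integer(mcmc_iterations),
              mcmc_burnin = as.integer(mcmc_burnin),
              posterior_threshold = posterior_threshold,
              random_seed = as.integer(random_seed))
  if (cfg$mcmc_burnin >= cfg$mcmc_iterations)
    stop("mcmc_burnin must be smaller than mcmc_iterations")
  if (cfg$maf_threshold <= 0 || cfg$maf_threshold >= 0.5)
    stop("maf_threshold must be in (0, 0.5)")
  if (cfg$posterior_threshold <= 0 || cfg$posterior_threshold >= 1)
    stop("posterior_threshold must be in (0, 1)")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read a run configuration from a flat key = value text file
#'
#' Lines are \code{key = value}; blank lines and \code{#} comments are
#' ignored. Unknown keys are an error, so a typo cannot silently fall back to
#' a default.
#'
#' @param path configuration file.
#' @return A \code{\link{run_config}}.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!all(grepl("=", lines, fixed = TRUE)))
    stop("malformed configuration line (expected key = value)")
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  known <- names(formals(run_config))
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(keys))
    stop("duplicated configuration key")
  args <- lapply(vals, function(v) as.numeric(v))
  names(args) <- keys
  do.call(run_config, args)
}

#' Write a run configuration as a flat key = value text file
#'
#' @param cfg a \code{\link{run_config}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  writeLines(sprintf("%s = %s", names(cfg),
                     vapply(cfg, format, character(1), scientific = FALSE)),
             path)
  invisible(path)
}
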