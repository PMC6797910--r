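#' Analysis configuration
#'
#' Bundles the tunable parameters of the convergence scan and its bootstrap
#' calibration.  Defaults follow the published workflow for temperature in
#' degrees Celsius; for depth analyses the conventional bin width is 0.2 on
#' the log10-meters scale.
#'
#' @param bin_width Width of the trait bins used to place candidate cutoffs.
#'   Default 1.75 (degrees C); use 0.2 for log10(depth in m).
#' @param min_transitions Minimum number of independent ancestral-to-convergent
#'   transition events a scenario must contain to be retained (guards against
#'   phylogenetic pseudoreplication). Default 5.
#' @param pp_threshold Posterior-probability floor below which a site is not
#'   bootstrapped. Default 0.5.
#' @param n_sims Number of null and of convergent simulations per site in the
#'   bootstrap. Default 1000.
#' @param confidence Bootstrap confidence level used for both the upper (null)
#'   and lower (convergent) thresholds. Default 0.95.
#' @param noise_concentration Dirichlet concentration used when perturbing the
#'   ancestral profile for null simulations; larger means less noise.
#'   Default 100.
#' @param blen_noise_sd Standard deviation (log scale) of optional lognormal
#'   branch-length multipliers applied in bootstrap simulations; 0 disables
#'   branch-length noise. Default 0.
#' @param seed Integer seed from which all per-site random substreams are
#'   derived. Default 1.
#'
#' @return An object of class `pcoc_config` (a named list).
#' @export
pcoc_config <- function(bin_width = 1.75,
                        min_transitions = 5L,
                        pp_threshold = 0.5,
                        n_sims = 1000L,
                        confidence = 0.95,
                        noise_concentration = 100,
                        blen_noise_sd = 0,
                        seed = 1L) {
  cfg <- list(
    bin_width = as.numeric(bin_width),
    min_transitions = as.integer(min_transitions),
    pp_threshold = as.numeric(pp_threshold),
    n_sims = as.integer(n_sims),
    confidence = as.numeric(confidence),
    noise_concentration = as.numeric(noise_concentration),
    blen_noise_sd = as.numeric(blen_noise_sd),
    seed = as.integer(seed)
  )
  if (!is.finite(cfg$bin_width) || cfg$bin_width <= 0)
    stop("bin_width must be > 0", call. = FALSE)
  if (cfg$min_transitions < 1L)
    stop("min_transitions must be >= 1", call. = FALSE)
  if (!(cfg$pp_threshold > 0 && cfg$pp_threshold < 1))
    stop("pp_threshold must lie strictly between 0 and 1", call. = FALSE)
  if (cfg$n_sims < 1L)
    stop("n_sims must be >= 1", call. = FALSE)
  if (!(cfg$confidence > 0.5 && cfg$confidence < 1))
    stop("confidence must lie strictly between 0.5 and 1", call. = FALSE)
  if (cfg$noise_concentration <= 0)
    stop("noise_concentration must be > 0", call. = FALSE)
  if (cfg$blen_noise_sd < 0)
    stop("blen_noise_sd must be >= 0", call. = FALSE)
  structure(cfg, class = "pcoc_config")
}

#' @export
print.pcoc_config <- function(x, ...) {
  cat("<pcoc_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Deterministic per-site substream seed, kept below 2^31 - 1.
site_seed <- function(seed, site_index, salt = 0) {
  (as.numeric(seed) * 48271 + as.numeric(site_index) * 69621 +
     as.numeric(salt) * 16807) %% 2147483647 + 1
}
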