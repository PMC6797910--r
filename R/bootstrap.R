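# Simulation bootstrap: per site, the maximum-likelihood profile pair and
# maximum-PP scenario recovered by the scan are reused to simulate null
# (ancestral-profile-with-noise) and convergent columns on the site's
# gap-pruned tree; re-scoring them yields a null PP distribution (upper
# threshold: specificity) and a convergent PP distribution (lower threshold:
# sensitivity), against which the observed PP is classified.

#' Perturb a profile with Dirichlet noise
#'
#' Draws from `Dirichlet(concentration * profile)` and floors/renormalizes as
#' profile loading does.  Larger concentrations mean smaller perturbations;
#' the draw equals the profile in the concentration limit and has mean equal
#' to the profile at any concentration.
#'
#' @param profile A 20-vector of frequencies.
#' @param concentration Positive Dirichlet concentration.
#' @return A perturbed 20-vector summing to one.  Uses the current RNG state.
#' @export
perturb_profile <- function(profile, concentration) {
  if (!is.finite(concentration) || concentration <= 0)
    stop("concentration must be > 0", call. = FALSE)
  pi <- rate_model(profile)$pi
  g <- rgamma(20, shape = concentration * pi, rate = 1)
  if (sum(g) <= 0) g <- pi  # astronomically unlikely; keep the draw proper
  g <- pmax(g / sum(g), 1e-6)
  setNames(g / sum(g), AA_ALPHABET)
}

# Dirichlet perturbation of one profile, one independent draw per column.
perturb_profile_cols <- function(pi, concentration, ncols) {
  g <- matrix(rgamma(20L * ncols, shape = rep(concentration * pi, ncols),
                     rate = 1), 20, ncols)
  tot <- colSums(g)
  tot[tot <= 0] <- 1
  g <- pmax(sweep(g, 2, tot, "/"), 1e-6)
  sweep(g, 2, colSums(g), "/")
}

# Inverse-ECDF (type 1) quantile: smallest order statistic whose ECDF >= p.
quantile_type1 <- function(x, p) {
  x <- sort(x)
  x[max(1L, ceiling(length(x) * p))]
}

#' Bootstrap PP thresholds for one site
#'
#' Simulates `n_sims` null columns (the ancestral profile with Dirichlet
#' noise, no scenario) and `n_sims` convergent columns (ancestral/convergent
#' profiles with changes forced on the scenario's transition branches) on the
#' site's gap-pruned tree, scores every column with the same scenario and
#' profile set, and returns the `confidence` quantile of the null PPs
#' (upper threshold) and the `1 - confidence` quantile of the convergent PPs
#' (lower threshold).
#'
#' @param tree The site's (gap-pruned) `phylo` tree.
#' @param scenario The site's maximum-PP `pcoc_scenario`.
#' @param fit One row of a [scan_alignment()] report (needs `site_index`,
#'   `best_profile_anc_id`, `best_profile_conv_id`).
#' @param profiles The `profile_set` used in the scan.
#' @param config A [pcoc_config()]; `n_sims`, `confidence`,
#'   `noise_concentration`, `blen_noise_sd` and `seed` are used.  The RNG
#'   substream is derived from `config$seed` and the site index.
#' @return A list of class `pcoc_thresholds`: `site_index`,
#'   `threshold_upper`, `threshold_lower`, `n_sims`, `null_pps`, `conv_pps`.
#' @export
calibrate_site <- function(tree, scenario, fit, profiles,
                           config = pcoc_config()) {
  if (is.null(scenario)) stop("scenario is required", call. = FALSE)
  ct <- compile_tree(tree)
  cls <- scenario_edge_class(ct, scenario, min_transitions = 0L)
  pa <- profiles$freq[fit$best_profile_anc_id, ]
  pc <- profiles$freq[fit$best_profile_conv_id, ]
  n <- config$n_sims

  set.seed(site_seed(config$seed, fit$site_index))
  blen_sim <- NULL
  if (config$blen_noise_sd > 0) {
    blen_sim <- matrix(ct$blen, ct$n_all, 2L * n) *
      matrix(exp(rnorm(ct$n_all * 2L * n, -config$blen_noise_sd^2 / 2,
                       config$blen_noise_sd)), ct$n_all, 2L * n)
  }
  Pi_null <- perturb_profile_cols(pa, config$noise_concentration, n)
  null_states <- sim_columns_int(
    ct, NULL, Pi_null,
    blen = if (is.null(blen_sim)) NULL else blen_sim[, seq_len(n)])
  conv_states <- sim_columns_int(
    ct, cls, matrix(pa, 20, n), matrix(pc, 20, n),
    blen = if (is.null(blen_sim)) NULL else blen_sim[, n + seq_len(n)])

  null_fit <- fit_columns(ct, null_states, cls, profiles)
  conv_fit <- fit_columns(ct, conv_states, cls, profiles)
  structure(
    list(
      site_index = fit$site_index,
      threshold_upper = quantile_type1(null_fit$pp, config$confidence),
      threshold_lower = quantile_type1(conv_fit$pp, 1 - config$confidence),
      n_sims = n,
      null_pps = null_fit$pp,
      conv_pps = conv_fit$pp
    ),
    class = "pcoc_thresholds"
  )
}

#' Classify a site's PP against its bootstrap thresholds
#'
#' `adaptive` when the PP sits at or above the upper (null) threshold and
#' strictly above the lower one; `non_adaptive` when at or below the lower
#' (convergent) threshold and strictly below the upper one; otherwise
#' `unresolved`, which covers both the gap between the thresholds and their
#' overlap region.
#'
#' @param pp Observed posterior probability.
#' @param thresholds A `pcoc_thresholds` (or list with `threshold_upper`,
#'   `threshold_lower`).
#' @return `"adaptive"`, `"non_adaptive"`, or `"unresolved"`.
#' @export
classify_site <- function(pp, thresholds) {
  up <- thresholds$threshold_upper
  lo <- thresholds$threshold_lower
  if (pp >= up && pp > lo) return("adaptive")
  if (pp <= lo && pp < up) return("non_adaptive")
  "unresolved"
}

#' Bootstrap-calibrate a scan report
#'
#' Runs [calibrate_site()] for every site whose maximum PP reached the
#' threshold and fills in `threshold_upper`, `threshold_lower` and the final
#' `call`; `below_threshold` and `skipped_gaps` rows pass through untouched.
#'
#' @param report A `pcoc_report` from [scan_alignment()].
#' @param alignment,tree,scenarios,profiles The inputs of the scan.
#' @param config The [pcoc_config()] of the scan.
#' @return The report with thresholds and final calls filled in.
#' @export
pcoc_bootstrap <- function(report, alignment, tree, scenarios, profiles,
                           config = pcoc_config()) {
  taxa <- rownames(alignment)
  base_tree <- if (setequal(taxa, tree$tip.label)) tree else
    prune_tips(tree, taxa)
  scen_by_id <- setNames(unclass(scenarios), purrr::map_chr(scenarios, "id"))
  enc <- encode_alignment(alignment)
  tree_cache <- list()
  todo <- which(!report$call %in% c("skipped_gaps", "below_threshold"))
  for (s in todo) {
    row <- report[s, ]
    key <- paste(which(!is.na(enc[, row$site_index])), collapse = ",")
    if (is.null(tree_cache[[key]])) {
      present <- taxa[as.integer(strsplit(key, ",")[[1]])]
      tree_cache[[key]] <- if (setequal(present, base_tree$tip.label))
        base_tree else prune_tips(base_tree, present)
    }
    th <- calibrate_site(tree_cache[[key]], scen_by_id[[row$best_scenario_id]],
                         row, profiles, config)
    report$threshold_upper[s] <- th$threshold_upper
    report$threshold_lower[s] <- th$threshold_lower
    report$call[s] <- classify_site(row$max_pp, th)
  }
  report
}
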