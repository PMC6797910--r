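# Synthetic convergence studies: the fixture generator for tests and the
# scaled-down stand-in for a transcriptome-scale discovery experiment.

#' Balanced test tree
#'
#' A fully balanced rooted bifurcating tree with `n_tips` tips (a power of
#' two), uniform branch lengths, tips `t1..tn`, and deterministic internal
#' node ids.
#'
#' @param n_tips Number of tips (power of 2, >= 4).
#' @param blen Branch length for every edge (substitutions/site).
#' @return A `phylo` tree with node ids.
#' @export
sim_balanced_tree <- function(n_tips, blen = 0.15) {
  if (n_tips < 4 || bitwAnd(n_tips, n_tips - 1L) != 0)
    stop("n_tips must be a power of two >= 4", call. = FALSE)
  build <- function(lo, hi) {
    if (lo == hi) return(sprintf("t%d:%g", lo, blen))
    mid <- (lo + hi) %/% 2
    sprintf("(%s,%s):%g", build(lo, mid), build(mid + 1, hi), blen)
  }
  mid <- n_tips %/% 2
  parse_newick(sprintf("(%s,%s);", build(1, mid), build(mid + 1, n_tips)))
}

#' Simulate a continuous trait on a tree under Brownian motion
#'
#' @param tree A `phylo` tree with node ids.
#' @param sigma Brownian motion standard deviation per unit branch length.
#' @param root_value Trait value at the root.
#' @return A tibble (`node_id`, `value`, `is_tip`) covering every node.
#'   Uses the current RNG state.
#' @export
sim_bm_traits <- function(tree, sigma = 1, root_value = 0) {
  ct <- compile_tree(tree)
  vals <- numeric(ct$n_all)
  vals[ct$root] <- root_value
  for (v in rev(ct$postorder)) {
    if (v == ct$root) next
    vals[v] <- vals[ct$parent[v]] + rnorm(1, 0, sigma * sqrt(ct$blen[v]))
  }
  tibble::tibble(node_id = ct$ids, value = vals,
                 is_tip = seq_len(ct$n_all) <= ct$n_tip)
}

#' Generate a synthetic convergence study
#'
#' Emulates the discovery setting at desk scale: a balanced 64-tip tree on
#' which a fixed number of clades carry a shifted trait value (the
#' "convergent" habitat), tip traits with observation noise, and an
#' alignment mixing planted convergent sites (simulated under the trait-true
#' scenario with a contrasting profile pair) with null sites (single
#' profile).  The defaults are the package's standard study conditions:
#' 7 independent transitions, 100 convergent + 400 null sites, the compact
#' 10-profile set with a hydrophobic-ancestral / charged-convergent pair.
#'
#' @param n_tips Tips in the balanced tree (power of 2).
#' @param clade_size Tips per convergent clade.
#' @param n_transition_clades Number of convergent clades (independent
#'   transitions).
#' @param trait_low,trait_high Trait values of the ancestral and convergent
#'   habitats (default 0 and 10, e.g. degrees C).
#' @param trait_sd Observation noise SD on tip trait values.
#' @param blen Branch length of every edge.
#' @param n_convergent,n_null Planted and null site counts.
#' @param profiles A `profile_set` (default the bundled `"c10"` set).
#' @param pair_ids Length-2 character vector: ancestral and convergent
#'   profile ids for planted sites.
#' @param seed Integer seed.
#' @return List with `tree`, `traits` (tip tibble `taxon`,`value`),
#'   `true_scenario` (the planted `pcoc_scenario`), `alignment`, `truth`.
#' @export
sim_convergence_study <- function(n_tips = 64, clade_size = 4,
                                  n_transition_clades = 7,
                                  trait_low = 0, trait_high = 10,
                                  trait_sd = 0.5, blen = 0.15,
                                  n_convergent = 100, n_null = 400,
                                  profiles = load_profiles("c10"),
                                  pair_ids = c("hydrophobic", "charged"),
                                  seed = 1) {
  n_clades <- n_tips %/% clade_size
  if (n_transition_clades >= n_clades)
    stop("n_transition_clades must be below n_tips / clade_size",
         call. = FALSE)
  tree <- sim_balanced_tree(n_tips, blen)
  set.seed(site_seed(seed, 0, salt = 7))
  # spread the convergent clades across the tree
  conv_clades <- unique(round(seq(1, n_clades, length.out =
                                    n_transition_clades + 1)))[
                                      seq_len(n_transition_clades)]
  clade_of <- ceiling(seq_len(n_tips) / clade_size)
  is_conv_tip <- clade_of %in% conv_clades
  tip_num <- as.integer(sub("^t", "", tree$tip.label))
  traits <- tibble::tibble(
    taxon = tree$tip.label,
    value = ifelse(is_conv_tip[tip_num], trait_high, trait_low) +
      rnorm(n_tips, 0, trait_sd)
  )
  # trait-true binary states per node: a node is convergent iff all its tip
  # descendants are convergent
  ct <- compile_tree(tree)
  n_desc_conv <- n_desc <- numeric(ct$n_all)
  conv_named <- setNames(is_conv_tip, paste0("t", seq_len(n_tips)))
  for (v in ct$postorder) {
    if (v <= ct$n_tip) {
      n_desc[v] <- 1
      n_desc_conv[v] <- as.numeric(conv_named[[ct$ids[v]]])
    }
    if (v != ct$root) {
      p <- ct$parent[v]
      n_desc[p] <- n_desc[p] + n_desc[v]
      n_desc_conv[p] <- n_desc_conv[p] + n_desc_conv[v]
    }
  }
  node_state <- setNames(ifelse(n_desc_conv == n_desc, trait_high, trait_low),
                         ct$ids)
  true_scenario <- scenario_from_cutoff(tree, node_state,
                                        (trait_low + trait_high) / 2)
  sim <- simulate_dataset(tree, true_scenario, n_convergent, n_null,
                          matrix(pair_ids, 1, 2), profiles)
  list(tree = tree, traits = traits, true_scenario = true_scenario,
       alignment = sim$alignment, truth = sim$truth)
}

#' Run the full continuous-trait convergence pipeline
#'
#' Brownian-motion trait reconstruction, scenario enumeration, the
#' alignment-wide PCOC scan, and (optionally) the simulation bootstrap, in
#' one call.
#'
#' @param alignment Character matrix (taxa x sites).
#' @param tree A `phylo` tree with node ids.
#' @param traits Trait table (`taxon`, `value`) covering >= 4 tree tips.
#' @param profiles A `profile_set`.
#' @param config A [pcoc_config()].
#' @param bootstrap Run bootstrap calibration (default `TRUE`).
#' @return List with `values` (node trait estimates), `scenarios`, and
#'   `report` (a `pcoc_report`).
#' @export
run_pcoc <- function(alignment, tree, traits, profiles = load_profiles("c60"),
                     config = pcoc_config(), bootstrap = TRUE) {
  tree_tr <- prune_to_traits(tree, traits)
  values <- reconstruct_bm(tree_tr, traits)
  scenarios <- enumerate_scenarios(tree_tr, values, config)
  if (length(scenarios) == 0L)
    stop("no scenario passed the min_transitions filter; ",
         "nothing to scan", call. = FALSE)
  aln <- alignment[intersect(rownames(alignment), tree_tr$tip.label), ,
                   drop = FALSE]
  report <- scan_alignment(aln, tree_tr, scenarios, profiles, config)
  if (bootstrap)
    report <- pcoc_bootstrap(report, aln, tree_tr, scenarios, profiles, config)
  list(values = values, scenarios = scenarios, report = report)
}
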