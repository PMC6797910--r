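# The per-site substitution process is the profile-driven one-parameter
# process (the canonical CAT-Poisson choice): q_ij = beta * pi_j for i != j,
# with beta = 1 / (1 - sum(pi^2)) so that one unit of branch length equals
# one expected substitution per site at stationarity.  Transition
# probabilities have the closed form
#   P_ij(t) = exp(-beta t) * delta_ij + (1 - exp(-beta t)) * pi_j.

#' Rate model for a single amino-acid profile
#'
#' @param profile A 20-vector of residue frequencies (order
#'   `ACDEFGHIKLMNPQRSTVWY`), or a 1-row slice of a `profile_set`.
#' @return A `rate_model`: list with `pi` (frequencies, floored and
#'   renormalized) and `beta` (rate normalization, > 1).
#' @export
rate_model <- function(profile) {
  pi <- as.numeric(profile)
  if (length(pi) != 20L || any(!is.finite(pi)) || any(pi < 0) || sum(pi) <= 0)
    stop("profile must be 20 nonnegative finite frequencies", call. = FALSE)
  pi <- floor_profile(pi)
  structure(list(pi = setNames(pi, AA_ALPHABET), beta = 1 / (1 - sum(pi^2))),
            class = "rate_model")
}

#' Closed-form transition probability matrix
#'
#' @param model A [rate_model()] (or a raw 20-vector profile).
#' @param t Branch length (>= 0), expected substitutions per site.
#' @return A row-stochastic 20x20 matrix, reversible with respect to the
#'   profile.
#' @export
transition_matrix <- function(model, t) {
  if (!inherits(model, "rate_model")) model <- rate_model(model)
  if (!is.finite(t) || t < 0) stop("branch length t must be >= 0", call. = FALSE)
  w <- exp(-model$beta * t)
  P <- w * diag(20) + (1 - w) * matrix(model$pi, 20, 20, byrow = TRUE)
  dimnames(P) <- list(AA_ALPHABET, AA_ALPHABET)
  P
}

# Vectorized column simulation on a compiled tree.
#
# edge_class: 0/1/2 per node (NULL => all ancestral).
# Pi_a, Pi_c: 20 x ncols matrices of per-replicate profiles (Pi_c may be NULL
# when edge_class has no class >= 1).  blen optionally overrides ct$blen (a
# vector, or an n_all x ncols matrix for per-replicate branch lengths).
# Uses the current RNG state.  Returns an ntip x ncols integer matrix (1..20).
sim_columns_int <- function(ct, edge_class, Pi_a, Pi_c = NULL, blen = NULL) {
  ncols <- ncol(Pi_a)
  if (is.null(edge_class)) edge_class <- integer(ct$n_all)
  if (is.null(blen)) blen <- ct$blen
  blen_mat <- if (is.matrix(blen)) blen else NULL
  beta_a <- 1 / (1 - colSums(Pi_a^2))
  cum_a <- apply(Pi_a, 2, cumsum)
  if (!is.null(Pi_c)) {
    beta_c <- 1 / (1 - colSums(Pi_c^2))
    cum_c <- apply(Pi_c, 2, cumsum)
  }
  draw <- function(cum) {
    u <- runif(ncols)
    as.integer(colSums(cum < matrix(u, 20, ncols, byrow = TRUE)) + 1L)
  }
  state <- matrix(0L, ct$n_all, ncols)
  state[ct$root, ] <- draw(cum_a)
  for (v in rev(ct$postorder)) {
    if (v == ct$root) next
    ps <- state[ct$parent[v], ]
    cls <- edge_class[v]
    if (cls == 2L) {
      state[v, ] <- draw(cum_c)
    } else {
      if (cls == 1L) {
        beta <- beta_c; cum <- cum_c
      } else {
        beta <- beta_a; cum <- cum_a
      }
      tlen <- if (is.null(blen_mat)) rep(blen[v], ncols) else blen_mat[v, ]
      keep <- runif(ncols) < exp(-beta * tlen)
      new <- draw(cum)
      state[v, ] <- as.integer(ifelse(keep, ps, new))
    }
  }
  out <- state[seq_len(ct$n_tip), , drop = FALSE]
  rownames(out) <- ct$tip_labels
  out
}

#' Simulate one alignment column along a tree
#'
#' Evolves a single site under the profile process: the root state is drawn
#' from the ancestral profile, ancestral branches evolve under it, convergent
#' branches evolve under the convergent profile, and on transition branches
#' the child state is drawn directly from the convergent profile (the
#' substitution process conditioned on at least one event).
#'
#' @param tree A `phylo` tree with node ids.
#' @param scenario A `pcoc_scenario`, or `NULL` for non-convergent evolution.
#' @param profile_anc Ancestral profile (20-vector).
#' @param profile_conv Convergent profile; required when `scenario` is given.
#' @return Named character vector of residues, one per tip.  Uses the current
#'   RNG state; call `set.seed()` first for reproducibility.
#' @export
simulate_column <- function(tree, scenario = NULL, profile_anc,
                            profile_conv = NULL) {
  ct <- compile_tree(tree)
  pa <- rate_model(profile_anc)$pi
  edge_class <- NULL
  Pi_c <- NULL
  if (!is.null(scenario)) {
    if (is.null(profile_conv))
      stop("profile_conv is required when a scenario is given", call. = FALSE)
    unknown <- setdiff(scenario$convergent_branches, ct$ids)
    if (length(unknown))
      stop("scenario references unknown branch ids: ",
           paste(head(unknown, 5), collapse = ", "), call. = FALSE)
    edge_class <- scenario_edge_class(ct, scenario, min_transitions = 0L)
    Pi_c <- matrix(rate_model(profile_conv)$pi, 20, 1)
  }
  states <- sim_columns_int(ct, edge_class, matrix(pa, 20, 1), Pi_c)
  setNames(AA_ALPHABET[states[, 1]], rownames(states))
}

#' Simulate an alignment with planted convergent sites
#'
#' Generates `n_convergent` columns under a convergent scenario (ancestral /
#' convergent profile pair drawn per site from `profile_pairs`) and `n_null`
#' columns under a single ancestral profile, then shuffles nothing: convergent
#' sites come first.
#'
#' @param tree A `phylo` tree with node ids.
#' @param scenario A `pcoc_scenario` (may be `NULL` when `n_convergent = 0`).
#' @param n_convergent,n_null Nonnegative site counts.
#' @param profile_pairs Two-column matrix or data frame of profile ids
#'   (ancestral, convergent) to sample from.
#' @param profiles A `profile_set` containing those ids.
#' @return List with `alignment` (character matrix) and `truth` (tibble:
#'   `site_index`, `type` in `convergent`/`null`, `profile_anc`,
#'   `profile_conv`).  Uses the current RNG state.
#' @export
simulate_dataset <- function(tree, scenario, n_convergent, n_null,
                             profile_pairs, profiles) {
  stopifnot(n_convergent >= 0, n_null >= 0)
  pairs <- as.matrix(profile_pairs)
  if (ncol(pairs) != 2L) stop("profile_pairs must have two columns", call. = FALSE)
  bad <- setdiff(as.vector(pairs), profiles$ids)
  if (length(bad))
    stop("profile ids not in profile set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  ct <- compile_tree(tree)
  n_total <- n_convergent + n_null
  aln <- matrix("-", ct$n_tip, n_total, dimnames = list(ct$tip_labels, NULL))
  truth <- tibble::tibble(
    site_index = seq_len(n_total),
    type = rep(c("convergent", "null"), c(n_convergent, n_null)),
    profile_anc = NA_character_,
    profile_conv = NA_character_
  )
  if (n_convergent > 0) {
    if (is.null(scenario))
      stop("scenario required to simulate convergent sites", call. = FALSE)
    edge_class <- scenario_edge_class(ct, scenario, min_transitions = 0L)
    pick <- pairs[sample.int(nrow(pairs), n_convergent, replace = TRUE), ,
                  drop = FALSE]
    Pi_a <- t(profiles$freq[pick[, 1], , drop = FALSE])
    Pi_c <- t(profiles$freq[pick[, 2], , drop = FALSE])
    states <- sim_columns_int(ct, edge_class, Pi_a, Pi_c)
    aln[, seq_len(n_convergent)] <- AA_ALPHABET[states]
    truth$profile_anc[seq_len(n_convergent)] <- pick[, 1]
    truth$profile_conv[seq_len(n_convergent)] <- pick[, 2]
  }
  if (n_null > 0) {
    pick <- pairs[sample.int(nrow(pairs), n_null, replace = TRUE), 1]
    Pi_a <- t(profiles$freq[pick, , drop = FALSE])
    states <- sim_columns_int(ct, NULL, Pi_a)
    aln[, n_convergent + seq_len(n_null)] <- AA_ALPHABET[states]
    truth$profile_anc[n_convergent + seq_len(n_null)] <- pick
  }
  list(alignment = aln, truth = truth)
}
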