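# Independent oracles used across the suite.  Each reimplements the checked
# quantity from first principles (exhaustive enumeration, closed forms,
# direct matrix algebra), sharing none of the package's fast paths.

# Log-likelihood of one column by exhaustive summation over all ancestral
# state assignments, with per-edge transition matrices built from
# transition_matrix() (itself checked against the matrix exponential).
enum_site_loglik <- function(tree, column, scenario, pa, pc, model) {
  ct <- traitpcoc:::compile_tree(tree)
  cls <- if (is.null(scenario)) integer(ct$n_all) else
    traitpcoc:::scenario_edge_class(ct, scenario, 0L)
  edgeP <- vector("list", ct$n_all)
  for (v in seq_len(ct$n_all)) {
    if (v == ct$root) next
    use_conv <- switch(model, null = FALSE, PC = cls[v] >= 1L, OC = FALSE,
                       PCOC = cls[v] >= 1L)
    forced <- switch(model, null = FALSE, PC = FALSE, OC = cls[v] == 2L,
                     PCOC = cls[v] == 2L)
    if (forced) {
      pi_f <- if (model == "PCOC") pc else pa
      edgeP[[v]] <- matrix(pi_f, 20, 20, byrow = TRUE)
    } else {
      edgeP[[v]] <- transition_matrix(if (use_conv) pc else pa, ct$blen[v])
    }
  }
  internals <- setdiff(seq_len(ct$n_all), seq_len(ct$n_tip))
  tips_states <- match(column[ct$ids[seq_len(ct$n_tip)]], AA_ALPHABET)
  grid <- as.matrix(expand.grid(rep(list(1:20), length(internals))))
  state <- matrix(0L, nrow(grid), ct$n_all)
  state[, seq_len(ct$n_tip)] <- matrix(tips_states, nrow(grid), ct$n_tip,
                                       byrow = TRUE)
  state[, internals] <- grid
  pa_norm <- traitpcoc::rate_model(pa)$pi
  prob <- pa_norm[state[, ct$root]]
  for (v in seq_len(ct$n_all)) {
    if (v == ct$root) next
    prob <- prob * edgeP[[v]][cbind(state[, ct$parent[v]], state[, v])]
  }
  log(sum(prob))
}

# GLS/ML marginal ancestral estimates from the full Brownian-motion
# covariance matrix: mu_hat = (1'C^-1 x)/(1'C^-1 1), then the conditional
# expectation mu_hat + c_n' C^-1 (x - mu_hat).
gls_ancestral <- function(tree, tipvals) {
  ct <- traitpcoc:::compile_tree(tree)
  depth <- numeric(ct$n_all)
  anc <- vector("list", ct$n_all)
  for (v in rev(ct$postorder)) {
    if (v == ct$root) {
      anc[[v]] <- v
    } else {
      depth[v] <- depth[ct$parent[v]] + ct$blen[v]
      anc[[v]] <- c(anc[[ct$parent[v]]], v)
    }
  }
  shared <- function(u, v) {
    common <- intersect(anc[[u]], anc[[v]])
    max(depth[common])
  }
  n_tip <- ct$n_tip
  C <- outer(seq_len(n_tip), seq_len(n_tip), Vectorize(shared))
  diag(C) <- depth[seq_len(n_tip)]
  x <- tipvals[ct$ids[seq_len(n_tip)]]
  Cinv <- solve(C)
  one <- rep(1, n_tip)
  mu <- as.numeric((one %*% Cinv %*% x) / (one %*% Cinv %*% one))
  est <- vapply(seq_len(ct$n_all), function(nn) {
    if (nn <= n_tip) return(unname(x[nn]))
    cn <- vapply(seq_len(n_tip), function(t) shared(nn, t), numeric(1))
    mu + as.numeric(cn %*% Cinv %*% (x - mu))
  }, numeric(1))
  setNames(est, ct$ids)
}

# Direct two-sided hypergeometric p-value for a 2x2 table.
hyper_2x2_pvalue <- function(tab) {
  rs <- rowSums(tab)
  cs <- colSums(tab)
  k_all <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
  probs <- dhyper(k_all, rs[1], rs[2], cs[1])
  obs <- dhyper(tab[1, 1], rs[1], rs[2], cs[1])
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# Brute-force cutoff sweep for scenario enumeration (direct rule application
# over ape's edge matrix).
sweep_scenarios_oracle <- function(tree, vals, bin_width, min_transitions) {
  ids <- traitpcoc::tree_ids(tree)
  v <- vals[ids]
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  lo <- min(v)
  k_max <- ceiling((max(v) - lo) / bin_width) - 1
  out <- list()
  seen <- character(0)
  if (k_max < 1) return(out)
  for (k in seq_len(k_max)) {
    cutoff <- lo + k * bin_width
    conv <- v >= cutoff
    if (conv[root]) conv <- !conv
    nodes <- setdiff(seq_along(ids), root)
    conv_nodes <- nodes[conv[nodes]]
    trans <- conv_nodes[!conv[parent[conv_nodes]]]
    if (length(trans) < min_transitions) next
    key <- paste(sort(ids[conv_nodes]), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- list(cutoff = cutoff,
                                    convergent = sort(ids[conv_nodes]),
                                    transitions = sort(ids[trans]))
  }
  out
}

# Random rooted tree with ids and strictly positive branch lengths.
random_test_tree <- function(n_tips, min_bl = 0.05, max_bl = 1) {
  tr <- ape::rtree(n_tips, br = function(n) runif(n, min_bl, max_bl))
  traitpcoc:::validate_tree(tr)
}

# Random scenario on a tree: mark the subtrees below a few random internal
# edges as convergent.
random_scenario <- function(tree, n_seeds = 2) {
  ct <- traitpcoc:::compile_tree(tree)
  vals <- setNames(rep(0, ct$n_all), ct$ids)
  non_root <- setdiff(seq_len(ct$n_all), ct$root)
  picks <- sample(non_root, min(n_seeds, length(non_root)))
  # a node is convergent iff some picked node lies on its root path
  for (v in ct$postorder) {
    if (v %in% picks) vals[ct$ids[v]] <- 10
  }
  for (v in rev(ct$postorder)) {
    if (v != ct$root && vals[ct$ids[ct$parent[v]]] == 10)
      vals[ct$ids[v]] <- 10
  }
  if (max(vals) == 0) vals[ct$ids[non_root[1]]] <- 10
  scenario_from_cutoff(tree, vals, 5)
}

# Trait values realizing "these tips are convergent": hi on every node whose
# tip descendants are all in conv_tips, lo elsewhere.
clade_closure_values <- function(tree, conv_tips, hi = 10, lo = 0) {
  ct <- traitpcoc:::compile_tree(tree)
  n_conv <- n_all <- numeric(ct$n_all)
  for (v in ct$postorder) {
    if (v <= ct$n_tip) {
      n_all[v] <- 1
      n_conv[v] <- as.numeric(ct$ids[v] %in% conv_tips)
    }
    if (v != ct$root) {
      p <- ct$parent[v]
      n_all[p] <- n_all[p] + n_all[v]
      n_conv[p] <- n_conv[p] + n_conv[v]
    }
  }
  vals <- ifelse(n_conv == n_all, hi, lo)
  vals[ct$root] <- lo
  setNames(vals, ct$ids)
}

c10 <- traitpcoc::load_profiles("c10")
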