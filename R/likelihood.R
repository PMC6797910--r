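# Site-wise likelihood machinery: Felsenstein pruning with branch-specific
# closed-form matrices, the four site models (null, PC, OC, PCOC), posterior
# probabilities, and the alignment-wide scan maximized over scenarios.

# Pure-R mirror of prune_loglik_cpp, kept as an independent slow path for
# cross-checking the compiled engine.
prune_loglik_r <- function(postorder, parent, blen, edge_class, tipstates,
                           profiles, beta, pairs, ntip) {
  n_all <- length(parent)
  ncols <- ncol(tipstates)
  P <- nrow(pairs)
  out <- matrix(NA_real_, ncols, P)
  for (cc in seq_len(ncols)) {
    for (p in seq_len(P)) {
      pa <- pairs[p, 1]
      pc <- pairs[p, 2]
      L <- matrix(1, 20, n_all)
      L[, seq_len(ntip)] <- 0
      L[cbind(tipstates[, cc], seq_len(ntip))] <- 1
      logscale <- 0
      for (v in postorder) {
        mx <- max(L[, v])
        if (mx <= 0) {
          out[cc, p] <- -Inf
          break
        }
        L[, v] <- L[, v] / mx
        logscale <- logscale + log(mx)
        par <- parent[v]
        if (par == 0L) {
          out[cc, p] <- log(sum(profiles[, pa] * L[, v])) + logscale
          break
        }
        cls <- edge_class[v]
        prof <- if (cls >= 1L) pc else pa
        pi <- profiles[, prof]
        dot <- sum(pi * L[, v])
        if (cls == 2L) {
          L[, par] <- L[, par] * dot
        } else {
          w <- exp(-beta[prof] * blen[v])
          L[, par] <- L[, par] * (w * L[, v] + (1 - w) * dot)
        }
      }
    }
  }
  out
}

engine_call <- function(ct, edge_class, tipstates, prof_t, beta, pairs,
                        use_cpp = TRUE) {
  storage.mode(tipstates) <- "integer"
  storage.mode(pairs) <- "integer"
  if (use_cpp) {
    prune_loglik_cpp(as.integer(ct$postorder), as.integer(ct$parent),
                     as.numeric(ct$blen), as.integer(edge_class),
                     tipstates, prof_t, as.numeric(beta), pairs,
                     as.integer(ct$n_tip))
  } else {
    prune_loglik_r(ct$postorder, ct$parent, ct$blen, edge_class, tipstates,
                   prof_t, beta, pairs, ct$n_tip)
  }
}

encode_column <- function(column, tip_labels) {
  if (is.null(names(column)))
    stop("column must be named by taxon", call. = FALSE)
  missing <- setdiff(tip_labels, names(column))
  if (length(missing))
    stop("column lacks states for tips: ", paste(missing, collapse = ", "),
         call. = FALSE)
  st <- match(column[tip_labels], AA_ALPHABET)
  if (any(is.na(st)))
    stop("column contains gaps or non-residue characters at: ",
         paste(tip_labels[is.na(st)], collapse = ", "),
         "; gap-prune the tree first", call. = FALSE)
  matrix(st, ncol = 1)
}

#' Gap-prune a tree for one alignment column
#'
#' Removes taxa whose state is a gap and suppresses the resulting unary
#' nodes (branch lengths summed).
#'
#' @param tree A `phylo` tree with node ids.
#' @param column Named character vector of residues/gaps, indexed by tip.
#' @return List with `tree` (pruned `phylo`, or `NULL` when fewer than two
#'   taxa remain) and `column` (the ungapped states).
#' @export
prune_gaps <- function(tree, column) {
  keep <- names(column)[column %in% AA_ALPHABET]
  keep <- intersect(tree$tip.label, keep)
  if (length(keep) == length(tree$tip.label))
    return(list(tree = tree, column = column[tree$tip.label]))
  if (length(keep) < 2L) return(list(tree = NULL, column = column[keep]))
  list(tree = prune_tips(tree, keep), column = column[keep])
}

check_distinct_profiles <- function(pa, pc) {
  if (max(abs(pa - pc)) < 1e-12)
    stop("ancestral and convergent profiles must differ under PC/PCOC",
         call. = FALSE)
}

#' Log-likelihood of one column under one site model
#'
#' Felsenstein pruning with branch-specific matrices of the closed-form
#' profile process.  Models: `null` (ancestral profile everywhere), `PC`
#' (convergent branches switch to the convergent profile, no change forced),
#' `OC` (ancestral profile everywhere, but transition branches are
#' conditioned on at least one substitution event), and `PCOC` (profile
#' change plus the conditioned transition branches).  The root prior is the
#' ancestral profile.
#'
#' @param tree A `phylo` tree with node ids; must match the column's taxa
#'   (gap-prune first, see [prune_gaps()]).
#' @param column Named character vector of residues (no gaps).
#' @param scenario A `pcoc_scenario` (required for PC/OC/PCOC).
#' @param profile_anc Ancestral profile (20-vector).
#' @param profile_conv Convergent profile (required for PC/PCOC).
#' @param model One of `"null"`, `"PC"`, `"OC"`, `"PCOC"`.
#' @return The log-likelihood (may be `-Inf`).
#' @export
site_likelihood <- function(tree, column, scenario = NULL, profile_anc,
                            profile_conv = NULL,
                            model = c("null", "PC", "OC", "PCOC")) {
  model <- match.arg(model)
  ct <- compile_tree(tree)
  tipstates <- encode_column(column, ct$tip_labels)
  pa <- rate_model(profile_anc)$pi
  pc <- if (!is.null(profile_conv)) rate_model(profile_conv)$pi else pa
  if (model %in% c("PC", "PCOC")) {
    if (is.null(profile_conv))
      stop("profile_conv required for model ", model, call. = FALSE)
    check_distinct_profiles(pa, pc)
  }
  cls <- integer(ct$n_all)
  if (model != "null") {
    if (is.null(scenario))
      stop("scenario required for model ", model, call. = FALSE)
    unknown <- setdiff(scenario$convergent_branches, ct$ids)
    if (length(unknown))
      stop("scenario references branch ids absent from the tree: ",
           paste(head(unknown, 5), collapse = ", "), call. = FALSE)
    cls <- scenario_edge_class(ct, scenario, min_transitions = 0L)
  }
  prof_t <- cbind(pa, pc)
  beta <- 1 / (1 - colSums(prof_t^2))
  spec <- switch(model,
    null = list(cls = integer(ct$n_all), pairs = cbind(1L, 1L)),
    PC   = list(cls = ifelse(cls == 2L, 1L, cls), pairs = cbind(1L, 2L)),
    OC   = list(cls = ifelse(cls == 1L, 0L, cls), pairs = cbind(1L, 1L)),
    PCOC = list(cls = cls, pairs = cbind(1L, 2L))
  )
  engine_call(ct, spec$cls, tipstates, prof_t, beta, spec$pairs)[1, 1]
}

ordered_pairs <- function(K) {
  g <- expand.grid(anc = seq_len(K), conv = seq_len(K))
  as.matrix(g[g$anc != g$conv, , drop = FALSE])
}

pp_from_loglik <- function(ll1, ll0) {
  ifelse(is.infinite(ll0) & is.infinite(ll1) & ll0 < 0 & ll1 < 0,
         0.5, stats::plogis(ll1 - ll0))
}

# Batch fit of many columns on one compiled tree under one scenario:
# null model maximized over single profiles, PCOC over ordered pairs.
# Returns a tibble (one row per column).
fit_columns <- function(ct, tipstates, edge_class, profiles,
                        include_pc_oc = FALSE, use_cpp = TRUE) {
  prof_t <- profile_matrix_t(profiles)
  beta <- profiles$beta
  K <- length(beta)
  null_ll <- engine_call(ct, integer(ct$n_all), tipstates, prof_t, beta,
                         cbind(seq_len(K), seq_len(K)), use_cpp)
  pairs <- ordered_pairs(K)
  pcoc_ll <- engine_call(ct, edge_class, tipstates, prof_t, beta, pairs,
                         use_cpp)
  best_null <- max.col(null_ll, ties.method = "first")
  best_pair <- max.col(pcoc_ll, ties.method = "first")
  ll0 <- null_ll[cbind(seq_len(nrow(null_ll)), best_null)]
  ll1 <- pcoc_ll[cbind(seq_len(nrow(pcoc_ll)), best_pair)]
  out <- tibble::tibble(
    best_profile_anc_id = profiles$ids[pairs[best_pair, 1]],
    best_profile_conv_id = profiles$ids[pairs[best_pair, 2]],
    loglik_null = ll0,
    loglik_pcoc = ll1,
    pp = pp_from_loglik(ll1, ll0)
  )
  if (include_pc_oc) {
    n <- nrow(out)
    ll_pc <- ll_oc <- numeric(n)
    cls_pc <- ifelse(edge_class == 2L, 1L, edge_class)
    cls_oc <- ifelse(edge_class == 1L, 0L, edge_class)
    for (i in seq_len(n)) {
      pr <- pairs[best_pair[i], , drop = FALSE]
      ts <- tipstates[, i, drop = FALSE]
      ll_pc[i] <- engine_call(ct, cls_pc, ts, prof_t, beta, pr, use_cpp)[1, 1]
      ll_oc[i] <- engine_call(ct, cls_oc, ts, prof_t, beta,
                              cbind(pr[1], pr[1]), use_cpp)[1, 1]
    }
    out$loglik_pc <- ll_pc
    out$loglik_oc <- ll_oc
  }
  out
}

#' Posterior probability of convergent evolution at one site
#'
#' Fits the null model (maximized over single profiles of the set) and the
#' PCOC model (maximized over ordered profile pairs with distinct ancestral
#' and convergent profiles) to one column under one scenario, and converts
#' the likelihood ratio into a posterior probability under equal (0.5/0.5)
#' model priors.
#'
#' @param tree A `phylo` tree matching the column's taxa (gap-pruned).
#' @param column Named character vector of residues (no gaps).
#' @param scenario A `pcoc_scenario`.
#' @param profiles A `profile_set`.
#' @return A one-row tibble: `scenario_id`, `best_profile_anc_id`,
#'   `best_profile_conv_id`, `loglik_null`, `loglik_pcoc`, `loglik_pc`,
#'   `loglik_oc`, `pp`.
#' @export
site_pp <- function(tree, column, scenario, profiles) {
  ct <- compile_tree(tree)
  tipstates <- encode_column(column, ct$tip_labels)
  cls <- scenario_edge_class(ct, scenario, min_transitions = 0L)
  fit <- fit_columns(ct, tipstates, cls, profiles, include_pc_oc = TRUE)
  dplyr::bind_cols(tibble::tibble(scenario_id = scenario$id), fit)
}

#' Scan an alignment for convergent profile shifts
#'
#' For each column: taxa with gaps are pruned from the tree; every scenario
#' that still carries at least `min_transitions` transition events on the
#' pruned tree is evaluated with [site_pp()]'s model comparison; the maximum
#' PCOC posterior probability across scenarios is recorded together with the
#' maximizing scenario.  Columns with fewer than four ungapped taxa or no
#' viable scenario are marked `skipped_gaps`; columns whose maximum PP falls
#' below `pp_threshold` are marked `below_threshold` and are excluded from
#' bootstrap calibration.  Remaining columns are provisionally `unresolved`
#' until [pcoc_bootstrap()] assigns their final call.
#'
#' @param alignment Character matrix (taxa x sites); taxa must be tree tips.
#' @param tree A `phylo` tree with node ids.
#' @param scenarios A `pcoc_scenario_set` (non-empty).
#' @param profiles A `profile_set`.
#' @param config A [pcoc_config()].
#' @return A `pcoc_report`: tibble with one row per column — `site_index`,
#'   `max_pp`, `best_cutoff`, `best_scenario_id`, `n_transitions`,
#'   `threshold_upper`, `threshold_lower`, `call`, plus the fitted profile
#'   ids and log-likelihoods used downstream.
#' @export
scan_alignment <- function(alignment, tree, scenarios, profiles,
                           config = pcoc_config()) {
  if (length(scenarios) == 0L)
    stop("no scenarios supplied", call. = FALSE)
  taxa <- rownames(alignment)
  extra <- setdiff(taxa, tree$tip.label)
  if (length(extra))
    stop("alignment taxa absent from tree: ", paste(extra, collapse = ", "),
         call. = FALSE)
  base_tree <- if (setequal(taxa, tree$tip.label)) tree else
    prune_tips(tree, taxa)
  enc <- encode_alignment(alignment)
  n_sites <- ncol(alignment)

  empty_row <- function(site, call) tibble::tibble(
    site_index = site, max_pp = NA_real_, best_cutoff = NA_real_,
    best_scenario_id = NA_character_, n_transitions = NA_integer_,
    threshold_upper = NA_real_, threshold_lower = NA_real_, call = call,
    best_profile_anc_id = NA_character_, best_profile_conv_id = NA_character_,
    loglik_null = NA_real_, loglik_pcoc = NA_real_
  )

  patterns <- apply(!is.na(enc), 2, function(z) paste(which(z), collapse = ","))
  rows <- vector("list", n_sites)
  for (key in unique(patterns)) {
    sites <- which(patterns == key)
    present <- as.integer(strsplit(key, ",")[[1]])
    if (length(present) < 4L) {
      for (s in sites) rows[[s]] <- empty_row(s, "skipped_gaps")
      next
    }
    ptree <- prune_tips(base_tree, taxa[present])
    ct <- compile_tree(ptree)
    viable <- list()
    for (sc in scenarios) {
      cls <- scenario_edge_class(ct, sc, config$min_transitions)
      if (!is.null(cls))
        viable[[length(viable) + 1L]] <- list(scenario = sc, cls = cls,
                                              n_trans = sum(cls == 2L))
    }
    if (!length(viable)) {
      for (s in sites) rows[[s]] <- empty_row(s, "skipped_gaps")
      next
    }
    tipstates <- enc[match(ct$tip_labels, taxa), sites, drop = FALSE]
    fits <- lapply(viable, function(vb)
      fit_columns(ct, tipstates, vb$cls, profiles))
    # argmax over scenarios on the log-likelihood difference, which PP is
    # monotone in: PP saturates at 1 in double precision and would tie
    ll_mat <- vapply(fits, function(f) f$loglik_pcoc - f$loglik_null,
                     numeric(length(sites)))
    ll_mat <- matrix(ll_mat, nrow = length(sites))
    ll_mat[is.nan(ll_mat)] <- -Inf
    best_s <- max.col(ll_mat, ties.method = "first")
    for (j in seq_along(sites)) {
      s <- sites[j]
      vb <- viable[[best_s[j]]]
      f <- fits[[best_s[j]]][j, ]
      call <- if (f$pp < config$pp_threshold) "below_threshold" else "unresolved"
      rows[[s]] <- tibble::tibble(
        site_index = s, max_pp = f$pp, best_cutoff = vb$scenario$cutoff,
        best_scenario_id = vb$scenario$id, n_transitions = vb$n_trans,
        threshold_upper = NA_real_, threshold_lower = NA_real_, call = call,
        best_profile_anc_id = f$best_profile_anc_id,
        best_profile_conv_id = f$best_profile_conv_id,
        loglik_null = f$loglik_null, loglik_pcoc = f$loglik_pcoc
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pcoc_report", class(out))
  out
}
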