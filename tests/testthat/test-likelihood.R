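test_that("degenerate likelihoods match closed expectations", {
  pa <- rep(0.05, 20)
  # no time to change: conflicting tips have probability zero
  tr0 <- parse_newick("(A:0,B:0);")
  expect_identical(site_likelihood(tr0, c(A = "A", B = "C"), NULL, pa,
                                   model = "null"), -Inf)
  # independence at stationarity: probability (1/20)^2
  tr1 <- parse_newick("(A:1e6,B:1e6);")
  ll <- site_likelihood(tr1, c(A = "A", B = "C"), NULL, pa, model = "null")
  expect_equal(exp(ll), 1 / 400, tolerance = 1e-6)
})

test_that("pruning equals exhaustive enumeration for every model", {
  set.seed(21)
  for (i in 1:6) {
    tr <- random_test_tree(5)
    sc <- random_scenario(tr)
    col <- setNames(sample(AA_ALPHABET, 5, TRUE), tr$tip.label)
    pa <- c10$freq[sample(10, 1), ]
    pc <- c10$freq[sample(10, 1), ]
    while (identical(pc, pa)) pc <- c10$freq[sample(10, 1), ]
    for (m in c("null", "PC", "OC", "PCOC")) {
      got <- site_likelihood(tr, col, sc, pa, pc, model = m)
      want <- enum_site_loglik(tr, col, sc, pa, pc, m)
      expect_lt(abs(got - want), 1e-9)
    }
  }
})

test_that("site likelihoods are proper distributions over columns", {
  set.seed(22)
  tr <- random_test_tree(3)
  sc <- random_scenario(tr)
  pa <- c10$freq["hydrophobic", ]
  pc <- c10$freq["charged", ]
  cols <- as.matrix(expand.grid(1:20, 1:20, 1:20))
  ct <- traitpcoc:::compile_tree(tr)
  prof_t <- cbind(pa, pc)
  beta <- 1 / (1 - colSums(prof_t^2))
  cls <- traitpcoc:::scenario_edge_class(ct, sc, 0L)
  specs <- list(null = list(cls = integer(ct$n_all), pairs = cbind(1L, 1L)),
                PC = list(cls = ifelse(cls == 2L, 1L, cls),
                          pairs = cbind(1L, 2L)),
                OC = list(cls = ifelse(cls == 1L, 0L, cls),
                          pairs = cbind(1L, 1L)),
                PCOC = list(cls = cls, pairs = cbind(1L, 2L)))
  tipstates <- t(cols)
  rownames(tipstates) <- NULL
  for (m in names(specs)) {
    ll <- traitpcoc:::engine_call(ct, specs[[m]]$cls, tipstates, prof_t, beta,
                                  specs[[m]]$pairs)
    expect_equal(sum(exp(ll[, 1])), 1, tolerance = 1e-9)
  }
})

test_that("compiled and reference engines agree", {
  set.seed(23)
  for (i in 1:3) {
    tr <- random_test_tree(sample(4:10, 1))
    ct <- traitpcoc:::compile_tree(tr)
    sc <- random_scenario(tr)
    cls <- traitpcoc:::scenario_edge_class(ct, sc, 0L)
    tipstates <- matrix(sample.int(20, ct$n_tip * 6, TRUE), ct$n_tip, 6)
    pairs <- traitpcoc:::ordered_pairs(10)
    a <- traitpcoc:::engine_call(ct, cls, tipstates, t(c10$freq), c10$beta,
                                 pairs, use_cpp = TRUE)
    b <- traitpcoc:::engine_call(ct, cls, tipstates, t(c10$freq), c10$beta,
                                 pairs, use_cpp = FALSE)
    expect_lt(max(abs(a - b)), 1e-10)
  }
})

test_that("posterior probabilities follow Bayes with equal priors", {
  expect_equal(traitpcoc:::pp_from_loglik(0, 0), 0.5)
  expect_equal(traitpcoc:::pp_from_loglik(log(3), 0), 0.75)
  expect_equal(traitpcoc:::pp_from_loglik(-Inf, -Inf), 0.5)
  expect_equal(traitpcoc:::pp_from_loglik(-Inf, 0), 0)
  # strictly increasing in the log-likelihood difference
  d <- seq(-5, 5, length.out = 41)
  pp <- traitpcoc:::pp_from_loglik(d, 0)
  expect_true(all(diff(pp) > 0))
})

test_that("a clean convergent column earns a near-certain PP", {
  tr <- sim_balanced_tree(8, 0.3)
  vals <- clade_closure_values(tr, c("t5", "t6", "t7", "t8"))
  sc <- scenario_from_cutoff(tr, vals, 5)
  col <- setNames(c(rep("D", 4), rep("K", 4)), paste0("t", 1:8))
  # sharply contrasting set: near-pure D, near-pure K, and a D/K mixture
  tsv <- tempfile(fileext = ".tsv")
  rows <- rbind(
    asp = ifelse(AA_ALPHABET == "D", 0.98, 0.02 / 19),
    lys = ifelse(AA_ALPHABET == "K", 0.98, 0.02 / 19),
    mix = ifelse(AA_ALPHABET %in% c("D", "K"), 0.40, 0.20 / 18))
  writeLines(c(paste(c("id", AA_ALPHABET), collapse = "\t"),
               vapply(rownames(rows), function(r)
                 paste(c(r, format(rows[r, ], digits = 10)), collapse = "\t"),
                 character(1))), tsv)
  sharp <- load_profiles(tsv)
  fit <- site_pp(tr, col, sc, sharp)
  expect_gt(fit$pp, 0.99)
  expect_equal(fit$pp,
               traitpcoc:::pp_from_loglik(fit$loglik_pcoc, fit$loglik_null))
})

test_that("gap pruning preserves paths and flags degenerate columns", {
  tr <- parse_newick("((A:1,B:2):0.5,((C:1,D:1):0.25,E:2):1);")
  col <- setNames(c("A", "C", "-", "D", "E"), c("A", "B", "C", "D", "E"))
  pg <- prune_gaps(tr, col)
  expect_setequal(pg$tree$tip.label, c("A", "B", "D", "E"))
  d_full <- ape::cophenetic.phylo(tr)
  d_p <- ape::cophenetic.phylo(pg$tree)
  expect_equal(d_p, d_full[rownames(d_p), colnames(d_p)], tolerance = 1e-12)
  # no gaps: identity
  col2 <- setNames(rep("A", 5), c("A", "B", "C", "D", "E"))
  expect_identical(prune_gaps(tr, col2)$tree, tr)
  # all gapped
  col3 <- setNames(rep("-", 5), c("A", "B", "C", "D", "E"))
  expect_null(prune_gaps(tr, col3)$tree)
})

test_that("the alignment scan fills the report contract", {
  set.seed(24)
  tr <- sim_balanced_tree(16, 0.25)
  vals <- clade_closure_values(tr, paste0("t", 9:16))
  sc <- scenario_from_cutoff(tr, vals, 5)
  cfg <- pcoc_config(min_transitions = sc$n_transitions)
  scen <- structure(list(sc), class = "pcoc_scenario_set")

  aln <- cbind(
    setNames(rep("A", 16), paste0("t", 1:16)),                  # constant
    c(rep("L", 8), rep("E", 8)),                                # convergent
    c(rep("-", 13), "A", "A", "A")                              # too gappy
  )
  rownames(aln) <- paste0("t", 1:16)
  rep <- scan_alignment(aln, tr, scen, c10, cfg)
  expect_equal(nrow(rep), 3L)
  # a constant column carries no profile-shift signal
  expect_lte(rep$max_pp[1], 0.5 + 1e-6)
  expect_equal(rep$call[1], "below_threshold")
  expect_gt(rep$max_pp[2], 0.9)
  expect_equal(rep$call[3], "skipped_gaps")
  expect_true(is.na(rep$max_pp[3]))
  expect_error(scan_alignment(aln, tr, structure(list(),
                                                 class = "pcoc_scenario_set"),
                              c10, cfg), "no scenarios")
})

test_that("taxon order does not affect PPs", {
  set.seed(25)
  study <- sim_convergence_study(n_tips = 16, clade_size = 4,
                                 n_transition_clades = 2, n_convergent = 3,
                                 n_null = 3, seed = 5)
  cfg <- pcoc_config(min_transitions = 2)
  res1 <- scan_alignment(study$alignment, study$tree,
                         structure(list(study$true_scenario),
                                   class = "pcoc_scenario_set"), c10, cfg)
  perm <- sample(nrow(study$alignment))
  res2 <- scan_alignment(study$alignment[perm, ], study$tree,
                         structure(list(study$true_scenario),
                                   class = "pcoc_scenario_set"), c10, cfg)
  expect_equal(res2$max_pp, res1$max_pp, tolerance = 1e-12)
})
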