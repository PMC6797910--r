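test_that("profile perturbation is a seeded Dirichlet around the profile", {
  pa <- c10$freq["hydrophobic", ]
  # concentration limit: essentially no noise
  set.seed(1)
  expect_lt(max(abs(perturb_profile(pa, 1e9) - pa)), 1e-3)
  # determinism
  set.seed(41)
  d1 <- perturb_profile(pa, 100)
  set.seed(41)
  d2 <- perturb_profile(pa, 100)
  expect_identical(d1, d2)
  expect_equal(sum(d1), 1, tolerance = 1e-12)
  # Dirichlet mean equals the profile
  set.seed(42)
  draws <- traitpcoc:::perturb_profile_cols(pa, 100, 10000)
  expect_lt(max(abs(rowMeans(draws) - pa)), 0.01)
  expect_error(perturb_profile(pa, 0), "concentration")
})

test_that("the inverse-ECDF quantile rule is deterministic and monotone", {
  x <- c(0.9, 0.1, 0.5, 0.3, 0.7)
  expect_equal(traitpcoc:::quantile_type1(x, 0.95), 0.9)
  expect_equal(traitpcoc:::quantile_type1(x, 0.05), 0.1)
  expect_equal(traitpcoc:::quantile_type1(x, 0.5), 0.5)
  # monotone in confidence
  set.seed(43)
  y <- runif(100)
  qs <- vapply(c(0.8, 0.9, 0.95, 0.99), function(p)
    traitpcoc:::quantile_type1(y, p), numeric(1))
  expect_true(all(diff(qs) >= 0))
})

test_that("classification covers the green, red, white and overlap regions", {
  th <- function(u, l) list(threshold_upper = u, threshold_lower = l)
  expect_equal(classify_site(0.99, th(0.9, 0.2)), "adaptive")
  expect_equal(classify_site(0.55, th(0.9, 0.2)), "unresolved")
  expect_equal(classify_site(0.05, th(0.9, 0.2)), "non_adaptive")
  # overlapping thresholds are always unresolved
  expect_equal(classify_site(0.6, th(0.5, 0.7)), "unresolved")
})

make_boot_fixture <- function(n_tips = 32, clades = 5, n_sims = 100,
                              seed = 1) {
  tr <- sim_balanced_tree(n_tips, 0.15)
  conv <- paste0("t", unlist(lapply(seq_len(clades) * 4 - 3, function(s)
    s:(s + 1))))
  vals <- clade_closure_values(tr, conv)
  sc <- scenario_from_cutoff(tr, vals, 5)
  cfg <- pcoc_config(n_sims = n_sims, min_transitions = sc$n_transitions,
                     seed = seed)
  fit <- tibble::tibble(site_index = 1L,
                        best_profile_anc_id = "hydrophobic",
                        best_profile_conv_id = "charged")
  list(tree = tr, scenario = sc, config = cfg, fit = fit)
}

test_that("bootstrap thresholds are bit-identical under a fixed seed", {
  fx <- make_boot_fixture(n_sims = 60)
  th1 <- calibrate_site(fx$tree, fx$scenario, fx$fit, c10, fx$config)
  th2 <- calibrate_site(fx$tree, fx$scenario, fx$fit, c10, fx$config)
  expect_identical(th1$null_pps, th2$null_pps)
  expect_identical(th1$conv_pps, th2$conv_pps)
  expect_identical(th1$threshold_upper, th2$threshold_upper)
  expect_identical(th1$threshold_lower, th2$threshold_lower)
})

test_that("contrasting profiles separate the null and convergent regimes", {
  fx <- make_boot_fixture(n_tips = 64, clades = 8, n_sims = 150)
  th <- calibrate_site(fx$tree, fx$scenario, fx$fit, c10, fx$config)
  expect_lt(th$threshold_upper, th$threshold_lower)
  expect_gt(mean(th$conv_pps), mean(th$null_pps) + 0.4)
})

test_that("a forced equal-profile calibration leaves sites unresolved", {
  fx <- make_boot_fixture(n_sims = 200)
  fit <- fx$fit
  fit$best_profile_conv_id <- "hydrophobic"  # diagnostic: pi_C = pi_A
  # disable Dirichlet noise so the two arms share one generator
  cfg <- pcoc_config(n_sims = fx$config$n_sims,
                     min_transitions = fx$config$min_transitions,
                     noise_concentration = 1e9, seed = 1)
  th <- calibrate_site(fx$tree, fx$scenario, fit, c10, cfg)
  # with no profile shift the regimes cannot separate: the lower threshold
  # sits below the upper one (the forced transition events still lift some
  # convergent-arm PPs, so the arms are not literally identical), and any
  # PP between the thresholds stays unresolved
  expect_gte(th$threshold_upper, th$threshold_lower)
  expect_lt(median(th$conv_pps), 0.5)
  expect_lt(median(th$null_pps), 0.5)
  mid <- (th$threshold_upper + th$threshold_lower) / 2
  expect_equal(classify_site(mid, th), "unresolved")
})

test_that("fresh simulations respect the advertised error rates", {
  fx <- make_boot_fixture(n_tips = 64, clades = 8, n_sims = 200)
  th <- calibrate_site(fx$tree, fx$scenario, fx$fit, c10, fx$config)
  ct <- traitpcoc:::compile_tree(fx$tree)
  cls <- traitpcoc:::scenario_edge_class(ct, fx$scenario, 0L)
  pa <- c10$freq["hydrophobic", ]
  pc <- c10$freq["charged", ]
  n <- 1000
  set.seed(77)
  null_states <- traitpcoc:::sim_columns_int(
    ct, NULL, traitpcoc:::perturb_profile_cols(pa, 100, n))
  conv_states <- traitpcoc:::sim_columns_int(
    ct, cls, matrix(pa, 20, n), matrix(pc, 20, n))
  null_pp <- traitpcoc:::fit_columns(ct, null_states, cls, c10)$pp
  conv_pp <- traitpcoc:::fit_columns(ct, conv_states, cls, c10)$pp
  calls_null <- vapply(null_pp, classify_site, character(1), thresholds = th)
  calls_conv <- vapply(conv_pp, classify_site, character(1), thresholds = th)
  alpha <- 0.05
  expect_lte(sum(calls_null == "adaptive"),
             alpha * n + 3 * sqrt(alpha * (1 - alpha) * n))
  expect_lte(sum(calls_conv == "non_adaptive"),
             alpha * n + 3 * sqrt(alpha * (1 - alpha) * n))
})

test_that("bootstrapping a report fills thresholds and final calls", {
  study <- sim_convergence_study(n_tips = 32, clade_size = 4,
                                 n_transition_clades = 5, n_convergent = 4,
                                 n_null = 6, seed = 9)
  cfg <- pcoc_config(n_sims = 60, seed = 9)
  scen <- structure(list(study$true_scenario), class = "pcoc_scenario_set")
  rep0 <- scan_alignment(study$alignment, study$tree, scen, c10, cfg)
  rep1 <- pcoc_bootstrap(rep0, study$alignment, study$tree, scen, c10, cfg)
  done <- !rep1$call %in% c("below_threshold", "skipped_gaps")
  expect_true(all(!is.na(rep1$threshold_upper[done])))
  expect_true(all(rep1$call %in% c("adaptive", "non_adaptive", "unresolved",
                                   "below_threshold", "skipped_gaps")))
  # untouched rows pass through
  expect_identical(rep1$call[!done], rep0$call[!done])
  # determinism end to end
  rep2 <- pcoc_bootstrap(rep0, study$alignment, study$tree, scen, c10, cfg)
  expect_identical(rep1, rep2)
})
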