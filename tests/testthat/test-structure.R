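test_that("ordered quantile normalization follows the (r - 0.5)/n rule", {
  got <- ordered_quantile_normalize(c(5, 1, 9))
  expect_equal(got, c(0, qnorm(1 / 6), qnorm(5 / 6)), tolerance = 1e-10)
  expect_equal(got[3], 0.9674216, tolerance = 1e-6)

  x <- sort(rnorm(50))
  expect_true(all(diff(ordered_quantile_normalize(x)) > 0))

  # ties share the average-rank score
  tied <- ordered_quantile_normalize(c(2, 2, 7))
  expect_equal(tied[1], tied[2])

  # tie-free output is centred and invariant to monotone transforms
  set.seed(51)
  y <- rexp(101)
  ny <- ordered_quantile_normalize(y)
  expect_lt(abs(mean(ny)), 1e-9)
  expect_equal(ordered_quantile_normalize(log(y)), ny)
  expect_error(ordered_quantile_normalize(3), "at least 2")
})

make_annot <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    site_index = seq_len(n),
    ss_class = sample(c("helix", "sheet", "coil"), n, TRUE),
    exposure_class = sample(c("exposed", "interface", "buried"), n, TRUE),
    bfactor = rnorm(n)
  )
}

test_that("the two-way ANOVA controls its null and sees planted effects", {
  annot <- make_annot(200, 52)
  # labels independent of the response: no term should be extreme
  depth_sites <- sample(200, 40)
  temp_sites <- sample(200, 40)
  null_fit <- bfactor_anova(annot, depth_sites, temp_sites)
  expect_equal(null_fit$term, c("depth", "temperature", "depth:temperature"))
  expect_true(all(null_fit$p.value > 0.001))

  # planted mean shift on depth-adaptive sites is detected
  shifted <- annot
  shifted$bfactor[depth_sites] <- shifted$bfactor[depth_sites] + 1
  power_fit <- bfactor_anova(shifted, depth_sites, temp_sites)
  expect_lt(power_fit$p.value[power_fit$term == "depth"], 0.01)

  expect_error(bfactor_anova(annot, seq_len(200), temp_sites), "depth")
})

test_that("Type III equals Type I sums of squares under balance", {
  grid <- expand.grid(d = c(FALSE, TRUE), t = c(FALSE, TRUE),
                      rep = 1:25)
  set.seed(53)
  annot <- tibble::tibble(
    site_index = seq_len(nrow(grid)),
    ss_class = "coil", exposure_class = "buried",
    bfactor = rnorm(nrow(grid)) + grid$d * 0.5 + grid$t * 0.2
  )
  depth_sites <- annot$site_index[grid$d]
  temp_sites <- annot$site_index[grid$t]
  t3 <- bfactor_anova(annot, depth_sites, temp_sites)
  df <- tibble::tibble(
    y = ordered_quantile_normalize(annot$bfactor),
    depth = factor(grid$d), temperature = factor(grid$t))
  t1 <- anova(lm(y ~ depth * temperature, data = df))
  expect_equal(t3$sumsq, t1$`Sum Sq`[1:3], tolerance = 1e-10)
})

test_that("the exact contingency test matches hypergeometric sums", {
  expect_equal(exact_contingency_test(matrix(c(2, 2, 2, 2), 2)), 1)
  expect_equal(exact_contingency_test(matrix(c(3, 1, 1, 3), 2)), 34 / 70,
               tolerance = 1e-12)
  set.seed(54)
  for (i in 1:40) {
    tab <- matrix(rpois(4, 4) + 1, 2)
    expect_equal(exact_contingency_test(tab), hyper_2x2_pvalue(tab),
                 tolerance = 1e-12)
  }
  # symmetry under row and column permutations (2x3)
  tab <- matrix(c(5, 1, 2, 4, 3, 3), 2)
  p <- exact_contingency_test(tab)
  expect_equal(exact_contingency_test(tab[2:1, ]), p, tolerance = 1e-12)
  expect_equal(exact_contingency_test(tab[, c(2, 3, 1)]), p, tolerance = 1e-12)
  # agreement with fisher.test on r x c tables
  expect_equal(p, fisher.test(tab)$p.value, tolerance = 1e-7)
  expect_error(exact_contingency_test(matrix(c(0, 0, 1, 2), 2)), "margin")
  big <- matrix(c(300, 100, 200, 100), 2)
  expect_error(exact_contingency_test(big), "exceeds 500")
  set.seed(55)
  p_mc <- exact_contingency_test(big, monte_carlo = TRUE, B = 20000)
  expect_lt(abs(p_mc - fisher.test(big)$p.value), 0.02)
})

test_that("context comparison excludes unresolved sites and tests both contrasts", {
  report <- tibble::tibble(
    site_index = 1:16,
    max_pp = 0.9, best_cutoff = 1, best_scenario_id = "c1.0000",
    n_transitions = 5L, threshold_upper = 0.8, threshold_lower = 0.1,
    call = c(rep("adaptive", 6), rep("non_adaptive", 6),
             rep("unresolved", 2), rep("below_threshold", 2))
  )
  class(report) <- c("pcoc_report", class(report))
  annot <- tibble::tibble(
    site_index = 1:16,
    ss_class = rep(c("helix", "sheet"), 8),
    exposure_class = c(rep("exposed", 6), rep("buried", 6),
                       rep("exposed", 4)),
    bfactor = rnorm(16)
  )
  res <- compare_site_context(report, annot)
  expect_equal(res$contrast, c("ss_class", "exposure_class"))
  # identical class distributions in both groups
  expect_equal(res$p.value[res$contrast == "ss_class"], 1)
  # complete separation: all adaptive exposed, all non-adaptive buried
  expect_equal(res$p.value[res$contrast == "exposure_class"], 2 / choose(12, 6),
               tolerance = 1e-12)
  # unresolved and below-threshold sites are excluded from the tables
  expect_equal(sum(res$table[[1]]), 12)
  expect_equal(sum(res$table[[2]]), 12)
  # degenerate reports error
  rep_bad <- report
  rep_bad$call[1:6] <- "unresolved"
  expect_error(compare_site_context(rep_bad, annot), "no adaptive")
})
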