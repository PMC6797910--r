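# Downstream structural-context statistics: relate adaptive / non-adaptive
# site calls to predicted flexibility (B-factor), secondary structure and
# solvent exposure.

ss_levels <- c("helix", "sheet", "coil")
exposure_levels <- c("exposed", "interface", "buried")

#' Read a per-site structural annotation table
#'
#' @param path TSV with header columns `site`, `ss_class`
#'   (helix/sheet/coil), `exposure_class` (exposed/interface/buried) and
#'   `bfactor`.
#' @return A tibble with columns `site_index`, `ss_class`, `exposure_class`,
#'   `bfactor`.
#' @export
read_structure_annotation <- function(path) {
  tb <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    site = readr::col_integer(),
    ss_class = readr::col_character(),
    exposure_class = readr::col_character(),
    bfactor = readr::col_double()
  ))
  if (!all(c("site", "ss_class", "exposure_class", "bfactor") %in% names(tb)))
    stop("annotation TSV needs columns site, ss_class, exposure_class, bfactor",
         call. = FALSE)
  bad_ss <- setdiff(unique(tb$ss_class), ss_levels)
  if (length(bad_ss))
    stop("unknown ss_class: ", paste(bad_ss, collapse = ", "), call. = FALSE)
  bad_ex <- setdiff(unique(tb$exposure_class), exposure_levels)
  if (length(bad_ex))
    stop("unknown exposure_class: ", paste(bad_ex, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(tb$bfactor)))
    stop("non-finite bfactor values", call. = FALSE)
  if (anyDuplicated(tb$site))
    stop("duplicate site in annotation", call. = FALSE)
  tibble::tibble(site_index = tb$site, ss_class = tb$ss_class,
                 exposure_class = tb$exposure_class, bfactor = tb$bfactor)
}

#' Ordered quantile normalization
#'
#' Maps the value of rank `r` (average ranks for ties) to the standard
#' normal quantile at `(r - 0.5) / n`; the result depends on the input only
#' through its ranks, so any monotone transformation of the input yields the
#' same output.
#'
#' @param values Numeric vector (length >= 2, finite).
#' @return Numeric vector of normal scores.
#' @export
ordered_quantile_normalize <- function(values) {
  if (length(values) < 2L)
    stop("need at least 2 values", call. = FALSE)
  if (any(!is.finite(values)))
    stop("values must be finite", call. = FALSE)
  r <- rank(values, ties.method = "average")
  qnorm((r - 0.5) / length(values))
}

#' Two-way ANOVA of normalized flexibility on adaptiveness
#'
#' Models the ordered-quantile-normalized B-factor as a function of
#' predicted depth-adaptiveness, temperature-adaptiveness, and their
#' interaction, with Type III sums of squares (sum-to-zero contrasts, each
#' term tested against the full model).
#'
#' @param annot Structural annotation tibble (see
#'   [read_structure_annotation()]).
#' @param depth_adaptive,temp_adaptive Integer vectors of site indices
#'   predicted adaptive for each trait.
#' @return A tibble with columns `term`, `sumsq`, `df`, `statistic`
#'   (F), `p.value`.
#' @export
bfactor_anova <- function(annot, depth_adaptive, temp_adaptive) {
  df <- tibble::tibble(
    y = ordered_quantile_normalize(annot$bfactor),
    depth = factor(annot$site_index %in% depth_adaptive, c(FALSE, TRUE),
                   c("no", "yes")),
    temperature = factor(annot$site_index %in% temp_adaptive, c(FALSE, TRUE),
                         c("no", "yes"))
  )
  for (f in c("depth", "temperature")) {
    n_lev <- table(df[[f]])
    if (any(n_lev < 2L))
      stop("factor '", f, "' level '", names(n_lev)[n_lev < 2L][1],
           "' has fewer than 2 sites", call. = FALSE)
  }
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  fit <- lm(y ~ depth * temperature, data = df)
  a3 <- car::Anova(fit, type = 3)
  keep <- !rownames(a3) %in% c("(Intercept)", "Residuals")
  tibble::tibble(
    term = rownames(a3)[keep],
    sumsq = a3$`Sum Sq`[keep],
    df = a3$Df[keep],
    statistic = a3$`F value`[keep],
    p.value = a3$`Pr(>F)`[keep]
  )
}

#' Exact conditional test of an r x c contingency table
#'
#' Fisher-style two-sided exact test: enumerates all nonnegative integer
#' tables with the observed margins and sums the (multivariate
#' hypergeometric) probabilities of those no more probable than the observed
#' table, with a 1e-12 relative tolerance on the comparison.
#'
#' @param table An r x c matrix of nonnegative integer counts with positive
#'   row and column margins; total at most 500.
#' @param monte_carlo Use Monte Carlo approximation instead of full
#'   enumeration (for tables too large to enumerate).
#' @param B Number of Monte Carlo replicates.
#' @return The two-sided p-value.
#' @export
exact_contingency_test <- function(table, monte_carlo = FALSE, B = 1e5) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table must hold nonnegative integers", call. = FALSE)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("zero row/column margin", call. = FALSE)
  n <- sum(tab)
  if (monte_carlo) {
    sims <- stats::r2dtable(B, rs, cs)
    lp_obs <- table_log_prob(tab, rs, cs)
    lp_sim <- vapply(sims, table_log_prob, numeric(1), rs = rs, cs = cs)
    return((sum(lp_sim <= lp_obs + 1e-7) + 1) / (B + 1))
  }
  if (n > 500)
    stop("table total ", n, " exceeds 500; use monte_carlo = TRUE",
         call. = FALSE)
  lp_obs <- table_log_prob(tab, rs, cs)
  probs <- enumerate_table_log_probs(rs, cs)
  sum(exp(probs[probs <= lp_obs + log1p(1e-12)]))
}

# log multivariate hypergeometric probability of a table given its margins
table_log_prob <- function(tab, rs, cs) {
  sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(sum(tab) + 1) -
    sum(lgamma(tab + 1))
}

# Log-probabilities of every nonnegative integer table with the given
# margins, by depth-first enumeration over cells (last row/column implied).
enumerate_table_log_probs <- function(rs, cs) {
  r <- length(rs)
  c_ <- length(cs)
  const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(sum(rs) + 1)
  buf <- numeric(1024)
  n_out <- 0L
  push <- function(x) {
    if (n_out == length(buf)) buf[2L * n_out] <<- NA_real_
    n_out <<- n_out + 1L
    buf[n_out] <<- x
  }
  recurse <- function(i, j, row_left, col_left, acc) {
    if (i == r) {
      # last row forced by column remainders
      if (any(col_left < 0)) return()
      push(const + acc - sum(lgamma(col_left + 1)))
      return()
    }
    if (j == c_) {
      # last cell of row i forced by the row margin
      x <- row_left
      if (x < 0 || x > col_left[c_]) return()
      cl <- col_left
      cl[c_] <- cl[c_] - x
      recurse(i + 1, 1, rs[i + 1], cl, acc - lgamma(x + 1))
      return()
    }
    for (x in 0:min(row_left, col_left[j])) {
      cl <- col_left
      cl[j] <- cl[j] - x
      recurse(i, j + 1, row_left - x, cl, acc - lgamma(x + 1))
    }
  }
  recurse(1, 1, rs[1], cs, 0)
  buf[seq_len(n_out)]
}

#' Contingency tests of structural context for called sites
#'
#' Builds (adaptive vs non-adaptive) x class tables for secondary structure
#' and for solvent exposure — the non-adaptive sites supplying the
#' "expected" class distribution — and runs the exact conditional test on
#' each.  Unresolved, below-threshold and gap-skipped sites are excluded;
#' classes absent from both groups are dropped from the table.
#'
#' @param report A `pcoc_report` with final calls.
#' @param annot Structural annotation tibble sharing `site_index`.
#' @return A tibble with columns `contrast` (`ss_class`, `exposure_class`),
#'   `p.value`, and `table` (list column of the tested count matrices).
#' @export
compare_site_context <- function(report, annot) {
  joined <- dplyr::inner_join(
    tidy(report)[, c("site_index", "call")], annot, by = "site_index")
  joined <- dplyr::filter(joined, .data$call %in% c("adaptive", "non_adaptive"))
  if (!any(joined$call == "adaptive"))
    stop("no adaptive sites among annotated sites", call. = FALSE)
  if (!any(joined$call == "non_adaptive"))
    stop("no non-adaptive sites among annotated sites", call. = FALSE)
  one_contrast <- function(class_col, levels) {
    tab <- table(factor(joined$call, c("adaptive", "non_adaptive")),
                 factor(joined[[class_col]], levels))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                dimnames = dimnames(tab))
    tibble::tibble(contrast = class_col,
                   p.value = exact_contingency_test(m),
                   table = list(m))
  }
  dplyr::bind_rows(one_contrast("ss_class", ss_levels),
                   one_contrast("exposure_class", exposure_levels))
}
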