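# Amino-acid profile sets: the K categories of the site-heterogeneous (CAT)
# model.  Each profile is a 20-vector of residue frequencies acting as the
# stationary distribution of the substitution process at a site.

# Fixed-point flooring: entries below the floor are pinned at it and the
# remaining mass is rescaled, so the result both sums to one and keeps every
# residue at probability >= floor.
floor_profile <- function(pi, floor = 1e-6) {
  pi <- pi / sum(pi)
  for (i in 1:25) {
    low <- pi < floor * (1 - 1e-12)
    if (!any(low)) break
    pi[low] <- floor
    free <- !low
    pi[free] <- pi[free] * (1 - sum(low) * floor) / sum(pi[free])
  }
  pi
}

new_profile_set <- function(freq, ids) {
  freq <- as.matrix(freq)
  stopifnot(ncol(freq) == 20L)
  if (any(freq < 0) || any(rowSums(freq) <= 0))
    stop("profiles must be nonnegative with positive row sums", call. = FALSE)
  # floor and renormalize so every residue keeps nonzero probability
  freq <- t(apply(freq, 1, floor_profile))
  colnames(freq) <- AA_ALPHABET
  rownames(freq) <- ids
  structure(
    list(freq = freq, ids = ids, beta = 1 / (1 - rowSums(freq^2))),
    class = "profile_set"
  )
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("<profile_set> %d profiles x 20 residues\n", nrow(x$freq)))
  cat("  ids: ", paste(head(x$ids, 6), collapse = ", "),
      if (length(x$ids) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Load an amino-acid profile set
#'
#' Reads a TSV of profile frequencies (`id` column plus one column per residue
#' in the order `ACDEFGHIKLMNPQRSTVWY`), or returns one of the bundled
#' synthetic sets: `"c60"` (60 categories, the default analysis size) or
#' `"c10"` (a compact 10-category subset for simulation studies).  Rows are
#' floored at 1e-6 and renormalized to sum to one.
#'
#' @param source File path, or `"c60"` / `"c10"`.
#' @return A `profile_set` object.
#' @export
load_profiles <- function(source = "c60") {
  if (source %in% c("c60", "c10"))
    return(default_profiles(source))
  if (!file.exists(source)) stop("no such profile file: ", source, call. = FALSE)
  tb <- readr::read_tsv(source, comment = "#", show_col_types = FALSE)
  if (!"id" %in% names(tb) || ncol(tb) < 21L)
    stop("profile TSV needs an 'id' column plus 20 residue columns",
         call. = FALSE)
  freq <- as.matrix(tb[, setdiff(names(tb), "id")])
  if (ncol(freq) != 20L)
    stop("profile TSV row has ", ncol(freq), " frequency columns; expected 20",
         call. = FALSE)
  if (any(!is.finite(freq)) || any(freq < 0))
    stop("profile frequencies must be finite and nonnegative", call. = FALSE)
  if (any(rowSums(freq) <= 0))
    stop("all-zero profile row: ",
         paste(tb$id[rowSums(freq) <= 0], collapse = ", "), call. = FALSE)
  if (nrow(freq) < 2L) stop("need at least 2 profiles", call. = FALSE)
  new_profile_set(freq, as.character(tb$id))
}

#' Write a profile set to TSV
#'
#' @param profiles A `profile_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  tb <- tibble::as_tibble(profiles$freq)
  tb <- dplyr::bind_cols(tibble::tibble(id = profiles$ids), tb)
  readr::write_tsv(tb, path)
  invisible(path)
}

# Bundled synthetic profile sets.  Ten biochemically motivated base classes
# (hydrophobic, aromatic, basic, acidic, amide, hydroxyl, tiny, turn-former,
# thiol, charged-mixed); the 60-category set mixes each base with the uniform
# distribution at six concentration levels.  These are stand-ins constructed
# by the package, not the empirically fitted CAT categories.
default_profiles <- function(which = c("c60", "c10")) {
  which <- match.arg(which)
  groups <- list(
    hydrophobic = c("A", "I", "L", "M", "V"),
    aromatic    = c("F", "W", "Y"),
    basic       = c("K", "R", "H"),
    acidic      = c("D", "E"),
    amide       = c("N", "Q"),
    hydroxyl    = c("S", "T"),
    tiny        = c("G", "A", "S"),
    turn        = c("P", "G", "N"),
    thiol       = c("C", "M", "A"),
    charged     = c("D", "E", "K", "R")
  )
  base <- t(vapply(groups, function(g) {
    v <- rep(0, 20)
    v[match(g, AA_ALPHABET)] <- 1 / length(g)
    v
  }, numeric(20)))
  if (which == "c10") {
    freq <- 0.9 * base + 0.1 / 20
    return(new_profile_set(freq, names(groups)))
  }
  weights <- c(0.95, 0.85, 0.70, 0.55, 0.40, 0.25)
  rows <- list()
  ids <- character(0)
  for (w in weights) {
    rows[[length(rows) + 1L]] <- w * base + (1 - w) / 20
    ids <- c(ids, sprintf("%s_%02d", names(groups), round(100 * w)))
  }
  new_profile_set(do.call(rbind, rows), ids)
}

# K x 20 -> engine orientation (20 x K)
profile_matrix_t <- function(profiles) t(profiles$freq)
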