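# Convergent scenarios: binarizations of the reconstructed continuous trait.
# A scenario is a set of "convergent" branches (branch = edge above the named
# node) plus the subset of transition branches where the ancestral state
# switches to convergent.  The root is ancestral by construction: whenever the
# greater-than-cutoff side contains the root the orientation is inverted, so
# "convergent" then means the less-than-cutoff side.

#' Bin node trait values
#'
#' Bins are anchored at the minimum observed node value:
#' `bin(v) = floor((v - min) / bin_width)`.
#'
#' @param values Node values from [reconstruct_bm()] (tibble `node_id`,
#'   `value`) or a named numeric vector.
#' @param bin_width Positive bin width (1.75 for degrees C, 0.2 for log10 m).
#' @return A tibble with columns `node_id`, `value`, `bin` (integer, >= 0).
#' @export
bin_node_values <- function(values, bin_width) {
  vals <- as_node_values(values)
  if (length(vals) == 0L) stop("empty node value map", call. = FALSE)
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("bin_width must be > 0", call. = FALSE)
  tibble::tibble(
    node_id = names(vals),
    value = unname(vals),
    bin = as.integer(floor((vals - min(vals)) / bin_width))
  )
}

#' Build the convergent scenario implied by one trait cutoff
#'
#' Nodes with value `>= cutoff` form the default convergent side; if that side
#' contains the root, the orientation is inverted (convergent = `< cutoff`)
#' so the root is always in the ancestral state.  Convergent branches are
#' edges whose child node is convergent; transition branches are convergent
#' branches with an ancestral parent.  A branch whose parent is convergent
#' and whose child is ancestral (a reversion) leaves the child's subtree
#' ancestral and is not counted as a transition.
#'
#' @param tree A `phylo` tree with node ids.
#' @param values Node values (tibble or named vector) covering every node.
#' @param cutoff Trait cutoff, strictly between the minimum and maximum node
#'   values.
#' @return A `pcoc_scenario`: list with `id`, `cutoff`, `inverted`,
#'   `convergent_branches`, `transition_branches`, `n_transitions`.
#' @export
scenario_from_cutoff <- function(tree, values, cutoff) {
  vals <- as_node_values(values)
  ct <- compile_tree(tree)
  missing <- setdiff(ct$ids, names(vals))
  if (length(missing))
    stop("node values missing for: ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  v <- vals[ct$ids]
  if (!(cutoff > min(v) && cutoff < max(v)))
    stop(sprintf("cutoff %g outside the open range of node values (%g, %g)",
                 cutoff, min(v), max(v)), call. = FALSE)
  conv <- v >= cutoff
  inverted <- FALSE
  if (conv[ct$root]) {
    conv <- !conv
    inverted <- TRUE
  }
  non_root <- setdiff(seq_len(ct$n_all), ct$root)
  conv_nodes <- non_root[conv[non_root]]
  trans_nodes <- conv_nodes[!conv[ct$parent[conv_nodes]]]
  structure(
    list(
      id = sprintf("c%.4f", cutoff),
      cutoff = as.numeric(cutoff),
      inverted = inverted,
      convergent_branches = unname(ct$ids[conv_nodes]),
      transition_branches = unname(ct$ids[trans_nodes]),
      n_transitions = length(trans_nodes)
    ),
    class = "pcoc_scenario"
  )
}

#' @export
print.pcoc_scenario <- function(x, ...) {
  cat(sprintf(
    "<pcoc_scenario %s> cutoff %.4f%s: %d convergent branches, %d transitions\n",
    x$id, x$cutoff, if (x$inverted) " (inverted)" else "",
    length(x$convergent_branches), x$n_transitions))
  invisible(x)
}

#' Enumerate retained convergent scenarios
#'
#' Places a candidate cutoff at every interior bin boundary
#' (`min + k * bin_width`, `k = 1, ..., ceiling(range / bin_width) - 1`),
#' builds the scenario for each, drops scenarios with fewer than
#' `min_transitions` independent transitions, and deduplicates scenarios
#' sharing the same convergent branch set (keeping the lowest cutoff).
#'
#' @param tree A `phylo` tree with node ids.
#' @param values Node values covering every node (tibble or named vector).
#' @param config A [pcoc_config()].
#' @return A list of `pcoc_scenario` objects ordered by cutoff (class
#'   `pcoc_scenario_set`); may be empty.
#' @export
enumerate_scenarios <- function(tree, values, config = pcoc_config()) {
  vals <- as_node_values(values)
  lo <- min(vals)
  hi <- max(vals)
  rng <- hi - lo
  k_max <- ceiling(rng / config$bin_width) - 1
  scen <- list()
  seen <- character(0)
  if (k_max >= 1) {
    for (k in seq_len(k_max)) {
      cand <- scenario_from_cutoff(tree, vals, lo + k * config$bin_width)
      if (cand$n_transitions < config$min_transitions) next
      key <- paste(sort(cand$convergent_branches), collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      scen[[length(scen) + 1L]] <- cand
    }
  }
  structure(scen, class = "pcoc_scenario_set")
}

#' @export
print.pcoc_scenario_set <- function(x, ...) {
  cat(sprintf("<pcoc_scenario_set> %d scenario(s)\n", length(x)))
  for (s in x) print(s)
  invisible(x)
}

#' @rdname enumerate_scenarios
#' @param x A `pcoc_scenario_set`.
#' @param ... Unused.
#' @export
tidy.pcoc_scenario_set <- function(x, ...) {
  tibble::tibble(
    id = purrr::map_chr(x, "id"),
    cutoff = purrr::map_dbl(x, "cutoff"),
    inverted = purrr::map_lgl(x, "inverted"),
    n_convergent = purrr::map_int(x, ~ length(.x$convergent_branches)),
    n_transitions = purrr::map_int(x, "n_transitions")
  )
}

#' Write scenarios to JSON
#'
#' @param scenarios A `pcoc_scenario_set` (or list of `pcoc_scenario`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenarios <- function(scenarios, path) {
  payload <- lapply(scenarios, function(s) {
    list(id = s$id, cutoff = s$cutoff, inverted = s$inverted,
         convergent_branches = as.list(s$convergent_branches),
         transition_branches = as.list(s$transition_branches))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read scenarios from JSON
#'
#' @param path Path written by [write_scenarios()].
#' @return A `pcoc_scenario_set`.
#' @export
read_scenarios <- function(path) {
  payload <- jsonlite::read_json(path)
  scen <- lapply(payload, function(s) {
    cb <- unlist(s$convergent_branches)
    tb <- unlist(s$transition_branches)
    if (is.null(cb)) cb <- character(0)
    if (is.null(tb)) tb <- character(0)
    if (!all(tb %in% cb))
      stop("scenario ", s$id, ": transition branches not a subset of ",
           "convergent branches", call. = FALSE)
    structure(
      list(id = s$id, cutoff = as.numeric(s$cutoff),
           inverted = isTRUE(s$inverted),
           convergent_branches = as.character(cb),
           transition_branches = as.character(tb),
           n_transitions = length(tb)),
      class = "pcoc_scenario"
    )
  })
  structure(scen, class = "pcoc_scenario_set")
}

# Recompute a scenario's branch classes on a (possibly gap-pruned) tree.
# State of each surviving node = membership of its id in the scenario's
# convergent set; edge classes: 0 ancestral, 1 convergent, 2 transition.
# Returns NULL when fewer than min_transitions transitions survive.
scenario_edge_class <- function(ct, scenario, min_transitions = 1L) {
  conv <- ct$ids %in% scenario$convergent_branches
  cls <- integer(ct$n_all)
  non_root <- setdiff(seq_len(ct$n_all), ct$root)
  for (v in non_root) {
    if (conv[v]) cls[v] <- if (conv[ct$parent[v]]) 1L else 2L
  }
  if (sum(cls == 2L) < min_transitions) return(NULL)
  cls
}
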