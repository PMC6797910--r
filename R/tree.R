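# Rooted trees are held as ape "phylo" objects whose every node carries a
# stable string id: tip labels for tips, node labels for internal nodes.
# Internal nodes that arrive unlabeled are named "n<postorder index>" with a
# 0-based index over all nodes, a pure function of the input topology, so the
# edge above a node can be referenced bit-stably across runs ("branch id" =
# child node id).

#' Parse a rooted Newick string
#'
#' @param text A single rooted Newick statement terminated by `;`.
#'
#' @return An `ape::phylo` tree. Unlabeled internal nodes receive
#'   deterministic ids `n<postorder index>` (0-based, counted over all nodes);
#'   absent branch lengths default to 1.
#' @export
#'
#' @examples
#' tr <- parse_newick("((A:1,B:2):0.5,C:3);")
#' sum(tr$edge.length)
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop(sprintf("Newick parse error: %d '(' but %d ')'", n_open, n_close),
         call. = FALSE)
  if (!grepl(";\\s*$", text))
    stop("Newick parse error: statement must end with ';'", call. = FALSE)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("Newick parse error: could not read a tree from input", call. = FALSE)
  validate_tree(tr)
}

validate_tree <- function(tr) {
  if (anyDuplicated(tr$tip.label)) {
    dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(tr$tip.label)))
    stop("empty tip label", call. = FALSE)
  if (is.null(tr$edge.length)) {
    tr$edge.length <- rep(1, nrow(tr$edge))
  } else {
    tr$edge.length[is.na(tr$edge.length)] <- 1
    if (any(tr$edge.length < 0)) {
      bad <- which(tr$edge.length < 0)[1]
      stop(sprintf("negative branch length %g above node %d",
                   tr$edge.length[bad], tr$edge[bad, 2]), call. = FALSE)
    }
  }
  assign_node_ids(tr)
}

# Fill in missing internal-node labels with "n<postorder index>" (0-based over
# all nodes, children visited in edge-matrix order).
assign_node_ids <- function(tr) {
  po <- postorder_nodes(tr)
  n_tip <- length(tr$tip.label)
  n_node <- tr$Nnode
  lab <- tr$node.label
  if (is.null(lab)) lab <- rep("", n_node)
  lab[is.na(lab)] <- ""
  for (k in seq_along(po)) {
    v <- po[k]
    if (v > n_tip && !nzchar(lab[v - n_tip])) lab[v - n_tip] <- paste0("n", k - 1L)
  }
  if (anyDuplicated(c(tr$tip.label, lab)))
    stop("node ids are not unique after label assignment", call. = FALSE)
  tr$node.label <- lab
  tr
}

# Postorder over ape node numbers: children (in edge row order) before
# parents, root last. Iterative to avoid deep recursion.
postorder_nodes <- function(tr) {
  n_tip <- length(tr$tip.label)
  n_all <- n_tip + tr$Nnode
  kids <- vector("list", n_all)
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1]
    kids[[p]] <- c(kids[[p]], tr$edge[i, 2])
  }
  root <- n_tip + 1L
  out <- integer(n_all)
  n_out <- 0L
  stack <- list(list(node = root, stage = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (top$stage == 1L) {
      stack[[length(stack) + 1L]] <- list(node = top$node, stage = 2L)
      ch <- kids[[top$node]]
      if (length(ch))
        for (c_ in rev(ch))
          stack[[length(stack) + 1L]] <- list(node = c_, stage = 1L)
    } else {
      n_out <- n_out + 1L
      out[n_out] <- top$node
    }
  }
  out
}

#' Node ids of a tree
#'
#' @param tree A tree from [parse_newick()] (or any `phylo` whose nodes are
#'   fully labeled).
#' @return Character vector of ids indexed by ape node number
#'   (tips `1..Ntip`, then internal nodes).
#' @export
tree_ids <- function(tree) {
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label)))
    tree <- assign_node_ids(tree)
  c(tree$tip.label, tree$node.label)
}

#' Write a tree as Newick
#'
#' @param tree A `phylo` tree.
#' @param path Optional path; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to `path`.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree, digits = 15)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Restrict a tree to a set of tips
#'
#' Drops all other tips and suppresses the resulting unary nodes, summing
#' branch lengths so that path lengths among retained tips are preserved.
#'
#' @param tree A `phylo` tree with node ids.
#' @param keep Character vector of tip labels to retain (>= 2).
#' @return The pruned `phylo` tree; node ids of surviving nodes are unchanged.
#' @export
prune_tips <- function(tree, keep) {
  keep <- unique(keep)
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    stop("tips not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  if (length(keep) < 2L)
    stop("need at least 2 tips to keep", call. = FALSE)
  if (setequal(keep, tree$tip.label)) return(tree)
  pruned <- ape::keep.tip(tree, keep)
  pruned$edge.length[is.na(pruned$edge.length)] <- 0
  pruned
}

#' Prune a tree to the taxa of a trait table
#'
#' Reconciles a tree with a trait table covering only a subset of its tips
#' (e.g. alignments with more taxa than trait-mapped species).
#'
#' @param tree A `phylo` tree.
#' @param traits A trait table (tibble with columns `taxon`, `value`) or a
#'   named numeric vector.
#' @return The tree restricted to trait-bearing tips.
#' @export
prune_to_traits <- function(tree, traits) {
  tv <- as_trait_vector(traits)
  shared <- intersect(tree$tip.label, names(tv))
  if (length(shared) < 4L)
    stop(sprintf("only %d tree tip(s) have trait values; need at least 4",
                 length(shared)), call. = FALSE)
  prune_tips(tree, shared)
}

# Flatten a phylo into the vector form used by the likelihood engine and the
# simulator: parent/branch-length/ids indexed by ape node number, plus a
# postorder.  blen is the length of the edge above each node (0 at the root).
compile_tree <- function(tree) {
  ids <- tree_ids(tree)
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  parent <- integer(n_all)
  blen <- numeric(n_all)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  blen[tree$edge[, 2]] <- tree$edge.length
  list(
    n_tip = n_tip,
    n_all = n_all,
    parent = parent,
    blen = blen,
    ids = ids,
    postorder = postorder_nodes(tree),
    root = n_tip + 1L,
    tip_labels = tree$tip.label
  )
}

# Total height (max root-to-tip path length); used for epsilon substitution.
tree_height <- function(tree) {
  ct <- compile_tree(tree)
  depth <- numeric(ct$n_all)
  for (v in rev(ct$postorder)) {
    if (v != ct$root) depth[v] <- depth[ct$parent[v]] + ct$blen[v]
  }
  max(depth[seq_len(ct$n_tip)])
}
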