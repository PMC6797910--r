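#' Ancestral reconstruction of a continuous trait under Brownian motion
#'
#' Maximum-likelihood (equivalently generalized-least-squares) marginal
#' estimates of the trait at every internal node, by a linear-time two-pass
#' message-passing scheme: an upward pass combines each node's subtree
#' observations into a precision-weighted mean, a downward pass folds in the
#' rest of the tree.  Tips keep their observed values.  Point estimates only;
#' reconstruction uncertainty is not propagated.
#'
#' @param tree A `phylo` tree whose every tip has a trait value.
#' @param traits Trait table (tibble `taxon`,`value`) or named numeric vector.
#' @return A tibble with columns `node_id`, `value`, `is_tip` — one row per
#'   node of the tree.
#' @export
#'
#' @examples
#' tr <- parse_newick("(A:1,B:4);")
#' reconstruct_bm(tr, c(A = 0, B = 10))  # root estimate 2.0
reconstruct_bm <- function(tree, traits) {
  tv <- as_trait_vector(traits)
  if (length(tree$tip.label) < 2L)
    stop("tree must have at least 2 tips", call. = FALSE)
  missing <- setdiff(tree$tip.label, names(tv))
  if (length(missing))
    stop("tips without trait values: ", paste(missing, collapse = ", "),
         call. = FALSE)
  ct <- compile_tree(tree)
  # zero-length branches get a small epsilon so precisions stay finite
  eps <- 1e-8 * max(tree_height(tree), 1e-12)
  bl <- ct$blen
  bl[bl <= 0] <- eps
  bl[ct$root] <- 0

  up_mean <- numeric(ct$n_all)   # subtree ML mean at each node
  up_var <- numeric(ct$n_all)    # extra variance carried by that mean
  kids <- vector("list", ct$n_all)
  for (v in seq_len(ct$n_all)) if (v != ct$root) {
    p <- ct$parent[v]
    kids[[p]] <- c(kids[[p]], v)
  }
  for (v in ct$postorder) {
    if (v <= ct$n_tip) {
      up_mean[v] <- tv[[ct$ids[v]]]
      up_var[v] <- 0
    } else {
      w <- 1 / (up_var[kids[[v]]] + bl[kids[[v]]])
      up_mean[v] <- sum(w * up_mean[kids[[v]]]) / sum(w)
      up_var[v] <- 1 / sum(w)
    }
  }

  # Downward pass: out_mean/out_var hold the message from the rest of the
  # tree arriving at each node (variance Inf at the root).
  out_mean <- numeric(ct$n_all)
  out_var <- rep(Inf, ct$n_all)
  est <- numeric(ct$n_all)
  for (v in rev(ct$postorder)) {
    if (v == ct$root) {
      est[v] <- up_mean[v]
    } else if (v > ct$n_tip) {
      p <- ct$parent[v]
      sibs <- setdiff(kids[[p]], v)
      prec <- 1 / (up_var[sibs] + bl[sibs])
      means <- up_mean[sibs]
      if (is.finite(out_var[p])) {
        prec <- c(prec, 1 / out_var[p])
        means <- c(means, out_mean[p])
      }
      out_mean[v] <- sum(prec * means) / sum(prec)
      out_var[v] <- 1 / sum(prec) + bl[v]
      w_in <- 1 / up_var[v]
      w_out <- 1 / out_var[v]
      if (!is.finite(w_in)) {
        est[v] <- up_mean[v]
      } else {
        est[v] <- (w_in * up_mean[v] + w_out * out_mean[v]) / (w_in + w_out)
      }
    }
  }
  est[seq_len(ct$n_tip)] <- tv[ct$ids[seq_len(ct$n_tip)]]

  tibble::tibble(
    node_id = ct$ids,
    value = est,
    is_tip = seq_len(ct$n_all) <= ct$n_tip
  )
}

# Named-vector view of a node-value tibble.
as_node_values <- function(values) {
  if (is.data.frame(values)) {
    stopifnot(all(c("node_id", "value") %in% names(values)))
    setNames(as.numeric(values$value), values$node_id)
  } else if (is.numeric(values) && !is.null(names(values))) {
    values
  } else {
    stop("values must be a (node_id, value) data frame or named numeric vector",
         call. = FALSE)
  }
}
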