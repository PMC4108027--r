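#' Collapse poorly supported nodes into polytomies
#'
#' Contracts every internal edge whose child node has a numeric bootstrap
#' support strictly below `threshold` percent: the children of the removed
#' node are promoted to its parent, so poorly supported resolution becomes a
#' polytomy. "Strictly below" means a support exactly at the threshold
#' survives. Nodes without a numeric support (the root, unlabelled nodes) are
#' never collapsed. Path lengths from root to every leaf are preserved when
#' branch lengths are present. The leaf set and leaf annotations are
#' unchanged; the operation is idempotent at a fixed threshold.
#'
#' @param tree a [gene_tree][as_gene_tree].
#' @param threshold percent support in (0, 100]; default 50.
#' @return the collapsed tree, with a `collapse_report` attribute (see
#'   [collapse_report()]): a list with `threshold`, `n_collapsed`, and
#'   `collapsed_supports`.
#' @examples
#' tr <- read_gene_tree("((a,b)40,(c,d)90);")
#' collapse_report(collapse_low_support(tr, 50))
#' @export
collapse_low_support <- function(tree, threshold = 50) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 100) {
    stop("`threshold` must be a single percentage in (0, 100]", call. = FALSE)
  }
  n <- length(tree$tip.label)
  if (n <= 1 || tree$Nnode <= 1) {
    report <- new_collapse_report(threshold, numeric(0))
    attr(tree, "collapse_report") <- report
    return(as_gene_tree(tree))
  }
  nd <- tree_nodes(tree)
  sup <- node_supports(tree)
  internal <- n + seq_len(tree$Nnode)
  bad <- internal[internal != nd$root & !is.na(sup[internal - n]) &
                    sup[internal - n] < threshold]
  report <- new_collapse_report(threshold, unname(sup[as.character(bad)]))
  if (length(bad) == 0) {
    attr(tree, "collapse_report") <- report
    return(as_gene_tree(tree))
  }
  is_bad <- logical(nd$n_tip + length(internal))
  is_bad[bad] <- TRUE
  # promote children of collapsed nodes, accumulating edge lengths so
  # root-to-leaf path lengths are unchanged
  promote <- function(v) { # returns surviving replacement children of v
    unlist(lapply(nd$children[[v]], function(ch) {
      if (is_bad[ch]) {
        out <- promote(ch)
        if (!is.na(nd$elen[ch])) {
          nd$elen[out] <<- ifelse(is.na(nd$elen[out]), nd$elen[ch],
                                  nd$elen[out] + nd$elen[ch])
        }
        out
      } else ch
    }))
  }
  for (v in c(nd$root, setdiff(internal, c(bad, nd$root)))) {
    nd$children[[v]] <- promote(v)
  }
  for (v in bad) nd$children[[v]] <- integer(0)
  # drop collapsed nodes from the structure by rebuilding from the root
  keep <- rep(TRUE, length(is_bad))
  keep[bad] <- FALSE
  nd2 <- nd
  nd2$children <- lapply(nd$children, function(k) k[keep[k]])
  out <- nodes_to_tree(nd2, template = tree, attrs = list(collapse_report = report))
  out
}

new_collapse_report <- function(threshold, supports) {
  structure(
    list(threshold = threshold, n_collapsed = length(supports),
         collapsed_supports = supports),
    class = "collapse_report"
  )
}

#' @rdname collapse_low_support
#' @export
collapse_report <- function(tree) attr(tree, "collapse_report")

#' @export
print.collapse_report <- function(x, ...) {
  cat(sprintf("<collapse_report> threshold %g%%: %d node(s) collapsed",
              x$threshold, x$n_collapsed), "\n")
  if (x$n_collapsed > 0) {
    cat("  supports removed:",
        paste(format(x$collapsed_supports), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Root a gene tree by an outgroup
#'
#' Places the root on the edge separating the outgroup leaves (or their most
#' recent common ancestor) from the rest of the tree. Node labels are treated
#' as edge supports and follow their edge when its orientation flips, so
#' bootstrap values stay attached to the bipartitions they measure. If the
#' outgroup is not monophyletic on the unrooted topology, the tree is rooted
#' on the edge above the smallest clade (under the input orientation)
#' containing all outgroup leaves and the result is flagged
#' `outgroup_not_clean`. The unrooted topology (the set of bipartitions) is
#' unchanged.
#'
#' @param tree a [gene_tree][as_gene_tree].
#' @param outgroup_leaves character vector of leaf labels, all present in the
#'   tree and not the whole leaf set.
#' @return the rooted tree, with a `rooting` attribute: list with `outgroup`
#'   and logical `clean`.
#' @examples
#' tr <- read_gene_tree("(alga,(m1,(s1,a1)));")
#' root_by_outgroup(tr, "alga")
#' @export
root_by_outgroup <- function(tree, outgroup_leaves) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  missing <- setdiff(outgroup_leaves, tips)
  if (length(outgroup_leaves) == 0) {
    stop("`outgroup_leaves` must be non-empty", call. = FALSE)
  }
  if (length(missing) > 0) {
    stop("outgroup leaf (leaves) not in tree: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (setequal(outgroup_leaves, tips)) {
    stop("outgroup cannot be the entire leaf set", call. = FALSE)
  }
  n <- length(tips)
  og <- sort(match(outgroup_leaves, tips))
  sets <- node_leafsets(tree)
  nd <- tree_nodes(tree)

  # a clean rooting edge has the outgroup exactly on one side
  all_tips <- seq_len(n)
  edge_node <- NA_integer_
  for (v in seq_along(sets)) {
    if (v == nd$root) next
    below <- sort(sets[[v]])
    if (identical(below, og) || identical(sort(setdiff(all_tips, below)), og)) {
      edge_node <- v
      break
    }
  }
  clean <- !is.na(edge_node)
  if (!clean) {
    m <- mrca_node(tree, tips[og])
    if (m == nd$root) {
      warning("outgroup spans the root as read; tree left as-is ",
              "[outgroup_not_clean]", call. = FALSE)
      attr(tree, "rooting") <- list(outgroup = tips[og], clean = FALSE)
      return(as_gene_tree(tree))
    }
    edge_node <- m
  }
  out <- reroot_at_edge(nd, edge_node)
  nodes_to_tree(out, template = tree,
                attrs = list(rooting = list(outgroup = tips[og], clean = clean)))
}

# Reroot on the edge above `v`: new root has children {v, old-parent side}.
# Edges on the path from v's parent to the old root flip orientation; labels
# (supports) and lengths ride with their edge. The split edge keeps its
# support on both halves; its length is halved across them. An old root left
# with a single child is suppressed (its merged edge takes the surviving
# child's support).
reroot_at_edge <- function(nd, v) {
  path <- integer(0)
  u <- nd$parent[v]
  while (!is.na(u)) {
    path <- c(path, u)
    u <- nd$parent[u]
  }
  if (length(path) == 0) stop("cannot reroot at the root edge", call. = FALSE)

  nn <- length(nd$label)
  R <- nn + 1L
  nd$parent <- c(nd$parent, NA_integer_)
  nd$children <- c(nd$children, list(c(v, path[1]))) # placeholder order
  nd$elen <- c(nd$elen, NA_real_)
  nd$label <- c(nd$label, "")

  old_label <- nd$label
  old_elen <- nd$elen

  # flip edges along the path: new child path[i] gets the old edge between
  # path[i] and path[i+1] (which had child path[i+1] ... wait, orientation):
  # old edge (parent = path[i+1]? no: parent(path[i]) = path[i+1]).
  for (i in seq_along(path)) {
    ui <- path[i]
    if (i < length(path)) {
      # edge between ui and path[i+1], old child = ui; it flips so that
      # path[i+1] becomes the child: label/length move to path[i+1]
      nd$children[[ui]] <- c(setdiff(nd$children[[ui]], if (i == 1) v else path[i - 1]),
                             path[i + 1])
    } else {
      nd$children[[ui]] <- setdiff(nd$children[[ui]], if (i == 1) v else path[i - 1])
    }
  }
  # labels: edge (path[i] -> path[i+1]) in the new tree is the old edge whose
  # child was path[i]; assign old child's label/length to the new child
  for (i in seq_along(path)) {
    if (i < length(path)) {
      nd$label[path[i + 1]] <- old_label[path[i]]
      nd$elen[path[i + 1]] <- old_elen[path[i]]
    }
  }
  # split edge above v: both halves keep its support (a pendant edge has
  # none) and share its length
  half <- if (!is.na(old_elen[v])) old_elen[v] / 2 else NA_real_
  nd$elen[v] <- half
  nd$label[path[1]] <- if (v > nd$n_tip) old_label[v] else ""
  nd$elen[path[1]] <- half
  nd$children[[R]] <- c(v, path[1])
  nd$parent[v] <- R
  nd$parent[path[1]] <- R
  for (i in seq_along(path)[-1]) nd$parent[path[i]] <- path[i - 1]
  nd$root <- R
  nd$label[R] <- ""

  # suppress a former root reduced to one child
  old_root <- path[length(path)]
  if (length(nd$children[[old_root]]) == 1 && old_root > nd$n_tip) {
    ch <- nd$children[[old_root]]
    gp <- nd$parent[old_root]
    l1 <- nd$elen[old_root]
    l2 <- old_elen[ch]
    merged <- if (is.na(l1)) l2 else if (is.na(l2)) l1 else l1 + l2
    nd$children[[gp]] <- replace(nd$children[[gp]],
                                 nd$children[[gp]] == old_root, ch)
    nd$parent[ch] <- gp
    nd$elen[ch] <- merged
    # merged edge keeps the support of the surviving (old) edge above ch
    nd$label[ch] <- old_label[ch]
    nd$children[[old_root]] <- integer(0)
  }
  nd
}

#' Most recent common ancestor of a set of leaves
#'
#' @param tree a rooted `gene_tree`/`phylo`.
#' @param leaves non-empty character vector of leaf labels.
#' @return the node number (phylo numbering: leaves `1..n`, internals
#'   `n+1..`) of the lowest node whose leaf set contains all `leaves`; a
#'   single leaf is its own MRCA.
#' @export
mrca_node <- function(tree, leaves) {
  stopifnot(inherits(tree, "phylo"), length(leaves) >= 1)
  idx <- match(leaves, tree$tip.label)
  if (anyNA(idx)) {
    stop("leaf (leaves) not in tree: ",
         paste(leaves[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx <- unique(idx)
  if (length(idx) == 1) return(idx)
  ape::getMRCA(tree, idx)
}
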