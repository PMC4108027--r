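#' Gene trees with bootstrap supports
#'
#' A `gene_tree` is an [ape::read.tree()]-style `phylo` object with two
#' conventions layered on top: internal node labels, when numeric, are
#' bootstrap supports on the 0--100 scale (the RAxML dialect, where the
#' support of an internal edge is stored on its child node), and leaves may
#' carry species annotations (see [assign_taxa()]) kept in a `species`
#' attribute keyed by leaf label so they survive any re-arrangement.
#'
#' Absent supports (empty or non-numeric labels) mean "never collapse": the
#' root, leaves and nodes of an already collapsed tree carry no support.
#'
#' @param phy a `phylo` object.
#' @return `as_gene_tree()` returns the same tree classed as
#'   `c("gene_tree", "phylo")`, with `node.label` padded to one entry per
#'   internal node.
#' @seealso [read_gene_tree()], [collapse_low_support()], [root_by_outgroup()]
#' @export
as_gene_tree <- function(phy) {
  if (!inherits(phy, "phylo")) {
    stop("`phy` must be a 'phylo' object", call. = FALSE)
  }
  if (is.null(phy$node.label)) {
    phy$node.label <- rep("", phy$Nnode)
  } else {
    phy$node.label[is.na(phy$node.label)] <- ""
    length(phy$node.label) <- phy$Nnode
    phy$node.label[is.na(phy$node.label)] <- ""
  }
  if (anyDuplicated(phy$tip.label)) {
    dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
    stop("duplicate leaf labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  class(phy) <- unique(c("gene_tree", class(phy)))
  phy
}

#' @rdname as_gene_tree
#' @export
is_gene_tree <- function(phy) inherits(phy, "gene_tree")

#' Bootstrap supports of the internal nodes
#'
#' Parses the internal node labels of a tree into numeric supports.
#' Non-numeric or empty labels give `NA` (support absent, never collapsed).
#'
#' @param tree a `gene_tree` (or any `phylo` with node labels).
#' @return numeric vector of length `tree$Nnode`, named by internal node
#'   number (`Ntip + 1`, ...), values in \[0, 100\] or `NA`.
#' @export
node_supports <- function(tree) {
  n <- length(tree$tip.label)
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", tree$Nnode)
  sup <- suppressWarnings(as.numeric(lab))
  sup[!is.na(lab) & lab == ""] <- NA_real_
  names(sup) <- as.character(n + seq_len(tree$Nnode))
  sup
}

#' Species annotations of the leaves
#'
#' @param tree a `gene_tree`.
#' @return named character vector (leaf label -> species code), in
#'   `tree$tip.label` order; `NA` for unannotated leaves.
#' @export
tip_species <- function(tree) {
  sp <- attr(tree, "species")
  out <- rep(NA_character_, length(tree$tip.label))
  names(out) <- tree$tip.label
  if (!is.null(sp)) {
    hit <- intersect(names(sp), tree$tip.label)
    out[hit] <- sp[hit]
  }
  out
}

#' @export
print.gene_tree <- function(x, ...) {
  n <- length(x$tip.label)
  sup <- node_supports(x)
  sp <- tip_species(x)
  cat(sprintf(
    "<gene_tree> %d leaves, %d internal nodes (%d with support)\n",
    n, x$Nnode, sum(!is.na(sup))
  ))
  if (any(!is.na(sp))) {
    tab <- sort(table(sp), decreasing = TRUE)
    cat("  species: ", paste0(names(tab), " (", tab, ")", collapse = ", "),
        "\n", sep = "")
  }
  rep <- attr(x, "collapse_report")
  if (!is.null(rep)) {
    cat(sprintf("  collapsed: %d node(s) below %g%% support\n",
                rep$n_collapsed, rep$threshold))
  }
  rt <- attr(x, "rooting")
  if (!is.null(rt)) {
    cat(sprintf("  rooted by outgroup {%s}%s\n",
                paste(rt$outgroup, collapse = ", "),
                if (rt$clean) "" else " [outgroup_not_clean]"))
  }
  invisible(x)
}

# ---- internal parent/children representation -------------------------------
#
# Nodes are numbered as in phylo: leaves 1..n, internals n+1..n+m. The
# representation is a list of parallel vectors so collapsing and rerooting can
# rewire edges without fighting ape's edge-matrix bookkeeping. Supports/labels
# and edge lengths ride on the child node of each edge.

tree_nodes <- function(tree) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  nn <- n + m
  parent <- rep(NA_integer_, nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  children <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    children[[p]] <- c(children[[p]], tree$edge[i, 2])
  }
  elen <- rep(NA_real_, nn)
  if (!is.null(tree$edge.length)) elen[tree$edge[, 2]] <- tree$edge.length
  lab <- character(nn)
  lab[seq_len(n)] <- tree$tip.label
  nl <- tree$node.label
  if (is.null(nl)) nl <- rep("", m)
  lab[n + seq_len(m)] <- ifelse(is.na(nl), "", nl)
  root <- which(is.na(parent) & seq_len(nn) > n)
  if (length(root) != 1) root <- n + 1L
  list(n_tip = n, parent = parent, children = children,
       elen = elen, label = lab, root = root)
}

quote_newick_label <- function(x) {
  bad <- grepl("[^A-Za-z0-9_.|-]", x)
  x[bad] <- paste0("'", gsub("'", "''", x[bad]), "'")
  x
}

nodes_newick <- function(nd, v = nd$root) {
  build <- function(v) {
    kids <- nd$children[[v]]
    lab <- if (v <= nd$n_tip) quote_newick_label(nd$label[v]) else nd$label[v]
    core <- if (length(kids) == 0) {
      lab
    } else {
      paste0("(", paste(vapply(kids, build, character(1)), collapse = ","),
             ")", lab)
    }
    if (!is.na(nd$elen[v]) && v != nd$root) {
      core <- paste0(core, ":", format(nd$elen[v], digits = 15))
    }
    core
  }
  paste0(build(v), ";")
}

# Rebuild a gene_tree from the internal representation, carrying over the
# species annotations and any flags passed in `attrs`.
nodes_to_tree <- function(nd, template = NULL, attrs = list()) {
  txt <- nodes_newick(nd)
  phy <- ape::read.tree(text = txt)
  if (is.null(phy)) stop("internal error: rebuilt Newick failed to parse")
  out <- as_gene_tree(phy)
  if (!is.null(template)) {
    for (a in c("species", "collapse_report", "rooting")) {
      if (!is.null(attr(template, a))) attr(out, a) <- attr(template, a)
    }
  }
  for (a in names(attrs)) attr(out, a) <- attrs[[a]]
  out
}

# Leaf set under each node (list indexed by node number), via one postorder.
node_leafsets <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(n)) sets[[i]] <- i
  # accumulate children into parents in postorder over edges
  for (i in ape::postorder(tree)) {
    p <- tree$edge[i, 1]
    ch <- tree$edge[i, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}
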