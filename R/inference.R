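#' Does a clade span both sides of the focal split?
#'
#' A node is *spanning* when its leaf set contains at least one gene from
#' side A and at least one from side B of the focal split (by default: at
#' least one moss gene and at least one tracheophyte gene). Algal-outgroup
#' leaves are transparent: they neither make a clade spanning nor block it.
#' Each clade spanning the split is evidence for one gene copy in the A/B
#' common ancestor.
#'
#' @param tree a taxon-annotated `gene_tree` (see [assign_taxa()]).
#' @param node node number (phylo numbering); may be a leaf.
#' @param scheme a [lineage_scheme()].
#' @param split a [focal_split()].
#' @return logical.
#' @export
is_spanning <- function(tree, node, scheme = default_lineage_scheme(),
                        split = focal_split()) {
  side <- tip_split_sides(tree, scheme, split)
  sets <- node_leafsets(tree)
  stopifnot(node >= 1, node <= length(sets))
  s <- side[sets[[node]]]
  any(s == "A", na.rm = TRUE) && any(s == "B", na.rm = TRUE)
}

tip_split_sides <- function(tree, scheme, split) {
  sp <- tip_species(tree)
  if (all(is.na(sp))) {
    stop("tree has no species annotations; run assign_taxa() first",
         call. = FALSE)
  }
  if (anyNA(sp)) {
    stop("unannotated leaves: ",
         paste(tree$tip.label[is.na(sp)], collapse = ", "), call. = FALSE)
  }
  split_side(unname(sp), scheme, split)
}

#' Minimum gene copy number in the A/B common ancestor
#'
#' Implements a parsimony-style reading of a collapsed, rooted,
#' taxon-annotated gene family tree: every clade containing genes from both
#' sides of the focal split must trace back to a distinct gene copy in the
#' A/B common ancestor. Starting at the most recent common ancestor of all
#' A- and B-side leaves, the count recurses into each spanning child clade,
#' and the *leftover* leaves at a node (those under its non-spanning
#' children, algal-outgroup leaves excluded) add one further ancestral copy
#' when they still include both an A-side and a B-side gene -- the treatment
#' of unresolved polytomies where mixed genes hang loose.
#'
#' Two modes:
#' \describe{
#'   \item{`paper`}{the default; the leftover rule above. On a fully resolved
#'     binary tree this equals the number of minimal spanning nodes (spanning
#'     nodes with no spanning child).}
#'   \item{`strict`}{the leftover bonus applies only at nodes with no
#'     spanning child, i.e. only minimal spanning clades are counted. Never
#'     exceeds the `paper` count; on binary trees the two coincide. Provided
#'     because the leftover rule can overcount when collapsing has hidden
#'     nesting.}
#' }
#'
#' The result is *ND* (not determined) when the tree has no A-side or no
#' B-side leaves at all -- the family was not detected in one lineage and the
#' ancestral count at this split is undefined.
#'
#' @param tree a collapsed, rooted, taxon-annotated `gene_tree`. Collapsing
#'   and rooting are the caller's responsibility ([collapse_low_support()],
#'   [root_by_outgroup()]); an unrooted tree is used as read.
#' @param scheme a [lineage_scheme()].
#' @param split a [focal_split()]; default moss vs tracheophytes.
#' @param mode `"paper"` or `"strict"`.
#' @param family optional family name carried into the result.
#' @return an object of class `ancestral_count`: a list with `family`,
#'   `mode`, `min_copies` (integer, `NA` when ND), `nd` (logical),
#'   `spanning_clades` and `bonus_nodes` (tibbles: node, support, per-side
#'   and per-group leaf counts), and `uncounted_clades` (root-level clades
#'   with B-side genes from several groups but no A-side gene; reported,
#'   never counted). Use [tidy()][generics::tidy] / [clade_report()] and
#'   [glance()][generics::glance] on it.
#' @examples
#' tm <- taxon_map(c("Pp", "Sm", "At"),
#'                 c("physcomitrella", "selaginella", "arabidopsis"))
#' tr <- read_gene_tree("((Pp1,Pp2)90,(Sm1,At1)80);") |> assign_taxa(tm)
#' min_ancestral_copies(tr)
#' @export
min_ancestral_copies <- function(tree, scheme = default_lineage_scheme(),
                                 split = focal_split(),
                                 mode = c("paper", "strict"),
                                 family = NA_character_) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n == 0) stop("empty tree", call. = FALSE)
  side <- tip_split_sides(tree, scheme, split)
  sp <- unname(tip_species(tree))
  grp <- rep("other", length(sp))
  in_scheme <- sp %in% scheme$species
  grp[in_scheme] <- lineage_of(sp[in_scheme], scheme)
  if (all(is.na(side))) {
    stop("tree contains only outgroup/unplaced leaves; nothing to infer",
         call. = FALSE)
  }

  nd_flag <- !any(side == "A", na.rm = TRUE) || !any(side == "B", na.rm = TRUE)
  empty <- clade_row_tibble(tree, integer(0), side, grp)
  if (nd_flag) {
    return(new_ancestral_count(family, mode, NA_integer_, TRUE,
                               empty, empty, empty, split, tree))
  }

  sets <- node_leafsets(tree)
  sup <- node_supports(tree)
  children <- tree_nodes(tree)$children
  has_a <- vapply(sets, function(s) any(side[s] == "A", na.rm = TRUE), logical(1))
  has_b <- vapply(sets, function(s) any(side[s] == "B", na.rm = TRUE), logical(1))
  spanning <- has_a & has_b

  focal_tips <- which(!is.na(side))
  v0 <- mrca_node(tree, tree$tip.label[focal_tips])

  clades <- integer(0)
  bonuses <- integer(0)
  count <- function(v) {
    kids <- children[[v]]
    sc <- kids[spanning[kids]]
    total <- 0L
    if (length(sc) == 0) {
      # v itself is spanning (guaranteed on the recursion path): one clade
      clades <<- c(clades, v)
      return(1L)
    }
    for (c in sc) total <- total + count(c)
    leftover <- unlist(sets[setdiff(kids, sc)])
    if (mode == "paper" &&
        any(side[leftover] == "A", na.rm = TRUE) &&
        any(side[leftover] == "B", na.rm = TRUE)) {
      bonuses <<- c(bonuses, v)
      total <- total + 1L
    }
    total
  }
  copies <- count(v0)

  # root-level clades with B-side genes but no A-side gene: reported (they
  # may witness further ancestral copies under a stricter reading) but never
  # counted; irrelevant when the whole tree was counted as a single clade
  unc <- if (v0 %in% clades) integer(0) else {
    kids <- children[[v0]]
    kids[kids > n & !spanning[kids] & has_b[kids]]
  }

  new_ancestral_count(
    family, mode, copies, FALSE,
    clade_row_tibble(tree, clades, side, grp, sup),
    clade_row_tibble(tree, bonuses, side, grp, sup, leftover_of = children,
                     spanning = spanning, sets = sets),
    clade_row_tibble(tree, unc, side, grp, sup),
    split, tree
  )
}

clade_row_tibble <- function(tree, nodes, side, grp, sup = NULL,
                             leftover_of = NULL, spanning = NULL, sets = NULL) {
  n <- length(tree$tip.label)
  if (is.null(sets)) sets <- if (length(nodes)) node_leafsets(tree) else list()
  rows <- lapply(nodes, function(v) {
    leaves <- if (!is.null(leftover_of)) {
      kids <- leftover_of[[v]]
      unlist(sets[kids[!spanning[kids]]])
    } else {
      sets[[v]]
    }
    g <- grp[leaves]
    tibble::tibble(
      node = as.integer(v),
      support = if (!is.null(sup) && v > n) unname(sup[as.character(v)]) else NA_real_,
      n_leaves = length(leaves),
      n_side_a = sum(side[leaves] == "A", na.rm = TRUE),
      n_side_b = sum(side[leaves] == "B", na.rm = TRUE),
      composition = paste(
        vapply(split(leaves, g), length, integer(1)),
        names(split(leaves, g)),
        sep = " ", collapse = ", "
      )
    )
  })
  if (length(rows) == 0) {
    return(tibble::tibble(node = integer(0), support = numeric(0),
                          n_leaves = integer(0), n_side_a = integer(0),
                          n_side_b = integer(0), composition = character(0)))
  }
  dplyr::bind_rows(rows)
}

new_ancestral_count <- function(family, mode, copies, nd, clades, bonuses,
                                uncounted, split, tree) {
  structure(
    list(family = family, mode = mode,
         min_copies = as.integer(copies), nd = nd,
         spanning_clades = clades, bonus_nodes = bonuses,
         uncounted_clades = uncounted,
         split = split, n_leaves = length(tree$tip.label)),
    class = "ancestral_count"
  )
}

#' @export
print.ancestral_count <- function(x, ...) {
  fam <- if (is.na(x$family)) "" else paste0(" [", x$family, "]")
  cat(sprintf("<ancestral_count>%s mode=%s\n", fam, x$mode))
  if (x$nd) {
    cat("  min copies in A/B ancestor: ND",
        "(family not detected on one side of the split)\n")
  } else {
    cat(sprintf("  min copies in A/B ancestor: %d (%d spanning clade(s) + %d polytomy bonus)\n",
                x$min_copies, nrow(x$spanning_clades), nrow(x$bonus_nodes)))
    if (nrow(x$uncounted_clades) > 0) {
      cat(sprintf("  note: %d root-level B-only clade(s) reported, not counted\n",
                  nrow(x$uncounted_clades)))
    }
  }
  invisible(x)
}

#' Per-clade report of an ancestral count
#'
#' One row per counted spanning clade and per polytomy bonus node, with the
#' clade's support and per-lineage leaf composition; root-level clades with
#' tracheophyte genes but no moss gene appear with `counted = FALSE`. An ND
#' family gives a zero-row table carrying an `nd` attribute.
#'
#' @param result an `ancestral_count` from [min_ancestral_copies()].
#' @return a tibble with columns `type` (`"clade"`, `"bonus"`,
#'   `"b_only"`), `counted`, `node`, `support`, `n_leaves`, `n_side_a`,
#'   `n_side_b`, `composition`.
#' @export
clade_report <- function(result) {
  stopifnot(inherits(result, "ancestral_count"))
  out <- dplyr::bind_rows(
    dplyr::mutate(result$spanning_clades, type = "clade", counted = TRUE),
    dplyr::mutate(result$bonus_nodes, type = "bonus", counted = TRUE),
    dplyr::mutate(result$uncounted_clades, type = "b_only", counted = FALSE)
  )
  out <- dplyr::relocate(out, "type", "counted")
  attr(out, "nd") <- result$nd
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname clade_report
#' @param x an `ancestral_count`.
#' @param ... unused.
#' @export
tidy.ancestral_count <- function(x, ...) clade_report(x)

#' @rdname clade_report
#' @export
glance.ancestral_count <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    mode = x$mode,
    min_copies = x$min_copies,
    nd = x$nd,
    n_spanning_clades = nrow(x$spanning_clades),
    n_bonus_nodes = nrow(x$bonus_nodes),
    n_uncounted_b_only = nrow(x$uncounted_clades),
    n_leaves = x$n_leaves
  )
}

#' One-call analysis of a gene family tree
#'
#' The standard pipeline: annotate leaves, collapse poorly supported nodes,
#' root by the algal outgroup when one is present (with a warning when none
#' is, in which case the tree is used as read), then infer the minimum
#' ancestral copy number.
#'
#' @param tree a `gene_tree`.
#' @param map a [taxon_map()]; omit if the tree is already annotated.
#' @param scheme a [lineage_scheme()].
#' @param split a [focal_split()].
#' @param threshold collapse threshold (percent), default 50.
#' @param mode `"paper"` or `"strict"`.
#' @param family optional family name.
#' @param strict passed to [assign_taxa()].
#' @return an `ancestral_count`.
#' @export
analyze_tree <- function(tree, map = NULL, scheme = default_lineage_scheme(),
                         split = focal_split(), threshold = 50,
                         mode = c("paper", "strict"),
                         family = NA_character_, strict = TRUE) {
  mode <- match.arg(mode)
  if (!is.null(map)) tree <- assign_taxa(tree, map, strict = strict)
  tree <- collapse_low_support(tree, threshold)
  sp <- tip_species(tree)
  grp <- rep("other", length(sp))
  in_scheme <- sp %in% scheme$species
  grp[in_scheme] <- lineage_of(sp[in_scheme], scheme)
  og <- tree$tip.label[grp == "algal_outgroup"]
  if (length(og) > 0 && length(og) < length(tree$tip.label)) {
    tree <- root_by_outgroup(tree, og)
  } else if (length(og) == 0) {
    warning("no algal outgroup leaf detected; tree processed as read",
            call. = FALSE)
  }
  min_ancestral_copies(tree, scheme, split, mode, family = family)
}
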