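# Independent oracles and random-tree generators used across the suite.

# Canonical unrooted bipartitions of a tree (each non-trivial bipartition as
# the lexically smaller side), via ape::prop.part -- independent of the
# package's own tree bookkeeping.
canon_bips <- function(tr) {
  tr <- ape::unroot(tr)
  p <- ape::prop.part(tr)
  labs <- attr(p, "labels")
  out <- vapply(p, function(s) {
    side <- sort(labs[s])
    other <- sort(setdiff(labs, side))
    if (length(side) <= 1 || length(other) <= 1) return(NA_character_)
    a <- paste(side, collapse = ",")
    b <- paste(other, collapse = ",")
    if (a < b) a else b
  }, character(1))
  sort(unique(out[!is.na(out)]))
}

# Brute-force minimal-spanning-node count: enumerate every node, mark it
# spanning if its leaf set holds >=1 A-side and >=1 B-side gene, count the
# spanning nodes none of whose children is spanning. Uses phangorn for the
# per-node leaf sets, independent of the package's traversals.
oracle_min_spanning <- function(tr, side) {
  n <- ape::Ntip(tr)
  desc <- phangorn::Descendants(tr, seq_len(n + tr$Nnode), "tips")
  span <- vapply(desc, function(s) {
    any(side[s] == "A", na.rm = TRUE) && any(side[s] == "B", na.rm = TRUE)
  }, logical(1))
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  cnt <- 0L
  for (v in which(span)) {
    k <- kids[[as.character(v)]]
    if (is.null(k) || !any(span[k])) cnt <- cnt + 1L
  }
  cnt
}

# Random binary gene tree with species drawn from the default scheme.
random_annotated_tree <- function(n_tips, pool = c("physcomitrella",
                                                   "selaginella", "oryza",
                                                   "arabidopsis",
                                                   "chlamydomonas")) {
  tr <- ape::rtree(n_tips)
  tr$node.label <- rep("", tr$Nnode)
  sp <- sample(pool, n_tips, replace = TRUE)
  names(sp) <- tr$tip.label
  attr(tr, "species") <- sp
  as_gene_tree(tr)
}

split_sides_of <- function(tree) {
  sp <- tip_species(tree)
  ifelse(sp == "physcomitrella", "A",
         ifelse(sp == "chlamydomonas", NA_character_, "B"))
}

# Count of internal edges (edges whose child is an internal node), read
# straight off the edge matrix.
n_internal_edges <- function(tr) {
  sum(tr$edge[, 2] > ape::Ntip(tr))
}

roundtrip <- function(tree) {
  f <- withr::local_tempfile(fileext = ".tree", .local_envir = parent.frame())
  write_gene_tree(tree, f)
  read_gene_tree(f)
}
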