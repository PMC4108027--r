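#' Read a Newick gene tree with bootstrap supports
#'
#' Reads a Newick file in the RAxML dialect: internal node labels, when
#' numeric, are bootstrap supports for the edge above the labelled node.
#' Supports may be on the percent (0--100) or proportion (0--1) scale;
#' `support_scale = "auto"` rescales proportions to percent when the largest
#' numeric internal label is at most 1.
#'
#' @param path path to a Newick file, or a literal Newick string containing
#'   `";"` (convenient for tests and examples).
#' @param support_scale one of `"auto"`, `"percent"`, `"proportion"`.
#' @return a [gene_tree][as_gene_tree].
#' @examples
#' tr <- read_gene_tree("((a:1,b:1)95:1,c:1);")
#' node_supports(tr)
#' @export
read_gene_tree <- function(path, support_scale = c("auto", "percent", "proportion")) {
  support_scale <- match.arg(support_scale)
  if (length(path) != 1 || !is.character(path)) {
    stop("`path` must be a single file path or Newick string", call. = FALSE)
  }
  txt <- if (file.exists(path)) {
    paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "")
  } else if (grepl("[();]", path)) {
    path # literal Newick
  } else {
    stop("file not found: ", path, call. = FALSE)
  }
  txt <- trimws(txt)
  check_newick_syntax(txt)

  # single-leaf degenerate tree: "a;" (ape mis-parses it)
  if (!grepl("(", txt, fixed = TRUE)) {
    lab <- sub(";\\s*$", "", txt)
    lab <- sub(":[0-9eE+.-]+$", "", lab)
    lab <- gsub("^'|'$", "", lab)
    phy <- structure(
      list(edge = matrix(integer(0), 0, 2), tip.label = lab, Nnode = 0L),
      class = "phylo", order = "cladewise"
    )
    out <- phy
    out$node.label <- character(0)
    class(out) <- c("gene_tree", "phylo")
    return(out)
  }

  phy <- withCallingHandlers(
    ape::read.tree(text = txt),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (is.null(phy)) {
    stop("Newick format error in ", path, call. = FALSE)
  }
  tree <- as_gene_tree(phy)
  sup <- node_supports(tree)
  if (any(!is.na(sup))) {
    scale_up <- switch(support_scale,
      percent = FALSE,
      proportion = TRUE,
      auto = max(sup, na.rm = TRUE) <= 1
    )
    if (scale_up) {
      keep <- !is.na(sup)
      tree$node.label[keep] <- format(sup[keep] * 100, digits = 15)
      sup <- node_supports(tree)
    }
    if (any(sup < 0 | sup > 100, na.rm = TRUE)) {
      stop("bootstrap supports outside [0, 100] after scaling: ",
           paste(stats::na.omit(sup[sup < 0 | sup > 100]), collapse = ", "),
           call. = FALSE)
    }
  }
  tree
}

# Minimal syntactic validation so malformed input fails loudly with a byte
# offset instead of ape's NULL-and-warning behaviour.
check_newick_syntax <- function(txt) {
  bytes <- charToRaw(txt)
  depth <- 0L
  in_quote <- FALSE
  semi_at <- NA_integer_
  for (i in seq_along(bytes)) {
    ch <- rawToChar(bytes[i])
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0) {
        stop("Newick format error: unbalanced ')' at byte ", i, call. = FALSE)
      }
    }
    if (ch == ";" && depth == 0L && is.na(semi_at)) semi_at <- i
  }
  if (depth > 0) {
    stop("Newick format error: ", depth, " unclosed '(' at byte ",
         length(bytes), call. = FALSE)
  }
  if (is.na(semi_at)) {
    stop("Newick format error: no terminating ';' by byte ",
         length(bytes), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a gene tree to Newick
#'
#' Supports are written as internal node labels on the 0--100 scale;
#' `read_gene_tree(write_gene_tree(t, f))` reproduces topology, leaf labels
#' and supports exactly.
#'
#' @param tree a [gene_tree][as_gene_tree].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_tree <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) == 1) {
    writeLines(paste0(quote_newick_label(tree$tip.label), ";"), path)
    return(invisible(path))
  }
  nd <- tree_nodes(tree)
  writeLines(nodes_newick(nd), path)
  invisible(path)
}

#' Taxon maps: resolving gene IDs to species codes
#'
#' A taxon map is an ordered table of rules `(pattern, species)`. A leaf
#' label is resolved by the first rule whose pattern matches the start of the
#' label (patterns are regular expressions implicitly anchored at the start,
#' so a plain prefix like `"AT"` works as a literal prefix).
#'
#' @param pattern character vector of prefixes/patterns.
#' @param species character vector of species codes, same length.
#' @return a tibble of class `taxon_map` with columns `pattern`, `species`.
#' @examples
#' tm <- taxon_map(c("AT", "Pp"), c("arabidopsis", "physcomitrella"))
#' @export
taxon_map <- function(pattern, species) {
  stopifnot(is.character(pattern), is.character(species),
            length(pattern) == length(species), length(pattern) > 0)
  out <- tibble::tibble(pattern = pattern, species = species)
  class(out) <- c("taxon_map", class(out))
  out
}

#' @rdname taxon_map
#' @param path a 2-column TSV (pattern, species), no header required; a
#'   header line `pattern<TAB>species` is tolerated.
#' @export
read_taxon_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("pattern", "species"),
                          colClasses = "character", quote = "",
                          comment.char = "#", fileEncoding = "UTF-8")
  if (nrow(df) > 0 && identical(tolower(df$pattern[1]), "pattern")) {
    df <- df[-1, , drop = FALSE]
  }
  taxon_map(df$pattern, df$species)
}

match_species <- function(labels, map) {
  out <- rep(NA_character_, length(labels))
  for (i in seq_len(nrow(map))) {
    hit <- is.na(out) & grepl(paste0("^(", map$pattern[i], ")"), labels)
    out[hit] <- map$species[i]
  }
  out
}

#' Annotate gene-tree leaves with species codes
#'
#' Applies a [taxon_map()] to every leaf label, first matching rule wins.
#'
#' @param tree a [gene_tree][as_gene_tree].
#' @param map a [taxon_map()].
#' @param strict if `TRUE` (default) an unmatched leaf is an error; otherwise
#'   unmatched leaves get species `"unknown"` and a warning lists them.
#' @return the tree with species annotations (see [tip_species()]).
#' @export
assign_taxa <- function(tree, map, strict = TRUE) {
  stopifnot(inherits(tree, "phylo"), inherits(map, "taxon_map"))
  sp <- match_species(tree$tip.label, map)
  if (anyNA(sp)) {
    bad <- tree$tip.label[is.na(sp)]
    if (strict) {
      stop("no taxon-map rule matches leaf label(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    warning("unmatched leaf label(s) assigned species 'unknown': ",
            paste(bad, collapse = ", "), call. = FALSE)
    sp[is.na(sp)] <- "unknown"
  }
  names(sp) <- tree$tip.label
  attr(tree, "species") <- sp
  as_gene_tree(tree)
}
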