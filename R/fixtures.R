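#' Default taxon map for the packaged fixtures and simulator output
#'
#' Two-letter genus/species prefixes resolving fixture gene IDs (e.g.
#' `At1`, `Pp3`, `Sm2`) to the species codes of [default_lineage_scheme()].
#'
#' @return a [taxon_map()].
#' @export
default_taxon_map <- function() {
  taxon_map(
    pattern = c("At", "Mt", "Pt", "Vv", "Cp", "Os", "Sb",
                "Sm", "Pp", "Cr", "Nh", "Pm", "Sp"),
    species = c("arabidopsis", "medicago", "populus", "vitis", "carica",
                "oryza", "sorghum", "selaginella", "physcomitrella",
                "chlamydomonas", "nitella", "penium", "spirogyra")
  )
}

#' Toy gene trees reproducing the published family-tree narratives
#'
#' Deterministic small Newick trees, one per pectin-related gene family,
#' whose clade composition follows the published figure and
#' supplementary-tree descriptions: e.g. the GAUT tree has two resolved
#' clades containing moss + lycophyte + angiosperm genes, one resolved
#' moss-free clade, and loose moss/angiosperm leaves plus the *Spirogyra*
#' algal root in a root polytomy. Clades described as resolved carry support
#' 100; described polytomies are written as multifurcations. Leaf counts
#' inside each described clade are arbitrary small numbers (the inferred
#' ancestral count does not depend on them; see the package vignette).
#'
#' Family names match [reference_family_census()], so inferred counts can be
#' joined against the published census.
#'
#' @param dir optional directory; when given, each tree is written to
#'   `<dir>/<slug>.tree` along with `taxon_map.tsv` and
#'   `lineage_scheme.tsv`.
#' @return a named list of `gene_tree` objects (unannotated; pass through
#'   [assign_taxa()] with [default_taxon_map()], or use [analyze_tree()]).
#' @examples
#' fx <- make_figure_fixtures()
#' analyze_tree(fx[["Polygalacturonases"]], default_taxon_map(),
#'              family = "Polygalacturonases")
#' @export
make_figure_fixtures <- function(dir = NULL) {
  span <- function(pp, sm, os, at) {
    sprintf("(%s,(%s,(%s,%s)100)100)100", pp, sm, os, at)
  }
  newicks <- c(
    # two moss+tracheophyte clades, a moss-free clade, loose moss/angiosperm
    # leaves and the algal root in one root polytomy
    "Galacturonosyltransferases (GAUTs)" = paste0(
      "(Sp1,",
      "((Pp1,Pp2)100,(Sm1,(Os1,At1)100)100)100,",
      "((Pp3,Pp4)100,(Sm2,(Os2,At2)100)100)100,",
      "(Sm3,(Os3,(At3,At4)100)100)100,",
      "Pp7,Pp8,At7,Os5);"
    ),
    # four spanning clades; loose moss and lycophyte leaves in the root
    # polytomy with the chlorophyte algal root
    "Polygalacturonases" = paste0(
      "(Cr1,",
      span("Pp1", "Sm1", "Os1", "At1"), ",",
      span("Pp2", "Sm2", "Os2", "At2"), ",",
      span("Pp3", "Sm3", "Os3", "At3"), ",",
      span("Pp4", "Sm4", "Os4", "At4"), ",",
      "Pp9,Sm9);"
    ),
    # two spanning clades inside the root polytomy (with the algal root and
    # loose moss/tracheophyte leaves), a third resolved spanning clade, and a
    # moss+lycophyte subclade sister to an angiosperm-only polytomy
    "Pectin methylesterases" = paste0(
      "(Pm1,",
      span("Pp1", "Sm1", "Os1", "At1"), ",",
      span("Pp2", "Sm2", "Os2", "At2"), ",",
      span("Pp3", "Sm3", "Os3", "At3"), ",",
      "((Pp4,Sm4)100,(At6,At7,Os6,Mt1)100)100,",
      "Pp5,At5,Os7);"
    ),
    # two spanning clades and one angiosperm-only clade; no algal root
    "HG methyltransferases" = paste0(
      "(", span("Pp1", "Sm1", "Os1", "At1"), ",",
      span("Pp2", "Sm2", "Os2", "At2"), ",",
      "((At3,Mt1)100,(Os3,Sb1)100)100);"
    ),
    # one small spanning clade resolved from the (also spanning) rest
    "Pectate lyase-like proteins" =
      "((Pp1,(Sm1,At1)100)100,(Pp2,Pp3,Os1,At2,Sm2)100);",
    # all moss genes monophyletic, sister to all tracheophyte genes
    "UDP-Glucuronic acid epimerases" = paste0(
      "(Cr1,((Pp1,(Pp2,Pp3)100)100,",
      "(Sm1,(Os1,(At1,Mt1)100)100)100)100);"
    ),
    # as above, with a three-species algal outgroup clade
    "UDP-Rhamnose synthases" = paste0(
      "((Cr1,(Sp1,Pm1)100)100,((Pp1,(Pp2,Pp3)100)100,",
      "(Sm1,(Os1,(At1,At2)100)100)100)100);"
    ),
    # unrooted and poorly resolved, moss genes grouped in one clade
    "GAUT-like proteins (GATLs)" =
      "((Pp1,Pp2,Pp3)100,Os1,At1,Sm1,Vv1,(At2,Mt1)100);",
    # moss clade sister to tracheophytes; no algal root
    "Galactan galactosyltransferases" = paste0(
      "((Pp1,(Pp2,(Pp3,Pp4)100)100)100,",
      "(Sm1,((Os1,Sb1)100,(At1,(At2,Mt1)100)100)100)100);"
    ),
    "RG-II xylosyltransferases" = paste0(
      "(Nh1,(Pp1,(Sm1,((Os1,Sb1)100,(At1,Vv1)100)100)100)100);"
    ),
    # a single moss gene, no lycophyte
    "Pectin acetylesterases" = paste0(
      "(Cr1,(Pp1,((Os1,Sb1)100,((At1,At2)100,Mt1)100)100)100);"
    ),
    "Pectin acetyltransferases" = paste0(
      "(Cr1,((Pp1,(Pp2,Pp3)100)100,",
      "(Sm1,(Os1,(At1,Mt1)100)100)100)100);"
    ),
    # families with no moss members: ancestral count is ND
    "XGA xylosyltransferases" =
      "((At1,At2)100,(Os1,(Vv1,Mt1)100)100);",
    "RG-I arabinosyltransferases" =
      "((Pm1,Nh1)100,((At1,At2)100,(Os1,Sb1)100)100);",
    "Pectin methylesterase inhibitors (PMEIs)" =
      "((At1,Mt1)100,At2);",
    "Polygalacturonase inhibitor proteins (PGIPs)" =
      "((Os1,Sb1)100,(At1,(At2,Mt1)100)100);"
  )
  trees <- lapply(newicks, read_gene_tree)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    slugs <- fixture_slugs(names(trees))
    for (i in seq_along(trees)) {
      write_gene_tree(trees[[i]], file.path(dir, paste0(slugs[i], ".tree")))
    }
    tm <- default_taxon_map()
    utils::write.table(as.data.frame(tm), file.path(dir, "taxon_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    sc <- default_lineage_scheme()
    utils::write.table(as.data.frame(sc), file.path(dir, "lineage_scheme.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  trees
}

fixture_slugs <- function(x) {
  s <- tolower(gsub("[^A-Za-z0-9]+", "_", x))
  gsub("^_|_$", "", s)
}
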