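#' Lineage groups recognised by the package
#'
#' Species are binned into broad land-plant lineages plus an algal outgroup
#' bin. Tracheophytes (vascular plants) are the union of `lycophyte`,
#' `monocot`, `eudicot` and `basal_angiosperm`.
#'
#' @export
lineage_groups <- c("bryophyte", "lycophyte", "monocot", "eudicot",
                    "basal_angiosperm", "algal_outgroup", "other")

#' Lineage schemes: species to lineage-group assignments
#'
#' A lineage scheme maps species codes to [lineage_groups]. The default
#' scheme covers the ten genomes of the reference species tree (seven
#' angiosperms, the lycophyte *Selaginella moellendorffii*, the moss
#' *Physcomitrella patens*, the chlorophyte *Chlamydomonas reinhardtii*) plus
#' three charophyte algae used as extra outgroups (*Nitella hyalina*,
#' *Penium margaritaceum*, *Spirogyra pratensis*).
#'
#' @param species character vector of species codes.
#' @param group character vector of lineage groups (see [lineage_groups]).
#' @return a tibble of class `lineage_scheme` with columns `species`,
#'   `group`.
#' @examples
#' default_lineage_scheme()
#' @export
lineage_scheme <- function(species, group) {
  stopifnot(is.character(species), is.character(group),
            length(species) == length(group))
  bad <- setdiff(unique(group), lineage_groups)
  if (length(bad) > 0) {
    stop("unknown lineage group(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(lineage_groups, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(species)) {
    stop("duplicate species in scheme: ",
         paste(unique(species[duplicated(species)]), collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(species = species, group = group)
  class(out) <- c("lineage_scheme", class(out))
  out
}

#' @rdname lineage_scheme
#' @export
default_lineage_scheme <- function() {
  lineage_scheme(
    species = c("arabidopsis", "medicago", "populus", "carica", "vitis",
                "oryza", "sorghum",
                "selaginella", "physcomitrella",
                "chlamydomonas", "nitella", "penium", "spirogyra"),
    group = c(rep("eudicot", 5), rep("monocot", 2),
              "lycophyte", "bryophyte",
              rep("algal_outgroup", 4))
  )
}

#' @rdname lineage_scheme
#' @param path TSV with columns (species, group); a header line is tolerated.
#' @export
read_lineage_scheme <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("species", "group"),
                          colClasses = "character", quote = "",
                          comment.char = "#", fileEncoding = "UTF-8")
  if (nrow(df) > 0 && identical(tolower(df$species[1]), "species")) {
    df <- df[-1, , drop = FALSE]
  }
  lineage_scheme(df$species, df$group)
}

#' Lineage group of a species
#'
#' @param species character vector of species codes.
#' @param scheme a [lineage_scheme()].
#' @return character vector of lineage groups.
#' @export
lineage_of <- function(species, scheme = default_lineage_scheme()) {
  stopifnot(inherits(scheme, "lineage_scheme"))
  idx <- match(species, scheme$species)
  if (anyNA(idx)) {
    stop("species not in lineage scheme: ",
         paste(unique(species[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  scheme$group[idx]
}

#' The focal ancestral split
#'
#' The inference counts gene copies in the common ancestor of two disjoint
#' lineage sets A and B. The default is the deepest split among the land
#' plants sampled here: bryophytes (the moss) versus tracheophytes
#' (lycophyte + monocots + eudicots). Sets may mix lineage groups and
#' individual species codes; `algal_outgroup` species may not be members of
#' either side.
#'
#' @param set_a,set_b character vectors of lineage groups and/or species
#'   codes; disjoint and non-empty.
#' @return a list of class `focal_split` with elements `set_a`, `set_b`.
#' @examples
#' focal_split() # moss vs tracheophytes
#' focal_split("monocot", "eudicot") # angiosperm-wide clades
#' @export
focal_split <- function(set_a = "bryophyte",
                        set_b = c("lycophyte", "monocot", "eudicot",
                                  "basal_angiosperm")) {
  stopifnot(is.character(set_a), is.character(set_b),
            length(set_a) > 0, length(set_b) > 0)
  if (length(intersect(set_a, set_b)) > 0) {
    stop("focal split sides must be disjoint; shared: ",
         paste(intersect(set_a, set_b), collapse = ", "), call. = FALSE)
  }
  if ("algal_outgroup" %in% c(set_a, set_b)) {
    stop("algal_outgroup cannot be a member of the focal split", call. = FALSE)
  }
  structure(list(set_a = set_a, set_b = set_b), class = "focal_split")
}

#' @export
print.focal_split <- function(x, ...) {
  cat("<focal_split> A = {", paste(x$set_a, collapse = ", "),
      "}  vs  B = {", paste(x$set_b, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

# Side of the split for each species code: "A", "B" or NA (outgroup / other /
# not named by the split). A side term matches either the species code itself
# or its lineage group. Leaves labelled "unknown" (lenient taxon mapping) sit
# outside the split.
split_side <- function(species, scheme, split) {
  known <- species %in% scheme$species | species == "unknown"
  if (!all(known)) {
    stop("species not in lineage scheme: ",
         paste(unique(species[!known]), collapse = ", "), call. = FALSE)
  }
  grp <- rep("other", length(species))
  in_scheme <- species %in% scheme$species
  grp[in_scheme] <- lineage_of(species[in_scheme], scheme)
  side <- rep(NA_character_, length(species))
  in_set <- function(set) species %in% set | grp %in% set
  a <- in_set(split$set_a)
  b <- in_set(split$set_b)
  if (any(a & b)) {
    stop("species matched by both sides of the focal split: ",
         paste(unique(species[a & b]), collapse = ", "), call. = FALSE)
  }
  side[a] <- "A"
  side[b] <- "B"
  side[grp == "algal_outgroup"] <- NA_character_
  side
}
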