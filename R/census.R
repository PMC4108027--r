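#' Per-family, per-species gene census
#'
#' Counts gene IDs per (family, species) from long-format gene lists,
#' resolving species through a [taxon_map()], and attaches the inferred
#' minimum ancestral copy number per family when results are supplied.
#'
#' @param gene_lists a data frame with columns `family`, `gene_id` (long
#'   format, one row per gene).
#' @param map a [taxon_map()].
#' @param results optional named list of `ancestral_count` objects (names =
#'   family) or a data frame with columns `family`, `min_copies` (`NA` = ND).
#' @param strict if `TRUE` an unmapped gene ID is an error; otherwise such
#'   genes count under species `"unknown"`.
#' @return a tibble of class `family_table`: one row per family, one count
#'   column per species code, plus `min_ancestral` (integer, `NA` = ND) and
#'   `detected_in_moss` (any `physcomitrella` gene). Duplicate gene IDs
#'   within a family are dropped with a warning.
#' @export
build_family_table <- function(gene_lists, map, results = NULL, strict = TRUE) {
  stopifnot(is.data.frame(gene_lists),
            all(c("family", "gene_id") %in% names(gene_lists)))
  gl <- tibble::as_tibble(gene_lists)
  dup <- duplicated(gl[c("family", "gene_id")])
  if (any(dup)) {
    warning(sum(dup), " duplicate gene ID(s) within a family dropped",
            call. = FALSE)
    gl <- gl[!dup, , drop = FALSE]
  }
  sp <- match_species(gl$gene_id, map)
  if (anyNA(sp)) {
    if (strict) {
      stop("gene ID(s) matching no taxon-map rule: ",
           paste(utils::head(unique(gl$gene_id[is.na(sp)]), 10), collapse = ", "),
           call. = FALSE)
    }
    sp[is.na(sp)] <- "unknown"
  }
  gl$species <- sp
  wide <- gl |>
    dplyr::count(.data$family, .data$species) |>
    tidyr::pivot_wider(names_from = "species", values_from = "n",
                       values_fill = 0L)
  wide$min_ancestral <- extract_min_copies(wide$family, results)
  moss_col <- intersect("physcomitrella", names(wide))
  wide$detected_in_moss <- if (length(moss_col)) wide$physcomitrella > 0 else FALSE
  as_family_table(wide)
}

extract_min_copies <- function(families, results) {
  if (is.null(results)) return(rep(NA_integer_, length(families)))
  if (is.data.frame(results)) {
    idx <- match(families, results$family)
    return(as.integer(results$min_copies[idx]))
  }
  vapply(families, function(f) {
    r <- results[[f]]
    if (is.null(r)) NA_integer_ else as.integer(r$min_copies)
  }, integer(1), USE.NAMES = FALSE)
}

#' @rdname build_family_table
#' @param x a data frame with a `family` column and numeric per-species
#'   count columns; optional `min_ancestral` (NA = ND).
#' @export
as_family_table <- function(x) {
  stopifnot(is.data.frame(x), "family" %in% names(x))
  out <- tibble::as_tibble(x)
  num <- census_count_cols(out)
  for (cc in num) {
    if (any(out[[cc]] < 0, na.rm = TRUE)) {
      stop("negative count in column ", cc, call. = FALSE)
    }
    out[[cc]] <- as.integer(out[[cc]])
  }
  if (!"min_ancestral" %in% names(out)) out$min_ancestral <- NA_integer_
  if (!"detected_in_moss" %in% names(out) && "physcomitrella" %in% names(out)) {
    out$detected_in_moss <- out$physcomitrella > 0
  }
  class(out) <- unique(c("family_table", class(out)))
  out
}

census_count_cols <- function(x) {
  setdiff(names(x)[vapply(x, is.numeric, logical(1))],
          c("min_ancestral"))
}

#' Census summary: totals row and detection counts
#'
#' Reproduces the standard summary of a family census: total gene count per
#' species, the total of inferred ancestral copies (ND families contribute 0
#' and are counted separately in `n_nd_families`), and how many families have
#' at least one gene in a chosen species.
#'
#' @param table a `family_table`.
#' @param detect_species species whose presence defines "detected";
#'   default `"physcomitrella"`.
#' @return a list of class `census_summary`: `species_totals` (named integer
#'   vector), `ancestral_total`, `n_nd_families`, `n_families`,
#'   `n_detected_families`, `detect_species`.
#' @export
summarize_census <- function(table, detect_species = "physcomitrella") {
  stopifnot(inherits(table, "family_table"))
  cols <- census_count_cols(table)
  totals <- vapply(table[cols], function(x) sum(x, na.rm = TRUE), numeric(1))
  nd <- is.na(table$min_ancestral)
  detected <- if (detect_species %in% cols) {
    sum(table[[detect_species]] > 0, na.rm = TRUE)
  } else 0L
  structure(
    list(
      species_totals = as.integer(round(totals)) |> stats::setNames(cols),
      ancestral_total = sum(table$min_ancestral[!nd]),
      n_nd_families = sum(nd),
      n_families = nrow(table),
      n_detected_families = as.integer(detected),
      detect_species = detect_species
    ),
    class = "census_summary"
  )
}

#' @export
print.census_summary <- function(x, ...) {
  cat("<census_summary>", x$n_families, "families\n")
  cat("  gene totals:",
      paste0(names(x$species_totals), " = ", x$species_totals, collapse = ", "),
      "\n")
  cat(sprintf("  ancestral copies total: %d (%d ND famil%s contributing 0)\n",
              x$ancestral_total, x$n_nd_families,
              if (x$n_nd_families == 1) "y" else "ies"))
  cat(sprintf("  families with >=1 %s gene: %d of %d\n",
              x$detect_species, x$n_detected_families, x$n_families))
  invisible(x)
}

#' @rdname summarize_census
#' @export
glance.census_summary <- function(x, ...) {
  tibble::tibble(
    n_families = x$n_families,
    ancestral_total = x$ancestral_total,
    n_nd_families = x$n_nd_families,
    n_detected_families = x$n_detected_families,
    detect_species = x$detect_species
  )
}

#' @rdname summarize_census
#' @export
glance.family_table <- function(x, ...) glance(summarize_census(x))

#' Reference census of the 16 pectin-related gene families
#'
#' The published per-family census this package was validated against:
#' gene counts for *Arabidopsis thaliana* and *Physcomitrella patens* and the
#' reported minimum copy number in the moss/tracheophyte common ancestor
#' (ND where no moss member was detected), transcribed into
#' `inst/extdata/pectin_family_census.tsv`.
#'
#' @return a `family_table` with 16 rows.
#' @examples
#' summarize_census(reference_family_census())
#' @export
reference_family_census <- function() {
  path <- system.file("extdata", "pectin_family_census.tsv",
                      package = "copymin", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          fileEncoding = "UTF-8")
  df$min_ancestral <- suppressWarnings(as.integer(df$min_ancestral))
  as_family_table(df)
}

#' Write a family table as TSV (ND spelled out)
#'
#' @param table a `family_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_family_table <- function(table, path) {
  out <- as.data.frame(table)
  out$min_ancestral <- ifelse(is.na(out$min_ancestral), "ND",
                              as.character(out$min_ancestral))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
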