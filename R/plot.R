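#' Plot the clade evidence behind an ancestral count
#'
#' Bar chart of the counted spanning clades and polytomy bonus nodes of an
#' [min_ancestral_copies()] result, split by side of the focal split, with
#' uncounted B-only clades shown greyed for context.
#'
#' @param object an `ancestral_count`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ancestral_count <- function(object, ...) {
  rep <- clade_report(object)
  if (nrow(rep) == 0) {
    return(
      ggplot2::ggplot() +
        ggplot2::annotate("text", x = 0, y = 0,
                          label = "ND: family absent on one side of the split") +
        ggplot2::theme_void()
    )
  }
  long <- rep |>
    dplyr::mutate(clade = paste0(.data$type, " @", .data$node)) |>
    tidyr::pivot_longer(c("n_side_a", "n_side_b"),
                        names_to = "side", values_to = "n_genes") |>
    dplyr::mutate(side = ifelse(.data$side == "n_side_a",
                                "A side", "B side"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$clade, y = .data$n_genes,
                               fill = .data$side,
                               alpha = .data$counted)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                guide = "none") +
    ggplot2::labs(
      x = NULL, y = "genes in clade",
      title = sprintf("Minimum ancestral copies: %s",
                      if (object$nd) "ND" else object$min_copies),
      subtitle = sprintf("%d spanning clade(s) + %d polytomy bonus (mode = %s)",
                         nrow(object$spanning_clades),
                         nrow(object$bonus_nodes), object$mode)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a family census table
#'
#' Dot plot of gene counts per family and species, ordered by total family
#' size; ND families are marked.
#'
#' @param object a `family_table`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.family_table <- function(object, ...) {
  cols <- census_count_cols(object)
  long <- object |>
    tidyr::pivot_longer(dplyr::all_of(cols),
                        names_to = "species", values_to = "n_genes") |>
    dplyr::mutate(family = stats::reorder(.data$family, .data$n_genes, sum))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$n_genes, y = .data$family,
                               colour = .data$species)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = "genes", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
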