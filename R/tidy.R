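# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a gene scan
#'
#' One row per (gene, blocked metabolite) pair; genes with empty footprints
#' are dropped.
#'
#' @param x a [scan_all_genes()] result.
#' @param ... unused.
#' @return A tibble with columns `gene`, `metabolite`.
#' @exportS3Method generics::tidy
tidy.gene_scan <- function(x, ...) {
  out <- tidyr::unnest(dplyr::select(tibble::as_tibble(x), "gene", "blocked"), "blocked")
  dplyr::rename(out, metabolite = "blocked")
}

#' One-row summary of a gene scan
#'
#' @param x a [scan_all_genes()] result.
#' @param ... unused.
#' @return A tibble with gene counts, the empty-footprint fraction and the
#'   native blocked count.
#' @exportS3Method generics::glance
glance.gene_scan <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_nonempty = sum(x$n_blocked > 0),
    fraction_empty = mean(x$n_blocked == 0),
    n_native_blocked = nrow(attr(x, "native_blocked")),
    epsilon = attr(x, "epsilon")
  )
}

#' Tidy a footprint ranking
#'
#' @param x a [rank_against_reference()] result.
#' @param ... unused.
#' @return The ranking as a plain tibble.
#' @exportS3Method generics::tidy
tidy.footprint_ranking <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a footprint ranking
#'
#' @param x a [rank_against_reference()] result.
#' @param ... unused.
#' @return A tibble with the reference label and size, candidate counts and
#'   the top similarity.
#' @exportS3Method generics::glance
glance.footprint_ranking <- function(x, ...) {
  tibble::tibble(
    reference = attr(x, "reference"),
    n_reference = attr(x, "n_reference"),
    n_genes = nrow(x),
    n_nonempty = sum(x$n_blocked > 0),
    top_gene = if (nrow(x)) x$gene[1] else NA_character_,
    top_jc = if (nrow(x)) x$jc[1] else NA_real_
  )
}

#' Plot the distribution of footprint similarities
#'
#' Histogram of per-gene Jaccard coefficients against the reference
#' deficiency, over genes with a non-empty footprint.
#'
#' @param object a [rank_against_reference()] result.
#' @param binwidth histogram bin width.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.footprint_ranking <- function(object, binwidth = 0.05, ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$n_blocked > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$jc)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey35", colour = "white") +
    ggplot2::labs(
      x = "Jaccard coefficient vs reference deficiency",
      y = "genes",
      title = paste0("Footprint similarity to ", attr(object, "reference"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a production profile
#'
#' @param object a [production_profile()].
#' @param ... unused.
#' @return A ggplot object (metabolites ordered by production).
#' @exportS3Method ggplot2::autoplot
autoplot.production_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$metabolite <- stats::reorder(df$metabolite, df$production)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metabolite, y = .data$production)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "maximal production rate (flux units)",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
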