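# Footprint comparison: Jaccard coefficient on blocked sets, generalized
# Jaccard on proportional-reduction vectors, ranking of knockout footprints
# against a reference deficiency, and the JC histogram.

#' Jaccard coefficient of two id sets
#'
#' `|A intersect B| / |A union B|`. Two empty sets compare as 0, with the
#' `empty` attribute flagged, since similarity of nothing to nothing is not
#' evidence of agreement.
#'
#' @param A,B character vectors (or `blocked_set` tibbles with an `id`
#'   column); duplicates ignored.
#' @return Value in \[0, 1\]; attribute `empty = TRUE` when both sets are
#'   empty.
#' @export
jaccard <- function(A, B) {
  if (is.data.frame(A)) A <- A$id
  if (is.data.frame(B)) B <- B$id
  A <- unique(as.character(A))
  B <- unique(as.character(B))
  u <- length(union(A, B))
  if (u == 0) return(structure(0, empty = TRUE))
  length(intersect(A, B)) / u
}

#' Generalized Jaccard coefficient of two reduction vectors
#'
#' `sum_i min(x_i, y_i) / sum_i max(x_i, y_i)` over per-metabolite
#' proportional reductions of maximal production rates. For binary vectors
#' this reduces to the plain Jaccard coefficient of their supports.
#'
#' @param x,y numeric vectors on the same metabolite index set, entries in
#'   \[0, 1\]. Named vectors or [reduction_profile()] tibbles are aligned by
#'   metabolite id; mismatched index sets are an error.
#' @return Value in \[0, 1\]; attribute `empty = TRUE` when both vectors are
#'   all-zero.
#' @export
generalized_jaccard <- function(x, y) {
  as_red <- function(v) {
    if (is.data.frame(v)) stats::setNames(v$reduction, v$metabolite) else v
  }
  x <- as_red(x)
  y <- as_red(y)
  if (!is.null(names(x)) && !is.null(names(y))) {
    if (!setequal(names(x), names(y))) {
      stop("reduction vectors are indexed by different metabolite sets", call. = FALSE)
    }
    y <- y[names(x)]
  } else if (length(x) != length(y)) {
    stop("reduction vectors have different lengths", call. = FALSE)
  }
  if (any(x < -1e-12 | x > 1 + 1e-12) || any(y < -1e-12 | y > 1 + 1e-12)) {
    stop("reductions must lie in [0, 1]", call. = FALSE)
  }
  den <- sum(pmax(x, y))
  if (den == 0) return(structure(0, empty = TRUE))
  sum(pmin(x, y)) / den
}

#' Rank gene-knockout footprints against a reference deficiency
#'
#' For every scanned gene, compares its blocked-metabolite footprint with
#' the reference footprint by Jaccard coefficient and, when production
#' profiles are available, by generalized Jaccard over proportional
#' reduction vectors. Results are sorted by JC descending, ties broken by
#' JCg then gene id. Marker metabolites (e.g. the SAM and BH4 species) are
#' flagged per gene when present in its footprint.
#'
#' The generalized coefficient is computed over metabolites producible in
#' the native model only: natively blocked metabolites carry reduction 0
#' under every condition and would merely cancel.
#'
#' @param scan a [scan_all_genes()] result (with `profiles = TRUE` if JCg is
#'   wanted).
#' @param reference the reference footprint: a `blocked_set` delta, e.g.
#'   from [deficiency_delta()].
#' @param reference_profile optional perturbed [production_profile()] of the
#'   reference condition (enables JCg).
#' @param markers metabolite ids to flag (`has_<id>` columns).
#' @return A `footprint_ranking` tibble: `gene`, `jc`, `jcg`, `n_blocked`,
#'   `n_intersection`, `n_union`, marker flags.
#' @export
rank_against_reference <- function(scan, reference, reference_profile = NULL,
                                   markers = character()) {
  stopifnot(inherits(scan, "gene_scan"))
  ref_hash <- attr(reference, "model_hash")
  if (!is.null(ref_hash) && !identical(ref_hash, attr(scan, "model_hash"))) {
    stop("reference and scan were computed on different models (hash mismatch)",
         call. = FALSE)
  }
  ref_ids <- reference$id
  native_prof <- attr(scan, "native_profile")
  epsilon <- attr(scan, "epsilon")

  ref_red <- NULL
  producible <- NULL
  if (!is.null(reference_profile) && "profile" %in% names(scan)) {
    producible <- native_prof$metabolite[!is_flux_zero(native_prof$production, epsilon)]
    ref_red_full <- reduction_profile(native_prof, reference_profile, epsilon)
    ref_red <- stats::setNames(ref_red_full$reduction, ref_red_full$metabolite)[producible]
  }

  rows <- purrr::map(seq_len(nrow(scan)), function(i) {
    ids <- scan$blocked[[i]]
    jc <- jaccard(ids, ref_ids)
    jcg <- NA_real_
    if (!is.null(ref_red)) {
      red_full <- reduction_profile(native_prof, scan$profile[[i]], epsilon)
      red <- stats::setNames(red_full$reduction, red_full$metabolite)[producible]
      jcg <- as.numeric(generalized_jaccard(red, ref_red))
    }
    out <- tibble::tibble(
      gene = scan$gene[i],
      jc = as.numeric(jc),
      jcg = jcg,
      n_blocked = length(ids),
      n_intersection = length(intersect(ids, ref_ids)),
      n_union = length(union(ids, ref_ids))
    )
    for (mk in markers) out[[paste0("has_", mk)]] <- mk %in% ids
    out
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, dplyr::desc(.data$jc),
                        dplyr::desc(dplyr::coalesce(.data$jcg, -Inf)), .data$gene)
  structure(out, class = c("footprint_ranking", class(out)),
            model = attr(scan, "model"), model_hash = attr(scan, "model_hash"),
            reference = attr(reference, "label"), markers = markers,
            n_reference = length(ref_ids))
}

#' Histogram of Jaccard coefficients
#'
#' Distribution of footprint similarities across genes, the ranking's
#' summary view. Genes with empty footprints can be excluded, matching the
#' convention of comparing only genes with a non-empty blocked set.
#'
#' @param ranking a [rank_against_reference()] result.
#' @param binwidth bin width on \[0, 1\].
#' @param nonempty_only drop genes with empty footprints first?
#' @return Tibble with columns `bin_lo`, `bin_hi`, `count`.
#' @export
jc_histogram <- function(ranking, binwidth = 0.05, nonempty_only = TRUE) {
  x <- if (nonempty_only) ranking$jc[ranking$n_blocked > 0] else ranking$jc
  breaks <- seq(0, 1, by = binwidth)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  cnt <- if (length(x)) {
    tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
             nbins = length(breaks) - 1L)
  } else {
    integer(length(breaks) - 1L)
  }
  tibble::tibble(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L], count = cnt)
}
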