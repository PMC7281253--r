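# Blocked-metabolite / blocked-reaction sets, perturbation deltas, the
# all-gene scan, and production profiles.

new_blocked_set <- function(ids, kind, model, label, epsilon) {
  out <- tibble::tibble(id = sort(unique(as.character(ids))))
  structure(out,
            class = c("blocked_set", class(out)),
            kind = kind, model = model$id, model_hash = model_hash(model),
            label = label, epsilon = epsilon)
}

#' @export
print.blocked_set <- function(x, ...) {
  cat("<blocked_set> ", attr(x, "kind"), "s, model=", attr(x, "model"),
      ", perturbation=", attr(x, "label"), ", n=", nrow(x), "\n", sep = "")
  NextMethod()
}

#' Blocked metabolites of a model state
#'
#' A metabolite is blocked when the maximal flux of its irreversible sink
#' reaction is zero: no steady-state flux distribution synthesizes it de
#' novo from the medium. Unlike the flux-sum definition (see
#' [is_blocked_fluxsum()]), this catches cofactors that a cycle regenerates
#' but that cannot be replenished — the case that matters when pools are
#' diluted by cell division.
#'
#' @param model a [metabolic_model()]; sink-augmented internally if needed.
#' @param epsilon zero-flux tolerance.
#' @param label perturbation label recorded in the result.
#' @return A `blocked_set` tibble (column `id`) with provenance attributes.
#' @export
blocked_metabolites <- function(model, epsilon = flux_epsilon(), label = "native") {
  base <- model
  if (!has_sinks(model)) model <- add_sinks(model)
  prod <- production_profile(model, label = label)
  new_blocked_set(prod$metabolite[is_flux_zero(prod$production, epsilon)],
                  "metabolite", base, label, epsilon)
}

#' Blocked reactions of a model state
#'
#' Reactions whose maximum absolute flux is zero, from flux variability
#' analysis. Computed on the bare network by default: instrumentation sinks
#' are artificial drains that would unblock dead-end-limited reactions, so
#' they are removed first unless `with_sinks = TRUE`.
#'
#' @param model a [metabolic_model()].
#' @param epsilon zero-flux tolerance.
#' @param with_sinks keep sink reactions in place while testing?
#' @param label perturbation label recorded in the result.
#' @return A `blocked_set` tibble of reaction ids.
#' @export
blocked_reactions <- function(model, epsilon = flux_epsilon(), with_sinks = FALSE,
                              label = "native") {
  if (!with_sinks && has_sinks(model)) {
    model$reactions <- model$reactions[!model$reactions$sink, ]
  }
  ranges <- fva(model)
  blocked <- is_flux_zero(ranges$min, epsilon) & is_flux_zero(ranges$max, epsilon)
  # instrumentation sinks are never reported as blocked metabolism
  blocked <- blocked & !model$reactions$sink[match(ranges$reaction, model$reactions$id)]
  new_blocked_set(ranges$reaction[blocked], "reaction", model, label, epsilon)
}

#' Per-metabolite maximal production rates
#'
#' The full map metabolite -> maximal sink flux for one model state; the
#' raw material for proportional-reduction vectors and the generalized
#' Jaccard coefficient.
#'
#' @param model a sink-augmented [metabolic_model()] (augmented internally
#'   if needed).
#' @param label perturbation label recorded in the result.
#' @return A `production_profile` tibble with columns `metabolite`,
#'   `production`.
#' @export
production_profile <- function(model, label = "native") {
  base_hash_model <- model
  if (!has_sinks(model)) model <- add_sinks(model)
  mets <- model$metabolites$id
  S <- stoich_matrix(model)
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  n <- nrow(model$reactions)
  sink_pos <- match(sink_id(mets), model$reactions$id)
  vals <- purrr::map_dbl(sink_pos, function(j) {
    obj <- numeric(n)
    obj[j] <- 1
    res <- lp_solve(obj, S, lb, ub, sense = "max")
    if (res$status != "optimal") {
      stop("production LP ended with status ", res$status, call. = FALSE)
    }
    res$objective
  })
  out <- tibble::tibble(metabolite = mets, production = pmax(vals, 0))
  structure(out, class = c("production_profile", class(out)),
            model = model$id, model_hash = model_hash(base_hash_model),
            label = label)
}

#' Proportional production reductions between two model states
#'
#' For each metabolite, `(native - perturbed) / native`, clamped to
#' \[0, 1\], and defined as 0 when the metabolite is not producible natively
#' (a natively blocked metabolite cannot be reduced further).
#'
#' @param native,perturbed [production_profile()]s on the same metabolite
#'   set.
#' @param epsilon zero-flux tolerance.
#' @return Tibble with columns `metabolite`, `reduction`.
#' @export
reduction_profile <- function(native, perturbed, epsilon = flux_epsilon()) {
  if (!identical(native$metabolite, perturbed$metabolite)) {
    stop("production profiles cover different metabolite sets", call. = FALSE)
  }
  red <- ifelse(native$production <= epsilon, 0,
                pmin(pmax((native$production - perturbed$production) / native$production, 0), 1))
  tibble::tibble(metabolite = native$metabolite, reduction = red)
}

#' Metabolites newly blocked by a gene knockout
#'
#' The knockout's metabolic footprint: the set difference between blocked
#' metabolites after and before knocking out the genes.
#'
#' @param model a [metabolic_model()].
#' @param genes gene ids to knock out together.
#' @param epsilon zero-flux tolerance.
#' @param native optional precomputed native [blocked_metabolites()] (reused
#'   across many deltas by [scan_all_genes()]).
#' @return A `blocked_set` of newly blocked metabolite ids.
#' @export
knockout_delta <- function(model, genes, epsilon = flux_epsilon(), native = NULL) {
  if (is.null(native)) native <- blocked_metabolites(model, epsilon)
  after <- blocked_metabolites(knockout_genes(model, genes), epsilon,
                               label = paste0("ko:", paste(genes, collapse = "+")))
  delta_set(after, native)
}

#' Metabolites newly blocked by a cofactor deficiency
#'
#' Models deficiency of a metabolite pool (e.g. all intracellular folate
#' forms) by blocking every reaction consuming any member of the pool, then
#' takes the after-minus-before blocked-set difference.
#'
#' @param model a [metabolic_model()].
#' @param targets metabolite ids forming the pool.
#' @param epsilon zero-flux tolerance.
#' @param native optional precomputed native blocked set.
#' @inheritParams block_consumers
#' @return A `blocked_set` of newly blocked metabolite ids.
#' @export
deficiency_delta <- function(model, targets, epsilon = flux_epsilon(), native = NULL,
                             exclude_reactions = character(),
                             exclude_transporters = FALSE) {
  if (is.null(native)) native <- blocked_metabolites(model, epsilon)
  pert <- block_consumers(model, targets, exclude_reactions = exclude_reactions,
                          exclude_transporters = exclude_transporters)
  after <- blocked_metabolites(pert, epsilon,
                               label = paste0("deficiency:", paste(targets, collapse = "+")))
  delta_set(after, native)
}

#' Full deficiency footprint: blocked delta plus production profile
#'
#' Convenience wrapper around [block_consumers()] that returns everything a
#' footprint comparison needs: the newly blocked metabolites and the
#' perturbed per-metabolite production profile (for generalized-Jaccard
#' ranking), computed on one shared model state.
#'
#' @inheritParams deficiency_delta
#' @return List with elements `delta` (a `blocked_set`), `profile` (the
#'   perturbed [production_profile()]) and `native` (the native blocked
#'   set).
#' @export
deficiency_footprint <- function(model, targets, epsilon = flux_epsilon(),
                                 exclude_reactions = character(),
                                 exclude_transporters = FALSE) {
  native <- blocked_metabolites(model, epsilon)
  pert <- block_consumers(model, targets, exclude_reactions = exclude_reactions,
                          exclude_transporters = exclude_transporters)
  label <- paste0("deficiency:", paste(targets, collapse = "+"))
  profile <- production_profile(add_sinks_if_absent(pert), label = label)
  after <- new_blocked_set(
    profile$metabolite[is_flux_zero(profile$production, epsilon)],
    "metabolite", model, label, epsilon)
  list(delta = delta_set(after, native), profile = profile, native = native)
}

add_sinks_if_absent <- function(model) {
  if (has_sinks(model)) model else add_sinks(model)
}

delta_set <- function(after, native) {
  ids <- setdiff(after$id, native$id)
  out <- tibble::tibble(id = sort(ids))
  structure(out, class = class(after),
            kind = attr(after, "kind"), model = attr(after, "model"),
            model_hash = attr(native, "model_hash"),
            label = attr(after, "label"), epsilon = attr(after, "epsilon"))
}

#' Blocked-metabolite footprint of every single-gene knockout
#'
#' Computes [knockout_delta()] for each gene. The native blocked set is
#' computed once and reused; genes disabling the same reaction set share one
#' evaluation, and genes disabling nothing short-circuit to an empty
#' footprint (both verified against naive per-gene evaluation in the test
#' suite). Optionally also returns per-gene production profiles for
#' generalized-Jaccard ranking.
#'
#' @param model a [metabolic_model()].
#' @param epsilon zero-flux tolerance.
#' @param profiles also compute per-gene perturbed production profiles?
#' @param dedupe share evaluations between genes with identical
#'   disabled-reaction signatures?
#' @return A `gene_scan` tibble with columns `gene`, `n_blocked`, `blocked`
#'   (list column), and if requested `profile` (list column); attributes
#'   carry the native blocked set and native profile.
#' @export
scan_all_genes <- function(model, epsilon = flux_epsilon(), profiles = FALSE,
                           dedupe = TRUE) {
  sunk <- if (has_sinks(model)) model else add_sinks(model)
  native_prof <- production_profile(sunk)
  native <- new_blocked_set(
    native_prof$metabolite[is_flux_zero(native_prof$production, epsilon)],
    "metabolite", model, "native", epsilon)

  genes <- model$genes
  sig <- purrr::map_chr(genes, function(g) {
    paste(disabled_reactions(model, g), collapse = ",")
  })
  groups <- if (dedupe) split(seq_along(genes), sig) else
    split(seq_along(genes), seq_along(genes))

  delta <- vector("list", length(genes))
  prof <- vector("list", length(genes))
  for (grp in groups) {
    g1 <- genes[grp[[1]]]
    off <- disabled_reactions(model, g1)
    if (!length(off)) {
      res_ids <- character()
      res_prof <- if (profiles) native_prof
    } else {
      pert <- sunk
      pert$reactions$lb[off] <- 0
      pert$reactions$ub[off] <- 0
      p <- production_profile(pert, label = paste0("ko:", g1))
      res_ids <- setdiff(p$metabolite[is_flux_zero(p$production, epsilon)], native$id)
      res_prof <- if (profiles) p
    }
    for (i in grp) {
      delta[[i]] <- sort(res_ids)
      prof[[i]] <- res_prof
    }
  }

  out <- tibble::tibble(
    gene = genes,
    n_blocked = lengths(delta),
    blocked = delta
  )
  if (profiles) out$profile <- prof
  structure(out, class = c("gene_scan", class(out)),
            model = model$id, model_hash = model_hash(model),
            native_blocked = native, native_profile = native_prof,
            epsilon = epsilon)
}

#' @export
print.gene_scan <- function(x, ...) {
  cat("<gene_scan> model=", attr(x, "model"), ", ", nrow(x), " genes, ",
      sum(x$n_blocked > 0), " with non-empty footprint\n", sep = "")
  NextMethod()
}

#' Collapse a blocked set over compartments
#'
#' Report view that strips compartment tags (`_c`, `_m`, ... suffixes, or
#' the model's compartment field) so that one species blocked in any
#' compartment reports once under its base id.
#'
#' @param x a `blocked_set`.
#' @param model the model the set was computed on (for compartment lookup);
#'   if omitted, a trailing `_<tag>` suffix is stripped from ids.
#' @return Tibble with columns `base_id`, `n_species`.
#' @export
collapse_compartments <- function(x, model = NULL) {
  ids <- x$id
  base <- if (!is.null(model)) {
    comp <- model$metabolites$compartment[match(ids, model$metabolites$id)]
    ifelse(!is.na(comp) & nzchar(comp),
           mapply(function(i, cc) sub(paste0("_", cc, "$"), "", i), ids, comp),
           sub("_[a-zA-Z0-9]$", "", ids))
  } else {
    sub("_[a-zA-Z0-9]$", "", ids)
  }
  dplyr::count(tibble::tibble(base_id = base), .data$base_id, name = "n_species")
}
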