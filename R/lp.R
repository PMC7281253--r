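# LP-facing operations: single-reaction maximization (FBA with a one-hot
# objective), flux variability analysis, maximal sink flux, and the
# flux-sum-style blockedness test used as the definitional contrast.

#' Zero-flux decision threshold
#'
#' Every blockedness decision in the package routes through this single
#' predicate: a flux is zero iff `|x| <= epsilon`. The default sits between
#' simplex tolerance (~1e-9) and the smallest meaningful flux relative to
#' typical uptake bounds; override globally with
#' `options(fluxblock.epsilon = ...)`.
#'
#' @param x numeric flux value(s).
#' @param epsilon tolerance in flux units.
#' @return Logical vector.
#' @export
is_flux_zero <- function(x, epsilon = flux_epsilon()) {
  abs(x) <= epsilon
}

#' @rdname is_flux_zero
#' @export
flux_epsilon <- function() {
  getOption("fluxblock.epsilon", 1e-6)
}

#' Maximize (or minimize) the flux of one reaction
#'
#' Solves the flux balance program: optimize \eqn{c^T v} subject to
#' \eqn{Sv = 0} and \eqn{lb \le v \le ub}, with `c` the indicator of the
#' named reaction.
#'
#' @param model a [metabolic_model()].
#' @param reaction reaction id to optimize.
#' @param sense `"max"` or `"min"`.
#' @return List with `status`, `objective`, `flux` (named flux vector).
#' @export
maximize_flux <- function(model, reaction, sense = "max") {
  idx <- rxn_index(model, reaction)
  obj <- numeric(nrow(model$reactions))
  obj[idx] <- 1
  res <- lp_solve(obj, stoich_matrix(model), model$reactions$lb, model$reactions$ub,
                  sense = sense)
  if (!is.null(res$flux)) names(res$flux) <- model$reactions$id
  res
}

#' Maximal de-novo production rate of a metabolite
#'
#' The maximal flux of the metabolite's irreversible sink reaction: positive
#' iff the metabolite can be continuously synthesized from the medium at
#' steady state.
#'
#' @param model a sink-augmented [metabolic_model()] (see [add_sinks()]).
#' @param metabolite metabolite id.
#' @return Non-negative flux value.
#' @export
max_production <- function(model, metabolite) {
  met_index(model, metabolite)
  sk <- sink_id(metabolite)
  if (!sk %in% model$reactions$id) {
    stop("no sink reaction for ", metabolite, "; call add_sinks() first", call. = FALSE)
  }
  res <- maximize_flux(model, sk)
  if (res$status != "optimal") {
    stop("production LP for ", metabolite, " ended with status ", res$status, call. = FALSE)
  }
  res$objective
}

#' Flux variability analysis
#'
#' Per-reaction minimal and maximal achievable flux under the model's
#' constraints.
#'
#' @param model a [metabolic_model()].
#' @param reactions reaction ids; default all.
#' @return Tibble with columns `reaction`, `min`, `max`.
#' @export
fva <- function(model, reactions = model$reactions$id) {
  rxn_index(model, reactions)
  S <- stoich_matrix(model)
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  n <- nrow(model$reactions)
  one <- function(id, sense) {
    obj <- numeric(n)
    obj[match(id, model$reactions$id)] <- 1
    res <- lp_solve(obj, S, lb, ub, sense = sense)
    if (res$status != "optimal") {
      stop("FVA LP for ", id, " ended with status ", res$status, call. = FALSE)
    }
    res$objective
  }
  tibble::tibble(
    reaction = reactions,
    min = purrr::map_dbl(reactions, one, sense = "min"),
    max = purrr::map_dbl(reactions, one, sense = "max")
  )
}

#' Is a metabolite blocked under the flux-sum definition?
#'
#' The classical turnover-based definition calls a metabolite blocked when
#' its maximal flux-sum \eqn{\Phi = 0.5 \sum_j |S_{ij} v_j|} is zero, which
#' holds iff no reaction touching the metabolite can carry flux. A
#' metabolite regenerated inside a cycle has \eqn{\Phi > 0} even when its
#' de-novo synthesis is impossible — the discrepancy that motivates the sink
#' definition used by [blocked_metabolites()]. Instrumentation sinks are
#' ignored here.
#'
#' @param model a [metabolic_model()]; sinks, if present, are excluded.
#' @param metabolite metabolite id.
#' @param epsilon zero-flux tolerance.
#' @return `TRUE` iff every touching reaction has FVA range (0, 0).
#' @export
is_blocked_fluxsum <- function(model, metabolite, epsilon = flux_epsilon()) {
  met_index(model, metabolite)
  rxn <- model$reactions
  touching <- purrr::map_lgl(rxn$stoich, function(s) metabolite %in% names(s)) & !rxn$sink
  if (!any(touching)) return(TRUE)
  ranges <- fva(model, rxn$id[touching])
  all(is_flux_zero(ranges$min, epsilon) & is_flux_zero(ranges$max, epsilon))
}
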