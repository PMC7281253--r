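#' Add an irreversible sink reaction for every metabolite
#'
#' Sinks are instrumentation: reaction `SK_<metabolite>` consumes one unit of
#' the metabolite and produces nothing, with bounds `[0, 1e6]`. The maximal
#' sink flux measures de-novo producibility of the metabolite from the
#' medium; see [max_production()] and [blocked_metabolites()].
#'
#' @param model a [metabolic_model()].
#' @return A new model with one sink per metabolite appended. Calling
#'   [add_sinks()] on an already sink-augmented model is an error.
#' @export
add_sinks <- function(model) {
  sink_ids <- paste0("SK_", model$metabolites$id)
  clash <- intersect(sink_ids, model$reactions$id)
  if (length(clash)) {
    stop("sink id collision (already sink-augmented?): ",
         paste(utils::head(clash, 5), collapse = ", "), call. = FALSE)
  }
  sinks <- tibble::tibble(
    id = sink_ids,
    stoich = purrr::map(model$metabolites$id, function(m) stats::setNames(-1, m)),
    lb = 0, ub = FLUX_CAP, gpr = "", exchange = FALSE, sink = TRUE
  )
  model$reactions <- dplyr::bind_rows(model$reactions, sinks)
  model
}

has_sinks <- function(model) any(model$reactions$sink)

sink_id <- function(metabolite) paste0("SK_", metabolite)

#' Simulate gene knockouts
#'
#' Gene defects are modeled by setting both flux bounds of every reaction
#' whose GPR rule evaluates to `FALSE` (knocked genes false, all others true;
#' AND = complex, OR = isozymes) to zero. Reactions without a GPR rule are
#' never disabled.
#'
#' @param model a [metabolic_model()].
#' @param genes character vector of gene ids to knock out. An empty set is
#'   the identity.
#' @return The perturbed model (the input is never modified).
#' @export
knockout_genes <- function(model, genes) {
  genes <- as.character(genes)
  unknown <- setdiff(genes, model$genes)
  if (length(unknown)) {
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!length(genes)) return(model)
  off <- disabled_reactions(model, genes)
  model$reactions$lb[off] <- 0
  model$reactions$ub[off] <- 0
  model
}

# row indices of reactions disabled by knocking out `genes`
disabled_reactions <- function(model, genes) {
  which(!purrr::map_lgl(model$reactions$gpr, gpr_eval, knocked = genes))
}

#' Block every reaction consuming any of a set of metabolites
#'
#' Models a cofactor deficiency (e.g. absence of all intracellular folate
#' forms): every reaction that can consume a target metabolite in some
#' admissible direction — negative coefficient with `ub > 0`, or positive
#' coefficient with `lb < 0` — has both bounds set to zero. Instrumentation
#' sinks are never blocked (they consume everything by construction).
#'
#' @param model a [metabolic_model()].
#' @param targets character vector of metabolite ids (the cofactor forms).
#' @param exclude_reactions reaction ids exempt from the blockade (used e.g.
#'   to re-run a deficiency after stripping the cofactor from chosen steps).
#' @param exclude_transporters if `TRUE`, reactions that move every one of
#'   their metabolites between compartments unchanged (same base id on both
#'   sides) are exempt.
#' @return The perturbed model. A target with no consumer triggers a warning.
#' @export
block_consumers <- function(model, targets, exclude_reactions = character(),
                            exclude_transporters = FALSE) {
  targets <- as.character(targets)
  met_index(model, targets)
  if (!length(targets)) return(model)
  rxn <- model$reactions
  consumer_of <- function(s, lb, ub, t) {
    co <- s[t]
    !is.na(co) && ((co < 0 && ub > 0) || (co > 0 && lb < 0))
  }
  exempt <- rxn$sink | rxn$id %in% exclude_reactions
  if (exclude_transporters) exempt <- exempt | purrr::map_lgl(rxn$stoich, is_transport)
  hit <- rep(FALSE, nrow(rxn))
  for (t in targets) {
    cons <- purrr::pmap_lgl(list(rxn$stoich, rxn$lb, rxn$ub), consumer_of, t = t) & !exempt
    if (!any(cons)) warning("metabolite ", t, " has no consuming reaction", call. = FALSE)
    hit <- hit | cons
  }
  model$reactions$lb[hit] <- 0
  model$reactions$ub[hit] <- 0
  model
}

# transport step: every base id (compartment tag stripped) occurs with both
# signs, i.e. the reaction only relocates species
is_transport <- function(s) {
  if (length(s) < 2) return(FALSE)
  base <- sub("_[a-zA-Z0-9]+$", "", names(s))
  all(vapply(unique(base), function(b) {
    co <- s[base == b]
    any(co > 0) && any(co < 0)
  }, logical(1)))
}

#' Delete reactions outright
#'
#' @param model a [metabolic_model()].
#' @param reactions reaction ids whose bounds are set to zero.
#' @return The perturbed model.
#' @export
delete_reactions <- function(model, reactions) {
  idx <- rxn_index(model, reactions)
  model$reactions$lb[idx] <- 0
  model$reactions$ub[idx] <- 0
  model
}

#' Remove a cofactor couple from chosen reactions
#'
#' Deletes both members of a consumed/produced cofactor pair (e.g. the
#' 10-formyl-THF / THF couple of the two folate-dependent purine-synthesis
#' steps) from a reaction's stoichiometry, leaving all other coefficients
#' untouched. The reaction then proceeds without the cofactor.
#'
#' @param model a [metabolic_model()].
#' @param reactions reaction ids to strip.
#' @param pairs list of length-2 character vectors
#'   `c(consumed_cofactor, produced_cofactor)`; for each reaction the first
#'   pair present with opposite signs is removed.
#' @return The modified model; a reaction containing no listed pair with
#'   opposite signs is an error.
#' @export
strip_cofactor <- function(model, reactions, pairs) {
  idx <- rxn_index(model, reactions)
  if (!is.list(pairs)) pairs <- list(pairs)
  for (i in idx) {
    s <- model$reactions$stoich[[i]]
    hit <- NULL
    for (p in pairs) {
      a <- s[p[[1]]]
      b <- s[p[[2]]]
      if (!is.na(a) && !is.na(b) && a * b < 0) {
        hit <- p
        break
      }
    }
    if (is.null(hit)) {
      stop("reaction ", model$reactions$id[i],
           ": no cofactor pair present with opposite signs (tried: ",
           paste(purrr::map_chr(pairs, paste, collapse = "/"), collapse = ", "), ")",
           call. = FALSE)
    }
    model$reactions$stoich[[i]] <- s[!names(s) %in% hit]
  }
  model
}

#' Declarative perturbation records
#'
#' A `perturbation` captures a network modification as data so that runs can
#' be serialized and replayed: a gene knockout, a consumer blockade
#' (cofactor deficiency), a reaction deletion, or a cofactor strip.
#'
#' @param kind one of `"gene_knockout"`, `"consumer_blockade"`,
#'   `"reaction_deletion"`, `"cofactor_strip"`.
#' @param payload gene/metabolite/reaction id character vector; for
#'   `"cofactor_strip"` a list with elements `reactions` and `pairs`.
#' @param label free-text label; defaults to a readable summary.
#' @return An object of class `perturbation`.
#' @export
perturbation <- function(kind = c("gene_knockout", "consumer_blockade",
                                  "reaction_deletion", "cofactor_strip"),
                         payload, label = NULL) {
  kind <- match.arg(kind)
  if (kind == "cofactor_strip") {
    stopifnot(is.list(payload), all(c("reactions", "pairs") %in% names(payload)))
    if (!length(payload$reactions)) stop("empty perturbation payload", call. = FALSE)
  } else {
    payload <- as.character(payload)
    if (!length(payload)) stop("empty perturbation payload", call. = FALSE)
  }
  if (is.null(label)) {
    label <- if (kind == "cofactor_strip") {
      paste0("strip:", paste(payload$reactions, collapse = "+"))
    } else {
      paste0(sub("_.*", "", kind), ":", paste(payload, collapse = "+"))
    }
  }
  structure(list(kind = kind, payload = payload, label = label), class = "perturbation")
}

#' Apply a perturbation record to a model
#'
#' @param model a [metabolic_model()].
#' @param p a [perturbation()].
#' @return The perturbed model.
#' @export
apply_perturbation <- function(model, p) {
  stopifnot(inherits(p, "perturbation"))
  switch(p$kind,
    gene_knockout = knockout_genes(model, p$payload),
    consumer_blockade = block_consumers(model, p$payload),
    reaction_deletion = delete_reactions(model, p$payload),
    cofactor_strip = strip_cofactor(model, p$payload$reactions, p$payload$pairs)
  )
}
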