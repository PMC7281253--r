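#' Construct a constraint-based metabolic model
#'
#' A `metabolic_model` holds a stoichiometric network: a metabolite table, a
#' reaction table (stoichiometry, flux bounds, gene-protein-reaction rules)
#' and the gene universe. It is the object every analysis in this package
#' operates on. Steady-state analyses solve linear programs over the flux
#' cone \eqn{\{v : Sv = 0,\ lb \le v \le ub\}} where `S` is the stoichiometric
#' matrix implied by the reaction table.
#'
#' Reactions are *exchange* (boundary) reactions when all their stoichiometric
#' coefficients share one sign, i.e. metabolites appear on only one side;
#' the flag is derived, never user-set. Sink reactions added by [add_sinks()]
#' are instrumentation and carry `sink = TRUE`.
#'
#' @param metabolites data frame with columns `id` (unique, non-empty) and
#'   optionally `name` and `compartment`.
#' @param reactions data frame with columns `id` (unique), `stoich` (list of
#'   named numeric vectors: metabolite id -> signed coefficient), `lb`, `ub`
#'   (finite flux bounds, `lb <= ub`) and optionally `gpr` (boolean
#'   gene-protein-reaction rule as a string, `""` for none).
#' @param genes character vector of gene identifiers; defaults to the genes
#'   referenced by the GPR rules.
#' @param id model label used in result provenance.
#' @return An object of class `metabolic_model`.
#' @examples
#' toy <- metabolic_model(
#'   metabolites = tibble::tibble(id = c("A", "B")),
#'   reactions = tibble::tibble(
#'     id = c("EX_A", "R1"),
#'     stoich = list(c(A = 1), c(A = -1, B = 1)),
#'     lb = c(0, 0), ub = c(10, 1000),
#'     gpr = c("", "g1")
#'   )
#' )
#' toy
#' @export
metabolic_model <- function(metabolites, reactions, genes = NULL, id = "model") {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  stopifnot(is.character(id), length(id) == 1L)
  if (!"id" %in% names(metabolites)) stop("`metabolites` needs an `id` column", call. = FALSE)
  metabolites$id <- as.character(metabolites$id)
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"compartment" %in% names(metabolites)) metabolites$compartment <- NA_character_
  metabolites <- metabolites[, c("id", "name", "compartment")]

  req <- c("id", "stoich", "lb", "ub")
  miss <- setdiff(req, names(reactions))
  if (length(miss)) stop("`reactions` is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  reactions$id <- as.character(reactions$id)
  if (!"gpr" %in% names(reactions)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (!"sink" %in% names(reactions)) reactions$sink <- FALSE
  reactions$lb <- as.numeric(reactions$lb)
  reactions$ub <- as.numeric(reactions$ub)
  reactions$stoich <- purrr::map(reactions$stoich, function(s) {
    s <- s[s != 0]
    storage.mode(s) <- "double"
    s
  })
  reactions$exchange <- purrr::map_lgl(reactions$stoich, is_one_sided) & !reactions$sink
  reactions <- reactions[, c("id", "stoich", "lb", "ub", "gpr", "exchange", "sink")]

  if (is.null(genes)) genes <- sort(unique(unlist(purrr::map(reactions$gpr, gpr_genes))))
  genes <- as.character(genes)

  model <- structure(
    list(id = id, metabolites = metabolites, reactions = reactions, genes = genes),
    class = "metabolic_model"
  )
  validate_model(model)
}

is_one_sided <- function(s) {
  length(s) > 0 && (all(s > 0) || all(s < 0))
}

validate_model <- function(model) {
  met <- model$metabolites
  rxn <- model$reactions
  if (anyDuplicated(met$id)) stop("duplicate metabolite ids", call. = FALSE)
  if (anyDuplicated(rxn$id)) stop("duplicate reaction ids", call. = FALSE)
  referenced <- unique(unlist(purrr::map(rxn$stoich, names)))
  unknown <- setdiff(referenced, met$id)
  if (length(unknown)) {
    stop("stoichiometry references undeclared metabolites: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(rxn$lb)) || any(!is.finite(rxn$ub))) {
    stop("all flux bounds must be finite", call. = FALSE)
  }
  bad <- rxn$id[rxn$lb > rxn$ub]
  if (length(bad)) stop("lb > ub for reaction(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(rxn))) {
    gg <- gpr_genes(rxn$gpr[i])
    miss <- setdiff(gg, model$genes)
    if (length(miss)) {
      stop("reaction ", rxn$id[i], ": GPR references undeclared gene(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      "  reactions: ", nrow(x$reactions),
      " (", sum(x$reactions$exchange), " exchange, ",
      sum(x$reactions$sink), " sinks)",
      "  genes: ", length(x$genes), "\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model a [metabolic_model()].
#' @return A sparse `dgCMatrix` (metabolites x reactions) with dimnames.
#' @export
stoich_matrix <- function(model) {
  met_ids <- model$metabolites$id
  rxn <- model$reactions
  ii <- unlist(purrr::map(rxn$stoich, function(s) match(names(s), met_ids)))
  jj <- rep(seq_len(nrow(rxn)), lengths(rxn$stoich))
  xx <- unlist(rxn$stoich, use.names = FALSE)
  Matrix::sparseMatrix(
    i = ii, j = jj, x = xx,
    dims = c(length(met_ids), nrow(rxn)),
    dimnames = list(met_ids, rxn$id)
  )
}

met_index <- function(model, ids, what = "metabolite") {
  idx <- match(ids, model$metabolites$id)
  if (anyNA(idx)) {
    stop("unknown ", what, " id(s): ", paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

rxn_index <- function(model, ids) {
  idx <- match(ids, model$reactions$id)
  if (anyNA(idx)) {
    stop("unknown reaction id(s): ", paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

#' Deterministic content hash of a model
#'
#' Canonically serializes ids, stoichiometry, bounds and GPR rules and returns
#' an MD5 digest. Used to guard against comparing results computed on
#' different model states.
#'
#' @param model a [metabolic_model()].
#' @return A hex digest string.
#' @export
model_hash <- function(model) {
  rxn <- model$reactions
  lines <- c(
    paste0("M\t", model$metabolites$id),
    purrr::map_chr(seq_len(nrow(rxn)), function(i) {
      s <- rxn$stoich[[i]]
      s <- s[order(names(s))]
      paste0("R\t", rxn$id[i], "\t",
             paste(names(s), format(s, digits = 15, trim = TRUE), sep = ":", collapse = ","),
             "\t", format(rxn$lb[i], digits = 15), "\t", format(rxn$ub[i], digits = 15),
             "\t", rxn$gpr[i])
    }),
    paste0("G\t", model$genes)
  )
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(lines, f)
  unname(tools::md5sum(f))
}

# Large finite flux cap used for sink upper bounds and to replace infinite
# bounds on import: keeps every LP bounded for the simplex backend.
FLUX_CAP <- 1e6
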