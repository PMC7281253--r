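# Result serialization (TSV + JSON sidecar with run metadata) and the
# packaged default folate species list.

result_meta <- function(x) {
  list(
    kind = attr(x, "kind") %||% NULL,
    model = attr(x, "model") %||% NULL,
    model_hash = attr(x, "model_hash") %||% NULL,
    label = attr(x, "label") %||% NULL,
    epsilon = attr(x, "epsilon") %||% NULL,
    package_version = as.character(utils::packageVersion("fluxblock"))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a blocked set or production profile
#'
#' Writes `<base>.tsv` (one row per element) and `<base>.json` (the same
#' data plus run metadata: model hash, perturbation label, zero tolerance,
#' package version).
#'
#' @param x a `blocked_set` or `production_profile`.
#' @param base output path without extension.
#' @return Invisibly, the two paths written.
#' @export
write_result <- function(x, base) {
  tsv <- paste0(base, ".tsv")
  json <- paste0(base, ".json")
  utils::write.table(as.data.frame(x), tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- result_meta(x)
  jsonlite::write_json(c(meta, list(data = as.data.frame(x))), json,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(c(tsv = tsv, json = json))
}

#' Read a perturbation from JSON
#'
#' JSON object with fields `kind`, `payload` (array of ids, or for
#' `cofactor_strip` an object with `reactions` and `pairs`), optional
#' `label`.
#'
#' @param path JSON file path.
#' @return A [perturbation()].
#' @export
read_perturbation <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  payload <- if (identical(x$kind, "cofactor_strip")) {
    pairs <- x$payload$pairs
    if (is.matrix(pairs)) pairs <- asplit(pairs, 1)
    if (is.data.frame(pairs)) pairs <- asplit(as.matrix(pairs), 1)
    list(reactions = x$payload$reactions, pairs = pairs)
  } else {
    unlist(x$payload)
  }
  perturbation(x$kind, payload, label = x$label %||% NULL)
}

#' Default folate species list
#'
#' The canonical intracellular folate forms (base identifiers in Recon /
#' BiGG nomenclature: folate, dihydro- and tetrahydrofolate, the one-carbon
#' loaded THF forms). The folate-deficiency construct blocks every reaction
#' consuming any form of folate; since genome-scale reconstructions never
#' enumerate that set themselves, this curated default ships as editable
#' data. Species are matched by base id across all intracellular
#' compartments (the extracellular pool is a supply, not the cellular
#' cofactor pool).
#'
#' @param model optional [metabolic_model()]: when given, the base ids are
#'   expanded to the model's matching non-extracellular species ids.
#' @param base_ids override the packaged base-id list.
#' @return Without a model, a tibble (`base_id`, `description`); with one, a
#'   character vector of species ids.
#' @export
folate_species <- function(model = NULL, base_ids = NULL) {
  if (is.null(base_ids)) {
    path <- system.file("extdata", "folate_species_default.tsv", package = "fluxblock")
    tab <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    if (is.null(model)) return(tibble::as_tibble(tab))
    base_ids <- tab$base_id
  }
  if (is.null(model)) return(tibble::tibble(base_id = base_ids, description = NA_character_))
  ids <- model$metabolites$id
  comp <- model$metabolites$compartment
  base <- ifelse(!is.na(comp) & nzchar(comp),
                 mapply(function(i, cc) sub(paste0("_", cc, "$"), "", i), ids, comp),
                 sub("_[a-zA-Z0-9]$", "", ids))
  extracellular <- !is.na(comp) & comp %in% c("e", "ext", "extracellular")
  ids[base %in% base_ids & !extracellular]
}
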