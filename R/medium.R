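#' Growth-medium specifications
#'
#' A medium is a table of exchange reactions (or external compounds
#' resolvable to one) with maximal uptake rates. Applying a medium closes the
#' uptake direction of every exchange reaction not listed and caps the uptake
#' of listed ones; secretion directions are untouched.
#'
#' @param entries named numeric vector or two-column data frame
#'   (`id`, `uptake`) of non-negative maximal uptake rates.
#' @return A tibble of class `medium_spec` with columns `id`, `uptake`.
#' @export
medium_spec <- function(entries) {
  if (is.data.frame(entries)) {
    stopifnot(all(c("id", "uptake") %in% names(entries)))
    out <- tibble::tibble(id = as.character(entries$id), uptake = as.numeric(entries$uptake))
  } else {
    stopifnot(is.numeric(entries), !is.null(names(entries)))
    out <- tibble::tibble(id = names(entries), uptake = as.numeric(entries))
  }
  if (any(is.na(out$uptake)) || any(out$uptake < 0)) {
    stop("uptake rates must be non-negative", call. = FALSE)
  }
  if (anyDuplicated(out$id)) stop("duplicate medium ids", call. = FALSE)
  class(out) <- c("medium_spec", class(out))
  out
}

#' Read a medium from TSV or JSON
#'
#' TSV: two columns `id`, `uptake` (header optional if exactly two unnamed
#' columns). JSON: an object mapping id to uptake rate.
#'
#' @param path file path; format inferred from the `.json` extension.
#' @return A [medium_spec()].
#' @export
read_medium <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(medium_spec(unlist(x)))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("id", "uptake") %in% names(df))) {
    df <- utils::read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                            col.names = c("id", "uptake"))
  }
  medium_spec(df)
}

#' Write a medium to TSV
#'
#' @param medium a [medium_spec()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_medium <- function(medium, path) {
  utils::write.table(as.data.frame(medium)[, c("id", "uptake")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Constrain a model to a growth medium
#'
#' Every exchange reaction's uptake direction is closed unless the reaction
#' (or the external compound it exchanges) appears in the medium, in which
#' case uptake is capped at the stated rate. The uptake direction of an
#' exchange reaction is read off its stoichiometry — the direction that
#' imports the compound into the network — not from a bound-sign convention,
#' because SBML dialects differ.
#'
#' @param model a [metabolic_model()].
#' @param medium a [medium_spec()], or anything [medium_spec()] accepts.
#' @return The constrained model; unresolvable medium ids are an error.
#' @export
apply_medium <- function(model, medium) {
  if (!inherits(medium, "medium_spec")) medium <- medium_spec(medium)
  rxn <- model$reactions
  exch <- which(rxn$exchange)

  # resolve each medium entry to exchange-reaction indices
  resolved <- vector("list", nrow(medium))
  bad <- character()
  for (k in seq_len(nrow(medium))) {
    id <- medium$id[k]
    hit <- exch[rxn$id[exch] == id]
    if (!length(hit)) {
      hit <- exch[purrr::map_lgl(rxn$stoich[exch], function(s) id %in% names(s))]
    }
    if (!length(hit)) bad <- c(bad, id)
    resolved[[k]] <- hit
  }
  if (length(bad)) {
    stop("medium id(s) not resolvable to an exchange reaction: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  cap <- rep(0, nrow(rxn))
  listed <- rep(FALSE, nrow(rxn))
  for (k in seq_len(nrow(medium))) {
    cap[resolved[[k]]] <- pmax(cap[resolved[[k]]], medium$uptake[k])
    listed[resolved[[k]]] <- TRUE
  }

  for (i in exch) {
    imports_forward <- all(rxn$stoich[[i]] > 0)
    r <- if (listed[i]) cap[i] else 0
    if (imports_forward) {
      model$reactions$ub[i] <- min(rxn$ub[i], r)
      model$reactions$lb[i] <- min(model$reactions$lb[i], model$reactions$ub[i])
    } else {
      model$reactions$lb[i] <- max(rxn$lb[i], -r)
      model$reactions$ub[i] <- max(model$reactions$ub[i], model$reactions$lb[i])
    }
  }
  model
}
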