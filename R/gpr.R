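# Gene-protein-reaction (GPR) boolean rules.
#
# Grammar: rule := term ("or" term)* ; term := factor ("and" factor)* ;
# factor := gene-id | "(" rule ")". AND models complex subunits (all genes
# required), OR models isozymes (any gene suffices). Case-insensitive
# keywords; everything else is a gene token.

gpr_tokens <- function(gpr) {
  if (is.na(gpr) || !nzchar(trimws(gpr))) return(character())
  g <- gsub("(", " ( ", gpr, fixed = TRUE)
  g <- gsub(")", " ) ", g, fixed = TRUE)
  strsplit(trimws(g), "\\s+")[[1]]
}

#' Genes referenced by a GPR rule
#'
#' @param gpr a GPR rule string (e.g. `"g1 and (g2 or g3)"`); `""` or `NA`
#'   means no rule.
#' @return Character vector of gene identifiers (possibly empty).
#' @export
gpr_genes <- function(gpr) {
  tok <- gpr_tokens(gpr)
  unique(tok[!tolower(tok) %in% c("and", "or", "(", ")")])
}

#' Evaluate a GPR rule under a gene knockout
#'
#' Knocked-out genes evaluate to `FALSE`, every other gene to `TRUE`. A
#' reaction with an empty rule is never disabled by knockouts, so the empty
#' rule evaluates to `TRUE`.
#'
#' @param gpr a GPR rule string.
#' @param knocked character vector of knocked-out gene ids.
#' @return `TRUE` if the reaction remains catalyzed, else `FALSE`.
#' @export
gpr_eval <- function(gpr, knocked) {
  tok <- gpr_tokens(gpr)
  if (!length(tok)) return(TRUE)
  expr <- vapply(tok, function(t) {
    tl <- tolower(t)
    if (tl == "and") "&&"
    else if (tl == "or") "||"
    else if (t %in% c("(", ")")) t
    else if (t %in% knocked) "FALSE"
    else "TRUE"
  }, character(1))
  out <- try(eval(parse(text = paste(expr, collapse = " "), keep.source = FALSE),
                  envir = baseenv()), silent = TRUE)
  if (inherits(out, "try-error") || !is.logical(out) || length(out) != 1L || is.na(out)) {
    stop("malformed GPR rule: ", gpr, call. = FALSE)
  }
  out
}
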