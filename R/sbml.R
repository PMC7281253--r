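# SBML Level 3 + FBC v2 import/export, built directly on xml2. The dialect
# written (and read back) is the one cobrapy emits: "M_"/"R_"/"G_" id
# prefixes, flux bounds as shared fbc parameters, GPR rules as nested
# fbc:and / fbc:or gene-product associations. The reader is prefix-agnostic
# in its XPath so other namespace spellings of the same constructs work.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

sbml_sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

num_attr <- function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE)

# first attribute whose (possibly prefixed) name matches
attr_any <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- grep(paste0("(^|:)", name, "$"), names(at))
  if (!length(hit)) NA_character_ else unname(at[hit[1L]])
}

#' Write a model as SBML Level 3 with FBC
#'
#' @param model a [metabolic_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  met <- model$metabolites
  rxn <- model$reactions
  comps <- unique(ifelse(is.na(met$compartment) | !nzchar(met$compartment),
                         "c", met$compartment))
  met_comp <- ifelse(is.na(met$compartment) | !nzchar(met$compartment),
                     "c", met$compartment)

  # shared flux-bound parameters
  bounds <- sort(unique(c(rxn$lb, rxn$ub)))
  pid <- stats::setNames(paste0("fb_", seq_along(bounds)), num_attr(bounds))
  par_xml <- paste0('      <parameter id="', pid, '" value="', names(pid),
                    '" constant="true" sboTerm="SBO:0000626"/>', collapse = "\n")

  sp_xml <- paste0(
    '      <species id="M_', sbml_sid(met$id), '" name="', xml_escape(met$name),
    '" compartment="', sbml_sid(met_comp),
    '" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
    collapse = "\n")

  comp_xml <- paste0('      <compartment id="', sbml_sid(comps),
                     '" constant="true"/>', collapse = "\n")

  gpr_xml <- function(g) {
    if (!nzchar(g)) return("")
    node <- gpr_assoc_xml(g)
    paste0("        <fbc:geneProductAssociation>\n", node,
           "\n        </fbc:geneProductAssociation>\n")
  }

  rx_xml <- purrr::map_chr(seq_len(nrow(rxn)), function(i) {
    s <- rxn$stoich[[i]]
    reac <- s[s < 0]
    prod <- s[s > 0]
    ref <- function(sv, sign) {
      if (!length(sv)) return("")
      paste0('          <speciesReference species="M_', sbml_sid(names(sv)),
             '" stoichiometry="', num_attr(sign * sv), '" constant="true"/>',
             collapse = "\n")
    }
    paste0(
      '      <reaction id="R_', sbml_sid(rxn$id[i]),
      '" reversible="', if (rxn$lb[i] < 0) "true" else "false",
      '" fast="false" fbc:lowerFluxBound="', pid[[num_attr(rxn$lb[i])]],
      '" fbc:upperFluxBound="', pid[[num_attr(rxn$ub[i])]], '">\n',
      gpr_xml(rxn$gpr[i]),
      if (length(reac)) paste0("        <listOfReactants>\n", ref(reac, -1),
                               "\n        </listOfReactants>\n") else "",
      if (length(prod)) paste0("        <listOfProducts>\n", ref(prod, 1),
                               "\n        </listOfProducts>\n") else "",
      "      </reaction>")
  })

  gp_xml <- if (length(model$genes)) {
    paste0(
      "    <fbc:listOfGeneProducts>\n",
      paste0('      <fbc:geneProduct fbc:id="G_', sbml_sid(model$genes),
             '" fbc:label="', xml_escape(model$genes), '"/>', collapse = "\n"),
      "\n    </fbc:listOfGeneProducts>\n")
  } else ""

  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'level="3" version="1" fbc:required="false">\n',
    '  <model id="', sbml_sid(model$id), '" fbc:strict="true">\n',
    "    <listOfCompartments>\n", comp_xml, "\n    </listOfCompartments>\n",
    "    <listOfSpecies>\n", sp_xml, "\n    </listOfSpecies>\n",
    "    <listOfParameters>\n", par_xml, "\n    </listOfParameters>\n",
    "    <listOfReactions>\n", paste0(rx_xml, collapse = "\n"),
    "\n    </listOfReactions>\n",
    gp_xml,
    "  </model>\n</sbml>\n")
  writeLines(doc, path)
  invisible(path)
}

# nested fbc:and / fbc:or / fbc:geneProductRef for one GPR rule
gpr_assoc_xml <- function(gpr, indent = "          ") {
  tok <- gpr_tokens(gpr)
  node <- gpr_parse(tok)
  render <- function(nd, ind) {
    if (is.character(nd)) {
      return(paste0(ind, '<fbc:geneProductRef fbc:geneProduct="G_', sbml_sid(nd), '"/>'))
    }
    tag <- paste0("fbc:", nd$op)
    kids <- paste(vapply(nd$args, render, character(1), ind = paste0(ind, "  ")),
                  collapse = "\n")
    paste0(ind, "<", tag, ">\n", kids, "\n", ind, "</", tag, ">")
  }
  render(node, indent)
}

# recursive-descent GPR parser: or-expr := and-expr ("or" and-expr)*;
# and-expr := atom ("and" atom)*; atom := gene | "(" or-expr ")"
gpr_parse <- function(tokens) {
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  take <- function() {
    t <- peek()
    pos <<- pos + 1L
    t
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      args <- c(args, list(parse_and()))
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      args <- c(args, list(parse_atom()))
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_atom <- function() {
    t <- take()
    if (is.na(t)) stop("malformed GPR", call. = FALSE)
    if (t == "(") {
      e <- parse_or()
      if (!identical(take(), ")")) stop("malformed GPR: unbalanced parentheses", call. = FALSE)
      return(e)
    }
    if (t %in% c(")", "and", "or")) stop("malformed GPR near '", t, "'", call. = FALSE)
    t
  }
  out <- parse_or()
  if (pos <= length(tokens)) stop("malformed GPR: trailing tokens", call. = FALSE)
  out
}

strip_prefix <- function(x, prefix) {
  ifelse(startsWith(x, prefix), substring(x, nchar(prefix) + 1L), x)
}

#' Read a model from SBML Level 3 with FBC
#'
#' Accepts the dialect written by [write_sbml()] and by cobrapy: flux bounds
#' as fbc parameter references, GPR rules as fbc gene-product associations,
#' `M_`/`R_`/`G_` id prefixes (stripped on read). Reactions lacking a GPR
#' get an empty rule. Infinite bound parameters are clamped to the
#' package's finite flux cap. A reaction without resolvable bounds, or a
#' GPR referencing an undeclared gene product, is a hard error naming the
#' reaction.
#'
#' @param path SBML file path.
#' @return A [metabolic_model()].
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  mnode <- xml2::xml_find_first(doc, "//*[local-name()='model']")
  model_id <- attr_any(mnode, "id")
  if (is.na(model_id)) model_id <- "model"

  sp <- xml2::xml_find_all(doc, "//*[local-name()='listOfSpecies']/*[local-name()='species']")
  sp_id <- vapply(sp, attr_any, character(1), "id")
  boundary <- vapply(sp, function(n) identical(attr_any(n, "boundaryCondition"), "true"),
                     logical(1))
  mets <- tibble::tibble(
    id = strip_prefix(sp_id, "M_"),
    name = dplyr::coalesce(vapply(sp, attr_any, character(1), "name"),
                           strip_prefix(sp_id, "M_")),
    compartment = vapply(sp, attr_any, character(1), "compartment")
  )
  sid_map <- stats::setNames(mets$id, sp_id)
  boundary_ids <- sp_id[boundary]
  mets <- mets[!boundary, ]

  pars <- xml2::xml_find_all(doc, "//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  par_val <- stats::setNames(
    as.numeric(vapply(pars, attr_any, character(1), "value")),
    vapply(pars, attr_any, character(1), "id"))
  par_val[par_val == Inf] <- FLUX_CAP
  par_val[par_val == -Inf] <- -FLUX_CAP

  gp <- xml2::xml_find_all(doc, "//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  gp_id <- vapply(gp, attr_any, character(1), "id")
  gp_label <- vapply(gp, function(n) {
    lbl <- attr_any(n, "label")
    if (is.na(lbl)) NA_character_ else lbl
  }, character(1))
  genes <- ifelse(is.na(gp_label), strip_prefix(gp_id, "G_"), gp_label)
  gene_map <- stats::setNames(genes, gp_id)

  rx <- xml2::xml_find_all(doc, "//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  parse_reaction <- function(node) {
    rid_raw <- attr_any(node, "id")
    rid <- strip_prefix(rid_raw, "R_")
    bound_of <- function(which_attr, fallback_num) {
      ref <- attr_any(node, which_attr)
      if (!is.na(ref)) {
        if (!ref %in% names(par_val)) {
          stop("reaction ", rid, ": flux bound parameter '", ref, "' not declared",
               call. = FALSE)
        }
        return(par_val[[ref]])
      }
      direct <- attr_any(node, fallback_num)
      if (!is.na(direct)) return(as.numeric(direct))
      NA_real_
    }
    lb <- bound_of("lowerFluxBound", "lowerBound")
    ub <- bound_of("upperFluxBound", "upperBound")
    if (is.na(lb) || is.na(ub)) {
      stop("reaction ", rid, ": missing flux bounds", call. = FALSE)
    }
    sref <- function(side, sign) {
      refs <- xml2::xml_find_all(
        node, paste0("./*[local-name()='", side, "']/*[local-name()='speciesReference']"))
      if (!length(refs)) return(numeric())
      ids <- vapply(refs, attr_any, character(1), "species")
      st <- as.numeric(vapply(refs, function(n) {
        v <- attr_any(n, "stoichiometry")
        if (is.na(v)) "1" else v
      }, character(1)))
      keep <- !ids %in% boundary_ids
      stats::setNames(sign * st[keep], unname(sid_map[ids[keep]]))
    }
    s <- c(sref("listOfReactants", -1), sref("listOfProducts", 1))
    s <- tapply(s, names(s), sum)[unique(names(s))]  # merge duplicate species refs
    assoc <- xml2::xml_find_first(node, "./*[local-name()='geneProductAssociation']")
    gpr <- if (inherits(assoc, "xml_missing")) "" else assoc_to_gpr(assoc, gene_map, rid)
    list(id = rid, stoich = as.numeric(s) |> stats::setNames(names(s)),
         lb = unname(lb), ub = unname(ub), gpr = gpr)
  }
  parsed <- purrr::map(rx, parse_reaction)
  rxn <- tibble::tibble(
    id = purrr::map_chr(parsed, "id"),
    stoich = purrr::map(parsed, "stoich"),
    lb = purrr::map_dbl(parsed, "lb"),
    ub = purrr::map_dbl(parsed, "ub"),
    gpr = purrr::map_chr(parsed, "gpr")
  )
  metabolic_model(mets, rxn, genes = unname(genes), id = strip_prefix(model_id, "M_"))
}

# nested association node -> GPR string
assoc_to_gpr <- function(node, gene_map, rid) {
  walk <- function(n) {
    nm <- xml2::xml_name(n)
    if (nm == "geneProductRef") {
      ref <- attr_any(n, "geneProduct")
      if (!ref %in% names(gene_map)) {
        stop("reaction ", rid, ": GPR references undeclared gene product '",
             ref, "'", call. = FALSE)
      }
      return(gene_map[[ref]])
    }
    kids <- xml2::xml_children(n)
    parts <- vapply(kids, walk, character(1))
    if (nm == "and") return(paste0("(", paste(parts, collapse = " and "), ")"))
    if (nm == "or") return(paste0("(", paste(parts, collapse = " or "), ")"))
    if (length(parts) == 1L) return(parts)
    stop("reaction ", rid, ": unsupported GPR association node '", nm, "'", call. = FALSE)
  }
  out <- walk(xml2::xml_children(node)[[1L]])
  sub("^\\((.*)\\)$", "\\1", out)
}
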