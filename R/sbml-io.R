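# SBML Level 3 I/O with fbc-style flux bounds and gene-product
# associations. Writes a strict, minimal document; the reader handles that
# document plus generic fbc models with the same constructs. Internal ids
# are sanitized for SBML (the tabular dialect's "A[c]" is not a valid SId);
# original ids travel in name/label attributes and are restored on read.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sanitize_sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

# recursive-descent parse of a GPR string into an and/or tree
gpr_ast <- function(gpr) {
  toks <- gpr_tokens(gpr)
  if (!length(toks)) return(NULL)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { tk <- toks[pos]; pos <<- pos + 1L; tk }
  parse_atom <- function() {
    tk <- advance()
    if (is.na(tk)) stop("truncated gpr rule: ", gpr)
    if (tk == "(") {
      inner <- parse_or()
      if (!identical(advance(), ")")) stop("unbalanced gpr rule: ", gpr)
      inner
    } else if (tolower(tk) %in% c("and", "or", ")")) {
      stop("malformed gpr rule: ", gpr)
    } else tk
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance(); args <- c(args, list(parse_atom()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance(); args <- c(args, list(parse_and()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  out <- parse_or()
  if (pos <= length(toks)) stop("malformed gpr rule: ", gpr)
  out
}

gpr_ast_to_string <- function(ast) {
  if (is.null(ast)) return("")
  if (is.character(ast)) return(ast)
  parts <- vapply(ast$args, function(a) {
    s <- gpr_ast_to_string(a)
    if (is.list(a)) paste0("(", s, ")") else s
  }, "")
  paste(parts, collapse = sprintf(" %s ", ast$op))
}

#' Write a metabolic model as SBML Level 3
#'
#' Emits SBML Level 3 Version 1 with fbc version 2 constructs: flux bounds
#' as shared constant parameters, gene-protein-reaction rules as nested
#' and/or gene-product associations, and a maximization objective on the
#' biomass reaction.
#'
#' @param model a [metabolic_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  ln <- character()
  add <- function(...) ln[[length(ln) + 1L]] <<- paste0(...)

  add('<?xml version="1.0" encoding="UTF-8"?>')
  add(sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
              SBML_NS, FBC_NS))
  add('  <model id="model" fbc:strict="true">')

  comps <- unique(model$metabolites$compartment)
  add("    <listOfCompartments>")
  for (cp in comps)
    add(sprintf('      <compartment id="%s" constant="true"/>',
                sanitize_sid(cp)))
  add("    </listOfCompartments>")

  add("    <listOfSpecies>")
  for (i in seq_len(nrow(model$metabolites)))
    add(sprintf(
      '      <species id="M_%s" name="%s" compartment="%s" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false"/>',
      sanitize_sid(model$metabolites$id[i]), esc(model$metabolites$id[i]),
      sanitize_sid(model$metabolites$compartment[i])))
  add("    </listOfSpecies>")

  bounds <- sort(unique(c(model$reactions$lb, model$reactions$ub)))
  bnd_id <- stats::setNames(sprintf("bnd_%d", seq_along(bounds)),
                            vapply(bounds, format, "", digits = 15))
  add("    <listOfParameters>")
  for (i in seq_along(bounds))
    add(sprintf('      <parameter id="bnd_%d" value="%s" constant="true"/>',
                i, format(bounds[i], digits = 15)))
  add("    </listOfParameters>")

  gpr_xml <- function(ast, indent) {
    pad <- strrep(" ", indent)
    if (is.character(ast))
      return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="G_%s"/>',
                     pad, sanitize_sid(ast)))
    tag <- if (ast$op == "and") "fbc:and" else "fbc:or"
    c(sprintf("%s<%s>", pad, tag),
      unlist(lapply(ast$args, gpr_xml, indent = indent + 2L)),
      sprintf("%s</%s>", pad, tag))
  }

  add("    <listOfReactions>")
  for (j in seq_len(nrow(model$reactions))) {
    rx <- model$reactions[j, ]
    v <- model$S[, j]
    add(sprintf(
      '      <reaction id="R_%s" name="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      sanitize_sid(rx$id), esc(rx$id),
      if (rx$lb < 0) "true" else "false",
      bnd_id[[format(rx$lb, digits = 15)]],
      bnd_id[[format(rx$ub, digits = 15)]]))
    react <- v[v < 0]; prod <- v[v > 0]
    if (length(react)) {
      add("        <listOfReactants>")
      for (m in names(react))
        add(sprintf(
          '          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
          sanitize_sid(m), format(-react[[m]], digits = 15)))
      add("        </listOfReactants>")
    }
    if (length(prod)) {
      add("        <listOfProducts>")
      for (m in names(prod))
        add(sprintf(
          '          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
          sanitize_sid(m), format(prod[[m]], digits = 15)))
      add("        </listOfProducts>")
    }
    ast <- gpr_ast(rx$gpr)
    if (!is.null(ast)) {
      add("        <fbc:geneProductAssociation>")
      for (line in gpr_xml(ast, 10L)) add(line)
      add("        </fbc:geneProductAssociation>")
    }
    add("      </reaction>")
  }
  add("    </listOfReactions>")

  add('    <fbc:listOfObjectives fbc:activeObjective="obj">')
  add('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
  add("        <fbc:listOfFluxObjectives>")
  add(sprintf(
    '          <fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="1"/>',
    sanitize_sid(model$reactions$id[model$reactions$objective])))
  add("        </fbc:listOfFluxObjectives>")
  add("      </fbc:objective>")
  add("    </fbc:listOfObjectives>")

  if (length(model$genes)) {
    add("    <fbc:listOfGeneProducts>")
    for (g in model$genes)
      add(sprintf('      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
                  sanitize_sid(g), esc(g)))
    add("    </fbc:listOfGeneProducts>")
  }
  add("  </model>")
  add("</sbml>")
  writeLines(ln, path)
  invisible(path)
}

#' Read an SBML Level 3 metabolic model
#'
#' Reads SBML Level 3 with fbc-style flux bounds (parameter references or
#' literal values), nested and/or gene-product associations, and an active
#' maximization objective. Species and gene labels written by
#' [write_sbml()] are restored to their original ids.
#'
#' @param path SBML file path.
#' @return a [metabolic_model()].
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  attr_of <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) NULL else v
  }

  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  bound_vals <- stats::setNames(
    as.numeric(xml2::xml_attr(params, "value")),
    xml2::xml_attr(params, "id"))

  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sp_sid <- xml2::xml_attr(sp_nodes, "id")
  sp_name <- xml2::xml_attr(sp_nodes, "name")
  sp_id <- ifelse(is.na(sp_name) | !nzchar(sp_name),
                  sub("^M_", "", sp_sid), sp_name)
  species <- data.frame(sid = sp_sid, id = sp_id,
                        compartment = xml2::xml_attr(sp_nodes, "compartment"),
                        stringsAsFactors = FALSE)

  gp_nodes <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gp_sid <- xml2::xml_attr(gp_nodes, "id")
  gp_label <- xml2::xml_attr(gp_nodes, "label")
  gene_of <- stats::setNames(
    ifelse(is.na(gp_label) | !nzchar(gp_label), sub("^G_", "", gp_sid),
           gp_label), gp_sid)

  parse_assoc <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- xml2::xml_attr(node, "geneProduct")
      g <- if (ref %in% names(gene_of)) gene_of[[ref]] else sub("^G_", "", ref)
      return(g)
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, function(k) {
      s <- parse_assoc(k)
      if (xml2::xml_name(k) %in% c("and", "or")) paste0("(", s, ")") else s
    }, "")
    paste(parts, collapse = if (nm == "and") " and " else " or ")
  }

  obj_ref <- xml2::xml_attr(
    xml2::xml_find_first(doc, ".//fbc:fluxObjective", ns), "reaction")

  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rx_nodes)) stop("no reactions found in ", path)
  rx_rows <- list(); stoichs <- list()
  for (node in rx_nodes) {
    sid <- xml2::xml_attr(node, "id")
    nm <- attr_of(node, "name")
    id <- if (!is.null(nm) && nzchar(nm)) nm else sub("^R_", "", sid)
    bound <- function(which, default) {
      ref <- attr_of(node, which)
      if (is.null(ref)) return(default)
      if (ref %in% names(bound_vals)) return(bound_vals[[ref]])
      v <- suppressWarnings(as.numeric(ref))
      if (is.na(v)) stop("unresolved flux bound '", ref, "' in reaction ", id)
      v
    }
    rev <- identical(attr_of(node, "reversible"), "true")
    lb <- bound("lowerFluxBound", if (rev) -1000 else 0)
    ub <- bound("upperFluxBound", 1000)

    coef <- stats::setNames(numeric(), character())
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(node, sprintf("./s:%s/s:speciesReference",
                                               side), ns)
      if (!length(refs)) next
      sgn <- if (side == "listOfReactants") -1 else 1
      met_sid <- xml2::xml_attr(refs, "species")
      idx <- match(met_sid, species$sid)
      if (any(is.na(idx)))
        stop("reaction '", id, "' references unknown metabolite(s): ",
             paste(met_sid[is.na(idx)], collapse = ", "))
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      for (k in seq_along(idx)) {
        met <- species$id[idx[k]]
        coef[met] <- (if (met %in% names(coef)) coef[[met]] else 0) +
          sgn * st[k]
      }
    }
    assoc <- xml2::xml_find_first(node, "./fbc:geneProductAssociation", ns)
    gpr <- if (inherits(assoc, "xml_missing")) "" else {
      kids <- xml2::xml_children(assoc)
      if (!length(kids)) "" else gsub("^\\((.*)\\)$", "\\1",
                                      parse_assoc(kids[[1]]))
    }
    stoichs[[id]] <- coef
    rx_rows[[id]] <- data.frame(
      id = id, lb = lb, ub = ub, gpr = gpr,
      objective = identical(sid, obj_ref), stringsAsFactors = FALSE)
  }
  reactions <- do.call(rbind, c(rx_rows, make.row.names = FALSE))
  if (!any(reactions$objective)) {
    # fall back: a reaction literally named as a biomass function
    bio <- grep("biomass", reactions$id, ignore.case = TRUE)
    if (length(bio) == 1L) reactions$objective[bio] <- TRUE
    else stop("no active objective found in ", path)
  }
  mets <- unique(unlist(lapply(stoichs, names)))
  S <- matrix(0, length(mets), nrow(reactions),
              dimnames = list(mets, reactions$id))
  for (j in seq_along(stoichs)) S[names(stoichs[[j]]), j] <- stoichs[[j]]
  metabolites <- data.frame(
    id = mets,
    compartment = species$compartment[match(mets, species$id)],
    stringsAsFactors = FALSE)
  metabolites$compartment[is.na(metabolites$compartment)] <- "c"
  genes <- unique(unname(gene_of))
  if (!length(genes)) genes <- NULL
  metabolic_model(metabolites, reactions, S, genes = genes)
}
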