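#' Genome-scale (or toy) metabolic model
#'
#' Stoichiometric model for flux balance analysis: metabolites with
#' compartments, reactions with flux bounds (mmol gDW^-1 h^-1) and
#' boolean gene-protein-reaction (GPR) rules, and one biomass objective
#' reaction whose flux represents growth rate. Exchange reactions (the
#' interface with the medium) are recognized as reactions touching exactly
#' one metabolite; by convention uptake is a negative exchange flux.
#'
#' @param metabolites data.frame with columns `id` and `compartment`.
#' @param reactions data.frame with columns `id`, `lb`, `ub`, `gpr`
#'   (boolean expression over gene ids with `and`/`or`/parentheses, empty
#'   for spontaneous or orphan reactions) and `objective` (logical,
#'   exactly one TRUE).
#' @param stoichiometry numeric matrix, metabolites x reactions, dimnames
#'   matching the id columns.
#' @param genes character vector of declared gene ids; defaults to the
#'   genes referenced by the GPR rules.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            genes = NULL) {
  if (!all(c("id", "compartment") %in% names(metabolites)))
    stop("'metabolites' needs columns id, compartment")
  if (!all(c("id", "lb", "ub", "gpr", "objective") %in% names(reactions)))
    stop("'reactions' needs columns id, lb, ub, gpr, objective")
  S <- as.matrix(stoichiometry)
  if (!identical(rownames(S), as.character(metabolites$id)) ||
      !identical(colnames(S), as.character(reactions$id)))
    stop("stoichiometry dimnames must match metabolite and reaction ids")
  if (any(reactions$lb > reactions$ub))
    stop("reaction bounds must satisfy lb <= ub")
  if (sum(reactions$objective) != 1L)
    stop("exactly one reaction must carry the biomass objective")
  gpr_genes <- unique(unlist(lapply(reactions$gpr, gpr_gene_ids)))
  if (is.null(genes)) genes <- gpr_genes
  missing <- setdiff(gpr_genes, genes)
  if (length(missing))
    stop("gpr references undeclared gene(s): ",
         paste(missing, collapse = ", "))
  reactions$exchange <- colSums(S != 0) == 1L
  rownames(reactions) <- rownames(metabolites) <- NULL
  structure(list(metabolites = metabolites, reactions = reactions,
                 S = S, genes = genes),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf(
    "metabolic_model: %d metabolites, %d reactions (%d exchange), %d genes\n",
    nrow(x$metabolites), nrow(x$reactions), sum(x$reactions$exchange),
    length(x$genes)))
  cat("objective:", x$reactions$id[x$reactions$objective], "\n")
  invisible(x)
}

# ---- GPR rules ------------------------------------------------------------

gpr_tokens <- function(gpr) {
  if (is.na(gpr) || !nzchar(trimws(gpr))) return(character())
  spaced <- gsub("([()])", " \\1 ", gpr)
  toks <- strsplit(trimws(spaced), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Gene ids referenced by a GPR rule
#' @param gpr GPR expression string.
#' @return character vector of gene ids (empty for empty rules).
#' @export
gpr_gene_ids <- function(gpr) {
  toks <- gpr_tokens(gpr)
  unique(toks[!(tolower(toks) %in% c("and", "or")) & !(toks %in% c("(", ")"))])
}

#' Evaluate a GPR rule under a gene knockout state
#'
#' AND joins subunits of a complex, OR joins isozymes. An empty rule means
#' the reaction needs no gene product and survives any deletion.
#'
#' @param gpr GPR expression string.
#' @param gene_states named logical vector; genes not named are considered
#'   present (TRUE).
#' @return logical: is the reaction still catalyzed?
#' @export
eval_gpr <- function(gpr, gene_states = logical()) {
  toks <- gpr_tokens(gpr)
  if (!length(toks)) return(TRUE)
  expr <- vapply(toks, function(tk) {
    lt <- tolower(tk)
    if (lt == "and") "&" else if (lt == "or") "|"
    else if (tk %in% c("(", ")")) tk
    else sprintf("`%s`", tk)
  }, "")
  env <- new.env(parent = baseenv())
  for (g in gpr_gene_ids(gpr))
    assign(g, if (g %in% names(gene_states)) gene_states[[g]] else TRUE,
           envir = env)
  out <- try(eval(parse(text = paste(expr, collapse = " "))[[1]], env),
             silent = TRUE)
  if (inherits(out, "try-error") || !is.logical(out) || is.na(out))
    stop("malformed gpr rule: ", gpr)
  out
}

# ---- reaction equation strings -------------------------------------------

parse_equation_side <- function(side) {
  side <- trimws(side)
  if (!nzchar(side)) return(stats::setNames(numeric(), character()))
  terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  coefs <- numeric(); mets <- character()
  for (term in terms) {
    parts <- strsplit(term, "\\s+")[[1]]
    if (length(parts) == 1L) {
      coefs <- c(coefs, 1); mets <- c(mets, parts)
    } else if (length(parts) == 2L &&
               !is.na(suppressWarnings(as.numeric(parts[1])))) {
      coefs <- c(coefs, as.numeric(parts[1])); mets <- c(mets, parts[2])
    } else {
      stop("malformed equation term: '", term, "'")
    }
  }
  stats::setNames(coefs, mets)
}

#' Parse a reaction equation string
#'
#' Dialect: `"2 A[c] + B[c] --> C[c]"`. Either side may be empty (exchange
#' reactions, e.g. `"A[e] -->"`). The arrow is `-->`; reversibility is
#' carried by the bounds columns, not the arrow.
#'
#' @param equation equation string.
#' @return named numeric vector of stoichiometric coefficients
#'   (consumption negative).
#' @export
parse_reaction_equation <- function(equation) {
  sides <- strsplit(equation, "-->", fixed = TRUE)[[1]]
  if (length(sides) > 2L || !grepl("-->", equation, fixed = TRUE))
    stop("equation must contain a single '-->': '", equation, "'")
  lhs <- parse_equation_side(sides[1])
  rhs <- parse_equation_side(if (length(sides) == 2L) sides[2] else "")
  mets <- union(names(lhs), names(rhs))
  out <- stats::setNames(numeric(length(mets)), mets)
  out[names(lhs)] <- out[names(lhs)] - lhs
  out[names(rhs)] <- out[names(rhs)] + rhs
  out[out != 0]
}

format_reaction_equation <- function(stoich) {
  fmt <- function(v) paste(
    ifelse(abs(v) == 1, names(v), sprintf("%g %s", abs(v), names(v))),
    collapse = " + ")
  paste(fmt(stoich[stoich < 0]), "-->", fmt(stoich[stoich > 0]))
}

met_compartment <- function(met_id) {
  m <- regmatches(met_id, regexec("\\[([^]]+)\\]$", met_id))[[1]]
  if (length(m) == 2L) m[2] else "c"
}

# build a model from a reactions table (id, equation, lb, ub, gpr,
# objective); shared by the tabular reader and the toy-model factory
model_from_table <- function(tab, genes = NULL) {
  stoichs <- lapply(seq_len(nrow(tab)), function(i)
    tryCatch(parse_reaction_equation(tab$equation[i]),
             error = function(e) stop("reaction '", tab$id[i], "': ",
                                      conditionMessage(e), call. = FALSE)))
  mets <- unique(unlist(lapply(stoichs, names)))
  S <- matrix(0, length(mets), nrow(tab),
              dimnames = list(mets, tab$id))
  for (i in seq_along(stoichs)) S[names(stoichs[[i]]), i] <- stoichs[[i]]
  metabolites <- data.frame(
    id = mets, compartment = vapply(mets, met_compartment, ""),
    stringsAsFactors = FALSE)
  reactions <- data.frame(id = tab$id, lb = tab$lb, ub = tab$ub,
                          gpr = tab$gpr,
                          objective = as.logical(tab$objective),
                          stringsAsFactors = FALSE)
  metabolic_model(metabolites, reactions, S, genes = genes)
}

#' Read / write the tabular reaction dialect
#'
#' TSV with one reaction per row and columns `id`, `equation`, `lb`, `ub`,
#' `gpr`, `objective`. Uptake is a negative flux on an exchange reaction
#' (a reaction with a single metabolite). Round-trips losslessly.
#'
#' @param model a [metabolic_model()].
#' @param path file path.
#' @return `read_metabolic_table` returns a [metabolic_model()].
#' @export
write_metabolic_table <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  eq <- vapply(seq_len(ncol(model$S)), function(j) {
    v <- model$S[, j]; format_reaction_equation(v[v != 0])
  }, "")
  tab <- data.frame(id = model$reactions$id, equation = eq,
                    lb = model$reactions$lb, ub = model$reactions$ub,
                    gpr = model$reactions$gpr,
                    objective = model$reactions$objective,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_metabolic_table
#' @export
read_metabolic_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = character())
  req <- c("id", "equation", "lb", "ub", "gpr", "objective")
  if (!all(req %in% names(tab)))
    stop("model table needs columns: ", paste(req, collapse = ", "))
  model_from_table(tab)
}

#' Read a metabolic model (SBML or tabular dialect)
#'
#' @param path file path.
#' @param dialect `"sbml"` or `"table"`; guessed from the file extension
#'   by default.
#' @return a [metabolic_model()].
#' @export
read_model <- function(path, dialect = c("auto", "sbml", "table")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "table"
  switch(dialect, sbml = read_sbml(path), table = read_metabolic_table(path))
}
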