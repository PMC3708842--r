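# Linear programming backend for flux balance analysis: the package's
# two-phase Bland-rule simplex (R/lp-solver.R) on the bounded standard
# form. Infinite bounds are replaced by a large box (FLUX_BIG) so every LP
# is bounded.

FLUX_BIG <- 1e5

solve_flux_lp <- function(S, lb, ub, objective, maximize = TRUE) {
  lp_bounded(S, pmax(lb, -FLUX_BIG), pmin(ub, FLUX_BIG), objective,
             maximize = maximize)
}

#' Maximize growth by flux balance analysis
#'
#' Solves the linear program: maximize the biomass objective flux subject
#' to steady-state mass balance (S v = 0) and the reaction flux bounds.
#'
#' @param model a [metabolic_model()].
#' @return object of class `flux_solution`: list with `status`
#'   (`"optimal"`, `"infeasible"` or `"failed"`), `objective` (growth
#'   rate, h^-1) and `fluxes` (named vector).
#' @export
fba_max_growth <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  obj <- as.numeric(model$reactions$objective)
  sol <- solve_flux_lp(model$S, model$reactions$lb, model$reactions$ub, obj)
  names(sol$fluxes) <- model$reactions$id
  structure(sol, class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  if (x$status == "optimal")
    cat(sprintf("flux_solution: optimal, growth %.6g\n", x$objective))
  else cat("flux_solution:", x$status, "\n")
  invisible(x)
}

#' Configure a computational minimal medium
#'
#' Closes the uptake (lower) bound of every exchange reaction except a
#' whitelist of freely available inorganic exchanges, then opens the named
#' carbon exchange at the given uptake rate (uptake is flux into the cell,
#' i.e. a negative exchange flux; the lower bound is set to `-uptake`).
#' Secretion (upper) bounds are untouched.
#'
#' @param model a [metabolic_model()].
#' @param carbon_exchange id of the sole carbon source's exchange
#'   reaction.
#' @param uptake maximum uptake rate in mmol gDW^-1 h^-1 (default 10).
#' @param keep_open ids of exchange reactions whose uptake stays at its
#'   current bound (minerals, water, ...); default none.
#' @return the modified model.
#' @export
set_minimal_medium <- function(model, carbon_exchange, uptake = 10,
                               keep_open = character()) {
  stopifnot(inherits(model, "metabolic_model"))
  ex <- model$reactions$exchange
  if (!carbon_exchange %in% model$reactions$id[ex])
    stop("'", carbon_exchange, "' is not an exchange reaction")
  close_idx <- ex & !(model$reactions$id %in% c(carbon_exchange, keep_open))
  model$reactions$lb[close_idx] <- pmax(model$reactions$lb[close_idx], 0)
  model$reactions$lb[model$reactions$id == carbon_exchange] <- -uptake
  model
}

#' Growth after deleting a gene
#'
#' Evaluates every reaction's GPR rule with the gene absent; reactions
#' whose rule evaluates false lose their flux (bounds set to 0), and
#' growth is re-maximized. The gene is essential for maximum growth if the
#' deletion lowers the optimum by more than `tol` relative (a gene can be
#' essential for maximum growth yet leave nonzero growth).
#'
#' @param model a [metabolic_model()].
#' @param gene declared gene id.
#' @param tol relative growth-difference tolerance (default 1e-6,
#'   numerical LP noise).
#' @return list with `growth`, `full_growth`, `essential_for_max`,
#'   `disabled_reactions`.
#' @export
gene_deletion_growth <- function(model, gene, tol = 1e-6) {
  stopifnot(inherits(model, "metabolic_model"))
  if (!gene %in% model$genes) stop("unknown gene: ", gene)
  full <- fba_max_growth(model)
  if (full$status != "optimal") stop("base model does not solve")
  state <- stats::setNames(FALSE, gene)
  off <- !vapply(model$reactions$gpr, eval_gpr, TRUE,
                 gene_states = state)
  del_model <- model
  del_model$reactions$lb[off] <- 0
  del_model$reactions$ub[off] <- 0
  del <- fba_max_growth(del_model)
  growth <- if (del$status == "optimal") del$objective else 0
  list(growth = growth, full_growth = full$objective,
       essential_for_max = (full$objective - growth) >
         tol * max(full$objective, .Machine$double.eps),
       disabled_reactions = model$reactions$id[off])
}

#' Growth as a function of a fixed flux
#'
#' For each value, the reaction's flux is clamped (lb = ub = value) and
#' growth re-maximized; values outside the feasible region are reported as
#' infeasible.
#'
#' @param model a [metabolic_model()].
#' @param reaction reaction id to clamp.
#' @param values numeric vector of flux values.
#' @return data.frame with columns flux, growth (NA when infeasible),
#'   status.
#' @export
flux_scan <- function(model, reaction, values) {
  stopifnot(inherits(model, "metabolic_model"))
  j <- match(reaction, model$reactions$id)
  if (is.na(j)) stop("unknown reaction: ", reaction)
  rows <- lapply(values, function(v) {
    m <- model
    m$reactions$lb[j] <- v
    m$reactions$ub[j] <- v
    sol <- fba_max_growth(m)
    data.frame(flux = v,
               growth = if (sol$status == "optimal") sol$objective
               else NA_real_,
               status = sol$status, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Flux variability analysis
#'
#' With the biomass flux held at (1 - `opt_tol`) times its optimum or
#' better, each reaction's flux is minimized and maximized in turn, giving
#' the attainable flux range at (near-)maximal growth. A reaction whose
#' whole range lies within `zero_tol` of zero must be off for maximum
#' growth.
#'
#' @param model a [metabolic_model()].
#' @param opt_tol fraction of the optimum the objective may drop (default
#'   0: maximum growth exactly, within solver tolerance).
#' @param zero_tol absolute flux threshold for the zero-required flag
#'   (default 1e-6 mmol gDW^-1 h^-1).
#' @return object of class `fva_result`: data.frame with columns reaction,
#'   min, max, zero_required; attributes `growth` and `opt_tol`.
#' @export
fva <- function(model, opt_tol = 0, zero_tol = 1e-6) {
  stopifnot(inherits(model, "metabolic_model"))
  if (opt_tol < 0 || opt_tol >= 1) stop("'opt_tol' must be in [0, 1)")
  base <- fba_max_growth(model)
  if (base$status != "optimal")
    stop("base model is ", base$status, "; FVA needs a finite optimum")
  m <- model
  j_obj <- which(m$reactions$objective)
  m$reactions$lb[j_obj] <- max(m$reactions$lb[j_obj],
                               (1 - opt_tol) * base$objective)

  n <- nrow(m$reactions)
  mins <- maxs <- numeric(n)
  for (j in seq_len(n)) {
    obj <- numeric(n); obj[j] <- 1
    lo <- solve_flux_lp(m$S, m$reactions$lb, m$reactions$ub, obj,
                        maximize = FALSE)
    hi <- solve_flux_lp(m$S, m$reactions$lb, m$reactions$ub, obj,
                        maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem failed for reaction ", m$reactions$id[j])
    mins[j] <- lo$objective; maxs[j] <- hi$objective
  }
  out <- data.frame(reaction = m$reactions$id, min = mins, max = maxs,
                    zero_required = abs(mins) <= zero_tol &
                      abs(maxs) <= zero_tol,
                    stringsAsFactors = FALSE)
  structure(out, class = c("fva_result", "data.frame"),
            growth = base$objective, opt_tol = opt_tol,
            zero_tol = zero_tol)
}

#' Genes in pathways that must be off at maximum growth
#'
#' Collects the genes that (alone or in combination) directly catalyze a
#' reaction whose flux must be zero for maximum growth (from [fva()]), and
#' removes those that are themselves essential for maximum growth, leaving
#' the non-essential genes whose activity the cell must silence to grow
#' optimally.
#'
#' @param model a [metabolic_model()].
#' @param fva_result an [fva()] result computed on the same model and
#'   medium.
#' @param essential_flags named logical vector gene -> essential for
#'   maximum growth; computed via [gene_deletion_growth()] for every gene
#'   when omitted.
#' @return object of class `must_off_report`: list with
#'   `zero_required_reactions`, `implicated_genes`, `essential_excluded`,
#'   `genes` (final non-essential implicated set) and `count`.
#' @export
must_be_off_genes <- function(model, fva_result, essential_flags = NULL) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(fva_result, "fva_result"))
  if (is.null(essential_flags)) {
    essential_flags <- vapply(
      model$genes,
      function(g) gene_deletion_growth(model, g)$essential_for_max,
      logical(1))
  }
  zero_rxns <- fva_result$reaction[fva_result$zero_required]
  idx <- match(zero_rxns, model$reactions$id)
  implicated <- unique(unlist(lapply(model$reactions$gpr[idx],
                                     gpr_gene_ids)))
  if (is.null(implicated)) implicated <- character()
  essential <- names(essential_flags)[essential_flags]
  final <- setdiff(implicated, essential)
  structure(list(zero_required_reactions = zero_rxns,
                 implicated_genes = implicated,
                 essential_excluded = intersect(implicated, essential),
                 genes = final, count = length(final)),
            class = "must_off_report")
}

#' @export
print.must_off_report <- function(x, ...) {
  cat(sprintf(
    "must_off_report: %d zero-required reaction(s), %d implicated gene(s), %d non-essential\n",
    length(x$zero_required_reactions), length(x$implicated_genes), x$count))
  if (x$count) cat("genes:", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}
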