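#' Toy metabolic models with known optima
#'
#' Small stoichiometrically consistent models, each with a biomass
#' objective, a single exchanged carbon source (uptake bound 10), GPR
#' rules, and a closed-form optimal growth rate stored in the
#' `analytic_optimum` attribute. They are desk-scale analogs of the flux
#' configurations that make forced pathway activity costly:
#'
#' * `linear_chain` - substrate -> biomass through one unbranched path;
#'   optimum 10, bound-limited by uptake.
#' * `futile_cycle` - uptake splits between a carbon branch and an energy
#'   branch feeding biomass (B + E -> biomass); a two-reaction cycle burns
#'   energy without net product, so growth is (10 - cycle flux)/2 and the
#'   cycle must be off at the optimum of 5.
#' * `costly_bypass` - a direct conversion competes with a bypass that
#'   additionally consumes energy; the bypass must be off at the optimum
#'   of 20/3.
#' * `parallel_paths` - two isozyme-like branches share the flux; optimum
#'   10 with neither branch forced to zero, and the uptake step carries an
#'   OR rule over two genes.
#'
#' @param variant one of `"linear_chain"`, `"futile_cycle"`,
#'   `"costly_bypass"`, `"parallel_paths"`.
#' @return a [metabolic_model()] with attribute `analytic_optimum`.
#' @export
make_toy_metabolic_model <- function(variant = c("linear_chain",
                                                 "futile_cycle",
                                                 "costly_bypass",
                                                 "parallel_paths")) {
  variant <- match.arg(variant)
  row <- function(id, equation, lb, ub, gpr = "", objective = FALSE)
    data.frame(id = id, equation = equation, lb = lb, ub = ub, gpr = gpr,
               objective = objective, stringsAsFactors = FALSE)
  tab <- switch(variant,
    linear_chain = rbind(
      row("EX_A",    "A[e] -->",          -10, 1000),
      row("UPT",     "A[e] --> A[c]",       0, 1000, "g_upt"),
      row("CONV",    "A[c] --> B[c]",       0, 1000, "g_conv"),
      row("BIOMASS", "B[c] -->",            0, 1000, objective = TRUE)),
    futile_cycle = rbind(
      row("EX_A",    "A[e] -->",          -10, 1000),
      row("UPT",     "A[e] --> A[c]",       0, 1000, "g_upt"),
      row("R_B",     "A[c] --> B[c]",       0, 1000, "g_b"),
      row("R_E",     "A[c] --> E[c]",       0, 1000, "g_e"),
      row("CYC1",    "B[c] + E[c] --> D[c]", 0, 1000, "g_cyc"),
      row("CYC2",    "D[c] --> B[c]",       0, 1000, "g_cyc"),
      row("BIOMASS", "B[c] + E[c] -->",     0, 1000, objective = TRUE)),
    costly_bypass = rbind(
      row("EX_A",    "A[e] -->",          -10, 1000),
      row("UPT",     "A[e] --> A[c]",       0, 1000, "g_upt"),
      row("R_E",     "A[c] --> 2 E[c]",     0, 1000, "g_e"),
      row("R_DIR",   "A[c] --> B[c]",       0, 1000, "g_dir"),
      row("R_BYP",   "A[c] + E[c] --> B[c]", 0, 1000, "g_byp"),
      row("BIOMASS", "B[c] + E[c] -->",     0, 1000, objective = TRUE)),
    parallel_paths = rbind(
      row("EX_A",    "A[e] -->",          -10, 1000),
      row("UPT",     "A[e] --> A[c]",       0, 1000, "g_u1 or g_u2"),
      row("P1",      "A[c] --> B[c]",       0, 1000, "g_p1"),
      row("P2",      "A[c] --> B[c]",       0, 1000, "g_p2"),
      row("BIOMASS", "B[c] -->",            0, 1000, objective = TRUE)))
  model <- model_from_table(tab)
  attr(model, "analytic_optimum") <- switch(variant,
    linear_chain = 10, futile_cycle = 5, costly_bypass = 20 / 3,
    parallel_paths = 10)
  attr(model, "variant") <- variant
  model
}
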