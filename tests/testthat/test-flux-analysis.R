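toy_variants <- c("linear_chain", "futile_cycle", "costly_bypass",
                  "parallel_paths")

test_that("model construction validates structure and GPR rules", {
  tab <- data.frame(id = "R1", equation = "A[c] --> Bmissing",
                    lb = 0, ub = 10, gpr = "", objective = TRUE)
  m <- lofadapt:::model_from_table(tab)   # both metabolites auto-declared
  expect_s3_class(m, "metabolic_model")
  expect_error(lofadapt:::model_from_table(
    data.frame(id = "R1", equation = "A[c] >> B[c]", lb = 0, ub = 1,
               gpr = "", objective = TRUE)), "R1")
  expect_error(lofadapt:::model_from_table(
    data.frame(id = "R1", equation = "A[c] --> B[c]", lb = 5, ub = 1,
               gpr = "", objective = TRUE)), "lb <= ub")
  expect_error(lofadapt:::model_from_table(
    data.frame(id = c("R1", "R2"), equation = c("A[c] -->", "B[c] -->"),
               lb = 0, ub = 1, gpr = "", objective = c(TRUE, TRUE))),
    "exactly one")

  expect_true(eval_gpr("", c(g1 = FALSE)))
  expect_true(eval_gpr("g1 or g2", c(g1 = FALSE)))
  expect_false(eval_gpr("g1 and g2", c(g1 = FALSE)))
  expect_false(eval_gpr("g1 and (g2 or g3)", c(g2 = FALSE, g3 = FALSE)))
  expect_error(eval_gpr("g1 and and g2"), "malformed")
  expect_identical(sort(gpr_gene_ids("g1 and (g2 or g1)")), c("g1", "g2"))
})

test_that("tabular and SBML dialects round-trip models losslessly", {
  for (v in toy_variants) {
    m <- make_toy_metabolic_model(v)
    tsv <- withr::local_tempfile(fileext = ".tsv")
    xml <- withr::local_tempfile(fileext = ".xml")
    write_metabolic_table(m, tsv)
    write_sbml(m, xml)
    mt <- read_model(tsv)
    mx <- read_model(xml)
    for (back in list(mt, mx)) {
      expect_identical(back$reactions$id, m$reactions$id)
      expect_equal(back$reactions$lb, m$reactions$lb)
      expect_equal(back$reactions$ub, m$reactions$ub)
      expect_identical(back$reactions$gpr, m$reactions$gpr)
      expect_identical(back$reactions$objective, m$reactions$objective)
      expect_equal(back$S[rownames(m$S), colnames(m$S)], m$S)
      expect_identical(sort(back$genes), sort(m$genes))
    }
  }
})

test_that("FBA optima match closed forms and the vertex oracle", {
  for (v in toy_variants) {
    m <- make_toy_metabolic_model(v)
    sol <- fba_max_growth(m)
    expect_identical(sol$status, "optimal")
    expect_equal(sol$objective, attr(m, "analytic_optimum"),
                 tolerance = 1e-6)
    expect_equal(sol$objective, oracle_fba(m), tolerance = 1e-6)
    # mass balance at the optimum
    expect_lt(max(abs(m$S %*% sol$fluxes)), 1e-6)
  }

  # all-zero bounds give zero growth
  m0 <- make_toy_metabolic_model("linear_chain")
  m0$reactions$lb[] <- 0; m0$reactions$ub[] <- 0
  expect_equal(fba_max_growth(m0)$objective, 0, tolerance = 1e-9)

  # a bounded useless reaction does not change the optimum
  tab <- data.frame(
    id = c("EX_A", "UPT", "CONV", "BIOMASS", "USELESS"),
    equation = c("A[e] -->", "A[e] --> A[c]", "A[c] --> B[c]",
                 "B[c] -->", "X[c] --> Y[c]"),
    lb = c(-10, 0, 0, 0, 0), ub = c(1000, 1000, 1000, 1000, 5),
    gpr = "", objective = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(fba_max_growth(lofadapt:::model_from_table(tab))$objective,
               10, tolerance = 1e-6)
})

test_that("minimal-medium setup controls uptake correctly", {
  m <- make_toy_metabolic_model("linear_chain")
  expect_error(set_minimal_medium(m, "CONV"), "not an exchange")
  m0 <- set_minimal_medium(m, "EX_A", uptake = 0)
  expect_equal(fba_max_growth(m0)$objective, 0, tolerance = 1e-9)
  m10 <- set_minimal_medium(m, "EX_A", uptake = 10)
  m20 <- set_minimal_medium(m, "EX_A", uptake = 20)
  expect_equal(fba_max_growth(m10)$objective, 10, tolerance = 1e-6)
  expect_equal(fba_max_growth(m20)$objective,
               2 * fba_max_growth(m10)$objective, tolerance = 1e-6)
})

test_that("gene deletions follow the GPR rules", {
  m <- make_toy_metabolic_model("linear_chain")
  # declared gene absent from every rule: growth unchanged, non-essential
  m$genes <- c(m$genes, "g_orphan")
  d0 <- gene_deletion_growth(m, "g_orphan")
  expect_equal(d0$growth, d0$full_growth, tolerance = 1e-9)
  expect_false(d0$essential_for_max)
  # sole gene of the only biomass-feeding conversion: growth 0, essential
  d1 <- gene_deletion_growth(m, "g_conv")
  expect_equal(d1$growth, 0, tolerance = 1e-9)
  expect_true(d1$essential_for_max)
  expect_error(gene_deletion_growth(m, "nope"), "unknown gene")

  # isozymes: deleting one of an OR pair leaves growth unchanged
  p <- make_toy_metabolic_model("parallel_paths")
  expect_equal(gene_deletion_growth(p, "g_u1")$growth, 10, tolerance = 1e-6)
  expect_equal(gene_deletion_growth(p, "g_p1")$growth, 10, tolerance = 1e-6)
  # the costly bypass's direct route is essential for *maximum* growth
  # even though its loss leaves nonzero growth
  cb <- make_toy_metabolic_model("costly_bypass")
  dd <- gene_deletion_growth(cb, "g_dir")
  expect_true(dd$essential_for_max)
  expect_gt(dd$growth, 0)

  # oracle check: deletion growth equals vertex enumeration on the
  # bound-disabled model
  del <- cb
  off <- !vapply(cb$reactions$gpr, eval_gpr, TRUE,
                 gene_states = c(g_dir = FALSE))
  del$reactions$lb[off] <- 0; del$reactions$ub[off] <- 0
  expect_equal(dd$growth, oracle_fba(del), tolerance = 1e-6)
})

test_that("flux scans trace the LP value function", {
  m <- make_toy_metabolic_model("futile_cycle")
  opt <- fba_max_growth(m)
  sc <- flux_scan(m, "CYC1", c(0, 1, 2, 5, 8, 10))
  expect_equal(sc$growth[1], opt$objective, tolerance = 1e-6)
  expect_true(all(diff(sc$growth) <= 1e-9))      # non-increasing in |v|
  # concavity on the 5-point interior grid
  g <- sc$growth[1:5]
  expect_true(all(diff(diff(g)) <= 1e-6))
  # clamping at the optimal flux reproduces the unconstrained optimum
  sc0 <- flux_scan(m, "BIOMASS", opt$objective)
  expect_equal(sc0$growth, opt$objective, tolerance = 1e-6)
  out <- flux_scan(m, "CYC1", 50)
  expect_identical(out$status, "infeasible")
  expect_true(is.na(out$growth))
  expect_error(flux_scan(m, "NOPE", 0), "unknown reaction")
})

test_that("FVA ranges and zero-required sets match vertex enumeration", {
  for (v in toy_variants) {
    m <- make_toy_metabolic_model(v)
    got <- fva(m)
    oracle <- oracle_fva(m)
    expect_equal(got$min, oracle$min, tolerance = 1e-6)
    expect_equal(got$max, oracle$max, tolerance = 1e-6)
    # FVA brackets the FBA solution
    flux <- fba_max_growth(m)$fluxes
    expect_true(all(flux >= got$min - 1e-6 & flux <= got$max + 1e-6))
  }
  lc <- fva(make_toy_metabolic_model("linear_chain"))
  expect_equal(lc$min, lc$max, tolerance = 1e-9)   # unique pathway
  fc <- fva(make_toy_metabolic_model("futile_cycle"))
  expect_identical(fc$reaction[fc$zero_required], c("CYC1", "CYC2"))
  pp <- fva(make_toy_metabolic_model("parallel_paths"))
  expect_false(any(pp$zero_required))
  branches <- pp$reaction %in% c("P1", "P2")
  expect_true(all(pp$max[branches] - pp$min[branches] > 1))
})

test_that("must-be-off reports implicate the cycle genes only", {
  m <- make_toy_metabolic_model("futile_cycle")
  rep0 <- must_be_off_genes(make_toy_metabolic_model("linear_chain"),
                            fva(make_toy_metabolic_model("linear_chain")))
  expect_identical(rep0$count, 0L)
  rep1 <- must_be_off_genes(m, fva(m))
  expect_identical(rep1$genes, "g_cyc")
  expect_identical(rep1$zero_required_reactions, c("CYC1", "CYC2"))

  # membership rule: a gene also catalyzing an active reaction is still
  # implicated when it appears in a zero-required reaction's rule
  m2 <- m
  m2$reactions$gpr[m2$reactions$id == "CYC1"] <- "g_cyc or g_b"
  rep2 <- must_be_off_genes(m2, fva(m2))
  expect_true(all(c("g_cyc", "g_b") %in% rep2$implicated_genes))
  # g_b also catalyzes the essential carbon branch, so it is excluded as
  # essential; only the dedicated cycle gene survives into the final set
  expect_identical(rep2$essential_excluded, "g_b")
  expect_identical(rep2$genes, "g_cyc")
})

test_that("optima scale with proportional bounds", {
  for (v in c("linear_chain", "costly_bypass")) {
    m <- make_toy_metabolic_model(v)
    m2 <- m
    m2$reactions$lb <- 2 * m$reactions$lb
    m2$reactions$ub <- pmin(2 * m$reactions$ub, 1e5)
    expect_equal(fba_max_growth(m2)$objective,
                 2 * fba_max_growth(m)$objective, tolerance = 1e-6)
  }
})
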