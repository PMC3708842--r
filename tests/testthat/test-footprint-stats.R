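# helper: build a small footprint dataset from a log2 matrix
fp_from_log2 <- function(L, n_ref, reps) {
  conds <- rep(names(reps), reps)
  ids <- c(sprintf("ref_%d", seq_len(n_ref)),
           sprintf("sel_%s_%d", conds, unlist(lapply(reps, seq_len))))
  arrays <- data.frame(
    array = ids,
    role = c(rep("ref", n_ref), rep("sel", sum(reps))),
    condition = c(rep(NA, n_ref), conds),
    replicate = c(rep(NA, n_ref), unlist(lapply(reps, seq_len))))
  colnames(L) <- ids
  rownames(L) <- sprintf("g%03d", seq_len(nrow(L)))
  footprint_dataset(2^L, arrays)
}

test_that("summary statistic follows the sign-concordant minimum rule", {
  expect_identical(summarize_gene(c(0.8, 1.2, 2.0)), 0.8)
  expect_identical(summarize_gene(c(1.2, -0.3, 2.0)), 0)
  expect_identical(summarize_gene(c(-0.5, -0.9)), -0.5)
  expect_identical(summarize_gene(c(0, 1, 2)), 0)     # zero has no sign
  expect_identical(summarize_gene(1.7), 1.7)
  expect_error(summarize_gene(numeric()), "no replicate")
  # property: |s| <= min |replicates|, sign shared or zero
  set.seed(1)
  for (i in 1:200) {
    v <- stats::rnorm(sample(2:5, 1))
    s <- summarize_gene(v)
    expect_lte(abs(s), min(abs(v)))
    expect_true(s == 0 || sign(s) %in% sign(v))
  }
  # vectorized null path agrees with the scalar rule
  m <- matrix(stats::rnorm(300), 100, 3)
  expect_equal(lofadapt:::summarize_rows(m), apply(m, 1, summarize_gene))
})

test_that("normalization centres unselected genes and recovers offsets", {
  set.seed(21)
  n <- 200
  base <- stats::rnorm(n, 0, 1.5)
  L <- replicate(8, base + stats::rnorm(n, 0, 0.05))
  hit <- which(rank(base) == n %/% 2)  # mid-intensity gene
  L[hit, 6] <- base[hit] + 2           # offset +2 in one selected array
  ds <- fp_from_log2(L, n_ref = 5, reps = c(ala = 3))
  nm <- normalize_footprint(ds, span = 0.3)
  sel1 <- nm$values[, "sel_ala_1"]
  # derived oracle: direct subtraction of the reference mean
  direct <- L[, 6] - rowMeans(L[, 1:5])
  expect_equal(unname(sel1[hit]), unname(direct[hit]), tolerance = 0.15)
  expect_equal(unname(sel1[hit]), 2, tolerance = 0.15)
  expect_lt(max(abs(sel1[-hit])), 0.2)
  expect_lt(abs(mean(sel1[-hit])), 0.05)
  expect_error(normalize_footprint(ds, span = 0), "span")
  # fewer than 2 reference arrays rejected
  ds1 <- fp_from_log2(L[, -(2:5)], n_ref = 1, reps = c(ala = 3))
  expect_error(normalize_footprint(ds1), "2 reference")
})

test_that("loess normalization removes smooth intensity-dependent bias", {
  cfg <- footprint_sim_config(seed = 17, n_genes = 5000,
                              replicates_per_condition = c(sel = 3),
                              bias_amplitude = 0.5)
  sim <- simulate_footprint_dataset(cfg)
  nm <- normalize_footprint(sim$dataset, span = 0.3)
  sel <- nm$arrays$array[nm$arrays$role == "sel"]
  for (j in sel)
    expect_lt(abs(stats::cor(nm$values[, j], nm$ref_mean)), 0.05)
})

test_that("normalization is idempotent on a flat noiseless dataset", {
  set.seed(8)
  base <- stats::rnorm(300, 0, 1.5)
  L <- replicate(8, base)          # every array identical: nothing to do
  ds <- fp_from_log2(L, n_ref = 5, reps = c(sel = 3))
  nm <- normalize_footprint(ds)
  expect_lt(mean(abs(nm$values)), 1e-8)   # regression on itself
  ds2 <- fp_from_log2(nm$values, n_ref = 5, reps = c(sel = 3))
  nm2 <- normalize_footprint(ds2)
  expect_lt(mean(abs(nm2$values - nm$values)), 1e-6)
})

test_that("null model reproduces seeds and degenerates to zeros", {
  # hand-built normalized object: all replicate sds zero, reference zero
  vals <- cbind(matrix(1, 50, 5), matrix(0.7, 50, 3))
  arrays <- data.frame(
    array = c(sprintf("ref_%d", 1:5), sprintf("sel_a_%d", 1:3)),
    role = c(rep("ref", 5), rep("sel", 3)),
    condition = c(rep(NA, 5), rep("a", 3)),
    replicate = c(rep(NA, 5), 1:3))
  vals[, 1:5] <- 0
  colnames(vals) <- arrays$array
  rownames(vals) <- sprintf("g%02d", 1:50)
  nm <- structure(list(values = vals, arrays = arrays,
                       ref_mean = rep(0, 50), span = 0.3),
                  class = "normalized_footprint")
  null <- build_null(nm, "a", n_pseudo = 1000, seed = 4)
  expect_identical(null$summaries, rep(0, 1000))
  expect_error(build_null(nm, "a", df = 2), "df")

  cfg <- footprint_sim_config(seed = 13, n_genes = 300,
                              replicates_per_condition = c(a = 3))
  nm2 <- normalize_footprint(simulate_footprint_dataset(cfg)$dataset)
  n1 <- build_null(nm2, "a", n_pseudo = 1000, seed = 99)
  n2 <- build_null(nm2, "a", n_pseudo = 1000, seed = 99)
  expect_identical(n1$summaries, n2$summaries)
})

test_that("null draw scale matches the sampled real-gene sd", {
  # constant-sd genes: pooled pseudo-replicate draws must have that sd
  set.seed(6)
  n <- 400
  vals <- cbind(matrix(stats::rnorm(n * 5, 0, 1e-8), n, 5),
                t(replicate(n, stats::rnorm(3, 0, 1))))
  # rescale each gene's selected replicates to sd exactly 0.5
  sel <- vals[, 6:8]
  sel <- sweep(sel - rowMeans(sel), 1, apply(sel, 1, stats::sd), "/") * 0.5
  vals[, 6:8] <- sel + 1
  arrays <- data.frame(
    array = c(sprintf("ref_%d", 1:5), sprintf("sel_a_%d", 1:3)),
    role = c(rep("ref", 5), rep("sel", 3)),
    condition = c(rep(NA, 5), rep("a", 3)),
    replicate = c(rep(NA, 5), 1:3))
  colnames(vals) <- arrays$array
  rownames(vals) <- sprintf("g%03d", seq_len(n))
  nm <- structure(list(values = vals, arrays = arrays,
                       ref_mean = rep(0, n), span = 0.3),
                  class = "normalized_footprint")
  null <- build_null(nm, "a", n_pseudo = 50000, df = 4, seed = 12,
                     keep_draws = TRUE)
  expect_equal(stats::sd(as.vector(null$draws)), 0.5, tolerance = 0.02)
})

test_that("empirical p-values count strict magnitude exceedances", {
  null <- structure(list(summaries = c(1, -1, 2, -2, 3, -3, 4, -4, 5, -5),
                         n_pseudo = 10L, df = 4, seed = 1, condition = "a",
                         n_replicates = 3L), class = "null_summary_model")
  expect_equal(unname(footprint_pvalues(2.5, null)), 6 / 10)
  expect_equal(unname(footprint_pvalues(0, null)), 1)   # all nonzero
  expect_equal(unname(footprint_pvalues(3, null)), 4 / 10)  # ties not counted
  expect_equal(unname(footprint_pvalues(99, null)), 1 / 10) # floored
})

test_that("plug-in FDR calling matches a brute-force threshold scan", {
  set.seed(33)
  p <- c(rep(1e-4, 20), stats::runif(980))
  res <- call_significant(p, target_fdr = 0.05)
  expect_true(all(res$significant[1:20]))
  expect_lte(res$fdr_estimate, 0.05)

  # oracle: try every observed p as threshold directly
  for (i in 1:20) {
    pv <- stats::runif(200)^sample(1:3, 1)
    got <- call_significant(pv, target_fdr = 0.1)
    ests <- vapply(pv, function(a) a * length(pv) / sum(pv <= a), 0)
    ok <- pv[ests <= 0.1]
    oracle_cut <- if (length(ok)) max(ok) else 0
    expect_equal(got$cutoff, oracle_cut)
    expect_identical(got$significant, pv <= oracle_cut & oracle_cut > 0)
  }
  none <- call_significant(rep(1, 50), target_fdr = 0.05)
  expect_identical(none$n_significant, 0L)
  expect_identical(none$cutoff, 0)
})

test_that("essential-gene exclusion drops listed genes only", {
  cfg <- footprint_sim_config(seed = 2, n_genes = 400,
                              replicates_per_condition = c(a = 2))
  ds <- simulate_footprint_dataset(cfg)$dataset
  expect_identical(exclude_essentials(ds, character())$values, ds$values)
  ess <- rownames(ds$values)[1:30]
  out <- exclude_essentials(ds, ess)
  expect_identical(nrow(out$values), 370L)
  expect_identical(attr(out, "n_excluded"), 30L)
  expect_warning(exclude_essentials(ds, c(ess, "nope")), "not present")
  expect_error(exclude_essentials(ds, rownames(ds$values)), "every gene")
})

test_that("detection power increases with spiked effect size", {
  power_at <- function(effect) {
    cfg <- footprint_sim_config(seed = 50, n_genes = 1000,
                                replicates_per_condition = c(a = 3),
                                frac_beneficial = 0.05,
                                effect_size = effect)
    sim <- simulate_footprint_dataset(cfg)
    res <- footprint_significance(sim$dataset, n_pseudo = 20000, seed = 50)
    truth <- sim$truth$gene[sim$truth$label == "beneficial"]
    hits <- res$calls$gene[res$calls$significant & res$calls$sign > 0]
    mean(truth %in% hits)
  }
  p <- vapply(c(1, 2, 4), power_at, 0)
  expect_true(all(diff(p) >= 0))
  expect_gte(p[3], 0.9)
})

test_that("footprint TSV round-trips datasets", {
  cfg <- footprint_sim_config(seed = 3, n_genes = 50,
                              replicates_per_condition = c(ala = 3,
                                                           asn = 2))
  ds <- simulate_footprint_dataset(cfg)$dataset
  path <- withr::local_tempfile(fileext = ".tsv")
  write_footprint_tsv(ds, path)
  back <- read_footprint_tsv(path)
  expect_equal(unname(back$values), unname(ds$values), tolerance = 1e-12)
  expect_identical(rownames(back$values), rownames(ds$values))
  expect_identical(back$arrays$role, ds$arrays$role)
  expect_identical(back$arrays$condition, ds$arrays$condition)
})
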