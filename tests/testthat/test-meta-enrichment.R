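test_that("call tables enforce disjoint subset structure", {
  tested <- list(c1 = c("a", "b", "c"))
  expect_error(condition_call_table(tested, list(c1 = c("a")),
                                    list(c1 = c("a")), c(a = "enzyme")),
               "overlap")
  expect_error(condition_call_table(tested, list(c1 = c("z")),
                                    list(c1 = character()), c(a = "enzyme")),
               "subsets")
  ct <- condition_call_table(tested, list(c1 = "a"), list(c1 = "b"),
                             c(a = "enzyme"))
  expect_identical(unname(ct$classes[c("b", "c")]),
                   c("unclassified", "unclassified"))
})

test_that("z-score calling picks the plug-in cutoff over the pooled matrix", {
  genes <- sprintf("g%03d", 1:100)
  z0 <- matrix(0, 100, 5, dimnames = list(genes, paste0("c", 1:5)))
  expect_warning(ct0 <- call_from_zscores(z0), "no attainable")
  expect_identical(sum(lengths(ct0$beneficial)), 0L)

  set.seed(2)
  z <- matrix(stats::rnorm(1000), 200, 5,
              dimnames = list(sprintf("g%03d", 1:200), paste0("c", 1:5)))
  z[1, 1] <- 10
  ct <- call_from_zscores(z, 0.05)
  expect_lte(attr(ct, "cutoff"), 10)
  expect_true("g001" %in% ct$beneficial$c1)

  # brute-force oracle over every observed |z| threshold, 500-entry matrix
  set.seed(9)
  zb <- matrix(c(stats::rnorm(490), stats::rnorm(10, 6)), 100, 5,
               dimnames = list(sprintf("g%03d", 1:100), paste0("c", 1:5)))
  got <- attr(call_from_zscores(zb, 0.05), "cutoff")
  az <- abs(as.vector(zb))
  est <- vapply(sort(unique(az)), function(cc)
    2 * stats::pnorm(cc, lower.tail = FALSE) * length(az) / sum(az >= cc), 0)
  oracle <- min(sort(unique(az))[est <= 0.05])
  expect_equal(got, oracle, tolerance = 1e-12)

  # monotone: stricter FDR never lowers the cutoff
  cuts <- vapply(c(0.2, 0.1, 0.05, 0.01), function(f)
    attr(call_from_zscores(zb, f), "cutoff"), 0)
  expect_true(all(diff(cuts) >= 0))
})

test_that("probe resampling p-values behave at the extremes", {
  set.seed(4)
  pool <- stats::rnorm(100)
  p_null <- probe_resampling_pvalue(rep(mean(pool), 5), pool,
                                    n_resamples = 2000, seed = 1)
  expect_gt(p_null, 0.5)
  p_top <- probe_resampling_pvalue(rep(max(pool), 5), pool,
                                   n_resamples = 2000, seed = 1)
  expect_lt(p_top, 0.01)
  expect_gte(p_top, 1 / 2001)
  expect_identical(
    probe_resampling_pvalue(1:3, pool, 500, seed = 7),
    probe_resampling_pvalue(1:3, pool, 500, seed = 7))
  # seed-invariance within Monte-Carlo error
  p1 <- probe_resampling_pvalue(pool[1:5], pool, 5000, seed = 1)
  p2 <- probe_resampling_pvalue(pool[1:5], pool, 5000, seed = 2)
  expect_lt(abs(p1 - p2), 2 / sqrt(5000))
  expect_error(probe_resampling_pvalue(numeric(), pool), "empty")
  expect_error(probe_resampling_pvalue(1:10, 1:5), "at least as large")
})

test_that("class enrichment resampling flags spikes and centres the null", {
  sim <- simulate_call_matrix(2000, 50, base_rate = 0.02,
                              spiked_classes = c(regulator = 5), seed = 21)
  enr <- resample_class_enrichment(sim$calls, "beneficial",
                                   n_draws = 2000, seed = 21)
  expect_true(enr$significant[enr$class == "regulator"])
  expect_identical(sum(enr$significant), 1L)

  # one class holding every gene: observed equals the condition sums, and
  # the simulated null is centred on it (p near 1/2 by binomial symmetry)
  one <- simulate_call_matrix(500, 20, base_rate = 0.05, seed = 5,
                              class_labels = rep("only", 500))
  e1 <- resample_class_enrichment(one$calls, "beneficial",
                                  n_draws = 4000, seed = 5)
  expect_identical(e1$observed, sum(lengths(one$calls$beneficial)))
  expect_equal(e1$p, 0.5, tolerance = 0.1)

  # a class with no tested members anywhere is not testable
  tested <- list(c1 = c("a", "b"))
  ct <- condition_call_table(tested, list(c1 = "a"), list(c1 = character()),
                             c(a = "enzyme", b = "enzyme", z = "ghost"))
  expect_error(resample_class_enrichment(ct, "beneficial", n_draws = 10),
               ">= 1000")

  # BH q-values agree with the direct definition
  q_oracle <- function(p) {
    m <- length(p); o <- order(p); q <- numeric(m)
    q[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
    pmin(q, 1)
  }
  expect_equal(enr$q, q_oracle(enr$p), tolerance = 1e-12)
})

test_that("class/condition fractions count recurrence correctly", {
  genes <- c("a", "b")
  tested <- stats::setNames(rep(list(genes), 20), sprintf("c%02d", 1:20))
  ben <- lapply(seq_len(20), function(i) {
    out <- character()
    if (TRUE) out <- c(out, "a")          # a beneficial everywhere
    if (i == 1) out <- c(out, "b")        # b in exactly 1 of 20
    out
  })
  names(ben) <- names(tested)
  del <- stats::setNames(rep(list(character()), 20), names(tested))
  ct <- condition_call_table(tested, ben, del, c(a = "x", b = "x"))
  fr <- class_condition_fractions(ct, "beneficial")
  expect_equal(fr$fraction[fr$threshold == 0.05], 1)       # both count
  expect_equal(fr$fraction[fr$threshold == 0.25], 0.5)     # only a
  expect_equal(fr$fraction[fr$threshold == 0.75], 0.5)
})

test_that("recurrent gene lists match direct counting", {
  sim <- simulate_call_matrix(300, 30, base_rate = 0.1, seed = 14)
  got <- recurrent_beneficial_genes(sim$calls, min_conditions = 5)
  counts <- table(unlist(sim$calls$beneficial))
  oracle <- sort(names(counts[counts >= 5]))
  expect_identical(sort(got$gene), oracle)
  expect_true(all(diff(got$n_conditions) <= 0))
  # boundary: exactly min_conditions is included
  k <- got$n_conditions[nrow(got)]
  expect_gte(k, 5)
  expect_identical(nrow(recurrent_beneficial_genes(sim$calls, 1000)), 0L)
})

test_that("null allele rate equals codon-table enumeration", {
  expect_identical(null_allele_rate(per_nt_rate = 0)$rate, 0)
  # codon whose nine neighbours are all sense codons
  expect_identical(null_allele_rate(codon_freq = c(CCC = 1))$rate, 0)

  # independent oracle: enumerate against the standard genetic code table
  gc_tab <- Biostrings::GENETIC_CODE
  rna <- names(gc_tab)
  dna <- chartr("U", "T", rna)
  stops <- dna[gc_tab == "*"]
  sense <- setdiff(dna, stops)
  hits <- 0L
  for (cod in sense) {
    s <- strsplit(cod, "")[[1]]
    for (pos in 1:3) for (b in setdiff(c("A", "C", "G", "T"), s[pos])) {
      mut <- s; mut[pos] <- b
      if (paste0(mut, collapse = "") %in% stops) hits <- hits + 1L
    }
  }
  p_oracle <- hits / (length(sense) * 9)
  got <- null_allele_rate()
  expect_equal(got$p_stop_gain, p_oracle, tolerance = 1e-12)
  expect_equal(got$rate, 1e-10 * 1000 * 0.5 * p_oracle, tolerance = 1e-12)
})

test_that("footprint calls convert into a call table", {
  cfg <- footprint_sim_config(seed = 61, n_genes = 300,
                              replicates_per_condition = c(a = 3),
                              frac_beneficial = 0.05, frac_deleterious = 0.05)
  sim <- simulate_footprint_dataset(cfg)
  res <- footprint_significance(sim$dataset, n_pseudo = 20000, seed = 61)
  classes <- stats::setNames(rep("enzyme", 300), rownames(sim$dataset$values))
  ct <- as_condition_call_table(res, classes)
  df <- res$calls
  expect_identical(sort(ct$beneficial$a),
                   sort(df$gene[df$significant & df$sign > 0]))
  expect_identical(sort(ct$deleterious$a),
                   sort(df$gene[df$significant & df$sign < 0]))
})
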