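#' Simulate a per-condition significance call matrix
#'
#' Generates a class-labelled [condition_call_table()] in which every
#' gene x condition call is drawn independently: beneficial calls at a
#' class-dependent rate (`base_rate` times the class's multiplier in
#' `spiked_classes`, 1 for unspiked classes) and deleterious calls at the
#' base rate for every class. Used as the test bed for the binomial
#' resampling class-enrichment statistics, with the spiked classes recorded
#' as ground truth.
#'
#' @param n_genes,n_conditions counts.
#' @param class_labels named character vector gene -> class; default
#'   assigns eight coarse functional classes (enzyme, regulator, membrane,
#'   carrier, structural, RNA, factor, cell process) with realistic
#'   proportions.
#' @param base_rate per-gene per-condition probability of a beneficial
#'   call for an unspiked class (default 0.02).
#' @param spiked_classes named numeric vector class -> rate multiplier;
#'   rates after multiplication must stay at or below 1.
#' @param seed integer seed.
#' @return list with `calls` (a [condition_call_table()]) and `truth`
#'   (list with `spiked_classes` and the per-class beneficial rates).
#' @export
simulate_call_matrix <- function(n_genes, n_conditions, class_labels = NULL,
                                 base_rate = 0.02,
                                 spiked_classes = numeric(), seed = 1L) {
  if (n_genes < 1L || n_conditions < 1L) stop("counts must be >= 1")
  check_fraction(base_rate, "base_rate", open_lo = FALSE)
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    if (is.null(class_labels)) {
      pool <- c(enzyme = 0.34, regulator = 0.10, membrane = 0.16,
                carrier = 0.08, structural = 0.06, RNA = 0.04,
                factor = 0.07, `cell process` = 0.15)
      pool <- c(pool, unclassified = 1 - sum(pool))
      class_labels <- stats::setNames(
        sample(names(pool), n_genes, replace = TRUE, prob = pool), genes)
    } else {
      if (length(class_labels) != n_genes)
        stop("'class_labels' must label every gene")
      names(class_labels) <- genes
    }
    mult <- stats::setNames(rep(1, length(unique(class_labels))),
                            unique(class_labels))
    if (length(spiked_classes)) {
      unknown <- setdiff(names(spiked_classes), names(mult))
      if (length(unknown))
        stop("spiked class not present in labels: ",
             paste(unknown, collapse = ", "))
      mult[names(spiked_classes)] <- spiked_classes
    }
    rate_ben <- base_rate * mult[class_labels]
    if (any(rate_ben > 1))
      stop("spiked multiplier drives a call rate above 1")

    conds <- sprintf("cond%03d", seq_len(n_conditions))
    tested <- ben <- del <- stats::setNames(vector("list", n_conditions),
                                            conds)
    for (cond in conds) {
      tested[[cond]] <- genes
      is_ben <- stats::runif(n_genes) < rate_ben
      # deleterious calls at the base rate, never overlapping beneficial
      is_del <- !is_ben & stats::runif(n_genes) < base_rate
      ben[[cond]] <- genes[is_ben]
      del[[cond]] <- genes[is_del]
    }
    list(calls = condition_call_table(tested, ben, del, class_labels),
         truth = list(spiked_classes = names(spiked_classes),
                      beneficial_rates = stats::setNames(
                        base_rate * mult, names(mult))))
  })
}

#' Simulate a two-replicate expression comparison
#'
#' Per-gene log2 ratios in two biological replicates: a true effect
#' (+`true_log2_effect` for `n_up` genes, the negative for `n_down`, zero
#' otherwise) plus independent Normal(0, `noise_sd`) noise per replicate.
#'
#' @param n_genes total genes; `n_up + n_down` must not exceed it.
#' @param n_up,n_down numbers of truly up-/down-regulated genes.
#' @param true_log2_effect magnitude of the true log2 change (default 2).
#' @param noise_sd per-replicate noise standard deviation (> 0).
#' @param seed integer seed.
#' @param condition contrast label.
#' @return list with `expr` (an [expression_comparison()]) and `truth`
#'   (data.frame gene/effect/label).
#' @export
simulate_expression_pair <- function(n_genes, n_up = 0L, n_down = 0L,
                                     true_log2_effect = 2, noise_sd = 0.3,
                                     seed = 1L, condition = "mutant_vs_parent") {
  if (n_up + n_down > n_genes) stop("n_up + n_down must be <= n_genes")
  if (noise_sd <= 0) stop("'noise_sd' must be > 0")
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    effect <- numeric(n_genes)
    changed <- sample.int(n_genes, n_up + n_down)
    if (n_up) effect[changed[seq_len(n_up)]] <- abs(true_log2_effect)
    if (n_down) effect[changed[n_up + seq_len(n_down)]] <-
        -abs(true_log2_effect)
    expr <- expression_comparison(
      genes,
      rep1 = effect + stats::rnorm(n_genes, 0, noise_sd),
      rep2 = effect + stats::rnorm(n_genes, 0, noise_sd),
      condition = condition)
    truth <- data.frame(gene = genes, effect = effect,
                        label = ifelse(effect > 0, "up",
                                       ifelse(effect < 0, "down", "null")),
                        stringsAsFactors = FALSE)
    list(expr = expr, truth = truth)
  })
}

#' Simulate an exponential growth curve with serial dilutions
#'
#' The undiluted-equivalent culture density grows as
#' `initial_od * 2^(t / doubling_time)`; each dilution event divides the
#' observed density by its factor from that time onward, and the recorded
#' cumulative dilution lets the fitting stage undo it. The observed
#' absorbance is the diluted density plus the blank background plus
#' Normal(0, `noise_sd`) reader noise.
#'
#' @param doubling_time minutes per doubling (> 0).
#' @param sample_times reading times in minutes, strictly increasing.
#' @param dilution_events optional data.frame with columns `time` and
#'   `factor` (> 1): cultures diluted `factor`-fold at `time`.
#' @param blank background absorbance (default 0.04).
#' @param noise_sd absorbance noise sd (default 0).
#' @param seed integer seed.
#' @param initial_od starting background-corrected absorbance (default
#'   0.01).
#' @param strain,media optional labels passed through.
#' @return a [growth_curve()].
#' @export
simulate_growth_curve <- function(doubling_time, sample_times,
                                  dilution_events = NULL, blank = 0.04,
                                  noise_sd = 0, seed = 1L,
                                  initial_od = 0.01,
                                  strain = NA_character_,
                                  media = NA_character_) {
  if (doubling_time <= 0) stop("'doubling_time' must be > 0")
  if (any(diff(sample_times) <= 0))
    stop("sample times must be strictly increasing")
  cumdil <- rep(1, length(sample_times))
  if (!is.null(dilution_events) && nrow(dilution_events)) {
    if (any(dilution_events$factor <= 1))
      stop("dilution factors must be > 1")
    ev <- dilution_events[order(dilution_events$time), , drop = FALSE]
    for (i in seq_len(nrow(ev)))
      cumdil[sample_times >= ev$time[i]] <-
        cumdil[sample_times >= ev$time[i]] * ev$factor[i]
  }
  with_seed(seed, {
    density <- initial_od * 2^(sample_times / doubling_time)
    noise <- if (noise_sd > 0)
      stats::rnorm(length(sample_times), 0, noise_sd) else 0
    growth_curve(sample_times, density / cumdil + blank + noise,
                 blank = blank, cumulative_dilution = cumdil,
                 strain = strain, media = media)
  })
}
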