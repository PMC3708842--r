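#' Per-condition significance call table
#'
#' Container for the meta-analysis: per condition, the set of genes tested
#' and the subsets whose null mutations were called significantly
#' beneficial or deleterious, plus a functional class label per gene
#' (enzyme, regulator, membrane, ...). Genes without a known class get
#' `"unclassified"`.
#'
#' @param tested named list condition -> character vector of tested genes.
#' @param beneficial,deleterious named lists condition -> character vector
#'   of called genes; must be disjoint subsets of the tested set for that
#'   condition.
#' @param classes named character vector gene -> functional class.
#' @return object of class `condition_call_table`.
#' @export
condition_call_table <- function(tested, beneficial, deleterious, classes) {
  conds <- names(tested)
  if (is.null(conds) || any(!nzchar(conds)))
    stop("'tested' must be a named list of conditions")
  beneficial <- beneficial[conds]; deleterious <- deleterious[conds]
  names(beneficial) <- conds; names(deleterious) <- conds
  for (cond in conds) {
    b <- beneficial[[cond]] <- as.character(beneficial[[cond]])
    d <- deleterious[[cond]] <- as.character(deleterious[[cond]])
    if (length(intersect(b, d)))
      stop("beneficial and deleterious sets overlap in condition ", cond)
    if (!all(c(b, d) %in% tested[[cond]]))
      stop("call sets must be subsets of the tested set in condition ", cond)
  }
  all_genes <- unique(unlist(tested))
  cl <- classes[all_genes]
  cl[is.na(cl)] <- "unclassified"
  names(cl) <- all_genes
  structure(list(conditions = conds, tested = tested,
                 beneficial = beneficial, deleterious = deleterious,
                 classes = cl),
            class = "condition_call_table")
}

#' @export
print.condition_call_table <- function(x, ...) {
  cat(sprintf(
    "condition_call_table: %d conditions, %d genes, %d classes\n",
    length(x$conditions), length(x$classes),
    length(unique(x$classes))))
  cat(sprintf("total beneficial calls %d, deleterious %d\n",
              sum(lengths(x$beneficial)), sum(lengths(x$deleterious))))
  invisible(x)
}

#' Build a call table from significance_calls output
#'
#' Convenience bridge from the footprint pipeline into the meta-analysis
#' containers.
#'
#' @param calls a [footprint_significance()] result.
#' @param classes named character vector gene -> functional class.
#' @return a [condition_call_table()].
#' @export
as_condition_call_table <- function(calls, classes) {
  stopifnot(inherits(calls, "significance_calls"))
  df <- calls$calls
  conds <- unique(df$condition)
  tested <- lapply(conds, function(cond) unique(df$gene[df$condition == cond]))
  ben <- lapply(conds, function(cond)
    df$gene[df$condition == cond & df$significant & df$sign > 0])
  del <- lapply(conds, function(cond)
    df$gene[df$condition == cond & df$significant & df$sign < 0])
  names(tested) <- names(ben) <- names(del) <- conds
  condition_call_table(tested, ben, del, classes)
}

#' Significance calling from a pooled z-score matrix
#'
#' For deletion-library datasets distributed as per-experiment z-scores
#' with a standard-normal null, a single |z| cutoff is chosen over the
#' pooled matrix: the smallest cutoff c whose plug-in estimate
#' `2 * (1 - Phi(c)) * N / #\{|z| >= c\}` is at or below the target FDR.
#' Entries with z >= c are beneficial, z <= -c deleterious.
#'
#' @param z numeric gene x condition matrix of z-scores (rownames = genes);
#'   NAs mark untested gene/condition pairs.
#' @param target_fdr pooled target FDR (default 0.05).
#' @param classes named character vector gene -> functional class.
#' @return a [condition_call_table()] with attribute `cutoff`.
#' @export
call_from_zscores <- function(z, target_fdr = 0.05,
                              classes = stats::setNames(
                                rep("unclassified", nrow(z)), rownames(z))) {
  check_fraction(target_fdr, "target_fdr", open_hi = TRUE)
  if (!is.matrix(z) || is.null(rownames(z)) || is.null(colnames(z)))
    stop("'z' must be a matrix with gene rownames and condition colnames")
  az <- abs(z[!is.na(z)])
  n_total <- length(az)
  cand <- sort(unique(az))
  n_ge <- n_total - findInterval(cand, sort(az), left.open = TRUE)  # #{|z| >= c}
  est <- 2 * stats::pnorm(cand, lower.tail = FALSE) * n_total / n_ge
  ok <- est <= target_fdr
  if (!any(ok)) {
    warning("no attainable cutoff at the requested FDR; no calls made")
    cutoff <- Inf
  } else {
    cutoff <- min(cand[ok])
  }
  conds <- colnames(z)
  tested <- lapply(conds, function(cond) rownames(z)[!is.na(z[, cond])])
  ben <- lapply(conds, function(cond)
    rownames(z)[!is.na(z[, cond]) & z[, cond] >= cutoff])
  del <- lapply(conds, function(cond)
    rownames(z)[!is.na(z[, cond]) & z[, cond] <= -cutoff])
  names(tested) <- names(ben) <- names(del) <- conds
  out <- condition_call_table(tested, ben, del, classes)
  attr(out, "cutoff") <- cutoff
  out
}

#' Probe-resampling p-value for a gene score
#'
#' Significance of a gene's mean probe-level score by resampling same-size
#' sets from the genome-wide pool of probe scores. Two-sided by magnitude;
#' the +1 numerator/denominator convention keeps finite-resampling p-values
#' strictly positive.
#'
#' @param gene_probe_scores numeric vector of the gene's probe scores.
#' @param all_probe_scores genome-wide pool of probe scores (at least as
#'   large as the gene set).
#' @param n_resamples number of resampled sets (default 10,000).
#' @param seed integer seed.
#' @return single p-value.
#' @export
probe_resampling_pvalue <- function(gene_probe_scores, all_probe_scores,
                                    n_resamples = 10000L, seed = 1L) {
  k <- length(gene_probe_scores)
  if (!k || !length(all_probe_scores)) stop("empty input scores")
  if (length(all_probe_scores) < k)
    stop("pool must be at least as large as the gene's probe set")
  if (n_resamples < 1L) stop("'n_resamples' must be >= 1")
  obs <- mean(gene_probe_scores)
  with_seed(seed, {
    draws <- matrix(sample(all_probe_scores, k * n_resamples, replace = TRUE),
                    nrow = k)
    means <- colMeans(draws)
    (1 + sum(abs(means) >= abs(obs))) / (n_resamples + 1)
  })
}

#' Binomial-resampling test for functional class enrichment
#'
#' Tests whether a functional class contributes more beneficial (or
#' deleterious) null mutations across all conditions than expected from
#' class size alone. For each class and condition a simulated count is
#' drawn as Binomial(n tested class members, average per-gene call
#' probability in that condition); counts are summed across conditions, and
#' the one-tailed p-value is the fraction of simulated sums at or above the
#' observed total, floored at `1/(n_draws+1)`. Benjamini-Hochberg q-values
#' are computed across classes, separately per direction.
#'
#' @param calls a [condition_call_table()].
#' @param direction `"beneficial"` or `"deleterious"`.
#' @param n_draws number of simulated draws, at least 1000 (default
#'   10,000).
#' @param seed integer seed.
#' @param class_fdr FDR for the significance flag (default 0.01).
#' @return object of class `class_enrichment_result`: data.frame with
#'   columns class, direction, n_tested_total, observed, expected, p, q,
#'   testable, significant; attributes `n_draws` and `seed`.
#' @export
resample_class_enrichment <- function(calls, direction = c("beneficial",
                                                           "deleterious"),
                                      n_draws = 10000L, seed = 1L,
                                      class_fdr = 0.01) {
  stopifnot(inherits(calls, "condition_call_table"))
  direction <- match.arg(direction)
  if (n_draws < 1000L) stop("'n_draws' must be >= 1000")
  called <- calls[[direction]]
  classes <- sort(unique(calls$classes))
  conds <- calls$conditions

  with_seed(seed, {
    rows <- list()
    for (cl in classes) {
      members <- names(calls$classes)[calls$classes == cl]
      observed <- 0L; expected <- 0; n_tested_total <- 0L
      sums <- numeric(n_draws)
      for (cond in conds) {
        tested <- calls$tested[[cond]]
        n_cl <- length(intersect(members, tested))
        if (!n_cl) next
        p_bar <- length(called[[cond]]) / length(tested)
        observed <- observed + length(intersect(members, called[[cond]]))
        expected <- expected + n_cl * p_bar
        n_tested_total <- n_tested_total + n_cl
        sums <- sums + stats::rbinom(n_draws, n_cl, p_bar)
      }
      testable <- n_tested_total > 0L
      p <- if (testable)
        max(mean(sums >= observed), 1 / (n_draws + 1)) else NA_real_
      rows[[cl]] <- data.frame(
        class = cl, direction = direction,
        n_tested_total = n_tested_total, observed = observed,
        expected = expected, p = p, testable = testable,
        stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, c(rows, make.row.names = FALSE))
    res$q <- NA_real_
    res$q[res$testable] <- stats::p.adjust(res$p[res$testable], method = "BH")
    res$significant <- !is.na(res$q) & res$q < class_fdr
    structure(res, class = c("class_enrichment_result", "data.frame"),
              n_draws = as.integer(n_draws), seed = seed)
  })
}

#' Fraction of class members recurrently significant
#'
#' For each functional class and each threshold t, the fraction of class
#' members whose null mutation was called (in the given direction) in at
#' least t of the conditions.
#'
#' @param calls a [condition_call_table()].
#' @param direction `"beneficial"` or `"deleterious"`.
#' @param thresholds fractions of the condition count (default 5%, 25%,
#'   50%, 75%).
#' @return data.frame with columns class, threshold, n_members, fraction.
#' @export
class_condition_fractions <- function(calls,
                                      direction = c("beneficial",
                                                    "deleterious"),
                                      thresholds = c(0.05, 0.25, 0.5, 0.75)) {
  stopifnot(inherits(calls, "condition_call_table"))
  direction <- match.arg(direction)
  if (any(thresholds <= 0 | thresholds > 1))
    stop("'thresholds' must lie in (0, 1]")
  n_cond <- length(calls$conditions)
  counts <- table(unlist(calls[[direction]]))
  genes <- names(calls$classes)
  gene_counts <- stats::setNames(rep(0L, length(genes)), genes)
  gene_counts[names(counts)] <- as.integer(counts)

  rows <- list()
  for (cl in sort(unique(calls$classes))) {
    members <- genes[calls$classes == cl]
    for (t in thresholds) {
      need <- t * n_cond
      frac <- mean(gene_counts[members] >= need - 1e-9)
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, threshold = t, n_members = length(members),
        fraction = frac, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Recurrently beneficial genes
#'
#' Genes whose null mutations were beneficial in at least `min_conditions`
#' conditions, sorted by call count (descending), ties broken by gene id.
#'
#' @param calls a [condition_call_table()].
#' @param min_conditions minimum number of beneficial calls (default 10).
#' @return data.frame with columns gene, n_conditions, class.
#' @export
recurrent_beneficial_genes <- function(calls, min_conditions = 10L) {
  stopifnot(inherits(calls, "condition_call_table"))
  if (min_conditions < 1L) stop("'min_conditions' must be >= 1")
  counts <- table(unlist(calls$beneficial))
  keep <- counts[counts >= min_conditions]
  if (!length(keep))
    return(data.frame(gene = character(), n_conditions = integer(),
                      class = character(), stringsAsFactors = FALSE))
  df <- data.frame(gene = names(keep), n_conditions = as.integer(keep),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$n_conditions, df$gene), , drop = FALSE]
  df$class <- unname(calls$classes[df$gene])
  rownames(df) <- NULL
  df
}

#' Rate of spontaneous null alleles per gene per division
#'
#' Order-of-magnitude estimate of how often null alleles arise, assuming
#' nulls come only from nonsense (stop-gain) point mutations in the
#' considered fraction of the ORF. The stop-gain probability is computed by
#' exhaustive enumeration over every sense codon, codon position and
#' alternative base (61 x 3 x 3 outcomes under the default uniform codon
#' model), and the rate is
#'
#'   per_nt_rate x orf_length x considered_fraction x P(stop gain).
#'
#' @param per_nt_rate point mutation rate per nucleotide per division
#'   (default 1e-10).
#' @param orf_length ORF length in nucleotides (default 1000).
#' @param considered_fraction fraction of the ORF in which a nonsense
#'   mutation is assumed to abolish function (default 0.5, the first half).
#' @param codon_freq optional named numeric vector of codon usage weights
#'   over sense codons (DNA alphabet, e.g. `c(ATG = 1, ...)`); default
#'   uniform over the 61 sense codons.
#' @return list of class `null_allele_rate` with elements `rate`,
#'   `p_stop_gain`, and the assumptions used.
#' @export
null_allele_rate <- function(per_nt_rate = 1e-10, orf_length = 1000,
                             considered_fraction = 0.5, codon_freq = NULL) {
  if (per_nt_rate < 0 || orf_length <= 0)
    stop("rates and lengths must be positive")
  check_fraction(considered_fraction, "considered_fraction")
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1L, paste0, collapse = "")
  stops <- c("TAA", "TAG", "TGA")
  sense <- setdiff(codons, stops)
  if (is.null(codon_freq)) {
    codon_freq <- stats::setNames(rep(1, length(sense)), sense)
  } else {
    if (is.null(names(codon_freq)) || any(!names(codon_freq) %in% sense))
      stop("'codon_freq' must be named by sense codons")
    sense <- names(codon_freq)
  }
  w <- codon_freq / sum(codon_freq)

  # per sense codon: fraction of the 9 single-base substitutions that
  # create a stop codon
  p_codon <- vapply(sense, function(cod) {
    hits <- 0L
    split <- strsplit(cod, "")[[1]]
    for (pos in 1:3) for (b in setdiff(bases, split[pos])) {
      mut <- split; mut[pos] <- b
      if (paste0(mut, collapse = "") %in% stops) hits <- hits + 1L
    }
    hits / 9
  }, numeric(1))
  p_stop <- sum(w * p_codon)

  structure(list(rate = per_nt_rate * orf_length * considered_fraction *
                   p_stop,
                 p_stop_gain = p_stop,
                 per_nt_rate = per_nt_rate, orf_length = orf_length,
                 considered_fraction = considered_fraction),
            class = "null_allele_rate")
}

#' @export
print.null_allele_rate <- function(x, ...) {
  cat(sprintf(
    "null allele rate: %.3g per gene per division\n  (P(stop gain) = %.4f, %g nt ORF, fraction %.2f, %.3g per nt)\n",
    x$rate, x$p_stop_gain, x$orf_length, x$considered_fraction,
    x$per_nt_rate))
  invisible(x)
}
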