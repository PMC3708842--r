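#' Normalize footprint arrays against the pre-selection reference
#'
#' Each array is first sum-normalized on the ratio scale (scaled so its
#' total equals the mean array total), then log2-transformed so increases
#' and decreases have similar magnitudes. Each array's log2 values are then
#' regressed, with a locally weighted (loess) fit, on the per-gene mean of
#' the log2 reference arrays, and the fitted value is subtracted. After
#' normalization, insertions whose abundance did not respond to selection
#' are centred near zero, and smooth intensity-dependent biases are
#' removed. Reference arrays themselves are normalized the same way; their
#' residuals feed the null model of [build_null()].
#'
#' @param dataset a [footprint_dataset()] with at least two reference
#'   arrays (the reference mean is otherwise too unstable a regressor).
#' @param span loess span (fraction of points in each local fit), default
#'   0.3. The fit is locally linear with tricube weights and no robustness
#'   iterations.
#' @return an object of class `normalized_footprint`: list with `values`
#'   (gene x array matrix of normalized log2 enrichments), `arrays` (role
#'   table as in the input), `ref_mean` (the regressor) and `span`.
#' @export
normalize_footprint <- function(dataset, span = 0.3) {
  stopifnot(inherits(dataset, "footprint_dataset"))
  if (!is.numeric(span) || span <= 0 || span > 1)
    stop("'span' must be in (0, 1]")
  ref_cols <- dataset$arrays$array[dataset$arrays$role == "ref"]
  if (length(ref_cols) < 2L)
    stop("at least 2 reference arrays are required for normalization")

  v <- dataset$values
  totals <- colSums(v)
  scaled <- sweep(v, 2L, mean(totals) / totals, "*")
  L <- log2(pmax(scaled, 1e-6))
  ref_mean <- rowMeans(L[, ref_cols, drop = FALSE])

  norm <- L
  if (stats::sd(ref_mean) < 1e-8) {
    # degenerate regressor (e.g. an already-flattened dataset): a local
    # regression is undefined, so centre each array instead
    norm <- sweep(L, 2L, colMeans(L))
  } else {
    for (j in seq_len(ncol(L))) {
      fit <- stats::loess(y ~ x,
                          data = data.frame(x = ref_mean, y = L[, j]),
                          span = span, degree = 1, family = "gaussian",
                          control = stats::loess.control(surface = "interpolate"))
      norm[, j] <- L[, j] - stats::predict(fit, ref_mean)
    }
  }
  if (any(!is.finite(norm)))
    stop("normalization produced non-finite values")
  structure(list(values = norm, arrays = dataset$arrays,
                 ref_mean = ref_mean, span = span),
            class = "normalized_footprint")
}

#' @export
print.normalized_footprint <- function(x, ...) {
  cat(sprintf("normalized_footprint: %d genes, %d arrays (span %.2f)\n",
              nrow(x$values), ncol(x$values), x$span))
  invisible(x)
}

#' Sign-concordant minimum summary statistic
#'
#' Per-gene fitness summary across biological replicates: the normalized
#' value closest to zero if all replicates share a strict sign, and zero
#' otherwise. A replicate exactly at zero has no sign and breaks
#' concordance. The statistic is deliberately conservative: its magnitude
#' never exceeds the weakest replicate.
#'
#' @param replicate_values numeric vector of normalized log2 enrichments
#'   (one per replicate); must be non-empty.
#' @return single numeric summary.
#' @export
summarize_gene <- function(replicate_values) {
  if (!length(replicate_values)) stop("no replicate values supplied")
  if (any(!is.finite(replicate_values))) stop("replicate values must be finite")
  s <- sign(replicate_values)
  if (all(s > 0) || all(s < 0))
    replicate_values[which.min(abs(replicate_values))]
  else 0
}

# vectorized form used for the pseudo-gene null (rows = pseudo-genes)
summarize_rows <- function(m) {
  r <- ncol(m)
  pos <- rowSums(m > 0)
  neg <- rowSums(m < 0)
  minabs <- do.call(pmin, lapply(seq_len(r), function(j) abs(m[, j])))
  ifelse(pos == r, minabs, ifelse(neg == r, -minabs, 0))
}

#' Per-condition gene summary statistics
#'
#' @param normalized a [normalize_footprint()] result.
#' @param condition condition label; default all selected conditions.
#' @return a gene x condition matrix of summary statistics.
#' @export
gene_summaries <- function(normalized,
                           condition = unique(
                             normalized$arrays$condition[
                               normalized$arrays$role == "sel"])) {
  stopifnot(inherits(normalized, "normalized_footprint"))
  out <- sapply(condition, function(cond) {
    cols <- normalized$arrays$array[normalized$arrays$role == "sel" &
                                      normalized$arrays$condition == cond]
    if (!length(cols)) stop("unknown condition: ", cond)
    summarize_rows(normalized$values[, cols, drop = FALSE])
  })
  out <- matrix(out, nrow = nrow(normalized$values),
                dimnames = list(rownames(normalized$values), condition))
  out
}

#' Simulated null distribution of the summary statistic
#'
#' Builds a null distribution of pseudo-genes for one condition. Each
#' pseudo-gene gets as many draws as the condition has replicates; each
#' draw comes from a t-distribution with `df` degrees of freedom, rescaled
#' so its standard deviation equals the replicate standard deviation of a
#' randomly chosen real gene (the t variate is divided by sqrt(df/(df-2)),
#' so the distribution's sd, not its scale parameter, matches) and shifted
#' by the median normalized reference residual of an independently chosen
#' (possibly different) gene. The same sign-concordant minimum summary is
#' then applied to each pseudo-gene.
#'
#' @param normalized a [normalize_footprint()] result.
#' @param condition condition label with at least 2 replicates.
#' @param n_pseudo number of pseudo-genes (default 500,000).
#' @param df degrees of freedom of the heavy-tailed draw; must be > 2.
#' @param seed integer seed.
#' @param keep_draws keep the raw pseudo-replicate draw matrix for
#'   distributional diagnostics (default FALSE; memory-heavy at the
#'   default `n_pseudo`).
#' @return an object of class `null_summary_model` with elements
#'   `summaries` (length `n_pseudo`), `n_pseudo`, `df`, `seed`,
#'   `condition`, `n_replicates`, and `draws` when `keep_draws`.
#' @export
build_null <- function(normalized, condition, n_pseudo = 500000L, df = 4,
                       seed = 1L, keep_draws = FALSE) {
  stopifnot(inherits(normalized, "normalized_footprint"))
  if (df <= 2) stop("'df' must be > 2 (infinite variance otherwise)")
  a <- normalized$arrays
  sel_cols <- a$array[a$role == "sel" & a$condition %in% condition]
  if (length(sel_cols) < 2L)
    stop("condition must have at least 2 replicates")
  ref_cols <- a$array[a$role == "ref"]
  r <- length(sel_cols)

  sds <- apply(normalized$values[, sel_cols, drop = FALSE], 1L, stats::sd)
  ref_med <- apply(normalized$values[, ref_cols, drop = FALSE], 1L,
                   stats::median)
  n_genes <- length(sds)

  with_seed(seed, {
    idx_sd <- sample.int(n_genes, n_pseudo, replace = TRUE)
    idx_mu <- sample.int(n_genes, n_pseudo, replace = TRUE)
    scale <- sds[idx_sd] / sqrt(df / (df - 2))
    draws <- matrix(stats::rt(n_pseudo * r, df), n_pseudo, r) * scale +
      ref_med[idx_mu]
    out <- list(summaries = summarize_rows(draws),
                n_pseudo = as.integer(n_pseudo), df = df, seed = seed,
                condition = condition, n_replicates = r)
    if (keep_draws) out$draws <- draws
    structure(out, class = "null_summary_model")
  })
}

#' @export
print.null_summary_model <- function(x, ...) {
  cat(sprintf(
    "null_summary_model: %d pseudo-genes, %d replicates, df = %g (%s)\n",
    x$n_pseudo, x$n_replicates, x$df, x$condition))
  invisible(x)
}

#' Empirical p-values against a simulated null
#'
#' p is the fraction of pseudo-genes whose summary statistic strictly
#' exceeds the observed value in magnitude, floored at `1/n_pseudo` so a
#' finite simulation never reports p = 0. Ties in magnitude count as not
#' exceeding. A zero observed summary gets the fraction of nonzero null
#' summaries.
#'
#' @param summaries numeric vector of observed gene summary statistics.
#' @param null a [build_null()] result.
#' @return numeric vector of p-values, same length and names as
#'   `summaries`.
#' @export
footprint_pvalues <- function(summaries, null) {
  stopifnot(inherits(null, "null_summary_model"))
  n <- null$n_pseudo
  sorted <- sort(abs(null$summaries))
  exceed <- n - findInterval(abs(summaries), sorted)
  p <- pmax(exceed / n, 1 / n)
  names(p) <- names(summaries)
  p
}

#' Plug-in FDR significance calling
#'
#' Chooses the largest p-value threshold alpha whose plug-in false
#' discovery estimate `alpha * n_tested / #\{p <= alpha\}` stays at or below
#' the target, and flags genes at or below it. If no threshold satisfies
#' the bound, no gene is called and the cutoff is reported as 0.
#'
#' @param p numeric vector of per-gene p-values.
#' @param n_tested number of genes tested (defaults to `length(p)`).
#' @param target_fdr target false discovery rate in (0,1), default 0.05.
#' @return list with `significant` (logical vector), `cutoff`,
#'   `fdr_estimate` (plug-in estimate at the cutoff; NA when nothing is
#'   called) and `n_significant`.
#' @export
call_significant <- function(p, n_tested = length(p), target_fdr = 0.05) {
  check_fraction(target_fdr, "target_fdr", open_hi = TRUE)
  alphas <- sort(unique(p))
  k <- findInterval(alphas, sort(p))          # #{p <= alpha}
  est <- alphas * n_tested / k
  ok <- est <= target_fdr
  if (!any(ok))
    return(list(significant = rep(FALSE, length(p)), cutoff = 0,
                fdr_estimate = NA_real_, n_significant = 0L))
  cutoff <- max(alphas[ok])
  sig <- p <= cutoff
  list(significant = sig, cutoff = cutoff,
       fdr_estimate = est[which(ok)[sum(ok)]],
       n_significant = sum(sig))
}

#' Full footprint significance pipeline
#'
#' Runs essential-gene exclusion, normalization, gene summaries, simulated
#' nulls, p-values and per-condition plug-in FDR calling in one step. Each
#' condition gets its own null distribution and its own significance
#' cutoff; per-condition null seeds are derived from `seed` by offsetting
#' with the condition index.
#'
#' @param dataset a [footprint_dataset()].
#' @param essential_ids essential gene ids to exclude before testing.
#' @param span loess span, default 0.3.
#' @param n_pseudo pseudo-genes per condition null (default 500,000).
#' @param df t degrees of freedom for the null (default 4).
#' @param seed integer seed for the null simulations.
#' @param target_fdr per-condition target FDR, default 0.05.
#' @return object of class `significance_calls`: list with `calls` (long
#'   data.frame gene/condition/summary/p/significant/sign), `conditions`
#'   (per-condition cutoff, FDR estimate and call count), `excluded`
#'   (dropped essential ids present in the data), `normalized` and
#'   `params`.
#' @export
footprint_significance <- function(dataset, essential_ids = character(),
                                   span = 0.3, n_pseudo = 500000L, df = 4,
                                   seed = 1L, target_fdr = 0.05) {
  stopifnot(inherits(dataset, "footprint_dataset"))
  excluded <- intersect(essential_ids, rownames(dataset$values))
  if (length(essential_ids))
    dataset <- exclude_essentials(dataset, essential_ids)
  normalized <- normalize_footprint(dataset, span = span)
  conds <- footprint_conditions(dataset)
  summ <- gene_summaries(normalized, conds)

  calls <- list(); cond_rows <- list()
  for (i in seq_along(conds)) {
    cond <- conds[i]
    null <- build_null(normalized, cond, n_pseudo = n_pseudo, df = df,
                       seed = seed + i)
    p <- footprint_pvalues(summ[, cond], null)
    cs <- call_significant(p, target_fdr = target_fdr)
    calls[[cond]] <- data.frame(
      gene = rownames(summ), condition = cond, summary = summ[, cond],
      p = p, significant = cs$significant,
      sign = ifelse(cs$significant, sign(summ[, cond]), 0L),
      row.names = NULL, stringsAsFactors = FALSE)
    cond_rows[[cond]] <- data.frame(
      condition = cond, cutoff = cs$cutoff, fdr_estimate = cs$fdr_estimate,
      n_significant = cs$n_significant, stringsAsFactors = FALSE)
  }
  structure(list(calls = do.call(rbind, c(calls, make.row.names = FALSE)),
                 conditions = do.call(rbind, c(cond_rows,
                                               make.row.names = FALSE)),
                 excluded = excluded, normalized = normalized,
                 params = list(span = span, n_pseudo = n_pseudo, df = df,
                               seed = seed, target_fdr = target_fdr)),
            class = "significance_calls")
}

#' @export
print.significance_calls <- function(x, ...) {
  cat(sprintf("significance_calls: %d genes x %d conditions (%d excluded)\n",
              length(unique(x$calls$gene)), nrow(x$conditions),
              length(x$excluded)))
  print(x$conditions, row.names = FALSE)
  invisible(x)
}

#' Genes significant in at least one condition
#' @param calls a [footprint_significance()] result.
#' @return character vector of gene ids.
#' @export
significant_genes <- function(calls) {
  stopifnot(inherits(calls, "significance_calls"))
  sort(unique(calls$calls$gene[calls$calls$significant]))
}
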