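#' Expression comparison (mutant vs parent, two replicates)
#'
#' Per-gene log2 expression ratios of one mutant-vs-parent contrast in two
#' biological replicates. Two replicates are required because the false
#' discovery estimator builds its null from replicate half-differences.
#'
#' @param genes character vector of gene ids.
#' @param rep1,rep2 numeric log2 ratios, one per gene.
#' @param condition contrast label.
#' @return object of class `expression_comparison`.
#' @export
expression_comparison <- function(genes, rep1, rep2, condition = "contrast") {
  if (length(genes) != length(rep1) || length(rep1) != length(rep2))
    stop("genes, rep1 and rep2 must have equal length")
  if (any(!is.finite(rep1)) || any(!is.finite(rep2)))
    stop("log-ratios must be finite")
  structure(list(genes = as.character(genes), rep1 = rep1, rep2 = rep2,
                 condition = condition),
            class = "expression_comparison")
}

#' @export
print.expression_comparison <- function(x, ...) {
  cat(sprintf("expression_comparison '%s': %d genes, 2 replicates\n",
              x$condition, length(x$genes)))
  invisible(x)
}

#' Call differential expression at a fold-change threshold
#'
#' Averages the two replicates per gene and classifies genes as up
#' (average log2 ratio at or above log2(threshold)), down (at or below
#' the negative), or unchanged. The boundary counts as called. The
#' replicate half-differences `(rep1 - rep2)/2` are attached as this
#' contrast's contribution to the null sample: they have zero mean and the
#' same noise distribution as the replicate average.
#'
#' @param expr an [expression_comparison()].
#' @param fold_threshold fold-change threshold on the linear scale, > 1
#'   (default 2, i.e. 1 on the log2 scale).
#' @return object of class `de_call_set`: list with `up`, `down`,
#'   `unchanged` (gene id vectors), `average` (named), `null_sample`,
#'   `log2_threshold`, `condition`.
#' @export
call_de <- function(expr, fold_threshold = 2) {
  stopifnot(inherits(expr, "expression_comparison"))
  if (fold_threshold <= 1) stop("'fold_threshold' must exceed 1")
  thr <- log2(fold_threshold)
  avg <- stats::setNames((expr$rep1 + expr$rep2) / 2, expr$genes)
  up <- expr$genes[avg >= thr]
  down <- expr$genes[avg <= -thr]
  structure(list(up = up, down = down,
                 unchanged = setdiff(expr$genes, c(up, down)),
                 average = avg,
                 null_sample = (expr$rep1 - expr$rep2) / 2,
                 log2_threshold = thr, condition = expr$condition),
            class = "de_call_set")
}

#' @export
print.de_call_set <- function(x, ...) {
  cat(sprintf("de_call_set '%s': %d up, %d down of %d genes (|log2| >= %g)\n",
              x$condition, length(x$up), length(x$down), length(x$average),
              x$log2_threshold))
  invisible(x)
}

#' Estimate the false discovery rate from replicate half-differences
#'
#' Pools the half-difference null samples of all supplied call sets into a
#' single null distribution (per-contrast nulls via `pool = FALSE`). The
#' expected number of false positives for a contrast is the number of null
#' values strictly exceeding the log2 threshold in magnitude, rescaled to
#' the contrast's gene count; the FDR is that expectation divided by the
#' number of genes called, capped at 1, and NA when nothing was called.
#'
#' @param callsets list of [call_de()] results.
#' @param pool pool the null across contrasts (default TRUE).
#' @return data.frame with columns condition, n_called, expected_fp, fdr,
#'   n_null.
#' @export
estimate_fdr <- function(callsets, pool = TRUE) {
  if (inherits(callsets, "de_call_set")) callsets <- list(callsets)
  if (!length(callsets) || !all(vapply(callsets, inherits, TRUE,
                                       "de_call_set")))
    stop("'callsets' must be a list of de_call_set objects")
  pooled <- unlist(lapply(callsets, `[[`, "null_sample"))
  if (!length(pooled)) stop("empty null sample")
  rows <- lapply(callsets, function(cs) {
    null <- if (pool) pooled else cs$null_sample
    n_genes <- length(cs$average)
    n_called <- length(cs$up) + length(cs$down)
    efp <- sum(abs(null) > cs$log2_threshold) * n_genes / length(null)
    data.frame(condition = cs$condition, n_called = n_called,
               expected_fp = efp,
               fdr = if (n_called) min(efp / n_called, 1) else NA_real_,
               n_null = length(null), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Hypergeometric overlap significance of two gene sets
#'
#' Upper-tail hypergeometric probability of the sets overlapping at least
#' as much as observed, with a Bonferroni correction for the number of set
#' pairs compared.
#'
#' @param setA,setB character vectors of gene ids.
#' @param universe size of the gene universe both sets are drawn from.
#' @param n_comparisons number of comparisons for the Bonferroni
#'   adjustment (default 1).
#' @return list with `overlap`, `p`, `p_bonferroni`.
#' @export
overlap_significance <- function(setA, setB, universe, n_comparisons = 1L) {
  setA <- unique(as.character(setA)); setB <- unique(as.character(setB))
  if (length(setA) > universe || length(setB) > universe)
    stop("set sizes cannot exceed the universe")
  ov <- length(intersect(setA, setB))
  p <- stats::phyper(ov - 1L, length(setA), universe - length(setA),
                     length(setB), lower.tail = FALSE)
  list(overlap = ov, p = p, p_bonferroni = min(1, p * n_comparisons))
}
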