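#' Growth curve container
#'
#' Timestamped absorbance readings (600 nm) with the blank background of a
#' cell-free well and the cumulative dilution factor in effect at each
#' reading, so serially diluted cultures can be stitched back into one
#' exponential trajectory.
#'
#' @param time sampling times in minutes, strictly increasing.
#' @param absorbance raw absorbance readings (blank included).
#' @param blank background absorbance of media without cells.
#' @param cumulative_dilution total dilution applied before each reading
#'   (>= 1, non-decreasing); default 1 everywhere.
#' @param strain,media optional labels.
#' @return object of class `growth_curve`.
#' @export
growth_curve <- function(time, absorbance, blank = 0,
                         cumulative_dilution = rep(1, length(time)),
                         strain = NA_character_, media = NA_character_) {
  if (length(time) != length(absorbance) ||
      length(time) != length(cumulative_dilution))
    stop("time, absorbance and cumulative_dilution must have equal length")
  if (any(diff(time) <= 0)) stop("sample times must be strictly increasing")
  if (any(cumulative_dilution < 1) || any(diff(cumulative_dilution) < 0))
    stop("cumulative dilution factors must be >= 1 and non-decreasing")
  structure(list(time = time, absorbance = absorbance, blank = blank,
                 cumulative_dilution = cumulative_dilution,
                 strain = strain, media = media),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf(
    "growth_curve: %d readings over %.0f min (blank %.3g, max dilution %gx)\n",
    length(x$time), diff(range(x$time)), x$blank,
    max(x$cumulative_dilution)))
  invisible(x)
}

#' Fit an exponential-phase doubling time
#'
#' Least-squares line on log2(background-corrected absorbance x cumulative
#' dilution) versus time; the reciprocal slope is the doubling time in
#' minutes. The fitting window is selected on the background-corrected
#' absorbance before dilution multiplication (default the plate-reader
#' range 0.015625-0.0625), or given explicitly as reading indices for
#' hand-identified exponential regions. The fit is accepted only if its
#' r-squared reaches `r2_min` (0.99 for plate windows; 0.95 is the
#' convention for serial-dilution fits).
#'
#' @param curve a [growth_curve()].
#' @param window numeric length-2 absorbance range `c(lo, hi)` applied to
#'   the background-corrected readings (default `c(0.015625, 0.0625)`).
#' @param indices optional integer vector of reading indices; overrides
#'   `window`.
#' @param r2_min minimum r-squared for acceptance (default 0.99).
#' @return object of class `doubling_time_fit`: list with `doubling_time`
#'   (minutes), `r_squared`, `n_points`, `window` (indices used),
#'   `accepted`.
#' @export
fit_doubling_time <- function(curve, window = c(0.015625, 0.0625),
                              indices = NULL, r2_min = 0.99) {
  stopifnot(inherits(curve, "growth_curve"))
  corrected <- curve$absorbance - curve$blank
  if (is.null(indices)) {
    if (length(window) != 2L || window[1] >= window[2])
      stop("'window' must be c(lo, hi) with lo < hi")
    indices <- which(corrected >= window[1] & corrected <= window[2])
  } else {
    indices <- sort(unique(as.integer(indices)))
    if (any(indices < 1L | indices > length(curve$time)))
      stop("'indices' out of range")
  }
  if (length(indices) < 3L)
    stop("fitting window holds fewer than 3 points")
  y_lin <- corrected[indices] * curve$cumulative_dilution[indices]
  bad <- sum(y_lin <= 0)
  if (bad)
    stop(sprintf("%d non-positive corrected value(s) in the window", bad))
  fit <- stats::lm(log2(y_lin) ~ curve$time[indices])
  slope <- unname(stats::coef(fit)[2])
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact data is legitimate
  dt <- 1 / slope
  structure(list(doubling_time = dt, r_squared = r2,
                 n_points = length(indices), window = indices,
                 accepted = is.finite(dt) && dt > 0 && r2 >= r2_min),
            class = "doubling_time_fit")
}

#' @export
print.doubling_time_fit <- function(x, ...) {
  cat(sprintf(
    "doubling_time_fit: %.2f min (r2 = %.4f, %d points, %saccepted)\n",
    x$doubling_time, x$r_squared, x$n_points, if (x$accepted) "" else "not "))
  invisible(x)
}

#' Mann-Whitney comparison of mutant and parent doubling times
#'
#' Rank-sum test of whether a mutant doubles faster than the parent strain
#' (one-sided: mutant doubling times stochastically smaller) or differs
#' (two-sided). Exact permutation p-values are used for small untied
#' samples, the normal approximation otherwise; fully tied data yields
#' p = 1 with a warning.
#'
#' @param mutant_fits,parent_fits numeric vectors of doubling times
#'   (minutes), at least 2 each.
#' @param sided `"one"` (mutant faster) or `"two"`.
#' @return list with `U` (Mann-Whitney statistic for the mutant sample)
#'   and `p`.
#' @export
compare_strains <- function(mutant_fits, parent_fits,
                            sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (length(mutant_fits) < 2L || length(parent_fits) < 2L)
    stop("at least 2 measurements per group are required")
  if (length(unique(c(mutant_fits, parent_fits))) == 1L) {
    warning("all measurements tied; p = 1")
    return(list(U = length(mutant_fits) * length(parent_fits) / 2, p = 1))
  }
  exact <- max(length(mutant_fits), length(parent_fits)) <= 10L
  wt <- suppressWarnings(stats::wilcox.test(
    mutant_fits, parent_fits,
    alternative = if (sided == "one") "less" else "two.sided",
    exact = exact, correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Compare many strains against the parent with FDR control
#'
#' Runs [compare_strains()] for every strain/media combination and applies
#' Benjamini-Hochberg across the whole set, mirroring a single FDR budget
#' for the entire screening dataset.
#'
#' @param fits named list of numeric vectors, one per strain (and medium),
#'   of mutant doubling times.
#' @param parent_fits numeric vector of parent doubling times.
#' @param sided `"one"` or `"two"`.
#' @param target_fdr significance cutoff on the q-values (default 0.05).
#' @return data.frame with columns strain, n, mean_doubling, U, p, q,
#'   significant.
#' @export
compare_strain_set <- function(fits, parent_fits, sided = c("one", "two"),
                               target_fdr = 0.05) {
  sided <- match.arg(sided)
  check_fraction(target_fdr, "target_fdr", open_hi = TRUE)
  if (is.null(names(fits))) stop("'fits' must be a named list of strains")
  rows <- lapply(names(fits), function(s) {
    cmp <- compare_strains(fits[[s]], parent_fits, sided = sided)
    data.frame(strain = s, n = length(fits[[s]]),
               mean_doubling = mean(fits[[s]]), U = cmp$U, p = cmp$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q <= target_fdr
  out
}

#' Read / write growth curves as CSV
#'
#' Columns: time, absorbance, blank, cumulative_dilution, strain, media,
#' replicate. One file may hold several curves, keyed by
#' strain/media/replicate.
#'
#' @param curves list of [growth_curve()] objects (replicate taken from
#'   names, or 1..n).
#' @param path file path.
#' @return `read_growth_csv` returns a list of [growth_curve()] objects.
#' @export
write_growth_csv <- function(curves, path) {
  if (inherits(curves, "growth_curve")) curves <- list(curves)
  rows <- lapply(seq_along(curves), function(i) {
    g <- curves[[i]]
    data.frame(time = g$time, absorbance = g$absorbance, blank = g$blank,
               cumulative_dilution = g$cumulative_dilution,
               strain = g$strain, media = g$media, replicate = i,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_growth_csv
#' @export
read_growth_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  key <- interaction(df$strain, df$media, df$replicate, drop = TRUE)
  lapply(split(df, key), function(d)
    growth_curve(d$time, d$absorbance, blank = d$blank[1],
                 cumulative_dilution = d$cumulative_dilution,
                 strain = d$strain[1], media = d$media[1]))
}
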