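#' Configuration for the footprint-data generator
#'
#' Collects and validates the parameters of [simulate_footprint_dataset()].
#' The defaults mirror the selection design the significance pipeline is
#' built for: five pre-selection reference hybridizations and four
#' amino-acid selection conditions with three biological replicates each
#' (two for asparagine), gene-level replicate noise drawn from a
#' t-distribution with 4 degrees of freedom.
#'
#' @param seed integer seed; every draw in the generator is derived from it.
#' @param n_genes number of genes.
#' @param n_reference_arrays number of pre-selection reference arrays
#'   (default 5).
#' @param replicates_per_condition named integer vector mapping condition
#'   labels to replicate counts. Default: alanine/aspartate/glutamine with
#'   3 replicates, asparagine with 2.
#' @param noise_df degrees of freedom of the heavy-tailed replicate noise;
#'   must exceed 2 so the variance is finite (default 4).
#' @param sd_distribution per-gene noise-scale sampler for the selected
#'   (post-selection) arrays: a function(n) returning n positive standard
#'   deviations, or a single number. Default lognormal around 0.3 log2
#'   units, a typical gene-level spread between independent biological
#'   selections.
#' @param ref_noise_sd per-gene noise-scale sampler for the reference
#'   arrays (default 0.1 log2 units). Reference arrays are technical
#'   re-hybridizations of the same pre-selection library, so their
#'   gene-level noise is well below the between-selection biological
#'   noise of the selected arrays.
#' @param frac_beneficial,frac_deleterious fractions of genes spiked with a
#'   positive (beneficial insertion) or negative (deleterious) fitness
#'   effect; must lie in `[0,1]` and sum to at most 1.
#' @param effect_size magnitude sampler (function(n) or single number) for
#'   the absolute spiked log2 enrichment; default 4.
#' @param bias_amplitude amplitude (log2 units) of the smooth,
#'   intensity-dependent per-array bias the loess normalization must remove
#'   (default 0.5).
#' @return a `footprint_sim_config` list.
#' @export
footprint_sim_config <- function(seed,
                                 n_genes = 2000L,
                                 n_reference_arrays = 5L,
                                 replicates_per_condition = c(
                                   alanine = 3L, aspartate = 3L,
                                   glutamine = 3L, asparagine = 2L),
                                 noise_df = 4,
                                 sd_distribution = function(n)
                                   stats::rlnorm(n, log(0.3), 0.4),
                                 ref_noise_sd = 0.1,
                                 frac_beneficial = 0,
                                 frac_deleterious = 0,
                                 effect_size = 4,
                                 bias_amplitude = 0.5) {
  if (n_genes < 1L || n_reference_arrays < 1L)
    stop("counts must be >= 1")
  if (is.null(names(replicates_per_condition)) ||
      any(!nzchar(names(replicates_per_condition))) ||
      any(replicates_per_condition < 1L))
    stop("'replicates_per_condition' must be a named vector of counts >= 1")
  if (!is.numeric(noise_df) || noise_df <= 2)
    stop("'noise_df' must be > 2 (finite noise variance is required)")
  check_fraction(frac_beneficial, "frac_beneficial", open_lo = FALSE)
  check_fraction(frac_deleterious, "frac_deleterious", open_lo = FALSE)
  if (frac_beneficial + frac_deleterious > 1)
    stop("frac_beneficial + frac_deleterious must be <= 1")
  structure(list(seed = seed, n_genes = as.integer(n_genes),
                 n_reference_arrays = as.integer(n_reference_arrays),
                 replicates_per_condition = replicates_per_condition,
                 noise_df = noise_df, sd_distribution = sd_distribution,
                 ref_noise_sd = ref_noise_sd,
                 frac_beneficial = frac_beneficial,
                 frac_deleterious = frac_deleterious,
                 effect_size = effect_size,
                 bias_amplitude = bias_amplitude),
            class = "footprint_sim_config")
}

#' Simulate a transposon footprint selection experiment
#'
#' Generates a ratio-scale gene x array matrix emulating competitive
#' selection of a transposon library. On the log2 scale each value is
#'
#'   per-gene baseline + smooth array bias + spiked effect + scaled noise,
#'
#' where the spiked effect is present only on post-selection arrays, the
#' bias is a slowly varying function of the gene's reference intensity (so
#' the loess stage has real work to do), and the noise is a t-variate with
#' `noise_df` degrees of freedom rescaled so its standard deviation (not
#' its raw scale) equals the gene's drawn sd. Values are exponentiated back
#' to the ratio scale and floored at 1e-6 to keep logs finite.
#'
#' @param config a [footprint_sim_config()].
#' @return a list with elements `dataset` (a [footprint_dataset()]) and
#'   `truth`, a data.frame with columns `gene`, `condition`, `effect`
#'   (signed log2 value, the same for every condition of a spiked gene) and
#'   `label` (`"beneficial"`, `"deleterious"` or `"null"`).
#' @export
simulate_footprint_dataset <- function(config) {
  stopifnot(inherits(config, "footprint_sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_genes
    genes <- sprintf("g%04d", seq_len(n))
    reps <- cfg$replicates_per_condition
    conds <- names(reps)

    baseline <- stats::rnorm(n, 0, 1.5)
    sd_g <- sample_spec(cfg$sd_distribution, n)
    sd_ref <- sample_spec(cfg$ref_noise_sd, n)
    if (any(sd_g <= 0) || any(sd_ref <= 0))
      stop("noise-scale samplers produced non-positive values")

    # spiked signed effects
    effect <- numeric(n)
    n_ben <- round(cfg$frac_beneficial * n)
    n_del <- round(cfg$frac_deleterious * n)
    spiked <- sample.int(n, n_ben + n_del)
    if (n_ben) effect[spiked[seq_len(n_ben)]] <-
        abs(sample_spec(cfg$effect_size, n_ben))
    if (n_del) effect[spiked[n_ben + seq_len(n_del)]] <-
        -abs(sample_spec(cfg$effect_size, n_del))
    label <- ifelse(effect > 0, "beneficial",
                    ifelse(effect < 0, "deleterious", "null"))

    u <- (baseline - min(baseline)) / diff(range(baseline))
    t_scale <- sqrt(cfg$noise_df / (cfg$noise_df - 2))
    draw_array <- function(shift, sd_vec) {
      amp <- stats::runif(1, -cfg$bias_amplitude, cfg$bias_amplitude)
      phase <- stats::runif(1, 0, pi)
      noise <- sd_vec * stats::rt(n, cfg$noise_df) / t_scale
      baseline + amp * sin(pi * u + phase) + shift + noise
    }

    cols <- list(); meta <- list()
    for (i in seq_len(cfg$n_reference_arrays)) {
      id <- sprintf("ref_%d", i)
      cols[[id]] <- draw_array(0, sd_ref)
      meta[[id]] <- data.frame(array = id, role = "ref",
                               condition = NA_character_,
                               replicate = NA_integer_)
    }
    for (cond in conds) {
      for (r in seq_len(reps[[cond]])) {
        id <- sprintf("sel_%s_%d", cond, r)
        cols[[id]] <- draw_array(effect, sd_g)
        meta[[id]] <- data.frame(array = id, role = "sel", condition = cond,
                                 replicate = r)
      }
    }
    values <- pmax(2^do.call(cbind, cols), 1e-6)
    rownames(values) <- genes
    arrays <- do.call(rbind, meta)

    truth <- data.frame(
      gene = rep(genes, times = length(conds)),
      condition = rep(conds, each = n),
      effect = rep(effect, times = length(conds)),
      label = rep(label, times = length(conds)),
      stringsAsFactors = FALSE)

    list(dataset = footprint_dataset(values, arrays), truth = truth)
  })
}
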