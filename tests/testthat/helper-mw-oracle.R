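# exact one-sided Mann-Whitney oracle: enumerate every split of the pooled
# values into groups of the observed sizes and count splits at least as
# extreme (as small a mutant rank sum) as observed
mw_exact_oracle <- function(x, y) {
  pool <- c(x, y); n <- length(x)
  splits <- utils::combn(length(pool), n)
  r <- rank(pool)
  obs <- sum(r[seq_len(n)])
  mean(apply(splits, 2, function(idx) sum(r[idx]) <= obs))
}
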