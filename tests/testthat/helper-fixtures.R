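# Shared fixtures (built lazily and cached for the whole run) and
# independent brute-force oracles.

.cache <- new.env(parent = emptyenv())

fixture_bundle <- function() {
  if (is.null(.cache$bundle))
    .cache$bundle <- generate_cohort(default_fixture_spec(seed = 1))
  .cache$bundle
}

fixture_model <- function() {
  if (is.null(.cache$model))
    .cache$model <- train_cn_model(pipeline_config(seed = 2))
  .cache$model
}

fixture_calls <- function() {
  if (is.null(.cache$calls))
    .cache$calls <- classify_cohort(fixture_bundle(), model = fixture_model())
  .cache$calls
}

# One somatic variant row with sane defaults.
make_variant <- function(ref = "C", alt = "A", gene = ".",
                         consequence = "missense", protein_change = NA,
                         tumor_dp = 100L, tumor_alt = 30L,
                         normal_dp = 100L, normal_alt = 0L,
                         filter = "PASS", chrom = "chr1", pos = 1000L) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
             consequence = consequence, protein_change = protein_change,
             tumor_dp = tumor_dp, tumor_alt = tumor_alt,
             normal_dp = normal_dp, normal_alt = normal_alt, filter = filter,
             tumor_af = tumor_alt / tumor_dp,
             normal_af = normal_alt / normal_dp, stringsAsFactors = FALSE)
}

# Variant table from a list of c(ref, alt) pairs.
variants_of <- function(pairs) {
  do.call(rbind, lapply(seq_along(pairs), function(i)
    make_variant(ref = pairs[[i]][1], alt = pairs[[i]][2],
                 pos = 1000L + i)))
}

# Exhaustive total-variation oracle: normalize and sum absolute differences
# term by term (no vectorized shortcut).
tv_oracle <- function(normal, tumor) {
  fn <- normal / sum(normal)
  ft <- tumor / sum(tumor)
  acc <- 0
  for (k in seq_along(fn)) acc <- acc + abs(ft[k] - fn[k])
  acc / 2
}

# Hand-rolled two-group log-rank chi-square via the observed-minus-expected
# table over event times (hypergeometric variance).
logrank_oracle <- function(time, event, grp) {
  g <- as.integer(factor(grp))
  stopifnot(max(g) == 2)
  U <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g == 1)
    U <- U + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  U^2 / V
}
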