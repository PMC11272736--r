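test_that("generation is deterministic for a fixed spec and seed", {
  spec <- cohort_spec(4, seed = 42)
  b1 <- generate_cohort(spec)
  b2 <- generate_cohort(spec)
  expect_identical(b1, b2)
  # a component generated alone matches the same component of a full bundle
  clin_only <- generate_cohort(spec, components = "clinical")
  expect_identical(b1$clinical, clin_only$clinical)
})

test_that("infeasible specs fail validation naming the offender", {
  plan <- data.frame(sample = c("A", "B"), signature_pole = FALSE,
                     pathogenic_pole = c(FALSE, TRUE), msi_h = FALSE,
                     cn_cluster4 = FALSE, tp53_nonsilent = FALSE,
                     degraded_qc = FALSE)
  expect_error(cohort_spec(2, plan), "sample B")
  expect_error(cohort_spec(0), "n_samples")
  bad <- default_survival_params()
  bad$multipliers$os[["p53abn"]] <- -1
  expect_error(cohort_spec(2, survival_params = bad), "multipliers")
})

test_that("planted POLE spectra sit strictly inside the rule region, others outside", {
  b <- fixture_bundle()
  truth <- b$truth
  for (id in truth$sample) {
    v <- filter_somatic(b$variants[b$variants$sample == id, ])
    s <- suppressWarnings(substitution_spectrum(v))
    if (truth$signature_pole[truth$sample == id]) {
      expect_gte(s$n_snv, 600)
      expect_gt(s$ca_rate, 0.25)
      expect_lt(s$cg_rate, 0.02)
      expect_gt(s$cg_rate, 0.005)
    } else {
      expect_lt(s$n_snv, 500)  # outside on the count criterion
    }
  }
})

test_that("planted MSI aggregates are well separated from the threshold", {
  b <- fixture_bundle()
  truth <- b$truth
  for (id in truth$sample) {
    r <- suppressWarnings(
      call_msi(b$ms_loci[b$ms_loci$sample == id, , drop = FALSE]))
    if (truth$msi_h[truth$sample == id]) {
      expect_gte(r$aggregate_score, 0.4)
    } else {
      expect_lte(r$aggregate_score, 0.1)
    }
  }
})

test_that("cluster-4 samples carry many alterations, quiet samples few", {
  b <- fixture_bundle()
  x <- cn_feature_matrix(b$cn_segments)
  alt <- x[, "n_gains"] + x[, "n_losses"]
  pos <- b$truth$cn_cluster4[match(rownames(x), b$truth$sample)]
  expect_true(all(alt[pos] >= 20))
  expect_true(all(alt[!pos] <= 8))
  expect_true(all(x[pos, "ploidy"] > 2.05))
})

test_that("training cohort label balance is assigned exactly", {
  spec <- cn_training_spec(seed = 3)
  expect_equal(sum(spec$subtype_plan$cn_cluster4), round(0.26 * 240))
  expect_equal(spec$n_samples, 240L)
})

test_that("degraded samples breach at least one QC rule, clean samples none", {
  b <- fixture_bundle()
  for (i in seq_len(nrow(b$qc))) {
    fl <- flag_msi_quality(b$qc[i, ])
    degraded <- b$truth$degraded_qc[b$truth$sample == b$qc$sample[i]]
    if (degraded) expect_gte(length(fl), 1) else expect_length(fl, 0)
  }
})

test_that("survival draws respect the planted hazard ordering at scale", {
  # large single-stratum cohorts: crude event rates must order by multiplier
  labels <- setNames(rep(c("NSMP", "p53abn", "POLEmut"), each = 400),
                     sprintf("X%04d", 1:1200))
  clin <- simulate_clinical(labels, seed = 77)
  rate <- tapply(clin$os_event, rep(c("NSMP", "p53abn", "POLEmut"),
                                    each = 400), mean)
  expect_gt(rate[["p53abn"]], rate[["NSMP"]])
  expect_gt(rate[["NSMP"]], rate[["POLEmut"]])
  expect_lt(rate[["POLEmut"]], 0.05)
})
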