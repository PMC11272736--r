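ev <- function(spectrum_defined = TRUE, pole_signature = FALSE,
               pole_pathogenic = FALSE, msi_call = "MSS",
               tp53_nonsilent = FALSE, cluster4 = FALSE) {
  list(spectrum_defined = spectrum_defined, pole_signature = pole_signature,
       pole_pathogenic = pole_pathogenic, msi_call = msi_call,
       tp53_nonsilent = tp53_nonsilent, cluster4 = cluster4)
}

test_that("cascade precedence is POLE > MSI > CN and POLEmut > dMMR > p53abn", {
  # a signature-POLE sample that is also MSI-H is POLE
  expect_equal(classify_tcga_analogue(ev(pole_signature = TRUE,
                                         msi_call = "MSI-H")), "POLE")
  expect_equal(classify_tcga_analogue(ev(msi_call = "MSI-H",
                                         cluster4 = TRUE)), "MSI")
  expect_equal(classify_tcga_analogue(ev(cluster4 = TRUE)), "CN_high")
  expect_equal(classify_tcga_analogue(ev()), "CN_low")
  # pathogenic POLE with a TP53 hit is POLEmut, not p53abn
  expect_equal(classify_surrogate(ev(pole_pathogenic = TRUE,
                                     tp53_nonsilent = TRUE)), "POLEmut")
  expect_equal(classify_surrogate(ev(msi_call = "MSI-H",
                                     tp53_nonsilent = TRUE)), "dMMR")
  expect_equal(classify_surrogate(ev(tp53_nonsilent = TRUE)), "p53abn")
  expect_equal(classify_surrogate(ev()), "NSMP")
  # signature-only POLE (no pathogenic variant) with MSI-H lands in dMMR:
  # the source of the cross-track MSI/dMMR asymmetry
  expect_equal(classify_tcga_analogue(ev(pole_signature = TRUE,
                                         msi_call = "MSI-H")), "POLE")
  expect_equal(classify_surrogate(ev(pole_signature = TRUE,
                                     msi_call = "MSI-H")), "dMMR")
})

test_that("samples are unclassifiable only without spectrum and MSI evidence", {
  und <- ev(spectrum_defined = FALSE, msi_call = "indeterminate")
  expect_equal(classify_tcga_analogue(und), "unclassifiable")
  expect_equal(classify_surrogate(und), "unclassifiable")
  # indeterminate MSI with a defined spectrum routes to the non-MSI branch
  expect_equal(classify_tcga_analogue(ev(msi_call = "indeterminate")),
               "CN_low")
  expect_equal(classify_surrogate(ev(msi_call = "indeterminate",
                                     tp53_nonsilent = TRUE)), "p53abn")
})

test_that("every classifiable sample gets exactly one label per track", {
  calls <- fixture_calls()
  expect_true(all(calls$tcga_label %in% c(endotype:::TCGA_LEVELS,
                                          "unclassifiable")))
  expect_true(all(calls$surrogate_label %in% c(endotype:::SURROGATE_LEVELS,
                                               "unclassifiable")))
  expect_equal(anyDuplicated(calls$sample), 0L)
  expect_equal(nrow(calls), 108L)
})

test_that("classification recovers every planted label exactly", {
  calls <- fixture_calls()
  truth <- fixture_bundle()$truth
  m <- match(calls$sample, truth$sample)
  expect_equal(calls$tcga_label, truth$tcga_truth[m])
  expect_equal(calls$surrogate_label, truth$surrogate_truth[m])
})

test_that("cohort summary computes half-up one-decimal percentages", {
  calls <- data.frame(
    sample = sprintf("S%03d", 1:108),
    tcga_label = rep(c("POLE", "MSI", "CN_low", "CN_high"), c(9, 51, 33, 15)),
    surrogate_label = rep(c("POLEmut", "dMMR", "NSMP", "p53abn"),
                          c(6, 53, 38, 11)))
  s <- summarize_cohort(calls)
  expect_equal(s$tcga$percent[s$tcga$subtype == "POLE"], 8.3)
  expect_equal(s$tcga$percent[s$tcga$subtype == "CN_low"], 30.6)  # half-up
  expect_equal(s$surrogate$percent[s$surrogate$subtype == "dMMR"], 49.1)
  expect_equal(sum(s$tcga$count), 108L)
  # percentages per track sum to ~100 after rounding
  expect_lt(abs(sum(s$tcga$percent) - 100), 0.2)
  expect_lt(abs(sum(s$surrogate$percent) - 100), 0.2)

  one <- data.frame(sample = "a", tcga_label = "MSI", surrogate_label = "dMMR")
  expect_equal(summarize_cohort(one)$tcga$percent[2], 100.0)
})

test_that("unclassifiable samples are excluded from summary denominators", {
  calls <- data.frame(
    sample = c("a", "b", "c"),
    tcga_label = c("POLE", "MSI", "unclassifiable"),
    surrogate_label = c("POLEmut", "dMMR", "unclassifiable"))
  s <- summarize_cohort(calls)
  expect_equal(s$n_classified[["tcga"]], 2L)
  expect_equal(s$n_unclassifiable, 1L)
  expect_equal(s$tcga$percent[s$tcga$subtype == "POLE"], 50.0)
})
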