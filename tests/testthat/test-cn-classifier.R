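seg <- function(chrom, start_mb, end_mb, cn, sample = NULL) {
  d <- data.frame(chrom = chrom, start = start_mb * 1e6, end = end_mb * 1e6,
                  copy_number = cn, stringsAsFactors = FALSE)
  if (!is.null(sample)) cbind(sample = sample, d) else d
}

test_that("feature extraction: diploid genome, single focal gain, hand values", {
  quiet <- seg("chr1", 0, 248, 2)
  f <- extract_cn_features(quiet)
  expect_equal(unname(f[["n_gains"]]), 0)
  expect_equal(unname(f[["n_losses"]]), 0)
  expect_equal(unname(f[["ploidy"]]), 2)
  expect_equal(unname(f[["altered_mb"]]), 0)

  # 3-Mb segment at cn=4 overlapping PTEN (chr10:87-87.35 Mb)
  amp <- seg("chr10", 86, 89, 4)
  f2 <- extract_cn_features(amp, selected_genes = c("PTEN", "TP53"))
  expect_equal(unname(f2[["n_gains"]]), 1)
  expect_equal(unname(f2[["gains_chr10"]]), 1)
  expect_equal(unname(f2[["gene_PTEN"]]), 1)
  expect_equal(unname(f2[["gene_TP53"]]), 0)
  expect_equal(unname(f2[["altered_mb"]]), 3)
  expect_equal(unname(f2[["ploidy"]]), 4) # only segment provided

  expect_warning(f0 <- extract_cn_features(quiet[0, ]), "no copy-number")
  expect_equal(unname(f0[["ploidy"]]), 2)
  expect_equal(unname(f0[["n_gains"]]), 0)
})

test_that("features are invariant to segment order and equal-CN splits", {
  b <- generate_cohort(cohort_spec(
    1, data.frame(sample = "S001", signature_pole = FALSE,
                  pathogenic_pole = FALSE, msi_h = FALSE, cn_cluster4 = TRUE,
                  tp53_nonsilent = FALSE, degraded_qc = FALSE),
    seed = 9), components = "cn_segments")
  s <- b$cn_segments[, c("chrom", "start", "end", "copy_number")]
  f_ref <- extract_cn_features(s)
  # shuffle rows
  f_shuf <- extract_cn_features(s[sample.int(nrow(s)), ])
  expect_equal(f_ref, f_shuf)
  # split the longest segment into two adjacent halves with equal CN
  i <- which.max(s$end - s$start)
  mid <- floor((s$start[i] + s$end[i]) / 2)
  split <- rbind(s[-i, ],
                 transform(s[i, ], end = mid),
                 transform(s[i, ], start = mid))
  expect_equal(f_ref, extract_cn_features(split))
  # and the planted cluster-4 signal is far above the quiet regime
  expect_gte(f_ref[["n_gains"]] + f_ref[["n_losses"]], 20)
})

test_that("gene selection ranks by prevalence with lexicographic ties", {
  gm <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                   start = c(0, 2e6, 0), end = c(1e6, 3e6, 1e6),
                   gene = c("B", "A", "C"))
  # B altered in 2 samples; A and C in 1 each -> tie broken A before C
  segs <- rbind(seg("chr1", 0, 0.5, 4, "s1"), seg("chr1", 2, 2.5, 4, "s1"),
                seg("chr1", 0, 0.5, 4, "s2"), seg("chr2", 0, 0.5, 0.8, "s3"))
  expect_equal(select_top_genes(segs, gm, k = 2), c("B", "A"))
  expect_warning(all3 <- select_top_genes(seg("chr1", 0, 0.5, 4, "s1"),
                                          gm, k = 3),
                 "padding")
  expect_equal(all3, c("B", "A", "C"))
})

test_that("Naive Bayes posteriors follow the closed-form Bayes rule", {
  # separable single feature
  x <- matrix(c(rep(0, 10) + rnorm(10, sd = 0.01),
                rep(100, 10) + rnorm(10, sd = 0.01)), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- rep(c(FALSE, TRUE), each = 10)
  fit <- nb_cluster4(x, y)
  expect_equal(predict(fit, x)$cluster4, y)

  # symmetric means, equal priors, x at the midpoint -> posterior 1/2;
  # with priors 0.74/0.26 the posterior equals the prior
  sym <- list(means = rbind(neg = c(f = -1), pos = c(f = 1)),
              vars = rbind(neg = c(f = 1), pos = c(f = 1)),
              priors = c(neg = 0.5, pos = 0.5), var_floor = 1e-9,
              features = "f")
  class(sym) <- "nb_cluster4"
  expect_equal(predict(sym, c(f = 0))$posterior, 0.5)
  sym$means <- rbind(neg = c(f = 0), pos = c(f = 2))
  sym$priors <- c(neg = 0.74, pos = 0.26)
  expect_equal(predict(sym, c(f = 1))$posterior, 0.26)

  expect_error(nb_cluster4(x, rep(TRUE, 20)), "single class")
})

test_that("posteriors agree with an independent Naive Bayes implementation", {
  skip_if_not_installed("e1071")
  set.seed(21)
  n <- 60
  x <- cbind(a = rnorm(n, rep(c(0, 2), each = n / 2)),
             b = rnorm(n, rep(c(1, 1.5), each = n / 2)),
             c = rnorm(n))
  y <- rep(c(FALSE, TRUE), each = n / 2)
  ours <- predict(nb_cluster4(x, y), x)$posterior
  ref <- e1071::naiveBayes(as.data.frame(x), factor(y))
  theirs <- predict(ref, as.data.frame(x), type = "raw")[, "TRUE"]
  expect_equal(ours, unname(theirs), tolerance = 1e-6)
})

test_that("posterior sums to one and the flag matches the argmax", {
  set.seed(22)
  x <- cbind(a = rnorm(30, rep(c(0, 1), each = 15)), b = rnorm(30))
  y <- rep(c(FALSE, TRUE), each = 15)
  fit <- nb_cluster4(x, y)
  pr <- predict(fit, x)
  expect_true(all(pr$posterior >= 0 & pr$posterior <= 1))
  expect_equal(pr$cluster4, pr$posterior > 0.5)
})

test_that("cross-validation is deterministic, bounded, perfect when separable", {
  set.seed(23)
  x <- matrix(c(rnorm(74, 0, 0.1), rnorm(26, 10, 0.1)), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- rep(c(FALSE, TRUE), c(74, 26))
  cv1 <- cross_validate(x, y, folds = 5, seed = 5)
  cv2 <- cross_validate(x, y, folds = 5, seed = 5)
  expect_identical(cv1, cv2)
  for (m in c("accuracy", "precision", "recall", "f1", "roc_auc"))
    expect_equal(cv1[[m]], 1)
  expect_error(cross_validate(x, rep(c(FALSE, TRUE), c(97, 3)), folds = 5),
               "stratification")
})

test_that("ROC-AUC matches an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(24)
  scores <- runif(50)
  labels <- runif(50) < scores
  if (length(unique(labels)) == 2) {
    ours <- endotype:::auc_rank(scores, labels)
    theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                             direction = "<")))
    expect_equal(ours, theirs)
  }
})

test_that("a trained model round-trips exactly through JSON", {
  model <- fixture_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_nb_model(model, path)
  back <- read_nb_model(path)
  b <- fixture_bundle()
  x <- cn_feature_matrix(b$cn_segments, selected_genes = model$selected_genes)
  expect_equal(predict(model, x), predict(back, x))
  expect_equal(model$means, back$means)
  expect_equal(model$priors, back$priors)
})
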