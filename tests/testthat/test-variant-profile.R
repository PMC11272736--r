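test_that("substitution spectrum matches hand-counted class fractions", {
  v <- variants_of(c(rep(list(c("C", "A")), 3), list(c("G", "T")),
                     list(c("C", "G")), rep(list(c("T", "C")), 5)))
  s <- substitution_spectrum(v)
  expect_equal(s$n_snv, 10L)
  expect_equal(s$ca_rate, 0.4)
  expect_equal(s$cg_rate, 0.1)
  expect_equal(sum(s$class_fractions), 1)

  pure <- substitution_spectrum(variants_of(rep(list(c("C", "A")), 4)))
  expect_equal(pure$ca_rate, 1)
  expect_equal(pure$cg_rate, 0)
})

test_that("spectrum is undefined without SNVs and never calls POLE", {
  indels <- make_variant(ref = "CA", alt = "C", consequence = "frameshift")
  expect_warning(s <- substitution_spectrum(indels), "undefined")
  expect_false(s$defined)
  expect_false(call_pole_signature(s))
})

test_that("spectrum is invariant under strand-swapping every record", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  set.seed(7)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                  character(1))
    v1 <- do.call(rbind, lapply(seq_len(n), function(j)
      make_variant(ref = ref[j], alt = alt[j], pos = j)))
    v2 <- do.call(rbind, lapply(seq_len(n), function(j)
      make_variant(ref = comp[[ref[j]]], alt = comp[[alt[j]]], pos = j)))
    s1 <- substitution_spectrum(v1); s2 <- substitution_spectrum(v2)
    expect_equal(s1$class_fractions, s2$class_fractions)
  }
})

test_that("POLE rule is strict at every boundary and monotone", {
  mk <- function(n, ca, cg) structure(list(n_snv = n, ca_rate = ca,
                                           cg_rate = cg, defined = TRUE),
                                      class = "substitution_spectrum")
  expect_true(call_pole_signature(mk(501, 0.25, 0.01)))
  expect_false(call_pole_signature(mk(500, 0.25, 0.01)))  # strict > 500
  expect_false(call_pole_signature(mk(501, 0.20, 0.01)))  # strict > 0.2
  expect_false(call_pole_signature(mk(501, 0.25, 0.03)))  # strict < 0.03
  # monotone: raising n_snv/ca or lowering cg never flips POLE -> non-POLE
  set.seed(11)
  for (i in 1:50) {
    n <- sample(400:700, 1); ca <- runif(1, 0.1, 0.4); cg <- runif(1, 0, 0.05)
    base <- call_pole_signature(mk(n, ca, cg))
    if (base) {
      expect_true(call_pole_signature(mk(n + sample(1:500, 1), ca, cg)))
      expect_true(call_pole_signature(mk(n, min(1, ca + runif(1, 0, 0.3)), cg)))
      expect_true(call_pole_signature(mk(n, ca, cg * runif(1))))
    }
  }
})

test_that("gene flags follow the whitelist and the non-silent rule", {
  syn <- make_variant(gene = "TP53", consequence = "synonymous",
                      protein_change = "L350L")
  expect_false(gene_flags(syn)$tp53_nonsilent)
  hot <- make_variant(gene = "POLE", consequence = "missense",
                      protein_change = "P286R")
  expect_true(gene_flags(hot)$pole_pathogenic)
  dom <- make_variant(gene = "POLE", consequence = "missense",
                      protein_change = "A300T")  # inside exonuclease domain
  expect_true(gene_flags(dom)$pole_pathogenic)
  out <- make_variant(gene = "POLE", consequence = "missense",
                      protein_change = "T899M") # outside the domain
  expect_false(gene_flags(out)$pole_pathogenic)
  mis <- make_variant(gene = "TP53", consequence = "missense",
                      protein_change = "R175H")
  expect_true(gene_flags(mis)$tp53_nonsilent)
  none <- gene_flags(make_variant()[0, ])
  expect_false(none$pole_pathogenic)
  expect_false(none$tp53_nonsilent)
})

test_that("VCF reading applies the paired somatic filter", {
  v <- rbind(make_variant(pos = 10L),
             make_variant(pos = 20L, ref = "G", alt = "T"),
             make_variant(pos = 30L, ref = "T", alt = "C"),
             make_variant(pos = 40L, filter = "artifact"),
             make_variant(pos = 50L, normal_alt = 10L),     # germline leak
             make_variant(pos = 60L, tumor_dp = 10L, tumor_alt = 5L))
  path <- withr::local_tempfile(fileext = ".vcf")
  endotype:::write_sample_vcf(v, path)
  got <- read_somatic_vcf(path)
  expect_equal(nrow(got), 3L)
  expect_setequal(got$pos, c(10L, 20L, 30L))
  # unfiltered read keeps everything and recovers allele fractions exactly
  all6 <- read_somatic_vcf(path, config = NULL)
  expect_equal(nrow(all6), 6L)
  expect_equal(sort(all6$normal_af), sort(v$normal_af))
})

test_that("VCF structural problems are explicit errors", {
  v <- rbind(make_variant(pos = 10L), make_variant(pos = 20L))
  path <- withr::local_tempfile(fileext = ".vcf")
  endotype:::write_sample_vcf(v, path)
  lines <- readLines(path)
  # missing normal column
  broken <- sub("\tNORMAL\t", "\tOTHER\t", lines)
  p2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(broken, p2)
  expect_error(read_somatic_vcf(p2), "NORMAL")
  # truncated record reported with its line number
  p3 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(lines, "chr1\t99\tbroken"), p3)
  expect_error(read_somatic_vcf(p3), "line")
})
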