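# Seeded synthetic tumor/normal cohort generator.
#
# Signals are planted strictly inside (or outside) the downstream decision
# regions, away from the boundaries, so that a correctly implemented pipeline
# recovers every planted label exactly:
#   * POLE-signature samples draw 600-2500 SNVs with a C>A class share of
#     0.27-0.38 and C>G share 0.008-0.018 (rule region: >500 / >0.2 / <0.03);
#     non-POLE samples stay below 500 SNVs.
#   * MSI-H samples get per-locus stepwise scores of 0.42-0.65 (call
#     threshold 0.3); stable samples stay at or below 0.08.
#   * Cluster-4 samples carry 3-6 whole-chromosome gains plus 22-32 focal
#     events genome-wide; quiet samples carry at most 8 alterations, drawn
#     from a fixed catalog of recurrent CNV regions.
# Each data component uses its own RNG substream (seed + small offset), so a
# component generated alone is identical to the same component inside a full
# bundle.

SEED_OFF <- c(variants = 1L, ms_loci = 2L, cn_segments = 3L,
              qc = 4L, clinical = 5L)

#' Generate a synthetic tumor/normal cohort
#'
#' @param spec a [cohort_spec()], e.g. [default_fixture_spec()].
#' @param components which data components to generate (subsetting is useful
#'   when e.g. only copy-number data is needed for classifier training).
#' @return object of class `cohort_bundle`: data frames `variants`,
#'   `ms_loci`, `cn_segments`, `qc`, `clinical` (all keyed by `sample`), and
#'   `truth` — the planted plan with derived truth labels. `truth` exists for
#'   recovery testing only; no classifier reads it.
#' @export
generate_cohort <- function(spec,
                            components = c("variants", "ms_loci",
                                           "cn_segments", "qc", "clinical")) {
  validate_cohort_spec(spec)
  components <- match.arg(components, several.ok = TRUE)
  plan <- spec$subtype_plan
  bundle <- list(variants = NULL, ms_loci = NULL, cn_segments = NULL,
                 qc = NULL, clinical = NULL,
                 truth = merge(plan, truth_labels(plan), by = "sample",
                               sort = FALSE))
  if ("variants" %in% components)
    bundle$variants <- with_seed(spec$seed + SEED_OFF[["variants"]],
                                 gen_variants(plan))
  if ("ms_loci" %in% components)
    bundle$ms_loci <- with_seed(spec$seed + SEED_OFF[["ms_loci"]],
                                gen_ms_loci(plan))
  if ("cn_segments" %in% components)
    bundle$cn_segments <- with_seed(spec$seed + SEED_OFF[["cn_segments"]],
                                    gen_cn_segments(plan))
  if ("qc" %in% components)
    bundle$qc <- with_seed(spec$seed + SEED_OFF[["qc"]], gen_qc(plan))
  if ("clinical" %in% components)
    bundle$clinical <- simulate_clinical(
      setNames(bundle$truth$surrogate_truth, plan$sample),
      params = spec$survival_params,
      censoring_rate = spec$censoring_rate,
      seed = spec$seed + SEED_OFF[["clinical"]],
      missing = spec$missing_clinical)
  structure(bundle, spec = spec, class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("Synthetic cohort bundle: %d samples\n", nrow(x$truth)))
  for (comp in c("variants", "ms_loci", "cn_segments", "qc", "clinical"))
    if (!is.null(x[[comp]]))
      cat(sprintf("  %-12s %d rows\n", comp, nrow(x[[comp]])))
  invisible(x)
}

# ---- variants ---------------------------------------------------------------

# Draw `n` SNVs with exact (largest-remainder) class counts for the target
# class shares, random chromosomes/positions, and paired read counts giving
# clean somatic allele fractions.
draw_snvs <- function(n, class_probs) {
  counts <- apportion(n, class_probs)
  glen <- genome_model()
  cls <- rep(SPECTRUM_CLASSES, counts)
  pyr_ref <- substr(cls, 1, 1)
  pyr_alt <- substr(cls, 3, 3)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- runif(n) < 0.5
  ref <- ifelse(flip, comp[pyr_ref], pyr_ref)
  alt <- ifelse(flip, comp[pyr_alt], pyr_alt)
  chrom <- sample_from(names(glen), n, replace = TRUE)
  pos <- floor(runif(n) * (glen[chrom] - 1)) + 1
  tdp <- sample_from(80:300, n, replace = TRUE)
  talt <- pmax(round(tdp * runif(n, 0.10, 0.60)), ceiling(tdp * 0.05))
  ndp <- sample_from(80:300, n, replace = TRUE)
  nalt <- ifelse(runif(n) < 0.05, 1L, 0L)
  data.frame(chrom = unname(chrom), pos = unname(pos), ref = unname(ref),
             alt = unname(alt), gene = ".",
             consequence = sample_from(c("missense", "synonymous", "other"),
                                       n, replace = TRUE,
                                       prob = c(0.5, 0.3, 0.2)),
             protein_change = NA_character_,
             tumor_dp = unname(tdp), tumor_alt = unname(talt),
             normal_dp = unname(ndp), normal_alt = unname(nalt),
             filter = "PASS", stringsAsFactors = FALSE)
}

# One fully specified planted variant row within a gene's interval.
gene_variant_row <- function(gene, consequence, protein_change, gm,
                             ref = "C", alt = "T") {
  g <- gm[gm$gene == gene, ][1, ]
  tdp <- sample_from(120:250)
  data.frame(chrom = g$chrom,
             pos = g$start + sample_from(seq_len(g$end - g$start - 1)),
             ref = ref, alt = alt, gene = gene, consequence = consequence,
             protein_change = protein_change,
             tumor_dp = tdp, tumor_alt = round(tdp * runif(1, 0.2, 0.5)),
             normal_dp = sample_from(120:250), normal_alt = 0L,
             filter = "PASS", stringsAsFactors = FALSE)
}

gen_variants_sample <- function(flags, gm) {
  if (flags$signature_pole) {
    n <- sample_from(600:2500)
    ca <- runif(1, 0.27, 0.38); cg <- runif(1, 0.008, 0.018)
    probs <- c(ca, cg, 0.35, 0.04, 0.12, 1 - ca - cg - 0.51)
  } else {
    n <- if (flags$msi_h) sample_from(150:450) else sample_from(30:200)
    ca <- runif(1, 0.05, 0.15); cg <- runif(1, 0.035, 0.09)
    probs <- c(ca, cg, 0.40, 0.07, 0.22, 1 - ca - cg - 0.69)
  }
  rows <- list(draw_snvs(n, probs))
  if (flags$pathogenic_pole) {
    rows <- c(rows, list(gene_variant_row(
      "POLE", "missense", sample_from(pole_whitelist()$hotspots), gm)))
  } else if (flags$signature_pole && runif(1) < 0.5) {
    # an innocuous POLE passenger outside the exonuclease domain
    rows <- c(rows, list(gene_variant_row("POLE", "missense", "T899M", gm)))
  }
  if (flags$tp53_nonsilent) {
    csq <- sample_from(c("missense", "nonsense", "frameshift"))
    if (csq == "frameshift") {
      rows <- c(rows, list(gene_variant_row("TP53", csq, "P152fs", gm,
                                            ref = "CA", alt = "C")))
    } else {
      rows <- c(rows, list(gene_variant_row(
        "TP53", csq, sample_from(c("R175H", "R273H", "R248Q", "R342*")), gm)))
    }
  } else if (runif(1) < 0.3) {
    rows <- c(rows, list(gene_variant_row("TP53", "synonymous", "L350L", gm)))
  }
  # a few somatic indels (never counted in the SNV spectrum)
  n_ind <- max(1L, round(0.03 * n))
  ind <- draw_snvs(n_ind, rep(1 / 6, 6))
  ind$ref <- paste0(ind$ref, "A")
  ind$consequence <- sample_from(c("frameshift", "inframe_indel"),
                                 n_ind, replace = TRUE)
  # decoy records that the somatic filter must remove
  dec <- draw_snvs(3, rep(1 / 6, 6))
  dec$filter[1] <- "artifact"
  dec$normal_alt[2] <- round(0.5 * dec$normal_dp[2])
  dec$tumor_dp[3] <- 10L
  dec$tumor_alt[3] <- 4L
  do.call(rbind, c(rows, list(ind, dec)))
}

gen_variants <- function(plan) {
  gm <- synthetic_gene_model()
  out <- lapply(seq_len(nrow(plan)), function(i) {
    v <- gen_variants_sample(plan[i, ], gm)
    cbind(sample = plan$sample[i], v, stringsAsFactors = FALSE)
  })
  v <- do.call(rbind, out)
  v$tumor_af <- v$tumor_alt / v$tumor_dp
  v$normal_af <- v$normal_alt / v$normal_dp
  rownames(v) <- NULL
  v
}

# ---- microsatellite loci ----------------------------------------------------

MS_N_LOCI <- 60L
MS_DEPTH <- 100L
MS_PROFILE <- c(0.1, 0.2, 0.4, 0.2, 0.1) # at ref length -2 .. +2

gen_ms_sample <- function(msi_h, ref_lengths) {
  n_loci <- length(ref_lengths)
  # per-locus planted stepwise score
  s <- if (msi_h) runif(n_loci, 0.42, 0.65) else runif(n_loci, 0, 0.08)
  rows <- lapply(seq_len(n_loci), function(j) {
    L <- ref_lengths[j]
    depth <- if (j > n_loci - 2L) 12L else MS_DEPTH  # last two loci unusable
    normal <- apportion(depth, MS_PROFILE)
    m <- round(depth * s[j])
    take <- apportion(m, normal)
    tumor <- c(m, normal - take)                     # shifted mass at L - 4
    data.frame(locus_id = sprintf("L%02d", j),
               repeat_length = c(L - 4L, (L - 2L):(L + 2L)),
               normal_count = c(0L, normal), tumor_count = tumor)
  })
  do.call(rbind, rows)
}

gen_ms_loci <- function(plan) {
  ref_lengths <- sample_from(10:16, MS_N_LOCI, replace = TRUE)
  out <- lapply(seq_len(nrow(plan)), function(i) {
    cbind(sample = plan$sample[i],
          gen_ms_sample(plan$msi_h[i], ref_lengths),
          stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---- copy-number segments ---------------------------------------------------

# Recurrent CNV regions: quiet (non-cluster-4) genomes draw their few
# incidental alterations from this fixed catalog, mimicking recurrent
# germline/passenger CNVs. Restricting quiet samples to a shared catalog
# keeps their feature patterns inside what any training cohort's negative
# class has seen, so planted-quiet samples sit away from the classifier's
# decision boundary; cluster-4 genomes alter the genome at large.
common_cnv_regions <- function() {
  data.frame(
    chrom = c("chr1", "chr2", "chr3", "chr5", "chr6", "chr8", "chr9",
              "chr10", "chr14", "chr17", "chr20", "chrX",
              "chr1", "chr4", "chr7", "chr10", "chr11", "chr12", "chr13",
              "chr15", "chr16", "chr18", "chr19", "chr22"),
    start = c(45e6, 47e6, 60e6, 1e6, 30e6, 127e6, 100e6, 87e6, 50e6,
              7.4e6, 10e6, 60e6,
              120e6, 100e6, 50e6, 121e6, 40e6, 25e6, 48.2e6,
              30e6, 50e6, 20e6, 30.1e6, 25e6),
    end = c(48e6, 49e6, 63e6, 2.5e6, 33e6, 128.5e6, 103e6, 88.5e6, 52e6,
            7.8e6, 12e6, 62e6,
            122e6, 102e6, 52e6, 122e6, 42e6, 26e6, 49.5e6,
            32e6, 52e6, 22e6, 31e6, 27e6),
    stringsAsFactors = FALSE)
}

# Place `k` disjoint focal events on `chroms` using 10-Mb tiles.
place_focal <- function(k, chroms, len_range_mb, cn_pool) {
  glen <- genome_model()
  ev_chrom <- sample_from(chroms, k, replace = TRUE)
  out <- list()
  for (ch in unique(ev_chrom)) {
    n_ev <- sum(ev_chrom == ch)
    ntiles <- floor(glen[[ch]] / 1e7)
    tiles <- sample_from(seq_len(ntiles) - 1L, min(n_ev, ntiles))
    for (t in tiles) {
      start <- t * 1e7 + floor(runif(1, 0, 2e6))
      len <- floor(runif(1, len_range_mb[1], len_range_mb[2]) * 1e6)
      out <- c(out, list(data.frame(chrom = ch, start = start,
                                    end = start + len,
                                    copy_number = sample_from(cn_pool))))
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

gen_cn_sample <- function(cluster4) {
  glen <- genome_model()
  chroms <- names(glen)
  whole <- character(0)
  alt <- NULL
  if (cluster4) {
    whole <- sample_from(chroms, sample_from(3:6))
    alt <- place_focal(sample_from(22:32), setdiff(chroms, whole),
                       c(2, 7), c(0.5, 1, 3.2, 4))
  } else {
    k <- sample_from(0:8)
    if (k > 0) {
      reg <- common_cnv_regions()
      picked <- reg[sample_from(seq_len(nrow(reg)), k), , drop = FALSE]
      alt <- data.frame(chrom = picked$chrom, start = picked$start,
                        end = picked$end,
                        copy_number = sample_from(c(1, 3), k, replace = TRUE))
    }
  }
  segs <- list()
  for (ch in chroms) {
    L <- glen[[ch]]
    if (ch %in% whole) {
      segs <- c(segs, list(data.frame(chrom = ch, start = 0, end = L,
                                      copy_number = sample_from(c(3, 3.5, 4)))))
      next
    }
    a <- if (is.null(alt)) NULL else alt[alt$chrom == ch, , drop = FALSE]
    if (is.null(a) || nrow(a) == 0) {
      segs <- c(segs, list(data.frame(chrom = ch, start = 0, end = L,
                                      copy_number = 2)))
      next
    }
    a <- a[order(a$start), , drop = FALSE]
    pos <- 0
    for (r in seq_len(nrow(a))) {
      if (a$start[r] > pos)
        segs <- c(segs, list(data.frame(chrom = ch, start = pos,
                                        end = a$start[r], copy_number = 2)))
      segs <- c(segs, list(a[r, ]))
      pos <- a$end[r]
    }
    if (pos < L)
      segs <- c(segs, list(data.frame(chrom = ch, start = pos, end = L,
                                      copy_number = 2)))
  }
  do.call(rbind, segs)
}

gen_cn_segments <- function(plan) {
  out <- lapply(seq_len(nrow(plan)), function(i) {
    cbind(sample = plan$sample[i], gen_cn_sample(plan$cn_cluster4[i]),
          stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---- sequencing QC metrics --------------------------------------------------

QC_CLEAN_RANGES <- list(pct_mapped = c(95, 99.5), pct_on_target = c(70, 85),
                        pct_short_fragments = c(40, 70),
                        adapter_contamination = c(0.5, 3))
QC_DEGRADED_RANGES <- list(pct_mapped = c(85, 91.5), pct_on_target = c(50, 64),
                           pct_short_fragments = c(93.5, 98),
                           adapter_contamination = c(6.5, 10))

gen_qc <- function(plan) {
  metrics <- names(QC_CLEAN_RANGES)
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    vals <- vapply(metrics, function(m) runif(1, QC_CLEAN_RANGES[[m]][1],
                                              QC_CLEAN_RANGES[[m]][2]),
                   numeric(1))
    if (plan$degraded_qc[i]) {
      breach <- sample_from(metrics, sample_from(1:4))
      for (m in breach)
        vals[m] <- runif(1, QC_DEGRADED_RANGES[[m]][1],
                         QC_DEGRADED_RANGES[[m]][2])
      year <- sample_from(2008:2010)
    } else {
      year <- sample_from(2011:2016)
    }
    data.frame(sample = plan$sample[i], t(round(vals, 2)), sample_year = year,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# ---- clinical outcomes ------------------------------------------------------

#' Simulate subtype-dependent clinical outcomes
#'
#' Exponential event times per endpoint with multiplicative per-subtype
#' hazards and independent uniform administrative censoring (see
#' [default_survival_params()]). OS and PFS are drawn independently.
#'
#' @param labels named character vector: surrogate-track subtype per sample
#'   (names = sample ids).
#' @param params survival parameters.
#' @param censoring_rate see [cohort_spec()].
#' @param seed integer seed.
#' @param missing list of sample ids set missing per endpoint.
#' @return clinical data frame: `sample`, `os_months`, `os_event`,
#'   `pfs_months`, `pfs_event`, `histology`, `figo_stage`.
#' @export
simulate_clinical <- function(labels, params = default_survival_params(),
                              censoring_rate = 1, seed = 1,
                              missing = list(os = character(),
                                             pfs = character())) {
  with_seed(seed, {
    n <- length(labels)
    draw <- function(endpoint) {
      mult <- params$multipliers[[endpoint]]
      bad <- setdiff(unique(labels), names(mult))
      if (length(bad) > 0)
        stop_field("no hazard multiplier for subtype %s", bad[1])
      t_event <- rexp(n, rate = params$baseline[[endpoint]] * mult[labels])
      cens <- ifelse(runif(n) < censoring_rate,
                     runif(n, 0, params$max_followup), params$max_followup)
      list(time = pmin(t_event, cens), event = as.integer(t_event <= cens))
    }
    os <- draw("os"); pfs <- draw("pfs")
    out <- data.frame(sample = names(labels),
                      os_months = os$time, os_event = os$event,
                      pfs_months = pfs$time, pfs_event = pfs$event,
                      histology = sample_from(
                        c("endometrioid", "mixed", "serous", "carcinosarcoma",
                          "clear_cell"), n, replace = TRUE,
                        prob = c(0.84, 0.055, 0.02, 0.046, 0.039)),
                      figo_stage = sample_from(
                        c("I", "II", "III", "IV"), n, replace = TRUE,
                        prob = c(0.81, 0.065, 0.105, 0.02)),
                      stringsAsFactors = FALSE)
    out$os_months[out$sample %in% missing$os] <- NA_real_
    out$os_event[out$sample %in% missing$os] <- NA_integer_
    out$pfs_months[out$sample %in% missing$pfs] <- NA_real_
    out$pfs_event[out$sample %in% missing$pfs] <- NA_integer_
    rownames(out) <- NULL
    out
  })
}
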