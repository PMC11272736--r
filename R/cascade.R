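# Hierarchical subtype cascades and cohort summaries.
#
# Two tracks are always computed and neither consumes the other's output:
#   TCGA-analogue:      POLE (spectrum rule) > MSI (MSI-H) > CN high
#                       (predicted cluster 4) > CN low.
#   Surrogate-analogue: POLEmut (pathogenic POLE) > dMMR (MSI-H) > p53abn
#                       (non-silent TP53) > NSMP.
# A sample is unclassifiable only when its MSI status is indeterminate AND
# its spectrum is undefined (or its variant data are missing entirely).

TCGA_LEVELS <- c("POLE", "MSI", "CN_low", "CN_high")
SURROGATE_LEVELS <- c("POLEmut", "dMMR", "NSMP", "p53abn")

#' Classify one sample's evidence (TCGA-analogue track)
#'
#' @param evidence list with elements `spectrum_defined`, `pole_signature`,
#'   `msi_call` (`"MSI-H"`, `"MSS"` or `"indeterminate"`), `cluster4`
#'   (logical).
#' @return label in `POLE`, `MSI`, `CN_high`, `CN_low`, or `unclassifiable`.
#' @export
classify_tcga_analogue <- function(evidence) {
  if (!isTRUE(evidence$spectrum_defined) &&
      identical(evidence$msi_call, "indeterminate"))
    return("unclassifiable")
  if (isTRUE(evidence$pole_signature)) return("POLE")
  if (identical(evidence$msi_call, "MSI-H")) return("MSI")
  if (isTRUE(evidence$cluster4)) return("CN_high")
  "CN_low"
}

#' Classify one sample's evidence (surrogate-marker track)
#'
#' @param evidence list with `spectrum_defined`, `pole_pathogenic`,
#'   `msi_call`, `tp53_nonsilent`.
#' @return label in `POLEmut`, `dMMR`, `p53abn`, `NSMP`, or `unclassifiable`.
#' @export
classify_surrogate <- function(evidence) {
  if (!isTRUE(evidence$spectrum_defined) &&
      identical(evidence$msi_call, "indeterminate"))
    return("unclassifiable")
  if (isTRUE(evidence$pole_pathogenic)) return("POLEmut")
  if (identical(evidence$msi_call, "MSI-H")) return("dMMR")
  if (isTRUE(evidence$tp53_nonsilent)) return("p53abn")
  "NSMP"
}

#' Classify a cohort bundle
#'
#' Runs the full per-sample evidence pipeline — somatic filter, substitution
#' spectrum and POLE rule, gene flags, MSI scoring, copy-number feature
#' extraction and cluster-4 prediction, QC plausibility flags — then applies
#' both cascades. Per-sample failures are isolated: the sample is reported
#' `unclassifiable` with a reason and the rest of the cohort is unaffected.
#'
#' @param bundle a `cohort_bundle` (from [generate_cohort()] or
#'   [read_bundle()]).
#' @param model fitted [nb_cluster4()] model; if `NULL`, one is trained on a
#'   synthetic training cohort ([cn_training_spec()]) seeded from `config`.
#' @param config a [pipeline_config()] holding every threshold.
#' @return object of class `subtype_calls`: a data frame with one row per
#'   sample (labels for both tracks plus all intermediate evidence), with the
#'   config and model as attributes.
#' @export
classify_cohort <- function(bundle, model = NULL, config = pipeline_config()) {
  if (is.null(model)) model <- train_cn_model(config)
  ids <- if (!is.null(bundle$truth)) bundle$truth$sample else
    sort(unique(c(bundle$variants$sample, bundle$ms_loci$sample,
                  bundle$cn_segments$sample, bundle$clinical$sample)))
  gm <- config$gene_model %||% synthetic_gene_model()
  qc_present <- !is.null(bundle$qc)
  if (!qc_present)
    warning("no QC metrics available; MSI plausibility flags omitted",
            call. = FALSE)
  feats <- NULL
  if (!is.null(bundle$cn_segments))
    feats <- cn_feature_matrix(bundle$cn_segments, gm,
                               selected_genes = model$selected_genes,
                               gain_cutoff = model$gain_cutoff,
                               loss_cutoff = model$loss_cutoff)
  rows <- lapply(ids, function(id) {
    row <- data.frame(sample = id, n_snv = NA_integer_, ca_rate = NA_real_,
                      cg_rate = NA_real_, pole_signature = NA,
                      pole_pathogenic = NA, tp53_nonsilent = NA,
                      msi_score = NA_real_, msi_call = NA_character_,
                      cluster4_posterior = NA_real_, cluster4 = NA,
                      qc_flags = "", msi_at_risk = FALSE,
                      tcga_label = "unclassifiable",
                      surrogate_label = "unclassifiable",
                      reason = NA_character_, stringsAsFactors = FALSE)
    tryCatch({
      have_variants <- !is.null(bundle$variants) &&
        id %in% bundle$variants$sample
      spectrum_defined <- FALSE
      if (have_variants) {
        v <- filter_somatic(
          bundle$variants[bundle$variants$sample == id, , drop = FALSE],
          config$filter)
        spec <- withCallingHandlers(
          substitution_spectrum(v),
          warning = function(w) invokeRestart("muffleWarning"))
        spectrum_defined <- spec$defined
        row$n_snv <- spec$n_snv
        row$ca_rate <- spec$ca_rate
        row$cg_rate <- spec$cg_rate
        row$pole_signature <- call_pole_signature(spec, config$pole_rule)
        gf <- gene_flags(v, config$pole_whitelist)
        row$pole_pathogenic <- gf$pole_pathogenic
        row$tp53_nonsilent <- gf$tp53_nonsilent
      } else {
        row$pole_signature <- FALSE
        row$pole_pathogenic <- FALSE
        row$tp53_nonsilent <- FALSE
      }
      msi_call <- "indeterminate"
      if (!is.null(bundle$ms_loci) && id %in% bundle$ms_loci$sample) {
        msi <- withCallingHandlers(
          call_msi(bundle$ms_loci[bundle$ms_loci$sample == id, , drop = FALSE],
                   threshold = config$msi_threshold,
                   min_depth = config$msi_min_depth),
          warning = function(w) invokeRestart("muffleWarning"))
        row$msi_score <- msi$aggregate_score
        msi_call <- msi$call
      }
      row$msi_call <- msi_call
      if (!is.null(feats) && id %in% rownames(feats)) {
        pr <- predict(model, feats[id, , drop = FALSE])
        row$cluster4_posterior <- pr$posterior
        row$cluster4 <- pr$cluster4
      } else {
        row$cluster4 <- FALSE
      }
      if (qc_present && id %in% bundle$qc$sample) {
        fl <- flag_msi_quality(bundle$qc[bundle$qc$sample == id, ,
                                         drop = FALSE][1, ],
                               thresholds = config$qc_thresholds)
        row$qc_flags <- paste(fl, collapse = ";")
        row$msi_at_risk <- length(fl) > 0 && msi_call == "MSI-H"
      }
      ev <- list(spectrum_defined = spectrum_defined,
                 pole_signature = row$pole_signature,
                 pole_pathogenic = row$pole_pathogenic,
                 tp53_nonsilent = row$tp53_nonsilent,
                 msi_call = msi_call, cluster4 = row$cluster4)
      row$tcga_label <- classify_tcga_analogue(ev)
      row$surrogate_label <- classify_surrogate(ev)
      if (row$tcga_label == "unclassifiable")
        row$reason <- "spectrum undefined and MSI indeterminate"
      row
    }, error = function(e) {
      row$reason <- conditionMessage(e)
      row
    })
  })
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  structure(calls, config = config, model = model, class = c("subtype_calls",
                                                             "data.frame"))
}

#' @export
print.subtype_calls <- function(x, ...) {
  cat(sprintf("Subtype calls for %d samples (%d unclassifiable)\n",
              nrow(x), sum(x$tcga_label == "unclassifiable")))
  print(summarize_cohort(x))
  invisible(x)
}

#' Summarize cohort subtype distributions
#'
#' Counts and one-decimal percentages (half-up rounding) per subtype for both
#' tracks; unclassifiable samples are excluded from the denominators and
#' reported separately.
#'
#' @param calls a `subtype_calls` object (or a data frame with `tcga_label`
#'   and `surrogate_label` columns).
#' @return object of class `cohort_summary` with data frames `tcga` and
#'   `surrogate` (`subtype`, `count`, `percent`), `n_classified` per track
#'   and `n_unclassifiable`.
#' @export
summarize_cohort <- function(calls) {
  one_track <- function(labels, levels) {
    ok <- labels != "unclassifiable"
    n <- sum(ok)
    counts <- table(factor(labels[ok], levels = levels))
    data.frame(subtype = levels, count = as.integer(counts),
               percent = round_half_up(100 * as.integer(counts) / n, 1),
               stringsAsFactors = FALSE)
  }
  if (nrow(calls) == 0 || all(calls$tcga_label == "unclassifiable"))
    stop_field("no classifiable samples to summarize")
  structure(list(tcga = one_track(calls$tcga_label, TCGA_LEVELS),
                 surrogate = one_track(calls$surrogate_label,
                                       SURROGATE_LEVELS),
                 n_classified = c(
                   tcga = sum(calls$tcga_label != "unclassifiable"),
                   surrogate = sum(calls$surrogate_label != "unclassifiable")),
                 n_unclassifiable = sum(calls$tcga_label == "unclassifiable")),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Molecular subtype distribution\n")
  cat(sprintf("  TCGA-analogue (n = %d)        Surrogate-analogue (n = %d)\n",
              x$n_classified[["tcga"]], x$n_classified[["surrogate"]]))
  for (i in seq_len(nrow(x$tcga)))
    cat(sprintf("  %-8s %4d  %5.1f%%        %-8s %4d  %5.1f%%\n",
                x$tcga$subtype[i], x$tcga$count[i], x$tcga$percent[i],
                x$surrogate$subtype[i], x$surrogate$count[i],
                x$surrogate$percent[i]))
  if (x$n_unclassifiable > 0)
    cat(sprintf("  (%d unclassifiable sample(s) excluded)\n",
                x$n_unclassifiable))
  invisible(x)
}

#' Write per-sample calls as TSV
#'
#' @param calls `subtype_calls` object.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  write_tsv(as.data.frame(calls), path)
}
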