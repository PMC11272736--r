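# Cohort specifications for the synthetic tumor/normal generator.

#' Default survival parameters of the generator
#'
#' Exponential event times with multiplicative per-subtype hazards on the
#' surrogate-track truth label; the NSMP (CN-low-like) stratum is the
#' baseline. Overall-survival multipliers default to the observed magnitudes
#' of the study design this emulates (p53abn 12.84, dMMR 1.44, POLEmut 0.05
#' i.e. near-zero events); baseline rates are chosen so that a 108-sample
#' cohort followed for up to 140 months accrues roughly 20 OS and 28 PFS
#' events. Censoring is uniform administrative over `[0, max_followup]`.
#'
#' @return list with `baseline` (events/month for OS and PFS), `multipliers`
#'   (per endpoint, named by surrogate subtype) and `max_followup` (months).
#' @export
default_survival_params <- function() {
  list(baseline = c(os = 0.0015, pfs = 0.0022),
       multipliers = list(
         os = c(POLEmut = 0.05, dMMR = 1.44, NSMP = 1, p53abn = 12.84),
         pfs = c(POLEmut = 0.05, dMMR = 2.07, NSMP = 1, p53abn = 9.58)),
       max_followup = 140)
}

#' Construct a cohort specification
#'
#' A cohort spec fixes everything the generator needs: the per-sample planted
#' truth flags, the survival model, the censoring behaviour and the seed.
#' Flags per sample: `signature_pole` (ultramutated C>A-rich spectrum inside
#' the POLE rule region), `pathogenic_pole` (whitelisted POLE mutation;
#' requires `signature_pole`), `msi_h` (shifted microsatellite histograms,
#' aggregate score planted at or above 0.42), `cn_cluster4` (aneuploid
#' gain/loss-rich genome), `tp53_nonsilent` (somatic non-silent TP53
#' mutation), `degraded_qc` (FFPE-degraded sequencing metrics; affects QC
#' metrics only, not the molecular data).
#'
#' @param n_samples number of samples (>= 1).
#' @param subtype_plan data frame with a `sample` column and the six logical
#'   flag columns; defaults to all-`FALSE` flags.
#' @param survival_params see [default_survival_params()].
#' @param censoring_rate probability that a subject's administrative censor
#'   time is drawn uniformly on `[0, max_followup]` rather than being full
#'   follow-up (default 1).
#' @param missing_clinical list with character vectors `os` and `pfs`: sample
#'   ids whose time/status is set missing for that endpoint.
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples, subtype_plan = NULL,
                        survival_params = default_survival_params(),
                        censoring_rate = 1,
                        missing_clinical = list(os = character(), pfs = character()),
                        seed = 1) {
  if (n_samples < 1) stop_field("invalid spec: n_samples must be >= 1")
  if (is.null(subtype_plan)) {
    subtype_plan <- data.frame(sample = sprintf("S%03d", seq_len(n_samples)),
                               signature_pole = FALSE, pathogenic_pole = FALSE,
                               msi_h = FALSE, cn_cluster4 = FALSE,
                               tp53_nonsilent = FALSE, degraded_qc = FALSE,
                               stringsAsFactors = FALSE)
  }
  spec <- structure(list(n_samples = as.integer(n_samples),
                         subtype_plan = subtype_plan,
                         survival_params = survival_params,
                         censoring_rate = censoring_rate,
                         missing_clinical = missing_clinical,
                         seed = as.integer(seed)),
                    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#'
#' Fails with a message naming the offending field or sample when the spec is
#' infeasible, e.g. a sample planted as POLE-pathogenic without the
#' ultramutated signature (a pathogenic exonuclease-domain mutation without
#' its mutational consequence is not realizable in this generator).
#'
#' @param spec a [cohort_spec()].
#' @return the spec, invisibly.
#' @export
validate_cohort_spec <- function(spec) {
  if (spec$n_samples < 1L) stop_field("invalid spec: n_samples must be >= 1")
  plan <- spec$subtype_plan
  need <- c("sample", "signature_pole", "pathogenic_pole", "msi_h",
            "cn_cluster4", "tp53_nonsilent", "degraded_qc")
  miss <- setdiff(need, names(plan))
  if (length(miss) > 0)
    stop_field("invalid spec: subtype_plan lacks column(s) %s",
               paste(miss, collapse = ", "))
  if (nrow(plan) != spec$n_samples)
    stop_field("invalid spec: subtype_plan has %d rows but n_samples is %d",
               nrow(plan), spec$n_samples)
  if (anyDuplicated(plan$sample))
    stop_field("invalid spec: duplicated sample ids")
  bad <- plan$pathogenic_pole & !plan$signature_pole
  if (any(bad))
    stop_field("infeasible spec: sample %s planted pathogenic_pole without signature_pole",
               plan$sample[which(bad)[1]])
  for (ep in names(spec$survival_params$multipliers))
    if (any(spec$survival_params$multipliers[[ep]] <= 0))
      stop_field("invalid spec: hazard multipliers must be > 0 (%s)", ep)
  if (spec$censoring_rate < 0 || spec$censoring_rate > 1)
    stop_field("invalid spec: censoring_rate must be in [0, 1]")
  invisible(spec)
}

#' Planted truth labels of a plan
#'
#' Derives, per sample, the two truth labels implied by the planted flags
#' under the cascade precedences (POLE > MSI > CN for the TCGA-analogue
#' track; POLEmut > dMMR > p53abn > NSMP for the surrogate track).
#'
#' @param plan a `subtype_plan` data frame.
#' @return data frame with `sample`, `tcga_truth`, `surrogate_truth`.
#' @export
truth_labels <- function(plan) {
  tcga <- ifelse(plan$signature_pole, "POLE",
                 ifelse(plan$msi_h, "MSI",
                        ifelse(plan$cn_cluster4, "CN_high", "CN_low")))
  surro <- ifelse(plan$pathogenic_pole, "POLEmut",
                  ifelse(plan$msi_h, "dMMR",
                         ifelse(plan$tp53_nonsilent, "p53abn", "NSMP")))
  data.frame(sample = plan$sample, tcga_truth = tcga, surrogate_truth = surro,
             stringsAsFactors = FALSE)
}

#' The packaged 108-sample fixture specification
#'
#' The default validation cohort: 9 POLE-signature samples of which 6 carry a
#' whitelisted pathogenic POLE mutation (of the 3 signature-only samples, 2
#' are also MSI-H and 1 carries a non-silent TP53 mutation); 51 further MSI-H
#' samples; 15 CN-cluster-4 samples (6 of them TP53-mutant); 4 TP53-mutant
#' but otherwise quiet samples; the rest quiet. Under the cascades this plan
#' forces the subtype distribution 9/51/33/15 (TCGA-analogue) and 6/53/38/11
#' (surrogate). Nine samples carry FFPE-degraded QC metrics; two samples lack
#' OS time/status and one lacks PFS time/status.
#'
#' @param seed integer seed.
#' @return a [cohort_spec()] with `n_samples = 108`.
#' @export
default_fixture_spec <- function(seed = 1) {
  ids <- sprintf("S%03d", 1:108)
  plan <- data.frame(sample = ids,
                     signature_pole = FALSE, pathogenic_pole = FALSE,
                     msi_h = FALSE, cn_cluster4 = FALSE,
                     tp53_nonsilent = FALSE, degraded_qc = FALSE,
                     stringsAsFactors = FALSE)
  plan$signature_pole[1:9] <- TRUE
  plan$pathogenic_pole[1:6] <- TRUE
  plan$msi_h[7:8] <- TRUE            # signature-only POLE, also MSI-H
  plan$tp53_nonsilent[9] <- TRUE     # signature-only POLE, TP53-mutant
  plan$msi_h[10:60] <- TRUE          # 51 further MSI-H
  plan$cn_cluster4[61:75] <- TRUE    # 15 CN cluster 4
  plan$tp53_nonsilent[61:66] <- TRUE # 6 of them TP53-mutant
  plan$tp53_nonsilent[76:79] <- TRUE # 4 quiet TP53-mutant
  plan$degraded_qc[c(10:17, 105)] <- TRUE
  cohort_spec(108, plan, seed = seed,
              missing_clinical = list(os = c("S106", "S107"), pfs = "S108"))
}

#' Training-cohort specification for the cluster-4 predictor
#'
#' A 240-sample cohort with 26% cluster-4 positives (labels assigned, not
#' sampled: `round(0.26 * 240) = 62` positives) and quiet genomes otherwise,
#' mirroring the size and class balance of the TCGA training design.
#'
#' @param n_samples cohort size (default 240).
#' @param positive_fraction fraction of cluster-4 samples (default 0.26).
#' @param seed integer seed.
#' @return a [cohort_spec()].
#' @export
cn_training_spec <- function(n_samples = 240, positive_fraction = 0.26,
                             seed = 1) {
  ids <- sprintf("T%03d", seq_len(n_samples))
  plan <- data.frame(sample = ids,
                     signature_pole = FALSE, pathogenic_pole = FALSE,
                     msi_h = FALSE, cn_cluster4 = FALSE,
                     tp53_nonsilent = FALSE, degraded_qc = FALSE,
                     stringsAsFactors = FALSE)
  plan$cn_cluster4[seq_len(round(positive_fraction * n_samples))] <- TRUE
  cohort_spec(n_samples, plan, seed = seed)
}
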