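# Sequencing-quality plausibility flags for MSI calls, and IHC concordance.
#
# In FFPE material, poor DNA quality inflates apparent microsatellite
# instability. Four QC metrics predict such spurious MSI calls; a sample
# breaching any rule is FLAGGED (strict inequalities, OR-combined) so that an
# MSI-H call on it can be annotated as at risk of an FFPE artifact. The
# thresholds never alter the cascade's calls — they are an audit trail, not a
# classification rule.

#' Default QC risk thresholds
#'
#' A sample is flagged when: percentage of mapped reads below 92, percentage
#' of on-target reads below 66, percentage of short fragments above 93, or
#' adapter contamination above 6.34 (all strict).
#'
#' @return named list of thresholds.
#' @export
qc_thresholds <- function() {
  list(pct_mapped = 92, pct_on_target = 66, pct_short_fragments = 93,
       adapter_contamination = 6.34)
}

#' Flag QC metrics that predict spurious MSI calls
#'
#' @param qc one sample's QC metrics: a one-row data frame or named
#'   list/vector with `pct_mapped`, `pct_on_target`, `pct_short_fragments`,
#'   `adapter_contamination` (percentages). A missing metric skips its rule
#'   with a warning.
#' @param thresholds see [qc_thresholds()].
#' @return character vector of breached-rule names (empty when clean).
#' @export
flag_msi_quality <- function(qc, thresholds = qc_thresholds()) {
  qc <- as.list(qc)
  get_metric <- function(name) {
    val <- qc[[name]]
    if (is.null(val) || is.na(val)) {
      warning(sprintf("QC metric %s missing; rule skipped", name),
              call. = FALSE)
      return(NA_real_)
    }
    as.numeric(val)
  }
  flags <- character(0)
  m <- get_metric("pct_mapped")
  if (!is.na(m) && m < thresholds$pct_mapped) flags <- c(flags, "low_mapped")
  m <- get_metric("pct_on_target")
  if (!is.na(m) && m < thresholds$pct_on_target)
    flags <- c(flags, "low_on_target")
  m <- get_metric("pct_short_fragments")
  if (!is.na(m) && m > thresholds$pct_short_fragments)
    flags <- c(flags, "short_fragments")
  m <- get_metric("adapter_contamination")
  if (!is.na(m) && m > thresholds$adapter_contamination)
    flags <- c(flags, "adapter_contamination")
  flags
}

#' IHC vs WES MSI concordance
#'
#' Cross-tabulates mismatch-repair calls from immunohistochemistry (dMMR /
#' pMMR) against WES MSI calls (MSI-H / MSS) on the same samples and computes
#' percent agreement.
#'
#' @param ihc_calls named logical vector (or named character coercible to
#'   logical positives): `TRUE` = dMMR, names = sample ids.
#' @param wes_calls named logical vector: `TRUE` = MSI-H, same sample set.
#' @return object of class `concordance_result`: `table` (2x2, IHC as
#'   reference axis), `percent_agreement`, `n`.
#' @export
concordance <- function(ihc_calls, wes_calls) {
  if (!setequal(names(ihc_calls), names(wes_calls)))
    stop_field("sample sets differ: only in IHC {%s}; only in WES {%s}",
               paste(setdiff(names(ihc_calls), names(wes_calls)),
                     collapse = ","),
               paste(setdiff(names(wes_calls), names(ihc_calls)),
                     collapse = ","))
  wes_calls <- wes_calls[names(ihc_calls)]
  ihc <- factor(ifelse(ihc_calls, "dMMR", "pMMR"), levels = c("dMMR", "pMMR"))
  wes <- factor(ifelse(wes_calls, "MSI-H", "MSS"), levels = c("MSI-H", "MSS"))
  tab <- table(IHC = ihc, WES = wes)
  n <- length(ihc)
  agree <- 100 * (tab["dMMR", "MSI-H"] + tab["pMMR", "MSS"]) / n
  structure(list(table = tab, percent_agreement = agree, n = n),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("IHC vs WES MSI concordance: %.1f%% agreement (n = %d)\n",
              x$percent_agreement, x$n))
  print(x$table)
  invisible(x)
}

#' Nested-calls contingency construction
#'
#' Builds the call vectors of a sub-cohort from its printed marginals under
#' the nested-calls assumption: every WES MSI-H sample is also IHC-dMMR
#' (`wes_pos <= ihc_pos`), so the 2x2 table is forced to
#' `(wes_pos, ihc_pos - wes_pos, 0, n - ihc_pos)`.
#'
#' @param n sub-cohort size.
#' @param ihc_pos number of IHC-dMMR samples.
#' @param wes_pos number of WES MSI-H samples.
#' @return list with named logical vectors `ihc` and `wes` of length `n`.
#' @export
nested_concordance_table <- function(n, ihc_pos, wes_pos) {
  stopifnot(wes_pos <= ihc_pos, ihc_pos <= n)
  ids <- sprintf("C%03d", seq_len(n))
  ihc <- setNames(seq_len(n) <= ihc_pos, ids)
  wes <- setNames(seq_len(n) <= wes_pos, ids)
  list(ihc = ihc, wes = wes)
}
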