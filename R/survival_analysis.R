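# Survival evaluation of the subtype strata: Kaplan-Meier curves, k-group
# log-rank tests, and Cox proportional-hazards regression with the subtype as
# a categorical covariate (reference: CN low for the TCGA-analogue track,
# NSMP for the surrogate track). Efron tie handling throughout. A stratum
# with zero events is reported with the degenerate convention HR 0 and an
# infinite upper confidence limit.

drop_missing <- function(times, events, labels) {
  keep <- !is.na(times) & !is.na(events)
  list(times = times[keep], events = events[keep],
       labels = droplevels(factor(labels[keep])), n_dropped = sum(!keep))
}

#' Kaplan-Meier curves per group
#'
#' Product-limit estimator per group; a group with no events yields a flat
#' curve at 1.0 (with a warning).
#'
#' @param times follow-up times; `events` status (1 = event, 0 = censored);
#'   `labels` group membership. Subjects with missing time or status are
#'   dropped.
#' @param events event indicators.
#' @param labels group labels.
#' @return a [survival::survfit] object.
#' @export
km_curve <- function(times, events, labels) {
  d <- drop_missing(times, events, labels)
  for (g in levels(d$labels))
    if (sum(d$events[d$labels == g]) == 0)
      warning(sprintf("group %s has no events: flat curve at 1.0", g),
              call. = FALSE)
  survival::survfit(survival::Surv(d$times, d$events) ~ d$labels)
}

#' Multigroup log-rank test
#'
#' k-group log-rank chi-square with k-1 degrees of freedom.
#'
#' @inheritParams km_curve
#' @return list with `statistic`, `df`, `p_value`, `n_used`.
#' @export
logrank_test <- function(times, events, labels) {
  d <- drop_missing(times, events, labels)
  if (nlevels(d$labels) < 2) stop_field("log-rank test needs >= 2 groups")
  if (sum(d$events) == 0) stop_field("log-rank test needs >= 1 event")
  sd <- survival::survdiff(survival::Surv(d$times, d$events) ~ d$labels)
  df <- length(sd$n) - 1
  list(statistic = unname(sd$chisq), df = df,
       p_value = pchisq(sd$chisq, df, lower.tail = FALSE),
       n_used = sum(sd$n))
}

#' Cox proportional-hazards regression on subtype strata
#'
#' Partial-likelihood fit (Efron ties by default) with one indicator per
#' non-reference subtype and Wald 95% confidence intervals. Subtypes with
#' zero events are reported with the degenerate convention: hazard ratio 0,
#' confidence interval (0, Inf). Non-convergence is surfaced as an error.
#'
#' @inheritParams km_curve
#' @param reference reference subtype (must be a level of `labels`).
#' @param ties tie-handling method passed to [survival::coxph()].
#' @return object of class `cox_subtypes`: data frame `hr_table` (`subtype`,
#'   `n`, `pct`, `events`, `hr`, `lower95`, `upper95`), plus `logrank`
#'   (from [logrank_test()]), `reference`, `n_used`, `fit`.
#' @export
cox_subtypes <- function(times, events, labels, reference, ties = "efron") {
  d <- drop_missing(times, events, labels)
  if (!reference %in% levels(d$labels))
    stop_field("reference group %s absent from labels", reference)
  lab <- stats::relevel(d$labels, ref = reference)
  nonref <- setdiff(levels(lab), reference)
  ev_by <- tapply(d$events, lab, sum)
  if (sum(ev_by[nonref]) == 0)
    stop_field("no events outside the reference group; Cox model untestable")
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(d$times, d$events) ~ lab, ties = ties))
  if (!is.null(fit$fail))
    stop_field("Cox model failed to converge: %s", fit$fail)
  sm <- summary(fit)
  co <- sm$coefficients  # rows labXXX
  n_by <- table(lab)
  rows <- lapply(nonref, function(g) {
    nm <- paste0("lab", g)
    zero <- ev_by[[g]] == 0
    if (zero) {
      hr <- 0; lo <- 0; hi <- Inf
    } else {
      b <- co[nm, "coef"]; se <- co[nm, "se(coef)"]
      hr <- exp(b); lo <- exp(b - qnorm(0.975) * se)
      hi <- exp(b + qnorm(0.975) * se)
    }
    data.frame(subtype = g, n = as.integer(n_by[[g]]),
               pct = round_half_up(100 * n_by[[g]] / sum(n_by), 1),
               events = as.integer(ev_by[[g]]), hr = hr, lower95 = lo,
               upper95 = hi, stringsAsFactors = FALSE)
  })
  structure(list(hr_table = do.call(rbind, rows),
                 logrank = logrank_test(d$times, d$events, d$labels),
                 reference = reference, n_used = length(d$times),
                 n_dropped = d$n_dropped, ties = ties, fit = fit),
            class = "cox_subtypes")
}

#' @export
print.cox_subtypes <- function(x, ...) {
  cat(sprintf("Cox PH on subtype strata (reference %s; n = %d, %d dropped for missing time/status)\n",
              x$reference, x$n_used, x$n_dropped))
  cat(sprintf("  log-rank p = %.5g (chi-square %.3f, %d df)\n",
              x$logrank$p_value, x$logrank$statistic, x$logrank$df))
  t <- x$hr_table
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %-8s n=%3d (%.1f%%) events=%2d  HR %.3f [%.3f, %s]\n",
                t$subtype[i], t$n[i], t$pct[i], t$events[i], t$hr[i],
                t$lower95[i],
                if (is.infinite(t$upper95[i])) "Inf" else
                  sprintf("%.3f", t$upper95[i])))
  invisible(x)
}

#' Evaluate prognostic value of both classification tracks
#'
#' For each track (TCGA-analogue, surrogate) and endpoint (OS, PFS): log-rank
#' test across the subtype strata and Cox hazard ratios versus the track's
#' reference group (CN low, NSMP). Endpoints with no events outside the
#' reference are reported untestable.
#'
#' @param calls `subtype_calls` (or data frame with `sample`, `tcga_label`,
#'   `surrogate_label`).
#' @param clinical clinical data frame (see [read_clinical()]).
#' @param tracks,endpoints subsets to evaluate.
#' @return object of class `survival_eval`: nested list
#'   `result[[track]][[endpoint]]` of [cox_subtypes()] results (or a
#'   character reason when untestable).
#' @export
evaluate_survival <- function(calls, clinical,
                              tracks = c("tcga", "surrogate"),
                              endpoints = c("os", "pfs")) {
  merged <- merge(as.data.frame(calls)[, c("sample", "tcga_label",
                                           "surrogate_label")],
                  clinical, by = "sample")
  refs <- c(tcga = "CN_low", surrogate = "NSMP")
  labcol <- c(tcga = "tcga_label", surrogate = "surrogate_label")
  out <- list()
  for (tr in tracks) {
    out[[tr]] <- list()
    keep <- merged[[labcol[[tr]]]] != "unclassifiable"
    for (ep in endpoints) {
      tcol <- paste0(ep, "_months"); ecol <- paste0(ep, "_event")
      res <- tryCatch(
        cox_subtypes(merged[[tcol]][keep], merged[[ecol]][keep],
                     merged[[labcol[[tr]]]][keep], reference = refs[[tr]]),
        error = function(e) conditionMessage(e))
      out[[tr]][[ep]] <- res
    }
  }
  structure(list(result = out), class = "survival_eval")
}

#' @export
print.survival_eval <- function(x, ...) {
  for (tr in names(x$result)) {
    for (ep in names(x$result[[tr]])) {
      cat(sprintf("== %s track, %s ==\n", tr, toupper(ep)))
      r <- x$result[[tr]][[ep]]
      if (is.character(r)) cat("  untestable:", r, "\n") else print(r)
    }
  }
  invisible(x)
}

#' Serialize a survival evaluation as JSON
#'
#' @param eval a `survival_eval`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_survival_json <- function(eval, path) {
  strip <- function(r) {
    if (is.character(r)) return(list(untestable = r))
    list(logrank_p = r$logrank$p_value,
         logrank_statistic = r$logrank$statistic,
         reference = r$reference, n_used = r$n_used,
         hazard_ratios = r$hr_table)
  }
  obj <- lapply(eval$result, function(track) lapply(track, strip))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  invisible(path)
}
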