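# Gaussian Naive Bayes predictor of the TCGA serous-like copy-number cluster
# (cluster 4) from per-sample copy-number features.
#
# The class-conditional model is Gaussian per feature with empirical class
# priors; the features (gain/loss counts, per-chromosome counts, gene counts,
# ploidy, altered megabases) plainly violate the independence assumption, but
# the model is robust here, which is exactly why it was chosen. A variance
# floor of 1e-9 times the largest feature variance guards degenerate
# (constant) features, mirroring the usual variance-smoothing convention.

#' Fit the cluster-4 Gaussian Naive Bayes model
#'
#' @param x numeric feature matrix (samples x features), e.g. from
#'   [cn_feature_matrix()].
#' @param y logical (or 0/1) vector: `TRUE` for cluster-4 samples.
#' @param selected_genes optional character vector of the gene features frozen
#'   into the model (stored for provenance and reapplied at prediction time).
#' @param gain_cutoff,loss_cutoff the alteration cutoffs the features were
#'   extracted with (stored so prediction uses the same definition).
#' @return object of class `nb_cluster4` with per-class feature means and
#'   variances, class priors, and the variance floor.
#' @export
nb_cluster4 <- function(x, y, selected_genes = NULL,
                        gain_cutoff = 2.5, loss_cutoff = 1.5) {
  x <- as.matrix(x)
  y <- as.logical(y)
  stopifnot(nrow(x) == length(y), !anyNA(y))
  if (length(unique(y)) < 2L)
    stop_field("refusing to train: training labels contain a single class")
  if (min(table(y)) < 2L)
    stop_field("refusing to train: need at least 2 samples per class")
  mu <- rbind(neg = colMeans(x[!y, , drop = FALSE]),
              pos = colMeans(x[y, , drop = FALSE]))
  v <- rbind(neg = apply(x[!y, , drop = FALSE], 2, var),
             pos = apply(x[y, , drop = FALSE], 2, var))
  vmax <- max(v, na.rm = TRUE)
  floor_v <- if (vmax > 0) 1e-9 * vmax else 1e-9
  v[v < floor_v | is.na(v)] <- floor_v
  structure(list(means = mu, vars = v,
                 priors = c(neg = mean(!y), pos = mean(y)),
                 var_floor = floor_v, features = colnames(x),
                 selected_genes = selected_genes,
                 gain_cutoff = gain_cutoff, loss_cutoff = loss_cutoff,
                 n_train = nrow(x)),
            class = "nb_cluster4")
}

#' Predict cluster-4 membership
#'
#' @param object fitted [nb_cluster4()] model.
#' @param newdata feature matrix (or single feature vector) with the model's
#'   feature columns.
#' @param ... unused.
#' @return data frame with `posterior` (P(cluster 4 | features)) and
#'   `cluster4` (`posterior > 0.5`), one row per sample.
#' @export
predict.nb_cluster4 <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1,
                                               dimnames = list(NULL, names(newdata)))
  newdata <- as.matrix(newdata)
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing) > 0)
    stop_field("prediction features missing: %s",
               paste(utils::head(missing, 5), collapse = ", "))
  x <- newdata[, object$features, drop = FALSE]
  ll <- function(cls) {
    mu <- object$means[cls, ]; v <- object$vars[cls, ]
    rowSums(dnorm(x, mean = matrix(mu, nrow(x), ncol(x), byrow = TRUE),
                  sd = matrix(sqrt(v), nrow(x), ncol(x), byrow = TRUE),
                  log = TRUE)) + log(object$priors[[cls]])
  }
  lp <- cbind(neg = ll("neg"), pos = ll("pos"))
  m <- apply(lp, 1, max)
  post <- exp(lp[, "pos"] - m) / (exp(lp[, "neg"] - m) + exp(lp[, "pos"] - m))
  data.frame(sample = rownames(x) %||% seq_len(nrow(x)),
             posterior = unname(post), cluster4 = unname(post > 0.5),
             stringsAsFactors = FALSE)
}

#' @export
print.nb_cluster4 <- function(x, ...) {
  cat("Gaussian Naive Bayes cluster-4 predictor\n")
  cat(sprintf("  %d features, trained on %d samples (priors: cluster4 %.3f / other %.3f)\n",
              length(x$features), x$n_train, x$priors[["pos"]], x$priors[["neg"]]))
  if (!is.null(x$selected_genes))
    cat(sprintf("  gene features: %s ...\n",
                paste(utils::head(x$selected_genes, 6), collapse = ", ")))
  invisible(x)
}

#' @export
summary.nb_cluster4 <- function(object, ...) {
  print(object)
  sep <- abs(object$means["pos", ] - object$means["neg", ]) /
    sqrt(0.5 * (object$vars["pos", ] + object$vars["neg", ]))
  cat("  most separating features (standardized mean difference):\n")
  top <- sort(sep, decreasing = TRUE)[1:5]
  for (i in seq_along(top))
    cat(sprintf("    %-18s %.2f\n", names(top)[i], top[i]))
  invisible(object)
}

#' @export
coef.nb_cluster4 <- function(object, ...) {
  t(rbind(mean_other = object$means["neg", ], mean_cluster4 = object$means["pos", ],
          var_other = object$vars["neg", ], var_cluster4 = object$vars["pos", ]))
}

#' Serialize / reload a fitted model as JSON
#'
#' Exact round-trip of means, variances, priors, feature list, gene selection
#' and cutoffs, so a trained model can be shipped and reloaded bit-for-bit.
#'
#' @param model fitted `nb_cluster4` model.
#' @param path JSON file path.
#' @return `read_nb_model` returns the model; `write_nb_model` its path,
#'   invisibly.
#' @export
write_nb_model <- function(model, path) {
  obj <- unclass(model)
  obj$means <- as.list(as.data.frame(obj$means))
  obj$vars <- as.list(as.data.frame(obj$vars))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_nb_model
#' @export
read_nb_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- obj$features
  model <- list(
    means = rbind(neg = vapply(feats, function(f) obj$means[[f]][1], 0),
                  pos = vapply(feats, function(f) obj$means[[f]][2], 0)),
    vars = rbind(neg = vapply(feats, function(f) obj$vars[[f]][1], 0),
                 pos = vapply(feats, function(f) obj$vars[[f]][2], 0)),
    priors = c(neg = obj$priors[[1]], pos = obj$priors[[2]]),
    var_floor = obj$var_floor, features = feats,
    selected_genes = obj$selected_genes,
    gain_cutoff = obj$gain_cutoff, loss_cutoff = obj$loss_cutoff,
    n_train = obj$n_train)
  class(model) <- "nb_cluster4"
  model
}

# Area under the ROC curve via the rank (Mann-Whitney) formula; ties get
# average ranks. Positive class = TRUE.
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: positives and negatives are each shuffled and
# dealt round-robin into `folds` folds.
stratified_folds <- function(y, folds) {
  assign <- integer(length(y))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Stratified cross-validation of the cluster-4 predictor
#'
#' Stratified k-fold cross-validation with cluster 4 as the positive class.
#' Accuracy, precision, recall, F1 (all at the 0.5 posterior cut) and ROC-AUC
#' (from the posterior scores) are computed on each held-out fold and averaged
#' unweighted. Undefined precision/recall/F1 (zero denominator) count as 0.
#'
#' @param x feature matrix; `y` logical labels; see [nb_cluster4()].
#' @param y logical labels.
#' @param folds number of folds (default 5); both classes must have at least
#'   `folds` members.
#' @param seed integer seed controlling the fold split.
#' @return object of class `cv_metrics`: `accuracy`, `precision`, `recall`,
#'   `f1`, `roc_auc`, `fold_count`, `seed`, and the per-fold table.
#' @export
cross_validate <- function(x, y, folds = 5, seed = 1) {
  x <- as.matrix(x); y <- as.logical(y)
  stopifnot(nrow(x) == length(y))
  if (min(sum(y), sum(!y)) < folds)
    stop_field("stratification impossible: a class has fewer than %d members", folds)
  assign <- with_seed(seed, stratified_folds(y, folds))
  per_fold <- lapply(seq_len(folds), function(f) {
    tr <- assign != f; te <- !tr
    fit <- nb_cluster4(x[tr, , drop = FALSE], y[tr])
    pr <- predict(fit, x[te, , drop = FALSE])
    truth <- y[te]; pred <- pr$cluster4
    tp <- sum(pred & truth); fp <- sum(pred & !truth)
    fn <- sum(!pred & truth)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(accuracy = mean(pred == truth), precision = prec, recall = rec,
      f1 = f1, roc_auc = auc_rank(pr$posterior, truth))
  })
  tab <- do.call(rbind, per_fold)
  avg <- colMeans(tab)
  structure(c(as.list(avg), list(fold_count = folds, seed = seed,
                                 per_fold = tab)),
            class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, ...) {
  cat(sprintf("Stratified %d-fold CV (seed %s)\n", x$fold_count, x$seed))
  cat(sprintf("  accuracy %.3f  precision %.3f  recall %.3f  f1 %.3f  ROC-AUC %.3f\n",
              x$accuracy, x$precision, x$recall, x$f1, x$roc_auc))
  invisible(x)
}
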