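# Pipeline configuration and end-to-end entry points (the function-level
# equivalents of the command-line subcommands in inst/cli/endotype.R).

#' Pipeline configuration
#'
#' Gathers every threshold the pipeline applies in one serializable place:
#' the somatic filter, the POLE spectrum rule, the MSI threshold and minimum
#' locus depth, the copy-number gain/loss cutoffs, the QC risk thresholds,
#' and the seed used for model training.
#'
#' @param input_dir directory holding a written cohort (see [write_bundle()]).
#' @param out_dir output directory for calls/summary/survival files.
#' @param model_path optional JSON path of a trained cluster-4 model; when
#'   unset a model is trained on the synthetic training cohort.
#' @param filter a [filter_config()].
#' @param pole_rule a [pole_rule_params()].
#' @param msi_threshold MSI-H threshold on the aggregate stepwise difference
#'   (default 0.3, inclusive).
#' @param msi_min_depth minimum usable locus depth (default 20).
#' @param gain_cutoff,loss_cutoff copy-number alteration cutoffs.
#' @param n_top_genes number of gene features (default 25).
#' @param qc_thresholds see [qc_thresholds()].
#' @param seed integer seed (model training cohort and any other randomness).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, out_dir = NULL,
                            model_path = NULL,
                            filter = filter_config(),
                            pole_rule = pole_rule_params(),
                            msi_threshold = 0.3, msi_min_depth = 20,
                            gain_cutoff = 2.5, loss_cutoff = 1.5,
                            n_top_genes = 25,
                            qc_thresholds = endotype::qc_thresholds(),
                            seed = 1) {
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 model_path = model_path, filter = filter,
                 pole_rule = pole_rule, msi_threshold = msi_threshold,
                 msi_min_depth = msi_min_depth, gain_cutoff = gain_cutoff,
                 loss_cutoff = loss_cutoff, n_top_genes = n_top_genes,
                 qc_thresholds = qc_thresholds,
                 pole_whitelist = pole_whitelist(),
                 gene_model = NULL, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#'
#' Load -> dump -> load is stable (identical configs).
#'
#' @param config a [pipeline_config()]; `path` JSON file.
#' @param path JSON file path.
#' @return `read_pipeline_config` returns the config.
#' @export
write_pipeline_config <- function(config, path) {
  obj <- unclass(config)
  obj$filter <- unclass(obj$filter)
  obj$pole_rule <- unclass(obj$pole_rule)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipeline_config(
    input_dir = obj$input_dir, out_dir = obj$out_dir,
    model_path = obj$model_path,
    filter = do.call(filter_config, as.list(obj$filter)),
    pole_rule = do.call(pole_rule_params, as.list(obj$pole_rule)),
    msi_threshold = obj$msi_threshold, msi_min_depth = obj$msi_min_depth,
    gain_cutoff = obj$gain_cutoff, loss_cutoff = obj$loss_cutoff,
    n_top_genes = obj$n_top_genes,
    qc_thresholds = as.list(obj$qc_thresholds),
    seed = obj$seed)
  cfg$pole_whitelist <- list(
    hotspots = obj$pole_whitelist$hotspots,
    domain_range = as.integer(obj$pole_whitelist$domain_range))
  if (!is.null(obj$gene_model)) cfg$gene_model <- as.data.frame(obj$gene_model)
  cfg
}

#' Train the cluster-4 model on the synthetic training cohort
#'
#' Generates the 240-sample training cohort (26% cluster-4), selects the
#' most recurrently altered genes, extracts features at the configured
#' cutoffs and fits the Gaussian Naive Bayes model.
#'
#' @param config a [pipeline_config()] (supplies cutoffs, gene count, seed).
#' @return fitted [nb_cluster4()] model.
#' @export
train_cn_model <- function(config = pipeline_config()) {
  spec <- cn_training_spec(seed = config$seed)
  bundle <- generate_cohort(spec, components = "cn_segments")
  gm <- config$gene_model %||% synthetic_gene_model()
  genes <- suppressWarnings(
    select_top_genes(bundle$cn_segments, gm, k = config$n_top_genes,
                     gain_cutoff = config$gain_cutoff,
                     loss_cutoff = config$loss_cutoff))
  x <- cn_feature_matrix(bundle$cn_segments, gm, selected_genes = genes,
                         gain_cutoff = config$gain_cutoff,
                         loss_cutoff = config$loss_cutoff)
  y <- bundle$truth$cn_cluster4[match(rownames(x), bundle$truth$sample)]
  nb_cluster4(x, y, selected_genes = genes,
              gain_cutoff = config$gain_cutoff,
              loss_cutoff = config$loss_cutoff)
}

#' Generate and write a synthetic cohort (simulate step)
#'
#' @param spec a [cohort_spec()].
#' @param out_dir target directory.
#' @return the written `cohort_bundle`, invisibly.
#' @export
pipeline_simulate <- function(spec, out_dir) {
  bundle <- generate_cohort(spec)
  write_bundle(bundle, out_dir)
  invisible(bundle)
}

#' Classify a written cohort (classify step)
#'
#' Reads the cohort from `config$input_dir`, loads (or trains) the cluster-4
#' model, classifies every sample and writes `calls.tsv` plus a
#' `summary.json` mirroring the subtype-distribution table to
#' `config$out_dir`.
#'
#' @param config a [pipeline_config()] with `input_dir` and `out_dir` set.
#' @return the `subtype_calls`, invisibly.
#' @export
pipeline_classify <- function(config) {
  stopifnot(!is.null(config$input_dir), !is.null(config$out_dir))
  bundle <- read_bundle(config$input_dir, config = NULL)
  model <- if (!is.null(config$model_path)) read_nb_model(config$model_path)
           else train_cn_model(config)
  calls <- classify_cohort(bundle, model = model, config = config)
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  write_calls(calls, file.path(config$out_dir, "calls.tsv"))
  summ <- summarize_cohort(calls)
  jsonlite::write_json(
    list(tcga = summ$tcga, surrogate = summ$surrogate,
         n_classified = as.list(summ$n_classified),
         n_unclassifiable = summ$n_unclassifiable),
    file.path(config$out_dir, "summary.json"),
    digits = NA, auto_unbox = TRUE, dataframe = "rows")
  invisible(calls)
}

#' Evaluate survival of classified strata (evaluate step)
#'
#' Reads `calls.tsv` from `config$out_dir` and the clinical table from the
#' input directory, evaluates both tracks and endpoints, and writes
#' `survival.json`.
#'
#' @param config a [pipeline_config()].
#' @return the `survival_eval`, invisibly.
#' @export
pipeline_evaluate <- function(config) {
  stopifnot(!is.null(config$input_dir), !is.null(config$out_dir))
  calls <- read_tsv(file.path(config$out_dir, "calls.tsv"))
  clinical <- read_clinical(file.path(config$input_dir, "clinical.tsv"))
  eval <- evaluate_survival(calls, clinical)
  write_survival_json(eval, file.path(config$out_dir, "survival.json"))
  invisible(eval)
}
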