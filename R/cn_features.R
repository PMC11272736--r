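# Copy-number feature engineering for cluster-4 prediction.

#' Synthetic genome model
#'
#' Chromosome lengths (bases) of the synthetic genome used by the cohort
#' generator and the per-chromosome feature slots: chr1-chr22 and chrX, with
#' lengths approximating the human assembly at megabase resolution.
#'
#' @return named numeric vector of chromosome lengths in bases.
#' @export
genome_model <- function() {
  mb <- c(chr1 = 248, chr2 = 242, chr3 = 198, chr4 = 190, chr5 = 181,
          chr6 = 171, chr7 = 159, chr8 = 145, chr9 = 138, chr10 = 134,
          chr11 = 135, chr12 = 133, chr13 = 114, chr14 = 107, chr15 = 102,
          chr16 = 90, chr17 = 83, chr18 = 80, chr19 = 59, chr20 = 64,
          chr21 = 47, chr22 = 51, chrX = 156)
  mb * 1e6
}

#' Read a gene model from BED
#'
#' @param path BED file (0-based half-open: chrom, start, end, name).
#' @return data frame with columns `chrom`, `start`, `end`, `gene`.
#' @export
read_gene_model <- function(path) {
  gm <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "gene"),
                          stringsAsFactors = FALSE)
  stopifnot(all(gm$start < gm$end))
  gm
}

#' Packaged synthetic gene model
#'
#' Forty cancer-gene symbols placed at synthetic coordinates on the synthetic
#' genome (see `inst/extdata/genes_synthetic.bed`); used for gene-level
#' copy-number alteration counts. For real data supply your own BED via
#' [read_gene_model()].
#'
#' @return gene-model data frame.
#' @export
synthetic_gene_model <- function() {
  read_gene_model(system.file("extdata", "genes_synthetic.bed",
                              package = "endotype", mustWork = TRUE))
}

# Canonicalize one sample's segments: sort, then merge adjacent (touching)
# segments on the same chromosome with equal copy number, so feature counts
# are invariant to how a constant-CN run was split.
merge_segments <- function(segments) {
  if (nrow(segments) == 0L) return(segments)
  segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  out <- vector("list", nrow(segments))
  cur <- segments[1, , drop = FALSE]
  j <- 0L
  for (i in seq_len(nrow(segments))[-1]) {
    s <- segments[i, , drop = FALSE]
    if (s$chrom == cur$chrom && s$start <= cur$end &&
        isTRUE(all.equal(s$copy_number, cur$copy_number))) {
      cur$end <- max(cur$end, s$end)
    } else {
      j <- j + 1L; out[[j]] <- cur; cur <- s
    }
  }
  out[[j + 1L]] <- cur
  res <- do.call(rbind, out[seq_len(j + 1L)])
  rownames(res) <- NULL
  res
}

#' Extract per-sample copy-number features
#'
#' Computes the feature vector consumed by the cluster-4 Naive Bayes
#' predictor: total gain and loss counts, gain/loss counts per chromosome
#' (chr1-chr22, chrX), alteration counts for the selected genes, ploidy
#' (segment-length-weighted mean copy number), and the total altered genome
#' length in megabases. A gain is a (merged) segment with copy number above
#' `gain_cutoff`, a loss one below `loss_cutoff`; adjacent equal-CN segments
#' are merged first so counts are representation-independent. A gene is
#' counted once per altered segment overlapping it by at least one base.
#' The alteration rate per megabase of genome is also returned
#' (`alt_per_mb`) but is not part of the default classifier feature set.
#'
#' @param segments one sample's segment data frame: `chrom`, `start`, `end`
#'   (0-based half-open, bases), `copy_number`.
#' @param gene_model gene intervals, see [read_gene_model()].
#' @param selected_genes character vector of genes to expose as features
#'   (typically the 25 most recurrently altered in a training cohort, see
#'   [select_top_genes()]); defaults to all genes in `gene_model`.
#' @param gain_cutoff,loss_cutoff absolute copy-number cutoffs (defaults
#'   2.5 and 1.5).
#' @return named numeric vector of class `cn_features`.
#' @export
extract_cn_features <- function(segments, gene_model = synthetic_gene_model(),
                                selected_genes = NULL,
                                gain_cutoff = 2.5, loss_cutoff = 1.5) {
  chroms <- names(genome_model())
  if (is.null(selected_genes)) selected_genes <- sort(unique(gene_model$gene))
  empty <- nrow(segments) == 0L
  if (!empty) {
    stopifnot(all(segments$start < segments$end))
    segments <- merge_segments(segments)
  } else {
    warning("sample has no copy-number segments; features set to zero, ploidy 2.0",
            call. = FALSE)
  }
  gains_chrom <- setNames(numeric(length(chroms)), chroms)
  losses_chrom <- gains_chrom
  gene_counts <- setNames(numeric(length(selected_genes)), selected_genes)
  ploidy <- 2.0
  altered_mb <- 0
  alt_per_mb <- 0
  if (!empty) {
    len <- segments$end - segments$start
    cn <- segments$copy_number
    gain <- cn > gain_cutoff
    loss <- cn < loss_cutoff
    altered <- gain | loss
    gt <- tapply(gain, factor(segments$chrom, levels = chroms), sum)
    lt <- tapply(loss, factor(segments$chrom, levels = chroms), sum)
    gains_chrom[] <- ifelse(is.na(gt), 0, gt)
    losses_chrom[] <- ifelse(is.na(lt), 0, lt)
    ploidy <- sum(len * cn) / sum(len)
    altered_mb <- sum(len[altered]) / 1e6
    alt_per_mb <- sum(altered) / (sum(genome_model()) / 1e6)
    alt_seg <- segments[altered, , drop = FALSE]
    if (nrow(alt_seg) > 0L) {
      gm <- gene_model[gene_model$gene %in% selected_genes, , drop = FALSE]
      for (g in seq_len(nrow(gm))) {
        ov <- alt_seg$chrom == gm$chrom[g] &
          alt_seg$start < gm$end[g] & alt_seg$end > gm$start[g]
        gene_counts[gm$gene[g]] <- gene_counts[gm$gene[g]] + sum(ov)
      }
    }
  }
  out <- c(n_gains = sum(gains_chrom), n_losses = sum(losses_chrom),
           setNames(gains_chrom, paste0("gains_", chroms)),
           setNames(losses_chrom, paste0("losses_", chroms)),
           setNames(as.numeric(gene_counts), paste0("gene_", selected_genes)),
           ploidy = ploidy, altered_mb = altered_mb, alt_per_mb = alt_per_mb)
  class(out) <- "cn_features"
  out
}

#' Feature matrix for a cohort of segment calls
#'
#' @param segments cohort segment data frame with a `sample` column.
#' @param gene_model,selected_genes,gain_cutoff,loss_cutoff see
#'   [extract_cn_features()].
#' @param include_rate keep the `alt_per_mb` column (default `FALSE`: the
#'   classifier uses ploidy and altered megabases).
#' @return numeric matrix, one row per sample (rownames = sample ids).
#' @export
cn_feature_matrix <- function(segments, gene_model = synthetic_gene_model(),
                              selected_genes = NULL,
                              gain_cutoff = 2.5, loss_cutoff = 1.5,
                              include_rate = FALSE) {
  ids <- unique(segments$sample)
  rows <- lapply(ids, function(id) {
    s <- segments[segments$sample == id,
                  c("chrom", "start", "end", "copy_number"), drop = FALSE]
    unclass(extract_cn_features(s, gene_model, selected_genes,
                                gain_cutoff, loss_cutoff))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  if (!include_rate) m <- m[, colnames(m) != "alt_per_mb", drop = FALSE]
  m
}

#' Select the most recurrently altered genes in a training cohort
#'
#' Ranks genes by the number of training samples in which they carry at least
#' one copy-number alteration; ties are broken lexicographically. If fewer
#' than `k` genes are ever altered, the list is padded deterministically with
#' the lexicographically first unaltered genes of the model, with a warning.
#'
#' @param segments training cohort segment data frame (`sample` column).
#' @param gene_model gene intervals.
#' @param k number of genes to select (default 25).
#' @param gain_cutoff,loss_cutoff alteration cutoffs.
#' @return character vector of `k` gene symbols, in rank order.
#' @export
select_top_genes <- function(segments, gene_model = synthetic_gene_model(),
                             k = 25, gain_cutoff = 2.5, loss_cutoff = 1.5) {
  all_genes <- sort(unique(gene_model$gene))
  m <- cn_feature_matrix(segments, gene_model, selected_genes = all_genes,
                         gain_cutoff = gain_cutoff, loss_cutoff = loss_cutoff)
  gcols <- m[, paste0("gene_", all_genes), drop = FALSE]
  n_samples_altered <- colSums(gcols > 0)
  names(n_samples_altered) <- all_genes
  # order: descending prevalence, lexicographic within ties
  ord <- order(-n_samples_altered, names(n_samples_altered))
  ranked <- names(n_samples_altered)[ord]
  altered <- ranked[n_samples_altered[ranked] > 0]
  if (length(altered) >= k) return(ranked[seq_len(k)])
  warning(sprintf("only %d genes altered in training cohort; padding to %d",
                  length(altered), k), call. = FALSE)
  pad <- setdiff(all_genes, altered)
  c(altered, pad)[seq_len(k)]
}
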