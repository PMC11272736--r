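# Readers and writers for the pipeline's on-disk formats:
#   * one VCF v4.2 per sample (paired NORMAL/TUMOR genotype columns, gene and
#     consequence carried in INFO keys),
#   * one long-format microsatellite locus TSV per sample,
#   * cohort-level SEG-like TSV, QC TSV and clinical TSV.

VCF_INFO_KEYS <- c(gene = "GENE", consequence = "CSQCLASS",
                   protein_change = "AACHANGE")

vcf_header <- function() {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQCLASS,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=AACHANGE,Number=1,Type=String,Description=\"Protein change\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "NORMAL", "TUMOR"), collapse = "\t"))
}

write_sample_vcf <- function(variants, path) {
  lines <- vcf_header()
  if (nrow(variants) > 0) {
    v <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
    info <- sprintf("GENE=%s;CSQCLASS=%s;AACHANGE=%s",
                    v$gene, v$consequence,
                    ifelse(is.na(v$protein_change), ".", v$protein_change))
    normal <- sprintf("0/0:%d,%d:%d", v$normal_dp - v$normal_alt,
                      v$normal_alt, v$normal_dp)
    tumor <- sprintf("0/1:%d,%d:%d", v$tumor_dp - v$tumor_alt,
                     v$tumor_alt, v$tumor_dp)
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s\tGT:AD:DP\t%s\t%s",
                              v$chrom, v$pos, v$ref, v$alt, v$filter, info,
                              normal, tumor))
  }
  writeLines(lines, path)
}

#' Read somatic variants from a paired tumor/normal VCF
#'
#' Parses a VCF v4.2 with NORMAL and TUMOR genotype columns (AD/DP format
#' fields), reads the gene symbol, consequence class, and protein change from
#' configurable INFO keys, computes allele fractions from AD, and applies the
#' somatic filter. A missing normal column is an explicit error, as is a
#' malformed record (reported with its line number).
#'
#' @param path VCF file.
#' @param config a [filter_config()]; `NULL` returns all records unfiltered.
#' @param info_keys named character vector mapping `gene`, `consequence`,
#'   `protein_change` to INFO ids (defaults `GENE`, `CSQCLASS`, `AACHANGE`).
#' @param tumor_col,normal_col genotype column names.
#' @return variant data frame: `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `consequence`, `protein_change`, depths/alt counts, `filter`,
#'   `tumor_af`, `normal_af`.
#' @export
read_somatic_vcf <- function(path, config = filter_config(),
                             info_keys = VCF_INFO_KEYS,
                             tumor_col = "TUMOR", normal_col = "NORMAL") {
  raw <- readLines(path)
  body <- which(!startsWith(raw, "#"))
  nf <- lengths(regmatches(raw[body], gregexpr("\t", raw[body], fixed = TRUE)))
  if (length(body) > 0 && any(nf != nf[1]))
    stop_field("malformed VCF %s: inconsistent field count at line %d",
               path, body[which(nf != nf[1])[1]])
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), gene = character(),
                      consequence = character(), protein_change = character(),
                      tumor_dp = integer(), tumor_alt = integer(),
                      normal_dp = integer(), normal_alt = integer(),
                      filter = character(), tumor_af = numeric(),
                      normal_af = numeric(), stringsAsFactors = FALSE)
  if (length(body) == 0) {
    # still validate that the column header carries a normal column
    hdr <- raw[startsWith(raw, "#CHROM")]
    if (length(hdr) == 1 && !grepl(normal_col, hdr))
      stop_field("VCF %s lacks a %s genotype column", path, normal_col)
    return(empty)
  }
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop_field("malformed VCF %s: %s",
                                               path, conditionMessage(e)))
  gt_cols <- colnames(v@gt)
  if (!normal_col %in% gt_cols)
    stop_field("VCF %s lacks a %s genotype column", path, normal_col)
  if (!tumor_col %in% gt_cols)
    stop_field("VCF %s lacks a %s genotype column", path, tumor_col)
  fix <- vcfR::getFIX(v)
  ad <- vcfR::extract.gt(v, element = "AD")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  alt_count <- function(col) {
    as.integer(vapply(strsplit(ad[, col], ",", fixed = TRUE),
                      function(x) x[2], character(1)))
  }
  info_get <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    ifelse(is.na(x) | x == ".", NA_character_, x)
  }
  gene <- info_get(info_keys[["gene"]])
  out <- data.frame(
    chrom = unname(fix[, "CHROM"]), pos = as.integer(fix[, "POS"]),
    ref = unname(fix[, "REF"]), alt = unname(fix[, "ALT"]),
    gene = ifelse(is.na(gene), ".", gene),
    consequence = info_get(info_keys[["consequence"]]),
    protein_change = info_get(info_keys[["protein_change"]]),
    tumor_dp = as.integer(dp[, tumor_col]), tumor_alt = alt_count(tumor_col),
    normal_dp = as.integer(dp[, normal_col]), normal_alt = alt_count(normal_col),
    filter = unname(fix[, "FILTER"]), stringsAsFactors = FALSE)
  out$tumor_af <- out$tumor_alt / out$tumor_dp
  out$normal_af <- out$normal_alt / out$normal_dp
  filter_somatic(out, config)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Read a per-sample microsatellite locus table
#'
#' Long-format TSV with header `locus_id`, `repeat_length`, `normal_count`,
#' `tumor_count`.
#'
#' @param path TSV file.
#' @return locus data frame as consumed by [call_msi()].
#' @export
read_ms_loci <- function(path) {
  df <- read_tsv(path)
  need <- c("locus_id", "repeat_length", "normal_count", "tumor_count")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop_field("locus table %s lacks column(s) %s", path,
               paste(miss, collapse = ", "))
  df
}

#' Read cohort-level tables
#'
#' `read_cn_segments()` reads a SEG-like TSV (`sample`, `chrom`, `start`,
#' `end`, `copy_number`; 0-based half-open coordinates in bases);
#' `read_qc_metrics()` the per-sample QC TSV; `read_clinical()` the clinical
#' TSV (`sample`, `os_months`, `os_event`, `pfs_months`, `pfs_event`, plus
#' metadata).
#'
#' @param path TSV file.
#' @return data frame.
#' @export
read_cn_segments <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("sample", "chrom", "start", "end", "copy_number") %in%
                  names(df)))
  df
}

#' @rdname read_cn_segments
#' @export
read_qc_metrics <- function(path) read_tsv(path)

#' @rdname read_cn_segments
#' @export
read_clinical <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("sample", "os_months", "os_event", "pfs_months",
                  "pfs_event") %in% names(df)))
  df
}

#' Write a cohort bundle to a directory
#'
#' Emits `vcf/<sample>.vcf` and `ms/<sample>.tsv` per sample, plus cohort
#' `cn_segments.tsv`, `qc.tsv`, `clinical.tsv` and `truth.tsv`. The file set
#' round-trips through [read_bundle()].
#'
#' @param bundle a `cohort_bundle` from [generate_cohort()].
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  for (d in file.path(dir, c("", "vcf", "ms")))
    if (!dir.exists(d) && !dir.create(d, recursive = TRUE))
      stop_field("cannot create directory %s", d)
  ids <- bundle$truth$sample
  drop_sample <- function(df) df[, setdiff(names(df), "sample"), drop = FALSE]
  if (!is.null(bundle$variants))
    for (id in ids)
      write_sample_vcf(
        drop_sample(bundle$variants[bundle$variants$sample == id, ,
                                    drop = FALSE]),
        file.path(dir, "vcf", paste0(id, ".vcf")))
  if (!is.null(bundle$ms_loci))
    for (id in ids)
      write_tsv(drop_sample(bundle$ms_loci[bundle$ms_loci$sample == id, ,
                                           drop = FALSE]),
                file.path(dir, "ms", paste0(id, ".tsv")))
  if (!is.null(bundle$cn_segments))
    write_tsv(bundle$cn_segments, file.path(dir, "cn_segments.tsv"))
  if (!is.null(bundle$qc))
    write_tsv(bundle$qc, file.path(dir, "qc.tsv"))
  if (!is.null(bundle$clinical))
    write_tsv(bundle$clinical, file.path(dir, "clinical.tsv"))
  write_tsv(bundle$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read a cohort bundle from a directory
#'
#' Inverse of [write_bundle()]. Per-sample VCF parse failures are isolated:
#' the sample's variants are dropped with a warning (it will be reported as
#' unclassifiable downstream), other samples are unaffected.
#'
#' @param dir directory written by [write_bundle()].
#' @param config somatic filter applied to variants on read; `NULL` (default)
#'   keeps all records so the on-disk file round-trips.
#' @return a `cohort_bundle`.
#' @export
read_bundle <- function(dir, config = NULL) {
  truth <- read_tsv(file.path(dir, "truth.tsv"))
  ids <- truth$sample
  variants <- NULL
  if (dir.exists(file.path(dir, "vcf"))) {
    parts <- lapply(ids, function(id) {
      p <- file.path(dir, "vcf", paste0(id, ".vcf"))
      if (!file.exists(p)) return(NULL)
      v <- tryCatch(read_somatic_vcf(p, config = config),
                    error = function(e) {
                      warning(sprintf("sample %s: %s", id,
                                      conditionMessage(e)), call. = FALSE)
                      NULL
                    })
      if (is.null(v) || nrow(v) == 0) return(v)
      cbind(sample = id, v, stringsAsFactors = FALSE)
    })
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (length(parts) > 0) variants <- do.call(rbind, parts)
  }
  ms <- NULL
  if (dir.exists(file.path(dir, "ms"))) {
    parts <- lapply(ids, function(id) {
      p <- file.path(dir, "ms", paste0(id, ".tsv"))
      if (!file.exists(p)) return(NULL)
      cbind(sample = id, read_ms_loci(p), stringsAsFactors = FALSE)
    })
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (length(parts) > 0) ms <- do.call(rbind, parts)
  }
  read_if <- function(name, reader) {
    p <- file.path(dir, name)
    if (file.exists(p)) reader(p) else NULL
  }
  structure(list(variants = variants, ms_loci = ms,
                 cn_segments = read_if("cn_segments.tsv", read_cn_segments),
                 qc = read_if("qc.tsv", read_qc_metrics),
                 clinical = read_if("clinical.tsv", read_clinical),
                 truth = truth),
            class = "cohort_bundle")
}
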