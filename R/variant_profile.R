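# Somatic variant profile: filtering, substitution spectrum, POLE rule,
# gene-level flags.

VALID_CONSEQUENCES <- c("missense", "nonsense", "frameshift", "splice",
                        "inframe_indel", "synonymous", "other")
NONSILENT <- c("missense", "nonsense", "frameshift", "splice", "inframe_indel")

# The six pyrimidine-collapsed substitution classes.
SPECTRUM_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Default somatic filter configuration
#'
#' Paired tumor/normal post-calling filter applied to VCF records before any
#' classification: `FILTER == PASS`, tumor allele fraction at least
#' `min_tumor_af`, normal allele fraction at most `max_normal_af` (germline
#' leak guard), tumor depth at least `min_tumor_depth`. All thresholds are
#' configurable; these defaults are conventional paired-WES heuristics.
#'
#' @param min_tumor_af minimum tumor allele fraction (default 0.05).
#' @param max_normal_af maximum normal allele fraction (default 0.02).
#' @param min_tumor_depth minimum tumor read depth (default 20).
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(min_tumor_af = 0.05, max_normal_af = 0.02,
                          min_tumor_depth = 20) {
  stopifnot(min_tumor_af >= 0, min_tumor_af <= 1,
            max_normal_af >= 0, max_normal_af <= 1, min_tumor_depth >= 0)
  structure(list(min_tumor_af = min_tumor_af, max_normal_af = max_normal_af,
                 min_tumor_depth = min_tumor_depth),
            class = "filter_config")
}

#' Apply the somatic filter to a variant table
#'
#' @param variants data frame of somatic variants (see [read_somatic_vcf()]
#'   for the column contract).
#' @param config a [filter_config()]; `NULL` disables filtering.
#' @return the rows passing the filter.
#' @export
filter_somatic <- function(variants, config = filter_config()) {
  if (is.null(config)) return(variants)
  keep <- variants$filter == "PASS" &
    variants$tumor_af >= config$min_tumor_af &
    variants$normal_af <= config$max_normal_af &
    variants$tumor_dp >= config$min_tumor_depth
  variants[keep & !is.na(keep), , drop = FALSE]
}

is_snv <- function(ref, alt) {
  nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
}

# Pyrimidine-collapsed class of each SNV ("C>A", ..., "T>G"); NA for non-SNVs.
collapse_class <- function(ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- rep(NA_character_, length(ref))
  snv <- is_snv(ref, alt)
  r <- ref[snv]; a <- alt[snv]
  flip <- r %in% c("A", "G")
  r[flip] <- comp[r[flip]]
  a[flip] <- comp[a[flip]]
  out[snv] <- paste0(r, ">", a)
  out
}

#' Somatic substitution spectrum
#'
#' Counts somatic single-nucleotide substitutions and their pyrimidine-collapsed
#' class fractions. The C>A class pools C->A with its reverse-strand mirror
#' G->T, and likewise for the other five classes, the standard convention for
#' mutational spectra. Indels are ignored. POLE-ultramutated tumors show a
#' characteristic C>A-rich / C>G-poor spectrum, which is what the downstream
#' rule tests.
#'
#' @param variants variant data frame (post-filter).
#' @return object of class `substitution_spectrum` with fields `n_snv`,
#'   `ca_rate`, `cg_rate`, `class_fractions` (all six classes) and `defined`.
#'   With zero SNVs the spectrum is undefined (`defined = FALSE`, rates `NA`)
#'   and a warning is signalled; such samples cannot satisfy the POLE rule.
#' @export
substitution_spectrum <- function(variants) {
  cls <- collapse_class(variants$ref, variants$alt)
  cls <- cls[!is.na(cls)]
  n <- length(cls)
  if (n == 0L) {
    warning("spectrum undefined: no somatic SNVs", call. = FALSE)
    return(structure(list(n_snv = 0L, ca_rate = NA_real_, cg_rate = NA_real_,
                          class_fractions = setNames(rep(NA_real_, 6),
                                                     SPECTRUM_CLASSES),
                          defined = FALSE),
                     class = "substitution_spectrum"))
  }
  tab <- table(factor(cls, levels = SPECTRUM_CLASSES))
  frac <- as.numeric(tab) / n
  names(frac) <- SPECTRUM_CLASSES
  structure(list(n_snv = n, ca_rate = frac[["C>A"]], cg_rate = frac[["C>G"]],
                 class_fractions = frac, defined = TRUE),
            class = "substitution_spectrum")
}

#' @export
print.substitution_spectrum <- function(x, ...) {
  if (!x$defined) {
    cat("Substitution spectrum: undefined (no SNVs)\n")
    return(invisible(x))
  }
  cat(sprintf("Substitution spectrum: %d SNVs; C>A %.3f, C>G %.3f\n",
              x$n_snv, x$ca_rate, x$cg_rate))
  invisible(x)
}

#' POLE mutational-spectrum rule parameters
#'
#' Thresholds of the ultramutated-POLE rule: more than `min_snv` somatic SNVs,
#' a C>A fraction above `min_ca_rate`, and a C>G fraction below `max_cg_rate`.
#' All three inequalities are strict, exactly as the rule is stated.
#'
#' @param min_snv SNV-count threshold (default 500, strict `>`).
#' @param min_ca_rate C>A fraction threshold (default 0.2, strict `>`).
#' @param max_cg_rate C>G fraction threshold (default 0.03, strict `<`).
#' @return list of class `pole_rule_params`.
#' @export
pole_rule_params <- function(min_snv = 500, min_ca_rate = 0.2,
                             max_cg_rate = 0.03) {
  stopifnot(min_snv > 0, min_ca_rate > 0, max_cg_rate > 0,
            min_ca_rate > max_cg_rate)
  structure(list(min_snv = min_snv, min_ca_rate = min_ca_rate,
                 max_cg_rate = max_cg_rate),
            class = "pole_rule_params")
}

#' Call the POLE-ultramutated signature
#'
#' @param spectrum a [substitution_spectrum()].
#' @param params a [pole_rule_params()].
#' @return `TRUE` iff `n_snv > min_snv` and `ca_rate > min_ca_rate` and
#'   `cg_rate < max_cg_rate` (all strict). An undefined spectrum is never POLE.
#' @export
call_pole_signature <- function(spectrum, params = pole_rule_params()) {
  if (!inherits(spectrum, "substitution_spectrum"))
    stop_field("call_pole_signature() expects a substitution_spectrum")
  if (!isTRUE(spectrum$defined)) return(FALSE)
  spectrum$n_snv > params$min_snv &&
    spectrum$ca_rate > params$min_ca_rate &&
    spectrum$cg_rate < params$max_cg_rate
}

#' POLE exonuclease-domain pathogenicity whitelist
#'
#' Recurrent exonuclease-domain hotspot substitutions treated as pathogenic or
#' likely pathogenic, plus the residue window of the exonuclease domain:
#' any POLE missense change at a residue inside the window also qualifies.
#' This transparent, editable whitelist stands in for a curated clinical
#' knowledge base.
#'
#' @return list with `hotspots` (character vector of protein changes) and
#'   `domain_range` (two-element integer vector of residues, inclusive).
#' @export
pole_whitelist <- function() {
  list(hotspots = c("P286R", "V411L", "S297F", "A456P", "S459F"),
       domain_range = c(268L, 471L))
}

residue_number <- function(protein_change) {
  suppressWarnings(as.integer(sub("^[A-Za-z*]+([0-9]+).*$", "\\1",
                                  protein_change)))
}

#' Gene-level mutation flags
#'
#' Derives the two gene flags the surrogate-marker cascade consumes:
#' `pole_pathogenic` — any POLE variant on the pathogenicity whitelist
#' (hotspot protein change, or a missense inside the exonuclease-domain
#' residue window); `tp53_nonsilent` — any TP53 variant whose consequence is
#' missense, nonsense, frameshift, splice, or in-frame indel (synonymous
#' changes do not count).
#'
#' @param variants variant data frame (post-filter) with `gene`, `consequence`
#'   and `protein_change` columns.
#' @param whitelist POLE whitelist, see [pole_whitelist()].
#' @return named list `pole_pathogenic`, `tp53_nonsilent` (logicals).
#' @export
gene_flags <- function(variants, whitelist = pole_whitelist()) {
  if (nrow(variants) == 0L)
    return(list(pole_pathogenic = FALSE, tp53_nonsilent = FALSE))
  pole <- variants[variants$gene %in% "POLE", , drop = FALSE]
  pole_path <- FALSE
  if (nrow(pole) > 0L) {
    pc <- pole$protein_change
    hot <- !is.na(pc) & pc %in% whitelist$hotspots
    res <- residue_number(pc)
    dom <- pole$consequence == "missense" & !is.na(res) &
      res >= whitelist$domain_range[1] & res <= whitelist$domain_range[2]
    pole_path <- any(hot | dom)
  }
  tp53 <- variants[variants$gene %in% "TP53", , drop = FALSE]
  list(pole_pathogenic = pole_path,
       tp53_nonsilent = any(tp53$consequence %in% NONSILENT))
}
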