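# Genotype- and site-level quality filters: allelic balance, genotype
# quality, heterozygous VAF window, minimum alternate read support (SNV vs
# indel) and site missingness. "Allelic balance > 0.2" and the het VAF 20-80%
# window are distinct rules: AB is strict > on all non-ref calls, the window
# is inclusive and applies to hets only.

#' Quality-control thresholds
#'
#' @param ab_min Minimum allelic balance, strict (alt fraction must exceed
#'   this on every non-ref call). Default 0.2.
#' @param gq_min Minimum Phred genotype quality, strict. Default 20.
#' @param het_vaf_lo,het_vaf_hi Inclusive VAF window for heterozygous calls.
#'   Defaults 0.20 and 0.80.
#' @param min_alt_snv Minimum alt reads supporting an SNV. Default 10.
#' @param min_alt_indel Minimum alt reads supporting an indel. Default 7.
#' @param max_missing Maximum tolerated fraction of missing genotypes at a
#'   site, strict (a site at exactly this fraction fails). Default 0.25.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(ab_min = 0.2, gq_min = 20,
                          het_vaf_lo = 0.2, het_vaf_hi = 0.8,
                          min_alt_snv = 10, min_alt_indel = 7,
                          max_missing = 0.25) {
  stopifnot(ab_min >= 0, ab_min <= het_vaf_lo, het_vaf_lo <= het_vaf_hi,
            het_vaf_hi <= 1, min_alt_snv >= 0, min_alt_indel >= 0,
            max_missing >= 0, max_missing <= 1)
  structure(list(ab_min = ab_min, gq_min = gq_min,
                 het_vaf_lo = het_vaf_lo, het_vaf_hi = het_vaf_hi,
                 min_alt_snv = min_alt_snv, min_alt_indel = min_alt_indel,
                 max_missing = max_missing),
            class = "qc_thresholds")
}

#' Classify a variant key as SNV or indel
#'
#' SNV iff both alleles are single bases; anything else (including MNVs) is
#' grouped with indels, which carry the lower alt-read requirement.
#'
#' @param ref,alt Allele strings (vectorised).
#' @return Character vector of `"snv"` / `"indel"`.
#' @export
variant_type_of <- function(ref, alt) {
  stopifnot(all(nzchar(ref)), all(nzchar(alt)))
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "snv", "indel")
}

# Vectorised rule evaluation for non-ref genotype calls. Returns a list of
# character vectors of failed rule ids (empty = pass).
.qc_failed_rules <- function(gt_class, ref_reads, alt_reads, gq, vtype, thr) {
  n <- length(gt_class)
  tot <- ref_reads + alt_reads
  vaf <- ifelse(tot > 0, alt_reads / tot, NA_real_)
  min_alt <- ifelse(vtype == "snv", thr$min_alt_snv, thr$min_alt_indel)
  fail <- list(
    no_coverage = !is.na(tot) & tot == 0,
    allelic_balance = !is.na(vaf) & vaf <= thr$ab_min,
    genotype_quality = !is.na(gq) & gq <= thr$gq_min,
    het_vaf_window = gt_class == "het" & !is.na(vaf) &
      (vaf < thr$het_vaf_lo | vaf > thr$het_vaf_hi),
    min_alt_reads = !is.na(alt_reads) & alt_reads < min_alt
  )
  lapply(seq_len(n), function(i) {
    names(fail)[vapply(fail, `[`, logical(1), i)]
  })
}

#' Genotype-level QC outcome for one call
#'
#' @param call A one-row tibble or named list with `gt_class` (`"het"` or
#'   `"hom_alt"`), `ref_reads`, `alt_reads`, `gq`.
#' @param vtype `"snv"` or `"indel"` (see [variant_type_of()]).
#' @param thresholds A [qc_thresholds()] object.
#' @return A list with `passed` (logical) and `failed_rules` (character
#'   vector of rule ids; empty iff passed). Rule ids: `no_coverage`,
#'   `allelic_balance`, `genotype_quality`, `het_vaf_window`,
#'   `min_alt_reads`.
#' @export
passes_genotype_qc <- function(call, vtype, thresholds = qc_thresholds()) {
  stopifnot(call$gt_class %in% c("het", "hom_alt"))
  fr <- .qc_failed_rules(call$gt_class, call$ref_reads, call$alt_reads,
                         call$gq, vtype, thresholds)[[1]]
  list(passed = length(fr) == 0L, failed_rules = fr)
}

#' Fraction of missing genotypes at a site
#'
#' @param gt_class Character vector of genotype classes for all samples at
#'   one site.
#' @return Fraction in \[0, 1\].
#' @export
site_missingness <- function(gt_class) {
  stopifnot(length(gt_class) > 0)
  mean(gt_class == "missing")
}

#' Apply genotype- and site-level QC to joined variants
#'
#' Carriers failing any genotype rule are removed from carrier lists; sites
#' whose missingness reaches `max_missing` are removed entirely. A per-rule
#' removal log is returned (a call can fail several rules, so rule counts may
#' sum to more than the total removed).
#'
#' @param variants Tibble from [join_annotations()].
#' @param thresholds A [qc_thresholds()] object.
#' @return A list with `variants` (retained sites, filtered `carriers`) and
#'   `log` (tibble of `rule`, `n_failed`).
#' @export
apply_qc <- function(variants, thresholds = qc_thresholds()) {
  rules <- c("missingness", "no_coverage", "allelic_balance",
             "genotype_quality", "het_vaf_window", "min_alt_reads")
  counts <- stats::setNames(integer(length(rules)), rules)

  miss_frac <- lengths(variants$missing_samples) / variants$n_samples
  drop_site <- miss_frac >= thresholds$max_missing
  counts["missingness"] <- sum(drop_site)
  kept <- variants[!drop_site, , drop = FALSE]

  if (nrow(kept)) {
    vtype <- variant_type_of(kept$ref, kept$alt)
    kept$carriers <- lapply(seq_len(nrow(kept)), function(i) {
      cr <- kept$carriers[[i]]
      if (nrow(cr) == 0) return(cr)
      fr <- .qc_failed_rules(cr$gt_class, cr$ref_reads, cr$alt_reads, cr$gq,
                             vtype[i], thresholds)
      failed <- lengths(fr) > 0L
      if (any(failed)) {
        for (r in unlist(fr[failed])) counts[r] <<- counts[r] + 1L
      }
      cr[!failed, , drop = FALSE]
    })
  }
  list(variants = kept,
       log = tibble::tibble(rule = rules, n_failed = unname(counts)))
}
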