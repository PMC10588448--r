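# Gene x cohort-subset x rarity-tier-group collapsing and exact testing.
# Qualifying alleles are summed per cell (1 per het carrier, 2 per hom-alt),
# compared against control allele counts from the frequency table, and
# adjusted within per-gene families.

#' Rarity-tier groups used for burden testing
#'
#' Two groupings are tested per gene and subset: ultra-rare plus novel
#' (control AF < 0.005% or 0), and everything under 0.1%.
#'
#' @return Named list mapping group id to member tiers.
#' @export
tier_groups <- function() {
  list(
    ULTRA_RARE_PLUS_NOVEL = c("NOVEL", "ULTRA_RARE"),
    RARE_UNDER_0_1 = c("NOVEL", "ULTRA_RARE", "VERY_RARE", "RARE")
  )
}

#' Read a cohort-subset membership table
#'
#' TSV with a `sample_id` column plus one 0/1 column per subset. Subsets may
#' overlap; the special subset `PanCancer` (all samples) is prepended when
#' not already present.
#'
#' @param path Path to the TSV.
#' @param add_pancancer Prepend a PanCancer subset covering every listed
#'   sample. Default TRUE.
#' @return Named list of character vectors of sample ids.
#' @export
read_subsets <- function(path, add_pancancer = TRUE) {
  if (!file.exists(path)) stop("subset table not found: ", path, call. = FALSE)
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(x)) {
    stop("subset table must have a sample_id column", call. = FALSE)
  }
  cols <- setdiff(names(x), "sample_id")
  subsets <- lapply(cols, function(cl) x$sample_id[x[[cl]] == 1])
  names(subsets) <- cols
  if (add_pancancer && !"PanCancer" %in% cols) {
    subsets <- c(list(PanCancer = x$sample_id), subsets)
  }
  subsets
}

# Called allele number of one site within a subset: two alleles per subset
# sample with a non-missing genotype.
.site_an <- function(missing_samples, subset_ids) {
  2L * (length(subset_ids) - sum(missing_samples %in% subset_ids))
}

.case_total_policy <- function(site_ans, subset_ids, an_policy) {
  if (length(site_ans) == 0) return(2L * length(subset_ids))
  switch(an_policy,
    site_mean = as.integer(round(mean(site_ans))),
    site_median = as.integer(round(stats::median(site_ans))),
    two_n = 2L * length(subset_ids),
    stop("unknown an_policy: ", an_policy, call. = FALSE)
  )
}

#' Collapse qualifying case alleles for one gene, subset and tier group
#'
#' Case alt alleles sum 1 per heterozygous and 2 per homozygous-alt carrier
#' in the subset across qualifying (candidate, tier-in-group) variants. The
#' case total-allele denominator follows `an_policy`: the rounded mean (or
#' median) called allele number across all the gene's QC-passing sites in the
#' subset, or a flat `2N`.
#'
#' @param variants Classified variant tibble (after QC), all sites retained
#'   for the gene -- qualifying and not -- so the denominator reflects the
#'   gene's calling footprint.
#' @param gene Gene symbol.
#' @param subset_ids Character vector of subset sample ids.
#' @param tier_group One of `names(tier_groups())`.
#' @param an_policy `"site_mean"` (default), `"site_median"` or `"two_n"`.
#' @return Named integer vector `c(case_alt, case_total)`.
#' @export
case_allele_counts <- function(variants, gene, subset_ids,
                               tier_group = "ULTRA_RARE_PLUS_NOVEL",
                               an_policy = "site_mean") {
  members <- tier_groups()[[tier_group]]
  if (is.null(members)) stop("unknown tier group: ", tier_group, call. = FALSE)
  g <- variants[variants$gene == gene, , drop = FALSE]
  qual <- g[g$candidate & g$tier %in% members, , drop = FALSE]
  case_alt <- 0L
  if (nrow(qual)) {
    case_alt <- sum(vapply(qual$carriers, function(cr) {
      cr <- cr[cr$sample_id %in% subset_ids, , drop = FALSE]
      sum(ifelse(cr$gt_class == "hom_alt", 2L, 1L))
    }, numeric(1)))
  }
  site_ans <- vapply(g$missing_samples, .site_an, integer(1),
                     subset_ids = subset_ids)
  case_total <- .case_total_policy(site_ans, subset_ids, an_policy)
  if (case_alt > case_total) {
    stop("internal consistency error: case_alt (", case_alt,
         ") exceeds case_total (", case_total, ") for ", gene, call. = FALSE)
  }
  c(case_alt = as.integer(case_alt), case_total = case_total)
}

#' Classify control records through the case filtering workflow
#'
#' Joins the control frequency table with the annotation table and applies
#' the same consequence/CADD/AF candidate filters and rarity tiering as the
#' case side, so control allele counts aggregate over the gene's full
#' qualifying footprint, not only variants seen in cases.
#'
#' @param controls Tibble from [read_control_table()].
#' @param annotations Tibble from [read_annotation_table()].
#' @param boundaries A [tier_boundaries()] object.
#' @param cadd_min Strict CADD threshold for missense candidates.
#' @return Control tibble with `gene`, `tier` and `candidate` columns;
#'   unannotated control records are dropped.
#' @export
prepare_controls <- function(controls, annotations,
                             boundaries = tier_boundaries(), cadd_min = 15) {
  x <- dplyr::inner_join(controls, annotations, by = .key_cols)
  x$tier <- classify_rarity(x$af, boundaries)
  x$candidate <- is_candidate(x$consequence, x$af, x$cadd_phred,
                              boundaries, cadd_min)
  x
}

#' Collapse qualifying control alleles for one gene and tier group
#'
#' Control alt alleles sum AC over all qualifying control records; the
#' control total is the representative allele number of the gene's
#' qualifying records under `an_policy` (mean or median AN; falls back to
#' all the gene's records when none qualify).
#'
#' @param controls Classified control tibble from [prepare_controls()].
#' @param gene Gene symbol.
#' @param tier_group One of `names(tier_groups())`.
#' @param an_policy `"site_mean"` (default) or `"site_median"`.
#' @return Named integer vector `c(control_alt, control_total)`.
#' @export
control_allele_counts <- function(controls, gene,
                                  tier_group = "ULTRA_RARE_PLUS_NOVEL",
                                  an_policy = "site_mean") {
  members <- tier_groups()[[tier_group]]
  if (is.null(members)) stop("unknown tier group: ", tier_group, call. = FALSE)
  g <- controls[controls$gene == gene, , drop = FALSE]
  if (nrow(g) == 0) {
    stop("empty control footprint for gene ", gene, call. = FALSE)
  }
  qual <- g[g$candidate & g$tier %in% members, , drop = FALSE]
  control_alt <- sum(qual$ac)
  an_pool <- if (nrow(qual)) qual$an else g$an
  control_total <- switch(an_policy,
    site_mean = , two_n = as.integer(round(mean(an_pool))),
    site_median = as.integer(round(stats::median(an_pool))),
    stop("unknown an_policy: ", an_policy, call. = FALSE)
  )
  c(control_alt = as.integer(control_alt), control_total = control_total)
}

.burden_2x2 <- function(case_alt, case_total, control_alt, control_total,
                        convention) {
  if (convention == "alt_vs_total") {
    list(a = case_alt, b = case_total, c = control_alt, d = control_total)
  } else {
    list(a = case_alt, b = case_total - case_alt,
         c = control_alt, d = control_total - control_alt)
  }
}

#' Run the gene-collapsing burden analysis
#'
#' One exact test per gene x subset x tier group, with per-gene
#' multiple-testing adjustment across the subset-by-tier-group family.
#'
#' The default 2x2 convention, `alt_vs_total`, places the full allele-number
#' denominator (not the non-alt remainder) in the second column -- the
#' construction the published burden statistics use; `alt_vs_ref` gives the
#' textbook alt/non-alt table. With alt counts orders of magnitude below the
#' denominators the two differ only in distant decimals.
#'
#' @param variants Classified case variant tibble (QC-filtered).
#' @param controls Classified control tibble from [prepare_controls()].
#' @param subsets Named list of sample-id vectors (see [read_subsets()]).
#' @param genes Genes to test; defaults to all genes present on either side.
#' @param adjust `"bh"` (default) or `"bonferroni"`.
#' @param family_size Family size for adjustment within each gene; defaults
#'   to `length(subsets) * length(tier_groups())`.
#' @param an_policy Allele-number policy, see [case_allele_counts()].
#' @param convention `"alt_vs_total"` (default) or `"alt_vs_ref"`.
#' @return A tibble with one row per gene x subset x tier group, in
#'   deterministic gene/subset/tier order: counts, case/control AFs, exact
#'   test results and family-adjusted p-values (`fdr_greater`,
#'   `fdr_two_sided`).
#' @export
run_burden <- function(variants, controls, subsets, genes = NULL,
                       adjust = c("bh", "bonferroni"), family_size = NULL,
                       an_policy = "site_mean",
                       convention = c("alt_vs_total", "alt_vs_ref")) {
  adjust <- match.arg(adjust)
  convention <- match.arg(convention)
  if (is.null(genes)) {
    genes <- sort(unique(c(variants$gene, controls$gene)))
  }
  groups <- names(tier_groups())
  m_total <- if (is.null(family_size)) length(subsets) * length(groups) else family_size

  grid <- expand.grid(tier_group = groups, subset = names(subsets),
                      gene = genes, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$gene, genes), match(grid$subset, names(subsets)),
                     match(grid$tier_group, groups)), , drop = FALSE]

  rows <- lapply(seq_len(nrow(grid)), function(i) {
    gene <- grid$gene[i]; sname <- grid$subset[i]; tg <- grid$tier_group[i]
    cc <- case_allele_counts(variants, gene, subsets[[sname]], tg, an_policy)
    kk <- control_allele_counts(controls, gene, tg, an_policy)
    t2 <- .burden_2x2(cc[["case_alt"]], cc[["case_total"]],
                      kk[["control_alt"]], kk[["control_total"]], convention)
    res <- exact_table_test(t2$a, t2$b, t2$c, t2$d)
    tibble::tibble(
      gene = gene, subset = sname, tier_group = tg,
      case_alt = cc[["case_alt"]], case_total = cc[["case_total"]],
      control_alt = kk[["control_alt"]], control_total = kk[["control_total"]],
      case_af = cc[["case_alt"]] / cc[["case_total"]],
      control_af = kk[["control_alt"]] / kk[["control_total"]],
      res
    )
  })
  out <- dplyr::bind_rows(rows)

  adj_fun <- if (adjust == "bh") bh_adjust else bonferroni_adjust
  out <- dplyr::group_by(out, .data$gene)
  out <- dplyr::mutate(
    out,
    fdr_greater = adj_fun(.data$p_greater, m_total),
    fdr_two_sided = adj_fun(.data$p_two_sided, m_total)
  )
  dplyr::ungroup(out)
}

.fmt_p <- function(p) {
  s <- sprintf("%.9f", p)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

.group_label <- c(ULTRA_RARE_PLUS_NOVEL = "UltraRare", RARE_UNDER_0_1 = "Rare")

#' Format burden results as a publication-style TSV
#'
#' Columns: Gene, Subset (subset and tier-group tag fused, e.g.
#' `PanCancer_UltraRare`), case/control AF at 4 decimals, the four allele
#' counts, one-sided p, conditional-MLE OR (4 decimals), family-adjusted
#' one-sided p, two-sided p, family-adjusted two-sided p, and the sample OR.
#' P-values are printed at 9 decimal places with trailing zeros trimmed.
#'
#' @param results Tibble from [run_burden()].
#' @param path Optional output path; when given the TSV is written there.
#' @return A character-matrix tibble of the formatted table (invisibly when
#'   `path` is given).
#' @export
format_results_table <- function(results, path = NULL) {
  stopifnot(nrow(results) > 0)
  out <- tibble::tibble(
    Gene = results$gene,
    Subset = paste0(results$subset, "_",
                    .group_label[results$tier_group]),
    Cancer_AF = sprintf("%.4f", results$case_af),
    Control_AF = sprintf("%.4f", results$control_af),
    Cancer_Alt_Count = results$case_alt,
    Cancer_Total_Count = results$case_total,
    Control_Alt_Count = results$control_alt,
    Control_Total_Count = results$control_total,
    p_greater = .fmt_p(results$p_greater),
    OR_cmle = sprintf("%.4f", results$or_cmle),
    FDR_greater = .fmt_p(results$fdr_greater),
    p_twosided = .fmt_p(results$p_two_sided),
    FDR_twosided = .fmt_p(results$fdr_two_sided),
    OR_sample = sprintf("%.4f", results$or_sample)
  )
  if (!is.null(path)) {
    readr::write_tsv(out, path, progress = FALSE)
    return(invisible(out))
  }
  out
}
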