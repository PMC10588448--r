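# Synthetic case cohorts with read-level genotype fields plus matched
# population control tables, with known per-gene enrichment. The generator
# emulates the structure of a germline exome burden study: per-site control
# allele frequencies drawn from a rare-variant spectrum, heterozygous case
# carriers at rate 2*AF*lambda, Poisson depth with binomial allele sampling,
# and optional injected QC failures and missing genotypes.

#' Simulation configuration for a synthetic burden cohort
#'
#' Defaults describe the study conditions used throughout the calibration
#' checks: 500 diploid cases, a control panel of 20,000 alleles (a 20:1
#' control:case allele ratio, matching the scale relation of a large public
#' control panel to an exome cohort), six genes of 20 coding sites each, and
#' a rare-variant AF spectrum concentrated below 0.05% with a thin tail to
#' 0.04%.
#'
#' @param n_cases Number of diploid case samples.
#' @param control_an Control allele number (constant across sites by
#'   default, so allele-number policies are isolated from control noise).
#' @param genes Tibble with columns `gene` and `n_sites`.
#' @param af_spectrum Tibble with columns `af` and `weight` (weights sum
#'   to 1): the population AF spectrum sites are drawn from.
#' @param enrichment Named numeric vector gene -> lambda, the case AF
#'   multiplier (1 = null). Genes not named default to 1.
#' @param depth_mean Mean sequencing depth for carrier read draws.
#' @param missing_rate Per-genotype missing probability (applied to
#'   non-carrier genotypes so the carrier truth list stays exact).
#' @param qc_noise Fraction of carriers injected with a failing genotype
#'   (low GQ or out-of-window VAF).
#' @param control_sampling `"expected"` (default) sets control AC to
#'   round(AF * AN), so a site's rarity tier is a deterministic function of
#'   its spectrum draw; `"binomial"` samples AC ~ Binomial(AN, af), which is
#'   population-realistic but makes the novel tier a selection on control
#'   sampling noise and thereby anti-conservative for novel-tier burden.
#' @param seed Integer seed; the cohort is fully deterministic given it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_cases = 500,
                              control_an = 20000,
                              genes = tibble::tibble(
                                gene = paste0("G", 1:6), n_sites = 20L),
                              af_spectrum = tibble::tibble(
                                af = c(1e-5, 3e-5, 1e-4, 4e-4),
                                weight = c(0.30, 0.30, 0.25, 0.15)),
                              enrichment = NULL,
                              depth_mean = 40,
                              missing_rate = 0.01,
                              qc_noise = 0,
                              control_sampling = c("expected", "binomial"),
                              seed = 1L) {
  control_sampling <- match.arg(control_sampling)
  stopifnot(n_cases >= 1, control_an >= 1, depth_mean > 0,
            missing_rate >= 0, missing_rate <= 1,
            qc_noise >= 0, qc_noise <= 1,
            all(af_spectrum$af >= 0), all(af_spectrum$weight >= 0))
  if (abs(sum(af_spectrum$weight) - 1) > 1e-8) {
    stop("af_spectrum weights must sum to 1", call. = FALSE)
  }
  lambda <- stats::setNames(rep(1, nrow(genes)), genes$gene)
  if (!is.null(enrichment)) {
    if (any(enrichment < 0)) stop("enrichment lambdas must be >= 0", call. = FALSE)
    unknown <- setdiff(names(enrichment), genes$gene)
    if (length(unknown)) stop("enrichment names not in gene list: ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    lambda[names(enrichment)] <- enrichment
  }
  structure(list(n_cases = as.integer(n_cases),
                 control_an = as.integer(control_an),
                 genes = genes, af_spectrum = af_spectrum,
                 enrichment = lambda, depth_mean = depth_mean,
                 missing_rate = missing_rate, qc_noise = qc_noise,
                 control_sampling = control_sampling,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Splitmix-style per-replicate seed derivation: documented, portable, and
# kept below 2^31 so the result is always a valid 32-bit seed.
.derive_seed <- function(master_seed, index) {
  m <- as.integer(master_seed %% 2^31)
  s <- as.integer((index * 2654435769) %% 2^31)
  bitwXor(m, s)
}

# Read draw for a clean heterozygous carrier, clamped into the default
# QC-passing region: depth >= 20, alt reads >= 10, alt fraction in (0.2, 0.8].
.clean_reads <- function(n, depth_mean) {
  d <- pmax(stats::rpois(n, depth_mean), 20L)
  x <- stats::rbinom(n, d, 0.5)
  lo <- pmax(10L, floor(0.2 * d) + 1L)
  hi <- floor(0.8 * d)
  x <- pmin(pmax(x, lo), hi)
  list(depth = d, alt = x)
}

#' Simulate a case cohort with matched controls and known truth
#'
#' Per site: a control AF is drawn from the spectrum; control AC is sampled
#' (or rounded) against the control AN; each case sample is an independent
#' heterozygous carrier with probability `2 * af * lambda_gene` (capped
#' checked, error if above 1). Clean carriers get read support guaranteed to
#' pass default QC; a `qc_noise` fraction get a failing GQ (<= 20) or a VAF
#' pushed below the allelic-balance floor. Sites with a sampled control AC
#' of 0 are absent from the control table, so they classify as novel
#' downstream; the recorded truth tier is derived from the realized table.
#'
#' @param config A [simulation_config()] object.
#' @return An object of class `simulated_cohort`: a list with `variants`
#'   (joined-variant-shaped tibble with `carriers`/`missing_samples`),
#'   `control` (CHROM POS REF ALT AC AN AF tibble of sites with AC > 0),
#'   `annotation` (missense, CADD 25 annotation rows for every site),
#'   `truth` (per-site realized tier, lambda, carrier and noisy-carrier
#'   lists), `sample_ids` and the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  sample_ids <- sprintf("S%04d", seq_len(config$n_cases))

  sites <- dplyr::bind_rows(lapply(seq_len(nrow(config$genes)), function(gi) {
    g <- config$genes$gene[gi]
    ns <- config$genes$n_sites[gi]
    tibble::tibble(
      chrom = as.character(gi),
      pos = 1000L + 10L * seq_len(ns),
      ref = "A", alt = "G", gene = g,
      af_nominal = sample(config$af_spectrum$af, ns, replace = TRUE,
                          prob = config$af_spectrum$weight),
      lambda = unname(config$enrichment[g])
    )
  }))

  p_carrier <- 2 * sites$af_nominal * sites$lambda
  too_high <- which(p_carrier > 1)
  if (length(too_high)) {
    stop("impossible config: 2*AF*lambda > 1 at ", sites$gene[too_high[1]],
         " ", sites$chrom[too_high[1]], ":", sites$pos[too_high[1]],
         call. = FALSE)
  }

  sites$control_ac <- if (config$control_sampling == "binomial") {
    stats::rbinom(nrow(sites), config$control_an, sites$af_nominal)
  } else {
    as.integer(round(sites$af_nominal * config$control_an))
  }
  sites$control_an <- config$control_an

  carriers <- vector("list", nrow(sites))
  missing <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    is_carrier <- stats::runif(config$n_cases) < p_carrier[i]
    ids <- sample_ids[is_carrier]
    nc <- length(ids)
    if (nc) {
      rd <- .clean_reads(nc, config$depth_mean)
      gq <- rep(99L, nc)
      noisy <- stats::runif(nc) < config$qc_noise
      if (any(noisy)) {
        mode_gq <- noisy & stats::runif(nc) < 0.5
        mode_vaf <- noisy & !mode_gq
        gq[mode_gq] <- sample(0:20, sum(mode_gq), replace = TRUE)
        rd$alt[mode_vaf] <- pmax(1L, as.integer(round(0.12 * rd$depth[mode_vaf])))
      }
      carriers[[i]] <- tibble::tibble(
        sample_id = ids, gt_class = "het",
        ref_reads = rd$depth - rd$alt, alt_reads = rd$alt,
        gq = gq, noisy = noisy
      )
    } else {
      carriers[[i]] <- tibble::tibble(
        sample_id = character(0), gt_class = character(0),
        ref_reads = integer(0), alt_reads = integer(0),
        gq = integer(0), noisy = logical(0)
      )
    }
    non_carriers <- setdiff(sample_ids, ids)
    missing[[i]] <- non_carriers[
      stats::runif(length(non_carriers)) < config$missing_rate]
  }

  af_realized <- sites$control_ac / sites$control_an
  carrier_ids <- lapply(carriers, function(cr) cr$sample_id)
  noisy_ids <- lapply(carriers, function(cr) cr$sample_id[cr$noisy])
  truth <- tibble::tibble(
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alt,
    gene = sites$gene, lambda = sites$lambda,
    af_nominal = sites$af_nominal,
    control_ac = sites$control_ac,
    tier = classify_rarity(af_realized),
    carriers = carrier_ids,
    noisy_carriers = noisy_ids
  )

  variants <- tibble::tibble(
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alt,
    gene = sites$gene,
    consequence = "missense", hgvs_p = NA_character_,
    cadd_phred = 25, revel = NA_real_, acmg = NA_character_,
    ddg = NA_real_, domain = NA_character_,
    novel = sites$control_ac == 0L,
    control_ac = ifelse(sites$control_ac == 0L, 0L, sites$control_ac),
    control_an = ifelse(sites$control_ac == 0L, NA_integer_, sites$control_an),
    control_af = ifelse(sites$control_ac == 0L, 0, af_realized),
    n_samples = config$n_cases,
    carriers = lapply(carriers, function(cr) cr[names(cr) != "noisy"]),
    missing_samples = missing
  )

  keep <- sites$control_ac > 0L
  control <- tibble::tibble(
    CHROM = sites$chrom[keep], POS = sites$pos[keep],
    REF = sites$ref[keep], ALT = sites$alt[keep],
    AC = sites$control_ac[keep], AN = sites$control_an[keep],
    AF = af_realized[keep]
  )

  annotation <- tibble::tibble(
    CHROM = sites$chrom, POS = sites$pos, REF = sites$ref, ALT = sites$alt,
    GENE = sites$gene, CONSEQUENCE = "missense", HGVSP = NA_character_,
    CADD_PHRED = 25, REVEL = NA_real_, ACMG = NA_character_,
    DDG = NA_real_, DOMAIN = NA_character_
  )

  structure(list(variants = variants, control = control,
                 annotation = annotation, truth = truth,
                 sample_ids = sample_ids, config = config),
            class = "simulated_cohort")
}

#' Write a simulated cohort to standard file formats
#'
#' Emits the case VCF (GT:AD:GQ genotypes), the control frequency TSV, the
#' annotation TSV, a one-subset (PanCancer) membership TSV, and a truth JSON.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    case_vcf = file.path(dir, "cases.vcf"),
    control_tsv = file.path(dir, "controls.tsv"),
    annotation_tsv = file.path(dir, "annotations.tsv"),
    subset_tsv = file.path(dir, "subsets.tsv"),
    truth_json = file.path(dir, "truth.json")
  )

  v <- cohort$variants
  ids <- cohort$sample_ids
  depth_bg <- as.integer(round(cohort$config$depth_mean))
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(v)), function(i) {
    cr <- v$carriers[[i]]
    fields <- rep(sprintf("0/0:%d,0:99", depth_bg), length(ids))
    names(fields) <- ids
    fields[v$missing_samples[[i]]] <- "./.:.:."
    if (nrow(cr)) {
      gt <- ifelse(cr$gt_class == "hom_alt", "1/1", "0/1")
      fields[cr$sample_id] <- sprintf("%s:%d,%d:%d", gt, cr$ref_reads,
                                      cr$alt_reads, cr$gq)
    }
    paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".", "PASS", ".",
            "GT:AD:GQ", fields), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), paths$case_vcf)

  readr::write_tsv(cohort$control, paths$control_tsv, progress = FALSE)
  readr::write_tsv(cohort$annotation, paths$annotation_tsv, progress = FALSE)
  readr::write_tsv(tibble::tibble(sample_id = ids, PanCancer = 1L),
                   paths$subset_tsv, progress = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(seed = cohort$config$seed,
         enrichment = as.list(cohort$config$enrichment),
         sites = truth),
    paths$truth_json, auto_unbox = TRUE, digits = NA
  )
  paths
}

#' Classify and collapse a simulated cohort in memory
#'
#' Runs the QC, classification and burden stages directly on an in-memory
#' cohort (no file round trip): the replicate engine for calibration runs.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param thresholds A [qc_thresholds()] object.
#' @param boundaries A [tier_boundaries()] object.
#' @param ... Passed to [run_burden()].
#' @return The [run_burden()] result tibble.
#' @export
burden_from_cohort <- function(cohort, thresholds = qc_thresholds(),
                               boundaries = tier_boundaries(), ...) {
  qc <- apply_qc(cohort$variants, thresholds)
  cls <- classify_variants(qc$variants, boundaries)
  ctl <- prepare_controls(
    dplyr::rename(cohort$control, chrom = "CHROM", pos = "POS",
                  ref = "REF", alt = "ALT", ac = "AC", an = "AN", af = "AF"),
    dplyr::rename(cohort$annotation, chrom = "CHROM", pos = "POS",
                  ref = "REF", alt = "ALT", gene = "GENE")[
      , c("chrom", "pos", "ref", "alt", "gene")] |>
      dplyr::mutate(consequence = "missense", cadd_phred = 25),
    boundaries
  )
  run_burden(cls, ctl, subsets = list(PanCancer = cohort$sample_ids),
             genes = cohort$config$genes$gene, ...)
}

#' Type-I error / power calibration of the full pipeline
#'
#' Simulates `n_reps` cohorts on seeds derived from the master seed by a
#' splitmix-style scrambler, runs QC, classification and burden testing on
#' each, and summarises per gene: the fraction of replicates whose smallest
#' family-adjusted one-sided p falls below `alpha` (type-I rate under a null
#' lambda, power under enrichment) and the mean conditional-MLE odds ratio
#' of the <0.1% tier group (over finite estimates).
#'
#' @param config A [simulation_config()]; its `seed` is the master seed.
#' @param n_reps Number of replicates.
#' @param alpha Significance level on the family-adjusted p. Default 0.05.
#' @return A list with `per_gene` (tibble: gene, reject_rate, mean_or_rare,
#'   n_reps) and `reps` (per-replicate tibble of min adjusted p and rare-group
#'   OR per gene).
#' @export
evaluate_calibration <- function(config, n_reps, alpha = 0.05) {
  stopifnot(n_reps >= 1)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- .derive_seed(config$seed, r)
    cohort <- simulate_cohort(cfg)
    res <- burden_from_cohort(cohort)
    per_gene <- dplyr::summarise(
      dplyr::group_by(res, .data$gene),
      min_fdr_greater = min(.data$fdr_greater),
      or_rare = .data$or_cmle[.data$tier_group == "RARE_UNDER_0_1"][1],
      .groups = "drop"
    )
    per_gene$rep <- r
    reps[[r]] <- per_gene
  }
  reps <- dplyr::bind_rows(reps)
  per_gene <- dplyr::summarise(
    dplyr::group_by(reps, .data$gene),
    reject_rate = mean(.data$min_fdr_greater < alpha),
    mean_or_rare = mean(.data$or_rare[is.finite(.data$or_rare)]),
    n_reps = dplyr::n(),
    .groups = "drop"
  )
  list(per_gene = per_gene, reps = reps)
}
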