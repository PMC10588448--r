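# hand-built classified variant rows for collapsing checks
mk_variants <- function(gene, tiers, carrier_sets, gt_class = "het",
                        candidate = TRUE, missing_sets = NULL, n_samples = 10) {
  n <- length(tiers)
  if (is.null(missing_sets)) missing_sets <- replicate(n, character(0), FALSE)
  tibble::tibble(
    chrom = "1", pos = 100L + seq_len(n), ref = "A", alt = "G",
    gene = gene, tier = tiers, candidate = candidate,
    carriers = lapply(carrier_sets, function(ids) {
      tibble::tibble(sample_id = ids,
                     gt_class = rep(gt_class, length.out = length(ids)),
                     ref_reads = 15L, alt_reads = 15L, gq = 99L)
    }),
    missing_samples = missing_sets,
    n_samples = n_samples
  )
}

samples10 <- sprintf("S%02d", 1:10)

test_that("case allele counts follow carrier genotypes and the AN policy", {
  v <- mk_variants("GA", c("NOVEL", "ULTRA_RARE"),
                   list(c("S01", "S02"), character(0)))
  # 2 het carriers among 10 samples at full call rate -> (2, 20)
  cc <- case_allele_counts(v, "GA", samples10, "ULTRA_RARE_PLUS_NOVEL")
  expect_equal(unname(cc), c(2L, 20L))
  # a hom-alt carrier contributes two alleles
  v2 <- mk_variants("GA", "NOVEL", list("S01"), gt_class = "hom_alt")
  expect_equal(case_allele_counts(v2, "GA", samples10,
                                  "ULTRA_RARE_PLUS_NOVEL")[["case_alt"]], 2L)
  # no qualifying variants: zero numerator over the call-rate denominator
  cc0 <- case_allele_counts(v, "GA", samples10, "RARE_UNDER_0_1",
                            an_policy = "two_n")
  expect_equal(cc0[["case_total"]], 20L)
  # missing genotypes shrink the site-mean denominator
  vm <- mk_variants("GA", "NOVEL", list("S01"),
                    missing_sets = list(c("S02", "S03")))
  expect_equal(case_allele_counts(vm, "GA", samples10,
                                  "ULTRA_RARE_PLUS_NOVEL")[["case_total"]], 16L)
  # carriers outside the subset do not count
  cc_sub <- case_allele_counts(v, "GA", c("S02", "S03"),
                               "ULTRA_RARE_PLUS_NOVEL")
  expect_equal(unname(cc_sub), c(1L, 4L))
})

test_that("control allele counts sum qualifying AC against a representative AN", {
  ctl <- tibble::tibble(
    chrom = "1", pos = 1:3, ref = "A", alt = "G", gene = "GA",
    ac = c(1L, 2L, 0L), an = 1000L, af = c(1e-3, 2e-3, 0),
    tier = c("ULTRA_RARE", "ULTRA_RARE", "NOVEL"), candidate = TRUE
  )
  kk <- control_allele_counts(ctl, "GA", "RARE_UNDER_0_1")
  expect_equal(unname(kk), c(3L, 1000L))
  # non-candidate records are excluded from the numerator
  ctl2 <- ctl; ctl2$candidate <- c(TRUE, FALSE, TRUE)
  expect_equal(control_allele_counts(ctl2, "GA",
                                     "RARE_UNDER_0_1")[["control_alt"]], 1L)
  expect_error(control_allele_counts(ctl, "GB", "RARE_UNDER_0_1"),
               "empty control footprint")
})

test_that("mutually exclusive het carriers collapse to the carrier-case count", {
  carriers <- list(c("S01", "S04"), "S02", "S07")
  v <- mk_variants("GA", rep("NOVEL", 3), carriers)
  cc <- case_allele_counts(v, "GA", samples10, "ULTRA_RARE_PLUS_NOVEL")
  expect_equal(cc[["case_alt"]], length(unique(unlist(carriers))))
})

test_that("disjoint subsets are additive and tier groups nest", {
  v <- mk_variants("GA", c("NOVEL", "VERY_RARE", "RARE"),
                   list(c("S01", "S06"), "S03", "S08"))
  left <- samples10[1:5]; right <- samples10[6:10]
  for (tg in names(tier_groups())) {
    a_all <- case_allele_counts(v, "GA", samples10, tg)[["case_alt"]]
    a_l <- case_allele_counts(v, "GA", left, tg)[["case_alt"]]
    a_r <- case_allele_counts(v, "GA", right, tg)[["case_alt"]]
    expect_equal(a_l + a_r, a_all)
  }
  a_ultra <- case_allele_counts(v, "GA", samples10,
                                "ULTRA_RARE_PLUS_NOVEL")[["case_alt"]]
  a_rare <- case_allele_counts(v, "GA", samples10,
                               "RARE_UNDER_0_1")[["case_alt"]]
  expect_gte(a_rare, a_ultra)
})

test_that("run_burden produces one adjusted row per gene, subset and tier group", {
  cfg <- small_sim_config()
  cohort <- simulate_cohort(cfg)
  res <- burden_from_cohort(cohort)
  expect_equal(nrow(res), 2 * 1 * 2)
  expect_equal(res$gene, rep(c("GA", "GB"), each = 2))
  expect_true(all(res$p_greater > 0 & res$p_greater <= 1))
  expect_true(all(res$fdr_greater >= res$p_greater - 1e-12))
  # empty cells test at p = 1
  empty <- res[res$case_alt == 0, ]
  if (nrow(empty)) expect_true(all(empty$p_greater == 1))
  # deterministic regeneration
  res2 <- burden_from_cohort(simulate_cohort(cfg))
  expect_equal(res, res2)
  # input row order does not matter
  cohort_perm <- cohort
  perm <- rev(seq_len(nrow(cohort$variants)))
  cohort_perm$variants <- cohort$variants[perm, ]
  expect_equal(burden_from_cohort(cohort_perm), res)
})

test_that("adjustment respects the declared family and method", {
  cfg <- small_sim_config()
  res <- burden_from_cohort(simulate_cohort(cfg))
  # default family: subsets x tier groups = 2 -> BH within gene
  g <- res[res$gene == "GA", ]
  expect_equal(g$fdr_greater, bh_adjust(g$p_greater, m_total = 2))
  # an explicit larger family scales the adjustment
  res4 <- burden_from_cohort(simulate_cohort(cfg), family_size = 4)
  g4 <- res4[res4$gene == "GA", ]
  expect_equal(g4$fdr_greater, bh_adjust(g$p_greater, m_total = 4))
  resb <- burden_from_cohort(simulate_cohort(cfg), adjust = "bonferroni")
  gb <- resb[resb$gene == "GA", ]
  expect_equal(gb$fdr_greater, bonferroni_adjust(gb$p_greater, 2))
})

test_that("the formatted report reproduces published cell formatting", {
  res <- tibble::tibble(
    gene = "RPA1", subset = "PanCancer", tier_group = "ULTRA_RARE_PLUS_NOVEL",
    case_alt = 35L, case_total = 11951L,
    control_alt = 466L, control_total = 267908L,
    case_af = 35 / 11951, control_af = 466 / 267908,
    p_greater = fisher_p_greater(35, 11951, 466, 267908),
    p_two_sided = fisher_p_two_sided(35, 11951, 466, 267908),
    or_sample = or_sample(35, 11951, 466, 267908),
    or_cmle = or_conditional_mle(35, 11951, 466, 267908),
    fdr_greater = 0.028068639, fdr_two_sided = 0.042509437
  )
  tab <- format_results_table(res)
  expect_equal(tab$Subset, "PanCancer_UltraRare")
  expect_equal(tab$Cancer_AF, "0.0029")
  expect_equal(tab$Control_AF, "0.0017")
  expect_equal(tab$p_greater, "0.00350858")
  expect_equal(tab$OR_cmle, "1.6837")
  expect_equal(tab$FDR_greater, "0.028068639")
  expect_equal(tab$p_twosided, "0.00531368")
  # written TSV regenerates identically
  p1 <- tempfile(); p2 <- tempfile()
  format_results_table(res, p1); format_results_table(res, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("recomputing the packaged burden counts matches the published table", {
  rep4 <- reproduce_table4()
  solid <- rep4[!rep4$shifted, ]
  expect_equal(solid$p_greater, solid$p_greater_pub, tolerance = 1e-6)
  expect_equal(solid$or_cmle, solid$or_pub, tolerance = 1e-4)
  expect_equal(solid$fdr_greater, solid$fdr_greater_pub, tolerance = 1e-6)
  expect_equal(rep4$p_greater, rep4$p_greater_pub, tolerance = 1e-6)
})
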