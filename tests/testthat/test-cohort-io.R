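test_that("case VCF records map to keyed genotype calls", {
  cases <- read_case_vcf(write_tiny_vcf())
  # 1:200 decomposes into two keyed records
  expect_equal(nrow(cases), 5)
  expect_equal(cases$pos, c(100L, 200L, 200L, 300L, 400L))

  r1 <- cases$calls[[1]]
  expect_equal(r1$gt_class, c("het", "hom_ref", "missing", "hom_ref"))
  expect_equal(r1$ref_reads[1], 10L)
  expect_equal(r1$alt_reads[1], 10L)
  expect_equal(r1$gq[1], 99L)
  expect_equal(cases$call_rate[1], 0.75)
})

test_that("multi-allelic decomposition assigns per-allele depths and conserves calls", {
  cases <- read_case_vcf(write_tiny_vcf())
  recA <- cases[cases$pos == 200 & cases$alt == "A", ]$calls[[1]]
  recT <- cases[cases$pos == 200 & cases$alt == "T", ]$calls[[1]]
  # S1 is GT=1/2: one het contribution to each decomposed record
  expect_equal(recA$gt_class[recA$sample_id == "S1"], "het")
  expect_equal(recT$gt_class[recT$sample_id == "S1"], "het")
  expect_equal(recA$alt_reads[recA$sample_id == "S1"], 6L)
  expect_equal(recT$alt_reads[recT$sample_id == "S1"], 7L)
  # S3 is 0/1: het for A only
  expect_equal(recA$gt_class[recA$sample_id == "S3"], "het")
  expect_equal(recT$gt_class[recT$sample_id == "S3"], "hom_ref")
  # conservation: 3 alt-supporting genotype calls across the two records
  n_alt_calls <- sum(recA$gt_class %in% c("het", "hom_alt")) +
    sum(recT$gt_class %in% c("het", "hom_alt"))
  expect_equal(n_alt_calls, 3)
})

test_that("records with inconsistent AD arity are skipped with a warning", {
  bad <- paste("1", "500", ".", "A", "C,G", ".", "PASS", ".", "GT:AD:GQ",
               "0/1:10,5:99", "0/0:20,0,0:99", "0/0:20,0,0:99",
               "0/0:20,0,0:99", sep = "\t")
  expect_warning(cases <- read_case_vcf(write_tiny_vcf(extra_records = bad)),
                 "AD arity")
  expect_false(any(cases$pos == 500))
})

test_that("garbled VCF input raises a format error", {
  p <- tempfile(fileext = ".vcf")
  writeLines(c("not a vcf", "at all"), p)
  expect_error(read_case_vcf(p), "malformed|VCF")
  expect_error(read_case_vcf(tempfile()), "not found")
})

test_that("control table validation enforces count and key contracts", {
  ctl <- read_control_table(write_tiny_control())
  expect_equal(ctl$af[ctl$pos == 200], 466 / 267908, tolerance = 1e-12)
  expect_equal(nrow(ctl), 4)

  # AF column absent: recomputed
  p <- tempfile()
  writeLines(c("CHROM\tPOS\tREF\tALT\tAC\tAN", "1\t10\tA\tG\t0\t1000"), p)
  expect_equal(read_control_table(p)$af, 0)

  # duplicate keys rejected
  p <- tempfile()
  writeLines(c("CHROM\tPOS\tREF\tALT\tAC\tAN",
               "1\t10\tA\tG\t1\t1000", "1\t10\tA\tG\t2\t1000"), p)
  expect_error(read_control_table(p), "duplicate key")

  # AC > AN rejected with the row named
  p <- tempfile()
  writeLines(c("CHROM\tPOS\tREF\tALT\tAC\tAN", "1\t10\tA\tG\t2000\t1000"), p)
  expect_error(read_control_table(p), "row 1")

  # non-integer counts rejected
  p <- tempfile()
  writeLines(c("CHROM\tPOS\tREF\tALT\tAC\tAN", "1\t10\tA\tG\t1.5\t1000"), p)
  expect_error(read_control_table(p), "integers")
})

test_that("annotation table maps consequences and enforces key-gene uniqueness", {
  ann <- read_annotation_table(write_tiny_annotation())
  expect_setequal(unique(ann$consequence),
                  c("missense", "stopgain", "frameshift_indel"))
  p <- tempfile()
  writeLines(c(paste("CHROM", "POS", "REF", "ALT", "GENE", "CONSEQUENCE",
                     sep = "\t"),
               "1\t10\tA\tG\tX\tmissense_variant",
               "1\t10\tA\tG\tX\tstop_gained"), p)
  expect_error(read_annotation_table(p), "duplicate \\(key, gene\\)")
  expect_equal(map_consequence(c("weird_term", "Missense_Variant")),
               c("other", "missense"))
})

test_that("joining attaches controls, marks novel, and drops unannotated with a count", {
  joined <- suppressMessages(tiny_joined())
  # 1:400 has no annotation -> dropped
  expect_false(any(joined$pos == 400))
  expect_equal(attr(joined, "n_unannotated"), 1)
  # 1:200 G>T absent from controls -> novel, AF treated as 0
  gt <- joined[joined$pos == 200 & joined$alt == "T", ]
  expect_true(gt$novel)
  expect_equal(gt$control_af, 0)
  expect_equal(gt$control_ac, 0L)
  # fully populated record
  ga <- joined[joined$pos == 200 & joined$alt == "A", ]
  expect_equal(ga$control_ac, 466L)
  expect_equal(ga$gene, "GENEA")
  # carriers exclude hom_ref and missing
  expect_equal(nrow(joined$carriers[[1]]), 1)
  expect_equal(joined$missing_samples[[1]], "S3")
})

test_that("join result is independent of input row order", {
  cases <- read_case_vcf(write_tiny_vcf())
  ctl <- read_control_table(write_tiny_control())
  ann <- read_annotation_table(write_tiny_annotation())
  j1 <- suppressMessages(join_annotations(cases, ctl, ann))
  j2 <- suppressMessages(join_annotations(cases[rev(seq_len(nrow(cases))), ],
                                          ctl[sample(nrow(ctl)), ],
                                          ann[sample(nrow(ann)), ]))
  key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt)
  j2 <- j2[match(key(j1), key(j2)), ]
  expect_equal(j1$control_ac, j2$control_ac)
  expect_equal(j1$gene, j2$gene)
  expect_equal(j1$carriers, j2$carriers)
})

test_that("zero joins across a large case set trigger a naming-mismatch error", {
  cases <- read_case_vcf(write_tiny_vcf())
  big <- dplyr::bind_rows(replicate(30, cases, simplify = FALSE))
  big$pos <- seq_len(nrow(big)) + 10000L
  ctl <- read_control_table(write_tiny_control())
  ann <- read_annotation_table(write_tiny_annotation())
  expect_error(join_annotations(big, ctl, ann), "chromosome naming")
})

test_that("the TSV interchange format round-trips joined records losslessly", {
  joined <- suppressMessages(tiny_joined())
  path <- tempfile(fileext = ".tsv")
  write_variants_tsv(joined, path)
  back <- read_variants_tsv(path)
  expect_equal(back$chrom, joined$chrom)
  expect_equal(back$pos, joined$pos)
  expect_equal(back$control_af, joined$control_af)
  expect_equal(back$carriers, joined$carriers)
  expect_equal(back$missing_samples, joined$missing_samples)
})
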