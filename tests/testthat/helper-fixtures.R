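# In-code fixtures: a tiny hand-written case VCF with matching control and
# annotation tables, and a small simulation configuration for fast tests.

write_tiny_vcf <- function(path = tempfile(fileext = ".vcf"),
                           extra_records = character(0)) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", "S4", sep = "\t"),
    # biallelic het with clean support
    paste("1", "100", ".", "C", "T", ".", "PASS", ".", "GT:AD:GQ",
          "0/1:10,10:99", "0/0:20,0:99", "./.:.:.", "0/0:18,0:95", sep = "\t"),
    # multi-allelic, S1 carries both alts (1/2), S3 het for alt 1
    paste("1", "200", ".", "G", "A,T", ".", "PASS", ".", "GT:AD:GQ",
          "1/2:5,6,7:80", "0/0:20,0,0:99", "0/1:12,8,0:70", "0/0:15,0,0:99",
          sep = "\t"),
    # indel het
    paste("1", "300", ".", "CT", "C", ".", "PASS", ".", "GT:AD:GQ",
          "0/1:9,7:45", "0/0:20,0:99", "0/0:22,0:99", "0/0:19,0:99",
          sep = "\t"),
    # two carriers, one with weak support
    paste("1", "400", ".", "A", "G", ".", "PASS", ".", "GT:AD:GQ",
          "0/1:10,11:99", "0/1:3,2:99", "0/0:20,0:99", "0/0:12,0:99",
          sep = "\t"),
    extra_records
  )
  writeLines(lines, path)
  path
}

write_tiny_control <- function(path = tempfile(fileext = ".tsv"),
                               rows = NULL) {
  if (is.null(rows)) {
    rows <- c(
      "1\t100\tC\tT\t4\t100000\t4e-05",
      "1\t200\tG\tA\t466\t267908\t0.0017394030786688",
      "1\t300\tCT\tC\t80\t100000\t0.0008",
      # a control-only record in the same gene footprint
      "1\t700\tG\tC\t2\t100000\t2e-05"
    )
  }
  writeLines(c("CHROM\tPOS\tREF\tALT\tAC\tAN\tAF", rows), path)
  path
}

write_tiny_annotation <- function(path = tempfile(fileext = ".tsv"),
                                  rows = NULL) {
  hdr <- paste("CHROM", "POS", "REF", "ALT", "GENE", "CONSEQUENCE", "HGVSP",
               "CADD_PHRED", "REVEL", "ACMG", "DDG", "DOMAIN", sep = "\t")
  if (is.null(rows)) {
    rows <- c(
      "1\t100\tC\tT\tGENEA\tmissense_variant\tp.M46V\t22.2\t0.28\tVUS\t1.9\tF",
      "1\t200\tG\tA\tGENEA\tmissense_variant\tp.R210C\t35\t0.59\tVUS\t0.6\tA",
      "1\t200\tG\tT\tGENEA\tstop_gained\tp.R210*\t38\tNA\tVUS\tNA\tA",
      "1\t300\tCT\tC\tGENEA\tframeshift_variant\tp.L53Ifs*53\tNA\tNA\tVUS\tNA\tF",
      # 1:400 left unannotated on purpose
      "1\t700\tG\tC\tGENEA\tmissense_variant\tp.Q420L\t25\t0.2\tVUS\tNA\tB"
    )
  }
  writeLines(c(hdr, rows), path)
  path
}

write_tiny_subsets <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c("sample_id\tHEM\tST",
               "S1\t1\t0", "S2\t1\t0", "S3\t0\t1", "S4\t0\t1"), path)
  path
}

tiny_joined <- function() {
  join_annotations(read_case_vcf(write_tiny_vcf()),
                   read_control_table(write_tiny_control()),
                   read_annotation_table(write_tiny_annotation()))
}

small_sim_config <- function(...) {
  simulation_config(
    n_cases = 60, control_an = 5000,
    genes = tibble::tibble(gene = c("GA", "GB"), n_sites = 8L),
    af_spectrum = tibble::tibble(af = c(1e-4, 1e-3), weight = c(0.5, 0.5)),
    depth_mean = 40, missing_rate = 0.05, seed = 11L, ...
  )
}

# random valid 2x2 tables for property-style checks
random_tables <- function(n, max_cell = 80, seed = 42) {
  set.seed(seed)
  tibble::tibble(
    a = sample(0:max_cell, n, TRUE), b = sample(0:max_cell, n, TRUE),
    c = sample(0:max_cell, n, TRUE), d = sample(0:max_cell, n, TRUE)
  )
}
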