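# Reading and key-joining the three input tables: case VCF, control
# allele-frequency table, variant annotation table. Keys are (chrom, pos, ref,
# alt) in 1-based VCF coordinates; multi-allelic records are decomposed to one
# keyed record per alternate allele on read. Indels are assumed pre-normalized
# upstream (GATK); no left-normalization or liftover is attempted.

.key_cols <- c("chrom", "pos", "ref", "alt")

.norm_chrom <- function(chrom, strip_chr = FALSE) {
  if (strip_chr) sub("^chr", "", chrom) else chrom
}

#' Read a multi-sample germline case VCF
#'
#' Reads a VCF 4.x file with per-genotype GT, AD and GQ fields and decomposes
#' multi-allelic records into one keyed record per alternate allele. A sample
#' whose GT, AD or GQ is missing at a site yields a `missing` genotype call
#' there. Records whose AD arity is inconsistent with the allele count are
#' skipped with a warning.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param strip_chr Strip a leading `"chr"` from chromosome names, to
#'   harmonize with GRCh37-style control tables.
#' @return A tibble with one row per (site, alt allele): the key columns
#'   `chrom`, `pos`, `ref`, `alt`, a `calls` list-column of per-sample
#'   genotype tibbles (`sample_id`, `gt_class`, `ref_reads`, `alt_reads`,
#'   `gq`), and `call_rate` (fraction of samples with a non-missing genotype).
#'   Input record order is preserved.
#' @export
read_case_vcf <- function(path, strip_chr = FALSE) {
  if (!file.exists(path)) stop("case VCF not found: ", path, call. = FALSE)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF header or body in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  samples <- colnames(v@gt)[-1]
  get_fmt <- function(el) {
    tryCatch(vcfR::extract.gt(v, element = el),
             error = function(e) matrix(NA_character_, nrow = nrow(fix),
                                        ncol = length(samples)))
  }
  gt <- get_fmt("GT"); ad <- get_fmt("AD"); gq <- get_fmt("GQ")

  alt_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  rows <- vector("list", sum(lengths(alt_list)))
  ri <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- alt_list[[i]]
    gts <- gt[i, ]; ads <- ad[i, ]; gqs <- gq[i, ]
    ad_split <- strsplit(ads, ",", fixed = TRUE)
    bad_arity <- !is.na(ads) & lengths(ad_split) != length(alts) + 1L
    if (any(bad_arity)) {
      warning("record ", fix[i, "CHROM"], ":", fix[i, "POS"],
              " has AD arity inconsistent with its allele count; skipped")
      next
    }
    gt_tokens <- strsplit(gts, "[/|]")
    miss <- is.na(gts) | vapply(gt_tokens, function(t) any(t == "."), logical(1)) |
      is.na(ads) | is.na(gqs)
    gq_num <- suppressWarnings(as.integer(gqs))
    for (j in seq_along(alts)) {
      n_alt <- integer(length(samples))
      n_alt[!miss] <- vapply(gt_tokens[!miss], function(t) sum(t == as.character(j)),
                             integer(1))
      cls <- ifelse(miss, "missing",
                    c("hom_ref", "het", "hom_alt")[pmin(n_alt, 2L) + 1L])
      ref_reads <- alt_reads <- rep(NA_integer_, length(samples))
      ok <- !miss
      ref_reads[ok] <- suppressWarnings(
        vapply(ad_split[ok], function(x) as.integer(x[1]), integer(1)))
      alt_reads[ok] <- suppressWarnings(
        vapply(ad_split[ok], function(x) as.integer(x[j + 1L]), integer(1)))
      ri <- ri + 1L
      rows[[ri]] <- tibble::tibble(
        chrom = unname(.norm_chrom(fix[i, "CHROM"], strip_chr)),
        pos = unname(as.integer(fix[i, "POS"])),
        ref = unname(fix[i, "REF"]),
        alt = alts[j],
        calls = list(tibble::tibble(
          sample_id = samples, gt_class = unname(cls),
          ref_reads = unname(ref_reads), alt_reads = unname(alt_reads),
          gq = unname(ifelse(miss, NA_integer_, gq_num))
        )),
        call_rate = mean(!miss)
      )
    }
  }
  dplyr::bind_rows(rows[seq_len(ri)])
}

#' Read a population control allele-frequency table
#'
#' Tab-separated with header columns CHROM POS REF ALT AC AN and optionally
#' AF plus ancestry-specific AF columns. AF is recomputed as AC/AN when the
#' column is absent and validated against it when present.
#'
#' @param path Path to the TSV (plain or gzipped).
#' @param strip_chr Strip a leading `"chr"` from chromosome names.
#' @return A tibble keyed by `chrom`, `pos`, `ref`, `alt` with `ac`, `an`,
#'   `af` and any extra ancestry columns.
#' @export
read_control_table <- function(path, strip_chr = FALSE) {
  if (!file.exists(path)) stop("control table not found: ", path, call. = FALSE)
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("CHROM", "POS", "REF", "ALT", "AC", "AN")
  if (!all(need %in% names(x))) {
    stop("control table must have columns ", paste(need, collapse = " "),
         "; missing: ", paste(setdiff(need, names(x)), collapse = " "),
         call. = FALSE)
  }
  if (any(x$AC != floor(x$AC)) || any(x$AN != floor(x$AN))) {
    stop("AC and AN must be integers in the control table", call. = FALSE)
  }
  if (any(x$AN <= 0)) stop("AN must be positive in the control table", call. = FALSE)
  bad <- which(x$AC > x$AN | x$AC < 0)
  if (length(bad)) {
    stop("control table row ", bad[1], ": AC (", x$AC[bad[1]],
         ") out of range for AN (", x$AN[bad[1]], ")", call. = FALSE)
  }
  af <- x$AC / x$AN
  if ("AF" %in% names(x)) {
    off <- which(abs(x$AF - af) > 1e-9)
    if (length(off)) {
      stop("control table row ", off[1], ": AF column (", x$AF[off[1]],
           ") disagrees with AC/AN (", af[off[1]], ")", call. = FALSE)
    }
  }
  out <- tibble::tibble(
    chrom = .norm_chrom(as.character(x$CHROM), strip_chr),
    pos = as.integer(x$POS), ref = x$REF, alt = x$ALT,
    ac = as.integer(x$AC), an = as.integer(x$AN), af = af
  )
  extra <- setdiff(names(x), c(need, "AF"))
  if (length(extra)) out <- dplyr::bind_cols(out, x[extra])
  dup <- duplicated(out[.key_cols])
  if (any(dup)) {
    k <- out[which(dup)[1], .key_cols]
    stop("duplicate key in control table: ", paste(unlist(k), collapse = ":"),
         " (decompose multi-allelic sites first)", call. = FALSE)
  }
  out
}

#' Read a variant annotation table
#'
#' Tab-separated with key columns CHROM POS REF ALT plus GENE, CONSEQUENCE
#' and the optional columns HGVSP, CADD_PHRED, REVEL, ACMG, DDG, DOMAIN.
#' Consequence strings are mapped to the package's closed consequence classes
#' through an editable dictionary (see [consequence_map()]).
#'
#' @param path Path to the TSV (plain or gzipped).
#' @param map Consequence dictionary tibble with columns `term` and `class`.
#' @param strip_chr Strip a leading `"chr"` from chromosome names.
#' @return A tibble keyed by `chrom`, `pos`, `ref`, `alt` with `gene`,
#'   `consequence` (mapped class), `hgvs_p`, `cadd_phred`, `revel`, `acmg`,
#'   `ddg`, `domain`.
#' @export
read_annotation_table <- function(path, map = consequence_map(),
                                  strip_chr = FALSE) {
  if (!file.exists(path)) stop("annotation table not found: ", path, call. = FALSE)
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("CHROM", "POS", "REF", "ALT", "GENE", "CONSEQUENCE")
  if (!all(need %in% names(x))) {
    stop("annotation table must have columns ", paste(need, collapse = " "),
         "; missing: ", paste(setdiff(need, names(x)), collapse = " "),
         call. = FALSE)
  }
  opt_num <- function(col) if (col %in% names(x)) as.numeric(x[[col]]) else NA_real_
  opt_chr <- function(col) if (col %in% names(x)) as.character(x[[col]]) else NA_character_
  out <- tibble::tibble(
    chrom = .norm_chrom(as.character(x$CHROM), strip_chr),
    pos = as.integer(x$POS), ref = x$REF, alt = x$ALT,
    gene = x$GENE,
    consequence = map_consequence(x$CONSEQUENCE, map),
    hgvs_p = opt_chr("HGVSP"),
    cadd_phred = opt_num("CADD_PHRED"),
    revel = opt_num("REVEL"),
    acmg = opt_chr("ACMG"),
    ddg = opt_num("DDG"),
    domain = opt_chr("DOMAIN")
  )
  if (any(!is.na(out$cadd_phred) & out$cadd_phred < 0)) {
    stop("CADD_PHRED must be non-negative", call. = FALSE)
  }
  dup <- duplicated(out[c(.key_cols, "gene")])
  if (any(dup)) {
    k <- out[which(dup)[1], c(.key_cols, "gene")]
    stop("duplicate (key, gene) in annotation table: ",
         paste(unlist(k), collapse = ":"), call. = FALSE)
  }
  out
}

#' Join case variants with control frequencies and annotations
#'
#' Case variants absent from the control table are treated as novel
#' (control AF = 0); case variants without an annotation are dropped with a
#' logged count. All three inputs must share the same key normalization
#' (decomposition and chromosome naming); a zero-join across a large case set
#' triggers a hard error suggesting chromosome-name harmonization.
#'
#' @param cases Tibble from [read_case_vcf()].
#' @param controls Tibble from [read_control_table()].
#' @param annotations Tibble from [read_annotation_table()].
#' @return A tibble of annotated variants: key columns, annotation columns,
#'   `control_ac`/`control_an`/`control_af` (0/NA/0 when novel), `novel`,
#'   `n_samples`, a `carriers` list-column (non-hom-ref, non-missing genotype
#'   calls, pre-QC) and a `missing_samples` list-column. The number of
#'   unannotated case variants dropped is attached as attribute
#'   `n_unannotated`.
#' @export
join_annotations <- function(cases, controls, annotations) {
  ann_hit <- dplyr::inner_join(cases[.key_cols], annotations[.key_cols],
                               by = .key_cols)
  ctl_hit <- dplyr::inner_join(cases[.key_cols], controls[.key_cols],
                               by = .key_cols)
  if (nrow(cases) > 100 && nrow(ann_hit) == 0 && nrow(ctl_hit) == 0) {
    stop("no case variant keys match the control or annotation tables ",
         "across >100 records; check chromosome naming (try strip_chr = TRUE) ",
         "and multi-allelic decomposition", call. = FALSE)
  }
  joined <- dplyr::inner_join(cases, annotations, by = .key_cols)
  n_unannotated <- nrow(cases) - nrow(joined)
  if (n_unannotated > 0) {
    message(n_unannotated, " case variant(s) without annotation dropped")
  }
  joined <- dplyr::left_join(
    joined, dplyr::select(controls, dplyr::all_of(c(.key_cols, "ac", "an", "af"))),
    by = .key_cols
  )
  joined$novel <- is.na(joined$ac)
  joined$control_ac <- ifelse(joined$novel, 0L, joined$ac)
  joined$control_an <- joined$an
  joined$control_af <- ifelse(joined$novel, 0, joined$af)
  joined$ac <- joined$an <- joined$af <- NULL

  joined$n_samples <- vapply(joined$calls, nrow, integer(1))
  joined$carriers <- lapply(joined$calls, function(cl) {
    cl[cl$gt_class %in% c("het", "hom_alt"), , drop = FALSE]
  })
  joined$missing_samples <- lapply(joined$calls, function(cl) {
    cl$sample_id[cl$gt_class == "missing"]
  })
  joined$calls <- NULL
  structure(joined, n_unannotated = n_unannotated)
}

#' Write / read the joined-variant TSV interchange format
#'
#' Flat, lossless round-trip of the annotated-variant stream: carriers are
#' packed as `sample:gt_class:ref_reads:alt_reads:gq` separated by `;`,
#' missing samples as a comma-separated list.
#'
#' @param x Tibble as produced by [join_annotations()] (optionally after QC
#'   and classification; extra atomic columns round-trip as-is).
#' @param path Output path.
#' @return `write_variants_tsv` returns `path` invisibly; `read_variants_tsv`
#'   returns the tibble.
#' @export
write_variants_tsv <- function(x, path) {
  flat <- x
  flat$carriers <- vapply(x$carriers, function(cr) {
    if (nrow(cr) == 0) return("")
    paste(sprintf("%s:%s:%d:%d:%d", cr$sample_id, cr$gt_class,
                  cr$ref_reads, cr$alt_reads, cr$gq), collapse = ";")
  }, character(1))
  flat$missing_samples <- vapply(x$missing_samples, paste, character(1),
                                 collapse = ",")
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_variants_tsv
#' @export
read_variants_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         chrom = readr::col_character(),
                         carriers = readr::col_character(),
                         missing_samples = readr::col_character(),
                         .default = readr::col_guess()))
  x$carriers <- lapply(ifelse(is.na(x$carriers), "", x$carriers), function(s) {
    if (s == "") {
      return(tibble::tibble(sample_id = character(0), gt_class = character(0),
                            ref_reads = integer(0), alt_reads = integer(0),
                            gq = integer(0)))
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    tibble::tibble(
      sample_id = vapply(parts, `[`, character(1), 1),
      gt_class = vapply(parts, `[`, character(1), 2),
      ref_reads = as.integer(vapply(parts, `[`, character(1), 3)),
      alt_reads = as.integer(vapply(parts, `[`, character(1), 4)),
      gq = as.integer(vapply(parts, `[`, character(1), 5))
    )
  })
  x$missing_samples <- lapply(ifelse(is.na(x$missing_samples), "",
                                     x$missing_samples), function(s) {
    if (s == "") character(0) else strsplit(s, ",", fixed = TRUE)[[1]]
  })
  tibble::as_tibble(x)
}

#' Consequence-class dictionary
#'
#' Maps annotation-tool consequence strings (VEP and ANNOVAR dialects) to the
#' closed classes `missense`, `frameshift_indel`, `stopgain`, `splice`,
#' `other`. The dictionary ships as editable TSV in the package's `extdata`.
#'
#' @param path Optional path to a replacement dictionary TSV with columns
#'   `term` and `class`.
#' @return A tibble with columns `term` and `class`.
#' @export
consequence_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "consequence_map.tsv", package = "rvburden",
                        mustWork = TRUE)
  }
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Map consequence strings to consequence classes
#'
#' @param x Character vector of annotation consequence terms.
#' @param map Dictionary tibble from [consequence_map()].
#' @return Character vector over the closed class set; unmapped terms become
#'   `"other"`.
#' @export
map_consequence <- function(x, map = consequence_map()) {
  cls <- map$class[match(tolower(x), tolower(map$term))]
  ifelse(is.na(cls), "other", cls)
}
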