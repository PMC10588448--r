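# Candidate selection (consequence class, control AF ceiling, CADD for
# missense), population-rarity tiers and protein-stability calls.

.rarity_levels <- c("NOVEL", "ULTRA_RARE", "VERY_RARE", "RARE", "LOW_FREQ",
                    "EXCLUDED")
.candidate_classes <- c("missense", "frameshift_indel", "stopgain", "splice")

#' Rarity-tier boundaries on control allele frequency
#'
#' Boundaries are fractions (0.005% = 5e-5). Novel means control AF exactly 0;
#' all other tier comparisons are strict `<`. The very-rare upper bound is not
#' pinned down by any published number; the default 0.05% is the geometric
#' midpoint between the ultra-rare and rare bounds and is configurable (the
#' statistics only consume the paper-defined ultra-rare+novel and <0.1%
#' groupings).
#'
#' @param ultra_rare_max Upper bound of the ultra-rare tier. Default 5e-5
#'   (0.005%).
#' @param very_rare_max Upper bound of the very-rare tier. Default 5e-4
#'   (0.05%).
#' @param rare_max Upper bound of the rare tier. Default 1e-3 (0.1%).
#' @param candidate_max Candidate-selection AF ceiling. Default 5e-3 (0.5%).
#' @return An object of class `tier_boundaries`.
#' @export
tier_boundaries <- function(ultra_rare_max = 5e-5, very_rare_max = 5e-4,
                            rare_max = 1e-3, candidate_max = 5e-3) {
  stopifnot(0 < ultra_rare_max, ultra_rare_max <= very_rare_max,
            very_rare_max <= rare_max, rare_max <= candidate_max)
  structure(list(ultra_rare_max = ultra_rare_max, very_rare_max = very_rare_max,
                 rare_max = rare_max, candidate_max = candidate_max),
            class = "tier_boundaries")
}

#' Assign population-rarity tiers from control allele frequency
#'
#' @param af Control allele frequencies (vectorised), in \[0, 1\].
#' @param boundaries A [tier_boundaries()] object.
#' @return Character vector over NOVEL, ULTRA_RARE, VERY_RARE, RARE,
#'   LOW_FREQ, EXCLUDED; exactly one tier per value.
#' @examples
#' classify_rarity(c(0, 1.3e-5, 4.1e-4, 1.763e-3))
#' @export
classify_rarity <- function(af, boundaries = tier_boundaries()) {
  if (any(af < 0) || any(af > 1)) {
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  b <- boundaries
  dplyr::case_when(
    af == 0 ~ "NOVEL",
    af < b$ultra_rare_max ~ "ULTRA_RARE",
    af < b$very_rare_max ~ "VERY_RARE",
    af < b$rare_max ~ "RARE",
    af < b$candidate_max ~ "LOW_FREQ",
    TRUE ~ "EXCLUDED"
  )
}

#' Candidate-variant filter
#'
#' A variant is a candidate when its consequence class is one of missense,
#' frameshift_indel, stopgain or splice, its control AF is below the
#' candidate ceiling (strict), and -- for missense only -- its CADD Phred
#' score is present and exceeds `cadd_min` (strict). Missense variants with
#' no CADD score are excluded (conservative reading of the retention filter).
#'
#' @param consequence Consequence classes (vectorised).
#' @param control_af Control allele frequencies.
#' @param cadd_phred CADD Phred scores (NA when absent).
#' @param boundaries A [tier_boundaries()] object.
#' @param cadd_min Strict CADD threshold for missense variants. Default 15.
#' @return Logical vector.
#' @export
is_candidate <- function(consequence, control_af, cadd_phred,
                         boundaries = tier_boundaries(), cadd_min = 15) {
  consequence %in% .candidate_classes &
    control_af < boundaries$candidate_max &
    (consequence != "missense" | (!is.na(cadd_phred) & cadd_phred > cadd_min))
}

#' Protein-stability call from a folding free-energy change
#'
#' A predicted \eqn{\Delta\Delta G_{Fold}} of about 1.5 kcal/mol shifts the
#' folded:unfolded ratio roughly 12-fold; at or beyond that magnitude a
#' missense variant is called destabilizing (positive) or stabilizing
#' (negative). The bound is inclusive.
#'
#' @param ddg Folding free-energy changes in kcal/mol (NA when no structural
#'   coverage).
#' @param cutoff Positive magnitude cutoff in kcal/mol. Default 1.5.
#' @return Character vector over destabilizing, stabilizing, neutral,
#'   unavailable.
#' @examples
#' classify_stability(c(1.9, 1.5, -0.9, NA))
#' @export
classify_stability <- function(ddg, cutoff = 1.5) {
  stopifnot(cutoff > 0)
  dplyr::case_when(
    is.na(ddg) ~ "unavailable",
    ddg >= cutoff ~ "destabilizing",
    ddg <= -cutoff ~ "stabilizing",
    TRUE ~ "neutral"
  )
}

#' Classify joined variants: type, tier, stability, candidacy
#'
#' Adds `vtype`, `tier`, `stability` and `candidate` columns to a joined
#' (and normally QC-filtered) variant tibble.
#'
#' @param variants Tibble from [join_annotations()] / [apply_qc()].
#' @param boundaries A [tier_boundaries()] object.
#' @param cadd_min Strict CADD threshold for missense candidates.
#' @param stability_cutoff Magnitude cutoff for stability calls, kcal/mol.
#' @return The input tibble with classification columns appended. The number
#'   of missense variants excluded for lacking a CADD score is attached as
#'   attribute `n_missense_no_cadd`.
#' @export
classify_variants <- function(variants, boundaries = tier_boundaries(),
                              cadd_min = 15, stability_cutoff = 1.5) {
  variants$vtype <- variant_type_of(variants$ref, variants$alt)
  variants$tier <- classify_rarity(variants$control_af, boundaries)
  variants$stability <- classify_stability(variants$ddg, stability_cutoff)
  variants$candidate <- is_candidate(variants$consequence, variants$control_af,
                                     variants$cadd_phred, boundaries, cadd_min)
  n_no_cadd <- sum(variants$consequence == "missense" &
                     is.na(variants$cadd_phred))
  if (n_no_cadd > 0) {
    message(n_no_cadd, " missense variant(s) without CADD score excluded ",
            "from candidacy")
  }
  structure(variants, n_missense_no_cadd = n_no_cadd)
}
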