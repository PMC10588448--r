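---
title: "Gene-collapsing rare-variant burden testing against population controls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-collapsing rare-variant burden testing against population controls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvburden)
```

## The design

rvburden implements the case/population-control collapsing design used to
screen genes for germline predisposition: does a case cohort carry more
rare, putatively damaging alleles in a gene than a large reference
population (a gnomAD-style non-cancer panel) does? Because individual rare
variants are too infrequent to test one at a time, qualifying alleles are
*collapsed* — summed per gene, per cohort subset (e.g. pan-cancer,
hematologic, solid, CNS), and per population-rarity tier group — into one
2×2 allele-count table per cell, and each cell is tested exactly.

The pipeline stages are composable functions with files at the boundaries:

1. **Ingestion** (`read_case_vcf`, `read_control_table`,
   `read_annotation_table`, `join_annotations`): a multi-sample germline VCF
   with per-genotype GT/AD/GQ, a control frequency table (CHROM POS REF ALT
   AC AN AF), and an annotation table (gene, consequence, CADD, optionally
   REVEL/ACMG/ΔΔG/domain). Multi-allelic records are decomposed to one keyed
   record per alternate allele on read; a sample with GT `1/2` contributes
   one heterozygous call to each decomposed record, with per-allele depths
   taken from the matching AD slot. Case variants absent from the control
   table are *novel* (control AF treated as 0), not an error; case variants
   without an annotation are dropped and counted.
2. **Genotype and site QC** (`apply_qc`).
3. **Candidate selection and tiering** (`classify_variants`).
4. **Collapsing and exact testing** (`run_burden`).
5. **Reporting** (`format_results_table`, `summarize_results`,
   `run_pipeline` with a JSON manifest of every threshold and per-stage
   count).

## Quality filters

Defaults in `qc_thresholds()`, all overridable:

| rule | default | reading |
|---|---|---|
| allelic balance | > 0.2 | strict, all non-reference calls |
| genotype quality | > 20 | strict (GQ of exactly 20 fails) |
| het VAF window | 0.20–0.80 | inclusive, heterozygous calls only |
| min alt reads, SNV | ≥ 10 | |
| min alt reads, indel | ≥ 7 | MNVs grouped with indels |
| site missingness | < 0.25 | strict (a site at exactly 25% is removed) |

Allelic balance and the het VAF window are deliberately kept as two separate
rules even though they share the 0.2 lower bound: the balance floor is a
strict inequality applied to every non-reference call, while the window is
inclusive and heterozygous-only, so a hom-alt call with VAF 0.95 passes the
floor and is exempt from the window. VAF is computed from AD alone
(alt/(ref+alt)); reads assigned to neither allele are ignored. A call can
fail several rules at once, so per-rule removal counts in the QC log can sum
to more than the number of calls removed.

## Candidate selection and rarity tiers

A variant qualifies when its consequence class is missense, frameshift
indel, stop-gain or splice; its control AF is below 0.5% (strict); and — for
missense only — CADD Phred exceeds 15 (strict). Missense variants lacking a
CADD score are excluded conservatively and counted, since the retention rule
is stated in terms of a computed score. Consequence strings from VEP- and
ANNOVAR-style annotations are mapped through an editable dictionary shipped
as `extdata/consequence_map.tsv`.

Rarity tiers are a pure function of control AF (`classify_rarity`): NOVEL at
exactly 0, then strict upper bounds of 0.005% (ULTRA_RARE), 0.05%
(VERY_RARE), 0.1% (RARE), 0.5% (LOW_FREQ), else EXCLUDED. The 0.05%
very-rare bound is the one boundary without a published number; we take the
decade midpoint between the defined ultra-rare and rare bounds and keep it
configurable. The statistics never consume it alone: the two tested tier
groups are the paper-defined unions *ultra-rare plus novel* (AF < 0.005% or
0) and *everything under 0.1%*.

Protein-stability calls (`classify_stability`) tag missense variants whose
predicted folding free-energy change reaches 1.5 kcal/mol in magnitude
(about a 12-fold shift in the folded:unfolded ratio) as destabilizing
(positive) or stabilizing (negative). The bound is inclusive: the published
set of significant variants includes one tabulated at exactly 1.5, so an
exclusive reading would contradict the source's own accounting.

## The 2×2 cell and its statistics

For gene *g*, subset *s* and tier group *t*: the case numerator adds one
allele per heterozygous and two per homozygous-alternate carrier in *s*
across qualifying variants; the control numerator sums AC over **all**
control-side variants passing the same candidate and tier filters, not just
those seen in cases. Denominators follow an allele-number policy
(`an_policy`): the default `site_mean` uses the rounded mean called allele
number across the gene's QC-passing sites in the subset (2 × non-missing
samples per site), which is why published case totals sit slightly under
2N; `site_median` and flat `two_n` are alternatives. Control totals
analogously use the control table's AN.

Two construction conventions for the 2×2 are supported. The default,
`alt_vs_total`, places the *full* allele-number denominator in the second
column — the construction under which the published burden statistics
(p-values, conditional-MLE odds ratios and adjusted values) reproduce
digit-for-digit — while `alt_vs_ref` gives the textbook alt/non-alt table.
With alt counts three to four orders of magnitude below the denominators
the two differ only far beyond the reported precision (e.g. 0.003509 vs
0.003447 one-sided for the headline cell), but matching the published
convention exactly is what makes the reproduction checks meaningful.

The machinery (`fisher_p_greater`, `fisher_p_two_sided`, `or_sample`,
`or_conditional_mle`, `bh_adjust`, `bonferroni_adjust`) is implemented from
first principles:

* The central hypergeometric pmf is computed through `lchoose`; tail sums
  use a single max-shift exponentiation. No factorial tables — margins of
  10⁵–10⁶ are routine.
* The two-sided p sums all support points whose pmf does not exceed the
  observed pmf by more than a relative 10⁻⁷, the summation convention of R's
  `fisher.test`, which is the convention behind published two-sided values.
* The conditional MLE odds ratio solves $E_\psi[X] = a$ on the log-odds
  scale by Newton iteration with a maintained bracket (the derivative of the
  conditional mean in log ψ is the conditional variance); it returns 0 or
  ∞ when the observed cell sits on the support boundary and satisfies
  $|E_{\hat\psi}[X] - a| < 10^{-10}$ otherwise.
* `bh_adjust` takes an explicit family size `m_total ≥ n`: per gene the
  family is subsets × tier groups (8 for a four-subset run), so unreported
  cells count as untested family members, which is how the published
  adjusted values arise from four observed p-values. The package defaults
  to BH because the published adjusted values are step-up BH values
  (smallest p × 8/1, next × 8/2, …), even where the accompanying text says
  Bonferroni; `adjust = "bonferroni"` is available.

`fisher.test`, `dhyper` and `p.adjust` serve as independent cross-checks in
the test suite — oracle equivalence against brute-force enumeration is
asserted for every 2×2 table with total ≤ 60 — but never as the
implementation.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure of the real study inputs: a
multi-sample case VCF with read-level fields, a matched control frequency
table spanning all rarity tiers, an annotation table, a subset table and a
truth log. Per site, a population AF is drawn from a configurable spectrum;
control AC defaults to round(AF × AN), so a site's tier is a deterministic
function of its draw (sites rounding to 0 are absent from the control table
and classify NOVEL downstream); each case sample is an independent
heterozygous carrier with probability 2·AF·λ, where λ is the per-gene
enrichment multiplier (λ = 1 is the null).

Defaults — 500 cases, control AN 20,000, six genes of 20 sites, spectrum
(10⁻⁵, 3×10⁻⁵, 10⁻⁴, 4×10⁻⁴) with weights (0.30, 0.30, 0.25, 0.15), mean
depth 40, 1% missingness — are chosen so that the control:case allele ratio
(20:1) matches the scale relation of a public control panel to an exome
cohort, a null gene carries about two qualifying case alleles, and λ = 10
yields roughly 20 expected carriers in the enriched gene: enough signal for
a power check without leaving the rare-variant regime.

Three deliberate idealizations keep the truth exact and the contracts
testable; they are also what a passing test does *not* establish about real
data:

* Clean carriers' read draws (depth ~ Poisson, alt ~ Binomial(d, ½)) are
  clamped into the QC-passing region, and injected noisy carriers (fraction
  `qc_noise`) are forced to fail (GQ ≤ 20 or VAF ≈ 0.12), so "QC removes
  exactly the injected noise" is a sharp property rather than a
  probabilistic one. Real data have borderline calls.
* Missingness is applied to non-carrier genotypes only, keeping the truth
  carrier list exact.
* `control_sampling = "binomial"` (AC ~ Binomial(AN, af)) is available and
  population-realistic, but it makes the novel tier a *selection on control
  sampling noise*: sites whose AC samples to zero still carry case alleles
  at rate 2·AF, so the novel-tier cell is anti-conservative under the null
  (we measured per-gene null rejection of 3–8% with it). This is a genuine
  caveat of AF-tiered burden designs with finite control panels, not a
  simulator artifact; the deterministic default avoids conflating it with
  the calibration of the test itself.

There is no linkage, haplotype structure, ancestry stratification or
base-level sequencing-error model, and carriers are het-only by default
(matching the mutually-exclusive heterozygous carriers observed in the
motivating screen); hom-alt genotypes are nevertheless handled throughout
(two alleles per carrier).

Replicate seeds derive from the master seed by a splitmix-style scrambler
(`xor(master, (index × 2654435769) mod 2³¹)`), documented so the stream is
reproducible from the seed alone and always a valid 32-bit seed.

## Calibration results the suite computes

`evaluate_calibration()` runs the full in-memory pipeline (QC →
classification → collapsing → testing → family adjustment) on each
replicate. The acceptance suite runs 200 null replicates and 100 replicates
each at λ = 3 and λ = 10 (seed 1) and asserts: per-gene family-adjusted null
rejection ≤ 5% at α = 0.05 (the exact test is conservative at these counts),
power ≥ 80% for the λ = 10 gene, and monotone growth of the mean
conditional-MLE odds ratio over λ ∈ {1, 3, 10}. These problem sizes keep the
full suite in the minutes range while leaving each cell squarely in the
small-count regime the method is meant for.

## Numerical and degenerate-input choices

* Boundary semantics are uniform: tier bounds and the candidate AF ceiling
  strict, the stability magnitude inclusive, QC per the table above.
* `or_sample` returns 0 / ∞ for single-zero cross products and 1 with a
  warning when both vanish; `or_conditional_mle` returns exact 0 / ∞ at the
  support boundary rather than failing.
* An upper-tail p at the support minimum returns exactly 1 (not a rounded
  sum).
* Ties in BH are handled by the step-up cummin, so tied p-values share an
  adjusted value.
* Indel keys are not left-normalized — inputs are assumed normalized
  upstream by the caller's pipeline — and chromosome naming is exact string
  match with an optional `"chr"`-strip to harmonize GRCh37-style resources.
* Hemizygous and sex-chromosome genotypes are treated as written (diploid);
  the genes this design targets are autosomal.

## Known limitations

The collapsing test inherits the limitations of the published design: no
covariate or ancestry adjustment (a mismatched case ancestry mix against a
pan-population control panel can masquerade as burden), no relatedness
pruning, and denominators reconstructed by an allele-number policy rather
than per-variant ANs (the published totals do not pin the exact rule; the
packaged count fixture bypasses the policy entirely, so the statistical
reproduction is policy-independent). Overlapping subsets are tested as
given, without cross-subset double-count correction, mirroring the
published stratification.
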