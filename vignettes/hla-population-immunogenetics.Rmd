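---
title: "Population immunogenetics of HLA blocks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population immunogenetics of HLA blocks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlapop)
```

# The scientific setting

The classical HLA loci (class I: *A*, *B*, *C*; class II: *DRB1*, the
composite *DRB3/4/5* slot, *DQA1*, *DQB1*, *DPA1*, *DPB1*) are the most
polymorphic genes in the human genome and sit in strong mutual linkage
disequilibrium (LD). In small, historically isolated populations -- the
setting this package is built for -- a handful of multi-locus haplotypes
("blocks" and conserved extended haplotypes, CEHs) can carry most of the
chromosome mass, observed homozygosity runs above Hardy-Weinberg
expectation because of inbreeding, and the ancestry of each block can be
read off reference panels from the continental ancestral groups.

`hlapop` implements the analysis chain such studies run: haplotype
frequency estimation, block/CEH linkage statistics, per-locus diversity
metrics, rule-based ancestry assignment, a permutation test for
*non-overlapping* allele associations, cross-population distance/tree/PCA
analyses, and the regression of HLA diversity on distance-from-Africa and
pathogen richness. A synthetic cohort generator stands in for deposited
genotype data so that every stage is testable offline.

# Nomenclature and resolution

Allele names are parsed into locus, 1--4 numeric name fields (leading
zeros preserved) and an optional expression suffix (`N`, `L`, `e1`, ...).
Design choices:

* **DRB3/DRB4/DRB5 are one composite locus** (`"DRB3/4/5"`). The three
  genes occupy alternative configurations of a single chromosomal slot;
  population tables list them in one column and use the token `NULL` for
  the structural absence of all three. `parse_allele("NULL",
  locus = "DRB3/4/5")` yields an allele-like *absent* state that passes
  through truncation unchanged.
* **Default working resolution is two fields.** Published tables print
  full-resolution sub-alleles but aggregate them onto bolded two-field
  parents for all downstream statistics; `truncate_name()` implements
  exactly that aggregation. Expression suffixes are retained on parse but
  dropped for two-field identity (a low-expression variant and its normal
  siblings pool); `keep_suffix = TRUE` opts out.
* Formatting then reparsing is the identity; truncation is idempotent and
  never pads.

Files are UTF-8 delimited text, comma or tab autodetected from the
header; haplotype strings join alleles with `~`, and writers emit
4-decimal frequencies, both conventions of the field's printed tables.

# The synthetic world

`synthetic_config()` states the world the tests assume rather than tuning
it: 218 unrelated subjects plus 36 typed family trios, nine loci, and a
22-haplotype ancestry-labelled pool (`default_haplotype_pool()`) whose
frequencies are patterned on the printed block tables of a strongly
endogamous Native American population -- near-rigid B~C pairing, a few
dominant CEHs, low class II diversity, and minority European / African /
Asian admixture haplotypes.

* **Inbreeding** is whole-haplotype identity-by-descent copying: with
  probability `F` the subject's second chromosome is a copy of the first.
  This population-level interpretation of consanguinity preserves the
  strong multi-locus LD (per-locus copying would break blocks). The
  default `F = 0.05` is the scale of the heterozygote deficit
  (`1 - OH/EH`, roughly 0.05 at HLA-B) reported for highly inbred
  isolates; no published value exists for the exact parameter, so the
  default was chosen once from that deficit and not revisited.
* **Trios** are generated without recombination, so family segregation
  can resolve phase exactly; `scramble_rate` creates recombinant
  chromosomes to exercise CEH-breaking.
* **Seeds**: every stochastic operation takes an explicit integer seed;
  one master seed spawns deterministic child seeds (kept below 2^31), so
  fixed seed means byte-identical output and adding one analysis never
  perturbs another's random stream.

The generator emulates haplotype-pool sampling only: no mutation,
no coalescent demography, no genotyping error. A green test therefore
establishes correctness of the estimators on pool-structured data, not
robustness to typing artifacts.

# Haplotype estimation

The estimator is the field's hybrid:

1. **Family segregation counting** (`count_phase_known()`): at each locus
   the transmitted parental allele is identified from Mendelian
   transmission; when unambiguous at every locus, both parental
   haplotypes are resolved and contribute one count each. Ambiguities are
   left to EM, never guessed; a child allele absent from the relevant
   parent is recorded as an inconsistency and the trio contributes
   nothing.
2. **Expectation-maximization** (`em_frequencies()`) on the unrelated
   remainder: the E-step distributes each subject's mass over
   phase-compatible haplotype pairs proportional to `2 f_i f_j` (or
   `f_i^2`), the M-step renormalizes expected chromosome counts. Only
   haplotypes compatible with at least one subject are enumerated
   (2^(k-1) pairs for k heterozygous loci), and candidates below
   `prune_threshold` (default 1e-7) are dropped between iterations --
   without ever removing a subject's last compatible pair. The
   log-likelihood is asserted non-decreasing at every iteration. EM on
   high-LD data is multimodal, so 5 seeded restarts are run (first from
   uniform, the rest from random initial frequencies); the best final
   log-likelihood wins, ties broken by lexicographic order of the
   estimate.
3. **The merge** (`combine_estimates()`): family-resolved chromosomes
   enter as fixed counts, EM mass is scaled to the remaining chromosomes,
   `frequency = (count + f_EM * 2N_EM) / 2N_total`.

Because study reports variously quote both the full set of typed
chromosomes and the complete-haplotype subset, tables always carry their
own `total_chromosomes` (2N) attribute and counts alongside frequencies;
the reader must surface both rather than assume one denominator.

# Linkage disequilibrium, blocks and CEHs

For a haplotype with frequency `h` and marginal frequencies `pA`, `pB`:

* `delta = h - pA * pB`;
* `delta_prime` is Lewontin's normalization, `delta / delta_max` with
  `delta_max = min(pA(1-pB), pB(1-pA))` for positive delta and
  `min(pA*pB, (1-pA)(1-pB))` for negative, clamped to `[-1, 1]` against
  rounding, and 0 when delta is 0;
* the **p-value** is a two-sided Fisher exact test on the 2x2 chromosome
  table (carrier vs non-carrier). The source studies do not name their
  test; Fisher was chosen for validity at the small counts typical of
  block tables, and a chi-square option is kept for comparison;
* the **t statistic** is `delta / sqrt(var(delta))` with
  `var = [pA(1-pA)pB(1-pB) + delta(1-2pA)(1-2pB) - delta^2] / 2N`.
  The t formula behind published tables is cited but never printed, and
  the common variance estimators do not reproduce those printed values;
  this implementation is therefore labelled a variant, validated only
  qualitatively (monotone in |delta| and in sqrt(2N)), with the
  conventional significance cutoff t >= 2.0.

`block_scan()` marginalizes a joint haplotype table onto block loci and
keeps haplotypes seen at least twice (`min_count = 2`, the printed-table
inclusion rule), sorted by descending frequency then haplotype string.
`extend_block()` treats each block as a composite allele, giving the CEH
statistics (B~C against DRB1~DQB1) and the HLA-A extension (A against the
4-locus CEH). All frequencies entering delta-prime come from unrounded
counts; comparisons against 4-decimal printed values tolerate 0.005.

# Diversity metrics

Per locus: observed heterozygosity (fraction of heterozygous subjects);
expected heterozygosity `EH = 1 - sum(p^2)` (plain estimator by default
-- it reproduces the published HLA-A value from the printed two-field
frequencies; the `2N/(2N-1)` unbiased factor is an option);
`PIC = 1 - sum(p^2) - [(sum(p^2))^2 - sum(p^4)]`; and
`PD = 1 - sum(G^2)` over *observed* genotype frequencies (forensic
convention; HWE-expected genotype frequencies can be supplied instead).
PIC is strictly below EH for any polymorphic locus, which the tests
assert on random frequency vectors.

The Hardy-Weinberg test is Monte-Carlo exact: the 2N observed allele
copies are repeatedly shuffled into N random pairs and the heterozygote
count (two-sided around its exact expectation under random pairing;
`statistic = "prob"` gives a Guo-Thompson-style conditional-probability
ordering instead) is compared with the observed value, with the
`(extreme + 1)/(steps + 1)` convention. The published default chain
length is 1e6 steps and is kept as the default; the test suite and the
acceptance script pass smaller explicit `n_steps` (400--2000), which
calibration tests show is ample for their cohort sizes, to stay inside
the runtime budgets.

# Ancestry assignment and aggregate block frequencies

A block is labelled with the continental group (Native American,
European, African, Asian) in which some reference panel carries it at
frequency >= 1% (two-field matching on the block's loci). When several
groups qualify, the highest maximum panel frequency wins -- the sources
do not specify a conflict rule, so this documented max-frequency rule
with a fixed precedence tie-break (NativeAmerican > European > African >
Asian) is this package's own choice. Mixed-ancestry panels never confer
a label; their support is reported separately, and a block supported
only there, or nowhere, is *NotPreviouslyReported*. ABF sums study
frequencies per label and conserves the included block mass exactly;
raising the threshold can only move blocks toward NotPreviouslyReported
(monotonicity, asserted in tests).

# Non-overlapping associations

The f* score asks whether alleles at two loci pair off into
near-exclusive partnerships. The original metric's formula is not
reproduced in the population literature that applies it, so `fstar()`
implements a documented stand-in: the fraction of haplotypes `(i, j)`
where each member is the modal partner of the other (mutual-best), with
a chance correction `(f* - e)/(1 - e)` where `e = max(p) * max(q)` is
the mutual-best fraction under an exactly independent joint (both loci
monomorphic gives `e = 1` and an adjusted score of 0 by convention).
The reported quantity, as in the source analyses, is the permutation
z-score: `permutation_null()` shuffles one locus's column (5000
permutations by default; marginals preserved exactly; which column is
shuffled is irrelevant by symmetry), and
`z = (observed - null mean)/null sd`. The z-ranking of locus pairs does
not depend on the score's absolute calibration, which is why the
stand-in is safe for the ranking claims the tests check (a rigid B~C
coupling always outranks loose class I / class II pairs).

# Cross-population analyses

* **DA distance**: `1 - (1/L) sum_loci sum_alleles sqrt(x y)` on
  outer-joined allele universes (absent = 0; published vectors summing
  below 0.995 are renormalized with a warning).
* **Neighbor joining** via `ape::nj`, with negative branch lengths
  clamped to zero. Bootstrap support (default 1200 replicates) resamples
  *alleles within loci* rather than loci: with only three loci the
  classic resample-loci unit is degenerate, and this departure from the
  tree-software default is deliberate and documented.
* **PCA**: column-centred SVD of the concatenated per-locus frequency
  vectors, unscaled (frequencies share units).

# The geography / pathogen-richness regression

Distances follow the waypoint convention of out-of-Africa diversity
models: the path from the East African origin is routed through fixed
waypoints rather than the direct geodesic. The five waypoints used by
prior compilations are not enumerated anywhere, so the defaults (Cairo,
Istanbul, Anadyr, Anchorage, Panama City -- an Africa exit, a Eurasian
bridge, a Beringian crossing and two American relays) follow that
routing's intent and are explicitly replaceable. Great circles use the
haversine formula with mean Earth radius 6371 km.

PIC values are logit-transformed before modelling. Outliers are
populations whose logit(PIC) at *any* analyzed locus lies beyond 2 SD of
that locus's mean -- single pass, computed once on the full data; the
sources do not say whether the rule re-iterates, and single-pass was
chosen as the simpler, order-independent reading. Models are ordinary
least squares of logit(PIC) on distance plus one richness measure, with
t-based 95% intervals; the Bonferroni family is the number of models
fitted in the run (locus x richness-measure x dataset). Richness values
are plain per-population numbers supplied as metadata: there is no
database client.

# Numerical conventions and degenerate inputs

* Frequencies entering any statistic come from unrounded counts;
  complete tables must sum to 1 within 1e-6, pools within 1e-9.
* LD on a monomorphic unit is undefined and reported as `NA` rows
  (flagged), never fabricated; `h > min(pA, pB)` beyond half-count slack
  is an error.
* Monomorphic loci give HWE p = 1 with a warning; a degenerate
  permutation null (sd = 0) reports an infinite or zero z with a
  warning; fewer than 2 permutations leave z as `NA`.
* Sorting everywhere is descending frequency, then lexicographic
  haplotype string, so printed tables are reproducible.

# Known limitations

* The t statistic is a variant (see above); printed t values from the
  source tables are not reproduced and are not asserted.
* Some published diversity rows are not derivable from the same papers'
  own printed frequency tables (most visibly DQA1/DPA1), plausibly a
  229- vs 218-subject dataset difference; such rows are documentation,
  not test oracles.
* The f*adj operationalization may differ from the original metric's
  (unpublished) form; only permutation-z-based conclusions should be
  compared across implementations.
* No genotype-uncertainty modelling, no missing-allele imputation, no
  G/P-group or allele-database validation, and no Ewens-Watterson
  neutrality test (an external confirmation step in the source studies,
  out of scope here).

# A worked miniature

```{r example}
cfg <- synthetic_config(n_subjects = 80, n_trios = 10, seed = 7)
sim <- simulate_cohort(cfg)
seg <- count_phase_known(sim$cohort)
em <- em_frequencies(sim$cohort[sim$cohort$role == "unrelated", ],
                     settings = em_settings(n_restarts = 2, seed = 7))
haps <- combine_estimates(seg$table, em)
head(block_scan(haps, c("B", "C")), 5)
diversity_summary(sim$cohort, loci = c("A", "B", "DRB1"),
                  n_steps = 2000, seed = 7)
```
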