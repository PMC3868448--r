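---
title: "Inferring a sodium-channel gene duplication from masked genotypes, crosses and qPCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring a sodium-channel gene duplication from masked genotypes, crosses and qPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navdup)
```

## The inference problem

Knockdown resistance (*kdr*) to pyrethroids in *Aedes aegypti* is tracked
through target-site mutations in the voltage-gated sodium channel gene
(NaV), notably Ile1011Met and Val1016Ile in the IIS6 region, together with
a third linked marker, the intron 20 sequence class ("A" or "B").  A
haplotype here is the joint state of one gene copy at these three markers;
only four of the eight combinations occur in the Brazilian field samples
this package models (`Ile+B+Val`, `Ile+A+Val`, `Ile+A+Ile`, `Met+A+Val`),
and the double mutant (`Met` with 1016 `Ile`) is excluded from the
population model because the two mutations arose independently on
non-recombining backgrounds.

Routine genotyping is allele-specific PCR, which reports, per site, only
which alleles are *present* — not how many copies carry them.  `navdup`
formalises this as a masking operator (`phenotype_of()`): a genotype is an
unordered pair of transmissible *chromosome units*, each either one
haplotype or a tandem *duplication* of two linked haplotypes, and its
molecular phenotype is the presence/absence union over all haplotypes.
The consequence driving everything else: a duplication pairing wild
`Ile+B+Val` with mutant `Met+A+Val` is typed `Ile/Met`, indistinguishable
from a true heterozygote, and a `Met/Met` call becomes unreachable for any
genotype built from that unit.  Three converging lines of evidence then
reveal the duplication:

1. **Population signature** — across localities, `Ile/Met + Val/Val`
   phenotypes are in excess of Hardy–Weinberg expectations and `Met/Met`
   is absent.
2. **Segregation** — crosses of `Ile/Ile` × `Ile/Met` parents throw 100%
   `Ile/Met` offspring when the `Ile/Met` parent is a duplication
   homozygote, and F2 broods of duplication heterozygotes segregate 1:3.
3. **Dosage** — TaqMan relative quantification shows the selected lineage
   carries many more copies of the region than the two expected of a
   single-copy diploid gene.

## Hardy–Weinberg analysis of masked phenotype tables

Population inputs are per-locality counts (or printed frequencies) of the
six two-site phenotype categories generated by the three canonical
single-copy haplotypes.  The analysis chain
(`analyze_population()`) is:

* **Count recovery.**  Published tables print proportions; counts are
  recovered as `freq * n` apportioned by largest remainder
  (`counts_from_frequencies()`), which inverts the printing exactly when
  the proportions were rounded from integers out of *n*.  Printed rounding
  slack up to 0.02 in the row sum is tolerated.
* **Haplotype frequencies.**  When every category decodes to a unique
  haplotype pair — true for the two- and three-haplotype single-copy
  models — gene counting applies: `p(h) = (2·hom + Σ het)/2n`.  For
  ambiguous sets the estimator is EM over the category→pair map (uniform
  start, convergence at max change < 1e-10, cap 1000 iterations); gene
  counting is its closed form and the two agree to 1e-9 where both apply
  (a property the tests assert, alongside a direct numerical likelihood
  maximisation as an independent check).
* **Expectations and fit.**  Category expectations are `p_i^2` and
  `2 p_i p_j` accumulated per category; the goodness-of-fit statistic is
  the usual `Σ (O − nE)²/(nE)` with the upper-tail chi-square p-value and
  no continuity correction.

**df convention.**  We use `df = k − 1`, where *k* counts the categories
of the haplotypes segregating in that sample (6 or 3), *without*
subtracting estimated parameters.  This is deliberate: it is the
convention that reproduces the published p-values (e.g. a two-haplotype
locality whose printed p matches df = 2 even where the printed df column
says 5).  Categories with zero expectation *and* zero observation
contribute 0 to the statistic but still count toward *k*; a positive count
in a zero-expectation category yields an infinite statistic with a
warning rather than an error.  A monomorphic sample (one category) returns
a vacuous fit (chi2 = 0, df = 0, p = 1).

Not every published row survives recomputation: a few printed expected
cells are internally inconsistent (column shifts and similar typesetting
damage), and one row's printed statistic differs from any value derivable
from its own printed frequencies.  The package always trusts
recomputation from the printed observed frequencies; the test suite pins
the rows whose printed cells are self-consistent.  Printed expected cells
were evidently computed from already-rounded frequencies, so agreement is
asserted to ±0.001 rather than exact 3-decimal equality.

## Cross segregation and the exact test

`cross_hypothesis()` encodes the three candidate constitutions of an
`Ile/Met` parent: **H1** plain heterozygote (no duplication), **H2a**
duplication homozygote, **H2b** duplication heterozygote.  Expected
offspring distributions come from convolving the parental gamete
distributions — each unit transmitted with probability 1/2, a duplication
transmitted intact — through the masking operator.  H1 and H2b both
predict 50:50 at site 1011, so they are intrinsically indistinguishable in
F1 (asserted as a property); only the all-`Ile/Met` prediction of H2a
discriminates.  The F2 check (`f2_segregation_test()`) uses the 1:3
`Ile/Ile`:`Ile/Met` expectation for offspring of two duplication
heterozygotes.

Comparing an observed brood with an hypothesis needs a concrete recipe the
source material does not spell out; ours is: render expected proportions
to integers by largest remainder (ties to the earlier category, which is
what reproduces the published (8, 22) rendering of 7.5/22.5), drop
categories empty in both rows, and run a two-sided Fisher exact test on
the resulting 2×2 observed-vs-expected table.  Two-sided means the
point-probability definition — the sum of hypergeometric point
probabilities not exceeding the observed table's (relative tolerance 1e-7
on the comparison) — stated explicitly because tail-doubling definitions
differ in general.  Tables with more than two non-empty categories are
refused rather than silently collapsed (they cannot arise in this model,
where `Met/Met` is unreachable).  A zero margin returns p = 1 with a
warning.  The implementation is checked against a from-first-principles
enumeration oracle and against `stats::fisher.test`.

One published verdict is knowingly not reproduced: the 9:9 brood tested
against H2a computes p = 0.00103 by every two-sided definition we tried,
a hair above the 0.001 threshold, so the package reports `**` where the
source prints `***`.

## Relative copy number (comparative CT)

Per replicate, ΔCT = CT(target) − CT(reference gene); per lineage × assay,
the mean and SD of ΔCT; per assay, ΔΔCT = μ[ΔCT](test) − μ[ΔCT](calibrator);
and finally `cn = cn_ref · 2^(−μ[ΔΔCT])` with `cn_ref = 2` for a diploid
single-copy calibrator.  The sign of the exponent deserves a note: more
template means *fewer* cycles, so extra copies produce a *negative* ΔΔCT,
and the printed form of the formula (without the minus) would send the
duplicated lineage below two copies; the published results (10 copies at
ΔΔCT −2.3) fix the intended convention, which is what we implement.
Amplification efficiency is fixed at 100% (one cycle = factor 2);
no efficiency-corrected variant is provided because none was used for the
numbers being reproduced.  Integer copy number rounds half away from
zero; full precision is kept internally and printed outputs round μ values
to one decimal.  `summarize_ddct()` enters the chain at the per-assay
μ[ΔCT] level (all that a published summary table provides);
`analyze_plate()` starts from well-level CTs.

## What the synthetic generators emulate — and what they do not

All generators take an explicit integer seed and are pure functions of
(scenario, seed), leaving the caller's RNG state untouched.

* `simulate_population()` draws each individual's two units independently
  from the declared unit frequencies (random union).  It emulates the HWE
  null over transmissible units, which is exactly what makes the
  duplication's phenotype-level heterozygote excess detectable.  It does
  **not** model selection, drift, migration, genotyping error or unequal
  crossing-over; a green recovery test establishes estimator correctness
  under the model's own assumptions, not robustness to their violation.
* `simulate_cross()` draws offspring gametes from `gametes_of()` —
  complete linkage of the duplication, no recombination, no viability
  differences.
* `simulate_clone_reads()` samples clones uniformly over haplotype
  *slots* (a duplication contributes two), so a wild/dup specimen shows
  its three haplotypes at 2:1 expected slot odds; errors flip one feature
  of a clone with the given probability.  Real cloning artefacts
  (chimeras, template switching) are not modelled.
* `simulate_qpcr()` adds iid Gaussian noise per well to CT values whose
  means encode log2 of the copy ratio — the simplest model consistent
  with published replicate SDs (0.03–0.11 cycles).  Propagating that
  noise through the 3-assay × 3-replicate design gives
  sd(μ[ΔΔCT]) = √(4σ²/9) ≈ 0.067 at σ = 0.1, so *exact* integer recovery
  of 10 copies has probability ≈ 0.72, not near-certainty; the test suite
  asserts that closed form rather than an optimistic round number.  At
  σ = 0 the round trip is exact for copies 2–12.  Between-pool biological
  copy-number variation defaults to off.

Default scenario values mirror the published designs: 3 assays ×
3 replicates for qPCR, ≥ 8 clones per specimen, the wild `Ile+B+Val` /
mutant `Met+A+Val` composition for the duplicated unit (any composition is
constructible via `dup_unit()`, anticipating that other duplication types
likely coexist elsewhere).

## Numerical and interface choices

* Haplotype strings parse case-insensitively (`"1011ile+b+1016val"`) and
  emit in canonical form; all eight haplotypes construct, with
  warning *flags* (not errors) outside the observed four, so model
  violations can be simulated deliberately.
* Within-duplication order is stored but never used (which copy is
  upstream is unknown); unit and genotype equality keys sort it away.
* Category identity is the pair of site calls; the intron call is carried
  alongside but does not define a category (population tables report it
  separately).
* Clone-classification rules are user-supplied JSON (motif or
  amplicon-length predicates per feature) because the diagnostic
  nucleotides are assay-specific and unpublished; the packaged rules and
  FASTA fixtures are synthetic and labelled as such.  JSON rather than
  YAML keeps the dependency footprint inside the declared stack.
* The CLI (`run_cli()`) exposes one subcommand per table kind plus
  `simulate`; every subcommand writes a full-precision CSV and a rounded
  text report and is byte-reproducible given inputs, options and seed.

## Known limitations

Nucleotide-level modelling of the intron indels and exon-20 synonymous
substitutions is out of scope (the diagnostic content is not published);
there is no exact HWE test, no F_ST or LD machinery, no likelihood-ratio
model selection across cross hypotheses, and no efficiency-corrected or
standard-curve qPCR quantification.  Copy-number variation among
individual insects — reported qualitatively in the source material — is
unquantified and defaults to off in the simulator.
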