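# navdup

Detecting a tandem duplication of the voltage-gated sodium channel (NaV,
*kdr* locus) gene in *Aedes aegypti* from three independent lines of
indirect molecular evidence, for medical-entomology and
insecticide-resistance researchers working with allele-specific PCR
(AS-PCR) genotypes, Mendelian crosses and TaqMan copy-number assays.

## The problem and the model

AS-PCR reports, per site, only the *set* of alleles present in an insect
— never dosage.  `navdup` models each gene copy as a haplotype
*(1011 allele, intron-20 class, 1016 allele)*, each transmissible
chromosome unit as either one haplotype or a tandem duplication of two
linked haplotypes, and the observable **molecular phenotype** of a diploid
genotype as the presence/absence union over all its haplotypes.  A
duplication pairing wild `1011Ile+B+1016Val` with mutant
`1011Met+A+1016Val` is therefore typed `Ile/Met` — indistinguishable from
a true heterozygote — and `Met/Met` becomes unobservable.  The package
implements the full inference chain built on that masking:

* **Hardy–Weinberg analysis** of six-category two-site phenotype tables:
  count recovery from printed frequencies (largest remainder), haplotype
  frequencies by gene counting with an EM generalisation
  (`p̂ᵢ` maximising the multinomial likelihood over category→pair maps),
  expectations `pᵢ²` / `2pᵢpⱼ`, and the fit statistic
  `χ² = Σ (O − nE)²/(nE)` with `df = k − 1`.
* **Cross segregation**: expected F1/F2 distributions under the
  no-duplication (H1), homozygous-duplication (H2a) and
  heterozygous-duplication (H2b) parental hypotheses via gamete
  convolution, compared with observed broods by a two-sided
  (point-probability) Fisher exact test on the observed-vs-expected 2×2.
* **Clone typing**: collapsing sequenced clones into per-specimen
  haplotype profiles; three haplotypes in one insect flags a duplication.
* **Relative copy number**: the comparative-CT chain
  ΔCT → μ[ΔCT] → ΔΔCT → `cn = cn_ref · 2^(−μ[ΔΔCT])`.
* **Seeded synthetic generators** for all four input kinds, and a CLI.

## Worked example

Population signature — a resistant field sample, n = 18, entered as the
printed phenotype frequencies:

```r
library(navdup)
apg <- analyze_population(freqs = c(0.056, 0, 0.222, 0.500, 0.222, 0), n = 18)
apg
#> Hardy-Weinberg analysis (n = 18 )
#>       category observed expected
#>  IleIle_ValVal    0.056    0.093
#>  IleIle_ValIle    0.000    0.204
#>  IleIle_IleIle    0.222    0.111
#>  IleMet_ValVal    0.500    0.221
#>  IleMet_ValIle    0.222    0.241
#>  MetMet_ValVal    0.000    0.130
#> chi2 = 14.7, df = 5, P = 0.0118
```

The `Ile/Met + Val/Val` class is at more than twice its HWE expectation
and `Met/Met` is absent — the population fingerprint of a masked
duplication.  Segregation: a brood of 20 that is 100% `Ile/Met` rejects
both 50:50 hypotheses and is compatible only with a duplication-homozygous
parent:

```r
classify_cross(c(`Ile/Ile` = 0, `Ile/Met` = 20))
#> Cross segregation (n = 20 )
#>  observed: Ile/Ile=0, Ile/Met=20
#>   H1             expected (10, 10)  P = 0.0004359  ***
#>   H2a            expected (0, 20)  P = 1  NS
#>   H2b            expected (10, 10)  P = 0.0004359  ***
#>  not rejected: H2a
```

Dosage: the packaged mean-ΔCT table (selected lineage EE, its F1 `Hyb`,
calibrator strain Rock) yields

```r
summarize_ddct(read.csv(system.file("extdata", "qpcr_mu_dct.csv",
                                    package = "navdup")))$per_lineage
#>  lineage mu_ddct sd_ddct cn_real cn
#>     Rock     0.0    0.00    2.00  2
#>       EE    -2.3    0.06   10.08 10
#>      Hyb    -1.7    0.06    6.35  6
```

i.e. ten copies of the region in the duplication-homozygous lineage and
six in the F1, against the calibrator's two — evidence not just of a
duplication but of further amplification.

The same analyses run from the shell, e.g.:

```sh
Rscript exec/navdup hwe \
  --input inst/extdata/population_phenotype_frequencies.csv \
  --output hwe_report.csv
Rscript exec/navdup cnv --input inst/extdata/qpcr_mu_dct.csv --output cnv.csv
Rscript exec/navdup simulate --scenario duplication --n 200 --seed 7 \
  --output simpop.csv
```

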