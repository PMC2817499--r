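# rlgsim — virtual Restriction Landmark Genome Scanning

`rlgsim` is an R package for simulating and analysing Restriction
Landmark Genome Scanning (RLGS) experiments in silico, aimed at
epigenomics researchers who use methylation-sensitive restriction
digestion to survey CpG methylation and its inheritance.

RLGS end-labels the cut sites of a rare-cutting landmark enzyme (NotI),
resolves the labelled fragments after a second digestion (MspI or its
methylation-sensitive isoschizomer HpaII) in a first gel dimension, then
digests in-gel with BamHI and resolves again in a second dimension. Every
landmark becomes a 2D spot whose intensity counts labelled DNA copies:

* 1D length = NotI cut → first cleavable MspI/HpaII or NotI cut
* 2D length = NotI cut → first cleavable BamHI cut inside the 1D extent
* intensity = 0.5 per contributing allele (1.0 = homozygous locus;
  a half-intensity spot is the heterozygote signature)

MspI cleaves C^mCGG while HpaII does not, and neither cleaves ^mCCGG or
^mC^mCGG, so [MspI]-vs-[HpaII] pattern differences report internal-CpG
methylation. The package covers the full analysis chain:

* **Digestion** — IUPAC-aware site scanning (Biostrings), per-site
  methylation states from a BED-like overlay, methylation-aware fragment
  walking per landmark and direction.
* **Spot patterns** — detection windows, log-linear mobility,
  copy-number intensities, deterministic co-migration merging.
* **Comparison** — spot matching, intensity classification
  (full / half / absent), methylation calls from combo differences.
* **Inheritance** — Mendelian class expectations from parental spot
  genotypes, exact binomial / exact multinomial segregation tests, BH
  correction, non-Mendelian flagging (e.g. a selfed panel of a
  heterozygote that stays entirely half-intensity).
* **Synthetic data** — planted N…B…M locus cassettes in screened random
  background, diploid parents with epialleles, reciprocal F1 and selfed
  panels under `mendelian`, `maintain_heterozygous` and
  `demethylate_progeny` transmission models, plus a packaged two-parent
  fixture emulating the rice Nipponbare × Kasalath spot-200 geometry.
* **CLI** — `inst/cli/rlgsim` with `simulate`, `digest`, `diff`,
  `segregate` and `run-all` subcommands over plain FASTA/TSV files.

## Worked example

```r
library(rlgsim)

fx <- nipponbare_kasalath_fixture(seed = 1)
pN <- diploid_pattern(fx$parent_N, "MspI")
subset(pN$spots, select = -loci)
#>          x1        x2 len_1d len_2d intensity n_loci
#> 1 0.7461028 0.4684485   1350    800       1.0      2
#> 2 0.5990269 0.3253983   2400   1400       0.5      1
#> 3 0.5220769 0.3253983   3243   1400       0.5      1
#> 4 0.4749203 0.1305784   3900   3000       1.0      2
#> 5 0.9647187 0.5533106    574    574       1.0      2
#> 6 0.6948069 0.3648026   1650   1200       1.0      2
```

The heterozygously methylated parent shows the focal 2400/1400 bp spot
at intensity 0.5: only the unmethylated allele is cut at the M site
(row 2), while the blocked allele runs through to the next cleavable cut
as a 3243 bp fragment (row 3). Background loci shared by both alleles
sit at 1.0. Selfing this parent under the methylation-maintenance model
keeps every progeny heterozygous:

```r
cls <- panel_spot_classes(fx$panels$selfed_N,
                          fx$focal$len_1d, fx$focal$len_2d)
table(cls$class)
#> half
#>    9
flag_non_mendelian(cls$class, spot_genotype(fx$parent_N),
                   cross_type = "self")
#>   locus n n_other count_absent count_half count_full expected_absent
#> 1 focal 9       0            0          9          0            0.25
#>   expected_half expected_full              test    p_value      p_adj
#> 1           0.5          0.25 exact_multinomial 0.01008606 0.01008606
#>              verdict
#> 1 non_mendelian_flag
```

Nine of nine half-intensity progeny are impossible to reconcile with the
Mendelian 1:2:1 expectation (exact multinomial p ≈ 0.0101), so the locus
is flagged as non-Mendelian — whereas a Mendelian simulation of the same
cross segregates the three classes and is not flagged.

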