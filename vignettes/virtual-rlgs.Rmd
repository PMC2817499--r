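---
title: "Virtual RLGS: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual RLGS: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlgsim)
```

## The method in brief

Restriction landmark genome scanning (RLGS) profiles thousands of genomic
loci at once by end-labelling the cut sites of a rare-cutting "landmark"
enzyme (NotI), resolving the labelled fragments by length after a second
digestion in a first gel dimension, digesting in-gel with a third enzyme
(BamHI) and resolving again in a second dimension. Each landmark fragment
becomes a spot whose intensity counts labelled DNA copies. Running the
second digestion with either member of the MspI/HpaII isoschizomer pair
turns the assay into a genome-wide CpG methylation survey: both enzymes
recognise CCGG, but when the internal cytosine is methylated (C^m^CGG)
MspI still cleaves while HpaII does not, and neither cleaves ^m^CCGG or
^m^C^m^CGG. A spot present in the [MspI] pattern but missing from the
[HpaII] pattern therefore reports internal-cytosine CpG methylation at
that site.

`rlgsim` reproduces this assay in silico on assembled (or simulated)
diploid genomes with per-allele methylation annotations, and adds the two
analysis layers the assay feeds: calling methylation differences between
patterns, and testing how spot classes segregate across progeny panels.

## Digestion model

Sites are found by IUPAC-aware scanning (Biostrings). All four built-in
enzymes have palindromic recognition sequences, so a forward-strand scan
is complete; user-defined non-palindromic enzymes are additionally
scanned on the reverse strand. Coordinates are 0-based half-open and a
fragment length is the difference of top-strand cut coordinates — the
few-nucleotide overhang asymmetry is far below gel resolution and is
ignored.

Each annotated site carries one of five methylation states
(`unmethylated`, `internal_C`, `outer_C`, `both_C`, `cpg_methylated`);
unannotated sites are unmethylated. Cleavability is a pure lookup in the
enzyme's sensitivity table. For every *cleavable* NotI landmark, the walk
in each direction ends at the first cleavable second-enzyme or NotI cut
(the 1D length) and, within that extent, at the first cleavable BamHI cut
(the 2D length). Blocked sites are transparent: the first cleavable cut
in walking order wins, so heterozygous blocking methylation lengthens one
allele's fragment rather than removing it.

Three modelling decisions here were genuinely open:

* **NotI methylation sensitivity.** RLGS surveys use NotI precisely
  because CpG methylation blocks it, so the default sensitivity table
  blocks NotI on `cpg_methylated` sites; `default_enzymes(notI_methylation_sensitive
  = FALSE)` disables this. The rice scenario the fixture emulates never
  methylates a NotI site, so the default is inert there.
* **`cpg_methylated` on CCGG sites.** The state is intended for
  non-CCGG sites, but the sensitivity tables must be total; both
  isoschizomers treat it as blocking (the conservative reading),
  which also preserves the invariant that HpaII-cleavable sites are a
  subset of MspI-cleavable sites.
* **Fragments that hit a chromosome boundary** (`sequence_end`) are
  excluded from patterns by default: physical genomic ends are blocked
  from labelling before the landmark digestion, and shear ends are
  unknowable in silico. `include_sequence_end = TRUE` restores them.

## Gel model and spot synthesis

The gel is reduced to what pattern comparison needs: per-dimension
detection windows (defaults 500–25,000 bp in 1D, 100–5,000 bp in 2D,
bracketing typical agarose/polyacrylamide resolution; the physical gel
geometry of the original protocol cannot be converted to base-pair ranges
without calibration data, so the windows are configuration) and a
normalised log-linear mobility `x = (log10(Lmax) − log10(L)) /
(log10(Lmax) − log10(Lmin))`. No Ogston/reptation physics: only relative
positions matter.

Each in-window fragment contributes the per-haplotype intensity quantum
0.5, so a locus present on both alleles gives 1.0 and a heterozygote
0.5 — the "half-intensity spot" that identifies heterozygosity in RLGS.
Fragments whose lengths agree within 1% (relative, both dimensions) are
merged by single linkage into one spot, with the representative lengths
taken from the first contributor in (chromosome, landmark, direction)
order — a deterministic stand-in for finite spot resolution. Fragments
with no internal BamHI cut run on the 2D diagonal and are kept by
default, as uncut fragments do in the in-gel digestion.

## Pattern comparison and methylation calls

Spot matching is greedy nearest-neighbour under the same 1% relative
length tolerance (length-based rather than gel-distance-based, so
comparisons are independent of the gel parameterisation), with
deterministic tie-breaking. Intensity classes (`full`, `half`, `absent`,
`other`) are bands around 1 and 0.5 of a baseline, default the modal
spot intensity of the pattern — the in-silico analogue of judging a spot
against its surrounding spots. The original analysis never quantified
its halving threshold; the 10% default tolerance is this package's
choice.

`msp_hpa_diff()` encodes the isoschizomer logic: [MspI]-only spots are
`internal_C_methylated` (homozygous at full, heterozygous at half
intensity), [MspI] full with [HpaII] half is the heterozygous call, and
equal intensity in both is unmethylated. Joint absence is *not callable
from patterns alone* — blocking methylation and sequence polymorphism are
indistinguishable without site-level confirmation — so such loci are
reported as `blocked_or_absent` only when a methylation-ignorant
reference pattern of the same genome is supplied.

## Segregation analysis

A locus is summarised per parent as which of the two alleles produce the
spot. Gametes carry either allele with probability 1/2, giving class
probabilities over {absent, half, full} for an outcross or selfing;
1:1 (half:absent) for a heterozygous producer crossed to a non-producer
and 1:2:1 for a selfed heterozygote are the canonical cases.

Observed class counts are tested exactly. Two classes use the two-sided
exact binomial; three or more use an exact multinomial under the same
two-sided rule (sum the probabilities of all outcomes no more probable
than the observed one, with a 1e-7 relative tie tolerance). The
multinomial is enumerated fully up to n = 20 and sampled (fixed,
reported seed) beyond that; it reduces exactly to the binomial when
classes collapse to two. Note that the p-value for the flagship
observation — nine of nine selfed progeny of a heterozygous parent all
half-intensity — is about 0.0101, not the (1/2)^9 ≈ 0.00195 probability
of the observed outcome itself, because other outcomes are at least as
extreme; either way the locus is flagged at α = 0.05.

Benjamini–Hochberg correction is applied across loci within a run
(the original analysis reported no multiplicity handling, but a default
must exist); `other`-classified individuals are excluded from the test
and surfaced in a QC column.

## The synthetic-data generator

The generator is first-class: it defines the study conditions the tests
and the acceptance script run under.

`build_locus()` plants an N…B…M cassette with declared cut-to-cut
spacings in uniform random background. The cassette span ±100 bp is
screened free of accidental NotI/CCGG/BamHI motifs (accidental sites
elsewhere are deliberately kept — they form the shared background
pattern); the 100 bp guard also guarantees that a methylation-blocked
allele's run-through fragment is >1% longer than the planted fragment
and therefore can never merge with, or match to, the focal spot.

`nipponbare_kasalath_fixture()` packages the two-cultivar scenario: one
~27 kb chromosome with three unmethylated background cassettes plus the
focal cassette at the published geometry's spacings (1400/1000 bp, i.e.
a 2400 bp 1D fragment cut to 1400 bp in 2D). The first parent is
B-present/B-present with the M site heterozygously `outer_C`-blocked —
focal spot at half intensity in *both* combos, since outer-cytosine
methylation blocks both isoschizomers. The second parent carries a
single point substitution disabling the BamHI site (GGATCC→GGATCA) on
both alleles — focal spot absent. Everything else is byte-identical
between parents, so every non-focal spot matches.

Crosses are simulated under three transmission models. `mendelian` draws
one (allele, epiallele) pair per parent per individual. `maintain_heterozygous`
keeps allele transmission Mendelian but re-establishes heterozygous
M-site methylation (with probability `maintenance_prob`, default 1) in
progeny carrying the focal spot-capable allele from the
methylation-heterozygous parent, reproducing the parent's half-intensity
configuration — this is a phenomenological stand-in for the observed
behaviour; the assay cannot distinguish maintenance from
re-establishment, and the model name should not be read mechanistically.
`demethylate_progeny` erases the focal epiallele. All simulation is
byte-reproducible from (inputs, seed).

What the generator does *not* emulate: whole-genome scale (thousands of
spots), partial digestion, spot-shape/exposure effects, recombination,
and more than one focal epilocus per fixture (composition covers
multi-locus needs). Passing tests therefore show the digestion logic,
intensity bookkeeping and inference are correct under controlled
geometry — not that the defaults are tuned for any particular real
genome.

## Problem sizes used in the checks

The packaged checks run the fixture end-to-end at the sizes the study
design implies: reciprocal F1 and selfed panels of nine individuals;
1:1 segregation verified on a 2,000-individual Mendelian F1 panel
(accepted within three binomial standard errors); oracle equivalence of
the fragment walker against a literal three-step digestion on 200 random
5 kb genomes with random overlays; and type-I control of the flagging
rule on 500 replicate Mendelian selfed panels of nine (nominal α = 0.05,
observed rate required ≤ 0.07). The exact multinomial is enumerated, not
sampled, at these panel sizes.

## Worked example

```{r example}
fx <- nipponbare_kasalath_fixture(seed = 1)
fx

# the heterozygously methylated parent: focal spot at half intensity
pN <- diploid_pattern(fx$parent_N, "MspI")
subset(pN$spots, select = -loci)
spot_intensity_at(pN, fx$focal$len_1d, fx$focal$len_2d)

# maintenance selfing: all nine progeny half-intensity, locus flagged
cls <- panel_spot_classes(fx$panels$selfed_N, fx$focal$len_1d, fx$focal$len_2d)
table(cls$class)
flag_non_mendelian(cls$class, spot_genotype(fx$parent_N), cross_type = "self")
```

## Known limitations

* Intensities are exact copy-number multiples of 0.5; there is no noise
  model, so intensity classification on real densitometry would need a
  calibrated tolerance.
* The co-migration/matching tolerance is a single relative-length
  number; real gels distort non-uniformly.
* Pattern-only comparison cannot attribute joint absence (see above);
  the `blocked_or_absent` call requires a reference genome digest.
* NotI–NotI fragments are double-labelled in the physical assay but
  counted at one intensity quantum per landmark-direction here; noted as
  a simplification.
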