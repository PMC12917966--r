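---
title: "Chloroplast SNP kinship analysis: models and methods"
author: "cpKin authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chloroplast SNP kinship analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpKin)
```

## The scientific problem

In Pinaceae the chloroplast genome is transmitted paternally, through
pollen, and does not recombine. A progeny's chloroplast haplotype should
therefore be an exact copy of its pollen parent's, apart from exceedingly
rare de novo mutations. This makes chloroplast SNP haplotypes a natural
instrument for verifying controlled crosses in conifer breeding programmes:
a progeny whose haplotype differs from its recorded father's was either
mislabelled, fathered by stray pollen ("pollen contamination"), or -- very
rarely -- affected by maternal leakage or mutation. cpKin implements the
full chain of inference: homoplasmic SNP calling from aligned reads, a
compact samples-by-loci genotype matrix, haplotype-distance parentage
classification, statistics that weigh the competing explanations, and a
distance-based tree of the resulting haplogroups. A synthetic-pedigree
simulator generates every input with known truth, so the whole chain is
testable with no external data.

## SNP calling model

Calling operates per sample on a pileup of aligned short reads and applies
four filters in sequence:

1. **Read filter.** Only uniquely and properly paired reads are used:
   mapping quality $\ge 20$, SAM proper-pair flag set, secondary and
   supplementary alignments excluded. MAPQ is used as the uniqueness
   signal; reads a mapper places ambiguously receive low MAPQ.
2. **Base filter.** Bases with Phred quality $< 20$ are removed from the
   pileup column.
3. **Depth filter.** Columns with post-filter depth $< 3$ are *missing*
   (`N`). The depth threshold is applied after the base-quality filter, so
   "depth" always means usable evidence; this is the stricter of the two
   possible orderings and is a deliberate choice.
4. **Homoplasmy filter.** A genotype is accepted only when the major base
   accounts for at least a fraction $h$ of the column (default
   $h = 0.9$). Chloroplasts are present in many copies per cell; a mixed
   column indicates heteroplasmy, contamination or mapping error, and the
   site is excluded (`N`) rather than called. The default tolerates a
   $\le 10\%$ minor allele, consistent with the detection limit of clean
   Sanger chromatograms (about 10--15%), which is how such calls are
   typically validated. Exact ties for the major base are excluded too --
   never resolved arbitrarily -- so calling is order-independent.

Only substitutions are called; a column whose majority evidence is an
indel or non-ACGT base is treated as missing. All coordinates are 1-based
on the forward strand of the reference.

## The genotype matrix and its missing-data policy

Per-sample calls are assembled into a samples $\times$ loci matrix in a
compact encoding: `-` for the reference base, the alternative base letter
for a substitution, `N` for missing or heteroplasmy-excluded calls. Loci
are biallelic by construction; conflicting alternative bases across
samples raise a multi-allelic error (or drop the locus in pipeline mode).

Comparisons use the **N-as-reference policy**: an `N` is treated as the
reference state, so every locus is comparable in every pair of samples.
The alternative `PAIRWISE_DELETE` policy (skip loci where either sample is
`N`) is available as a switch for sensitivity analysis. N-as-reference
maximises power on sparse panels but can hide a true mismatch behind a
missing call -- see *Limitations*.

The locus filter retains loci whose **alternative-allele frequency** is at
least 5% with at least 3 carriers. The filter deliberately measures the
frequency of the substitution relative to the reference rather than the
folded minor-allele frequency: near-fixed loci, where nearly every sample
carries the alternative base and the *reference* allele is the rare one,
represent fixed differences between the study germplasm and the reference
accession and are retained. (A folded MAF $\ge 5\%$ rule would silently
drop them: 1 reference carrier among 54 samples is 1.9%.)

Loci are annotated against a feature table of 1-based closed intervals. A
position inside a gene is GENIC (overlapping genes are joined with `/` and
counted once, keeping the genic/intergenic partition exact); a position
between genes is INTERGENIC and labelled `upstream ~ downstream` by its
flanking features. Positions outside the annotation span are an error
rather than a guess.

## Parentage classification

The haplotype distance between two matrix rows is the number of differing
loci after applying the missing-data policy; it is symmetric, zero on
identical rows, and satisfies the triangle inequality. Clones genotyped as
multiple ramets are first collapsed to a per-locus majority consensus;
loci where ramets disagree are reported as conflicts and excluded from
that clone's comparisons, so one mislabelled or miscalled ramet cannot
poison a whole family's classification.

Each progeny is compared with every sampled clone and classified in order
of precedence, a "match" being distance $\le$ `maxMismatch` (default 0):

| mode | meaning |
|---|---|
| `PATERNAL_MATCH` | matches the recorded father -- the expected outcome |
| `MATERNAL_MATCH` | matches the mother instead: candidate maternal leakage |
| `ALTERNATE_FATHER` | matches exactly one other sampled clone, the probable true pollen donor |
| `AMBIGUOUS` | matches several other clones (tie set reported) |
| `NOVEL` | matches nobody sampled: contamination by an unsampled male, or an unsampled recorded father |

`maxMismatch = 0` is the right default because de novo mutation is
negligible on this scale: with a chloroplast substitution rate of
$\mu \approx 2 \times 10^{-10}$ site$^{-1}$ yr$^{-1}$, a 121 kb haplotype
and a generation time of $g$ years, the expected number of new mutations
per transmission is $\lambda = \mu L g$. The generation time of the
breeding cycle is not something the package can know; it is an explicit
parameter, with 25 years as the default -- a typical conifer breeding
generation -- giving $\lambda \approx 6 \times 10^{-4}$, and any plausible
$g$ keeps $\lambda$ far below 0.02. `expectedDeNovo()` reports $\lambda$
and the Poisson tail $P(\ge k)$ so a user who *does* want to tolerate
mismatches can size `maxMismatch` rationally ($P(\ge 3)$ is of order
$10^{-11}$: three or more private SNPs in one progeny are never mutation).

Whether widespread discordance can be *leakage* rather than contamination
is tested with an exact upper-tail binomial test (`leakageTest()`): the
probability of observing at least the seen number of father-discordant
progeny if each progeny independently leaked with probability 1% (the
upper end of reported organellar leakage rates in conifers). The test is
exact, not a normal approximation, because progeny arrays are small
($n = 45$ in the motivating design).

## Haplogroup trees

The concatenated SNP matrix is summarised as pairwise mismatch distances
and clustered by neighbor-joining. NJ is used deliberately instead of a
likelihood tree search: with a 19--32 locus panel the tree serves to
display haplogroup membership, not to estimate evolutionary parameters,
and NJ on mismatch distances is exact on additive inputs and wholly
reproducible. Negative branch lengths (an NJ artefact on non-additive
input) are clamped to zero; zero-length internal branches can be
collapsed so identical haplotypes form honest polytomies. Support values
come from resampling loci (matrix columns) with replacement, rebuilding
the tree, and counting bipartitions -- the standard phylogenetic
bootstrap, seeded for reproducibility. Identical haplotypes are kept as
separate leaves so every sample is visible in the display. Because the
panel is tiny and invariant context is discarded, these supports are not
comparable with supports computed by other programs on other matrices;
they order clades by stability, nothing more.

## The synthetic-pedigree generator

`simulationConfig()` fixes the study conditions; the defaults describe the
motivating design and are not tuned per analysis:

| parameter | default | meaning |
|---|---|---|
| `nMothers` x `nFathers` | 9 x 5 | factorial tester design (45 progeny) |
| `genomeLength` | 121,000 bp | chloroplast genome scale |
| `nPolymorphicSites` | 32 | biallelic panel segregating among parents |
| `contaminationRate` | 0.2 | progeny fathered by an unsampled external male |
| `leakageRate` | 0 | maternal transmission |
| `deNovoMu` | 2e-10 /site/yr | chloroplast substitution rate |
| `generationYears` | 25 yr | breeding-cycle generation time |
| `depthMean` | 12.3x | mean sequencing depth |
| `readLength` / `insertSize` | 150 / 350 bp | paired-end read geometry |
| `baseErrorRate` | 0.001 | per-base sequencing error (~Q30) |
| `fracLowMapq` | 0.05 | pairs emitted low-MAPQ and not properly paired |
| `fracLowBaseq` | 0.02 | bases below the Q20 filter |

Transmission is whole-haplotype: each progeny copies its donor (father,
mother with probability `leakageRate`, or a member of a distinct external
donor pool with probability `contaminationRate`) and then receives
$\mathrm{Poisson}(\mu L g)$ de novo substitutions at uniform positions.
Reads are drawn at uniform fragment positions with independent per-base
errors. The generator emulates what the pipeline's filters need to see --
low-MAPQ and improperly paired reads, sub-threshold base qualities,
Poisson depth fluctuation and natural coverage gaps -- and deliberately
omits features of real data that the analysis does not model: indels and
rearrangements, the inverted-repeat duplication, reference bias, mapping
ambiguity between organelle and nucleus (numts), PCR duplicates, and
GC-dependent coverage. Passing tests therefore demonstrate the
correctness of the *inference machinery* under the stated model, not
robustness to every artefact of a real sequencing run. Circularity is
recorded on the reference but simulated reads never span the origin; with
fragments of 350 bp on a 121 kb molecule this discards a negligible
sliver of coverage and keeps every read's coordinates simple.

## Numerical and degenerate-input choices

* Ties: a tied majority base in a pileup column is `N`; a tied ramet
  majority is a masked (`NA`) consensus locus; tied zero-distance donors
  give `AMBIGUOUS`, never an arbitrary pick.
* An all-zero distance matrix yields a star tree; two-sample matrices are
  refused for tree building (`insufficient samples`).
* Empty inputs fail fast with the offending path or field named; an empty
  read set is legal and gives zero breadth, not an error.
* All randomness flows through explicit integer seeds; re-running any
  simulation or pipeline configuration reproduces byte-identical outputs.
* Probabilities use exact forms (`ppois`, `binom.test`) -- no normal
  approximations anywhere.

## Problem sizes used in examples and tests

The packaged demonstration pipeline simulates a 13 x 10 parental design
with 54 progeny on a 20 kb reference at 12.3x -- the cohort geometry of a
realistic discovery population on a reference short enough that the whole
example runs in well under a minute; every per-bp quantity scales
linearly with genome length, so nothing scientific depends on the
shortened molecule. Statistical recovery checks use 500--100,000
simulated progeny as each property requires. The packaged 75-sample
tester-design object (`testerDesignFixture()`) is a synthetic
reconstruction of a published design's *structure* (family sizes, shared
and conflicting haplotypes), built in code and labelled synthetic; it
exercises the classifier against known narrative truth but contains no
measured genotypes.

## Limitations

* With `maxMismatch = 0`, a single miscalled or missing cell puts a true
  paternal progeny into `NOVEL`: under the N-as-reference policy a
  progeny `N` at a locus where its father carries the alternative base
  counts as a mismatch. At 12x depth with realistic error rates a few
  percent of progeny are affected; the match report's distance columns
  make such one-off cases easy to audit, and `PAIRWISE_DELETE` or
  `maxMismatch = 1` are the appropriate sensitivity analyses.
* Parentage is exclusion-based, not likelihood-based: the package
  deliberately does not compute CERVUS-style LOD scores or exclusion
  probabilities, and a haplotype shared by two candidate fathers cannot be
  resolved (reported as `AMBIGUOUS`).
* The chloroplast is a single non-recombining locus: all progeny of one
  pollen parent are expected to be identical, so the method verifies
  paternity only. Maternal pedigree errors are invisible except through
  leakage.
* Annotation is coordinate-literal: a locus inside the inverted repeat is
  annotated at its stated coordinate only, and codon-level consequences
  are out of scope.
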