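---
title: "Simulating genome editing and carrier selection against polygenic deleterious load"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating genome editing and carrier selection against polygenic deleterious load}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`ragesim` simulates a closed animal breeding population — pig-like in size
and pedigree structure — that carries polygenic deleterious load while
being artificially selected for a quantitative breeding goal. Two traits
with independent genetic architectures act simultaneously:

* **Breeding goal.** A polygenic additive trait: 10,000 quantitative trait
  loci (1000 per chromosome at full scale) with effects $a_i$ drawn i.i.d.
  from $N(0, 1)$, or optionally magnitudes from a Gamma distribution with
  shape 11 and a random sign. The true breeding value of an individual is
  $\sum_i a_i d_i$ over QTL dosages $d_i \in \{0, 1, 2\}$. Because parents
  are chosen by rank-based truncation on true breeding values, the effect
  scale is free; we use unit scale.

* **Fitness.** A polygenic multiplicative trait representing survival to
  selection age: 10,000 fitness loci whose derived allele is deleterious
  with selection coefficient $s_i$ and shared dominance coefficient $h$.
  Genotype fitness at one locus is $1$, $1 - h s_i$, or $1 - s_i$ for
  dosage 0, 1, 2, and individual fitness is the product over loci,
  $w = \prod_i f(d_i, s_i, h)$. Selection coefficients come from a uniform
  mixture with equal thirds: small ($0 < s < 10^{-4}$), intermediate
  ($10^{-4} < s < 0.1$) and large ($0.1 < s < 1$). $h = 0.5$ is the
  codominant setup, $h = 0$ the recessive one; intermediate values are
  accepted. Fitness loci are sampled among loci with founder derived-allele
  frequency below 0.01 (codominant) or 0.1 (recessive), disjoint from the
  QTL.

Recurrent deleterious mutation acts at $10^{-4}$ per fitness locus per
individual: each new individual receives, per locus, with that
probability, a flip of one uniformly chosen wild-type allele copy. With
10,000 fitness loci this yields one expected de-novo deleterious mutation
per individual and genome; there is no back mutation and QTL never mutate.

## The breeding program

Each replicate runs three phases (generation counter to 45 at defaults):

1. **Burn-in, natural selection only** (15 generations): viability
   selection — each individual survives with probability $w$ — followed by
   random mating: 1000 matings per generation for 5 generations, then 500
   for 10, with 10 progeny per mating. The 10-progeny litter keeps cohort
   sizes (10,000 then 5,000) continuous with the later phases; the
   founder cohort is 2000 diploids assembled from the founder haplotype
   panel.
2. **Historical breeding** (20 generations): viability selection, then
   truncation selection of 25 sires and $n_{\text{dams}} =
   \lceil 5000 / (10\,\bar w_{\text{ref}}) \rceil$ dams on true breeding
   value, where $\bar w_{\text{ref}}$ is the mean fitness of the cohort
   entering historical breeding, frozen per replicate. Each dam is paired
   with one uniformly drawn sire and has 10 progeny. Cohort size then
   fluctuates with deleterious load around the 5000 target.
3. **Future breeding** (10 generations): as historical breeding, plus one
   intervention scenario. All scenarios of a replicate restart from the
   same snapshot taken at the end of historical breeding and from the same
   re-derived random stream, so scenario contrasts are paired.

Meiosis is Poisson: per chromosome (1 Morgan), the crossover count is
Poisson(length), breakpoints are uniform, there is no interference, and
the starting strand is a fair coin. Sexes are independent Bernoulli(1/2).
Generations do not overlap. Ties in truncation selection break by
ascending id.

Mutation is applied in all three phases by default; the reading that it
acts only through historical breeding is available via
`phasePlan(mutationPhases = c("burn_in", "historical"))`.

## Interventions

**Discovery.** At the end of historical breeding, with discovery rate $d$
and $S$ segregating deleterious variants, the discovered panel holds
$\operatorname{round}(d S)$ true deleterious loci (round half up) and
$S - \operatorname{round}(d S)$ false positives drawn from neutral
segregating loci, and is frozen for the whole future phase.

**RAGE** (removal of alleles by genome editing). Each future generation,
after sire selection, every selected sire is edited to homozygous wild
type at up to $k$ panel variants ($k \in \{1, 5, 20\}$), walking a
priority list and skipping variants the sire does not carry; only
variants segregating in the population are edited, and editing is
error-free and germline. Five prioritization strategies order the list:
descending allele frequency, ascending allele frequency, descending
homozygote-deficit score $p^2 N - \text{observed homozygotes}$, descending
frequency after excluding variants above 0.25 (intermediate), and a
random order drawn once per replicate and shared by all sires and
generations. Editing mortality $m$ kills each edited sire independently
and replaces it, in breeding-value rank order, with an unedited
lower-ranked candidate.

**Selection against carriers.** Before sire selection, the $n$ male
candidates with the highest deleterious load over the panel are removed
($n \in \{100, 250, 500\}$ at full scale), with load counted as total
allele count, heterozygous-only, or homozygous-only; ties at the cutoff
remove the higher id first.

Prioritization frequencies and homozygote counts are recomputed each
future generation on the post-viability candidate cohort. The
alternative — computing them on the 25 selected sires only — is exposed as
`editPolicy(freqSource = "sires")`; with 25 sires the frequency grid is
too coarse for the 0.25 threshold to act as intended, which is why the
cohort is the default reference.

## Founder haplotypes

Founders come from a forward Wright-Fisher burn-in at locus resolution:
candidate loci are placed uniformly on the 10-Morgan genome, an
all-wild-type population of size $N_e$ evolves for $10 N_e$ generations
under one-way mutation and Poisson recombination, and the founder panel is
drawn as fresh gametes from the final generation (so panels larger than
$2 N_e$ haplotypes are possible, as when a coalescent samples many
lineages). Candidate loci that segregate in the panel are downsampled to
the requested count. The default history is a constant $N_e$ of 100 — the
present-day size of the piecewise schedule, which is also representable
and stepped through explicitly, but is impractical to run forward at its
ancient sizes.

Two numerical choices matter here:

* The per-locus mutation rate is kept at $\theta = 4 N_e \mu = 0.01$.
  Larger $\theta$ lets independent recurrent mutations overlap at one
  locus; the merged trajectories inflate high frequencies and the
  spectrum drifts away from the neutral $1/i$ law. At $\theta = 0.01$ the
  panel spectrum is statistically indistinguishable from $1/i$
  (goodness-of-fit in the test suite), at the price that only about 5% of
  candidates segregate — hence the default 30-fold candidate
  oversampling.
* The panel must contain enough loci below the founder-frequency ceiling
  for the fitness trait. The generator sizes the candidate set as
  $n_{\text{QTL}} + n_{\text{neutral}} + \lceil 1.5\, n_{\text{fit}} /
  F(\text{ceiling}) \rceil$, where $F$ is the expected fraction of
  segregating loci below the ceiling under the $1/i$ spectrum
  ($H_c / H_{n-1}$); the factor 1.5 absorbs sampling fluctuation. Loci
  assigned to neither trait form the neutral pool from which
  false positives are drawn — the analogue of the abundant neutral
  variation in whole-genome sequence.

Panels can equally be imported from a haplotype-matrix TSV or a diploid
biallelic VCF (`importHaplotypes()`); imported and simulated panels are
interchangeable.

## What the generator does and does not emulate

The generator reproduces the features the interventions react to: a
neutral-like founder frequency spectrum, rare deleterious variants whose
frequency distribution is reshaped by dominance during historical
breeding (codominant variants stay rare; recessive ones drift to
intermediate frequencies), mutation-selection balance, linked inheritance
on a 10-Morgan genome, and load decomposable into heterozygous and
homozygous parts. It does not emulate: nucleotide-level mutation models or
bp-resolution variation outside the chosen loci, a sequential-coalescent
demographic history (the ancient piecewise sizes are impractical
forward-in-time), variable dominance across loci, pleiotropy between
fitness and the breeding goal, overlapping generations, or genomic
(estimated-breeding-value) selection — selection acts on true breeding
values. Passing tests therefore show that the interventions behave as
expected under these idealized conditions, not that their effect sizes
transfer quantitatively to real breeding programs.

## Scales, seeds and problem sizes

Two presets fix the study conditions. `paperPreset()` is the full scale:
10,000 + 10,000 loci, 4000 founder haplotypes, 25 sires, target population
5000, 50 replicates — a scenario grid at this scale is an overnight batch
job, not an interactive run. `deskPreset()` scales loci by 1/10 (1000 QTL,
1000 fitness loci, 1000-locus neutral pool) and the population by 1/5
(400 founder haplotypes, 200 then 100 burn-in matings, target 1000, 10
sires), keeping all rates and thresholds identical; the scale factors are
recorded in the configuration. The desk preset is what the test suite and
the acceptance script run: a full replicate takes seconds. Desk-scale
absolute numbers (segregating counts, loads, distinct edits) are reported
at their own scale and are not the full-scale values — and, as detailed
under limitations below, the desk population is small enough that the
frequency structure separating the prioritization strategies is itself
altered.

Replicate seeds derive deterministically from one master seed
(`replicateSeeds()`), every scenario of a replicate shares the replicate
seed and the historical snapshot, and the future phase reseeds from a
stream derived from the replicate seed so that baseline and intervention
futures start from identical states. Reruns under the same master seed
are bit-identical.

## Numerical and degenerate-case conventions

* Viability selection survives on `u <= w`; an empty survivor set is legal
  (and fatal only when a later step needs parents).
* `round(d S)` uses round-half-up; the panel errors if the neutral pool
  cannot supply the false-positive quota.
* Frequency ties in prioritization break by ascending locus index; the
  random strategy ignores frequencies entirely.
* Editing skips loci fixed in the reference cohort (frequency 0 or 1).
* Lethal alleles ($s = 1$) make derived homozygotes exact zeros in the
  fitness product; no logarithms are involved.
* The load summary counts all true fitness loci, including fixed ones;
  the segregating count reported alongside excludes them.

## Known limitations

Desk-scale populations drift much faster than full-scale ones: with 10
sires per generation the realized effective size during historical
breeding is a few dozen, so more deleterious variants fix (inflating the
homozygous load floor that editing cannot reach, since fixed variants are
never edited) and segregating counts fall well below a proportional
scaling.

This has a qualitative consequence for the strategy comparison. The
separation of prioritization strategies rests on a frequency structure:
deleterious variants held below intermediate frequencies by selection,
neutral false positives drifting higher. With the full-scale population
structure this holds (in our runs, about 1% of segregating recessive
deleterious variants exceed the 0.25 threshold, while false positives
have a median frequency near 0.2). At desk scale it does not: around 15%
of segregating recessive deleterious variants drift above 0.25, so the
intermediate-frequency strategy excludes variants that carry most of the
mean-fitness burden and high-frequency prioritization comes out ahead —
the reverse of the full-scale ranking; in the codominant desk case the
few surviving deleterious variants sit at one-or-two-copy frequencies
that sires rarely carry, most realized edits land on false positives, and
the strategies become statistically indistinguishable. The desk preset is
therefore suitable for exercising the machinery, invariants and paired
contrasts, not for reading off the full-scale strategy ranking; that
ranking requires the full population structure (an overnight grid).

The homozygote-deficit strategy inherits the full-scale result that it
does not outperform intermediate-frequency prioritization, and its scores
are noisier still in small cohorts. The stepped-demography founder
backend honors piecewise histories only at their recent, small sizes
within practical time.
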