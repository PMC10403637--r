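---
title: "Mining rare haplotype patterns by iterated chromosome overlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining rare haplotype patterns by iterated chromosome overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplomine)
```

## The problem

Genome-wide association studies report common "hit" variants whose modest
effects may in part be *synthetic*: a tag for rarer haplotypes of much
larger effect carried on a subset of hit-bearing chromosomes.  Testing that
hypothesis requires enumerating the haplotypes -- combinations of alleles on
one and the same phased chromosome, possibly *noncontiguous* -- that case
chromosomes share.  An $m$-SNP window holds $3^m - 1$ potential patterns,
so exhaustive enumeration is hopeless; but almost all of those patterns
never occur, and among those that do, many pick out exactly the same set of
chromosomes.  Closed-pattern mining exploits this: a pattern is **closed**
if it is the longest pattern shared by some group of chromosomes
(equivalently, the intersection of that group), and every observed pattern
has the same carriers as its **closure**, the shortest closed pattern
containing it.  Testing one closed pattern per carrier set tests everything
the data can distinguish.

## The overlap engine

`haplomine` implements a *top-down* closed-pattern miner.  Writing a
chromosome as the vector of its alleles at $m$ biallelic SNPs, the
**overlap** of $\sigma$ chromosomes is the set of (SNP, allele) pairs on
which they all agree.  Starting from the unique case haplotypes (iteration
0), each iteration forms overlaps of the current active set, discards
duplicates, purges patterns discovered at earlier iterations (merging their
comprising sets), and continues until an iteration yields nothing new.  The
*add-one property* guarantees completeness: any meta-chromosome comprising
$k$ chromosomes can always be extended by exactly one further chromosome
through one more overlap, so every grouping of the (filtered) seed set is
eventually formed and every closed pattern shared by at least $\sigma$
seeds is found.

Two extension strategies are provided.  `strategy = "pairwise"` forms all
$\binom{N_r}{\sigma}$ overlaps of the novel patterns of the previous
iteration -- the literal scheme, whose per-iteration cost is quadratic in
the novel-pattern count and which suits small instances or cluster-sharded
runs.  `strategy = "seed"` applies the add-one property directly: each
novel pattern is overlapped against the (filtered) reference set, which
discovers the identical closed-pattern set -- both strategies are checked
exactly against a brute-force all-subset oracle in the test suite -- at a
cost linear in the size of the closed-pattern lattice.  The pipeline
functions use `"seed"`; on one CPU it keeps iterations that would otherwise
form billions of pairwise overlaps inside a fixed overlap budget
(`max_overlaps`, default $5\times 10^6$, a hard error rather than a silent
truncation).

Work can be sharded without materializing combination lists:
`index_to_combination()` decodes a flat 0-based work-item index $I$ into
the $I$-th $\sigma$-tuple of chromosome indices by peeling layers off a
generalized triangular array, using the hockey-stick identity
$\sum_{j=0}^{N-\sigma}\binom{N-j}{\sigma} = \binom{N+1}{\sigma+1}$
(`partial_binomial_sum()`).  All of this is plain integer arithmetic in
doubles, exact below $2^{53}$, with an explicit error beyond.

## Filtering

The first pairwise overlap is the combinatorial bottleneck: $n$ unique
haplotypes yield up to $\binom{n}{2}$ meta-chromosomes, and unchecked
iteration explodes.  `filter_policy()` retains, after iteration 1 only,
the patterns most associated with case status: a Fisher p-value threshold,
then a cap (`max_keep`) with deterministic tie-breaking, then optionally a
*family rule* that keeps only the fewest-allele member among same-count
patterns not related as subset--superset.  The thresholds are tuned per
locus in practice so that per-iteration pattern counts stay tractable
(historically $10^5$--$10^6$ on cluster hardware); the cap, not the
threshold, does the real work at package-test scale.  The family rule is
off by default here because it exists to damp growth that primary
filtering cannot contain, a regime the test-scale problems never reach --
and when the signal of interest is a rare haplotype family, it can discard
the family's own members.

## The two-phase pipeline

**Phase 1** (`run_phase1()`) mines the unique case chromosomes of a
region of at most `max_snps` SNPs (larger regions are reduced
symmetrically from the ends, leftmost first).  All discovered closed
patterns plus the original contiguous haplotypes are ranked by marginal
Fisher p-value over case and control chromosomes (two per subject); those
below `candidate_p` are evaluated in a Cox proportional-hazards model with
age as the time axis, the per-subject copy number (0/1/2) as a continuous
additive term, adjusted for the subject covariates.  The
smallest-LRT-p candidate is designated the common haplotype h1 after
verifying by stepwise forward selection that no second haplotype enters at
`entry_p`, and is reduced to its minimal defining allele set (below).

**Phase 2** (`run_phase2()`) mines the h1-bearing case chromosomes of an
extended region, scoring iteration-1 patterns by the *conditional* Fisher
test restricted to h1 carriers.  Because every seed carries h1, every
mined pattern contains h1 and its carriers live among h1 carriers, which
keeps all conditional bookkeeping in the h1 submatrix.  Candidates below
`candidate_p` are collapsed to one representative per carrier chromosome
set -- the closure of that set -- because distinct mined variants tagging
one and the same chromosome set are a single statistical hypothesis; the
closures are then ranked by a fast Cox score screen (the score and LRT
are asymptotically equivalent, so the screen orders candidates without
deciding significance), and the top `max_candidates` are evaluated
exactly by the one-degree-of-freedom LRT against the model containing h1.
Patterns with LRT p below `entry_p` are reported; stepwise forward
selection over the strongest `stepwise_max` reported patterns yields the
final independent set, each adjoined to h1 for reporting.

**Replication** (`replicate_patterns()`) maps each pattern into an
independent case-control cohort by SNP id and evaluates a logistic dosage
model relative to the h1-alone model (age is a covariate there, never the
time axis: in a case-control sample, age at onset versus age at censoring
nearly separates the classes, which is also why the phase-2 screen must be
a Cox score, not a logistic one).  A candidate closed pattern need not be
closed in the replication population; when some SNPs are missing, the
pattern restricted to the shared SNPs is used, which has exactly the same
carriers as its closure there.  Patterns with no testable SNPs or no
carriers are "untestable", not failures.

**Permutation null** (`estimate_false_positive_rate()`): case labels are
permuted among h1 carriers so that the counts of case heterozygotes and
case homozygotes are both preserved -- keeping h1's own association intact
while destroying any within-carrier structure -- and conditional discovery
plus replication is re-run per permutation.  The fraction of permuted
discoveries (LRT p < `entry_p`, effect > 1) that replicate (p < 0.05,
effect > 1) estimates the false-positive replication rate; published
applications of this design report single-digit-percent fractions.

## Haplotype reduction

`reduce_pattern()` finds the minimal allele subset defining a haplotype: a
classification tree predicting carrier-of-h from h's own SNP columns is
grown to purity (Gini splits, `cp = -1`, `minsplit = 1`, depth at most
30, via `rpart`), and the alleles on the path isolating the carrier leaf
replace the pattern.  Monomorphic alleles and alleles implied by the
retained ones fall away.  The carrier chromosome set is asserted
unchanged -- reduction can never alter a frequency or effect estimate --
with a warning fallback to the original pattern otherwise.

## The synthetic cohort generator

Real phased biobank data are access-controlled, so every stage is
validated on synthetic cohorts (`simulate_cohort()`).  Chromosomes are
first-order founder mosaics: each copies segments from a pool of
`n_founders` founder haplotypes, switching founders with probability
`1 - ld_decay` per SNP step, which produces pairwise LD that decays with
distance plus the subset/superset haplotype-sharing structure a miner must
disentangle.  Embedded risk haplotypes are painted onto carriers drawn at
the target frequency.  Two carrier modes matter:

* `ibd = FALSE` (default): the pattern is painted over each carrier's own
  background, as for an old, recombined common haplotype.
* `ibd = TRUE`: all carriers copy one ancestral background chromosome
  carrying the pattern -- identity by descent, how a *recent rare*
  haplotype is actually shared.  This is not a convenience: painting a
  rare pattern onto independent backgrounds makes each pairwise overlap of
  carriers pick up private background agreements, so no mined pattern
  reproduces the full carrier set, while IBD sharing is exactly the
  mechanism by which real rare haplotypes are discoverable by overlap.

Phenotypes follow the dosage models the analysis assumes: a logistic model
with a baseline prevalence (case-control sampling) or an age-at-onset
model with exponential baseline hazard scaled by the per-copy hazard
ratio and censoring ages drawn near 65 (cohort sampling).  Covariates are
standard normal and effect-free by default.

What passing tests on these cohorts do *not* show: robustness to
imputation or phasing error, to coalescent genealogies with recombination
hotspots, or to population stratification -- none of which the generator
models.

## Validation scenarios and their sizes

The packaged simulation-study functions fix their scenarios once:

* **Oracle equivalence** (`oracle_agreement()`): 200 random instances of
  at most 12 unique chromosomes and 16 SNPs; the miner must equal
  brute-force all-subset intersection exactly, under both strategies.
* **Rare-subtype recovery** (`phase2_recovery()`): 20,000 subjects,
  40 SNPs, conditioning haplotype at frequency 0.02 (OR 1.3), an
  identity-by-descent rare subtype of 32 alleles on ~30 chromosomes at
  hazard ratio 4 per copy, onset-model cohort with baseline hazard
  0.0055/yr and censoring ~ N(65, 8) (about 30% cumulative incidence --
  chosen so that the carrier event count, which is what powers a
  rare-exposure Cox test, supports the study-wide 1e-5 report threshold).
  Success means some reported pattern has exactly the subtype's carrier
  chromosome set.  Conditional filter: p < 0.05 capped at 25 retained;
  candidate admission p < 0.01; 600 exact LRT evaluations after the score
  screen.
* **Logistic coverage** (`logistic_coverage()`): 200 case-control
  replicates of 2,000 subjects, embedded OR 2; Wald 95% CI coverage of
  the log odds ratio.
* **Null calibration** (`null_calibration()`): effect-free cohorts of
  1,500 subjects; marginal discovery must halt (no candidate below an
  admission threshold of 1e-8), and the permutation false-positive
  replication fraction must stay small (an undefined fraction -- no
  permuted discoveries at all -- is the strongest form of consistency).

These sizes make each check decisive on a single CPU in minutes; they are
stated here so that a reader knows exactly what was run.

## Numerical choices

* Fisher's exact test is the two-sided point-probability rule
  (tables with point probability at most $(1+10^{-7})$ times the observed
  are summed), the convention of standard implementations, computed by
  direct hypergeometric summation and cross-checked against
  `stats::fisher.test`.  Degenerate margins give p = 1 with a warning.
  When the miner scores tens of thousands of tables at once, a vectorized
  Pearson chi-square pre-screen routes only tables whose approximate p is
  below 0.2 -- an order of magnitude above any filtering threshold in use
  -- to the exact computation; the approximation never decides a
  threshold comparison.
* Chromosome counts (two per subject) are the exact-test units;
  per-subject copies 0/1/2 are the regression dosage.
* Cox models use age from 0 to onset/censoring with no delayed entry;
  LRTs are one degree of freedom per added term; non-convergent or
  carrier-free fits are flagged and excluded from selection, never
  silently dropped.
* Mining deduplicates on the canonical pattern key (strictly increasing
  SNP indices); comprising sets merge on collision so the purge rule can
  fire.  Empty overlaps are recorded once and never re-overlapped.  The
  iteration cap (default 25) is a hard error, so silent non-termination
  is impossible.
* Symmetric region reduction removes from the left end first when an odd
  number of SNPs must go (a deterministic convention; the choice is
  otherwise arbitrary).

## Known limitations

* The miner's completeness guarantee applies to the *filtered* seed set;
  filtering trades completeness for tractability exactly as the original
  cluster-scale procedure does, and rare patterns first appearing at deep
  iterations of the unfiltered lattice can be missed.
* Conditional discovery on case chromosomes is an aggressive search;
  its reported p-values are selection-biased by construction.  The
  replication and permutation machinery, not the discovery p-values,
  carry the inferential weight.
* The generator's founder mosaic is not a coalescent: no recombination
  map, no demography, no imputation error.
* Logistic models that include age as a covariate are appropriate for
  case-control samples only; applying them to cohort data where age
  encodes the outcome destroys the signal (the package therefore uses Cox
  machinery throughout discovery and logistic machinery only for
  case-control replication).
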