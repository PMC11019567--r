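---
title: "Methods: population-genetic analyses for multiallelic loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-genetic analyses for multiallelic loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlapop)
```

This vignette is the package's own account of the statistical methods it
implements, the defaults it chooses where the literature leaves a design
open, and what its validation does and does not demonstrate.

## Input conventions

A population file (`.pop`) carries optional `key: value` metadata lines,
then a tab-separated header with two columns per locus (`A_1`, `A_2`, ...),
then one row per individual. The untyped marker (default `****`) flags a
missing allele; an individual missing either allele at a locus is
*incomplete at that locus*. Single-locus statistics use per-locus deletion
(each locus keeps every individual typed there), which maximizes data use;
haplotype estimation deletes listwise over its requested locus set, because
a partially typed individual cannot constrain a multi-locus haplotype
without an imputation model we deliberately do not fit. Allele names are
free non-whitespace tokens: modern colon-delimited HLA names of any length
pass through untouched, and matching (including in binning filters) is
case-sensitive so that upstream case inconsistencies surface as data errors
instead of being silently folded.

Custom binning filters live in a `[CustomBinning]` configuration section.
Each locus line reads `locus: !group/member/member/...`, with further
groups on whitespace-indented continuation lines; `;;` starts a comment.
Applying a filter rewrites member alleles to their group identifier before
any analysis, which is how G-groups, supertypes, TCE groups or NMDP codes
are collapsed. Two deliberate strictnesses: an allele may not belong to two
groups at one locus, and a group identifier may not itself appear as a
member of another group — transitive binning is rejected as a conflict
rather than resolved, because silent cascades of renames are a common
source of irreproducible allele tallies.

## Hardy-Weinberg tests

The chi-square test compares observed genotype counts with expectations
$e_{ii} = n p_i^2$, $e_{ij} = 2 n p_i p_j$, where $p$ comes from the
observed gamete counts. Classes with expected count below `lump_below`
(default 5, the classical rule) are pooled into one lumped class; degrees
of freedom are the number of post-pooling classes minus $k$, floored at 1.
With many rare alleles the lumped class dominates and the chi-square
approximation is rough — that is what the exact test is for.

The exact test conditions on the observed allele counts $m_1, \dots, m_k$.
The probability of a genotype table is

$$P(\text{table}) = \frac{n!\ \prod_i m_i!\ 2^H}{(2n)!\ \prod_{i \le j} n_{ij}!},$$

with $H$ heterozygous individuals. When the number of compatible tables is
at most `max_tables` (default 50&nbsp;000) we enumerate them all; the
p-value sums $P$ over tables with $P \le P(\text{obs})$, and the
heterozygote excess/deficit tails sum over tables whose heterozygote count
is $\ge$ / $\le$ the observed one (the paper-family's "heterozygotes,
homozygotes" outputs are realized as these two tails; the exact statistic
is a convention of this package). Ties on $P$ are resolved with an absolute
tolerance of $10^{-12}$ on log-probabilities, because equal-probability
tables otherwise fall on one side or the other at the mercy of rounding.

Past `max_tables` we sample from the same conditional distribution by
shuffling the $2n$ gamete labels into $n$ random pairs. This sampler is
i.i.d. — each draw is an exact sample — so its validation reduces to
binomial error, unlike a Markov-chain sampler whose mixing would itself
need diagnostics; the classical switch-proposal chain is intentionally not
implemented. Monte-Carlo p-values use $(1 + x)/(1 + N)$ so that no
estimate is exactly zero. All samplers take explicit seeds and restore the
caller's RNG state.

## Ewens-Watterson neutrality test

Under neutrality, conditional on the gamete count $n$ and allele number
$k$, the allele-count configuration is parameter-free:

$$P(\text{config}) = \frac{n!}{\prod_j j^{a_j} a_j!}\,\big/\,|s(n,k)|,$$

with $a_j$ the number of alleles seen $j$ times and $|s(n,k)|$ the unsigned
Stirling number of the first kind, computed in log space by the triangular
recurrence (exact to double precision; no large-integer arithmetic needed).
The test statistic is homozygosity $F = \sum_i p_i^2$; we report the exact
null mean and standard deviation, the normalized deviate
$F_{nd} = (F_{obs} - E[F])/\mathrm{sd}(F)$, and the *lower-tail* p-value
$P(F \le F_{obs})$ — negative deviates and small p-values point toward
balancing selection, the usual direction of interest at immune loci. The
upper tail is also reported, so a directionality convention never hides
information.

Enumeration covers all partitions of $n$ into $k$ parts up to
`max_partitions` (default $5 \times 10^5$). Beyond that, a Hoppe-urn
(Chinese-restaurant) sampler draws configurations at the mutation rate
$\theta$ solved from $E[K(\theta, n)] = \sum_{i=0}^{n-1} \theta/(\theta+i)
= k$ (monotone in $\theta$, solved by bracketed root-finding), rejecting
runs whose realized allele count is not $k$. Conditioning by rejection at
the $\theta$ that centers $K$ on $k$ keeps the acceptance rate workable at
the sample sizes this package targets; the attempt cap ($10^6$) exists so
that a pathological request fails loudly with its acceptance rate instead
of spinning.

## EM haplotype estimation

Each individual complete at the requested loci contributes its
$2^{h-1}$ phase-consistent haplotype pairs ($h$ = heterozygous loci,
$h \ge 1$). The E-step weights pair $(h_1, h_2)$ by $f(h_1) f(h_2)$
(doubled when $h_1 \ne h_2$), normalized within the individual; the M-step
sets each haplotype frequency to its expected gamete share. This is exact
maximum likelihood under random union of gametes; the log-likelihood is
non-decreasing by construction and the suite asserts it to $10^{-9}$ slack.
Convergence is declared when $\max_h |\Delta f_h| < 10^{-7}$ (default),
capped at 1000 iterations; non-convergence is reported, never hidden.
Restart 0 starts uniform; optional extra restarts draw random simplex
points under the run seed and the best final likelihood wins. The default
is a single uniform start: for two-locus tables the likelihood surface is
mild and the uniform start is reproducible; restarts are there for larger
locus sets. The locus-set size is capped at 8 because the resolution
enumeration grows as $2^{h-1}$ per individual; with phase-unambiguous data
the EM reduces to direct gamete counting exactly, which the suite uses as
an oracle. Haplotypes with final frequency below $10^{-8}$ are dropped from
reports only after normalization, so reported frequencies still sum to 1 at
reporting precision.

## Linkage disequilibrium

From a two-locus haplotype frequency table $h_{ij}$ with margins $p_i$,
$q_j$: $D_{ij} = h_{ij} - p_i q_j$, normalized to $D'_{ij} = D_{ij}/D_{max}$
with the usual sign-dependent range bound. Summaries are the
frequency-weighted $D' = \sum_{ij} p_i q_j |D'_{ij}|$ and the Cramér-type

$$W_n = \sqrt{\frac{\sum_{ij} D_{ij}^2 / (p_i q_j)}{\min(I-1, J-1)}}.$$

The asymmetric measures compare conditional with unconditional
homozygosity: $F_{1|2} = \sum_j \sum_i h_{ij}^2 / q_j$ and
$W_{12} = \sqrt{(F_{1|2} - F_1)/(1 - F_1)}$, conditioning on the *second*
locus (reported as `ALD_1_2`), with $W_{21}$ the mirror image. For two
SNPs both equal $|r|$; they diverge when allele numbers differ, which is
their point at HLA loci. Numerics: radicands in $[-10^{-12}, 0)$ are
clamped to 0 (they arise from floating-point cancellation at independence),
anything more negative is an input-consistency error; a monomorphic focal
locus makes the measure undefined and it is reported as `NA`, never as 0,
because "no variation to predict" and "no association" are different
findings. Supplied margins must agree with the table to $10^{-9}$.

LD is computed from the EM point estimate as if known; estimation error is
not propagated into the measures. Significance therefore comes from a
permutation test: locus-2 genotypes are shuffled across individuals
(preserving both single-locus genotype distributions, destroying
association), the EM re-run per permutation, and the observed $W_n$
compared with the permuted ones using the same $(1+x)/(1+N)$ convention.
$W_n$ is the permutation statistic because it is a single bounded summary
defined for any allele-number combination; an EM likelihood-ratio statistic
would also be valid but ties the null distribution to EM convergence
behavior.

## Synthetic data generator

`simulation_spec()` + `sample_population()` draw $2n$ gametes from true
haplotype frequencies and pair them at random, so genotypes are in
Hardy-Weinberg proportions at the haplotype level by construction. The HWE
deviation parameter $f \in [0, 1)$ makes each individual, with probability
$f$, a duplicated single gamete draw — the inbreeding-mixture model, chosen
because it has closed-form expectations (heterozygosity $2pq(1-f)$ at a
biallelic locus) to test against. Missing markers are injected
independently per allele field. The generator emulates random mating,
selection-free transmission and typing dropout that is independent of
genotype; it does *not* emulate linked mutation processes, population
structure beyond the single-$f$ mixture, allele-specific typing failure, or
genotyping error. Passing tests therefore demonstrate correctness of the
estimators under their own sampling assumptions, not robustness to
structured real-world artifacts.

## Validation scale and reproducibility

The suite and `scripts/acceptance.R` run at desk scale, chosen so the full
battery completes in minutes on one core while keeping Monte-Carlo error
well inside the asserted 3-standard-error bands: 1000 random biallelic
tables for the SNP-equivalence bound; exact-vs-Monte-Carlo comparisons over
genotype tables with $k \le 4$, $n \le 12$ at 2000 samples;
Ewens-Watterson cases up to $n = 50$, $k = 6$ at 4000 samples; EM recovery
on a 2×3-allele system at $2n = 2000$ over 20 seeds; permutation
calibration with 200 replicates × 200 permutations at $n = 50$. Every
stochastic step takes an explicit seed, derived from one master seed in the
pipeline, and reruns are byte-identical — the end-to-end determinism test
hashes every output file.

## Output formats

The XML vocabulary is defined by this package and co-designed with its
reader: one `<populationReport>` per population with `<locus>`,
`<haplotypeEstimate>` and `<ldPair>` blocks mirroring the requested
analyses. Numeric attributes are serialized at full double precision (17
significant digits) so write → read round-trips exactly; frequency-like
values carry an additional 6-significant-digit `display` attribute for
human readers. TSV aggregation emits only files for which data exist, with
fixed, documented column sets; undefined values (e.g. ALD at a monomorphic
locus) are `NA`. The text report prints the LD columns as `D'`, `Wn`,
`ALD_1_2`, `ALD_2_1`, appending `# permu` and `p-value` only when a
permutation test ran.

## Known limitations

* The exact-test fallback threshold trades memory-free enumeration against
  Monte-Carlo noise; extremely polymorphic loci always take the sampler.
* The EM treats haplotype frequencies as free parameters; with many loci
  and rare alleles the likelihood can be flat and `converged = FALSE` with
  a boundary estimate is a real outcome, reported as such.
* Phase-known data are not used as such; everything goes through the
  unphased likelihood.
* ALD variance estimators and confidence intervals are out of scope;
  significance statements rest on the permutation test only.
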