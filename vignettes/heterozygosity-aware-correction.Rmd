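---
title: "Heterozygosity-aware hybrid correction of long reads: model and methods"
author: "HetCorr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterozygosity-aware hybrid correction of long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HetCorr)
```

# The problem

Long (third-generation) sequencing reads carry per-base error rates of
5--20%, so they are routinely corrected before downstream use. Hybrid
correction uses accurate short (next-generation) reads as evidence: short
reads are piled up on the long reads and each long-read base is replaced by
the majority vote. At a heterozygous site of a diploid genome this majority
vote is destructive: the reads genuinely carry two alleles, and voting
collapses the minority allele onto the majority one, erasing the
heterozygosity that downstream genotype analysis needs.

HetCorr separates *judging* a site from *correcting* it. Before any base is
replaced, a Bayesian classifier decides whether the pileup column looks
homozygous or heterozygous; only under a homozygous judgment does plain
majority replacement apply, while a heterozygous judgment protects the top
two alleles and re-assigns only bases outside them.

# The classifier

## Per-allele category probabilities

Each read base at a site is modelled as a draw from five categories (the
four nucleotides and the null label `N` for a deletion spanning the site),
ranked by observed frequency. With per-base error rate $e$:

* homozygous: the single true allele has probability $1-e$, each of the
  four error categories $e/4$;
* heterozygous: the two true alleles have probability $(1-e)/2$ each, the
  three error categories $e/3$ each.

The construction needs $e < 0.6$: at $e = 0.6$ the heterozygous allele
probability $(1-e)/2$ meets the error probability $e/3$ and the rank order
the model is built on inverts, so `categoryProbs()` refuses larger rates.

```{r}
categoryProbs("homozygous", e = 0.2)
categoryProbs("heterozygous", e = 0.15)
```

## Sequential binomial likelihood

Let $|X_1| \ge |X_2| \ge \dots \ge |X_5|$ be the ranked allele counts of a
column (ties broken in the fixed order A < C < G < T < N) and
$D_q = \sum_{j \ge q} |X_j|$ the suffix depths. Each rank follows a
binomial distribution conditional on the earlier ranks:

$$|X_q| \sim \mathrm{Bin}\!\left(D_q,\; \pi_q\right), \qquad
  \pi_q = \frac{p_q}{\sum_{j \ge q} p_j},$$

and the likelihood of the column is the product over the observed ranks
(ranks with zero count contribute nothing, because their remaining depth is
zero). This chain is algebraically identical to the multinomial probability
of the count vector under the category probabilities $p_1, \dots, p_5$ —
an identity the test suite verifies exhaustively for all count vectors of
depth up to 12 — but the chain form is what the classifier evaluates, and
both forms are kept: the multinomial is the independent oracle, never the
production path.

The decision multiplies the likelihood by the prior for each hypothesis and
takes the larger unnormalised posterior. Three deliberate conventions:

* a column with a single observed allele ($d = 1$) is judged homozygous
  directly, whatever the posteriors say;
* exact posterior ties go to homozygosity — the conservative direction,
  since fabricating heterozygosity is the costlier mistake;
* all probability arithmetic is in log space; the reported scores are
  unnormalised log posteriors, because only their comparison matters.

```{r}
classifySite(rankAlleles(c(A = 3, C = 2)), e = 0.2)
classifySite(rankAlleles(c(A = 9, C = 1)), e = 0.15)
```

A known asymmetry of this rank-statistics evaluation: the model scores the
*ordered* counts with per-rank probabilities rather than summing over the
assignments of alleles to categories. The over-counting factor is not
exactly equal under the two hypotheses (four exchangeable error categories
under homozygosity versus three under heterozygosity), so homozygous
columns whose errors happen to split over two alleles (for example counts
7/2/1 at depth 10) lean slightly heterozygous. At $e = 0.15$ and depth 10
this costs the classifier a few points of specificity (measured in the test
suite); sensitivity is unaffected.

## Priors

The default prior is an indifferent point prior
$P(\text{homozygous}) = P(\text{heterozygous}) = 0.5$. A Beta distribution
over the homozygosity probability ("a probability distribution of
probabilities") is also supported, reduced to a usable prior in one of
three modes, because plugging a density value into a posterior is not
itself a probability:

* `mean` (default): use the Beta expected value $a/(a+b)$;
* `sample`: one reproducible draw from the Beta, for sensitivity studies;
* `density_at_guess`: evaluate the density at a guess $\theta$ and at the
  complementary guess $1-\theta$ and renormalise the pair to sum to one.

## Combining long and short evidence

At every anchor site of the shared reference, the classifier judges the
long-read pileup (at the long-read error rate, default 0.15) and the
short-read pileup (default 0.05) separately, then combines:

* both judgments agree: adopt the short-read judgment (short reads are far
  more accurate);
* they disagree: adopt the homozygous judgment;
* only one exists (no coverage from the other source): it stands.

For long reads that fail to map to the reference, only short-read evidence
exists: short reads are mapped onto each such read individually and the
same classifier runs on the per-read pileup.

This combination rule has a quantifiable cost at low coverage that users
should understand. At long-read coverage $c$ the depth of a site is
approximately Poisson($c$), and the covering long reads are a binomial
50/50 sample of the two haplotypes. A truly heterozygous site whose long
reads all come from one haplotype (probability $2^{1-n}$ at depth $n$)
produces a single-allele column, which is judged homozygous *directly* and
vetoes the short-read heterozygous call; strongly unbalanced columns such
as 4:1 at $e = 0.15$ are likewise judged homozygous and veto. Integrated
over the depth distribution, these vetoes bound the attainable
heterozygosity retention well below 1 at 3--5x long-read coverage —
roughly 0.6--0.75 at 5x under the default simulation conditions — and the
bound is a property of the decision rules, not of the implementation. The
acceptance script reports the retention the pipeline actually achieves; it
rises steeply with long-read coverage as the veto probability decays.

# Correction rules

Per decided site, with a voting pool of ranked allele counts:

* homozygous: every read base aligned to the site is replaced with the most
  frequent pool allele;
* heterozygous: a base already among the top two pool alleles stays; any
  other base is replaced by one of the top two, chosen uniformly at random
  (seeded, so runs are reproducible);
* a winning null allele deletes the base from the output sequence;
* insertions relative to the reference have no anchor and are never
  touched; sites under the spacer mask of an assembled reference are never
  corrected.

For mapped long reads the pool merges the long-read and short-read counts
at the anchor (both pileups exist there; a short-only pool is available via
`pool = "short"`). For unmapped long reads the pool is the short-read
pileup on that read — the only evidence there is.

# The pipeline around the classifier

1. **Reference**: a pseudo reference is assembled from the long reads by a
   four-step overlap-layout-consensus procedure — Smith-Waterman overlap
   scoring between read pairs (score threshold $\theta$, aligned length
   within `[minLength, maxLength]`; a k-mer prefilter skips pairs sharing
   no seed but never changes the result for genuinely overlapping pairs),
   greedy layout in descending score order with per-column majority
   consensus, contig merging to a fixpoint, and linking of the final
   contigs (longest first) with runs of 50 `N` whose positions are masked
   from anchoring. The pseudo reference is a coordinate anchor, not
   biological truth, and any externally assembled FASTA can be substituted
   at this seam.
2. **Mapping**: reads are mapped by an internal semi-global aligner (match
   1, mismatch -1, gap -2), either seeded by shared 15-mers or
   exhaustively (the slow DP oracle); standard SAM from an external mapper
   can be imported instead. For simulated data a truth-anchored mode
   re-aligns each read inside a padded window around its known origin —
   the fast mode used by the desk-scale studies. A long read is *mapped*
   when strictly more than 90% of its bases align as match/substitution
   columns ("over 90%" is read literally, so exactly 0.90 is unmapped).
3. **Judging and correcting**, as above; corrected mapped and unmapped
   reads merge into the output set.
4. **Evaluation** (when ground truth exists): corrected reads are
   re-mapped to the truth reference and every planted heterozygous site is
   tested for retention.

# The simulator

The generator emulates a small diploid resequencing study: a uniform-random
genome (GC 0.5) of configurable length, default 100 kb; 500 heterozygous
SNPs planted at uniform distinct positions, the alternate allele uniform
over the three non-reference bases; reads drawn uniformly from the two
haplotypes with uniform starts and truncated-lognormal lengths
(`sdlog = 0.3`; defaults: mean 2000 for long reads, 100 for short reads);
and per-base errors applied independently — the long-read error budget
(default 0.15) split equally across substitutions, insertions and
deletions, short reads substitution-only at 0.05. Reads are emitted until
the requested coverage is reached, and each read records its true origin
(interval, strand, haplotype), which powers the truth-anchored mapper and
the evaluator.

What the simulator does *not* emulate: real genome composition and repeats
(uniform bases make mapping easier than reality), platform-specific error
profiles (homopolymer indel clustering, quality-dependent rates), GC and
coverage bias, and chimeric or strand-switching reads. Passing tests
therefore demonstrate the method's behaviour under its own model
assumptions, not performance on real data.

# Evaluation definitions

A planted site *retains* heterozygosity when the balance between its two
most frequent alleles, $|X_1|/(|X_1|+|X_2|)$, lies inside the heterozygous
interval (inclusive); `[0.20, 0.80]` is the conventional interval, with
`[0.25, 0.75]`, `[0.30, 0.70]` and `[0.35, 0.65]` as stricter presets.
Because the balance is at least 0.5 by construction, narrowing the interval
can only lose sites, so retention is monotone across the nested presets. A
site covered by fewer than two corrected reads cannot exhibit two alleles
and counts as lost. An alternative retention mode (`"majority"`, the top
allele's fraction of all bases) is available behind a flag; the default is
the top-two balance, since allele identity is audited separately by the
quality grade. Retention accuracy is the retained fraction of planted
sites, equivalently one minus the error rate.

The *difference value* audits allele identity: the proportion of the two
true alleles minus the proportion of the other two bases, over A/C/G/T
counts only (the null allele is excluded). Positive values mean the site is
still dominated by its true allele pair; values in (0, 0.3] grade *good*,
in (0.3, 1] *excellent*, exactly 0 a *draw*, negative values *poor*.

# Parameters at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `longErrorRate` | 0.15 | total long-read error (sub:ins:del = 1:1:1) |
| `shortErrorRate` | 0.05 | short-read substitution rate |
| `eLong`, `eShort` | matched to the data rates | classifier error rates (floored at 0.001, since the rank model needs $e > 0$) |
| `prior` | point 0.5 | prior probability of homozygosity |
| `threshold` | 0.90 | mapped-base fraction separating Lm from Lu (strict) |
| `minLength`, `theta` | 100, 100 | assembler overlap gates |
| `match, mismatch, gap` | 1, -1, -2 | alignment scores |
| `intervals` | 0.20--0.35 | heterozygous interval lower bounds |
| `pool` | merged | voting pool at anchors |

# Numerical and design choices

* Coordinates are 0-based half-open everywhere internally and in TSV
  outputs (noted in their headers); IRanges objects are 1-based as usual.
* Likelihoods in log space; `lchoose` for binomial coefficients; the final
  rank's degenerate binomial ($\pi = 1$) contributes zero log-probability.
* Ties: allele ranking A < C < G < T < N; assembler merge order descending
  score then lexicographic read-id pair; contig linking by descending
  length then first member id; posterior ties to homozygosity.
* Degenerate inputs: empty columns are uncallable and skipped; unmapped
  reads pass through correction unchanged; an empty voting pool skips the
  site; `maxLength` defaults to infinity because longer overlaps are
  better (the finite upper gate is kept configurable).
* Randomness: every stochastic step (simulation, heterozygous
  re-assignment, Beta sampling) takes an explicit seed, and pipeline stage
  seeds are derived from the master seed, so runs are byte-reproducible.

The test suite runs its end-to-end studies at 100 kb / 500 sites (the
default study size) and its unit fixtures at 0.4--8 kb; the noiseless
fixpoint check uses genome-spanning reads (100 long, 40 short over 2 kb)
so that every site has deterministic depth and the binomial sampling tail
cannot confound the zero-edit property being tested.

# Known limitations

* The homozygosity-wins combination rule bounds low-coverage retention, as
  quantified above; at 3x long-read coverage the depth distribution alone
  (20% of sites covered by fewer than two reads) caps retention at 0.80.
* The classifier considers at most two true alleles: tri-allelic sites and
  somatic fractions are out of scope.
* Quality strings are not modelled: counts are unweighted, and corrected
  FASTQ output carries constant qualities.
* The internal assembler is a faithful desk-scale implementation of the
  four-step overlap-layout-consensus description, not a production
  assembler; for large inputs substitute an external assembly at the
  reference seam.
* The truth-anchored mapper is only available for simulated reads; real
  data must come with SAM alignments or use the seeded mapper.
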