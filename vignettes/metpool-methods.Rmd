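---
title: "Quantifying metastatic potential from pooled in vivo barcoding: models and methods"
author: "metpool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying metastatic potential from pooled in vivo barcoding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metpool)
```

# The experimental system

In a pooled in vivo barcoding assay, each cancer cell line in a pool
carries a unique genomically integrated DNA barcode (26 nt here). The
pool is injected into the arterial circulation of immunodeficient mice;
weeks later, target organs (brain, lung, liver, kidney, bone) are
collected, cancer cells are isolated, and barcode abundances are read
out by amplicon or RNA sequencing. Because every line competes in the
same animals, the readout is an internally controlled measurement of
each line's ability to colonise each organ. `metpool` implements the
computational half of this assay: read-to-barcode assignment, potential
estimation with uncertainty, composition-corrected differential
expression, feature association, mini-pool CRISPR screen scoring, and a
forward simulator that stands in for the animal experiment so that every
stage can be tested against known ground truth.

# Read-to-barcode assignment

Sequencing libraries shear randomly, so a 75-bp read can cover a barcode
completely or only partially at either end. A barcode is a *candidate*
for a read when

* the full barcode (or its reverse complement) occurs in the read, or
* a terminal fragment of the barcode — a prefix at the read's 3' end or
  a suffix at the 5' end — covers **strictly more than half** of the
  barcode, i.e. at least 14 of 26 nt.

A read with exactly one candidate is assigned; zero candidates is
unassigned; several candidates is ambiguous and excluded from counts
(no multi-hit rescue is attempted, avoiding biased assignment).
Matching is exact by default; a Hamming tolerance of 1–2 mismatches can
be enabled (`match_params(max_mismatches = )`), with no indel handling —
substitutions dominate amplicon error profiles. `N` bases never match;
reads containing characters outside A/C/G/T/N are tallied as invalid.
Paired-end fragments count once: a fragment is assigned if either mate
is (ambiguous if the mates disagree). Counting therefore conserves
fragments exactly: assigned + unassigned + ambiguous equals the input.
The matcher is verified, read by read, against an exhaustive
sliding-window oracle implemented independently in the test suite.

# Metastatic potential

**Absolute potential** uses sorted-cell totals. With $c_{ik}$ the total
cancer cells isolated from organ $i$ of mouse $k$ and $p_{jk}$ the
barcode fraction of line $j$ in that sample,

$$M_{ij} = \frac{1}{n}\sum_{k=1}^{n} c_{ik}\, p_{jk},$$

the mean inferred cell number (units: cells).

**Relative potential** needs no cell sorting: with depth-normalized
(counts-per-million) organ counts $c_{ijk}$ and pre-injection replicate
counts $p_{jm}$,

$$rM_{ij} = \frac{\tfrac1n\sum_k c_{ijk}}{\tfrac1m\sum_m p_{jm}},$$

a dimensionless enrichment over the injected pool. A line absent from
every pre-injection replicate has no defined ratio and propagates as
`NA`, never infinity. An organ sample with zero assigned reads
contributes zero abundance for every line (a mouse without detectable
metastasis is data, not an error). **Penetrance** is the fraction of
mice in which a line passes a detection rule, by default ≥ 5 raw reads —
the assay states no threshold, and a small integer floor separates
presence from index-hopping noise while remaining configurable.

**Confidence intervals** are percentile bootstrap, resampling *mice*
(the biological replicate in both formulas) with replacement, B = 1000
by default, deterministic under a seed. For relative potential the
pre-injection denominator is held at its across-replicate mean while
organ mice are resampled, since the pre-injection pool is measured once
per experiment, not per mouse. A known property of the percentile
interval is coverage below nominal at small n (its coverage error is
O(1/n)); the package's coverage experiment
(`coverage_experiment()`) quantifies this at n = 10 and the acceptance
suite reports whatever it measures.

**Overall potential** collapses organs to one scalar per line as the
mean of floored log potentials, $\overline{P}_j = \tfrac1{|I|}\sum_i
\log_{10}\max(rM_{ij}, 10^{-4})$. The source assay uses such a scalar
without defining it; this floored log-mean is the package's own choice —
monotone, bounded, and symmetric in how it penalises absence. The floor
(default $10^{-4}$) bounds the penalty for organs where a line was never
seen and matches the lower end of the simulated potential range.

# Composition-corrected differential expression

An in vivo metastasis sample is a mixture of whichever lines grew in
that mouse, so comparing it to any single baseline confounds expression
change with composition change. The package builds the matched control
*in silico*: with $g_{ij}$ the baseline in vitro expression of gene $i$
in line $j$ and $p_j$ the sample's barcode-derived composition,

$$\hat g_i = \sum_j g_{ij}\, p_j,$$

computed on the linear scale (read-derived proportions mix linearly in
abundance, not in log space), then paired with its in vivo counterpart.
Testing operates on paired differences of log2(CPM + 0.5) — the
pseudocount is the conventional half-count; library-size CPM stands in
for more elaborate normalizations and is pluggable. The paired
moderated t follows the standard empirical-Bayes construction: gene-wise
variances $s_g^2$ with $d$ residual df are modelled as scaled-F around a
prior $(d_0, s_0^2)$ estimated by moment matching of $\log s_g^2$
(digamma/trigamma identities, Newton inversion of the trigamma), the
posterior variance is the df-weighted blend, and the statistic gains
$d_0$ df (capped at the total residual df across genes). Genes with
identical differences in every pair carry no variance information and
are excluded from inference (their fold-change is still reported).
Benjamini–Hochberg adjustment is applied across genes per organ. The
implementation is cross-checked against limma on the same data in the
test suite; limma is never used as the implementation.

Signature scoring replaces projection-style single-sample enrichment
with a transparent mean z-score: each gene standardized across samples,
scores averaged over the set. It preserves the comparative use (scores
across samples) and is invariant to gene-wise affine rescaling.

# Two-class feature association

Lines are gated into high / low classes by two thresholds on overall
potential, with lines between them excluded — the thresholds are not
printed in the source assay, so explicit two-threshold gating keeps the
choice visible and tunable. Binary features (mutations, binarized copy
number with the inclusive cutoffs ≤ −1 loss / ≥ +1 gain) are tested by
Fisher's exact test — exact and verifiable by brute-force hypergeometric
enumeration at these sample sizes — with the difference in class
proportions as effect. Continuous features use the same moderated-t
machinery as the DE module, with per-feature pooled variances squeezed
across features. Positive effects are enriched in the high class;
ranking is by signed effect with ties broken by q-value then name, so
orderings are deterministic. Missing values are dropped pairwise per
feature, as genomic characterization matrices are ragged.

# Mini-pool CRISPR screen

Guide counts are depth-normalized by the upper-quartile method: each
sample scaled so the 75th percentile of its nonzero counts equals the
geometric mean of per-sample 75th percentiles (idempotent by
construction). Guide log2 fold-changes are tissue means minus reference
means on log2(normalized + 0.5). Gene-level inference contrasts each
gene's guide LFCs against the distribution of non-targeting control
guides with a moderated two-sample t: anchoring to controls rather than
an intercept-only model makes the test robust to global outgrowth
differences between animals, which vary wildly in intracranial screens.
The reported gene LFC is the mean of its guides' LFCs.

# The simulator

`simulate_experiment()` is the package's stand-in for the animal
experiment. Defaults are the mapped study's design conditions: pools of
25 lines at 500 cells per line, 5 target organs, cohorts of 5 mice,
3 pre-injection replicates, $10^6$ reads per sample. Per mouse and
organ, each line seeds as an independent Bernoulli event; if seeded, its
outgrown cell number is
$\text{cells/line} \times 10^{\text{potential}} \times
\mathrm{LogNormal}(0, 0.5)$. The sample composition is the realized
cell numbers on the simplex, and sequencing draws a
Dirichlet–multinomial with concentration $100 \times p$ — amplicon
counts are overdispersed relative to multinomial, and the concentration
parameter exposes the multinomial limit ($\to\infty$) for testing.
True potentials default to Uniform(−4, 1) on the log10 scale, spanning
the four-plus orders of magnitude the assay resolves.

Penetrance defaults to a logistic function of true potential,
$\mathrm{plogis}(1.5(\text{potential} + 1.5))$: aggressive lines seed
nearly every mouse while weak lines seed few. This coupling is the
assay's own observed behaviour (petal width tracks petal length); an
independent uniform penetrance would make per-line detection rates an
uncorrelated noise source that the real assay does not exhibit. The
pre-injection pool is equal proportions with 10% lognormal jitter. The
true dispersion of the real assay is not knowable from published
numbers; these defaults are chosen to make recovery nontrivial, not to
match any dataset.

What the simulator does **not** model: spatial or vascular structure,
immune interactions, clonal evolution within lines, barcode PCR
chimeras, mouse-read contamination, or correlated seeding between
organs. Passing recovery tests therefore demonstrates the estimators'
correctness under the stated generative model, not performance on any
real dataset.

`emit_fastq()` materializes count tables as reads (barcode at a random
offset in random flanking sequence, optional per-base substitution
errors) so the full path from FASTQ to potential can be exercised;
with error rate 0 the round trip through `count_barcodes()` is
bit-exact. `simulate_expression()` generates lognormal baselines and
in vivo samples as exact linear mixtures plus spiked differential genes
and multiplicative noise — precisely the structure the DE module
assumes, with known differential gene identities.

# Numerical and degenerate-input choices

* "Over 50%" is a strict inequality: 13/26 nt is rejected, 14/26 accepted.
* All-zero count columns: composition undefined (`NA`) with a warning
  at pseudocount 0; zero-total *pre-injection* samples are an error
  (the denominator of every ratio), zero-total organ samples are valid
  zero-abundance observations.
* Ambiguous fragments are reported but never counted.
* `bh_fdr()` validates the input range and applies the standard step-up
  with monotonicity enforcement; the test suite checks it against a
  brute-force implementation of the rule.
* Variance moderation with fewer than two informative features degrades
  gracefully to no moderation.
* Bootstrap and simulation seeds are forked from one master seed by
  stable stage labels, so adding a stage never silently changes
  another's stream.

# Problem sizes used by the tests

The test and acceptance suites run entirely on simulated data at the
design conditions above: 25-line pools at depth $10^6$ for recovery;
125 lines (one big pool vs five 25-line sub-pools, the latter at 2500
cells per line) for the split-design concordance experiment, compared on
all floored log10 (line, organ) potentials; 2000 genes × 5 pairs for DE
calibration and power; 200 replicates × B = 1000 at n = 10 for bootstrap
coverage; 29 genes × 2 guides + 10 controls for the screen. The
matching oracle runs on ≥ 1000 randomized reads over barcode lengths
{8, 12, 26}.

# Known limitations

* The overall-potential scalar and the class-gating thresholds are
  declared stand-ins for undocumented choices in the source assay.
* The percentile bootstrap undercovers at small mouse numbers; users
  wanting calibrated intervals at n ≤ 10 should increase cohort size or
  treat the intervals as approximate.
* Mismatch-tolerant matching is Hamming-only; indel-heavy platforms
  would need alignment-based assignment.
* CPM normalization assumes library size is the only technical scale
  factor between paired samples; the normalization step is pluggable
  where that assumption fails.
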