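---
title: "Methods: cf-DNA quantification and targeted methylation diagnostics"
author: "cfMethDx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cf-DNA quantification and targeted methylation diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The diagnostic problem

Endometriosis diagnosis today requires laparoscopy. A candidate
non-invasive alternative combines two serum measurements from a single
blood draw:

1. **How much cell-free DNA (cf-DNA) circulates.** cf-DNA is released
   by apoptosis and necrosis; inflammatory disease elevates it. A
   single-copy housekeeping gene (RPP30) is quantified by qPCR against
   a standard curve, so the copy number is an absolute proxy for total
   cf-DNA.
2. **How a nine-gene panel is methylated.** Bisulfite treatment
   converts unmethylated cytosine to uracil (read as T) while
   5-methylcytosine stays C, so the C fraction at a CpG measures
   methylation. Nine amplicons (CALD1, RRP1, FN1, DIP2C, RMI2, TDRD5,
   USP1, HDAC1, DNMT1) are PCR-amplified from converted cf-DNA and
   sequenced paired-end 2 x 150 bp.

The package implements the full computational workflow — absolute
quantification, methylation calling, per-gene differential testing,
and a composite elastic-net INDEX classifier — plus a synthetic-data
generator so that every stage can be validated against planted truth
without any sequencing download.

# Synthetic data: what it emulates

`generatePanel()` draws amplicon references (120–280 nt by default,
within the 80–400 nt range typical for bisulfite amplicons) with at
least three CpGs each; for nine genes the panel carries the nine study
gene symbols. `simulateCohort()` draws the study conditions:

* **Group sizes** 38 cases / 40 controls.
* **Copy numbers** i.i.d. log-normal per group. The defaults put the
  medians at 8602 (cases) and 2224 (controls) — a 3.9x separation —
  with log-scale SDs 1.04 and 0.84 chosen so the mean/median ratios
  match the reported heavy right tails (means 14,762 and 3,166, maxima
  near 97,000).
* **Methylation.** Gene-level truth: each sample's per-gene methylation
  fraction is beta-distributed around its group mean with concentration
  60 (SD about 6 percentage points at 50% methylation), representing
  inter-individual epigenetic variation. Four genes (DIP2C, DNMT1,
  RRP1, USP1) are hypomethylated in cases by 15 percentage points;
  the other five are equal between groups. Gene-level truth (rather
  than per-CpG truth) is modeled because the classifier consumes
  gene-level percentages; per-CpG heterogeneity is outside the model.

`simulateBisulfiteReads()` models the bisulfite-converted **top strand
only** (amplicon bisulfite PCR primers fix one strand): each CpG
cytosine of a molecule is methylated with the sample's gene-level
probability; a methylated C survives as C with probability 0.995
(`methylatedProtection`), an unmethylated C converts to T with
probability 0.99 (`conversionEfficiency`); all non-CpG cytosines are
unmethylated. Substitution errors are applied uniformly at rate 0.001
per base; there are no indels, chimeras or PCR-duplicate structure
(the assignment step downstream is ungapped, so indel realism would
buy nothing here). R1 is the 5' read and R2 the reverse-complemented
3' read; they overlap whenever the amplicon is shorter than 300 nt.
Qualities are constant Q30 — merging tie-breaks only need quality
variation in targeted unit tests. Coverage defaults to 1000 read pairs
per amplicon per sample (the study does not state a depth; 1000 makes
the binomial noise on a gene percentage about +/-1.6 points).

`simulateQpcr()` generates the standard dilution series (a positive
control at 200,000 copies/uL diluted ten-fold over five points) and
per-sample Cq triplicates from Cq = intercept + slope log10(copies) +
N(0, sd), with the ideal slope -3.3219 (= -1/log10 2, perfect
doubling), intercept 40 cycles at one copy, and replicate noise 0.15
cycles.

Everything is seed-deterministic: identical seeds give byte-identical
FASTQ files and tables.

# Absolute quantification

`fitStandardCurve()` is ordinary least squares of Cq on
log10(copies); the amplification efficiency is E = 10^(-1/slope) - 1.
`quantifySample()` back-transforms **each replicate** through the
curve and averages the copies (not mean-Cq-then-back-transform: the
reported concentration is the mean of the triplicate concentrations;
with 0.15-cycle noise the two differ by well under 1%). Copies per mL
serum scale the per-reaction value by (eluate 50 uL / input 5 uL) /
(serum 1 mL) = x10; group comparisons are scale-invariant so all
ratio-type outputs are unaffected by which scale is used.

`summarizeGroups()` reports per-group mean/median/max/min, the
case-control differences, the mean and median ratios (printed
half-up-rounded to one decimal, full precision retained in
`*_raw` fields), and a one-way ANOVA (df 1, n-2) on **raw** copy
numbers, mirroring the original analysis despite the heavy tails; a
log10-scale ANOVA is available via `logScale = TRUE` and is the
better-calibrated choice for log-normal data.

# Methylation calling

`mergeReadPairs()` merges a pair by the best ungapped overlap (>= 20
nt, mismatch fraction <= 0.1; best = lowest mismatch fraction, ties to
the longer overlap). Disagreements resolve to the higher-Phred base
(quality ties to R1) and the merged quality is the per-base maximum.

`assignToAmplicon()` compares each merged read, in both orientations,
against every **bisulfite-expected** reference: non-CpG C positions
expect T (a residual C counts as an ordinary mismatch, which is what
makes incomplete conversion visible), CpG C positions accept C or T,
all other positions must match. Every ungapped offset with full
containment of the shorter sequence and aligned length >= 40 nt is
scored as mismatches / aligned length; the read goes to the unique
gene with minimal score <= 0.1, and ties between genes leave it
unassigned. The 40 nt floor exists because a very short perfect
overlap would otherwise outscore a full-length alignment. Both the
merge and the assignment are ungapped by design — amplicons are short
and the error model is substitution-only; on real indel-rich data an
aligner-based assignment would be needed, which is a documented
limitation, not a configuration option.

`countCpgSites()` tabulates C (methylated), T (unmethylated) and
other calls per CpG site and sample into a `SiteCountMatrix` (a
`RangedSummarizedExperiment`: rows = CpG sites addressed by gene and
1-based offset of the C, columns = samples, assays `c`, `t`,
`other`). It also tallies C/T at **non-CpG** cytosines: their T
fraction estimates the bisulfite conversion rate per sample. This QC
estimate is reported and asserted in tests but never used to correct
methylation rates.

`filterSites()` drops a site if **any** sample covers it with fewer
than 8 reads (the chi-square stage pools across samples, so a site
must be defined in everyone) or if its pooled rate across all samples
is exactly 0 or 1 (constant methylation carries no between-group
information). The mask is stored; counts are never deleted.
`normalizeLibraries()` computes factor_i = mean(totals) / total_i from
per-sample assigned-read totals, so every normalized total equals the
cohort mean; raw integer counts feed the chi-square stage, the factors
feed reporting only. `geneMethylation()` pools raw counts over a
gene's retained sites (coverage-weighted; the unweighted per-site mean
is available as `type = "mean"` but is noisier at uneven coverage).

# Differential methylation

One pooled 2 x 2 table per gene (group x {C, T}, raw counts summed
over retained sites and within-group samples) is tested with the
plain Pearson chi-square test of homogeneity, df = 1, no continuity
correction (pooled amplicon counts are large), alpha = 0.05 per gene
with no multiplicity correction by default (Benjamini-Hochberg is
available behind `adjust = "BH"`). A per-site 2 x k variant
(`perSite = TRUE`, df = k - 1) is available because the choice between
the two is genuinely open; one p-value per gene matches how the
results are tabulated. Direction is `hypo` when the pooled case rate
is below the pooled control rate.

**Known limitation — overdispersion.** Pooling counts across subjects
treats all reads as exchangeable. With real inter-individual variation
(the generator's beta concentration 60) and deep pooled counts, the
chi-square is anti-conservative: chance differences in group-mean
methylation of a null gene become "significant" at high coverage. The
default synthetic run therefore typically flags more than the four
planted genes. This is a property of the pooled test itself, faithfully
reproduced; the per-sample rate table is exported so users can run
subject-level tests. The package's null-calibration checks suppress
the dispersion (concentration 1e7) so they test the statistic, not
this artifact.

# The INDEX classifier

`buildFeatureTable()` assembles one row per sample: nine gene-level
methylation percentages plus log10 copy number (the copy numbers span
three decades; a raw-scale option exists). Standardization is **not**
baked into the table — features are z-scored inside each fit using
training-fold statistics only, so no test information leaks into the
transform (a unit test plants a test-only outlier to assert this).

`fitElasticNet()` minimizes the average logistic deviance plus
lambda [alpha |beta|_1 + (1-alpha)/2 |beta|_2^2] with an unpenalized
intercept (glmnet's parameterization). `tuneHyperparameters()` selects
(alpha, lambda) by stratified k-fold (k = 5) cross-validation
maximizing mean CV AUC over alpha in {0, 0.1, ..., 1} and, per alpha,
a 50-point log-spaced lambda grid from lambda_max down four decades;
ties prefer the larger lambda, then the larger alpha (the more
parsimonious model).

`repeatedHoldout()` benchmarks five families — CART (`rpart`),
logistic regression (`glm`), an RBF-kernel SVM (`e1071`, default
scale), random forest (500 trees), and the elastic net with inner
tuning — over stratified 70/30 train/test splits (the hold-out ratio
is not dictated by the study; 0.7 is configurable). Per split it
records AUC (rank-based, equal to the trapezoidal area), sensitivity,
specificity and accuracy at probability threshold 0.5 with case as
the positive class (standard definitions). The Youden-optimal
threshold is additionally estimated on each training fold and the
test metrics at that threshold are reported alongside — never as the
headline numbers. This matters in practice: when the planted effects
are strong enough that CV AUC saturates at 1 over a range of lambda,
the parsimony tie-break picks a heavily shrunk model whose
probabilities cluster near the class balance; ranking (AUC) is
unharmed but the fixed 0.5 threshold can classify almost everything
into one class, and the Youden columns make that visible. The default
split count is 5000; validation runs in this package use 200–500
splits, whose means estimate the same quantities.

`averageRoc()` evaluates each split's ROC on a fixed grid of 101 FPR
points (linear interpolation between ROC vertices, so tied scores
contribute sloped segments and a constant classifier averages to the
diagonal) and averages TPR vertically; the area under the averaged
curve is reported next to the mean of per-split AUCs.

`finalizeIndexModel()` refits the elastic net on the full table at
the tuned hyperparameters and stores the INDEX coefficients:

INDEX(x) = intercept + sum_j beta_j x_j,
p = 1 / (1 + exp(-INDEX)), status = case iff p > 0.5 (strict).

Betas are stored both on the standardized scale (with the training
center/scale) and back-transformed to the raw feature scale, since
either convention may be wanted downstream; JSON serialization keeps
full double precision so save/load round-trips predictions exactly.

# Numerical choices and degenerate inputs

* Standard-curve fits need >= 3 distinct concentrations; a
  non-negative fitted slope is flagged and blocks quantification.
* Replicate CV above 0.3 sets a QC flag without rejecting the sample.
* Constant feature columns standardize to zero (scale clamped to 1).
* glmnet is driven along a short decreasing lambda path ending at the
  requested lambda (convergence is unreliable when cold-starting at a
  single small lambda); with a single feature a zero dummy column is
  appended (glmnet requires two) and its coefficient discarded.
* Splits that leave fewer than 2 per class in train or 1 per class in
  test are redrawn and counted; splits are keyed to sorted sample ids,
  so row order never changes a partition.
* A zero chi-square margin marks a gene not-testable rather than
  erroring; genes with no retained sites are skipped with a record.

# Problem sizes used in the package's own checks

The test-suite and the acceptance script use the study's group sizes
(38/40) with 300 read pairs per amplicon and 200 hold-out splits for
the end-to-end runs; methylation-recovery checks use 1000 pairs per
amplicon over 20 seeds; the chi-square null uses 2000 simulated
tables; classifier calibration uses 500 splits at n = 200–400. These
sizes keep every estimate's Monte-Carlo error well inside the asserted
tolerances.

# What passing tests do and do not show

The generator plants gene-level methylation with beta dispersion,
substitution-only errors, uniform coverage and perfect sample labels.
Passing tests therefore demonstrate that the algorithms recover what
was planted under that model — they do not certify performance on real
serum data, where fragment-length effects, strand biases, indels,
incomplete conversion heterogeneity, batch effects and label noise all
exist. In particular the near-perfect synthetic AUC reflects the
planted effect sizes, not an expected clinical operating point.
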