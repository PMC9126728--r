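---
title: "Methods: nine-constitution discrimination from serum metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nine-constitution discrimination from serum metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcmforest)
```

# The problem

TCM constitution theory assigns each person one of nine types: the balanced
*Pinghe* type and eight biased types (*Qixu*, *Yangxu*, *Yinxu*, *Tanshi*,
*Shire*, *Qiyu*, *Xueyu*, *Tebing*). The conventional instrument is a
standardized questionnaire; the scientific question this package serves is
whether the serum metabolome — measured as an untargeted LC-MS feature table
of m/z × retention-time features — carries enough constitution-specific
signal to discriminate all nine types objectively.

The pipeline has four stages: (1) questionnaire scale scoring, used to
assemble single-type cohorts; (2) feature-table quality control against
pooled QC injections; (3) extraction of a per-type "unique m/z signature"
by one-vs-reference differential screening and set decomposition; (4) a
nine-class random-forest classifier on the pooled signatures, evaluated by
stratified 10-fold cross-validation.

# Questionnaire scoring

Each subscale (one per constitution) has items scored on five grades, 1–5.
For a subscale with $n$ items and original score $s=\sum_i x_i$,

$$\text{conversion} = \frac{s - n}{4n} \times 100 \in [0, 100].$$

Determination thresholds are taken literally from the standard: Pinghe "yes"
requires Pinghe $\ge 60$ with all biased subscales $< 30$ ("probably yes"
relaxes to $< 40$); a biased type is "yes" at $\ge 40$ and "probably yes" in
$[30, 40)$, both contingent on Pinghe $\ge 60$. Boundary conventions are
inclusive $\ge$ on the upper thresholds and strict $<$ below 30, and
$[30, 40)$ half-open, so the score 40 is "yes", 39.9 is "probably yes".

Two situations the standard leaves open are resolved as follows. When two
or more biased subscales reach "yes" the subject has a *mixed* constitution;
the package reports `final_type = "mixed"` rather than forcing a label,
because single-type cohort designs exclude such subjects. When the Pinghe
subscale falls below 60 no rule in the standard applies; every verdict is
"no" and the final type is `"undetermined"`.

The real item bank is not distributed with the package; subscale item counts
are configurable (default eight items per subscale), and the synthetic
questionnaire generator draws item scores so the target subscale's
conversion lands safely inside its "yes" region (target $\ge 45$, Pinghe
$\ge 65$, all others $\le 25$), keeping the generated determinations
unambiguous under the rules above.

# Quality control

**Instrument stability.** All pairwise Pearson correlations between the
pooled-QC replicate columns are computed across features, on the raw
intensity scale (the convention for near-identical replicate injections,
whose correlation is dominated by the features' dynamic range; a log10
option exists). Features with any absent QC value are excluded. The run
passes when the minimum off-diagonal $r^2$ exceeds 0.99.

**CV filter.** Per feature, CV = sample (n−1) SD / mean over the QC columns,
on raw intensities — the metabolomics QC convention; whether to compute it
on a transformed scale is genuinely open, and raw scale is the default
deliberately. Features with CV strictly above the threshold (default 0.30)
are removed; a CV of exactly 0.30 is retained. Degenerate features (QC mean
0, or fewer than two present QC values) have undefined CV and are removed
and logged. The filter is idempotent and never touches subject intensities
of retained features.

# Signature extraction

Each biased type $i$ is compared with the Pinghe reference feature-by-
feature using a two-sided Welch t-test on $\log_{10}(x+1)$, excluding
absent observations; a feature enters the differential set $D_i$ iff
$p < \alpha$ with $\alpha = 0.05$, uncorrected. The choices here — test
statistic, log scale, no multiplicity correction — are deliberate: the Welch
form avoids an equal-variance assumption between constitution groups,
logging symmetrizes multiplicative intensity noise, and the uncorrected
screen at 0.05 yields differential sets in the hundreds out of thousands of
features, the regime this design targets. A Mann–Whitney alternative is
available (`test = "wilcoxon"`), and $\alpha$ is a parameter.

The decomposition is one-vs-rest-union: for each type,
$C_i = D_i \cap \bigcup_{j \neq i} D_j$ (the "common" part) and
$U_i = D_i \setminus C_i$ (the "unique" signature), so
$|U_i| + |C_i| = |D_i|$ always, the $U_i$ are pairwise disjoint, and a
type may legitimately end up with an empty signature. The union
$\bigcup_i U_i$ is the modeling feature space; all nine classes' samples,
including the reference, are retained for modeling. An entirely empty
pooled signature stops the pipeline with advice to raise $\alpha$ or effect
sizes.

## The sensitivity ceiling of unique signatures

A structural property worth knowing: a feature truly differential *only* in
type $i$ is nevertheless removed from $U_i$ whenever any of the seven other
comparisons — null for that feature — fires at $\alpha$. Were the eight
tests independent, a unique feature would survive with probability
$(1-\alpha)^7 = 0.95^7 \approx 0.70$; because all eight comparisons share
the same 49-sample reference group, their false positives are positively
correlated and the survival probability rises to $\approx 0.77$ (measured
by direct simulation at $n = 49$ per group). Unique-signature recovery
sensitivity is therefore capped near 0.77 at $\alpha = 0.05$ regardless of
effect size or feature count — a property of the set-difference definition
itself, not an implementation artifact. False discoveries into $U_i$ are
conversely rare (a null feature must fire for exactly one type), well below
$\alpha \cdot p$ per class. The package's tests assert recovery against
this honest ceiling.

# Imputation

Missing intensities are filled with the per-constitution mean of the
feature's present values, falling back to the feature's grand mean, then 0.
Two scopes exist because the verbatim procedure — fill once from the full
data set before modeling (`global_by_class`) — lets class means computed
from test-fold samples leak into training. The default for cross-validation
is therefore `trainfold_by_class`: training rows are filled with
training-fold class means, and test rows with training-fold *grand* feature
means, since at prediction time a test sample's class is unknown and using
its label would itself leak. The global scope remains selectable to
reproduce the verbatim procedure, and a directional test documents that it
never measures worse than the deferred fill on average.

# The random forest

The classifier is implemented from first principles (C++ core): $n$
bootstrap training sets drawn with replacement (each the size of the
training set), one CART tree per set grown on Gini impurity
$1 - \sum_k p_k^2$, and majority voting. Defaults: 200 trees,
$\lfloor\sqrt{p}\rfloor$ candidate features, unlimited depth, minimum leaf
size 1, no pruning — the conventional classification-forest settings, since
the design specifies only "n training sets" and "m features".

Determinism and tie-breaking are fully specified so training is a pure
function of the seed:

* thresholds are midpoints between consecutive distinct sorted values; the
  left branch takes $x < t$;
* only strictly positive impurity decreases qualify; ties break to the
  lowest feature index, then the lowest threshold;
* leaf votes and forest votes break ties by the fixed class order (Pinghe
  first, then the eight biased types);
* a single RNG stream is consumed in documented order: per tree, bootstrap
  first, then per-node candidate subsets in preorder.

"$m$ features are randomly selected for each training set" is ambiguous
between per-tree and per-node subsampling; per-node (the canonical Breiman
form) is the default, with `feature_sampling = "per_tree"` available. With
`m_features = p` and `bootstrap = FALSE` every tree is the same exhaustive
CART, which the tests exploit by comparing against an independent plain-R
CART implementation.

# Evaluation

Folds are stratified: per-class seeded shuffle, remainders placed on the
least-loaded folds, so per-class counts per fold and overall fold sizes each
differ by at most one — guaranteeing every fold contains positives of every
class, which one-vs-rest accuracy needs. Per-class accuracy is
$(TP+TN)/(P+N)$ against all other classes pooled. Because "overall
accuracy" can mean two things, both are always reported: micro accuracy
(correct/total) and the mean of the nine one-vs-rest accuracies (for any
$K$-class confusion matrix the latter equals
$1 - 2(1-\text{micro})/K \ge \text{micro}$, so the two are interconvertible
but not interchangeable). Per-class accuracy is likewise reported both
pooled over folds and fold-averaged. Signatures are selected on the full
table before cross-validation by default, mirroring the pre-selection
design; `nested = TRUE` re-runs selection inside each training fold to
expose the selection bias.

# The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, at
the study's stated scale: nine classes × 49 subjects, thousands of features
per ion mode, per-feature lognormal baselines (log-mean 11.5, log-sd 1.0 —
intensities spanning ~2 orders of magnitude), multiplicative within-class
noise at CV 0.30 (a typical biological serum CV, and multiplicative so the
QC CV is well-defined and positive), planted class-specific effects of 1
log2 unit applied on the log scale with random sign, completely-at-random
missingness at rate 0.05, and six QC replicates whose per-feature target CVs
span 0.02–0.60 with 10% above the 0.30 cutoff. Feature IDs are synthesized
as `M{mz}T{rt}` with m/z uniform in 50–1000 Da and RT in 0–32 min,
matching the instrument's scan range and gradient. Where the study scale
is not stated (feature counts per mode), defaults are order-of-magnitude
choices — 2000 features, 30 unique features per biased class, 100 shared —
consistent with differential sets in the hundreds.

`study_config()` fixes the matched design used for the headline evaluation:
per-class unique counts of 5/52/11/18/104/0/23/209 (positive mode, in the
order Qixu, Yangxu, Yinxu, Tanshi, Shire, Qiyu, Xueyu, Tebing) and
26/16/32/37/49/2/161/64 (negative), with 800 shared features whose per-class
membership probabilities are set so expected per-class differential totals
land in the hundreds with the same asymmetry — notably a Qiyu class with
*no* unique features in positive mode, which the evaluation shows ranking
at or near the bottom in per-class accuracy, the expected behaviour for the
type with the weakest signature.

What the generator does **not** emulate: raw spectra, adducts, isotopes,
retention-time drift, batch effects, correlated metabolite modules, or
informative missingness (real LC-MS missingness is intensity-dependent;
here it is MCAR because the design states no mechanism). Passing tests
therefore show the pipeline implements its contracts and recovers planted
structure — not that real serum cohorts are this separable. One visible
consequence: with QC CVs planted up to 0.60 the raw-scale QC correlation
sits near $r^2 \approx 0.9$, so the strict $r^2 > 0.99$ stability pass is
exercised on cleaner constructed tables in the tests, while synthetic
cohorts exercise the failure path.

# Numerical and degenerate-input conventions

Zero-variance features yield no t-statistic and are never differential;
classes with fewer than two samples are an input error. A feature absent in
an entire class falls back to the grand mean, then 0. Fold seeds are
derived from the forest seed as $(s + 7919f) \bmod (2^{31}-1)$; mode seeds
in the pipeline as $(s + 1000003\,m) \bmod (2^{31}-1)$. Welch p-values use
the closed-form Satterthwaite degrees of freedom and are cross-checked
against `stats::t.test` in the tests.

# Problem sizes used in tests

Unit tests run on miniature cohorts (9 × 10 subjects, 40–500 features) where
the property under test does not depend on scale; the end-to-end acceptance
checks run the matched study scale (9 × 49, 2000 features, 200 trees,
10-fold CV) — once per ion mode for the headline pattern, ten seeds for the
rank stability of the weakest class, twenty seeds for signature recovery,
and one permuted-label control, totalling a few minutes of compute. The
`scripts/acceptance.R` entry point reruns the study-scale computation from
scratch and writes every headline quantity as JSON.

# Known limitations

* The unique-signature definition caps recovery sensitivity near 0.77 at
  $\alpha = 0.05$ (see above); a corrected or FDR-based screen would change
  the trade-off but is not part of this design.
* Uncorrected screening admits $\approx \alpha \cdot p$ false positives
  into the differential sets; most land in the common parts, a minority in
  the unique signatures.
* Signature pre-selection on the full table before cross-validation is an
  optimistic design; the nested mode quantifies the difference.
* Accuracies measured on synthetic cohorts characterize the pipeline, not
  real populations; mixed constitutions are out of scope by design.
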