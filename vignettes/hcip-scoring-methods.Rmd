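---
title: "Scoring AP-MS interactomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring AP-MS interactomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hippoapms implements the statistical workflow used to map a pathway
interactome (the human Hippo pathway being the motivating system) from
affinity-purification mass spectrometry (AP-MS): tagged bait proteins are
purified together with their interaction partners, proteins are identified
and counted from MS/MS spectra, and the analysis must separate genuine
interactors from the nonspecific background that co-purifies in every
experiment. This vignette explains the models behind each stage, the
tunable parameters, and the design decisions taken where the procedure was
genuinely open.

## Abundance model: NSAF

Spectral counts scale with both protein amount and protein length, so the
package uses the normalized spectral abundance factor. For run $r$ and
protein $j$ with length $L_j$ (amino acids) and spectral count
$\mathrm{SpC}_{r,j}$:

$$\mathrm{NSAF}_{r,j} =
  \frac{\mathrm{SpC}_{r,j}/L_j}{\sum_k \mathrm{SpC}_{r,k}/L_k}.$$

Each run's NSAF row sums to 1 over its detected proteins, making runs of
different depth comparable. `redistribute_shared_counts()` optionally
distributes shared peptide-group counts proportionally to unique evidence
(equal split when none exists); it is off by default because inputs are
assumed to be protein-level tables in which shared-peptide handling has
already happened upstream.

## Contaminant filtering against mock controls

Mock purifications of inert tagged proteins (GFP/RFP-style controls,
reserved bait token `CONTROL:<name>`) capture the nonspecific background.
The control abundance of a protein is the mean of its `control_top_n = 10`
highest NSAF values across all control runs, *padded with zeros* when the
protein appears in fewer than 10 controls. The zero padding is deliberate:
a contaminant seen in 4 of 74 controls at NSAF 0.01 is profiled at 0.004,
so frequent contaminants are penalized more than sporadic ones.

A candidate interaction (bait $i$, prey $j$) has
$\bar{X}_{i,j}$ = mean NSAF over all of bait $i$'s replicates (zeros
included for replicates where the prey is undetected — irreproducible preys
should score lower) and passes the control filter when the enrichment

$$E_{i,j} = \bar{X}_{i,j} / \max(\text{profile}_j, \text{floor}) > 10$$

strictly. Preys never seen in any control have profile 0; the floor —
the smallest non-zero profile value in the control set — keeps $E$ finite
and scale-free without granting absent preys infinite enrichment. Whether
the original analysis used the replicate mean or a per-replicate extreme is
not recoverable; the mean is the default and the statistic is isolated in
one function so the choice is swappable.

## WD scoring and the simulated-matrix threshold

The second filter is a CompPASS-family score combining abundance,
cross-bait frequency and replicate reproducibility. With $k$ bait groups,
$f_j$ the number of baits detecting prey $j$, $n_{i,j}$ the number of bait
$i$'s replicates detecting $j$, and
$\omega_j = \max(1, s_j/m_j)$ (the coefficient of variation of prey $j$'s
non-zero $\bar{X}$ values across baits, floored at 1, and 1 when
$f_j = 1$):

$$\mathrm{WD}_{i,j} = \sqrt{\bar{X}_{i,j}
  \left(\frac{k}{f_j}\,\omega_j\right)^{n_{i,j}}}.$$

A prey seen with few baits ($k/f_j$ large) and in all replicates
($n_{i,j}$ large) is up-weighted; ubiquitous background ($f_j \approx k$)
collapses toward $\sqrt{\bar{X}}$. Flooring $\omega$ at 1 is the
conservative choice — high cross-bait variance never *down*-weights an
interaction; a switch above the floor is deliberately not a default.

The pass threshold comes from a simulated data matrix: in each of
`n_permutations = 100` rounds, every prey's non-zero $(\bar{X}, n)$ entries
are reassigned uniformly at random (without replacement) to bait columns.
This preserves each prey's marginal signature — its frequency $f_j$ and
value multiset, i.e. exactly what makes a contaminant look like a
contaminant — while destroying bait specificity, which is the null the
threshold is meant to capture. All simulated WD scores are pooled and the
threshold is the 95% empirical quantile (`sim_quantile = 0.95`); a single
pooled quantile (not a per-round quantile) is used because all raw scores
are normalized to one value: $\mathrm{WD}^N = \mathrm{WD}/\text{threshold}$,
passing at $\mathrm{WD}^N \ge 1$ (inclusive).

Two numerical consequences are worth knowing. First, WD is a function of
$(\bar{X}, n, f, \omega, k)$ only, all of which are invariant under column
reassignment, so the pooled null equals the observed score distribution and
the filter acts as an empirical top-quantile cut — this is by construction,
and it makes the threshold exactly reproducible. Second, on very small
tables where the top score carries more than $1 - \text{sim\_quantile}$ of
the pooled mass, the quantile ties with the maximum and the top entry gets
$\mathrm{WD}^N = 1$ exactly (still passing, since the bound is inclusive).
$\mathrm{WD}^N$ is invariant under global rescaling of all abundances
(threshold scales as $\sqrt{c}$), and the permutation is seeded
(`rng_seed`) so the whole pipeline is deterministic.

## Profiles, distance, modules and rescue

For module discovery every protein gets a bait-relative profile: within
each run the prey NSAF is divided by the bait NSAF, ratios are averaged
over the bait's replicates (zeros included), giving a proteins x baits
matrix. Distances are uncentered Pearson,

$$d(x, y) = 1 - \frac{\sum_i x_i y_i}
  {\sqrt{\sum_i x_i^2}\sqrt{\sum_i y_i^2}},$$

a cosine-like measure in $[0, 1]$ for non-negative profiles that compares
co-purification *shape* without mean-centering sparse vectors. Modules are
cut from an average-linkage dendrogram (`n_major_clusters = 3` by default,
matching the three-module organization of the motivating interactome;
deeper cuts expose sub-modules). Profiles are sorted lexicographically
before clustering and module labels renumbered by smallest member, so
results are deterministic. Rather than clustering prey and bait axes
separately and transferring bait labels via centroids, the package exploits
the fact that a bait's own profile is a well-defined row (its self-ratio is
1): baits are clustered as ordinary rows of the same matrix, and one
distance matrix covers both axes.

The rescue stage increases sensitivity: a candidate that passes the
enrichment filter but misses the WD$^N$ threshold is rescued when its
profile has uncentered-Pearson similarity $r_u > 0$ (strict; configurable
via `rescue_similarity_min`) with at least one high-confidence interactor
of the same bait. Two readings of "distance greater than zero" are
possible — on the distance scale almost every pair qualifies, so the
package interprets the rule on the similarity scale (a non-zero
co-purification signal with an established partner). Rescue is restricted
to enrichment-passing candidates because the distance matrix in the
original procedure was derived after control filtering, and rescuing
enrichment-failing pairs would re-admit the contaminant background
wholesale. The profile matrix used for rescue covers *all* candidates (a
high-confidence-only matrix would contain no profile for the sub-threshold
prey being tested); module clustering, in contrast, runs on the
high-confidence network only. Rescue only ever adds edges.

## TOP3 quantification

Spectral counts saturate for abundant proteins, so condition comparisons
use precursor-ion intensities: a protein's abundance is the mean of its
three most intense precursor ions (`top3()`), normalized to the bait's
TOP3 in the same run. Proteins with fewer than three recorded precursors
are averaged over what exists and flagged low-evidence rather than dropped —
sparse interactors are often exactly the ones worth quantifying.
For two conditions with replicate relative abundances, the package reports

$$\log_2\mathrm{FC} = \log_2\frac{\bar{B} + \varepsilon}
  {\bar{A} + \varepsilon},$$

with $\varepsilon$ = half the smallest non-zero relative abundance in the
comparison (a shared pseudo-value that keeps absent proteins finite without
dominating detected ones), and a two-sided two-sample t-test on
$\log(\text{value} + \varepsilon)$. Relative abundances are ratio-scale and
right-skewed, hence the log transform; the equal-variance (Student) test is
the default because Welch degrees of freedom are unstable at $n = 3$ per
group — both choices are package decisions, not claims about the original
analysis. Stars follow the conventional bands (`*` p < 0.05, `**`
p < 0.01) with no multiple-testing correction by default, matching
per-protein asterisk reporting; Benjamini-Hochberg is available behind
`p_adjust = "BH"`. Groups that are both constant report p = 1 (equal
means) or p = 0 (different constants) with a degenerate flag.

## The synthetic generator

Real deposited AP-MS data are not desk-scale, so every stage is validated
against a generator with planted ground truth. The default configuration
simulates the study conditions used throughout the tests: 12 baits
partitioned evenly into 3 modules, 2 biological replicates, 300 true preys
(each attached to 1–3 baits of a single module with bait-relative abundance
log-uniform in $[0.01, 1]$), 150 contaminants, 20 mock controls, and an
expected depth of $10^4$ spectral counts per run.

The count model makes NSAF the natural abundance estimator: the expected
count of protein $j$ is $\text{depth} \cdot a_j L_j / \sum_k a_k L_k$ with
$a_j = 1$ for the bait, the planted relative abundance times the condition
factor for true preys, and the background abundance for contaminants;
realized counts are Poisson. Note that NSAF then estimates
$a_j / \sum_k a_k$ — the length factors cancel — which is what the
conservation tests assert. Poisson (not negative binomial) is the default
noise: it is the minimal model consistent with spectral counting, and
overdispersion is an extension point rather than a default. A run in which
the bait itself goes undetected would fail acquisition QC in practice, so
bait detection is conditioned on (minimum one count).

Where the underlying studies state no value, the generator takes one fixed,
realistic choice: protein lengths uniform in 100–1000 amino acids;
contaminant abundances follow a Zipf law with exponent 2 (about 4.4 orders
of magnitude of dynamic range across 150 background proteins, the kind of
skew contaminant repositories show) scaled so the top contaminant is half
as abundant as the bait; precursor intensities are lognormal with median
proportional to $a_j$, coefficient of variation 0.3 (0.1 in the
quantification recovery experiments), and $\max(3, L_j/50)$ precursors per
protein, independent of the count draw except through the shared $a_j$ —
TOP3 and NSAF are distinct estimators and are simulated as such.
Contaminants have identical expected abundance in bait and control runs,
which is precisely the assumption the control-enrichment filter makes.

What the generator does *not* emulate: peptide-level identification and
FDR, shared-peptide ambiguity, interactions between baits, correlated
(batch) contaminant structure, retention-time or chromatography artifacts,
and saturation of spectral counting. Passing recovery tests therefore
demonstrates that the statistics recover a planted signal under the stated
noise model — not that the thresholds are optimal for any particular real
dataset.

## Problem sizes and runtime choices

The recovery experiments run the full pipeline at the default generator
conditions over seeds 1–5 (precision/recall and module ARI), a
three-replicate two-condition design for the planted 4x effect, and
depths $10^2$–$10^4$ for the depth-monotonicity smoke test; each full
scoring run takes a few seconds. Oracle tests use deliberately tiny inputs
(tables up to 4 baits with exhaustive permutation enumeration, 3-profile
dendrograms, 5x8 NSAF fixtures) so that brute-force recomputation is
exact.

## Known limitations

* The WD functional form is one member of the CompPASS family; all of its
  ingredients are exposed in the stats table so the expression is
  swappable, but no alternative scorers (probabilistic models, external
  contaminant repositories) are bundled.
* The enrichment floor and the rescue similarity bound are data-driven
  conventions; with very few control runs the floor becomes noisy.
* Quantification starts from per-protein precursor intensity lists;
  feature extraction and alignment are upstream of this package.
* The deposited interaction tables of the motivating study are external
  downloads; the loaders accept their shape, but the published network
  counts cannot be recomputed without those files.
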