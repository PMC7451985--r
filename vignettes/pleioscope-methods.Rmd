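---
title: "Partitioning trait correlations to dissect vertical and horizontal pleiotropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning trait correlations to dissect vertical and horizontal pleiotropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pleioscope)
```

## The model

A single-cell trait table is two-level hierarchical data: cells nested in
clonal strains. For any pair of traits measured in the same cells, each
observation decomposes into a between-group deviation score
$b_{ij} = \bar x_j - \bar x$ and a within-group score
$w_{ij} = x_{ij} - \bar x_j$. The package's central quantity is the exact
decomposition

$$ r_{total} \;=\; \eta_{Bx}\eta_{By}\, r_B \;+\; \eta_{Wx}\eta_{Wy}\, r_W,
\qquad \eta_B^2 + \eta_W^2 = 1 \text{ per trait,} $$

where $r_B$ is the correlation of the $b$-scores (equivalently the
size-weighted correlation of strain means — the genetic correlation for
clonal strains), $r_W$ is the pooled within-strain correlation (the
environmental correlation), and $\eta^2$ is the fraction of each trait's sum
of squares at each level. The identity is algebraic, holds to machine
precision on every input, and is asserted in the test suite at $10^{-10}$.

The biological reading: a pair with high $r_W$ is inherently coupled —
nongenetic cell-to-cell variation moves both traits together — so a locus
affecting both is *vertical* pleiotropy. A pair whose $r_B$ significantly
exceeds its $r_W$ is coupled *by* genetic variation — *horizontal*
pleiotropy.

### Testing $r_B > r_W$

Both correlations are Fisher-transformed and compared one-tailed:

$$ z = \frac{\operatorname{atanh}(r_B^\ast) - \operatorname{atanh}(|r_W|)}
{\sqrt{1/(n_B-3) + 1/(n_W-3)}}, $$

with $r_B^\ast$ the sign-adjusted value ($|r_B|$, negated when $r_B$ and
$r_W$ disagree in sign — magnitudes are what matter for arbitrary pairs, and
an opposite-sign genetic correlation should not count as an excess). The
effective sample sizes are $n_B = J$ strains and $n_W = N - J$: the degrees
of freedom carried by the between- and within-deviation scores. This
convention is not arbitrary: at $\alpha = 0.01$ Bonferroni-corrected over
the full morphological panel of 5,645 pairs it yields the critical z of
4.63 (`critical_z(0.01, 5645)` = 4.6365); a two-tailed convention would give
4.78 instead. The choice is exposed (`alpha`, `m`) rather than hard-coded.

A caveat inherited from the design: $r_B$ is a correlation of strain means
and so mildly biased relative to a full bivariate mixed model; with hundreds
of cells per strain the bias is conservative (it shrinks $|r_B|$, never
inflating the excess). The pseudo-strain permutation null — cells reassigned
to groups of exactly the original sizes, within cell type — verifies that
the mean/single-cell asymmetry alone produces no significant excesses
(`pseudo_strain_null()`; the suite requires at most 1 of 190 pairs flagged,
and typically observes 0).

### Nonlinear dependence

`ace_max_correlation()` estimates the maximal correlation
$\sup_{\theta,\phi}\mathrm{corr}(\theta(Y), \phi(X))$ by alternating
conditional expectations, with conditional means estimated by a
deterministic equal-count binned smoother (50 bins, linear interpolation,
clamped ends). Two sharp external checks anchor it: for bivariate Gaussians
the maximal correlation equals $|\rho|$ (Gebelein), recovered at
$0.50 \pm 0.02$ for $\rho = 0.5$ at $n = 5\times10^4$; and $y = x^2$ with
symmetric $x$ has Pearson $r \approx 0$ but maximal correlation $\to 1$.
The binned smoother slightly biases the estimate upward at small $n$
(fewer than ~20 observations per bin); bin count adapts to keep at least 10
per bin.

## QTL mapping

Strain-mean phenotypes are scanned by Haley-Knott regression: at each marker
and 2-cM pseudomarker the expected genotype given the flanking markers is
computed under the Haldane map function, for fully homozygous
(doubled-haploid) recombinants coded $-1/+1$ — a coding that makes a QTL's
$\beta$ the half-difference of allele means. For a single regressor
$LOD = -(n/2)\log_{10}(1-R^2)$, so the scan is invariant to affine trait
rescaling and matches the closed form to $10^{-10}$ at observed markers.

Significance is per-trait empirical: the $(1-\alpha)$ quantile of
genome-wide maximum LOD over phenotype permutations, with the plus-one rule
$p = (\#\{null \ge obs\} + 1)/(n_{perm}+1)$. Across traits, per-chromosome
maximum-LOD p-values receive Benjamini–Hochberg q-values — deliberately more
conservative than a Storey-type $\pi_0$ estimate; with null-dominated
p-value sets the two differ little, and BH needs no density estimation.
Genome-wide type-I calibration is tested by simulation: with 200 null traits
and 1,000 permutations each, the detection fraction must sit inside the 95%
binomial interval around $\alpha = 0.05$.

Peaks are clustered into loci by single-linkage chaining at 5 cM: peaks more
than 5 cM apart start new loci, and dense runs with no gap over 2 cM are
never broken (the chaining rule subsumes this: any run with gaps $\le 2$ is
a fortiori chained at 5). The interplay of the 5- and 2-cM rules in
ambiguous configurations is genuinely underdetermined; chaining is our
documented reading, and a warning flags any cluster spanning more than
17 cM, the widest locus the approach is expected to produce. A simplified
conditional second scan (refit with the chromosome peak as covariate,
declare a second additive locus if a conditional peak $\ge 5$ cM away clears
the single-scan threshold) replaces an exhaustive two-dimensional search;
it is off by default (`second_scan = FALSE`).

A practical note on scale: peak localization error grows as panels shrink.
At 100 strains a LOD-12 peak wanders several cM, so a locus detected through
only two traits can fragment under the 5-cM rule; loci affecting three or
more traits chain robustly. The validation architecture therefore gives
vertical loci trait triples — which also matches the empirical regime, where
detected loci affect a median of ~5 traits.

## The synthetic-data generator

Every downstream stage is validated against simulations with known truth.
A cell's trait vector is

$$ y = \text{baseline} + \text{QTL mean shifts} + \text{strain effect}
 + \text{plate effect} + f(\text{pseudotime}) + \text{correlated cell noise}. $$

* **Genotypes**: per chromosome a Markov chain over markers with Haldane
  recombination fractions; independent chromosomes; allele frequency 1/2.
* **Three QTL mechanisms**: *vertical* effects act through a declared latent
  factor (loadings $\lambda$) that both fluctuates per cell — creating
  $r_W = \lambda_i\lambda_j$ — and is shifted by the allele; *direct
  horizontal* effects shift trait means only; *correlation-modifying*
  alleles set the within-strain correlation of a target pair to $\rho_0$ or
  $\rho_0+\delta$ via a Gaussian copula over per-context correlation
  matrices, changing the dependence without touching marginals. With
  `strain_coupling = TRUE` the same per-allele correlation applies to the
  strain random effects, the generative analog of an allele that makes
  genetic variation hitting one trait propagate to the other.
* **Cell cycle**: pseudotime is Uniform(0,1) per cell (asynchronous
  exponential-phase sampling); trajectories are deterministic bounded
  shapes — a monotone cubic $((2u-1)^3 + (2u-1))/2$, whose slope never
  vanishes so the trait-space curve cannot fold back on itself, and a
  single Gaussian bump ($\sigma = 0.15$). With the default amplitude 1 and
  unit cell noise, trajectories plus noise dominate strain variance
  (default 0.08), keeping broad-sense heritability near 6–12%, i.e. below
  the ~15% ceiling of the morphological regime the generator emulates.
* **Plate effects**: additive per (replicate × trait), SD 0.1 by default —
  the target of the mid-parent plate correction.
* **Seeding**: one substream per module derived from the master seed via
  `substream_seed()` (a Lehmer-style mix mod $2^{31}-1$); identical seeds
  give bit-identical outputs, and in the dose simulator drug and control
  tables share a seed so that a zero shift reproduces the control exactly.

What the generator does **not** emulate: image-level noise and segmentation
miscalls (only their 5-SD footprint), non-Gaussian trait marginals beyond
what Box-Cox can induce, epistasis, diploid heterozygotes, and branching
cell-fate structure. Passing tests therefore demonstrate the statistical
machinery, not robustness to every pathology of real images.

The defaults are the study conditions the package models: 374 strains,
225 markers on 16 chromosomes (~4,076 cM), 3 replicates, ~800 cells per
strain, 167 traits split 28/47/92 across unbudded/small/large cells (hence
378 + 1,081 + 4,186 = 5,645 pairs). Because the real within-strain
covariance magnitudes are not published, generator defaults reproduce the
qualitative regime (heritability, dilution of $r_W$ by the cell cycle), not
measured values. Validation runs use scaled panels — typically 100 strains ×
500 cells, 1,000 permutations — chosen so the full suite completes in a few
minutes while keeping every effect many standard errors from its decision
threshold.

## Cell-cycle conditioning

Asynchronously dividing cells mix cell-cycle stages, which can dilute a real
within-strain correlation (both traits track progression differently) and so
fabricate an apparent $r_B$–$r_W$ discrepancy. `infer_pseudotime()` orders
cells with a single-branch diffusion map: standardized traits, kNN graph
(k = 30, doubled on disconnection), adaptive Gaussian kernel, and the
leading nontrivial eigenvector of the symmetrized random-walk operator by
deterministic power iteration (fixed start vector, deflation of the trivial
eigenvector, orientation set by the anchor cell, ranks rescaled to [0,1]).
Branch detection is deliberately out of scope — only the position along the
division trajectory is used downstream. On low-noise synthetic trajectories
the Spearman correlation with truth exceeds 0.99; with pure noise the output
is still a valid ranking, with no ordering contract.

Cells are then split per strain into 16 equal-count pseudotime bins (8 bins
give very similar results) and like bins pooled across strains, so genotype
representation is constant per bin; strains with fewer cells than bins are
dropped for that cell type rather than padded. Partitioning each bin yields
a per-bin $r_W$ series, and for pairs with a discrepancy the score

$$ \text{percent resolved} = 100\cdot\max\!\left(0,
 \frac{\max_b r_{W,b} - r_W}{r_B - r_W}\right) \ \text{(capped at 100)} $$

on the sign-adjusted magnitude scale. Note the max over 16 bins rides on
per-bin sampling noise: with ~500 cells per bin the score has a noise floor
of roughly 15–25% even for pairs whose discrepancy is entirely genetic, so
"near zero" in the discrimination property is asserted as $\le 35\%$, while
genuine mixing pairs score well above 50%.

## Allele splits and the two horizontal modes

For each pleiotropic locus, strains are split by allele at the cluster's
most-represented marker (ties to the smaller position) and partitioning is
repeated per subset. The sign-adjusted drop
$\Delta r_B = |r_B(\text{all})| - r_B(\text{subset})$ distinguishes the two
ways a locus can create horizontal pleiotropy: a drop in **both** subsets
means the segregating locus itself couples the traits; a drop in exactly
**one** means one allele strengthens the coupling. "Drop" needs a threshold:
the default noise band is the 95th percentile of $|\Delta r_B|$ over random
strain bisections of matching sizes — halving a panel moves $r_B$ by
sampling noise alone, and the band guards against calling that noise a mode.
A raw-sign convention (band 0) is available, since the underlying reports
used raw sign patterns. Mean-shifting loci leave $r_W$ essentially untouched
under the split (median $|\Delta r_W|$ below 0.02 in the suite), the
expected signature since $r_W$ conditions on strain.

In the validation architecture the correlation-modifying loci also carry a
modest mean shift (0.25 per allele) — deliberately: a locus with no mean
effect is invisible to the scan, and the empirical mode-2 loci were by
construction mapped loci. The mean effect must stay modest, or its own
variance contribution inflates $r_B(\text{all})$ above the strong-coupling
subset and the locus drifts toward the both-drop mode.

## Context dependence

For mutation-accumulation panels, Pearson correlations are computed per line
and pair, and each (line, pair) gets a leave-one-out deviation score
(mean/SD over the *other* lines — the focal line would otherwise inflate its
own reference SD; an inclusive variant is a flag). Scores beyond 4 SD flag
correlation-altering mutations; scoring is done per pair across lines
(matching the per-pair histograms this mirrors) rather than per line across
pairs, and on raw $r$ rather than Fisher z, since the reports it emulates
plot $r$ units — the z variant is a flag. With two or more altered lines in
one panel the leave-one-out reference absorbs the other outlier (classic
masking), which is why the power property injects a single altered line.
At 1,000 cells/line a $0.1 \to 0.9$ shift is flagged with probability
$> 0.95$ (observed ~1.0).

For dose series, $\Delta r_W = r_W(\text{drug}) - r_W(\text{control})$ per
pair and dose, against a replicate-vs-replicate null built from
control-vs-control contrasts. The generator's paired-seed construction makes
"no effect" exactly zero, and recovered median $|\Delta r_W|$ is ordered in
dose whenever the configured shifts are.

## Numerical and interface decisions

* **Box-Cox λ**: grid $[-2, 2]$ step 0.1; normality scored by the
  probability-plot correlation coefficient of strain-model residuals
  (deterministic and O(n log n)); Shapiro–Wilk behind a flag (subsampled at
  fixed seed above n = 4,000, where the statistic is undefined). Ties break
  toward λ = 1; nonpositive traits shift by $-\min + 10^{-6}\cdot$range,
  recorded. The exact normality statistic behind "most normal" in the
  source methods is unstated; PPCC is our documented choice.
* **Pipeline order** is fixed — missingness, Box-Cox, plate correction,
  outlier filter — with outlier z-scores computed on transformed, corrected
  data; rerunning on its own output with the filters disabled is the
  identity.
* **Heritability** uses the one-way method of moments with the unbalanced
  $n_0$ correction and clips $\hat\sigma^2_B$ at zero.
* **wcc**: the underlying reports do not print their weighted-clustering
  formula; we use the complete-weighted-graph form
  $wcc_i = \sum_{j\ne k}\hat w_{ij}\hat w_{jk}\hat w_{ki} /
  ((\sum_j \hat w_{ij})^2 - \sum_j \hat w_{ij}^2)$ with $\hat w = w/\max w$,
  which is exact against brute-force triangle enumeration and equals 1 for
  equal weights; all numeric network claims are property-based for this
  reason. Edge weights are $|r_W|$ (edge thickness in the figures this
  mirrors carries no sign). Permutations shuffle the off-diagonal weight
  multiset onto random pairs.
* **Interfaces**: all tables are TSV with headers (UTF-8, `.` decimal, NA);
  simulation truth serializes to JSON at 17 significant digits, which
  round-trips doubles exactly. The package is driven from R — the exported
  functions, `run_pipeline()` (with md5 manifests for reproducibility
  checks), and `make_fixture()` are the interface; no shell wrapper is
  shipped.
* **Mapping phenotype** is the strain mean over retained cells (whether the
  original analysis used strain means or per-replicate values is not
  documented; means are the default, and the replicate-level alternative is
  a straightforward aggregation the user can supply).

## Known limitations

$r_B$ from strain means understates genetic correlations at few cells per
strain. The 5-cM clustering fragments weakly localized two-trait loci on
small panels. ACE's binned smoother is biased upward at small n. The
percent-resolved score has a max-statistic noise floor. Pseudotime assumes a
single non-branching trajectory, and the MA outlier scan masks co-occurring
outliers. All are discussed above where they arise.
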