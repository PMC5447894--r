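---
title: "trichoseq: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{trichoseq: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical choices a maintainer would want written
down. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The activity model

The scientific question is binary per gene and sample type: is the gene
transcriptionally engaged in this cell population at all? A fixed CPM or
raw-count cutoff answers it badly, because capture depends on library
depth, gene length and GC content, and because replicate noise near any
cutoff makes calls unstable. The package instead fits a hierarchical
negative-binomial model and makes the call from a posterior probability.

For gene $g$, sample $i$ of type $s(i)$:

$$y_{gi} \sim \mathrm{NB}(\mu_{gi}, \phi_g), \qquad
\log \mu_{gi} = \beta_{g,s(i)} + u_{gi} + o_{gi},$$

with $\mathrm{Var}(y) = \mu + \phi\mu^2$. The offset $o_{gi}$ is known at
fit time: $\log(\text{library size} \times \text{TMM factor})$ plus a
centered per-gene smooth in log length and GC (section 3). The hierarchy:

* $\beta_{g\cdot} \sim N(m, \mathrm{diag}(v))$ — unknown mean and diagonal
  variance, one entry per sample type;
* replicate random-effect precision $\lambda_g \sim \Gamma(a, b)$, with
  $u_{gi} \mid \lambda_g \sim N(0, 1/\lambda_g)$, one effect per biological
  replicate *nested within* sample type (see section 6);
* $\log \phi_g \sim N(m_\phi, v_\phi)$.

**Empirical Bayes.** Hyperparameters are initialized by method of moments
(offset-adjusted log mean counts for $m, v$; a variance/mean-ratio
dispersion estimate pooled across types for $m_\phi, v_\phi$) and refined
by coordinate ascent: alternate (i) per-gene joint posterior modes under
the current hyperpriors, fitted by damped Newton sweeps fully vectorized
across genes, and (ii) hyperparameter updates from the Laplace posterior
summaries — an EM on the Laplace-approximated marginal likelihood. The
E-step sums of squares include the conditional posterior variances of the
random effects and of $\log\phi_g$; dropping them makes the precision
estimate diverge (the classic EM degeneracy in which shrunken modes imply
ever-smaller variance). At most 50 rounds, stopping when the largest
hyperparameter change falls below tolerance; a `converged` flag reports
whichever happened. Slow drift of the gamma shape past 50 rounds is
possible and harmless: the fixed-effect prior (which drives the calls)
stabilizes within a few rounds.

**Posterior and call.** Per gene, the mode of
$(\beta_{g\cdot}, u_{g\cdot}, \log\phi_g)$ is found with the same sweeps;
$\lambda_g$ is set to its conditional gamma mode. The reported SD of
$\beta_{gs}$ is the profile (Schur-complement) curvature — the fixed-effect
row of the inverse Hessian over $(\beta_s, u_{i \in s})$, with dispersion
and precision held at their modes. Then
$P_{gs}(T) = 1 - \Phi\!\big((T - \hat\beta_{gs})/\widehat{\mathrm{sd}}\big)$,
and the gene is *active* in $s$ iff $P_{gs}(T) > 0.5$ — strictly; a tie is
inactive. Genes whose Newton sweeps have not met tolerance at the iteration
cap are flagged `failed` and reported inactive rather than returned as NaN.

**Threshold $T$** (`threshold_T`, natural-log scale of the linear
predictor). Default `NULL` resolves at fit time to the fixed-effect value
at which the expected count equals 1 CPM in the median-depth sample,
computed as `log(1e-6 * median(colSums(counts))) - median(colMeans(offsets))`.
The second term makes the rule invariant to the offset convention (raw log
library sizes, or the centered offsets the simulator emits). 1 CPM is the
field's conventional floor for "expressed"; the value is exposed because it
is a scientific choice, not a statistical one.

**Approximation quality.** The acceptance suite compares the Laplace
$P_{gs}(T)$ with a brute-force 2-D grid integration over
$(\beta_s, \log\phi)$ (random effects at mode) on large-count genes and
requires agreement within 0.02. Two caveats are worth recording. The
profile SD includes replicate-random-effect uncertainty that a fixed-$u$
grid lacks, so for very high-count genes evaluated at thresholds placed
artificially near the posterior mode the two constructions can disagree by
more than that; and the grid integrates dispersion uncertainty that
profiling ignores, with the opposite sign. Near the actual decision
boundary — where counts are around 1 CPM, both corrections are small, and
call stability is what matters — the approximations agree closely.

## 2. Normalization

* **TMM** (`tmm_factors`): the established weighted trimmed-mean-of-M-values
  definition — genes zero in either sample excluded; 30% of M-values and 5%
  of A-values trimmed from each tail; weights = inverse asymptotic binomial
  variances; reference sample = the one whose 75th-percentile CPM is
  closest to the mean of those percentiles; factors rescaled to geometric
  mean 1. The suite checks it against a brute-force oracle (1e-9) and
  against `edgeR::calcNormFactors` (1e-6). One subtlety: M- and A-values
  are exactly scale-free, but the precision weights are not, so scaling one
  column by a constant moves the factors at the third decimal; the tests
  assert exact invariance for M/A and 1% invariance for the factors.
* **log-CPM** (`logcpm`):
  $\log_2\!\big((y + c)/(L f + 2c) \times 10^6\big)$ with prior count
  $c = 0.5$ — strictly increasing in the count and bounded away from
  $-\infty$ at zero.
* **Length/GC smooth** (`length_gc_offsets`): an additive model of mean
  log-CPM on z-scores of log length and GC fraction, each component a
  local-linear loess (degree 1, span 0.5, exact "direct" surface so that
  the result is invariant to gene order), combined by two rounds of
  backfitting, centered to mean zero across genes. Genes favoured by
  capture get a positive offset, which the activity model absorbs so fixed
  effects are comparable across genes. The smooth is per-gene and shared
  across samples; sample-specific GC effects are out of scope.

## 3. Differential expression

Only genes active in at least one sample type **and** with median log2-CPM
strictly greater than `median_threshold = 3.71` enter testing. The bound is
interpreted on the log2-CPM scale produced by `logcpm` (the natural scale
for a median-expression filter) and is exposed as a parameter. The decision
bounds follow the printed conventions exactly: FDR inclusive
(`q <= 0.01` is significant), fold change strict (`|log2FC| = 1` does not
pass the filtered tally), median strict (exactly 3.71 is excluded),
activity strict (`p_active = 0.5` is inactive).

`voom_transform` computes log2-CPM, fits an unweighted first-pass linear
model (treatment + replicate block), smooths
$\sqrt{\text{residual SD}}$ against mean log2 count with lowess
(span 0.5), and assigns each observation the weight
$\text{trend}^{-4}$ evaluated at its fitted log2 count — linear
interpolation inside the trend's range, constant extrapolation outside.
`fit_models` runs per-gene weighted least squares (QR), reporting the
treatment coefficient (first sample type minus the second), its unscaled
SE, $s_g^2$ and the residual df. `moderate` estimates $(d_0, s_0^2)$ by
digamma/trigamma moment matching of $\log s_g^2$ (Newton inversion of the
trigamma function), shrinks
$\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$, and refers
$t = \hat\beta /(\mathrm{SE}_u \tilde s)$ to a t distribution on $d_0 + d$
df. If every $s_g^2$ is identical the $d_0 = \infty$ branch is taken and
flagged. The forced limits $d_0 \to 0$ (ordinary t) and $d_0 \to \infty$
(full shrinkage) are part of the acceptance suite, as is a cross-check of
weights, $d_0$, $s_0^2$ and moderated t against `limma::voom`/`eBayes`.

"Average Fc" is reported per direction as the arithmetic mean of
$2^{|\log_2 \mathrm{FC}|}$ over that direction's significant genes; genes
active in only one tissue have very large fold changes and dominate this
mean, which is a property of the definition, not a bug.

## 4. Enrichment

`sea` tests each term with at least `min_term_size = 5` background genes:
one-sided hypergeometric upper tail $P(X \ge k)$ on the 2×2 table of
foreground/background × in-term/not, BH across tested terms, odds ratio
with a 0.5 continuity correction only when a cell is zero. Terms with no
background genes after intersection are dropped, not reported. The
annotation is taken as flat term→gene sets: no ontology-graph propagation,
no parent–child algorithms — the implementable core of a singular
enrichment analysis. Depletion is out of scope. The p-value kernel
(`hyper_enrich_p`) is verified against exhaustive pmf summation for every
table with $N \le 200$ at 1e-12.

## 5. The synthetic generator: what a green test establishes

`simulate_counts` inverts the activity model: NB counts with per-gene
log-normal dispersion, per-sample replicate random effects, a log-linear
length/GC capture bias, and per-sample library sizes. Stated-world
defaults, chosen once:

| parameter | default | rationale |
|---|---|---|
| `n_replicates` | 4 | the experimental design being emulated |
| `lib_size_range` | 0.8–1.2 M | desk-scale surrogate for tens of millions of reads; the real depth distribution is not published |
| `disp_meanlog`, `disp_sdlog` | log(0.1), 0.4 | typical bulk RNA-seq biological-replicate dispersion around 0.1 with moderate spread |
| `replicate_sd` | 0.1 | ~10% multiplicative replicate noise beyond NB |
| `baseline_mean`, `baseline_sd` | 4.0, 1.5 | log expected counts at the reference scale; calibrated so the composition sum at the 5000-gene default is near 1 M, making `leak_mean` counts literal |
| `leak_mean` | 0.1 | inactive genes leak a small positive mean — the activity model must separate low counts from zero-ish counts, not zeros from non-zeros |
| `bias_strength` | (0.4, 0.25) | visible but not dominant length/GC bias |
| `frac_inactive`, `frac_de`, `lfc_magnitude` | 0.1, 0.1, 2 | a minority of tissue-exclusive genes; DE sign symmetric ± |

Per-sample relative abundances are renormalized so the expected column sum
equals the drawn library size exactly; the generator emits the implied true
offset matrix (length/GC bias plus log library-over-composition), the
expected-count matrix, and a full truth table. Fixed effects are therefore
recoverable on their own scale when the true offsets are supplied, which is
how the hyperprior-recovery acceptance test is constructed; the end-to-end
activity test instead uses estimated offsets, whose scale differs by the
log composition total — immaterial because the automatic threshold is
defined relative to the same offsets.

Randomness is a single seed driving per-gene hashed substreams, so
enlarging `n_genes` leaves earlier genes' features, truth and counts
bit-identical.

What the generator does **not** emulate: multimodal expression
distributions, correlated genes, isoforms, sample-specific GC effects,
batch structure, or count sharing across genes from multimapping. A green
test therefore establishes that the machinery is correct *under the model's
own assumptions* — parameter recovery, decision-rule calibration, FDR
control — not that those assumptions hold for any particular tissue.

`simulate_go_annotation` builds a flat toy annotation; designated enriched
terms are a supplied gene subset padded with ~20% random background genes.

## 6. Decisions where the design was genuinely open

* **Replicate random effects** are nested within sample type (one effect
  per sample), not shared across types. The samples being contrasted are
  physically different fractions of the same material, so replicate-level
  perturbations need not be common to both; nesting is also the more
  conservative choice for the activity posterior. The paired `replicate`
  column is still used as a block in the DE linear model, which costs
  little when the pairing carries no signal and helps when it does.
* **The length/GC smooth is additive**, not a joint 2-D surface: with only
  a few thousand genes per fit, an additive backfit is stabler and is
  enough to absorb a log-linear generative bias (verified in the tests by
  correlation of the fitted offset with log length under a known planted
  bias).
* **DE effects split symmetrically** (±half the log fold change per type)
  so baselines keep their interpretation as tissue-shared expression.
* **qPCR**: multi-reference normalization uses the geometric mean of
  reference quantities, and quantities are efficiency-corrected as
  $(1+E)^{-C_q}$; with $E = 1$ this reduces to the classic
  $2^{-\Delta C_q}$.
* **MDS/clustering construction**: Euclidean distance over the 500
  most-variable genes, classical (Torgerson) MDS with a deterministic sign
  convention, average linkage by default — standard QC-view choices,
  exposed as parameters since the originals are not specified.

## 7. Numerical safeguards

Newton steps are capped (±3 on means and random effects, ±1 on log
dispersion) and `log phi` is clamped to [−8, 4]; the linear predictor is
bounded before exponentiation; NB log-likelihoods go through `dnbinom` for
numerical robustness while score and curvature use the analytic forms.
Gamma-prior updates invert `log(shape) − digamma(shape)` by Newton from a
standard closed-form start. The mean–variance trend uses `lowess` with
constant extrapolation so extreme fitted counts cannot produce infinite
weights; any residual non-finite weight is floored to the smallest positive
one. All pipelines are deterministic given their inputs.

## 8. Known limitations

* The activity posterior is a Laplace approximation; its agreement with
  grid integration is verified at large counts (0.02), and the profile
  treatment of dispersion slightly narrows high-count posteriors (section
  1). No full MCMC is attempted.
* The EM for the dispersion prior uses posterior modes; mode-based
  summaries of a skewed dispersion posterior can bias the prior mean
  somewhat low without affecting the activity decision rule, which is
  dominated by the fixed-effect posterior.
* The hyperprior fit's `converged` flag can be FALSE on stiff datasets
  because the gamma shape drifts slowly; fixed-effect hyperparameters are
  insensitive to this.
* Two sample types only in the DE stage; multi-factor designs, duplicate
  correlation and thresholded (TREAT-style) tests are out of scope.
* Enrichment ignores the GO graph; terms are whatever flat sets the
  annotation provides.
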