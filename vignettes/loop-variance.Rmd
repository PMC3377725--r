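---
title: "Three-level variance decomposition in loop-design two-color microarrays"
author: "loopvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-level variance decomposition in loop-design two-color microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopvar)
```

## The problem

When a clinical expression study declares a gene "variable between
individuals", the claim depends entirely on what noise level it was tested
against. Variation in such data has (at least) three nested sources:

* **technical** — repeated hybridizations of the same RNA pool;
* **anatomic** — different sections of the same tissue specimen, which
  differ in cellular composition;
* **individual** — different donors.

A test calibrated only against technical replication underestimates the
null variance whenever anatomic heterogeneity exists, so it admits genes
whose apparent inter-individual variation is really within-specimen noise.
`loopvar` quantifies all three levels from a single interwoven loop of
dual-color arrays and measures what the choice of null does to gene
selection and to downstream functional enrichment.

## The design

The reference design (`fig1_design()`) has 12 hybridization units: nine
individuals (samples 1–9), three sections of individual 8 (8-1, 8-2, 8-3),
and two technical replicates of section 8-3 (8-3_1, 8-3_2) hybridized from
one RNA pool. The sample hierarchy declares composite expression values:
8-3 is the mean of its two replicates, and individual 8 the mean of its
three sections. Group G1 (individuals 1–9, with 8 as a composite) carries
individual variance, G2 (the three sections) anatomic variance, G3 (the two
replicates) technical variance.

The arrow set of the reference design is a package choice: a *doubly*
interwoven loop — a stride-1 and a
stride-2 directed cycle over the circularly ordered units — giving 24
arrays, in- and out-degree 2 for every unit (dye-balanced), and residual
degrees of freedom 24 − 12 = 12 per fully observed gene, enough to estimate
the per-gene residual SD. Any design expressible as units + directed arrays
can be supplied instead via `loop_design()` / `read_loop_design()`.

```{r design}
fx <- fig1_design()
validate_design(fx$design)
```

## The per-gene model

An array `tail -> head` measures, for each gene, the normalized log ratio

$$M_a = \gamma + \lambda_{\mathrm{tail}(a)} - \lambda_{\mathrm{head}(a)}
      + \varepsilon_a, \qquad \varepsilon_a \sim N(0, \sigma^2),$$

with the identifiability constraint $\sum_i \lambda_i = 0$ over the units
appearing in the gene's observed arrays. Here $\gamma$ is the gene-specific
dye effect (one per clone across the whole loop, not per array), $\lambda_i$
the log2 expression of unit $i$ relative to the unit mean, and $\sigma$ the
gene's residual SD. The dye convention is fixed once: the tail sample is
labeled in the numerator channel, so $M = \log_2(\text{num}/\text{den})$.

`fit_gene()` / `loop_fit()` solve this by least squares. Numerically the
constraint is imposed by a drop-one reparameterization (the last unit's
$\lambda$ is minus the sum of the others) followed by back-transformation,
so the reported $\lambda$ sum to zero exactly; the solve is a QR
factorization shared by all genes with the same missingness pattern, which
makes the gene-by-gene fit effectively a handful of matrix solves.
A gene is **singular** when the constrained design matrix on its observed
arrays is rank-deficient — the observed subgraph is disconnected, or
acyclic so that $\gamma$ is confounded with the $\lambda$ differences. Such
genes get only the flag; nothing is imputed. $\hat\sigma = \sqrt{RSS/df}$
with $df = n_{obs} - \mathrm{rank}$, reported only when $df \ge 1$.

Two gauge subtleties worth stating explicitly:

* $\lambda$ is identified only up to an additive constant; the fit fixes it
  by the unit-level sum-to-zero constraint, while the synthetic generator
  centres true $\lambda$ over the nine individual-level samples. Recovery
  comparisons therefore re-centre truth to the fit's gauge; every
  downstream quantity (series, D, AFC) is a pairwise difference and does
  not depend on the gauge at all.
* LOWESS normalization removes the array-wide intensity trend, which
  includes the *mean* dye effect over genes; after normalization $\gamma$
  is identified as the gene's dye effect relative to that array-wide trend.

## Normalization

`lowess_normalize()` computes per spot $M = \log_2(f_{num}/f_{den})$ and
$A = (\log_2 f_{num} + \log_2 f_{den})/2$ and subtracts a robust locally
weighted regression $\hat m(A)$ (Cleveland's LOWESS: tricube weights,
default span 0.3, 3 robustifying iterations — the community defaults for
MA-plot normalization).
Flagged spots are excluded from both fit and output. The fit is global per
array; print-tip-wise normalization is a possible extension, not
implemented, as no print-tip structure is modelled. Local regression has
edge bias, so validation checks bias removal on the interior 10–90%
intensity range. `aggregate_replicates()` then reduces replicate spots to
one value per gene per array (default: median of at least `min_valid = 2`
valid spots; fewer yields a missing value, which simply drops that array
from the gene's fit).

## Variance series and the D statistic

With composite values resolved (`composite_lambda()`), `build_series()`
pools $\lambda_i - \lambda_j$ over all ordered pairs of a group's samples
over all genes: S1 (G1, individual), S2 (G2, anatomic), S3 (G3, technical).
Ordered pairs make each series symmetric about zero by construction; their
SDs are the empirical scale of each variance level, and with
$\sigma_{tech} < \sigma_{ana} < \sigma_{ind}$ the distributions narrow
progressively from S1 to S3.

Per-gene variation across the experiment is summarized by

$$D = \frac{1}{n} \sum_{a=1}^{n}
      \left(\lambda_{\mathrm{tail}(a)} - \lambda_{\mathrm{head}(a)}\right)^2$$

over the design's $n$ arrows. Among the aggregation forms that summarize
pairwise variation, the mean of squared differences is used because it is
scale-stable in $n$ and reads as a variance;
a mean-of-absolute-differences variant is available via
`d_statistic(..., method = "mean_abs")` for sensitivity analysis. The
arrow set defaults to every array of the design, with
`arrow_scope = "inter_individual"` restricting to arrows whose endpoints
belong to different individuals.

The null distribution of D under a chosen variance level resamples $n$
values from that level's series with replacement — the bootstrap-style
choice for drawing from a pooled exchangeable series; the draw
count B defaults to $10^5$ and scales to $10^7$ if wanted. P-values are
empirical with add-one correction, $p = (1 + \#\{D_b \ge D\})/(B+1)$, or
via the upper tail of a Gaussian-kernel smoothed density (Silverman
bandwidth, recorded on the object) which extends resolution beyond the
largest draw; the empirical form is the default because it is
distribution-free and never anti-conservative.

```{r pipeline}
cfg <- sim_config(n_genes = 300, seed = 7)
truth <- simulate_truth(cfg, fx$design, fx$hierarchy)
spots <- simulate_spots(truth, fx$design, cfg)
fit <- loop_fit(normalize_arrays(spots), fx$design)
comp <- composite_lambda(fit, fx$hierarchy)
sapply(list(S1 = fx$design$groups$G1, S2 = fx$design$groups$G2,
            S3 = fx$design$groups$G3),
       function(g) sd(build_series(comp, g)$values))
```

## Selection and enrichment

`select_genes()` crosses two criteria: Benjamini–Hochberg FDR control at
5% on Pa (anatomic null) or Pt (technical null) — BH being the standard
step-up procedure for FDR control — and an averaged
fold change cutoff, $AFC = 2^{\mathrm{mean}_{i<j} |\lambda_i - \lambda_j|}$
over the nine individuals, at cutoffs 1.2–1.5. Because the technical null
is narrower than the anatomic one, $P_t \le P_a$ in distribution and the
technical criterion never selects fewer genes; the gap closes as the AFC
cutoff rises, which is precisely the variance-underestimation effect the
analysis is built to expose.

Functional coherence is compared with a local enrichment: the one-sided
Fisher exact (hypergeometric tail) p-value and its conservative EASE
variant, which recomputes the tail after removing one list hit from the
term (`max(k-1, 0)`). Terms are retained at EASE < 0.1 with at least 2
list genes; the significance score is $-\log_{10}$ of the EASE score (the
log base is a package choice, recorded here). No multiple-testing
correction is applied across terms — the retention rule filters on the raw
EASE score. The background defaults to all annotated genes and should in
practice be the non-singular fitted genes. `common_terms()` intersects the
retained terms of several criteria into a terms-by-criteria score matrix.

## What the generator emulates — and what it does not

`sim_config()` defaults define the reference conditions:

| parameter | default | meaning |
|---|---|---|
| `sigma_ind` | 0.3 | SD of per-individual effects (log2) |
| `sigma_ana` | 0.1 | SD of per-section effects |
| `sigma_tech` | 0.05 | SD of per-replicate effects |
| `sigma_resid` | 0.1 | array-level residual SD of M |
| `gamma_mean`, `gamma_sd` | 0.4, 0.2 | per-gene dye effect |
| `n_spot_reps` | 4 | replicate spots per gene (quadruplicate printing) |
| `sigma_spot` | 0.1 | spot-level measurement SD |
| `dye_bias_coeffs` | (0, 0, 0.01) | intensity-dependent bias $0.01A^2$ |
| `flag_prob` | 0.02 | invalid-spot probability |

Effects are additive on the log2 scale and nested — individual, plus a
section perturbation, plus a replicate perturbation — the minimal
generative structure that realizes all three S-series. The variance-level
SDs reflect the typical situation where individual variation dominates
anatomic, which dominates technical, at magnitudes typical for bulk tissue
expression; the dye-effect scale, spot noise, and flag rate are realistic
round numbers for spotted cDNA arrays. Intensity A is uniform per spot on 6–16, a plausible log2
scanner range.

The generator deliberately omits: spatial/print-tip artifacts, background
pixels, gene–gene correlation, array-specific residual scales (one
`sigma_resid` throughout), and intensity-dependent *variance*. Tests
passing on these simulations therefore validate the estimators and the
statistical machinery under the stated model — they do not certify
robustness to the spatial and correlation structure of real slides.

## Numerical choices and problem sizes

* Constraint handling: drop-one reparameterization + back-transform;
  singularity = QR rank deficiency of the constrained design.
* Empirical p floored at $1/(B+1)$; density p likewise, with the KDE tail
  computed in closed form as a mean of normal tails.
* Permutation draws, seeds and bandwidths are stored on the result
  objects; identical seeds reproduce identical draws.
* Validation runs at desk scale, chosen to keep the full suite within a
  few minutes while leaving sampling error far below the asserted margins:
  exact recovery and least-squares-oracle checks at 500–1000 genes /
  instances, bias and $\hat\sigma^2$ calibration at 2000 genes, the
  S-series ordering over 100 generator seeds at 1000 genes,
  null-uniformity and FDR checks at B = $10^4$ with 1000–2000 genes and
  200 replicates, and the exhaustive hypergeometric sweep to N = 60.

## Known limitations

* Plain least squares per gene: no empirical-Bayes variance moderation, by
  design — the analysis profiles raw variance levels.
* The technical and anatomic series come from a single individual
  (sections) and a single section (replicates); their SDs are estimated
  from few samples and inherit that uncertainty.
* LOWESS edge bias is not corrected; quantities near the intensity
  extremes are less reliable.
* D's null treats draws as exchangeable across genes (pooled series); no
  gene-stratified resampling.
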