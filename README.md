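# loopvar

Variance decomposition for loop-design two-color microarray studies.

Clinical expression studies face three nested sources of variation:
**technical** (repeated hybridizations of one RNA pool), **anatomic**
(different sections of one tissue specimen), and **individual** (different
donors). Which of these a significance test uses as its null matters: testing
against technical variance alone underestimates the noise whenever anatomic
variation exists, letting unstable genes into the "significant" list and
diluting downstream functional conclusions. `loopvar` implements the full
analysis for quantifying and comparing these variance levels from an
interwoven loop of dual-color arrays, and ships a spot-level synthetic
generator so every stage can be checked against known ground truth.

## The model

Each array co-hybridizes two samples (tail → head of an arrow in the loop).
After LOWESS normalization, the per-gene log ratio of array *a* is modelled
as

    M_a = γ + λ_tail(a) − λ_head(a) + ε_a,   ε_a ~ N(0, σ²),  Σ_i λ_i = 0

where γ is the gene's dye effect (relative labeling efficiency), λ_i the
log2 expression of sample *i* relative to the mean over samples, and σ the
gene's residual SD. γ, λ, σ are estimated gene-by-gene by constrained least
squares across the whole loop; genes whose observed arrays leave the system
rank-deficient are flagged *singular*.

From the fitted λ (with composite samples resolved as means of their
children — a section from its technical replicates, an individual from its
sections) the package builds three pooled series of pairwise differences
λ_i − λ_j: **S1** across individuals, **S2** across sections of one
individual, **S3** across technical replicates. Per-gene variation is
summarized by

    D = (1/n) Σ_arrows (λ_i − λ_j)²

and tested against a permutation null obtained by resampling *n* values
from S2 (anatomic null → Pa) or S3 (technical null → Pt). Genes are selected
at FDR 5% (Benjamini–Hochberg) combined with an averaged-fold-change cutoff
AFC = 2^(mean |λ_i − λ_j|) over individuals, and the biological coherence of
competing selections is compared with a local Fisher-exact / EASE-score
enrichment on a user-supplied annotation.

## Worked example

```r
library(loopvar)

fx  <- fig1_design()                     # 12-unit interwoven loop + hierarchy
cfg <- sim_config(n_genes = 500, seed = 42)
truth      <- simulate_truth(cfg, fx$design, fx$hierarchy)
spots      <- simulate_spots(truth, fx$design, cfg)
normalized <- normalize_arrays(spots)    # LOWESS + replicate aggregation
fit        <- loop_fit(normalized, fx$design)
fit
#> Loop-design log-linear fit
#>   genes: 500 (500 estimable without singularity)
#>   arrays: 24  units: 12

comp <- composite_lambda(fit, fx$hierarchy)
s2 <- build_series(comp, fx$design$groups$G2, "anatomic")
s3 <- build_series(comp, fx$design$groups$G3, "technical")

null_ana  <- permutation_null(s2, n = fx$design$n_arrows, B = 2e4, seed = 43)
null_tech <- permutation_null(s3, n = fx$design$n_arrows, B = 2e4, seed = 44)
dstats <- d_stat_table(fit, fx$design, fx$hierarchy, null_ana, null_tech)
select_genes(dstats)
#> Inter-individual variable gene selection (FDR 0.05 )
#>  anatomic:1.2  anatomic:1.3  anatomic:1.4  anatomic:1.5 technical:1.2
#>           411           175            36             2           411
#> technical:1.3 technical:1.4 technical:1.5
#>           175            36             2
```

The three series spreads from this run are SD(S1) = 0.434, SD(S2) = 0.167,
SD(S3) = 0.097 — the expected progressive narrowing from individual to
anatomic to technical variance (the generator's defaults put the true SDs
at 0.3, 0.1 and 0.05, plus measurement noise). Raising the AFC cutoff from
1.2 to 1.5 shrinks the selection from 411 genes to 2 and removes any gap
between the technical- and anatomic-null selections.

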