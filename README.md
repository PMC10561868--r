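# funspi

Spatial entropy curves, sparse functional PCA and survival modelling for
multitype cell imaging data.

Single-cell multiplex imaging (mIHC, MIBI, CODEX, IMC, ...) yields, per
subject, a point pattern of cells with phenotype labels. Classic diversity
indices (Shannon, Simpson) summarise the *composition* of such a pattern
but are blind to *where* the cells sit: any spatial rearrangement leaves
them unchanged. `funspi` quantifies the part of cell-type heterogeneity
that is attributable to spatial organisation, tracks it across distance
scales, and tests whether it predicts survival. It is aimed at
biostatisticians and imaging groups analysing tumor-microenvironment
cohorts.

## The method

Let `Y` be a cell's type (J types) and `Z` the unordered type pair of a
pair of cells, with `R = J(J+1)/2` categories. Distance ranges
`w_k = (d_{k-1}, d_k]`, `k = 1..K` (`K ≤ 50`), partition inter-cell
distances from 0 to the median inter-cell distance `d_K`, with breaks
equally spaced on a log scale. Writing `p(z_r)`, `p(w_k)`, `p(z_r | w_k)`
for the pair-category and range distributions, the co-occurrence entropy
decomposes exactly as

```
H(Z) = SPI(Z) + H^W(Z)

SPI_k  = Σ_r p(z_r|w_k) log[ p(z_r|w_k) / p(z_r) ]   (spatial information)
H_k^W  = Σ_r p(z_r|w_k) log[ 1 / p(z_r|w_k) ]        (residual entropy)
SPI(Z) = Σ_k p(w_k) SPI_k ,  H^W(Z) = Σ_k p(w_k) H_k^W
```

`SPI_k` is the Kullback–Leibler divergence of the local pair mix at range
`w_k` from the global mix — zero under complete spatial randomness,
positive when cells organise (e.g. same-type clusters at short range).
Per-subject curves `{SPI_ik}` are irregularly observed (subject-specific
ranges, undefined values at empty ranges), so they are summarised by
sparse functional PCA: local-linear smoothing of the pooled mean and
covariance, eigendecomposition `G(s,t) = Σ_l λ_l φ_l(s) φ_l(t)`, and
conditional-expectation (PACE) scores

```
ξ̂_il = λ̂_l φ̂_il' Σ̂_i^{-1} (SPI_i − μ̂_i),   Σ̂_i = Ĝ(S_ij, S_il) + σ̂² δ_jl .
```

The leading scores (smallest L with ≥ 92% variance explained) enter a Cox
model `log h_i(t) = log h_0(t) + U_i'γ + ξ_i'β` together with clinical
covariates, and a likelihood-ratio test of `H0: β = 0` (χ² with L degrees
of freedom) asks whether spatial heterogeneity carries survival
information beyond the clinical covariates.

A simulation module generates clustered versus completely random
multitype patterns, noise-perturbed SPI curves, proportional-hazards
survival times linked to the scores, and a three-model NRMSE benchmark
(clinical + spatial, spatial only, clinical only).

## Worked example

```r
library(funspi)

# two subjects: one clustered, one completely random
p1 <- simulate_pattern("clustered", J = 5, n_per_type = 600, seed = 1,
                       subject_id = "subj1")
p2 <- simulate_pattern("random", J = 5, n_per_type = 600, seed = 2,
                       subject_id = "subj2")
spi_curve(p1, K = 50)
#> <spi_curve> 50 distance ranges, R = 15 pair categories
#>   H(Z) = 2.64  SPI(Z) = 0.1207  H^W(Z) = 2.519
spi_curve(p2, K = 50)
#> <spi_curve> 50 distance ranges, R = 15 pair categories
#>   H(Z) = 2.664  SPI(Z) = 0.0001695  H^W(Z) = 2.664
```

Both subjects have identical type composition (maximum aspatial diversity,
`H(Y) = log 5`), but the clustered subject moves ~0.12 nats of
co-occurrence entropy into the spatial component — its short-range SPI
values are far above zero — while the random subject's SPI is ~0.0002
nats, numerically the "approximately zero at all ranges" signature of
complete spatial randomness.

A full cohort analysis chains the stages:

```r
patterns <- read_cell_table("cells.csv")        # x, y, cell_type, subject_id
tab <- spi_curves_table(patterns, K = 50)
fp <- fit_fpca(curves_to_sample(tab$curves), fve = 0.92)
rec <- assemble_records(read.csv("clinical.csv"),
                        fp$scores[, seq_len(fp$L)], covariates = "age")
lrt_spatial_effect(rec, clinical_covariates = "age")
#> <spatial_lrt> LRT of all score coefficients jointly zero
#>   statistic = ...  df = L  p = ...
```

or, from a shell, `Rscript inst/cli/funspi.R run --config config.yaml`.

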